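# Permutation null for annotation-keyword enrichment.
#
# Observed keyword enrichments in a gene set (e.g. the genes inside
# top-ranked ancestry windows) are compared against a null built by
# repeatedly drawing random gene sets of the same size from the gene
# universe and recording, per permutation, which keywords occur at all
# (binary occurrence, not gene-count weighting).  Keywords never seen in
# the permutations are the strongest signal; add-one empirical p-values
# avoid reporting zero from a finite number of permutations.

#' Build a permutation null of keyword occurrence
#'
#' @param universe Character vector of gene identifiers to sample from.
#' @param set_size Genes drawn per permutation (without replacement); must
#'   not exceed the universe size.
#' @param keyword_map Data frame with columns `gene`, `keyword` (one row
#'   per gene-keyword pair).
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed.
#' @param weighted If `TRUE`, count the number of sampled genes carrying
#'   the keyword instead of binary occurrence.
#' @return Named integer vector: per keyword, the number of permutations in
#'   which it occurred (or total gene count if `weighted`), with attributes
#'   `n_perm` and `set_size`.
#' @export
permutation_keyword_null <- function(universe, set_size, keyword_map,
                                     n_perm = 100L, seed = 1L,
                                     weighted = FALSE) {
  stopifnot(is.data.frame(keyword_map),
            all(c("gene", "keyword") %in% names(keyword_map)))
  universe <- unique(as.character(universe))
  if (set_size > length(universe)) {
    stop("set_size exceeds the gene universe")
  }
  km <- keyword_map[keyword_map$gene %in% universe, ]
  gene_idx <- split(match(km$gene, universe), km$keyword)
  counts <- stats::setNames(integer(length(gene_idx)), names(gene_idx))
  set.seed(seed)
  in_set <- logical(length(universe))
  for (i in seq_len(n_perm)) {
    pick <- sample.int(length(universe), set_size)
    in_set[] <- FALSE
    in_set[pick] <- TRUE
    hit <- vapply(gene_idx,
                  if (weighted) function(ix) sum(in_set[ix])
                  else function(ix) as.integer(any(in_set[ix])),
                  integer(1))
    counts <- counts + hit
  }
  structure(counts, n_perm = as.integer(n_perm),
            set_size = as.integer(set_size))
}

#' Flag observed keywords absent from the permutation null
#'
#' @param observed Character vector of keywords enriched in the real gene
#'   set.
#' @param null_counts Result of [permutation_keyword_null()].  Observed
#'   keywords missing from it have null count 0.
#' @param n_perm Number of permutations (taken from `null_counts` when
#'   available).
#' @return Data frame with `keyword`, `null_count`, `p` (add-one empirical
#'   p-value `(count + 1) / (n_perm + 1)`), `never_observed`.
#' @export
never_observed_keywords <- function(observed, null_counts, n_perm = NULL) {
  if (is.null(n_perm)) n_perm <- attr(null_counts, "n_perm")
  if (is.null(n_perm)) stop("n_perm not supplied and not found on null_counts")
  cnt <- null_counts[observed]
  cnt[is.na(cnt)] <- 0L
  out <- data.frame(keyword = observed, null_count = as.integer(cnt),
                    p = (as.integer(cnt) + 1) / (n_perm + 1),
                    never_observed = as.integer(cnt) == 0L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$null_count, out$keyword), ]
}

#' Extract genes overlapping a set of windows
#'
#' Utility joining window selections (e.g. from [select_top_windows()]) to
#' a gene coordinate table, for feeding [permutation_keyword_null()].
#'
#' @param windows Data frame with `chrom`, `start`, `end`.
#' @param genes Data frame with `gene`, `chrom`, `start`, `end`.
#' @return Character vector of unique gene ids overlapping any window.
#' @export
genes_in_windows <- function(windows, genes) {
  stopifnot(all(c("chrom", "start", "end") %in% names(windows)),
            all(c("gene", "chrom", "start", "end") %in% names(genes)))
  hits <- character(0)
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, ]
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) == 0 || nrow(w) == 0) next
    ov <- outer(g$start, w$end, "<=") & outer(g$end, w$start, ">=")
    hits <- c(hits, g$gene[rowSums(ov) > 0])
  }
  unique(hits)
}
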