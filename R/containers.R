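# Core data containers.
#
# Two light S3 containers are used throughout: a `freq_table` is a data frame
# of biallelic SNPs with a per-site alternate-allele frequency for one
# reference population; a `genotype_matrix` bundles a site table, animal ids
# and a site x animal matrix of diploid calls coded 0 (hom-ref), 1 (het),
# 2 (hom-alt) and NA (missing).  Coordinates are 1-based inclusive, the VCF
# convention, and sites are kept sorted by (chrom, pos).

site_order <- function(chrom, pos) order(as.character(chrom), pos)

#' Construct a reference allele-frequency table
#'
#' @param chrom Chromosome names (character or coercible).
#' @param pos 1-based positions.
#' @param ref,alt Single-base reference / alternate alleles.
#' @param af Alternate-allele frequency in `[0, 1]`.
#'
#' @return A data frame of class `freq_table`, sorted by (chrom, pos), with
#'   columns `chrom`, `pos`, `ref`, `alt`, `af`.
#' @export
freq_table <- function(chrom, pos, ref, alt, af) {
  pos <- as.integer(pos)
  chrom <- rep_len(as.character(chrom), length(pos))
  ref <- rep_len(as.character(ref), length(pos))
  alt <- rep_len(as.character(alt), length(pos))
  stopifnot(length(pos) == length(af))
  if (any(af < 0 | af > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  ft <- data.frame(chrom = chrom, pos = pos, ref = as.character(ref),
                   alt = as.character(alt), af = as.numeric(af),
                   stringsAsFactors = FALSE)
  ft <- ft[site_order(ft$chrom, ft$pos), , drop = FALSE]
  if (anyDuplicated(ft[c("chrom", "pos", "ref", "alt")])) {
    stop("duplicate (chrom, pos, ref, alt) sites in frequency table")
  }
  rownames(ft) <- NULL
  class(ft) <- c("freq_table", "data.frame")
  ft
}

#' Construct a genotype matrix
#'
#' @param sites Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param animals Character vector of animal identifiers (column order of
#'   `calls`).
#' @param calls Integer matrix, sites x animals, values in `{0, 1, 2, NA}`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sites`, `animals`, `calls`, sites sorted by (chrom, pos).
#' @export
genotype_matrix <- function(sites, animals, calls) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  calls <- as.matrix(calls)
  animals <- as.character(animals)
  if (nrow(calls) != nrow(sites) || ncol(calls) != length(animals)) {
    stop("calls must be a sites x animals matrix")
  }
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  sites <- data.frame(chrom = as.character(sites$chrom),
                      pos = as.integer(sites$pos),
                      ref = as.character(sites$ref),
                      alt = as.character(sites$alt),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(sites)) stop("duplicate sites in genotype matrix")
  o <- site_order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL
  calls <- calls[o, , drop = FALSE]
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(NULL, animals)
  structure(list(sites = sites, animals = animals, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d animals (%d missing calls)\n",
              nrow(x$sites), length(x$animals), sum(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), length(x$animals))

# (chrom, pos, ref, alt) identity key; the cross-population comparison key
# (chrom, pos) is built separately where the looser match is wanted.
site_key <- function(x) {
  s <- extract_sites(x)
  paste(s$chrom, s$pos, s$ref, s$alt, sep = ":")
}

pos_key <- function(x) {
  s <- extract_sites(x)
  paste(s$chrom, s$pos, sep = ":")
}

extract_sites <- function(x) {
  if (inherits(x, "genotype_matrix")) return(x$sites)
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "pos") %in% names(x)))
    if (!all(c("ref", "alt") %in% names(x))) {
      x$ref <- NA_character_
      x$alt <- NA_character_
    }
    return(x)
  }
  stop("cannot extract sites from object of class ", paste(class(x), collapse = "/"))
}

#' Subset a genotype matrix by site index
#'
#' @param g A [genotype_matrix()].
#' @param i Integer or logical index into the site rows.
#' @return The subsetted `genotype_matrix`.
#' @export
subset_sites <- function(g, i) {
  stopifnot(inherits(g, "genotype_matrix"))
  genotype_matrix(g$sites[i, , drop = FALSE], g$animals,
                  g$calls[i, , drop = FALSE])
}
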