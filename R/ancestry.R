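# Per-SNP and per-window ancestry statistics.
#
# The per-SNP statistic treats one individual's genotype call as a
# one-animal "population" (call coded 0 / 0.5 / 1) and measures its
# differentiation from a reference population's alternate-allele frequency:
#
#   Hs = PBT (1 - PBT) + Pbrai (1 - Pbrai)     (within heterozygosity)
#   Ht = 2 pbar (1 - pbar),  pbar = (PBT + Pbrai) / 2
#   bosind = (Ht - Hs) / Ht
#
# which equals (PBT - Pbrai)^2 / (2 Ht): zero when the call matches the
# reference frequency, 1 at a fixed difference.  Sites where Ht = 0 (both
# monomorphic for the same allele) carry no ancestry information and are
# undefined (NA), excluded from window means.  Per-SNP values are averaged
# in fixed, adjacent, non-overlapping windows anchored at position 1; a low
# window average against a reference marks the window as deriving from that
# reference's ancestry.

#' Per-SNP differentiation between a reference frequency and one call
#'
#' @param pbt Reference population alternate-allele frequency in `[0, 1]`
#'   (vectorized).
#' @param pbrai Individual's call coded 0 (hom-ref), 0.5 (het), 1 (hom-alt).
#' @return Numeric vector of per-SNP values in `[0, 1]`; `NA` where the
#'   statistic is undefined (`Ht = 0`).
#' @export
bosind_snp <- function(pbt, pbrai) {
  if (any(pbt < 0 | pbt > 1, na.rm = TRUE)) stop("pbt must lie in [0, 1]")
  if (!all(pbrai %in% c(0, 0.5, 1) | is.na(pbrai))) {
    stop("pbrai must be coded 0, 0.5 or 1")
  }
  hs <- pbt * (1 - pbt) + pbrai * (1 - pbrai)
  pbar <- (pbt + pbrai) / 2
  ht <- 2 * pbar * (1 - pbar)
  out <- (ht - hs) / ht
  out[ht == 0] <- NA_real_
  out
}

#' Average per-SNP values in fixed-size windows
#'
#' @param values Per-SNP statistic values (`NA` = undefined, excluded).
#' @param pos 1-based SNP positions, sorted ascending.
#' @param window Window size in bp (default 250 kb).
#' @param min_snps Minimum defined SNPs for a window to be callable
#'   (default 10).
#' @return Data frame with `win_index` (0-based), `start`, `end`, `mean`
#'   (`NA` when no defined SNPs), `n` (defined SNPs) and `callable`.
#'   Windows containing no SNPs at all are absent.
#' @export
window_average <- function(values, pos, window = 250000L, min_snps = 10L) {
  stopifnot(length(values) == length(pos))
  if (is.unsorted(pos)) stop("positions must be sorted ascending")
  win <- (pos - 1) %/% window
  ok <- !is.na(values)
  n <- rowsum(as.numeric(ok), win)
  s <- rowsum(ifelse(ok, values, 0), win)
  idx <- as.integer(rownames(n))
  m <- ifelse(n[, 1] > 0, s[, 1] / n[, 1], NA_real_)
  data.frame(win_index = idx,
             start = idx * as.numeric(window) + 1,
             end = (idx + 1) * as.numeric(window),
             mean = m, n = as.integer(n[, 1]),
             callable = n[, 1] >= min_snps,
             row.names = NULL)
}

# per-animal window means for one reference; returns long data frame
window_stats_one_ref <- function(g, ref, window, min_snps) {
  j <- join_on_sites(g, ref)
  gj <- j$genotypes
  pbt <- j$freqs$af
  out <- vector("list", length(gj$animals))
  for (a in seq_along(gj$animals)) {
    b <- bosind_snp(pbt, gj$calls[, a] / 2)
    per_chrom <- split(seq_along(b), gj$sites$chrom)
    wa <- do.call(rbind, lapply(names(per_chrom), function(ch) {
      i <- per_chrom[[ch]]
      cbind(chrom = ch,
            window_average(b[i], gj$sites$pos[i], window, min_snps))
    }))
    wa$animal <- gj$animals[a]
    out[[a]] <- wa
  }
  do.call(rbind, out)
}

#' Per-animal per-window ancestry statistics against two references
#'
#' Joins the cohort with each reference panel separately (each join keeps
#' the SNPs shared with that panel), computes per-SNP values for every
#' animal, and averages them within fixed windows.
#'
#' @param g Cohort [genotype_matrix()].  Missing calls are skipped for that
#'   animal.
#' @param ref_tau,ref_ind Taurine / indicine reference [freq_table()]s.
#' @param window Window size in bp (default 250 kb).
#' @param min_snps Minimum defined SNPs per window per side for the window
#'   to be callable (default 10).
#' @return A data frame of class `window_stats` with one row per animal x
#'   window: `animal`, `chrom`, `win_index`, `start`, `end`, `bosind_tau`,
#'   `n_snp_tau`, `bosind_ind`, `n_snp_ind`, `callable` (both sides meet
#'   `min_snps`).
#' @export
compute_window_stats <- function(g, ref_tau, ref_ind, window = 250000L,
                                 min_snps = 10L) {
  stopifnot(inherits(g, "genotype_matrix"))
  wt <- window_stats_one_ref(g, ref_tau, window, min_snps)
  wi <- window_stats_one_ref(g, ref_ind, window, min_snps)
  names(wt)[names(wt) %in% c("mean", "n", "callable")] <-
    c("bosind_tau", "n_snp_tau", "callable_tau")
  names(wi)[names(wi) %in% c("mean", "n", "callable")] <-
    c("bosind_ind", "n_snp_ind", "callable_ind")
  m <- merge(wt, wi[c("animal", "chrom", "win_index", "bosind_ind",
                      "n_snp_ind", "callable_ind")],
             by = c("animal", "chrom", "win_index"), all = TRUE)
  m$callable <- !is.na(m$callable_tau) & m$callable_tau &
    !is.na(m$callable_ind) & m$callable_ind
  m$start <- m$win_index * as.numeric(window) + 1
  m$end <- (m$win_index + 1) * as.numeric(window)
  m <- m[order(m$animal, m$chrom, m$win_index), ]
  rownames(m) <- NULL
  m <- m[c("animal", "chrom", "win_index", "start", "end",
           "bosind_tau", "n_snp_tau", "bosind_ind", "n_snp_ind", "callable")]
  structure(m, window = window, min_snps = min_snps,
            class = c("window_stats", "data.frame"))
}

#' Genome-wide composition summary per animal
#'
#' The global statistic per reference is the mean of the per-SNP values
#' over all defined SNPs (recovered exactly from the window table as the
#' n-weighted mean of window means, not the unweighted mean of windows).
#' The taurine window fraction is the fraction of callable windows whose
#' taurine-side average is below the indicine-side average; exact ties
#' contribute half a window to each side.
#'
#' @param stats A `window_stats` table from [compute_window_stats()].
#' @return Data frame with one row per animal: `animal`,
#'   `global_bosind_tau`, `global_bosind_ind`, `taurine_window_fraction`,
#'   `n_windows_callable`.
#' @export
animal_composition <- function(stats) {
  per_animal <- split(stats, stats$animal)
  out <- lapply(per_animal, function(s) {
    gt <- sum(s$bosind_tau * s$n_snp_tau, na.rm = TRUE) /
      sum(s$n_snp_tau[!is.na(s$bosind_tau)])
    gi <- sum(s$bosind_ind * s$n_snp_ind, na.rm = TRUE) /
      sum(s$n_snp_ind[!is.na(s$bosind_ind)])
    cal <- s[s$callable, ]
    frac <- if (nrow(cal) == 0) NA_real_ else {
      (sum(cal$bosind_tau < cal$bosind_ind) +
         0.5 * sum(cal$bosind_tau == cal$bosind_ind)) / nrow(cal)
    }
    data.frame(animal = s$animal[1], global_bosind_tau = gt,
               global_bosind_ind = gi, taurine_window_fraction = frac,
               n_windows_callable = nrow(cal), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Signed percent difference between the two window averages
#'
#' `pd = 100 (b_ind - b_tau) / ((b_ind + b_tau) / 2)`: positive values mark
#' taurine-like windows (the animal differs more from the indicine
#' reference), negative values indicine-like windows.  Undefined (`NA`)
#' when the window is not callable on both sides or both averages are zero.
#'
#' @param stats A `window_stats` table.
#' @return `stats` with an added `pd` column.
#' @export
window_percent_difference <- function(stats) {
  denom <- (stats$bosind_ind + stats$bosind_tau) / 2
  pd <- 100 * (stats$bosind_ind - stats$bosind_tau) / denom
  pd[!stats$callable | is.na(denom) | denom == 0] <- NA_real_
  stats$pd <- pd
  stats
}

#' Cohort-level per-window percent difference
#'
#' Averages each window's two-sided statistics over the animals for which
#' the window is callable, then forms the signed percent difference of the
#' cohort means.
#'
#' @param stats A `window_stats` table covering multiple animals.
#' @param min_animals Minimum callable animals for the window to be kept
#'   (default 1).
#' @return Data frame with `chrom`, `win_index`, `start`, `end`,
#'   `mean_bosind_tau`, `mean_bosind_ind`, `n_animals`, `pd`.
#' @export
cohort_percent_difference <- function(stats, min_animals = 1L) {
  cal <- stats[stats$callable, ]
  if (nrow(cal) == 0) stop("no callable windows")
  key <- interaction(cal$chrom, cal$win_index, drop = TRUE)
  agg <- do.call(rbind, lapply(split(cal, key), function(s) {
    data.frame(chrom = s$chrom[1], win_index = s$win_index[1],
               start = s$start[1], end = s$end[1],
               mean_bosind_tau = mean(s$bosind_tau),
               mean_bosind_ind = mean(s$bosind_ind),
               n_animals = nrow(s), stringsAsFactors = FALSE)
  }))
  agg <- agg[agg$n_animals >= min_animals, ]
  denom <- (agg$mean_bosind_ind + agg$mean_bosind_tau) / 2
  agg$pd <- ifelse(denom == 0, NA_real_,
                   100 * (agg$mean_bosind_ind - agg$mean_bosind_tau) / denom)
  agg <- agg[order(agg$chrom, agg$win_index), ]
  rownames(agg) <- NULL
  agg
}

#' Select the most extreme windows by percent difference
#'
#' Deterministically selects the `ceiling(fraction * n_callable)` windows
#' most extreme in the requested direction; `"taurine"` takes the largest
#' (most positive) percent differences, `"indicine"` the most negative.
#' Ties are broken by (chrom, win_index), and input order does not affect
#' the result.
#'
#' @param pd Data frame with `chrom`, `win_index` and `pd` columns (e.g.
#'   from [cohort_percent_difference()]); `NA` percent differences are not
#'   callable and are ignored.
#' @param direction `"taurine"` or `"indicine"`.
#' @param fraction Fraction of callable windows to select (default 0.05).
#' @return The selected rows, ordered most extreme first.
#' @export
select_top_windows <- function(pd, direction = c("taurine", "indicine"),
                               fraction = 0.05) {
  direction <- match.arg(direction)
  stopifnot(fraction > 0, fraction <= 1)
  cal <- pd[!is.na(pd$pd), ]
  n_sel <- ceiling(fraction * nrow(cal))
  key <- if (direction == "taurine") -cal$pd else cal$pd
  o <- order(key, as.character(cal$chrom), cal$win_index)
  out <- cal[o[seq_len(min(n_sel, nrow(cal)))], ]
  rownames(out) <- NULL
  out
}

#' Animals x windows percent-difference matrix for one chromosome
#'
#' Builds the matrix rendered as an introgression heatmap: one row per
#' animal (ordered by year of birth, oldest first; animals with missing
#' year are placed last with a message), one column per window, cell values
#' from [window_percent_difference()].
#'
#' @param stats A `window_stats` table.
#' @param chrom Chromosome to extract.
#' @param birth_years Optional named numeric vector, animal id -> year.
#' @return A numeric matrix with animal row names and window-start column
#'   names, with attribute `birth_years` in row order.
#' @export
heatmap_matrix <- function(stats, chrom, birth_years = NULL) {
  s <- window_percent_difference(stats[stats$chrom == chrom, ])
  if (nrow(s) == 0) stop("no windows on chromosome ", chrom)
  animals <- sort(unique(s$animal))
  wins <- sort(unique(s$win_index))
  m <- matrix(NA_real_, length(animals), length(wins),
              dimnames = list(animals, wins * attr(stats, "window") + 1))
  m[cbind(match(s$animal, animals), match(s$win_index, wins))] <- s$pd
  yrs <- rep(NA_real_, length(animals))
  if (!is.null(birth_years)) {
    yrs <- unname(birth_years[animals])
    if (anyNA(yrs)) {
      message(sum(is.na(yrs)), " animal(s) without birth year placed last")
    }
    o <- order(yrs, animals, na.last = TRUE)
    m <- m[o, , drop = FALSE]
    yrs <- yrs[o]
  }
  attr(m, "birth_years") <- yrs
  m
}

#' Render a heatmap matrix
#'
#' Convenience wrapper around \pkg{pheatmap} (if installed; otherwise a
#' base [graphics::image()] fallback) drawing taurine-like windows in red.
#'
#' @param m Matrix from [heatmap_matrix()].
#' @param ... Passed to the underlying plotting function.
#' @return Invisibly, the plotting object.
#' @export
plot_heatmap_matrix <- function(m, ...) {
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    invisible(pheatmap::pheatmap(m, cluster_rows = FALSE,
                                 cluster_cols = FALSE, ...))
  } else {
    graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                    col = grDevices::hcl.colors(64, "Reds", rev = TRUE), ...)
    invisible(NULL)
  }
}
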