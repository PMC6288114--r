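# Windowed read-depth analysis at a candidate locus.
#
# Read depth is aggregated into fixed 50 bp windows over a region,
# standardized to SD-from-mean units within each group's profile, and the
# carrier-vs-reference difference is scanned for runs of elevated windows
# (duplication signature: about two-fold depth for a homozygous
# duplication, 1.5-fold for a heterozygous one).  Deletion evidence comes
# from counting reads that fully span a short target interval: carriers of
# a deletion or sequence replacement show near-zero spanning reads.
#
# Candidate preset: the Celtic polled mutation is a 212 bp duplication
# replacing the 10 bp at chr1:1,706,051-1,706,060; the Friesian polled
# variant is an ~80 kb duplication at chr1:1.91-1.99 Mb.

#' Candidate polled-locus intervals
#'
#' @return Named list of 1-based inclusive intervals on chromosome 1:
#'   `celtic_replaced` (the replaced 10 bp), `celtic_duplication` (212 bp
#'   from its start), `friesian_duplication` (80 kb).
#' @export
polled_locus_presets <- function() {
  list(celtic_replaced = c(1706051, 1706060),
       celtic_duplication = c(1706051, 1706262),
       friesian_duplication = c(1910000, 1990000))
}

#' Aggregate depth into fixed windows
#'
#' @param x Either a per-base depth table (`chrom`, `pos`, `depth`) or a
#'   read-interval table (`start`, `end`), in which case each read is
#'   counted in the window containing its start.
#' @param region Length-2 vector, 1-based inclusive.
#' @param window Window size in bp (default 50).  A partial terminal window
#'   is kept and flagged via the `partial_last` attribute.
#' @param chrom Chromosome label for the output.
#' @param group Optional group label.
#' @return A `depth_profile` data frame (`chrom`, `start`, `end`, `count`).
#'   Empty regions give a zero-row profile.
#' @export
window_depth <- function(x, region, window = 50L, chrom = "1",
                         group = NULL) {
  stopifnot(length(region) == 2, region[1] <= region[2])
  starts <- seq(region[1], region[2], by = window)
  ends <- pmin(starts + window - 1, region[2])
  if (all(c("pos", "depth") %in% names(x))) {
    keep <- x$pos >= region[1] & x$pos <= region[2]
    w <- (x$pos[keep] - region[1]) %/% window + 1
    counts <- rowsum(x$depth[keep], w)
    cnt <- numeric(length(starts))
    cnt[as.integer(rownames(counts))] <- counts[, 1]
  } else if (all(c("start", "end") %in% names(x))) {
    keep <- x$start >= region[1] & x$start <= region[2]
    w <- (x$start[keep] - region[1]) %/% window + 1
    cnt <- tabulate(w, nbins = length(starts))
  } else {
    stop("x must have pos/depth or start/end columns")
  }
  depth_profile(chrom, starts, ends, cnt, window = window, group = group)
}

#' Standardize a depth profile to SD-from-mean units
#'
#' `z = (count - mean) / SD` computed across the windows of the region,
#' within the profile's own group, using the population SD (so the
#' z-scores have mean 0 and SD exactly 1).  A constant profile (SD 0)
#' returns all zeros with a warning.
#'
#' @param p A `depth_profile`.
#' @return Numeric vector of z-scores, one per window.
#' @export
standardize_profile <- function(p) {
  x <- p$count
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) {
    warning("constant depth profile; all z-scores set to 0")
    return(rep(0, length(x)))
  }
  (x - m) / s
}

#' Detect duplication signatures from carrier vs reference profiles
#'
#' Both profiles are standardized within their own group (so differing
#' cohort sequencing depths do not mimic copy-number changes), and maximal
#' runs of at least `min_windows` consecutive windows with carrier z minus
#' reference z at or above `z_threshold` are reported.  The fold change of
#' a run is the ratio of group-mean-normalized depths, which estimates the
#' copy factor (2 for a homozygous single-copy duplication, 1.5 for a
#' heterozygous one).
#'
#' @param carrier,reference `depth_profile`s over identical windows.
#' @param min_windows Minimum run length (default 4, so a >= 200 bp event
#'   is detectable in 50 bp windows while single-window noise is not).
#' @param z_threshold Minimum carrier-minus-reference z difference
#'   (default 2).
#' @return Data frame of class `duplication_calls`: `chrom`, `start`,
#'   `end`, `n_windows`, `fold_change`, `mean_z_diff`; zero rows when
#'   nothing is found.
#' @export
detect_duplication <- function(carrier, reference, min_windows = 4L,
                               z_threshold = 2) {
  stopifnot(nrow(carrier) == nrow(reference),
            all(carrier$start == reference$start))
  d <- standardize_profile(carrier) - standardize_profile(reference)
  above <- d >= z_threshold
  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1
  keep <- r$values & r$lengths >= min_windows
  out <- data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), n_windows = integer(0),
                    fold_change = numeric(0), mean_z_diff = numeric(0),
                    stringsAsFactors = FALSE)
  for (i in which(keep)) {
    idx <- starts_i[i]:ends_i[i]
    fold <- (mean(carrier$count[idx]) / mean(carrier$count)) /
      (mean(reference$count[idx]) / mean(reference$count))
    out <- rbind(out, data.frame(
      chrom = carrier$chrom[1], start = carrier$start[starts_i[i]],
      end = carrier$end[ends_i[i]], n_windows = length(idx),
      fold_change = fold, mean_z_diff = mean(d[idx]),
      stringsAsFactors = FALSE))
  }
  class(out) <- c("duplication_calls", "data.frame")
  out
}

#' Count reads fully spanning a target interval
#'
#' @param reads Read intervals: data frame with `start`, `end` and
#'   optionally `animal` (then counts are reported per animal).
#' @param target Length-2 vector, 1-based inclusive target interval.
#' @return Integer spanning-read count, or a named vector per animal.
#' @export
deletion_read_support <- function(reads, target) {
  stopifnot(length(target) == 2, target[1] <= target[2])
  spans <- reads$start <= target[1] & reads$end >= target[2]
  if ("animal" %in% names(reads)) {
    tapply(spans, reads$animal, sum)
  } else {
    sum(spans)
  }
}
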