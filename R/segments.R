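# Window-origin classification, introgressed-segment calling, and
# segment-length spectra.
#
# A window is assigned to the ancestry whose reference it differs from
# least; maximal runs of identically-labelled windows become segments.
# No-call windows break runs rather than extending them (absence of
# evidence is not continuation), and runs never bridge chromosomes.

#' Classify windows by ancestry origin
#'
#' `"taurine"` when the taurine-side window average is lower, `"indicine"`
#' when higher, `"no_call"` for exact ties or windows not callable on both
#' sides.
#'
#' @param stats A `window_stats` table from [compute_window_stats()].
#' @return `stats` with an added `origin` column.
#' @export
classify_windows <- function(stats) {
  origin <- rep("no_call", nrow(stats))
  ok <- stats$callable & !is.na(stats$bosind_tau) & !is.na(stats$bosind_ind)
  origin[ok & stats$bosind_tau < stats$bosind_ind] <- "taurine"
  origin[ok & stats$bosind_tau > stats$bosind_ind] <- "indicine"
  stats$origin <- origin
  stats
}

#' Call maximal same-origin segments from window labels
#'
#' Accepts either a classified `window_stats` table (with `origin`,
#' `animal`, `chrom`, `win_index` columns) or, for convenience, a plain
#' character vector of labels representing consecutive windows.  Runs break
#' at no-call windows, at gaps in the window index, and at chromosome or
#' animal boundaries.
#'
#' @param x Classified window table from [classify_windows()], or a
#'   character vector of labels in `{"taurine", "indicine", "no_call"}`.
#' @param window Window size in bp (taken from the table attribute when
#'   available; default 250 kb).
#' @return Data frame of class `segment_calls`: `animal`, `chrom`,
#'   `origin`, `start_win`, `end_win`, `n_windows`, `start`, `end`,
#'   `length_bp`.  No-call windows never appear in segments.
#' @export
call_segments <- function(x, window = 250000L) {
  if (is.character(x)) {
    x <- data.frame(animal = "animal", chrom = "1",
                    win_index = seq_along(x) - 1L, origin = x,
                    stringsAsFactors = FALSE)
  } else if (!is.null(attr(x, "window"))) {
    window <- attr(x, "window")
  }
  stopifnot(all(c("animal", "chrom", "win_index", "origin") %in% names(x)))
  x <- x[order(x$animal, x$chrom, x$win_index), ]
  out <- list()
  for (grp in split(x, list(x$animal, x$chrom), drop = TRUE)) {
    # a new run starts at a label change or a window-index gap
    brk <- c(TRUE, grp$origin[-1] != grp$origin[-nrow(grp)] |
               diff(grp$win_index) != 1L)
    run <- cumsum(brk)
    for (r in split(grp, run)) {
      if (r$origin[1] == "no_call") next
      out[[length(out) + 1L]] <- data.frame(
        animal = r$animal[1], chrom = r$chrom[1], origin = r$origin[1],
        start_win = min(r$win_index), end_win = max(r$win_index),
        n_windows = nrow(r), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    seg <- data.frame(animal = character(), chrom = character(),
                      origin = character(), start_win = integer(),
                      end_win = integer(), n_windows = integer(),
                      start = numeric(), end = numeric(),
                      length_bp = numeric(), stringsAsFactors = FALSE)
  } else {
    seg <- do.call(rbind, out)
    seg$start <- seg$start_win * as.numeric(window) + 1
    seg$end <- (seg$end_win + 1) * as.numeric(window)
    seg$length_bp <- seg$end - seg$start + 1
  }
  class(seg) <- c("segment_calls", "data.frame")
  seg
}

#' Segment length-frequency spectrum
#'
#' Histogram of segment lengths in windows, pooled over animals, with
#' normalized fractions.
#'
#' @param segments A `segment_calls` table from [call_segments()].
#' @param origin Which origin to tabulate (`"taurine"` or `"indicine"`).
#' @param label Dataset label stored on the result.
#' @return Data frame `length_windows`, `count`, `fraction` (fractions sum
#'   to 1; zero rows for empty input).
#' @export
length_spectrum <- function(segments, origin = "taurine", label = origin) {
  s <- segments[segments$origin == origin, ]
  if (nrow(s) == 0) {
    sp <- data.frame(length_windows = integer(), count = integer(),
                     fraction = numeric())
  } else {
    tab <- table(s$n_windows)
    sp <- data.frame(length_windows = as.integer(names(tab)),
                     count = as.integer(tab),
                     fraction = as.integer(tab) / sum(tab))
  }
  attr(sp, "label") <- label
  sp
}

#' Compare a real against a simulated segment-length spectrum
#'
#' Tabulates both spectra side by side, reports the maximum observed
#' segment length in each, and the empirical probability under the
#' simulated spectrum of a segment at least as long as the real maximum
#' (the exceedance fraction over simulated segments).  An exceedance of 0
#' is the "no simulated segment as long as the observed one" outcome that
#' argues for selection rather than drift.
#'
#' @param real,simulated Spectra from [length_spectrum()].
#' @return A list of class `spectrum_comparison`: `table` (merged
#'   spectra), `max_real`, `max_simulated`, `exceedance`.
#' @export
compare_spectra <- function(real, simulated) {
  lens <- sort(union(real$length_windows, simulated$length_windows))
  tab <- data.frame(
    length_windows = lens,
    real_count = real$count[match(lens, real$length_windows)],
    real_fraction = real$fraction[match(lens, real$length_windows)],
    sim_count = simulated$count[match(lens, simulated$length_windows)],
    sim_fraction = simulated$fraction[match(lens, simulated$length_windows)])
  tab[is.na(tab)] <- 0
  max_real <- if (nrow(real) == 0) NA_integer_ else max(real$length_windows)
  max_sim <- if (nrow(simulated) == 0) NA_integer_ else max(simulated$length_windows)
  exceed <- if (is.na(max_real) || sum(simulated$count) == 0) NA_real_ else {
    sum(simulated$count[simulated$length_windows >= max_real]) /
      sum(simulated$count)
  }
  structure(list(table = tab, max_real = max_real, max_simulated = max_sim,
                 exceedance = exceed),
            class = "spectrum_comparison")
}

#' @export
print.spectrum_comparison <- function(x, ...) {
  cat("Segment length spectra (lengths in windows)\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("max real: %s   max simulated: %s\n",
              x$max_real, x$max_simulated))
  cat(sprintf("simulated exceedance of real maximum: %s\n",
              format(x$exceedance)))
  invisible(x)
}

#' Export segment calls as BED
#'
#' Writes 0-based half-open intervals (the BED convention; internal
#' coordinates are 1-based inclusive windows).
#'
#' @param segments A `segment_calls` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = format(segments$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(segments$end, scientific = FALSE, trim = TRUE),
                    name = paste(segments$animal, segments$origin, sep = "|"))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
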