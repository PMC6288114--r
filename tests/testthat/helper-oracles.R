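# Independent oracles and small fixture builders used across test files.

# Weir & Cockerham (1984) variance components, coded site-by-site from the
# textbook formulas (r = 2 populations), independently of the vectorized
# implementation under test.
wc_fst_oracle <- function(calls1, calls2) {
  stopifnot(nrow(calls1) == nrow(calls2))
  num <- den <- 0
  per_site <- rep(NA_real_, nrow(calls1))
  for (s in seq_len(nrow(calls1))) {
    g1 <- calls1[s, ][!is.na(calls1[s, ])]
    g2 <- calls2[s, ][!is.na(calls2[s, ])]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    h1 <- mean(g1 == 1);      h2 <- mean(g2 == 1)
    r <- 2
    nbar <- mean(c(n1, n2))
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    if (a + b + cc != 0) {
      per_site[s] <- a / (a + b + cc)
      num <- num + a
      den <- den + a + b + cc
    }
  }
  list(per_site = per_site, mean_fst = num / den)
}

# run-length segment oracle: split the label string at no-calls, then rle
# within each chunk
segment_oracle <- function(labels) {
  chunks <- split(labels, cumsum(labels == "no_call"))
  out <- data.frame(origin = character(), n_windows = integer())
  for (ch in chunks) {
    ch <- ch[ch != "no_call"]
    if (length(ch) == 0) next
    r <- rle(ch)
    out <- rbind(out, data.frame(origin = r$values, n_windows = r$lengths))
  }
  rownames(out) <- NULL
  out
}

# brute-force binning oracle for window averages
window_mean_oracle <- function(values, pos, window) {
  idx <- (pos - 1) %/% window
  sapply(sort(unique(idx)), function(w) {
    v <- values[idx == w]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
}

make_sites <- function(n, chrom = "1") {
  data.frame(chrom = chrom, pos = seq_len(n) * 100L, ref = "A", alt = "C",
             stringsAsFactors = FALSE)
}

make_gm <- function(calls, chrom = "1") {
  calls <- as.matrix(calls)
  genotype_matrix(make_sites(nrow(calls), chrom),
                  sprintf("an%02d", seq_len(ncol(calls))), calls)
}

# diploid samples drawn from a frequency table (binomial genotypes)
sample_genotypes <- function(ft, n_animals, prefix = "s") {
  calls <- matrix(rbinom(nrow(ft) * n_animals, 2, ft$af), nrow(ft), n_animals)
  genotype_matrix(ft[c("chrom", "pos", "ref", "alt")],
                  sprintf("%s%03d", prefix, seq_len(n_animals)), calls)
}
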