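# The per-SNP differentiation statistic, window averaging, composition,
# percent differences and window ranking.

test_that("per-SNP statistic matches hand values and the closed form", {
  expect_equal(bosind_snp(0.5, 0.5), 0)
  expect_equal(bosind_snp(1, 0), 1)
  expect_equal(bosind_snp(0.2, 1), 0.32 / 0.48)

  set.seed(7)
  pbt <- runif(1e5)
  pbrai <- sample(c(0, 0.5, 1), 1e5, TRUE)
  b <- bosind_snp(pbt, pbrai)
  pbar <- (pbt + pbrai) / 2
  ht <- 2 * pbar * (1 - pbar)
  closed <- (pbt - pbrai)^2 / (2 * ht)
  closed[ht == 0] <- NA
  expect_equal(b, closed, tolerance = 1e-12)
  expect_true(all(b >= 0, na.rm = TRUE))
  # symmetry in the two "populations" (checked where both codings are valid)
  pbt2 <- sample(c(0, 0.5, 1), 1e4, TRUE)
  pbrai2 <- sample(c(0, 0.5, 1), 1e4, TRUE)
  expect_equal(bosind_snp(pbt2, pbrai2), bosind_snp(pbrai2, pbt2),
               tolerance = 1e-12)
  # undefined exactly when both are monomorphic for the same allele
  expect_true(all(is.na(b) == (pbt == pbrai & pbrai %in% c(0, 1))))
  expect_error(bosind_snp(1.2, 0), "pbt")
  expect_error(bosind_snp(0.5, 0.3), "pbrai")
})

test_that("window averages equal a brute-force binning oracle", {
  w <- window_average(c(0.1, 0.3), c(10L, 20L), window = 250000L)
  expect_equal(w$mean, 0.2)
  expect_equal(w$win_index, 0L)
  expect_false(w$callable)

  w_na <- window_average(c(NA_real_, NA_real_), c(10L, 20L))
  expect_true(is.na(w_na$mean) && w_na$n == 0)

  set.seed(8)
  pos <- sort(sample.int(1e6, 1000))
  vals <- runif(1000)
  vals[sample(1000, 50)] <- NA
  w4 <- window_average(vals, pos, window = 250000L)
  expect_equal(w4$mean, unname(window_mean_oracle(vals, pos, 250000L)))
  expect_error(window_average(1:2, c(20L, 10L)), "sorted")
})

test_that("window boundaries are anchored at position 1", {
  w <- window_average(c(1, 2, 3), c(250000L, 250001L, 500000L))
  expect_equal(w$win_index, c(0L, 1L))
  expect_equal(w$start, c(1, 250001))
  expect_equal(w$end, c(250000, 500000))
  expect_equal(w$mean, c(1, 2.5))
})

test_that("percent difference uses the symmetric form with taurine-positive sign", {
  st <- data.frame(bosind_tau = c(0.67, 0.4, 0.1), bosind_ind = c(0.11, 0.4, 0.3),
                   callable = TRUE)
  pd <- window_percent_difference(st)$pd
  expect_equal(pd[1], -143.59, tolerance = 1e-3)   # indicine-enriched region
  expect_equal(pd[2], 0)
  expect_equal(pd[3], 100)
  st$callable <- c(TRUE, FALSE, TRUE)
  expect_true(is.na(window_percent_difference(st)$pd[2]))
})

test_that("top-window selection is deterministic and sized by ceiling", {
  set.seed(9)
  pd <- data.frame(chrom = "1", win_index = 0:99, pd = rnorm(100))
  top <- select_top_windows(pd, "taurine", 0.05)
  expect_equal(nrow(top), 5L)
  expect_equal(top$pd, sort(pd$pd, decreasing = TRUE)[1:5])
  bot <- select_top_windows(pd, "indicine", 0.05)
  expect_equal(bot$pd, sort(pd$pd)[1:5])
  shuffled <- pd[sample(100), ]
  expect_identical(select_top_windows(shuffled, "taurine", 0.05), top)
})

test_that("composition and classification recover a synthetic mosaic", {
  fr <- draw_founder_frequencies(
    founder_model(4000, 0.25, chrom_length = 2e7, seed = 51))
  sp <- mosaic_spec(2e7, 0.1, 5e6, 10, seed = 52)
  mc <- simulate_mosaic_cohort(sp, fr)
  st <- compute_window_stats(mc$genotypes, fr$taurine, fr$indicine)
  cl <- classify_windows(st)

  truth_frac <- function(tr, w0, w1) {
    ov <- pmax(0, pmin(tr$end, w1) - pmax(tr$start, w0) + 1)
    sum(ov * (tr$origin == "taurine")) / sum(ov)
  }
  hits <- 0; total <- 0
  for (i in which(cl$origin != "no_call")) {
    tr <- mc$tracts[mc$tracts$animal == cl$animal[i], ]
    f <- truth_frac(tr, cl$start[i], cl$end[i])
    if (abs(f - 0.5) < 1e-9) next   # balanced het-ancestry window: no truth
    total <- total + 1
    hits <- hits + ((f > 0.5) == (cl$origin[i] == "taurine"))
  }
  expect_gt(total, 100)
  expect_gte(hits / total, 0.9)

  comp <- animal_composition(st)
  expect_lt(abs(mean(comp$taurine_window_fraction) -
                  tract_taurine_fraction(mc$tracts)), 0.05)
  # mostly indicine cohort: lower global differentiation from indicine
  expect_true(all(comp$global_bosind_ind < comp$global_bosind_tau))
})

test_that("composition fraction is half under symmetric references", {
  fr <- draw_founder_frequencies(
    founder_model(1500, 0.25, chrom_length = 5e6, seed = 53))
  sp <- mosaic_spec(5e6, 0.5, 1e6, 4, seed = 54)
  mc <- simulate_mosaic_cohort(sp, fr)
  st <- compute_window_stats(mc$genotypes, fr$taurine, fr$taurine)
  comp <- animal_composition(st)
  expect_equal(comp$taurine_window_fraction,
               rep(0.5, nrow(comp)))
})

test_that("all-taurine windows give composition fraction one", {
  st <- structure(data.frame(
    animal = "a1", chrom = "1", win_index = 0:9,
    start = 0:9 * 250000 + 1, end = 1:10 * 250000,
    bosind_tau = 0.05, n_snp_tau = 50L,
    bosind_ind = 0.40, n_snp_ind = 50L, callable = TRUE),
    window = 250000L, class = c("window_stats", "data.frame"))
  expect_equal(animal_composition(st)$taurine_window_fraction, 1)
})

test_that("heatmap matrices order animals by birth year and match pd", {
  st <- structure(data.frame(
    animal = rep(c("young", "old"), each = 3),
    chrom = "1", win_index = rep(0:2, 2),
    start = rep(0:2 * 250000 + 1, 2), end = rep(1:3 * 250000, 2),
    bosind_tau = c(0.1, 0.2, 0.3, 0.3, 0.2, 0.1), n_snp_tau = 50L,
    bosind_ind = 0.2, n_snp_ind = 50L, callable = TRUE),
    window = 250000L, class = c("window_stats", "data.frame"))
  m <- heatmap_matrix(st, "1", birth_years = c(young = 1999, old = 1950))
  expect_equal(rownames(m), c("old", "young"))
  expect_equal(dim(m), c(2L, 3L))
  pd <- window_percent_difference(st)
  expect_equal(unname(m["young", ]),
               pd$pd[pd$animal == "young"][order(pd$win_index[pd$animal == "young"])])
  expect_message(m2 <- heatmap_matrix(st, "1", birth_years = c(old = 1950)),
                 "without birth year")
  expect_equal(rownames(m2), c("old", "young"))
})
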