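# Windowed depth, SD standardization, duplication and deletion evidence.

test_that("window depth equals per-base summation", {
  base <- data.frame(chrom = "1", pos = 1:200, depth = 10)
  p <- window_depth(base, c(1, 200), window = 50)
  expect_equal(p$count, rep(500, 4))
  expect_equal(attr(p, "window"), 50)
  expect_false(attr(p, "partial_last"))

  empty <- window_depth(base[0, ], c(1, 200), window = 50)
  expect_equal(empty$count, rep(0L, 4))

  set.seed(31)
  track <- data.frame(chrom = "1", pos = sample(1:1000, 600),
                      depth = rpois(600, 8))
  got <- window_depth(track, c(1, 1000), window = 50)
  want <- sapply(seq(1, 1000, 50), function(s)
    sum(track$depth[track$pos >= s & track$pos <= s + 49]))
  expect_equal(got$count, as.numeric(want))
  # conservation: window counts sum to the per-base total
  expect_equal(sum(got$count), sum(track$depth))

  # read-interval input: reads are counted in their start window
  reads <- data.frame(start = c(1, 49, 51, 170), end = c(100, 148, 150, 269))
  pr <- window_depth(reads, c(1, 200), window = 50)
  expect_equal(pr$count, c(2, 1, 0, 1))

  # partial terminal window is kept and flagged
  pp <- window_depth(base, c(1, 120), window = 50)
  expect_equal(nrow(pp), 3)
  expect_true(attr(pp, "partial_last"))
})

test_that("standardization gives population z-scores", {
  flat <- window_depth(data.frame(pos = 1:100, depth = 4), c(1, 100), 50)
  expect_warning(z0 <- standardize_profile(flat), "constant")
  expect_equal(z0, c(0, 0))

  p <- structure(data.frame(chrom = "1", start = c(1, 51, 101, 151),
                            end = c(50, 100, 150, 200),
                            count = c(10, 10, 10, 30)),
                 class = c("depth_profile", "data.frame"))
  z <- standardize_profile(p)
  pop_sd <- sqrt(mean((p$count - 15)^2))
  expect_equal(z, (p$count - 15) / pop_sd)
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(z^2)), 1)
})

test_that("planted duplications are called with the right fold change", {
  dup <- polled_locus_presets()$celtic_duplication
  region <- c(1680001, 1730000)
  sv <- structural_variant("duplication", dup[1], dup[2], 1, "hom")

  same <- simulate_depth_profile(12.5, region, 50, seed = 600)
  expect_equal(nrow(detect_duplication(same, same)), 0L)

  hits <- 0; folds <- numeric(0)
  for (r in 1:20) {
    carrier <- simulate_depth_profile(12.5, region, 50, list(sv),
                                      seed = 700 + r, group = "PP")
    ref <- simulate_depth_profile(12.5, region, 50, seed = 800 + r)
    calls <- detect_duplication(carrier, ref)
    i <- which(calls$start <= dup[2] & calls$end >= dup[1])
    if (length(i)) {
      hits <- hits + 1
      folds <- c(folds, calls$fold_change[i[1]])
    }
  }
  expect_gte(hits, 19)
  expect_lt(abs(mean(folds) - 2), 0.2)

  # heterozygous duplication: copy factor 1 + 1/2
  svh <- structural_variant("duplication", dup[1], dup[2], 1, "het")
  fh <- sapply(1:20, function(r) {
    carrier <- simulate_depth_profile(12.5, region, 50, list(svh),
                                      seed = 900 + r)
    ref <- simulate_depth_profile(12.5, region, 50, seed = 950 + r)
    calls <- detect_duplication(carrier, ref, min_windows = 3,
                                z_threshold = 1.5)
    i <- which(calls$start <= dup[2] & calls$end >= dup[1])
    if (length(i)) calls$fold_change[i[1]] else NA_real_
  })
  expect_lt(abs(mean(fh, na.rm = TRUE) - 1.5), 0.2)
})

test_that("variant-free profile pairs rarely trigger calls", {
  fp <- sum(sapply(1:40, function(r) {
    a <- simulate_depth_profile(12.5, c(1680001, 1730000), 50, seed = 1100 + r)
    b <- simulate_depth_profile(12.5, c(1680001, 1730000), 50, seed = 1500 + r)
    nrow(detect_duplication(a, b)) > 0
  }))
  expect_lte(fp / 40, 0.075)
})

test_that("spanning-read counts match coverage geometry and vanish in carriers", {
  expect_equal(deletion_read_support(data.frame(start = 1, end = 50),
                                     c(100, 109)), 0)
  target <- polled_locus_presets()$celtic_replaced
  region <- c(1700001, 1712000)
  sp <- sapply(1:30, function(r) deletion_read_support(
    simulate_read_intervals(12.5, region, 100, seed = 40 + r), target))
  # depth x (read_len - target_len + 1) / read_len = 12.5 * 91 / 100
  expect_lt(abs(mean(sp) - 11.375), 1.5)

  del <- structural_variant("deletion", target[1], target[2],
                            genotype = "hom")
  hom <- sapply(1:10, function(r) deletion_read_support(
    simulate_read_intervals(12.5, region, 100, deletion = del,
                            seed = 70 + r), target))
  expect_true(all(hom == 0))

  delh <- structural_variant("deletion", target[1], target[2],
                             genotype = "het")
  het <- sapply(1:30, function(r) deletion_read_support(
    simulate_read_intervals(12.5, region, 100, deletion = delh,
                            seed = 170 + r), target))
  expect_lt(abs(mean(het) - 11.375 / 2), 1.5)

  per_animal <- deletion_read_support(
    data.frame(animal = c("a", "a", "b"),
               start = c(90, 95, 98), end = c(189, 194, 197)),
    c(100, 109))
  expect_equal(as.vector(per_animal), c(2, 1))
})
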