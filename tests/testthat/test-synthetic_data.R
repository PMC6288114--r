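# Generators: founder divergence, mosaic cohorts, planted fixed sites,
# depth profiles with structural variants.

test_that("founder draw degenerates correctly at F = 0 and is seeded", {
  m0 <- founder_model(50, 0, seed = 4)
  f0 <- draw_founder_frequencies(m0)
  expect_identical(f0$taurine$af, f0$indicine$af)

  m <- founder_model(200, 0.2, seed = 9)
  expect_identical(draw_founder_frequencies(m), draw_founder_frequencies(m))
  expect_error(founder_model(100, 1), "divergence_fst")
  expect_error(founder_model(100, -0.1), "divergence_fst")
  expect_error(founder_model(0, 0.2))
})

test_that("Balding-Nichols divergence is calibrated to the target FST", {
  fm <- founder_model(10000, 0.25, seed = 11)
  fr <- draw_founder_frequencies(fm)
  expect_true(all(fr$taurine$af >= 0 & fr$taurine$af <= 1))
  expect_true(all(fr$indicine$af >= 0 & fr$indicine$af <= 1))
  set.seed(3)
  ga <- sample_genotypes(fr$taurine, 200, "x")
  gb <- sample_genotypes(fr$indicine, 200, "y")
  fst <- weir_cockerham_fst(ga, gb)$mean_fst
  expect_lt(abs(fst - 0.25), 0.03)
})

test_that("mosaic tracts tile the chromosome and hit the target fraction", {
  fm <- founder_model(2000, 0.25, chrom_length = 5e7, seed = 21)
  fr <- draw_founder_frequencies(fm)

  sp0 <- mosaic_spec(5e7, 0, 5e6, 3, seed = 30)
  mc0 <- simulate_mosaic_cohort(sp0, fr)
  expect_true(all(mc0$tracts$origin == "indicine"))
  expect_equal(tract_taurine_fraction(mc0$tracts), 0)

  sp <- mosaic_spec(5e7, 0.1, 5e6, 20, seed = 31)
  mc <- simulate_mosaic_cohort(sp, fr)
  # tiling: per haplotype, tract lengths sum to the chromosome length
  per_hap <- tapply(mc$tracts$end - mc$tracts$start + 1,
                    interaction(mc$tracts$animal, mc$tracts$haplotype),
                    sum)
  expect_true(all(per_hap == 5e7))
  expect_true(all(mc$tracts$start >= 1 & mc$tracts$end <= 5e7))
  expect_lt(abs(tract_taurine_fraction(mc$tracts) - 0.1), 0.05)
  expect_identical(simulate_mosaic_cohort(sp, fr),
                   simulate_mosaic_cohort(sp, fr))
})

test_that("pure-taurine cohorts reproduce the taurine founder frequencies", {
  fm <- founder_model(1000, 0.25, chrom_length = 5e6, seed = 22)
  fr <- draw_founder_frequencies(fm)
  sp <- mosaic_spec(5e6, 1, 1e6, 40, seed = 33)
  mc <- simulate_mosaic_cohort(sp, fr)
  expect_true(all(mc$tracts$origin == "taurine"))
  obs <- compute_allele_frequencies(mc$genotypes)$af
  # binomial sampling error with 2 x 40 draws per site
  expect_lt(mean(abs(obs - fr$taurine$af)), 0.06)
})

test_that("planted fixed differences round-trip through find_fixed_alt", {
  fm <- founder_model(500, 0.25, chrom_length = 1e6, seed = 24)
  fr <- draw_founder_frequencies(fm)
  sp <- mosaic_spec(1e6, 0.1, 2e5, 8, seed = 25)
  mc <- simulate_mosaic_cohort(sp, fr)

  un <- plant_fixed_differences(mc$genotypes, fr$taurine, 0)
  expect_identical(un$genotypes, mc$genotypes)

  pl <- plant_fixed_differences(mc$genotypes, fr$taurine, 50, seed = 26)
  found <- find_fixed_alt(pl$genotypes, pl$taurus_freqs)
  # planted sites are a subset of what is recovered; any extra hits are
  # sites fixed by chance that also vanished from the reduced panel
  expect_true(all(paste(pl$planted$chrom, pl$planted$pos) %in%
                    paste(found$chrom, found$pos)))
  naturally_fixed <- find_fixed_alt(mc$genotypes, fr$taurine)
  expect_equal(nrow(found), 50 + nrow(naturally_fixed))

  expect_error(plant_fixed_differences(mc$genotypes, fr$taurine, 1e6),
               "n_fixed")
})

test_that("depth profiles follow the Poisson copy-factor model", {
  expect_error(simulate_depth_profile(0, c(1, 1000)), "positive")
  expect_error(simulate_depth_profile(10, c(1, 60), window = 50),
               "two windows")

  # no SVs: window means ~ depth x window
  p <- simulate_depth_profile(12.5, c(1, 50000), 50, seed = 41)
  expect_equal(nrow(p), 1000)
  expect_lt(abs(mean(p$count) - 12.5 * 50), 2)

  # homozygous duplication: dup/flank mean ratio ~ 2 over many windows
  sv <- structural_variant("duplication", 10001, 35000, 1, "hom")
  pd <- simulate_depth_profile(12.5, c(1, 60000), 50, list(sv), seed = 42)
  dup <- pd$start >= 10001 & pd$end <= 35000
  expect_lt(abs(mean(pd$count[dup]) / mean(pd$count[!dup]) - 2), 0.1)

  # heterozygous duplication: factor 1.5
  svh <- structural_variant("duplication", 10001, 35000, 1, "het")
  ph <- simulate_depth_profile(12.5, c(1, 60000), 50, list(svh), seed = 43)
  expect_lt(abs(mean(ph$count[dup]) / mean(ph$count[!dup]) - 1.5), 0.1)

  # homozygous deletion: zero expected depth over the deleted bases
  del <- structural_variant("deletion", 5001, 5400, genotype = "hom")
  means <- rowMeans(sapply(1:40, function(r)
    simulate_depth_profile(12.5, c(1, 10000), 50, list(del), seed = 100 + r)$count))
  prof <- simulate_depth_profile(12.5, c(1, 10000), 50, list(del), seed = 1)
  inside <- prof$start >= 5001 & prof$end <= 5400
  expect_lt(max(means[inside]), 1e-9)
  outside <- prof$end < 5001 | prof$start > 5400
  expect_lt(abs(mean(means[outside]) - 625), 15)
})

test_that("identical seeds give identical generator output everywhere", {
  sv <- structural_variant("duplication", 500, 800)
  expect_identical(simulate_depth_profile(10, c(1, 2000), 50, list(sv), seed = 5),
                   simulate_depth_profile(10, c(1, 2000), 50, list(sv), seed = 5))
  expect_identical(simulate_read_intervals(10, c(1, 5000), 100, seed = 6),
                   simulate_read_intervals(10, c(1, 5000), 100, seed = 6))
})
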