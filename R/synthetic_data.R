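# Synthetic-data generators.
#
# Everything the pipeline consumes can be generated here under a fixed seed:
# two reference panels diverged to a target FST (Balding-Nichols model), an
# admixed cohort whose genomes are mosaics of known ancestry tracts
# (emulating a graded-up breed), planted cohort-fixed alternate alleles, and
# windowed read-depth profiles carrying duplications or deletions.

#' Specify a pair of diverged founder populations
#'
#' The two reference panels are modelled with the Balding-Nichols
#' construction: an ancestral frequency `p` is drawn per site, and each
#' daughter population's frequency is drawn from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with `F` the target fixation
#' index.  Under this model the expected Weir-Cockerham FST between large
#' samples from the daughters equals `F`.
#'
#' @param n_sites Number of biallelic sites to generate.
#' @param divergence_fst Target fixation index `F` in `[0, 1)`.  `F = 0`
#'   degenerates to both daughters inheriting the ancestral frequency
#'   exactly.
#' @param chrom Chromosome name used for all sites.
#' @param chrom_length Chromosome length in bp; site positions are drawn
#'   uniformly without replacement from `1:chrom_length`.  Defaults to
#'   `500 * n_sites`.
#' @param freq_range Range of the uniform ancestral-frequency distribution;
#'   the default `[0.05, 0.95]` avoids near-monomorphic degenerate sites.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return An object of class `founder_model`.
#' @seealso [draw_founder_frequencies()]
#' @export
founder_model <- function(n_sites, divergence_fst, chrom = "1",
                          chrom_length = NULL, freq_range = c(0.05, 0.95),
                          seed = 1L) {
  stopifnot(n_sites >= 1, length(freq_range) == 2,
            freq_range[1] >= 0, freq_range[2] <= 1,
            freq_range[1] < freq_range[2])
  if (divergence_fst < 0 || divergence_fst >= 1) {
    stop("divergence_fst must lie in [0, 1)")
  }
  if (is.null(chrom_length)) chrom_length <- 500L * n_sites
  stopifnot(chrom_length >= n_sites)
  structure(list(n_sites = as.integer(n_sites),
                 divergence_fst = divergence_fst,
                 chrom = as.character(chrom),
                 chrom_length = as.integer(chrom_length),
                 freq_range = freq_range,
                 seed = as.integer(seed)),
            class = "founder_model")
}

#' Draw allele frequencies for two diverged reference populations
#'
#' @param model A [founder_model()].
#'
#' @return A list with two [freq_table()] elements, `taurine` and
#'   `indicine`, sharing site coordinates.
#' @export
draw_founder_frequencies <- function(model) {
  stopifnot(inherits(model, "founder_model"))
  set.seed(model$seed)
  n <- model$n_sites
  pos <- sort(sample.int(model$chrom_length, n))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1), USE.NAMES = FALSE)
  p <- runif(n, model$freq_range[1], model$freq_range[2])
  F <- model$divergence_fst
  if (F == 0) {
    p1 <- p
    p2 <- p
  } else {
    shape <- (1 - F) / F
    p1 <- rbeta(n, p * shape, (1 - p) * shape)
    p2 <- rbeta(n, p * shape, (1 - p) * shape)
  }
  list(taurine = freq_table(model$chrom, pos, ref, alt, p1),
       indicine = freq_table(model$chrom, pos, ref, alt, p2))
}

#' Specify a synthetic admixed mosaic cohort
#'
#' Each haplotype of each animal is tiled with ancestry tracts whose lengths
#' are exponential (a Markovian ancestry-switch process, the neutral default
#' for admixture `g` generations back with mean tract length about
#' `1 / (g r)`) and whose origins are drawn independently with probability
#' `taurine_target_fraction` of being taurine.
#'
#' @param chrom_length Chromosome length in bp.
#' @param taurine_target_fraction Expected taurine genome fraction in
#'   `[0, 1]`.
#' @param tract_mean Mean ancestry-tract length in bp.
#' @param n_animals Number of diploid animals.
#' @param missing_rate Per-call missing-genotype probability (default 0).
#' @param seed Integer seed.
#'
#' @return An object of class `mosaic_spec`.
#' @export
mosaic_spec <- function(chrom_length, taurine_target_fraction, tract_mean,
                        n_animals, missing_rate = 0, seed = 1L) {
  stopifnot(chrom_length >= 1, tract_mean > 0, n_animals >= 1,
            missing_rate >= 0, missing_rate < 1)
  if (taurine_target_fraction < 0 || taurine_target_fraction > 1) {
    stop("taurine_target_fraction must lie in [0, 1]")
  }
  structure(list(chrom_length = as.numeric(chrom_length),
                 taurine_target_fraction = taurine_target_fraction,
                 tract_mean = as.numeric(tract_mean),
                 n_animals = as.integer(n_animals),
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "mosaic_spec")
}

# Tile [1, chrom_length] with exponential tracts; 1-based inclusive, no gaps.
draw_tracts <- function(chrom_length, tract_mean, p_taurine) {
  starts <- numeric(0)
  cur <- 1
  repeat {
    starts <- c(starts, cur)
    cur <- cur + max(1, round(rexp(1, 1 / tract_mean)))
    if (cur > chrom_length) break
  }
  ends <- c(starts[-1] - 1, chrom_length)
  origin <- ifelse(runif(length(starts)) < p_taurine, "taurine", "indicine")
  data.frame(start = starts, end = ends, origin = origin,
             stringsAsFactors = FALSE)
}

#' Simulate an admixed mosaic cohort from two founder panels
#'
#' Alleles at each site are drawn from the allele frequency of the founder
#' population the containing ancestry tract descends from; the diploid call
#' is the sum of the two haplotype alleles.
#'
#' @param spec A [mosaic_spec()].
#' @param founders A list with `taurine` and `indicine` [freq_table()]s
#'   sharing site coordinates (e.g. from [draw_founder_frequencies()]).
#'
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `tracts`, the ground-truth ancestry tract set: a data frame with
#'   columns `animal`, `haplotype`, `chrom`, `start`, `end`, `origin`
#'   (1-based inclusive, tiling the chromosome).
#' @export
simulate_mosaic_cohort <- function(spec, founders) {
  stopifnot(inherits(spec, "mosaic_spec"))
  tau <- founders$taurine
  ind <- founders$indicine
  if (!identical(tau[c("chrom", "pos")], ind[c("chrom", "pos")])) {
    stop("founder tables must share site coordinates")
  }
  if (any(tau$pos > spec$chrom_length)) {
    stop("founder sites lie outside the chromosome length")
  }
  set.seed(spec$seed)
  n_sites <- nrow(tau)
  animals <- sprintf("animal_%02d", seq_len(spec$n_animals))
  calls <- matrix(0L, n_sites, spec$n_animals)
  tract_rows <- vector("list", 2L * spec$n_animals)
  k <- 0
  for (a in seq_len(spec$n_animals)) {
    geno <- integer(n_sites)
    for (h in 1:2) {
      tr <- draw_tracts(spec$chrom_length, spec$tract_mean,
                        spec$taurine_target_fraction)
      idx <- findInterval(tau$pos, tr$start)
      p_site <- ifelse(tr$origin[idx] == "taurine", tau$af, ind$af)
      geno <- geno + rbinom(n_sites, 1L, p_site)
      k <- k + 1
      tract_rows[[k]] <- data.frame(animal = animals[a], haplotype = h,
                                    chrom = tau$chrom[1], tr,
                                    stringsAsFactors = FALSE)
    }
    calls[, a] <- geno
  }
  if (spec$missing_rate > 0) {
    calls[runif(length(calls)) < spec$missing_rate] <- NA_integer_
  }
  list(genotypes = genotype_matrix(tau[c("chrom", "pos", "ref", "alt")],
                                   animals, calls),
       tracts = do.call(rbind, tract_rows))
}

#' Realized taurine fraction of a truth tract set
#'
#' @param tracts Tract data frame as returned by [simulate_mosaic_cohort()].
#' @param by_animal Return one fraction per animal instead of the pooled
#'   value.
#' @return Fraction of tract base pairs of taurine origin.
#' @export
tract_taurine_fraction <- function(tracts, by_animal = FALSE) {
  len <- tracts$end - tracts$start + 1
  tau <- len * (tracts$origin == "taurine")
  if (by_animal) {
    tapply(tau, tracts$animal, sum) / tapply(len, tracts$animal, sum)
  } else {
    sum(tau) / sum(len)
  }
}

#' Plant cohort-fixed alternate alleles
#'
#' Chooses `n_fixed` sites, makes every animal homozygous-alternate there,
#' and removes those sites from the taurine reference table, so that the
#' planted sites satisfy the definition of a fixed alternate allele absent
#' from the comparison panel.
#'
#' @param genotypes A [genotype_matrix()].
#' @param taurus_freqs Taurine [freq_table()].
#' @param n_fixed Number of sites to plant.
#' @param seed Integer seed.
#'
#' @return A list with the modified `genotypes`, the reduced `taurus_freqs`,
#'   and `planted`, the site table of planted positions.
#' @export
plant_fixed_differences <- function(genotypes, taurus_freqs, n_fixed,
                                    seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n_sites <- nrow(genotypes$sites)
  if (n_fixed > n_sites) stop("n_fixed exceeds the number of sites")
  if (n_fixed == 0) {
    return(list(genotypes = genotypes, taurus_freqs = taurus_freqs,
                planted = genotypes$sites[0, ]))
  }
  set.seed(seed)
  pick <- sort(sample.int(n_sites, n_fixed))
  genotypes$calls[pick, ] <- 2L
  planted <- genotypes$sites[pick, , drop = FALSE]
  drop <- pos_key(taurus_freqs) %in% pos_key(planted)
  taurus_freqs <- taurus_freqs[!drop, , drop = FALSE]
  class(taurus_freqs) <- c("freq_table", "data.frame")
  list(genotypes = genotypes, taurus_freqs = taurus_freqs, planted = planted)
}

#' Describe a structural variant for depth simulation
#'
#' @param kind `"duplication"` or `"deletion"`.
#' @param start,end 1-based inclusive interval on the simulated chromosome.
#' @param copies_per_haplotype Extra copies carried per affected haplotype
#'   (duplications only; >= 1).
#' @param genotype `"hom"` (both haplotypes affected) or `"het"`.
#' @return An object of class `sv_spec`.
#' @export
structural_variant <- function(kind = c("duplication", "deletion"),
                               start, end, copies_per_haplotype = 1L,
                               genotype = c("hom", "het")) {
  kind <- match.arg(kind)
  genotype <- match.arg(genotype)
  if (start > end) stop("start must be <= end")
  if (kind == "duplication" && copies_per_haplotype < 1) {
    stop("duplications carry at least one extra copy per haplotype")
  }
  structure(list(kind = kind, start = as.numeric(start),
                 end = as.numeric(end),
                 copies_per_haplotype = as.integer(copies_per_haplotype),
                 genotype = genotype),
            class = "sv_spec")
}

#' Simulate a windowed read-depth profile
#'
#' Window counts are Poisson with mean `mean_depth * window_bp * factor`.
#' The copy factor is 1 outside structural variants; over a duplicated
#' interval it is `1 + extra_copies / 2` with `extra_copies` the total extra
#' copies carried over both haplotypes (a homozygous duplication of one
#' extra copy per haplotype gives factor 2, a heterozygous one 1.5); over a
#' deleted interval it is `1 - deleted_haplotype_fraction` (0 for a
#' homozygous deletion).  Windows partially overlapped by a variant get the
#' factor prorated by overlapping base pairs.
#'
#' @param mean_depth Mean x-coverage (> 0).
#' @param region Length-2 vector, 1-based inclusive interval to profile.
#' @param window Window size in bp (default 50); the region must contain at
#'   least two windows.  A partial terminal window is kept and flagged in
#'   the `partial_last` attribute.
#' @param svs List of [structural_variant()] objects.
#' @param chrom Chromosome name.
#' @param group Optional group label (e.g. `"carrier"`).
#' @param seed Integer seed.
#'
#' @return A data frame of class `depth_profile` with columns `chrom`,
#'   `start`, `end`, `count`, and attributes `window`, `group`,
#'   `partial_last`.
#' @export
simulate_depth_profile <- function(mean_depth, region, window = 50L,
                                   svs = list(), chrom = "1", group = NULL,
                                   seed = 1L) {
  if (mean_depth <= 0) stop("mean_depth must be positive")
  stopifnot(length(region) == 2, region[1] <= region[2])
  if (inherits(svs, "sv_spec")) svs <- list(svs)
  span <- region[2] - region[1] + 1
  if (span < 2 * window) stop("region must contain at least two windows")
  starts <- seq(region[1], region[2], by = window)
  ends <- pmin(starts + window - 1, region[2])
  wlen <- ends - starts + 1
  factor <- rep(1, length(starts))
  for (sv in svs) {
    ov <- pmax(0, pmin(ends, sv$end) - pmax(starts, sv$start) + 1)
    if (sv$kind == "duplication") {
      extra <- sv$copies_per_haplotype * if (sv$genotype == "hom") 2 else 1
      factor <- factor + (ov / wlen) * extra / 2
    } else {
      del_frac <- if (sv$genotype == "hom") 1 else 0.5
      factor <- factor - (ov / wlen) * del_frac
    }
  }
  factor <- pmax(factor, 0)
  set.seed(seed)
  counts <- rpois(length(starts), mean_depth * wlen * factor)
  depth_profile(chrom, starts, ends, counts, window = window, group = group)
}

# shared constructor used by simulate_depth_profile() and window_depth()
depth_profile <- function(chrom, starts, ends, counts, window, group = NULL) {
  structure(data.frame(chrom = as.character(chrom), start = starts,
                       end = ends, count = as.numeric(counts),
                       stringsAsFactors = FALSE),
            window = window, group = group,
            partial_last = (ends[length(ends)] - starts[length(starts)] + 1) < window,
            class = c("depth_profile", "data.frame"))
}

#' Simulate aligned-read intervals over a region
#'
#' Reads of fixed length are placed uniformly over the region at the
#' requested mean depth.  If a deletion-type [structural_variant()] is
#' supplied, reads that would fully span the deleted interval are removed
#' from carrier haplotypes (all reads for a homozygous carrier, half for a
#' heterozygous one), mimicking the loss of spanning alignments at a
#' deleted or replaced sequence.
#'
#' @param mean_depth Mean x-coverage (> 0).
#' @param region Length-2 vector, 1-based inclusive.
#' @param read_length Read length in bp.
#' @param deletion Optional deletion [structural_variant()].
#' @param seed Integer seed.
#' @return Data frame with columns `start`, `end`, one row per read.
#' @export
simulate_read_intervals <- function(mean_depth, region, read_length = 100L,
                                    deletion = NULL, seed = 1L) {
  if (mean_depth <= 0) stop("mean_depth must be positive")
  stopifnot(length(region) == 2, region[2] - region[1] + 1 > read_length)
  set.seed(seed)
  span <- region[2] - region[1] + 1
  n_reads <- rpois(1, mean_depth * span / read_length)
  start <- region[1] + floor(runif(n_reads, 0, span - read_length + 1))
  reads <- data.frame(start = start, end = start + read_length - 1)
  if (!is.null(deletion)) {
    stopifnot(inherits(deletion, "sv_spec"), deletion$kind == "deletion")
    spans <- reads$start <= deletion$start & reads$end >= deletion$end
    drop_p <- if (deletion$genotype == "hom") 1 else 0.5
    reads <- reads[!(spans & runif(nrow(reads)) < drop_p), , drop = FALSE]
    rownames(reads) <- NULL
  }
  reads
}
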