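# Forward simulation of the breed-formation history and the
# Weir & Cockerham (1984) FST estimator.
#
# History modelled: one ancestral population at mutation-drift equilibrium,
# a split into two founder populations (taurine / indicine) that diverge
# neutrally, then an admixture phase that founds the composite breed with
# an F1 cross and continues for the stated number of generations either by
# random mating within the hybrid population ("cross", the default) or by
# repeated backcrossing to indicine sires ("grading_up").  No selection
# anywhere.
#
# The pre-admixture phases evolve allele frequencies per site (binomial
# resampling + infinite-sites injection; the exact marginal of the
# individual-based model under linkage equilibrium).  At admixture onset
# founder haplotypes are realized explicitly and the admixture phase is
# individual-based, with free recombination between loci, at most one
# crossover per locus per meiosis, and every admixed site tracing back to a
# labelled founder haplotype, so ancestry is known everywhere.
#
# Desk-scale runs divide the ancestral population size and the burn-in and
# divergence generation counts by `scale_factor` and multiply per-locus
# rates by it, preserving t/2N and theta = 4 N mu.  The admixture phase is
# an absolute 30-generation historical quantity and is deliberately NOT
# rescaled (see the methods vignette).

#' Parameters for the breed-formation simulation
#'
#' Defaults are the modelled breed history: ancestral diploid size 10,000,
#' 100,000 burn-in generations, 10,000 generations of divergence, a
#' 30-generation admixture phase yielding 1,000 sampled animals, and
#' mutation and recombination rates of 0.01 per locus of 10,000 kb.
#'
#' @param ancestral_N Ancestral (and founder) diploid population size.
#' @param burnin_gens Generations before the split.
#' @param divergence_gens Generations between split and admixture.
#' @param admixture_gens Generations of the admixture phase (the first
#'   forms the F1); not rescaled.
#' @param admixed_N Diploid size of the admixed population; not rescaled.
#' @param n_brahman_out Admixed animals sampled into the output.
#' @param n_founder_out Founder animals sampled per population.
#' @param n_loci Number of freely recombining loci.
#' @param locus_length Locus length in bp.
#' @param mutation_rate New mutations per locus per gamete per generation.
#' @param recombination_rate Within-locus crossover probability per meiosis.
#' @param admixture_mode `"cross"` (F1 then random mating) or
#'   `"grading_up"` (F1 then repeated backcrossing to indicine sires).
#' @param scale_factor Rescaling divisor `s >= 1`: divides `ancestral_N`,
#'   `burnin_gens`, `divergence_gens`; multiplies the per-generation
#'   mutation rate.
#' @param seed Integer seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(ancestral_N = 10000, burnin_gens = 100000,
                       divergence_gens = 10000, admixture_gens = 30,
                       admixed_N = 1000, n_brahman_out = 1000,
                       n_founder_out = 100, n_loci = 4,
                       locus_length = 1e7, mutation_rate = 0.01,
                       recombination_rate = 0.01,
                       admixture_mode = c("cross", "grading_up"),
                       scale_factor = 1, seed = 1L) {
  admixture_mode <- match.arg(admixture_mode)
  stopifnot(scale_factor >= 1, ancestral_N >= 2, admixed_N >= 2,
            n_loci >= 1, locus_length >= 1, mutation_rate >= 0,
            recombination_rate >= 0, recombination_rate <= 1,
            admixture_gens >= 0, divergence_gens >= 0, burnin_gens >= 0)
  p <- list(ancestral_N = ancestral_N, burnin_gens = burnin_gens,
            divergence_gens = divergence_gens,
            admixture_gens = admixture_gens, admixed_N = as.integer(admixed_N),
            n_brahman_out = as.integer(n_brahman_out),
            n_founder_out = as.integer(n_founder_out),
            n_loci = as.integer(n_loci), locus_length = locus_length,
            mutation_rate = mutation_rate,
            recombination_rate = recombination_rate,
            admixture_mode = admixture_mode, scale_factor = scale_factor,
            seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

# scaled quantities actually simulated
scaled_params <- function(p) {
  s <- p$scale_factor
  list(N = max(2L, as.integer(round(p$ancestral_N / s))),
       burnin = as.integer(round(p$burnin_gens / s)),
       divergence = as.integer(round(p$divergence_gens / s)),
       mu = p$mutation_rate * s)
}

# genotype_matrix from a haplotype matrix (sites x haplotypes, 0/1),
# pairing columns (2i-1, 2i) into diploid animals
haps_to_genotypes <- function(hmat, sites, prefix) {
  n_animals <- ncol(hmat) %/% 2L
  calls <- hmat[, seq(1, 2 * n_animals, by = 2), drop = FALSE] +
    hmat[, seq(2, 2 * n_animals, by = 2), drop = FALSE]
  genotype_matrix(sites, sprintf("%s_%03d", prefix, seq_len(n_animals)),
                  calls)
}

#' Simulate the breed-formation history
#'
#' @param p A [sim_params()] object.
#' @return An object of class `breed_sim`: a list with
#'   \describe{
#'     \item{taurine, indicine}{Sampled founder [genotype_matrix()] objects.}
#'     \item{admixed}{Sampled admixed cohort (absent if
#'       `admixture_gens = 0`).}
#'     \item{founder_freqs}{`taurine` / `indicine` [freq_table()]s of the
#'       full founder populations at admixture onset.}
#'     \item{sites}{Site table (loci are chromosomes `L01`, `L02`, ...).}
#'     \item{ancestry}{For the sampled admixed animals: `fraction` (per
#'       animal taurine genome fraction), `haplotype_taurine` (sites x
#'       haplotypes logical matrix), `realized_admixture` (cohort mean).}
#'     \item{params}{The input parameters.}
#'   }
#' @export
simulate_breed_formation <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  set.seed(p$seed)
  sc <- scaled_params(p)
  two_n <- 2L * sc$N
  theta_locus <- 4 * sc$N * sc$mu          # invariant under rescaling
  inj <- two_n * sc$mu * p$n_loci          # new mutations per generation

  # ancestral population at mutation-drift equilibrium: segregating-site
  # count theta * H_{2N-1} per locus, frequencies from the neutral SFS
  s0 <- round(theta_locus * p$n_loci * sum(1 / seq_len(two_n - 1)))
  if (s0 < 1) warning("expected segregating sites < 1; increase theta")
  k <- sample.int(two_n - 1, max(s0, 1), replace = TRUE,
                  prob = 1 / seq_len(two_n - 1))
  p_anc <- wf_onepop(k / two_n, two_n, sc$burnin, inj)
  div <- wf_twopop(p_anc, two_n, sc$divergence, inj)
  S <- length(div$p1)

  # assign loci and positions once, post hoc (sites are exchangeable while
  # only frequencies are tracked), then sort
  locus <- sort(sample.int(p$n_loci, S, replace = TRUE))
  pos <- unlist(lapply(tabulate(locus, p$n_loci), function(n)
    sort(sample.int(p$locus_length, n))), use.names = FALSE)
  sites <- data.frame(chrom = sprintf("L%02d", locus), pos = pos,
                      ref = "A", alt = "C", stringsAsFactors = FALSE)
  n_per_locus <- tabulate(locus, p$n_loci)
  locus_last <- cumsum(n_per_locus)
  locus_first <- locus_last - n_per_locus + 1L

  p_tau <- div$p1
  p_ind <- div$p2
  founder_freqs <- list(
    taurine = freq_table(sites$chrom, sites$pos, sites$ref, sites$alt, p_tau),
    indicine = freq_table(sites$chrom, sites$pos, sites$ref, sites$alt, p_ind))

  # realize founder haplotypes (linkage equilibrium within each founder
  # population at admixture onset)
  h_tau <- matrix(rbinom(S * two_n, 1L, p_tau), S, two_n)
  h_ind <- matrix(rbinom(S * two_n, 1L, p_ind), S, two_n)
  h_all <- cbind(h_tau, h_ind)

  n_fo <- min(p$n_founder_out, sc$N)
  tau_haps <- sample.int(two_n, 2L * n_fo)
  ind_haps <- sample.int(two_n, 2L * n_fo)
  out <- list(
    taurine = haps_to_genotypes(h_tau[, tau_haps, drop = FALSE], sites, "tau"),
    indicine = haps_to_genotypes(h_ind[, ind_haps, drop = FALSE], sites, "ind"),
    founder_freqs = founder_freqs, sites = sites, params = p)

  if (p$admixture_gens >= 1) {
    M <- p$admixed_N
    G <- 2L * M
    # F1: haplotype 1 from a taurine gamete, haplotype 2 from an indicine
    # gamete (founder populations are at linkage equilibrium, so a founder
    # gamete is distributionally a founder haplotype)
    src <- matrix(0L, S, G)
    src[, seq(1, G, 2)] <- rep(sample.int(two_n, M, replace = TRUE), each = S)
    src[, seq(2, G, 2)] <- rep(two_n + sample.int(two_n, M, replace = TRUE),
                               each = S)
    gens_breeding <- p$admixture_gens - 1L
    if (gens_breeding > 0) {
      for (g in seq_len(gens_breeding)) {
        if (p$admixture_mode == "cross") {
          parents <- cbind(sample.int(M, M, replace = TRUE),
                           sample.int(M, M, replace = TRUE))
          gam_parent <- as.vector(t(parents))   # gamete order 2j-1, 2j
          src <- meiosis_src(src, gam_parent, p, locus_first, locus_last,
                             sites$pos)
        } else {
          dams <- sample.int(M, M, replace = TRUE)
          maternal <- meiosis_src(src, dams, p, locus_first, locus_last,
                                  sites$pos)
          paternal <- matrix(rep(two_n + sample.int(two_n, M, replace = TRUE),
                                 each = S), S, M)
          src2 <- matrix(0L, S, G)
          src2[, seq(1, G, 2)] <- maternal
          src2[, seq(2, G, 2)] <- paternal
          src <- src2
        }
      }
    }
    alleles <- realize_alleles(h_all, src)
    n_out <- min(p$n_brahman_out, M)
    pick <- sort(sample.int(M, n_out))
    hap_cols <- as.vector(rbind(2L * pick - 1L, 2L * pick))
    adm_h <- alleles[, hap_cols, drop = FALSE]
    out$admixed <- haps_to_genotypes(adm_h, sites, "brahman")
    anc <- src[, hap_cols, drop = FALSE] <= two_n
    frac_hap <- colMeans(anc)
    frac <- (frac_hap[seq(1, length(frac_hap), 2)] +
               frac_hap[seq(2, length(frac_hap), 2)]) / 2
    names(frac) <- out$admixed$animals
    out$ancestry <- list(fraction = frac, haplotype_taurine = anc,
                         realized_admixture = mean(frac))
  }
  class(out) <- "breed_sim"
  out
}

# one generation of gametes: gam_parent[i] is the diploid parent (column
# pair) of gamete i; per-locus start coins and at most one crossover per
# locus at the within-locus recombination rate
meiosis_src <- function(src, gam_parent, p, locus_first, locus_last, pos) {
  G <- length(gam_parent)
  L <- length(locus_first)
  start_b <- matrix(rbinom(G * L, 1L, 0.5), G, L)
  bp <- matrix(0L, G, L)
  cross <- which(matrix(runif(G * L) < p$recombination_rate, G, L),
                 arr.ind = TRUE)
  if (nrow(cross) > 0) {
    u <- runif(nrow(cross), 0, p$locus_length)
    for (i in seq_len(nrow(cross))) {
      l <- cross[i, 2]
      if (locus_first[l] > locus_last[l]) next
      pl <- pos[locus_first[l]:locus_last[l]]
      bp[cross[i, 1], l] <- locus_first[l] + sum(pl <= u[i])
    }
    # bp beyond the locus end means the crossover falls after the last
    # site; the kernel clamps it to "no switch"
  }
  meiosis_gametes(src, 2L * gam_parent - 1L, 2L * gam_parent, start_b, bp,
                  locus_first, locus_last)
}

#' Weir & Cockerham (1984) two-population FST
#'
#' Sample-size-corrected variance-components estimator; the mean is the
#' ratio of summed components over sites (the vcftools "weighted"
#' estimate).  Sites with fewer than two non-missing genotypes in either
#' population are skipped; sites monomorphic for the same allele in both
#' samples have zero total variance and are excluded from the mean.
#'
#' @param a,b [genotype_matrix()] objects over identical sites.
#' @return List with `per_site` (data frame: `chrom`, `pos`, `fst`),
#'   `mean_fst`, and `n_sites` used in the mean.
#' @export
weir_cockerham_fst <- function(a, b) {
  stopifnot(inherits(a, "genotype_matrix"), inherits(b, "genotype_matrix"))
  if (!identical(a$sites[c("chrom", "pos")], b$sites[c("chrom", "pos")])) {
    stop("genotype matrices must share sites")
  }
  n1 <- rowSums(!is.na(a$calls))
  n2 <- rowSums(!is.na(b$calls))
  usable <- n1 >= 2 & n2 >= 2
  p1 <- rowSums(a$calls, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(b$calls, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(a$calls == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(b$calls == 1L, na.rm = TRUE) / n2

  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)

  va <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  vb <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  vc <- hbar / 2
  tot <- va + vb + vc
  informative <- usable & tot != 0
  fst <- rep(NA_real_, length(n1))
  fst[informative] <- va[informative] / tot[informative]
  list(per_site = data.frame(chrom = a$sites$chrom, pos = a$sites$pos,
                             fst = fst, stringsAsFactors = FALSE),
       mean_fst = sum(va[informative]) / sum(tot[informative]),
       n_sites = sum(informative))
}

#' Tune divergence generations to a target FST
#'
#' Bisection on the (paper-scale) divergence generation count, evaluating
#' each candidate as the mean Weir-Cockerham FST over `n_reps` seeded
#' replicate simulations, until the achieved FST is within `tol` of the
#' target.  This calibrates the separation time to an observed
#' differentiation level.
#'
#' @param target_fst Target mean FST (0 returns zero generations).
#' @param p A [sim_params()] template; `divergence_gens` is overridden.
#' @param measure `"admixed_taurine"` (FST between the admixed cohort and
#'   the taurine founders, the calibration comparison) or `"founders"`
#'   (between the two founder populations; skips the admixture phase).
#' @param tol Convergence tolerance on |achieved - target| (default 0.02).
#' @param n_reps Replicates per evaluation.
#' @param max_iter Maximum bisection steps.
#' @param upper Upper bracket in paper-scale generations (default
#'   `6 * ancestral_N`).
#' @return List with `divergence_gens` (paper scale), `achieved_fst`, and
#'   the bisection `trace`.
#' @export
tune_divergence <- function(target_fst, p,
                            measure = c("admixed_taurine", "founders"),
                            tol = 0.02, n_reps = 3L, max_iter = 10L,
                            upper = NULL) {
  measure <- match.arg(measure)
  stopifnot(inherits(p, "sim_params"), target_fst >= 0, target_fst < 1)
  if (target_fst == 0) {
    return(list(divergence_gens = 0, achieved_fst = 0,
                trace = data.frame(gens = 0, fst = 0)))
  }
  if (measure == "founders") p$admixture_gens <- 0
  if (is.null(upper)) upper <- 8 * p$ancestral_N
  evaluate <- function(gens, iter) {
    vals <- vapply(seq_len(n_reps), function(r) {
      q <- p
      q$divergence_gens <- gens
      q$seed <- p$seed + 7919L * iter + r
      sim <- simulate_breed_formation(q)
      if (measure == "founders") {
        weir_cockerham_fst(sim$taurine, sim$indicine)$mean_fst
      } else {
        weir_cockerham_fst(sim$admixed, sim$taurine)$mean_fst
      }
    }, numeric(1))
    mean(vals)
  }
  lo <- 0
  hi <- upper
  f_hi <- evaluate(hi, 0L)
  trace <- data.frame(gens = hi, fst = f_hi)
  if (f_hi < target_fst) {
    warning("target FST not reached at the upper bracket; returning it")
    return(list(divergence_gens = hi, achieved_fst = f_hi, trace = trace))
  }
  best <- c(gens = hi, fst = f_hi)
  for (it in seq_len(max_iter)) {
    mid <- round((lo + hi) / 2 / p$scale_factor) * p$scale_factor
    f_mid <- evaluate(mid, it)
    trace <- rbind(trace, data.frame(gens = mid, fst = f_mid))
    if (abs(f_mid - target_fst) < abs(best["fst"] - target_fst)) {
      best <- c(gens = mid, fst = f_mid)
    }
    if (abs(f_mid - target_fst) <= tol) break
    if (f_mid < target_fst) lo <- mid else hi <- mid
    if (hi - lo <= p$scale_factor) break
  }
  list(divergence_gens = unname(best["gens"]),
       achieved_fst = unname(best["fst"]), trace = trace)
}
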