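#' Configuration for the two-level hierarchical population simulator
#'
#' The generative model is a two-level Balding–Nichols hierarchy: an
#' ancestral allele frequency `p0` is drawn per locus, regional frequencies
#' are Beta-distributed around `p0` with differentiation `theta_region`, and
#' population frequencies are Beta-distributed around their regional
#' frequency with `theta_pop`. Genotypes are then drawn per population with
#' an inbreeding coefficient `F`, i.e. `P(het) = 2pq(1 - F)`. Under this
#' model the expected hierarchical fixation indices are
#' `PhiRT ~ theta_region` and `PhiPR ~ theta_pop`, which is what makes the
#' generator usable for parameter-recovery testing.
#'
#' Defaults describe a range-wide survey of a structured tree species:
#' two regions (northern with 7 populations, southern with 8), 12 diploid
#' individuals per population, 2022 biallelic loci, strong regional
#' differentiation (0.28) versus mild differentiation among populations
#' within regions (0.05), and small per-population inbreeding values of
#' either sign.
#'
#' @param n_regions number of regions.
#' @param pops_per_region integer vector, length `n_regions`.
#' @param n_per_pop diploid individuals per population.
#' @param n_loci number of biallelic loci.
#' @param theta_region region-level differentiation in `[0, 1)`.
#' @param theta_pop population-within-region differentiation in `[0, 1)`.
#' @param inbreeding_per_pop per-population F in `[-1, 1]`, recycled to the
#'   total number of populations.
#' @param ancestral_maf_range interval in `(0, 0.5]` from which ancestral
#'   minor allele frequencies are drawn uniformly.
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @return a `pop_sim_config` list.
#' @export
pop_sim_config <- function(n_regions = 2,
                           pops_per_region = c(7, 8),
                           n_per_pop = 12,
                           n_loci = 2022,
                           theta_region = 0.28,
                           theta_pop = 0.05,
                           inbreeding_per_pop = c(0.029, 0.011, 0.000,
                                                  -0.037, -0.059, -0.010,
                                                  0.140, -0.054, -0.001,
                                                  -0.004, -0.004, -0.006,
                                                  -0.048, 0.084, -0.017),
                           ancestral_maf_range = c(0.05, 0.5),
                           seed = 1) {
  n_pops <- sum(pops_per_region)
  inbreeding_per_pop <- rep_len(inbreeding_per_pop, n_pops)
  cfg <- list(n_regions = as.integer(n_regions),
              pops_per_region = as.integer(pops_per_region),
              n_per_pop = as.integer(n_per_pop),
              n_loci = as.integer(n_loci),
              theta_region = theta_region,
              theta_pop = theta_pop,
              inbreeding_per_pop = inbreeding_per_pop,
              ancestral_maf_range = ancestral_maf_range,
              seed = as.integer(seed))
  stopifnot_cfg(
    "pops_per_region must have length n_regions" =
      length(cfg$pops_per_region) == cfg$n_regions,
    "theta parameters must lie in [0, 1)" =
      cfg$theta_region >= 0 && cfg$theta_region < 1 &&
      cfg$theta_pop >= 0 && cfg$theta_pop < 1,
    "inbreeding values must lie in [-1, 1]" =
      all(abs(cfg$inbreeding_per_pop) <= 1),
    "ancestral_maf_range must be inside (0, 0.5]" =
      length(cfg$ancestral_maf_range) == 2 &&
      cfg$ancestral_maf_range[1] > 0 &&
      cfg$ancestral_maf_range[2] <= 0.5 &&
      diff(cfg$ancestral_maf_range) >= 0,
    "n_per_pop must be >= 1" = cfg$n_per_pop >= 1
  )
  class(cfg) <- "pop_sim_config"
  cfg
}

## Balding-Nichols draw of daughter frequencies around parent p with
## differentiation theta; theta = 0 copies the parent exactly
bn_draw <- function(p, theta) {
  if (theta == 0) return(p)
  lam <- (1 - theta) / theta
  ## guard degenerate parents: Beta shapes of 0 are undefined
  out <- p
  inner <- p > 0 & p < 1
  out[inner] <- rbeta(sum(inner), p[inner] * lam, (1 - p[inner]) * lam)
  out
}

#' Simulate genotypes under a two-level hierarchical island model
#'
#' Draws per-locus ancestral frequencies, regional and population
#' frequencies by nested Balding–Nichols sampling, and diploid genotypes
#' with per-population inbreeding. Every quantity of interest is recorded
#' in a truth ledger so that estimator recovery can be tested.
#'
#' Genotype probabilities per population are `p^2 + Fpq`, `2pq(1 - F)`,
#' `q^2 + Fpq`. Negative `F` can push a homozygote class negative for
#' extreme frequencies; probabilities are then clamped to zero,
#' renormalised, and a warning is raised.
#'
#' @param cfg a [pop_sim_config()].
#' @return list with `matrix` (a [genotype_matrix()]) and `truth`, a ledger
#'   carrying the configured thetas and F values, the realised per-region
#'   and per-population frequencies and the clean genotype matrix.
#' @export
simulate_hierarchical_genotypes <- function(cfg = pop_sim_config()) {
  stopifnot(inherits(cfg, "pop_sim_config"))
  set.seed(cfg$seed)
  L <- cfg$n_loci
  n_pops <- sum(cfg$pops_per_region)
  region_ids <- if (cfg$n_regions == 2) c("N", "S") else
    paste0("R", seq_len(cfg$n_regions))
  pop_ids <- sprintf("P%02d", seq_len(n_pops))
  pop_region <- rep(region_ids, cfg$pops_per_region)

  p0 <- runif(L, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
  p_region <- matrix(NA_real_, cfg$n_regions, L,
                     dimnames = list(region_ids, NULL))
  for (g in seq_len(cfg$n_regions))
    p_region[g, ] <- bn_draw(p0, cfg$theta_region)
  p_pop <- matrix(NA_real_, n_pops, L, dimnames = list(pop_ids, NULL))
  for (k in seq_len(n_pops))
    p_pop[k, ] <- bn_draw(p_region[pop_region[k], ], cfg$theta_pop)

  n <- cfg$n_per_pop
  calls <- matrix(NA_integer_, n_pops * n, L)
  clamped <- FALSE
  for (k in seq_len(n_pops)) {
    p <- p_pop[k, ]
    q <- 1 - p
    f <- cfg$inbreeding_per_pop[k]
    pr_hom_b <- p^2 + f * p * q      # B is the simulated allele, dose 2
    pr_het <- 2 * p * q * (1 - f)
    pr_hom_a <- q^2 + f * p * q
    if (any(pr_hom_b < 0) || any(pr_hom_a < 0)) clamped <- TRUE
    pr <- cbind(pmax(pr_hom_a, 0), pmax(pr_het, 0), pmax(pr_hom_b, 0))
    pr <- pr / rowSums(pr)
    ## one multinomial draw per locus for the n individuals of pop k
    rows <- (k - 1) * n + seq_len(n)
    u <- matrix(runif(n * L), n, L)
    cum1 <- matrix(pr[, 1], n, L, byrow = TRUE)
    cum2 <- matrix(pr[, 1] + pr[, 2], n, L, byrow = TRUE)
    calls[rows, ] <- (u > cum1) + (u > cum2)
  }
  if (clamped)
    warning("inbreeding F infeasible for some locus frequencies; ",
            "genotype probabilities clamped at zero")

  sample_id <- sprintf("%s_i%02d", rep(pop_ids, each = n),
                       rep(seq_len(n), n_pops))
  rownames(calls) <- sample_id
  snp_id <- sprintf("snp%05d", seq_len(L))
  colnames(calls) <- snp_id
  samples <- data.frame(sample_id = sample_id,
                        population = rep(pop_ids, each = n),
                        region = rep(pop_region, each = n),
                        duplicate_of = NA_character_,
                        dqc = NA_real_,
                        stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = snp_id, source = "RNA",
                     stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, samples, snps)
  truth <- list(kind = "hierarchical_genotypes",
                theta_region = cfg$theta_region,
                theta_pop = cfg$theta_pop,
                inbreeding_per_pop = setNames(cfg$inbreeding_per_pop,
                                              pop_ids),
                p_ancestral = p0,
                p_region = p_region,
                p_pop = p_pop,
                clean_calls = calls,
                samples = samples,
                snps = snps,
                config = cfg)
  class(truth) <- "truth_ledger"
  list(matrix = gm, truth = truth)
}

#' Simulate an array genotyping experiment from planted truth
#'
#' Takes the clean genotypes of a hierarchical simulation and emulates the
#' imperfections of a real array run: technical duplicate samples (exact
#' copies made *before* missingness so that concordance checks exercise
#' missing-data handling), a fraction of loci forced monomorphic (as
#' happens when an assay works but the queried site is invariant in the
#' genotyped sample), random NoCalls, and a per-sample dish-QC value.
#'
#' @param truth ledger from [simulate_hierarchical_genotypes()].
#' @param missing_rate per-call NoCall probability in `[0, 1)`.
#' @param n_duplicates number of duplicated samples to append.
#' @param mono_fraction fraction of loci forced monomorphic (all calls set
#'   to the major homozygote).
#' @param seed integer seed.
#' @param dqc_range range of simulated dish-QC values.
#' @return a [genotype_matrix()] with duplicate pairing and dqc recorded in
#'   the sample metadata and a logical `forced_monomorphic` column in the
#'   SNP metadata.
#' @export
simulate_array_experiment <- function(truth, missing_rate = 0.02,
                                      n_duplicates = 7,
                                      mono_fraction = 0,
                                      seed = 1,
                                      dqc_range = c(0.86, 0.99)) {
  stopifnot(inherits(truth, "truth_ledger"),
            truth$kind == "hierarchical_genotypes")
  if (missing_rate >= 1 || missing_rate < 0)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  set.seed(seed)
  calls <- truth$clean_calls
  samples <- truth$samples
  snps <- truth$snps
  L <- ncol(calls)

  mono_idx <- integer(0)
  if (mono_fraction > 0) {
    mono_idx <- sort(sample.int(L, round(mono_fraction * L)))
    for (j in mono_idx) {
      major <- if (mean(calls[, j]) / 2 > 0.5) 2L else 0L
      calls[, j] <- major
    }
  }
  snps$forced_monomorphic <- seq_len(L) %in% mono_idx

  if (n_duplicates > 0) {
    src <- sample(samples$sample_id, n_duplicates)
    dup_calls <- calls[src, , drop = FALSE]
    dup_ids <- paste0(src, "_dup")
    rownames(dup_calls) <- dup_ids
    calls <- rbind(calls, dup_calls)
    dup_meta <- samples[match(src, samples$sample_id), , drop = FALSE]
    dup_meta$sample_id <- dup_ids
    dup_meta$duplicate_of <- src
    samples <- rbind(samples, dup_meta)
    rownames(samples) <- NULL
  }

  if (missing_rate > 0) {
    drop <- matrix(runif(length(calls)) < missing_rate, nrow(calls))
    calls[drop] <- NA_integer_
  }
  samples$dqc <- runif(nrow(samples), dqc_range[1], dqc_range[2])
  genotype_matrix(calls, samples, snps)
}

#' Simulate STRUCTURE-style log-likelihood tables
#'
#' Emits replicate log-likelihoods per number of clusters K with a
#' piecewise-linear mean: a steep rise up to the true K, then a near-flat
#' plateau, plus Gaussian run-to-run noise. The kink at `k_true` is what
#' the Evanno delta-K statistic detects.
#'
#' @param k_true the planted number of clusters; must lie inside `k_range`.
#' @param k_range integer vector of K values to tabulate (default 1:15).
#' @param runs replicate runs per K (>= 2, otherwise the per-K standard
#'   deviation is undefined).
#' @param noise_sd standard deviation of run noise.
#' @param seed integer seed.
#' @param rise mean log-likelihood gain per K below `k_true`.
#' @param plateau mean gain per K above `k_true`.
#' @return data.frame with columns `K`, `run`, `lnP`.
#' @export
simulate_structure_likelihoods <- function(k_true, k_range = 1:15,
                                           runs = 10, noise_sd = 20,
                                           seed = 1, rise = 400,
                                           plateau = 5) {
  stopifnot_cfg(
    "k_true must lie inside k_range" = k_true %in% k_range,
    "runs must be >= 2" = runs >= 2,
    "noise_sd must be positive" = noise_sd > 0
  )
  set.seed(seed)
  k_range <- sort(unique(as.integer(k_range)))
  mean_l <- -30000 + rise * pmin(k_range, k_true) +
    plateau * pmax(k_range - k_true, 0)
  data.frame(
    K = rep(k_range, each = runs),
    run = rep(seq_len(runs), length(k_range)),
    lnP = rep(mean_l, each = runs) +
      rnorm(length(k_range) * runs, 0, noise_sd)
  )
}
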