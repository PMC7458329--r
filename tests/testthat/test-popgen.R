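test_that("allele frequencies are allele-count frequencies", {
  gm <- make_gm(list(rbind(c(0L), c(1L))))   # genotypes AA, AB
  af <- allele_frequencies(gm)
  expect_equal(unname(af$p[1, 1]), 0.25)     # B allele 1/4 => A 0.75
  expect_equal(unname(af$n[1, 1]), 2)
  ## monomorphic population
  gm2 <- make_gm(list(geno_counts(0, 0, 4)))
  expect_equal(unname(allele_frequencies(gm2)$p[1, 1]), 1)
  ## all NoCall: frequency missing
  gm3 <- make_gm(list(matrix(NA_integer_, 3, 1)))
  expect_true(is.na(allele_frequencies(gm3)$p[1, 1]))
})

test_that("diversity summary: HWE, fixation and the unbiased He", {
  ## exact HWE counts over several identical loci: f ~ 0, CI spans 0
  gm <- make_gm(list(geno_counts(25, 50, 25, n_loci = 20)))
  ds <- diversity_summary(gm, n_boot = 100, seed = 1)
  expect_lt(abs(ds$populations$f), 0.02)
  expect_true(ds$populations$ci_lower <= ds$populations$f &
                ds$populations$f <= ds$populations$ci_upper)
  ## complete fixation: Ho = 0, f = 1
  gm2 <- make_gm(list(geno_counts(50, 0, 50, n_loci = 5)))
  ds2 <- diversity_summary(gm2, n_boot = 50, seed = 1)
  expect_equal(ds2$populations$Ho, 0)
  expect_equal(ds2$populations$f, 1)
  ## worked small example: Ho 0.5, He (8/7) * 0.5
  gm3 <- make_gm(list(matrix(c(0L, 1L, 2L, 1L), 4, 1)))
  ds3 <- diversity_summary(gm3, n_boot = 50, seed = 1)
  expect_equal(ds3$populations$Ho, 0.5)
  expect_equal(ds3$populations$He, (8 / 7) * 0.5, tolerance = 1e-12)
  expect_equal(ds3$populations$f,
               oracle_wc_f(matrix(c(0L, 1L, 2L, 1L), 4, 1)),
               tolerance = 1e-12)
  ## single-individual population excluded with warning
  gm4 <- make_gm(list(geno_counts(3, 3, 0, 4), geno_counts(1, 0, 0, 4)))
  expect_warning(ds4 <- diversity_summary(gm4, n_boot = 20, seed = 1),
                 "excluded")
  expect_equal(nrow(ds4$populations), 1)
})

test_that("Weir-Cockerham f and theta match the direct-formula oracle", {
  for (s in 1:8) {
    set.seed(s)
    n_pops <- sample(2:5, 1)
    n_loci <- sample(5:20, 1)
    genos <- lapply(seq_len(n_pops), function(i) {
      m <- matrix(sample(c(0:2, NA), sample(6:15, 1) * n_loci, TRUE,
                         prob = c(.35, .3, .25, .1)), ncol = n_loci)
      storage.mode(m) <- "integer"
      m
    })
    gm <- make_gm(genos)
    ## per-population f
    for (i in seq_len(n_pops)) {
      sel <- gm$samples$population == sprintf("P%02d", i)
      st <- snpforge:::pop_locus_stats(gm$calls[sel, , drop = FALSE],
                                       rep("x", sum(sel)))
      bc <- snpforge:::wc_bc(st$n[1, ], st$p[1, ], st$h[1, ])
      f_pkg <- snpforge:::wc_f_from_bc(bc$b, bc$c)
      f_ora <- oracle_wc_f(gm$calls[sel, , drop = FALSE])
      if (!is.na(f_ora))
        expect_equal(f_pkg, f_ora, tolerance = 1e-10)
    }
    ## multi-population theta
    t_pkg <- wc_theta(gm$calls, gm$samples$population)
    t_ora <- oracle_wc_theta(gm$calls, gm$samples$population)
    expect_equal(t_pkg, t_ora, tolerance = 1e-10)
  }
})

test_that("hierarchical AMOVA limits, identity and permutation tests", {
  ## panmictic pool: indices near zero, permutation p not significant
  set.seed(5)
  p <- runif(300, 0.2, 0.8)
  genos <- lapply(1:6, function(i) {
    m <- vapply(p, function(pp) rbinom(10, 2, pp), integer(10))
    storage.mode(m) <- "integer"
    m
  })
  gm <- make_gm(genos, regions = rep(c("N", "S"), each = 3))
  am <- hierarchical_amova(gm, n_perm = 59, seed = 2)
  expect_lt(abs(am$indices["FstT"]), 0.02)
  expect_gt(am$p_values["FstT"], 0.05)
  ## near-fixation limit: regions close to alternate alleles, pops
  ## identical within regions (a little within-pop het keeps the
  ## within-region denominator positive)
  gm2 <- make_gm(list(geno_counts(9, 1, 0, 50), geno_counts(9, 1, 0, 50),
                      geno_counts(0, 1, 9, 50), geno_counts(0, 1, 9, 50)),
                 regions = c("N", "N", "S", "S"))
  am2 <- hierarchical_amova(gm2, n_perm = 0)
  expect_gt(am2$indices["FstR"], 0.85)
  ## Vb is a moment estimate and goes slightly negative here (flagged);
  ## its magnitude stays at the 1/n level
  expect_lt(abs(am2$indices["FstPR"]), 0.06)
  expect_true(am2$negative_components)
  ## index identity and percent partition
  expect_equal((1 - am$indices["FstR"]) * (1 - am$indices["FstPR"]),
               1 - am$indices["FstT"], tolerance = 1e-12,
               ignore_attr = TRUE)
  if (all(am$components >= 0))
    expect_equal(sum(am$percent), 100, tolerance = 1e-9)
  ## strong structure is detected as significant
  sim <- suppressWarnings(simulate_hierarchical_genotypes(
    pop_sim_config(n_loci = 200, seed = 6)))
  am3 <- hierarchical_amova(sim$matrix, n_perm = 59, seed = 3)
  expect_lt(am3$p_values["FstR"], 0.05)
  expect_lt(am3$p_values["FstT"], 0.05)
})

test_that("pairwise Fst limits and two-population recovery", {
  ## identical allele frequencies: theta ~ 0
  set.seed(9)
  p <- runif(400, 0.3, 0.7)
  mk <- function() {
    m <- vapply(p, function(pp) rbinom(15, 2, pp), integer(15))
    storage.mode(m) <- "integer"
    m
  }
  gm <- make_gm(list(mk(), mk()))
  pw <- pairwise_fst(gm, n_perm = 0)
  expect_lt(abs(pw$fst[1, 2]), 0.02)
  ## fixed alternate alleles: theta = 1
  gm2 <- make_gm(list(geno_counts(10, 0, 0, 20), geno_counts(0, 0, 10, 20)))
  expect_equal(pairwise_fst(gm2, n_perm = 0)$fst[1, 2], 1)
  ## two Balding-Nichols populations at theta 0.1: recovered +- 0.02
  cfg <- pop_sim_config(n_regions = 1, pops_per_region = 2,
                        n_per_pop = 25, n_loci = 2000, theta_region = 0,
                        theta_pop = 0.1, inbreeding_per_pop = 0,
                        seed = 17)
  sim <- simulate_hierarchical_genotypes(cfg)
  pw3 <- pairwise_fst(sim$matrix, n_perm = 0)
  expect_lt(abs(pw3$fst[1, 2] - 0.1), 0.02)
  ## permutation p-value flags differentiation
  pw4 <- pairwise_fst(gm2, n_perm = 59, seed = 1)
  expect_lt(pw4$p_values[1, 2], 0.05)
})

test_that("genetic distances follow the codominant squared scheme", {
  calls <- rbind(a = c(0L, 0L, 1L, 1L), b = c(0L, 2L, 1L, 2L),
                 d = c(0L, 0L, 1L, NA))
  gm <- genotype_matrix(calls,
                        data.frame(sample_id = c("a", "b", "d")))
  D <- genetic_distance_matrix(gm)
  expect_equal(D["a", "a"], 0)
  expect_equal(D["a", "b"], (0 + 4 + 0 + 1) / 4)
  expect_equal(D["a", "d"], 0 / 3)          # missing locus excluded
  expect_equal(D["b", "d"], (0 + 4 + 0) / 3)
  ## single locus AA vs BB: distance 4
  gm2 <- genotype_matrix(matrix(c(0L, 2L), 2, 1),
                         data.frame(sample_id = c("x", "y")))
  expect_equal(genetic_distance_matrix(gm2)["x", "y"], 4)
})

test_that("PCoA closed forms and distance reconstruction", {
  ## three mutually equidistant points: two equal axes, 50% each
  d2 <- matrix(1, 3, 3) - diag(3)
  pc <- pcoa(d2, n_axes = 2)
  expect_equal(pc$percent, c(50, 50), tolerance = 1e-9)
  ## collinear points: first axis explains 100%
  x <- c(0, 1, 3, 7)
  d2l <- outer(x, x, function(a, b) (a - b)^2)
  pcl <- pcoa(d2l, n_axes = 2)
  expect_equal(pcl$percent[1], 100, tolerance = 1e-9)
  ## reconstruction: squared inter-point distances reproduce the input
  set.seed(3)
  pts <- matrix(rnorm(20), 5, 4)
  d2r <- as.matrix(dist(pts))^2
  pcr <- pcoa(d2r, n_axes = 4)
  rec <- as.matrix(dist(pcr$coordinates))^2
  expect_equal(rec, d2r, tolerance = 1e-9, ignore_attr = TRUE)
  ## agreement with classical MDS from stats
  cmd <- cmdscale(sqrt(d2r), k = 2, eig = TRUE)
  expect_equal(abs(pcr$coordinates[, 1:2]), abs(cmd$points),
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("subset resampling degenerates and is deterministic", {
  sim <- simulate_hierarchical_genotypes(
    pop_sim_config(n_regions = 2, pops_per_region = c(2, 2),
                   n_per_pop = 10, n_loci = 120,
                   inbreeding_per_pop = 0, seed = 23))
  gm <- sim$matrix
  ## sets of all loci equal the full-panel estimate
  rs_all <- subset_resampling(gm, set_size = 120, n_sets = 3, seed = 1)
  am <- hierarchical_amova(gm, n_perm = 0)
  expect_equal(unique(round(rs_all$FstT, 12)),
               round(unname(am$indices["FstT"]), 12))
  ## same seed, same sets
  expect_equal(subset_resampling(gm, 30, 5, seed = 2),
               subset_resampling(gm, 30, 5, seed = 2))
  expect_error(subset_resampling(gm, 500, 2), "set_size")
})

test_that("site frequency spectrum binning", {
  sfs <- site_frequency_spectrum(c(0, 0.004, 0.25))
  expect_equal(sfs$count[1], 2)                     # rare bin
  expect_equal(sum(sfs$count), 3)
  expect_equal(sfs$count[sfs$bin == "(0.2,0.25]"], 1)
  ## all monomorphic: everything rare
  sfs2 <- site_frequency_spectrum(rep(0, 10))
  expect_equal(sfs2$count[1], 10)
  ## NA maf dropped
  expect_equal(sum(site_frequency_spectrum(c(0.1, NA))$count), 1)
})

test_that("Evanno delta-K: frozen example, flat tables, planted truth", {
  ## means (-1000, -800, -790, -788) with sd(L(2)) = 2 gives deltaK(2) = 95
  mk_runs <- function(m, spread) c(m - spread, m + spread)
  tbl <- data.frame(
    K = rep(1:4, each = 2), run = rep(1:2, 4),
    lnP = c(mk_runs(-1000, 1), mk_runs(-800, sqrt(2)),
            mk_runs(-790, 1), mk_runs(-788, 1)))
  ev <- evanno_delta_k(tbl)
  expect_equal(ev$sd_l[2], 2)
  expect_equal(ev$delta_k[2], 95)
  expect_true(is.na(ev$delta_k[1]) && is.na(ev$delta_k[4]))
  expect_equal(attr(ev, "best_k"), 2)
  ## linear mean likelihood: deltaK 0 at interior K
  tbl2 <- data.frame(K = rep(1:5, each = 2), run = rep(1:2, 5),
                     lnP = rep(seq(-900, -500, by = 100), each = 2) +
                       c(-1, 1))
  ev2 <- evanno_delta_k(tbl2)
  expect_equal(ev2$delta_k[2:4], rep(0, 3))
  ## zero sd excluded with warning
  tbl3 <- tbl
  tbl3$lnP[tbl3$K == 3] <- -790
  expect_warning(ev3 <- evanno_delta_k(tbl3), "zero")
  expect_true(is.na(ev3$delta_k[3]))
  ## planted kink recovered
  lk <- simulate_structure_likelihoods(k_true = 3, k_range = 1:10,
                                       runs = 10, noise_sd = 10, seed = 5)
  expect_equal(attr(evanno_delta_k(lk), "best_k"), 3)
})

test_that("hypervariable multiallelic loci: higher He, damped theta", {
  bi <- simulate_multiallelic_genotypes(n_pops = 8, n_per_pop = 15,
                                        n_loci = 40, n_alleles = 2,
                                        theta = 0.25, mu = 0, seed = 2)
  ms <- simulate_multiallelic_genotypes(n_pops = 8, n_per_pop = 15,
                                        n_loci = 40, n_alleles = 10,
                                        theta = 0.25, mu = 0.08, seed = 2)
  he_bi <- mean(ms_diversity(bi$a1, bi$a2, bi$pops)$He)
  he_ms <- mean(ms_diversity(ms$a1, ms$a2, ms$pops)$He)
  th_bi <- ms_theta(bi$a1, bi$a2, bi$pops)
  th_ms <- ms_theta(ms$a1, ms$a2, ms$pops)
  expect_gt(he_ms, he_bi)
  expect_lt(th_ms, th_bi)
  ## biallelic route agrees with the dosage-based estimator
  dose <- (bi$a1 == 2) + (bi$a2 == 2)
  storage.mode(dose) <- "integer"
  expect_equal(ms_theta(bi$a1, bi$a2, bi$pops),
               wc_theta(dose, bi$pops), tolerance = 1e-10)
})
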