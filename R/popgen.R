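## Per-population, per-locus summaries from a dosage matrix.
## Returns pops x loci matrices: n (called individuals), p (B-allele
## frequency) and h (observed het fraction).
pop_locus_stats <- function(calls, pops) {
  pops <- factor(pops)
  called <- !is.na(calls)
  n <- rowsum(called + 0, pops)
  dose <- calls
  dose[!called] <- 0L
  p <- rowsum(dose + 0, pops) / (2 * n)
  h <- rowsum((calls == 1 & called) + 0, pops) / n
  p[n == 0] <- NA
  h[n == 0] <- NA
  list(n = n, p = p, h = h, pops = levels(pops))
}

#' Per-population allele frequencies
#'
#' Allele-count frequencies of the B allele among called genotypes, per
#' population and locus, with the number of called individuals.
#'
#' @param gm a [genotype_matrix()] with `population` sample metadata.
#' @return list with matrices `p` (frequencies, `NA` where a population
#'   has no calls) and `n` (called individuals), populations in rows.
#' @export
allele_frequencies <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"),
            !is.null(gm$samples$population))
  st <- pop_locus_stats(gm$calls, gm$samples$population)
  list(p = st$p, n = st$n)
}

## Weir-Cockerham within-population components per locus for one
## population: b (among individuals within pop) and c (within individuals).
## Loci with fewer than 2 called individuals return NA.
wc_bc <- function(n, p, h) {
  ok <- !is.na(n) & n >= 2
  b <- c <- rep(NA_real_, length(n))
  b[ok] <- (n[ok] / (n[ok] - 1)) *
    (p[ok] * (1 - p[ok]) - (2 * n[ok] - 1) / (4 * n[ok]) * h[ok])
  c[ok] <- h[ok] / 2
  list(b = b, c = c)
}

## multilocus f = 1 - sum(c)/sum(b + c) over loci (ratio of sums)
wc_f_from_bc <- function(b, c) {
  s <- sum(b + c, na.rm = TRUE)
  if (s == 0) return(NA_real_)
  1 - sum(c, na.rm = TRUE) / s
}

#' Diversity and inbreeding summary per population
#'
#' Per population: observed heterozygosity `Ho` (mean over loci of the
#' observed het fraction), Nei's unbiased expected heterozygosity
#' `He = (2n/(2n-1)) (1 - p^2 - q^2)` averaged over loci, and the
#' Weir–Cockerham within-population inbreeding estimator `f`, multilocus
#' as a ratio of sums over loci, with a percentile bootstrap CI over loci.
#' `f` is declared significant when its CI excludes zero. Regional rows
#' are unweighted means of the per-population values; the overall row uses
#' unweighted means for Ho/He and pools the variance components across
#' populations for `f`.
#'
#' Populations with fewer than 2 genotyped individuals are excluded with a
#' warning.
#'
#' @param gm a [genotype_matrix()] with `population` (and optionally
#'   `region`) metadata.
#' @param n_boot bootstrap replicates over loci (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return list with data.frames `populations`, `regions`, `overall`.
#' @export
diversity_summary <- function(gm, n_boot = 1000, seed = 1, conf = 0.95) {
  stopifnot(inherits(gm, "genotype_matrix"),
            !is.null(gm$samples$population))
  pops <- factor(gm$samples$population)
  small <- names(which(table(pops) < 2))
  if (length(small)) {
    warning("populations with < 2 individuals excluded: ",
            paste(small, collapse = ", "))
    keep <- !(gm$samples$population %in% small)
    gm <- subset_samples(gm, keep)
    pops <- factor(gm$samples$population)
  }
  st <- pop_locus_stats(gm$calls, pops)
  L <- ncol(st$n)
  alpha <- (1 - conf) / 2
  set.seed(seed)
  boot_idx <- matrix(sample.int(L, L * n_boot, replace = TRUE), n_boot, L)

  per_pop <- lapply(seq_along(st$pops), function(k) {
    n <- st$n[k, ]; p <- st$p[k, ]; h <- st$h[k, ]
    he_l <- (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
    bc <- wc_bc(n, p, h)
    f <- wc_f_from_bc(bc$b, bc$c)
    fb <- apply(boot_idx, 1, function(idx)
      wc_f_from_bc(bc$b[idx], bc$c[idx]))
    ci <- quantile(fb, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    data.frame(population = st$pops[k],
               n = max(st$n[k, ], na.rm = TRUE),
               Ho = mean(h, na.rm = TRUE), He = mean(he_l, na.rm = TRUE),
               f = f, ci_lower = ci[1], ci_upper = ci[2],
               significant = ci[1] > 0 | ci[2] < 0,
               b_sum = sum(bc$b, na.rm = TRUE),
               c_sum = sum(bc$c, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  pop_df <- do.call(rbind, per_pop)

  if (!is.null(gm$samples$region)) {
    reg_of_pop <- gm$samples$region[match(pop_df$population,
                                          gm$samples$population)]
    pop_df$region <- reg_of_pop
    reg_df <- aggregate(pop_df[, c("Ho", "He", "f")],
                        list(region = reg_of_pop), mean)
  } else reg_df <- NULL

  ## overall f pools b and c across populations and loci
  B <- rowsum(do.call(rbind, lapply(seq_along(st$pops), function(k)
    wc_bc(st$n[k, ], st$p[k, ], st$h[k, ])$b)),
    rep(1, length(st$pops)), na.rm = TRUE)[1, ]
  C <- rowsum(do.call(rbind, lapply(seq_along(st$pops), function(k)
    wc_bc(st$n[k, ], st$p[k, ], st$h[k, ])$c)),
    rep(1, length(st$pops)), na.rm = TRUE)[1, ]
  f_all <- wc_f_from_bc(B, C)
  fb <- apply(boot_idx, 1, function(idx) wc_f_from_bc(B[idx], C[idx]))
  ci <- quantile(fb, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  overall <- data.frame(Ho = mean(pop_df$Ho), He = mean(pop_df$He),
                        f = f_all, ci_lower = ci[1], ci_upper = ci[2],
                        significant = ci[1] > 0 | ci[2] < 0)
  pop_df$b_sum <- pop_df$c_sum <- NULL
  list(populations = pop_df, regions = reg_df, overall = overall)
}

## Weir-Cockerham (1984) theta components per locus across populations.
## n, p, h are pops x loci matrices; returns per-locus a, b, c summed
## over the two alleles of a biallelic locus (factor 2, which cancels in
## the ratio but keeps the components on the documented scale).
wc_theta_components <- function(n, p, h) {
  L <- ncol(n)
  a <- b <- c <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    use <- !is.na(n[, l]) & n[, l] >= 1
    r <- sum(use)
    if (r < 2) next
    ni <- n[use, l]; pi <- p[use, l]; hi <- h[use, l]
    N <- sum(ni)
    nbar <- N / r
    if (nbar <= 1) next
    nc <- (N - sum(ni^2) / N) / (r - 1)
    if (nc <= 0) next
    pbar <- sum(ni * pi) / N
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / N
    inner <- pbar * (1 - pbar) - ((r - 1) / r) * s2
    a[l] <- 2 * (nbar / nc) *
      (s2 - (inner - hbar / 4) / (nbar - 1))
    b[l] <- 2 * (nbar / (nbar - 1)) *
      (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
    c[l] <- 2 * hbar / 2
  }
  list(a = a, b = b, c = c)
}

#' Multilocus Weir–Cockerham theta
#'
#' The 1984 differentiation estimator across the supplied populations,
#' multilocus as a ratio of sums of the per-locus variance components.
#'
#' @param calls dosage matrix (samples x loci, 0/1/2/NA).
#' @param pops population labels per sample.
#' @return the theta estimate (scalar).
#' @export
wc_theta <- function(calls, pops) {
  st <- pop_locus_stats(calls, pops)
  cp <- wc_theta_components(st$n, st$p, st$h)
  tot <- sum(cp$a + cp$b + cp$c, na.rm = TRUE)
  if (tot == 0) return(NA_real_)
  sum(cp$a, na.rm = TRUE) / tot
}

#' Pairwise Fst between populations
#'
#' Weir–Cockerham theta for every pair of populations (multilocus ratio of
#' sums) with optional permutation p-values obtained by shuffling
#' individuals between the two populations. When regions are available,
#' block means of the pairwise values (within each region and between
#' regions) are reported.
#'
#' @param gm a [genotype_matrix()].
#' @param n_perm permutations per pair (0 disables testing; default 999).
#' @param seed integer seed.
#' @return list with `fst` (symmetric matrix), `p_values` (or NULL) and
#'   `block_means`.
#' @export
pairwise_fst <- function(gm, n_perm = 999, seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"),
            !is.null(gm$samples$population))
  set.seed(seed)
  pop <- gm$samples$population
  ids <- sort(unique(pop))
  k <- length(ids)
  stopifnot(k >= 2)
  fst <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  diag(fst) <- 0
  pv <- if (n_perm > 0) fst else NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sel <- pop %in% c(ids[i], ids[j])
    calls <- gm$calls[sel, , drop = FALSE]
    labs <- pop[sel]
    obs <- wc_theta(calls, labs)
    fst[i, j] <- fst[j, i] <- obs
    if (n_perm > 0) {
      ge <- 0
      for (b in seq_len(n_perm)) {
        if (wc_theta(calls, sample(labs)) >= obs) ge <- ge + 1
      }
      pv[i, j] <- pv[j, i] <- (1 + ge) / (n_perm + 1)
    }
  }
  block_means <- NULL
  if (!is.null(gm$samples$region)) {
    reg <- gm$samples$region[match(ids, gm$samples$population)]
    ut <- upper.tri(fst)
    same <- outer(reg, reg, "==")
    block_means <- c(
      setNames(vapply(unique(reg), function(r)
        mean(fst[ut & same & outer(reg == r, reg == r, "&")]),
        numeric(1)), paste0("within_", unique(reg))),
      between = mean(fst[ut & !same]))
  }
  list(fst = fst, p_values = pv, block_means = block_means)
}

## Allele-level hierarchical variance components summed over loci.
## region/pop are per-sample labels; returns c(Va, Vb, Vc).
amova_components <- function(calls, region, pop) {
  pop <- as.character(pop); region <- as.character(region)
  st <- pop_locus_stats(calls, pop)
  n2 <- 2 * st$n                                  # allele copies
  reg_of_pop <- region[match(st$pops, pop)]
  Va <- Vb <- Vc <- 0
  G_all <- unique(reg_of_pop)
  for (l in seq_len(ncol(n2))) {
    np <- n2[, l]
    use <- np > 0
    if (sum(use) < 2) next
    np <- np[use]
    pp <- st$p[use, l]
    rg <- reg_of_pop[use]
    N <- sum(np)
    P <- length(np)
    G <- length(unique(rg))
    if (G < 2 || P <= G || N <= P) next
    Ng <- rowsum(np, rg)[, 1]
    pg <- rowsum(np * pp, rg)[, 1] / Ng
    pbar <- sum(np * pp) / N
    ss_wp <- 2 * sum(np * pp * (1 - pp))
    ss_ap <- 2 * sum(np * (pp - pg[rg])^2)
    ss_ar <- 2 * sum(Ng * (pg - pbar)^2)
    Sg <- rowsum(np^2, rg)[, 1]
    n1 <- (N - sum(Sg / Ng)) / (P - G)
    n2c <- (sum(Sg / Ng) - sum(np^2) / N) / (G - 1)
    n3 <- (N - sum(Ng^2) / N) / (G - 1)
    sc <- ss_wp / (N - P)
    sb <- (ss_ap / (P - G) - sc) / n1
    sa <- (ss_ar / (G - 1) - sc - n2c * sb) / n3
    Va <- Va + sa; Vb <- Vb + sb; Vc <- Vc + sc
  }
  c(Va = Va, Vb = Vb, Vc = Vc)
}

amova_indices <- function(v) {
  tot <- sum(v)
  c(FstR = unname(v[1] / tot),
    FstPR = unname(v[2] / (v[2] + v[3])),
    FstT = unname((v[1] + v[2]) / tot))
}

#' Hierarchical AMOVA over regions, populations and individuals
#'
#' Allele-level analysis of molecular variance: per locus, sums of squares
#' among regions, among populations within regions and within populations
#' are converted to variance components with the unbalanced-design
#' coefficients of the nested ANOVA, then summed over loci. The three
#' fixation indices are `FstR = Va/(Va+Vb+Vc)`,
#' `FstP/R = Vb/(Vb+Vc)` and `FstT = (Va+Vb)/(Va+Vb+Vc)`, which satisfy
#' `(1-FstR)(1-FstP/R) = (1-FstT)` by construction. Negative components
#' (possible with moment estimators) are retained and flagged.
#'
#' Permutation p-values: whole populations are permuted among regions for
#' `FstR`; individuals among populations within their region for
#' `FstP/R`; individuals among all populations for `FstT`.
#'
#' @param gm a [genotype_matrix()] with `population` and `region`
#'   metadata.
#' @param n_perm permutations (0 disables; default 999).
#' @param seed integer seed.
#' @return an `amova_result` list: `components`, `percent`, `indices`,
#'   `p_values`, `negative_components`.
#' @export
hierarchical_amova <- function(gm, n_perm = 999, seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"),
            !is.null(gm$samples$population),
            !is.null(gm$samples$region))
  set.seed(seed)
  pop <- gm$samples$population
  region <- gm$samples$region
  stopifnot("need >= 2 regions" = length(unique(region)) >= 2)
  obs_v <- amova_components(gm$calls, region, pop)
  obs <- amova_indices(obs_v)
  pvals <- c(FstR = NA_real_, FstPR = NA_real_, FstT = NA_real_)
  if (n_perm > 0) {
    pops_u <- unique(pop)
    reg_of_pop <- region[match(pops_u, pop)]
    ge <- c(0, 0, 0)
    for (b in seq_len(n_perm)) {
      ## (a) permute populations among regions
      pr <- setNames(sample(reg_of_pop), pops_u)
      ia <- amova_indices(amova_components(gm$calls, pr[pop], pop))
      ## (b) permute individuals among pops within regions
      pop_b <- pop
      for (r in unique(region)) {
        idx <- which(region == r)
        pop_b[idx] <- pop[idx][sample.int(length(idx))]
      }
      ib <- amova_indices(amova_components(gm$calls, region, pop_b))
      ## (c) permute individuals among all populations
      ord <- sample.int(length(pop))
      ic <- amova_indices(amova_components(gm$calls, region[ord],
                                           pop[ord]))
      ge <- ge + c(ia["FstR"] >= obs["FstR"],
                   ib["FstPR"] >= obs["FstPR"],
                   ic["FstT"] >= obs["FstT"])
    }
    pvals[] <- (1 + ge) / (n_perm + 1)
  }
  structure(list(
    components = obs_v,
    percent = 100 * obs_v / sum(obs_v),
    indices = obs,
    p_values = pvals,
    negative_components = any(obs_v < 0)),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Hierarchical AMOVA (allele level)\n")
  df <- data.frame(
    source = c("Among regions", "Among populations within regions",
               "Within populations"),
    variance = unname(x$components),
    percent = round(unname(x$percent), 2))
  print(df, row.names = FALSE)
  cat(sprintf("FstR = %.4f  FstP/R = %.4f  FstT = %.4f\n",
              x$indices["FstR"], x$indices["FstPR"], x$indices["FstT"]))
  if (!all(is.na(x$p_values)))
    cat(sprintf("permutation p: %.4g / %.4g / %.4g\n",
                x$p_values[1], x$p_values[2], x$p_values[3]))
  if (x$negative_components)
    cat("note: negative variance component(s) retained\n")
  invisible(x)
}

#' Squared genetic distances between individuals
#'
#' Codominant squared distance per locus: `d2 = (x - y)^2` on the
#' genotype dosage scale, i.e. `d2(AA,AB) = 1`, `d2(AA,BB) = 4`,
#' `d2(AB,AB) = 0`, `d2(AB,BB) = 1`, summed over co-called loci and
#' divided by the number of co-called loci (so pairs with different
#' missingness are comparable). Loci missing in either individual are
#' excluded pairwise.
#'
#' @param gm a [genotype_matrix()].
#' @return symmetric matrix of mean per-locus squared distances.
#' @export
genetic_distance_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  X <- gm$calls
  M <- (!is.na(X)) + 0
  P <- X; P[is.na(P)] <- 0
  Q <- P^2
  co <- M %*% t(M)
  d2 <- Q %*% t(M) + M %*% t(Q) - 2 * P %*% t(P)
  if (any(co == 0 & row(co) != col(co)))
    warning("some individual pairs share no co-called loci")
  out <- d2 / co
  diag(out) <- 0
  dimnames(out) <- list(rownames(X), rownames(X))
  out
}

#' Principal coordinate analysis
#'
#' Classical metric MDS by Gower double-centering of the squared-distance
#' matrix and eigendecomposition. Axes are sorted by eigenvalue and the
#' percentage of variance per axis is computed over the positive
#' eigenvalues only.
#'
#' @param d2 symmetric matrix of *squared* distances with zero diagonal
#'   (e.g. from [genetic_distance_matrix()]).
#' @param n_axes number of axes to return (default 3).
#' @return list with `coordinates` (individuals x axes), `eigenvalues`
#'   and `percent` (variance explained per returned axis).
#' @export
pcoa <- function(d2, n_axes = 3) {
  stopifnot(is.matrix(d2), nrow(d2) == ncol(d2),
            max(abs(d2 - t(d2))) < 1e-8, all(abs(diag(d2)) < 1e-12))
  n <- nrow(d2)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-9 * max(abs(e$values))
  n_axes <- min(n_axes, sum(pos))
  coords <- e$vectors[, seq_len(n_axes), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(n_axes)]), n_axes)
  rownames(coords) <- rownames(d2)
  colnames(coords) <- paste0("Axis", seq_len(n_axes))
  list(coordinates = coords, eigenvalues = e$values,
       percent = 100 * e$values[seq_len(n_axes)] / sum(e$values[pos]))
}

#' Resample random SNP subsets and re-estimate the parameter suite
#'
#' Draws `n_sets` random sets of `set_size` loci without replacement
#' within each set and recomputes overall Ho, He, f and the three AMOVA
#' fixation indices per set. Used to show that modest SNP panels recover
#' the full-panel estimates.
#'
#' @param gm a [genotype_matrix()] with population and region metadata.
#' @param set_size loci per set (default 80).
#' @param n_sets number of sets (default 50).
#' @param seed integer seed.
#' @return data.frame with one row per set and columns `set`, `Ho`, `He`,
#'   `f`, `FstR`, `FstPR`, `FstT`; attribute `means` holds column means.
#' @export
subset_resampling <- function(gm, set_size = 80, n_sets = 50, seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"),
            set_size <= ncol(gm$calls))
  seeds <- derive_seeds(seed, n_sets)
  rows <- lapply(seq_len(n_sets), function(s) {
    set.seed(seeds[s])
    idx <- sample.int(ncol(gm$calls), set_size)
    sub <- subset_loci(gm, idx)
    st <- pop_locus_stats(sub$calls, sub$samples$population)
    he <- (2 * st$n / (2 * st$n - 1)) * (1 - st$p^2 - (1 - st$p)^2)
    bc_all <- lapply(seq_along(st$pops), function(k)
      wc_bc(st$n[k, ], st$p[k, ], st$h[k, ]))
    f <- wc_f_from_bc(unlist(lapply(bc_all, `[[`, "b")),
                      unlist(lapply(bc_all, `[[`, "c")))
    am <- amova_indices(amova_components(sub$calls,
                                         sub$samples$region,
                                         sub$samples$population))
    data.frame(set = s, Ho = mean(rowMeans(st$h, na.rm = TRUE)),
               He = mean(rowMeans(he, na.rm = TRUE)), f = f,
               FstR = am["FstR"], FstPR = am["FstPR"], FstT = am["FstT"],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "means") <- colMeans(out[, -1])
  out
}

#' Site frequency spectrum of minor allele frequencies
#'
#' Histogram of per-SNP MAF with a dedicated first bin for rare SNPs
#' (`MAF <= rare_cutoff`), then regular bins of `bin_width` up to 0.5.
#' SNPs with undefined MAF are dropped.
#'
#' @param maf numeric vector of minor allele frequencies.
#' @param rare_cutoff the rare-SNP boundary (default 0.005, inclusive).
#' @param bin_width width of the regular bins (default 0.05).
#' @return data.frame `bin`, `count`.
#' @export
site_frequency_spectrum <- function(maf, rare_cutoff = 0.005,
                                    bin_width = 0.05) {
  maf <- maf[!is.na(maf)]
  breaks <- unique(c(rare_cutoff, seq(bin_width, 0.5, by = bin_width)))
  labs <- c(sprintf("<=%.3g", rare_cutoff),
            sprintf("(%.3g,%.3g]", c(rare_cutoff, head(breaks[-1], -1)),
                    breaks[-1]))
  bin <- cut(maf, breaks = c(-Inf, breaks), labels = labs, right = TRUE)
  as.data.frame(table(bin = bin), responseName = "count")
}

#' Evanno delta-K from STRUCTURE-style likelihood tables
#'
#' Per K: mean and sd of the replicate log-likelihoods, the first and
#' absolute second differences of the means, and
#' `deltaK = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))`, defined for interior
#' K only. The arg-max of deltaK over interior K with positive sd is the
#' suggested number of clusters.
#'
#' @param tbl data.frame with columns `K`, `run`, `lnP` (>= 2 runs per K,
#'   contiguous K range of length >= 3).
#' @return data.frame per K with `mean_l`, `sd_l`, `l_prime`,
#'   `l_doubleprime`, `delta_k`; attribute `best_k`.
#' @export
evanno_delta_k <- function(tbl) {
  stopifnot(all(c("K", "run", "lnP") %in% names(tbl)))
  ks <- sort(unique(tbl$K))
  stopifnot_cfg(
    "K range must be contiguous and of length >= 3" =
      length(ks) >= 3 && all(diff(ks) == 1),
    ">= 2 runs per K required" = all(table(tbl$K) >= 2))
  mean_l <- tapply(tbl$lnP, tbl$K, mean)[as.character(ks)]
  sd_l <- tapply(tbl$lnP, tbl$K, sd)[as.character(ks)]
  nk <- length(ks)
  l_prime <- c(NA, diff(mean_l))
  l_dp <- rep(NA_real_, nk)
  l_dp[2:(nk - 1)] <- abs(mean_l[3:nk] - 2 * mean_l[2:(nk - 1)] +
                            mean_l[1:(nk - 2)])
  delta_k <- l_dp / sd_l
  if (any(sd_l == 0, na.rm = TRUE)) {
    warning("zero run-to-run sd at some K; deltaK undefined there")
    delta_k[sd_l == 0] <- NA
  }
  out <- data.frame(K = ks, mean_l = as.numeric(mean_l),
                    sd_l = as.numeric(sd_l),
                    l_prime = as.numeric(l_prime),
                    l_doubleprime = l_dp, delta_k = delta_k)
  attr(out, "best_k") <- if (all(is.na(delta_k))) NA_integer_ else
    ks[which.max(delta_k)]
  out
}
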