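#' Simulate multiallelic (microsatellite-style) genotypes
#'
#' One-level island model with Dirichlet-distributed population allele
#' frequencies around an ancestral frequency vector, the multiallelic
#' generalisation of the Balding–Nichols Beta model:
#' `p_pop ~ Dirichlet(p_anc (1 - theta) / theta)`. A per-allele-copy
#' mutation to a uniformly random allele (rate `mu`) emulates the
#' recurrent mutation of hypervariable markers; homoplasy from such
#' mutation is what dampens differentiation estimates at microsatellites
#' relative to SNPs. With `n_alleles = 2` and `mu = 0` this reduces to a
#' biallelic island model.
#'
#' @param n_pops populations.
#' @param n_per_pop diploid individuals per population.
#' @param n_loci loci.
#' @param n_alleles alleles per locus.
#' @param theta differentiation parameter in `(0, 1)`.
#' @param mu per-allele-copy mutation rate (default 0).
#' @param seed integer seed.
#' @return list with integer allele matrices `a1`, `a2` (samples x loci)
#'   and `pops` labels.
#' @export
simulate_multiallelic_genotypes <- function(n_pops = 15, n_per_pop = 12,
                                            n_loci = 8, n_alleles = 10,
                                            theta = 0.3, mu = 0,
                                            seed = 1) {
  stopifnot(theta > 0, theta < 1, n_alleles >= 2)
  set.seed(seed)
  lam <- (1 - theta) / theta
  n_tot <- n_pops * n_per_pop
  a1 <- a2 <- matrix(NA_integer_, n_tot, n_loci)
  pops <- rep(sprintf("P%02d", seq_len(n_pops)), each = n_per_pop)
  rdirichlet1 <- function(alpha) {
    g <- rgamma(length(alpha), shape = alpha)
    g / sum(g)
  }
  for (l in seq_len(n_loci)) {
    anc <- rdirichlet1(rep(1, n_alleles))
    for (k in seq_len(n_pops)) {
      pk <- rdirichlet1(anc * lam)
      rows <- (k - 1) * n_per_pop + seq_len(n_per_pop)
      a1[rows, l] <- sample.int(n_alleles, n_per_pop, TRUE, prob = pk)
      a2[rows, l] <- sample.int(n_alleles, n_per_pop, TRUE, prob = pk)
    }
  }
  if (mu > 0) {
    hit <- runif(length(a1)) < mu
    a1[hit] <- sample.int(n_alleles, sum(hit), TRUE)
    hit <- runif(length(a2)) < mu
    a2[hit] <- sample.int(n_alleles, sum(hit), TRUE)
  }
  list(a1 = a1, a2 = a2, pops = pops)
}

## per-pop per-locus allele freq list and het-by-allele for multiallelic
## data; returns for locus l a list(n = named vec, p = alleles x pops,
## h = alleles x pops)
ms_locus_stats <- function(a1, a2, pops, l) {
  pops <- factor(pops)
  ok <- !is.na(a1[, l]) & !is.na(a2[, l])
  alleles <- sort(unique(c(a1[ok, l], a2[ok, l])))
  pl <- levels(pops)
  n <- tapply(ok, pops, sum)
  p <- h <- matrix(0, length(alleles), length(pl),
                   dimnames = list(alleles, pl))
  het <- a1[, l] != a2[, l]
  for (j in seq_along(pl)) {
    idx <- which(ok & pops == pl[j])
    if (!length(idx)) next
    cnt <- table(factor(c(a1[idx, l], a2[idx, l]), levels = alleles))
    p[, j] <- as.numeric(cnt) / (2 * length(idx))
    for (ai in seq_along(alleles)) {
      h[ai, j] <- mean(het[idx] &
                         (a1[idx, l] == alleles[ai] |
                            a2[idx, l] == alleles[ai]))
    }
  }
  list(n = n, p = p, h = h)
}

#' Diversity summary for multiallelic genotypes
#'
#' Observed heterozygosity (fraction of heterozygous individuals) and
#' Nei's unbiased expected heterozygosity `(2n/(2n-1))(1 - sum p_a^2)`,
#' per population averaged over loci.
#'
#' @param a1,a2 integer allele matrices (samples x loci).
#' @param pops population labels.
#' @return data.frame `population`, `Ho`, `He`.
#' @export
ms_diversity <- function(a1, a2, pops) {
  pops <- factor(pops)
  pl <- levels(pops)
  ho <- he <- matrix(NA_real_, length(pl), ncol(a1))
  for (l in seq_len(ncol(a1))) {
    st <- ms_locus_stats(a1, a2, pops, l)
    for (j in seq_along(pl)) {
      n <- st$n[pl[j]]
      if (is.na(n) || n < 2) next
      idx <- which(pops == pl[j] & !is.na(a1[, l]) & !is.na(a2[, l]))
      ho[j, l] <- mean(a1[idx, l] != a2[idx, l])
      he[j, l] <- (2 * n / (2 * n - 1)) * (1 - sum(st$p[, j]^2))
    }
  }
  data.frame(population = pl, Ho = rowMeans(ho, na.rm = TRUE),
             He = rowMeans(he, na.rm = TRUE), stringsAsFactors = FALSE)
}

#' Multilocus Weir–Cockerham theta for multiallelic genotypes
#'
#' The 1984 estimator generalised over alleles: per locus and allele the
#' variance components are computed from per-population allele
#' frequencies and heterozygote frequencies involving that allele, then
#' summed over alleles and loci (ratio of sums).
#'
#' @inheritParams ms_diversity
#' @return the theta estimate (scalar).
#' @export
ms_theta <- function(a1, a2, pops) {
  pops <- factor(pops)
  A <- B <- C <- 0
  for (l in seq_len(ncol(a1))) {
    st <- ms_locus_stats(a1, a2, pops, l)
    use <- !is.na(st$n) & st$n >= 1
    if (sum(use) < 2) next
    ni <- st$n[use]
    r <- length(ni)
    N <- sum(ni)
    nbar <- N / r
    if (nbar <= 1) next
    nc <- (N - sum(ni^2) / N) / (r - 1)
    for (ai in seq_len(nrow(st$p))) {
      pi <- st$p[ai, use]
      hi <- st$h[ai, use]
      pbar <- sum(ni * pi) / N
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / N
      inner <- pbar * (1 - pbar) - ((r - 1) / r) * s2
      A <- A + (nbar / nc) * (s2 - (inner - hbar / 4) / (nbar - 1))
      B <- B + (nbar / (nbar - 1)) *
        (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
      C <- C + hbar / 2
    }
  }
  if (A + B + C == 0) return(NA_real_)
  A / (A + B + C)
}

#' Read a microsatellite allele-pair CSV
#'
#' Expected layout: a `sample_id` column, optional `population` column,
#' then two columns per locus named `<locus>.1` and `<locus>.2` holding
#' integer allele codes (empty or NA for missing).
#'
#' @param path CSV path.
#' @return list with `a1`, `a2`, `loci`, `sample_id` and `pops` (NULL if
#'   no population column).
#' @export
read_microsat <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot("sample_id column required" = "sample_id" %in% names(df))
  pops <- df$population
  allele_cols <- grep("\\.[12]$", names(df), value = TRUE)
  loci <- unique(sub("\\.[12]$", "", allele_cols))
  a1 <- as.matrix(df[paste0(loci, ".1")])
  a2 <- as.matrix(df[paste0(loci, ".2")])
  storage.mode(a1) <- storage.mode(a2) <- "integer"
  colnames(a1) <- colnames(a2) <- loci
  list(a1 = a1, a2 = a2, loci = loci, sample_id = df$sample_id,
       pops = pops)
}
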