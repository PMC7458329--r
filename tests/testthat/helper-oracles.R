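## Independent oracles, deliberately written as plain transliterations of
## the textbook formulas (scalar loops, no shared code with R/).

## Weir-Cockerham (1984) within-population inbreeding f for one
## population: dosage matrix (individuals x loci), multilocus ratio of
## sums over loci.
oracle_wc_f <- function(calls) {
  num <- den <- 0
  for (l in seq_len(ncol(calls))) {
    x <- calls[, l]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2) next
    p <- sum(x) / (2 * n)
    h <- mean(x == 1)
    b <- (n / (n - 1)) * (p * (1 - p) - ((2 * n - 1) / (4 * n)) * h)
    cc <- h / 2
    num <- num + cc
    den <- den + b + cc
  }
  if (den == 0) NA_real_ else 1 - num / den
}

## Weir-Cockerham (1984) theta across populations, per-locus a/b/c
## accumulated as ratio of sums.
oracle_wc_theta <- function(calls, pops) {
  pops <- as.character(pops)
  ids <- unique(pops)
  A <- B <- C <- 0
  for (l in seq_len(ncol(calls))) {
    ni <- pi <- hi <- numeric(0)
    for (pp in ids) {
      x <- calls[pops == pp, l]
      x <- x[!is.na(x)]
      if (length(x) == 0) next
      ni <- c(ni, length(x))
      pi <- c(pi, sum(x) / (2 * length(x)))
      hi <- c(hi, mean(x == 1))
    }
    r <- length(ni)
    if (r < 2) next
    N <- sum(ni)
    nbar <- N / r
    if (nbar <= 1) next
    nc <- (N - sum(ni^2) / N) / (r - 1)
    pbar <- sum(ni * pi) / N
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / N
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                             hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
                                  ((r - 1) / r) * s2 -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  if (A + B + C == 0) NA_real_ else A / (A + B + C)
}

## exhaustive DUST scoring: per window, count triplets with table()
oracle_dust_flagged <- function(seq, window = 64, threshold = 20) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  w <- min(window, n)
  flagged <- logical(max(n - w + 1, 0))
  for (s in seq_along(flagged)) {
    win <- ch[s:(s + w - 1)]
    trips <- character(0)
    for (i in seq_len(length(win) - 2)) {
      t <- win[i:(i + 2)]
      if (all(t %in% c("A", "C", "G", "T")))
        trips <- c(trips, paste(t, collapse = ""))
    }
    k <- length(trips)
    if (k < 2) next
    cnt <- table(trips)
    score <- 10 * sum(cnt * (cnt - 1) / 2) / (k - 1)
    flagged[s] <- score >= threshold
  }
  flagged
}

## mask intervals from flags exactly as the implementation merges them
oracle_dust_intervals <- function(seq, window = 64, threshold = 20) {
  fl <- oracle_dust_flagged(seq, window, threshold)
  if (!any(fl)) return(NULL)
  n <- nchar(seq)
  w <- min(window, n)
  covered <- logical(n)
  for (s in which(fl)) covered[s:min(s + w - 1, n)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

## naive occurrence count of a k-mer in reference + its reverse
## complement, scanning every window by string comparison
oracle_kmer_hits <- function(kmer, reference) {
  total <- 0
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(kmer)))
  for (sq in reference) {
    n <- nchar(sq)
    k <- nchar(kmer)
    if (n < k) next
    wins <- substring(sq, 1:(n - k + 1), k:n)
    total <- total + sum(wins == kmer) + sum(wins == rc)
  }
  ## a palindromic k-mer matches itself on both strands; count once
  if (kmer == rc) total <- total / 2
  total
}

## worst-case probe verdict via the naive scan
oracle_screen_probe <- function(sequence, reference, k = 16,
                                max_hits = 100) {
  mx <- 0
  m <- regmatches(sequence,
                  regexec("^(.*)\\[(.+)/(.+)\\](.*)$", sequence))[[1]]
  for (allele in c(m[3], m[4])) {
    sq <- paste0(m[2], allele, m[5])
    n <- nchar(sq)
    for (i in 1:(n - k + 1)) {
      km <- substr(sq, i, i + k - 1)
      if (grepl("[^ACGT]", km)) next
      mx <- max(mx, oracle_kmer_hits(km, reference))
    }
  }
  list(max_hits = mx,
       verdict = if (mx > max_hits) "not_recommended" else "recommended")
}

## small genotype matrix builder: genos is a list of per-population
## dosage matrices (individuals x loci)
make_gm <- function(genos, regions = NULL) {
  pops <- sprintf("P%02d", seq_along(genos))
  calls <- do.call(rbind, genos)
  n_per <- vapply(genos, nrow, integer(1))
  samples <- data.frame(
    sample_id = sprintf("s%03d", seq_len(nrow(calls))),
    population = rep(pops, n_per),
    stringsAsFactors = FALSE)
  if (!is.null(regions)) samples$region <- rep(regions, n_per)
  rownames(calls) <- samples$sample_id
  genotype_matrix(calls, samples)
}

## dosage matrix from genotype count triple (nAA, nAB, nBB), one locus
## replicated n_loci times
geno_counts <- function(n_aa, n_ab, n_bb, n_loci = 1) {
  matrix(rep(c(rep(0L, n_aa), rep(1L, n_ab), rep(2L, n_bb)), n_loci),
         ncol = n_loci)
}
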