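#' Extract the 71-base probe context around a catalog SNP
#'
#' Pulls `flank_len` bases on each side of the SNP and encodes the site as
#' `[ref/alt]` at the center (position `flank_len + 1`), in both the
#' forward orientation and the reverse complement, since probes are
#' designed in both directions. When fewer than `flank_len` bases exist on
#' either side the candidate pair is returned with verdict
#' `flank_too_short` and no sequence.
#'
#' @param reference named character vector of contig sequences.
#' @param contig,pos,ref,alt the SNP (1-based position).
#' @param snp_id identifier carried into the output.
#' @param flank_len flank length in bases (default 35).
#' @return data.frame with one row per strand: `snp_id`, `strand`,
#'   `sequence`, `verdict` ("unscreened" or "flank_too_short").
#' @export
extract_probe_context <- function(reference, contig, pos, ref, alt,
                                  snp_id = sprintf("%s:%d", contig, pos),
                                  flank_len = 35) {
  sq <- reference[[contig]]
  if (is.null(sq)) stop("unknown contig: ", contig, call. = FALSE)
  n <- nchar(sq)
  if (pos < 1 || pos > n)
    stop("SNP position outside contig ", contig, call. = FALSE)
  if (pos - flank_len < 1 || pos + flank_len > n) {
    return(data.frame(snp_id = snp_id,
                      strand = c("forward", "reverse"),
                      sequence = NA_character_,
                      verdict = "flank_too_short",
                      stringsAsFactors = FALSE))
  }
  left <- substr(sq, pos - flank_len, pos - 1)
  right <- substr(sq, pos + 1, pos + flank_len)
  fwd <- sprintf("%s[%s/%s]%s", left, ref, alt, right)
  rev <- sprintf("%s[%s/%s]%s", revcomp_chr(right), revcomp_chr(ref),
                 revcomp_chr(alt), revcomp_chr(left))
  data.frame(snp_id = snp_id, strand = c("forward", "reverse"),
             sequence = c(fwd, rev), verdict = "unscreened",
             stringsAsFactors = FALSE)
}

## expand "AAA[C/T]GGG" into the two plain allele sequences
expand_probe_alleles <- function(sequence) {
  m <- regmatches(sequence, regexec("^(.*)\\[(.+)/(.+)\\](.*)$", sequence))[[1]]
  if (length(m) != 5) stop("malformed probe sequence", call. = FALSE)
  c(paste0(m[2], m[3], m[5]), paste0(m[2], m[4], m[5]))
}

#' Build a canonical k-mer occurrence index over a reference
#'
#' Every length-`k` window of every contig is counted; a k-mer and its
#' reverse complement collapse to one canonical key (the
#' lexicographically smaller of the two), because array hybridisation is
#' strand-agnostic. Windows containing non-ACGT characters are skipped.
#' Contigs shorter than `k` contribute nothing.
#'
#' @param reference named character vector of contig sequences.
#' @param k k-mer length (default 16).
#' @return a `kmer_index`: list with `k` and named integer `counts`.
#' @export
build_kmer_index <- function(reference, k = 16) {
  stopifnot(length(reference) > 0, k >= 1)
  all_kmers <- character(0)
  for (sq in reference) {
    n <- nchar(sq)
    if (n < k) next
    km <- substring(sq, 1:(n - k + 1), k:n)
    km <- km[!grepl("[^ACGT]", km)]
    all_kmers <- c(all_kmers, km)
  }
  if (length(all_kmers) == 0)
    return(structure(list(k = k, counts = integer(0)),
                     class = "kmer_index"))
  rc <- revcomp_chr(all_kmers)
  canon <- pmin(all_kmers, rc)
  counts <- table(canon)
  structure(list(k = k,
                 counts = setNames(as.integer(counts), names(counts))),
            class = "kmer_index")
}

#' Screen probe candidates against the reference k-mer index
#'
#' For each candidate the k-mers of both allele versions of the 71-base
#' sequence are looked up in the canonical index; `max_kmer_hits` is the
#' worst (largest) count seen and the verdict becomes `not_recommended`
#' iff it strictly exceeds `max_hits`. Candidates already marked
#' `flank_too_short` are passed through unchanged. K-mers with ambiguous
#' bases are skipped.
#'
#' @param probes data.frame from [extract_probe_context()] (any number of
#'   rows).
#' @param index a [build_kmer_index()] result.
#' @param max_hits verdict threshold (default 100, strict).
#' @return the probes data.frame with `max_kmer_hits` and updated
#'   `verdict`.
#' @export
screen_probes <- function(probes, index, max_hits = 100) {
  stopifnot(inherits(index, "kmer_index"))
  k <- index$k
  probes$max_kmer_hits <- NA_integer_
  for (i in seq_len(nrow(probes))) {
    if (probes$verdict[i] == "flank_too_short") next
    kmers <- character(0)
    for (sq in expand_probe_alleles(probes$sequence[i])) {
      n <- nchar(sq)
      if (n < k) next
      kmers <- c(kmers, substring(sq, 1:(n - k + 1), k:n))
    }
    kmers <- unique(kmers[!grepl("[^ACGT]", kmers)])
    if (length(kmers) == 0) {
      probes$verdict[i] <- "recommended"
      probes$max_kmer_hits[i] <- 0L
      next
    }
    canon <- pmin(kmers, revcomp_chr(kmers))
    hits <- index$counts[canon]
    hits[is.na(hits)] <- 0L
    mx <- max(hits)
    probes$max_kmer_hits[i] <- as.integer(mx)
    probes$verdict[i] <- if (mx > max_hits) "not_recommended" else
      "recommended"
  }
  probes
}

#' Randomly sample array content from the catalog
#'
#' Draws `n_target` SNPs honoring per-contig caps: at most
#' `per_contig_cap` SNPs from an ordinary contig (to maximise contig
#' coverage) and up to `long_contig_cap` from contigs at least
#' `long_contig_min_len` bases long. First picks (one random SNP per
#' contig) fill before second picks on long contigs. Deterministic under
#' `seed`.
#'
#' @param catalog data.frame from [select_catalog()] (needs `snp_id`,
#'   `contig`, `source`).
#' @param n_target number of SNPs to select.
#' @param contig_lengths named vector of contig lengths; when NULL no
#'   contig qualifies as long.
#' @param per_contig_cap ordinary cap (default 1).
#' @param long_contig_cap cap for long contigs (default 2).
#' @param long_contig_min_len length threshold; default the 90th
#'   percentile of `contig_lengths`.
#' @param seed integer seed.
#' @return the selected catalog rows, with attribute `composition`
#'   (counts by source).
#' @export
sample_array_content <- function(catalog, n_target, contig_lengths = NULL,
                                 per_contig_cap = 1, long_contig_cap = 2,
                                 long_contig_min_len = NULL, seed = 1) {
  stopifnot(nrow(catalog) > 0, n_target >= 1)
  set.seed(seed)
  split_idx <- split(seq_len(nrow(catalog)), catalog$contig)
  long <- character(0)
  if (!is.null(contig_lengths)) {
    if (is.null(long_contig_min_len))
      long_contig_min_len <- as.numeric(quantile(contig_lengths, 0.9))
    long <- names(contig_lengths)[contig_lengths >= long_contig_min_len]
  }
  cap <- ifelse(names(split_idx) %in% long, long_contig_cap,
                per_contig_cap)
  feasible <- sum(pmin(lengths(split_idx), cap))
  if (n_target > feasible)
    stop(sprintf("n_target %d exceeds the maximum feasible %d under caps",
                 n_target, feasible), call. = FALSE)
  picks <- lapply(seq_along(split_idx), function(i) {
    idx <- split_idx[[i]]
    take <- min(cap[i], length(idx))
    if (length(idx) == 1) idx[seq_len(take)] else
      sample(idx, take)
  })
  firsts <- vapply(picks, `[`, integer(1), 1)
  seconds <- as.integer(unlist(lapply(picks, function(p) p[-1])))
  pool <- c(firsts[sample.int(length(firsts))],
            seconds[sample.int(length(seconds))])
  sel <- sort(pool[seq_len(n_target)])
  out <- catalog[sel, , drop = FALSE]
  attr(out, "composition") <- table(out$source)
  out
}
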