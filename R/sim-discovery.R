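#' Configuration for the discovery-data simulator
#'
#' Controls the synthetic reference contigs and two-sample discovery VCF
#' used to exercise the ascertainment filters. The two samples mimic the
#' RAD-seq design of conifer SNP discovery: a haploid megagametophyte
#' (which can never be truly heterozygous) and a pooled diploid sample.
#'
#' @param n_contigs number of reference contigs.
#' @param contig_length bases per contig (>= 71 so a full probe window
#'   fits).
#' @param snp_rate,indel_rate per-base planting probabilities in `[0, 1]`.
#' @param cluster_fraction fraction of SNPs planted within 30 bp of another
#'   SNP.
#' @param lcr_fraction fraction of each contig's bases turned into a planted
#'   low-complexity (AT-repeat) stretch.
#' @param haploid_het_fraction fraction of variants given an artifactual
#'   heterozygous call in the haploid sample.
#' @param lowconf_fraction fraction of genotype calls given sub-threshold
#'   confidence.
#' @param excluded_contig_fraction fraction of contigs placed on an
#'   exclusion list (transposon / assembly-suspicious / similarity), cycled
#'   over the three reasons.
#' @param seed integer seed; fixed seed gives byte-identical outputs.
#' @return a `discovery_sim_config` list.
#' @export
discovery_sim_config <- function(n_contigs = 100,
                                 contig_length = 500,
                                 snp_rate = 0.01,
                                 indel_rate = 0.002,
                                 cluster_fraction = 0.15,
                                 lcr_fraction = 0.05,
                                 haploid_het_fraction = 0.05,
                                 lowconf_fraction = 0.05,
                                 excluded_contig_fraction = 0.05,
                                 seed = 1) {
  cfg <- list(n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              snp_rate = snp_rate, indel_rate = indel_rate,
              cluster_fraction = cluster_fraction,
              lcr_fraction = lcr_fraction,
              haploid_het_fraction = haploid_het_fraction,
              lowconf_fraction = lowconf_fraction,
              excluded_contig_fraction = excluded_contig_fraction,
              seed = as.integer(seed))
  rates <- c(cfg$snp_rate, cfg$indel_rate, cfg$cluster_fraction,
             cfg$lcr_fraction, cfg$haploid_het_fraction,
             cfg$lowconf_fraction, cfg$excluded_contig_fraction)
  stopifnot_cfg(
    "all rates must lie in [0, 1]" = all(rates >= 0 & rates <= 1),
    "contig_length must be >= 71" = cfg$contig_length >= 71
  )
  class(cfg) <- "discovery_sim_config"
  cfg
}

## distance from a point to a closed interval, 0 if inside
dist_to_span <- function(pos, start, end) {
  pmax(start - pos, pos - end, 0)
}

#' Simulate a discovery dataset with planted filter-tag truth
#'
#' Emits reference contigs, a two-sample VCF-style variant set (samples
#' `single_haploid` and `pool_diploid`), a mask interval set (planted
#' low-complexity stretches plus homopolymer runs found in the realised
#' sequence), contig exclusion lists, and a truth ledger listing for every
#' variant exactly the tags the ascertainment stage must assign.
#'
#' Expected tags are computed here by brute force on the *realised* data
#' (pairwise position scans, interval membership, run-length scans), not by
#' calling the ascertainment code, so tag-recovery tests are a genuine
#' two-route check. Tag semantics mirror the ascertainment defaults:
#' inclusive 60 bp indel vicinity, inclusive 30 bp SNP cluster window,
#' 35 bp minimum flank, homopolymer runs of 6+ within 5 bp, A/T and C/G
#' single-probe incompatibility, and confidence-based call nulling at
#' GT_CONF < 3 with all-NULL sites removed.
#'
#' @param cfg a [discovery_sim_config()].
#' @param dir optional directory; when given, writes `reference.fasta`,
#'   `discovery.vcf`, `mask.bed`, `excluded_*.txt` and `truth.json`.
#' @return list with `reference` (named character vector of contig
#'   sequences), `variants` (a [variant_set()] of the raw calls), `mask`
#'   (data.frame contig/start/end/type, 1-based closed), `excluded`
#'   (named list of contig id vectors) and `truth` (ledger data.frame with
#'   `removed` flag and `expected_tags`).
#' @export
simulate_discovery_dataset <- function(cfg = discovery_sim_config(),
                                       dir = NULL) {
  stopifnot(inherits(cfg, "discovery_sim_config"))
  set.seed(cfg$seed)
  M <- cfg$contig_length
  contig_ids <- sprintf("contig%04d", seq_len(cfg$n_contigs))
  bases <- c("A", "C", "G", "T")

  reference <- character(cfg$n_contigs)
  mask <- list()
  var_rows <- list()
  for (ci in seq_len(cfg$n_contigs)) {
    sq <- sample(bases, M, replace = TRUE)
    ## plant one AT-repeat low-complexity stretch per contig
    lcr_len <- round(cfg$lcr_fraction * M)
    lcr_iv <- NULL
    if (lcr_len >= 10) {
      s <- sample.int(M - lcr_len, 1)
      sq[s:(s + lcr_len - 1)] <- rep(c("A", "T"), length.out = lcr_len)
      lcr_iv <- c(s, s + lcr_len - 1)
      mask[[length(mask) + 1]] <- data.frame(
        contig = contig_ids[ci], start = s, end = s + lcr_len - 1,
        type = "lcr", stringsAsFactors = FALSE)
    }
    ## homopolymer runs of the realised sequence (run-length scan)
    r <- rle(sq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hp <- which(r$lengths >= 6)
    for (h in hp)
      mask[[length(mask) + 1]] <- data.frame(
        contig = contig_ids[ci], start = starts[h], end = ends[h],
        type = "homopolymer", stringsAsFactors = FALSE)

    ## plant variants: base SNPs, clustered SNPs, indels
    n_snp <- rbinom(1, M, cfg$snp_rate)
    n_ind <- rbinom(1, M, cfg$indel_rate)
    n_clu <- round(cfg$cluster_fraction * n_snp)
    n_base <- n_snp - n_clu
    avail <- 2:(M - 5)
    ## base SNPs are planted > 30 bp apart so clusters arise only from
    ## cluster_fraction; candidates violating the spacing are dropped
    cand <- sample(avail, min(2 * n_base, length(avail)))
    pos_base <- integer(0)
    for (p in cand) {
      if (length(pos_base) >= n_base) break
      if (!length(pos_base) || min(abs(pos_base - p)) > 30)
        pos_base <- c(pos_base, p)
    }
    pos_base <- sort(pos_base)
    pos_clu <- integer(0)
    if (n_clu > 0 && length(pos_base) > 0) {
      anchor <- sample(pos_base, n_clu, replace = TRUE)
      pos_clu <- anchor + sample(c(-30:-1, 1:30), n_clu, replace = TRUE)
      pos_clu <- pos_clu[pos_clu >= 2 & pos_clu <= M - 5]
    }
    pos_snp <- unique(c(pos_base, pos_clu))
    pos_ind <- sample(setdiff(avail, pos_snp), n_ind)
    pos_all <- c(pos_snp, pos_ind)
    type <- rep(c("SNP", "InDel"), c(length(pos_snp), length(pos_ind)))
    o <- order(pos_all)
    pos_all <- pos_all[o]; type <- type[o]
    if (length(pos_all) == 0) {
      reference[ci] <- paste(sq, collapse = "")
      next
    }
    ref <- alt <- character(length(pos_all))
    for (vi in seq_along(pos_all)) {
      p <- pos_all[vi]
      if (type[vi] == "SNP") {
        ref[vi] <- sq[p]
        alt[vi] <- sample(setdiff(bases, sq[p]), 1)
      } else if (runif(1) < 0.5) {     # deletion: multi-base ref
        len <- sample(2:4, 1)
        ref[vi] <- paste(sq[p:(p + len - 1)], collapse = "")
        alt[vi] <- sq[p]
      } else {                         # insertion: multi-base alt
        len <- sample(1:3, 1)
        ref[vi] <- sq[p]
        alt[vi] <- paste(c(sq[p], sample(bases, len, replace = TRUE)),
                         collapse = "")
      }
    }
    var_rows[[ci]] <- data.frame(
      contig = contig_ids[ci], pos = pos_all, ref = ref, alt = alt,
      type = type, lcr_start = if (is.null(lcr_iv)) NA else lcr_iv[1],
      lcr_end = if (is.null(lcr_iv)) NA else lcr_iv[2],
      stringsAsFactors = FALSE)
    reference[ci] <- paste(sq, collapse = "")
  }
  names(reference) <- contig_ids
  vars <- do.call(rbind, var_rows)
  if (is.null(vars)) stop("no variants simulated; raise snp_rate")
  mask <- if (length(mask)) do.call(rbind, mask) else
    data.frame(contig = character(0), start = integer(0),
               end = integer(0), type = character(0))
  nv <- nrow(vars)

  ## genotypes and confidences for the two discovery samples
  hap <- sample(c("hom_ref", "hom_alt"), nv, replace = TRUE)
  hap_het <- runif(nv) < cfg$haploid_het_fraction
  hap[hap_het] <- "het"
  dip <- sample(c("hom_ref", "het", "hom_alt"), nv, replace = TRUE,
                prob = c(0.25, 0.5, 0.25))
  conf <- matrix(runif(2 * nv, 5, 60), nv, 2)
  low <- matrix(runif(2 * nv) < cfg$lowconf_fraction, nv, 2)
  conf[low] <- runif(sum(low), 0, 2.99)
  calls <- cbind(single_haploid = hap, pool_diploid = dip)
  colnames(conf) <- colnames(calls)

  ## contig exclusion lists
  n_exc <- round(cfg$excluded_contig_fraction * cfg$n_contigs)
  exc_ids <- if (n_exc > 0) sample(contig_ids, n_exc) else character(0)
  reason <- rep(c("transposon", "suspicious_assembly", "similarity"),
                length.out = length(exc_ids))
  excluded <- split(exc_ids, factor(reason, levels = c(
    "transposon", "suspicious_assembly", "similarity")))

  ## ---- expected-tag truth, brute force over realised data ----
  nulled <- conf < 3
  removed <- nulled[, 1] & nulled[, 2]
  keep <- which(!removed)
  tags <- vector("list", nv)
  is_snp <- vars$type == "SNP"
  ind_end <- vars$pos + nchar(vars$ref) - 1L
  for (vi in keep) {
    tg <- character(0)
    ctg <- vars$contig[vi]
    p <- vars$pos[vi]
    if (!is_snp[vi]) tg <- c(tg, "TypeIndel")
    if (is_snp[vi]) {
      others <- keep[vars$contig[keep] == ctg & keep != vi]
      inds <- others[!is_snp[others]]
      if (length(inds) &&
          any(dist_to_span(p, vars$pos[inds], ind_end[inds]) <= 60))
        tg <- c(tg, "SnpGap")
      snps <- others[is_snp[others]]
      if (length(snps) && any(abs(vars$pos[snps] - p) <= 30))
        tg <- c(tg, "snpCluster")
      mi <- mask[mask$contig == ctg, , drop = FALSE]
      lcr <- mi[mi$type == "lcr", , drop = FALSE]
      if (nrow(lcr) && any(p >= lcr$start & p <= lcr$end))
        tg <- c(tg, "LowComplexityRegion")
      hp <- mi[mi$type == "homopolymer", , drop = FALSE]
      if (nrow(hp) && any(dist_to_span(p, hp$start, hp$end) <= 5))
        tg <- c(tg, "Homopolymer")
      pair <- sort(c(vars$ref[vi], vars$alt[vi]))
      if (identical(pair, c("A", "T")) || identical(pair, c("C", "G")))
        tg <- c(tg, "NonSingleProbeType")
      if (p <= 35 || p > M - 35) tg <- c(tg, "FlankTooShort")
    }
    if (!nulled[vi, 1] && calls[vi, 1] == "het")
      tg <- c(tg, "FailHaploidTest")
    if (ctg %in% exc_ids) tg <- c(tg, "ExcludedContig")
    tags[[vi]] <- tg
  }
  truth <- data.frame(
    variant_id = sprintf("%s:%d", vars$contig, vars$pos),
    contig = vars$contig, pos = vars$pos, type = vars$type,
    removed = removed,
    expected_tags = vapply(tags, function(t)
      paste(sort(t %||% character(0)), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)

  vs <- variant_set(vars[, c("contig", "pos", "ref", "alt", "type")],
                    calls, conf, source = "RAD")
  out <- list(reference = reference, variants = vs, mask = mask,
              excluded = excluded, truth = truth, config = cfg)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(reference, file.path(dir, "reference.fasta"))
    write_vcf(vs, file.path(dir, "discovery.vcf"))
    write_mask_bed(mask, file.path(dir, "mask.bed"))
    for (nm in names(excluded))
      writeLines(excluded[[nm]],
                 file.path(dir, sprintf("excluded_%s.txt", nm)))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         dataframe = "rows", na = "null")
    out$dir <- dir
  }
  out
}
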