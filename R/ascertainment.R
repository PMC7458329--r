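#' Ascertainment filter configuration
#'
#' Houses every constant of the SNP-exclusion filters. Defaults: RAD
#' genotype-confidence floor 3 and RNA genotype-quality floor 30 (calls
#' strictly below are NULLed), inclusive 60 bp indel-vicinity window,
#' inclusive 30 bp SNP-cluster window, 35 bp minimum flank, GATK's
#' published hard-filter thresholds for SNPs, the four single-probe allele
#' pairs A/C, A/G, C/T and G/T, homopolymer runs of 6+ bases tagged within
#' a 5 bp margin, and a DUST window of 64 with threshold 20.
#'
#' @param gt_conf_min RAD GT_CONF floor.
#' @param gq_min RNA GQ floor.
#' @param snp_gap_window indel vicinity in bases.
#' @param cluster_window SNP cluster window in bases.
#' @param flank_len minimum flank for probe design.
#' @param hard_filter_thresholds named list of annotation thresholds; names
#'   QD, FS, MQ, MQRankSum, ReadPosRankSum, SOR.
#' @param allowed_allele_pairs character vector of "X/Y" unordered pairs.
#' @param homopolymer_min_run minimum run length.
#' @param homopolymer_margin tag margin around runs.
#' @param dust_window,dust_threshold DUST scorer parameters.
#' @param cluster_min_neighbors neighbors (excluding the target) required
#'   inside the window to call a cluster; the published wording is
#'   ambiguous between 1 and 2, default 1.
#' @return an `ascertainment_config` list.
#' @export
ascertainment_config <- function(gt_conf_min = 3, gq_min = 30,
                                 snp_gap_window = 60, cluster_window = 30,
                                 flank_len = 35,
                                 hard_filter_thresholds = list(
                                   QD = 2.0, FS = 60.0, MQ = 40.0,
                                   MQRankSum = -12.5,
                                   ReadPosRankSum = -8.0, SOR = 3.0),
                                 allowed_allele_pairs = c("A/C", "A/G",
                                                          "C/T", "G/T"),
                                 homopolymer_min_run = 6,
                                 homopolymer_margin = 5,
                                 dust_window = 64, dust_threshold = 20,
                                 cluster_min_neighbors = 1) {
  cfg <- as.list(environment())
  stopifnot_cfg(
    "all windows must be > 0" =
      all(c(cfg$snp_gap_window, cfg$cluster_window, cfg$flank_len,
            cfg$dust_window) > 0)
  )
  class(cfg) <- "ascertainment_config"
  cfg
}

FILTER_TAGS <- c("LowConfidenceNulled", "TypeIndel", "SnpGap", "snpCluster",
                 "LowComplexityRegion", "Homopolymer",
                 "FailureOnGatkHardFilter", "FailHaploidTest",
                 "FlankTooShort", "NonSingleProbeType", "ExcludedContig")

#' Create an empty filter ledger
#'
#' The ledger is a logical matrix of variants by tags; tags are additive
#' because the filtering steps are simultaneous, and a variant PASSes iff
#' its tag set is empty.
#'
#' @param vs a [variant_set()].
#' @return a `filter_ledger`.
#' @export
new_filter_ledger <- function(vs) {
  tags <- matrix(FALSE, length(vs), length(FILTER_TAGS),
                 dimnames = list(vs$variants$variant_id, FILTER_TAGS))
  structure(list(tags = tags, exclusion_reasons = list()),
            class = "filter_ledger")
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat(sprintf("filter_ledger: %d variants, %d tagged\n",
              nrow(x$tags), sum(rowSums(x$tags) > 0)))
  print(colSums(x$tags))
  invisible(x)
}

ledger_tags <- function(ledger) {
  apply(ledger$tags, 1, function(r)
    paste(sort(FILTER_TAGS[r]), collapse = ";"))
}

#' NULL low-confidence genotype calls and drop empty sites
#'
#' Calls with confidence strictly below the source's floor (GT_CONF < 3
#' for RAD, GQ < 30 for RNA) are set to NULL; a missing confidence value
#' counts as sub-threshold. Sites left without any genotype call across
#' the samples are removed.
#'
#' @param vs a [variant_set()].
#' @param cfg an [ascertainment_config()].
#' @return list with `variants` (the surviving [variant_set()]), `removed`
#'   (data.frame of removed sites) and `n_nulled` (calls NULLed).
#' @export
null_low_confidence_calls <- function(vs, cfg = ascertainment_config()) {
  thr <- if (vs$source == "RAD") cfg$gt_conf_min else cfg$gq_min
  if (any(is.na(vs$conf) & !is.na(vs$calls)))
    message("calls with missing confidence treated as sub-threshold")
  low <- (is.na(vs$conf) | vs$conf < thr) & !is.na(vs$calls)
  calls <- vs$calls
  calls[low] <- NA_character_
  empty <- rowSums(!is.na(calls)) == 0
  out <- variant_set(vs$variants, calls, vs$conf, vs$source, vs$info)
  list(variants = subset_variants(out, !empty),
       removed = vs$variants[empty, , drop = FALSE],
       n_nulled = sum(low))
}

#' Tag indels and SNPs in their vicinity
#'
#' Indels get `TypeIndel`; a SNP gets `SnpGap` iff its position is within
#' `snp_gap_window` bases (inclusive) of any base of an indel's reference
#' span on the same contig.
#'
#' @param vs a [variant_set()].
#' @param ledger a filter ledger.
#' @param cfg an [ascertainment_config()].
#' @return the updated ledger.
#' @export
tag_indels_and_gap <- function(vs, ledger, cfg = ascertainment_config()) {
  v <- vs$variants
  is_ind <- v$type == "InDel"
  ledger$tags[is_ind, "TypeIndel"] <- TRUE
  span_end <- v$pos + nchar(v$ref) - 1L
  for (ctg in unique(v$contig[is_ind])) {
    si <- which(v$contig == ctg & v$type == "SNP")
    ii <- which(v$contig == ctg & is_ind)
    if (!length(si)) next
    for (j in ii) {
      d <- dist_to_span(v$pos[si], v$pos[j], span_end[j])
      ledger$tags[si[d <= cfg$snp_gap_window], "SnpGap"] <- TRUE
    }
  }
  ledger
}

#' Tag clustered SNPs
#'
#' A SNP is tagged `snpCluster` iff at least `cluster_min_neighbors` other
#' SNPs lie within `cluster_window` bases (inclusive) on either side;
#' tagging is symmetric, so every member of a cluster is tagged.
#'
#' @inheritParams tag_indels_and_gap
#' @return the updated ledger.
#' @export
tag_snp_clusters <- function(vs, ledger, cfg = ascertainment_config()) {
  v <- vs$variants
  for (ctg in unique(v$contig)) {
    si <- which(v$contig == ctg & v$type == "SNP")
    if (length(si) < 2) next
    p <- v$pos[si]
    nb <- vapply(seq_along(p), function(i)
      sum(abs(p[-i] - p[i]) <= cfg$cluster_window), integer(1))
    ledger$tags[si[nb >= cfg$cluster_min_neighbors], "snpCluster"] <- TRUE
  }
  ledger
}

#' Tag SNPs in masked intervals
#'
#' SNPs inside an interval of type "lcr" get `LowComplexityRegion`; SNPs
#' inside or within `homopolymer_margin` bases of a "homopolymer" interval
#' get `Homopolymer`. Intervals are 1-based closed (as returned by
#' [detect_masked_intervals()] or [read_mask_bed()]).
#'
#' @inheritParams tag_indels_and_gap
#' @param mask data.frame contig/start/end/type.
#' @return the updated ledger.
#' @export
tag_low_complexity <- function(vs, ledger, mask,
                               cfg = ascertainment_config()) {
  if (is.null(mask) || nrow(mask) == 0) return(ledger)
  v <- vs$variants
  is_snp <- v$type == "SNP"
  for (r in seq_len(nrow(mask))) {
    on <- is_snp & v$contig == mask$contig[r]
    if (!any(on)) next
    if (mask$type[r] == "lcr") {
      hit <- on & v$pos >= mask$start[r] & v$pos <= mask$end[r]
      ledger$tags[hit, "LowComplexityRegion"] <- TRUE
    } else if (mask$type[r] == "homopolymer") {
      hit <- on & dist_to_span(v$pos, mask$start[r], mask$end[r]) <=
        cfg$homopolymer_margin
      ledger$tags[hit, "Homopolymer"] <- TRUE
    }
  }
  ledger
}

#' Tag variants failing the hard-filter annotation thresholds
#'
#' Applies only to RNA-source variant sets (a no-op otherwise). A variant
#' is tagged `FailureOnGatkHardFilter` iff any *present* annotation
#' violates its threshold: QD < 2, FS > 60, MQ < 40, MQRankSum < -12.5,
#' ReadPosRankSum < -8, SOR > 3 (strict inequalities; absent annotations
#' never fail).
#'
#' @inheritParams tag_indels_and_gap
#' @return the updated ledger.
#' @export
tag_hard_filter <- function(vs, ledger, cfg = ascertainment_config()) {
  if (vs$source != "RNA" || is.null(vs$info)) return(ledger)
  thr <- cfg$hard_filter_thresholds
  lower_is_bad <- c(QD = TRUE, FS = FALSE, MQ = TRUE, MQRankSum = TRUE,
                    ReadPosRankSum = TRUE, SOR = FALSE)
  fail <- rep(FALSE, length(vs))
  for (nm in intersect(names(thr), names(vs$info))) {
    x <- vs$info[[nm]]
    bad <- if (lower_is_bad[[nm]]) x < thr[[nm]] else x > thr[[nm]]
    fail <- fail | (bad & !is.na(bad))
  }
  ledger$tags[fail, "FailureOnGatkHardFilter"] <- TRUE
  ledger
}

#' Tag variants heterozygous in the haploid sample
#'
#' A haploid sample cannot be truly heterozygous, so a het call there
#' marks the site as an artifact (`FailHaploidTest`). Homozygous or NULL
#' haploid calls pass. If the designated sample is absent the operation is
#' skipped with a warning.
#'
#' @inheritParams tag_indels_and_gap
#' @param haploid_sample column name of the haploid sample.
#' @return the updated ledger.
#' @export
tag_haploid_inconsistency <- function(vs, ledger,
                                      haploid_sample = "single_haploid") {
  if (!haploid_sample %in% colnames(vs$calls)) {
    warning("no haploid sample '", haploid_sample,
            "' in variant set; haploid test skipped")
    return(ledger)
  }
  het <- !is.na(vs$calls[, haploid_sample]) &
    vs$calls[, haploid_sample] == "het"
  ledger$tags[het, "FailHaploidTest"] <- TRUE
  ledger
}

#' Tag SNPs whose alleles need two probes
#'
#' A/T and C/G SNPs require separate probes per strand on the array, so
#' only the four pairs in `allowed_allele_pairs` are kept; all other SNP
#' allele pairs (including any with non-ACGT alleles) get
#' `NonSingleProbeType`.
#'
#' @inheritParams tag_indels_and_gap
#' @return the updated ledger.
#' @export
tag_allele_compatibility <- function(vs, ledger,
                                     cfg = ascertainment_config()) {
  v <- vs$variants
  is_snp <- v$type == "SNP"
  pair <- ifelse(v$ref < v$alt, paste(v$ref, v$alt, sep = "/"),
                 paste(v$alt, v$ref, sep = "/"))
  bad_base <- !(v$ref %in% c("A", "C", "G", "T")) |
    !(v$alt %in% c("A", "C", "G", "T"))
  if (any(is_snp & bad_base))
    message(sum(is_snp & bad_base), " SNPs with non-ACGT alleles tagged")
  hit <- is_snp & (!(pair %in% cfg$allowed_allele_pairs) | bad_base)
  ledger$tags[hit, "NonSingleProbeType"] <- TRUE
  ledger
}

#' Tag SNPs with insufficient flanking sequence
#'
#' A SNP needs `flank_len` reference bases on each side for probe design;
#' SNPs closer than that to a contig end get `FlankTooShort`.
#'
#' @inheritParams tag_indels_and_gap
#' @param contig_lengths named integer vector of contig lengths.
#' @return the updated ledger.
#' @export
tag_short_flanks <- function(vs, ledger, contig_lengths,
                             cfg = ascertainment_config()) {
  v <- vs$variants
  len <- contig_lengths[v$contig]
  if (any(is.na(len)))
    stop("variants on contigs absent from the reference", call. = FALSE)
  hit <- v$type == "SNP" &
    (v$pos <= cfg$flank_len | v$pos > len - cfg$flank_len)
  ledger$tags[hit, "FlankTooShort"] <- TRUE
  ledger
}

#' Tag variants on excluded contigs
#'
#' Contig exclusion lists come from external annotation (transposon
#' matches, assembly-suspicious contigs, similarity-flagged contigs). A
#' variant on any listed contig gets a single `ExcludedContig` tag with
#' every originating list recorded as a reason. Contig ids not present in
#' the variant set are warned about and ignored.
#'
#' @inheritParams tag_indels_and_gap
#' @param excluded named list of contig id character vectors.
#' @return the updated ledger.
#' @export
tag_excluded_contigs <- function(vs, ledger, excluded) {
  if (length(excluded) == 0) return(ledger)
  known <- unique(vs$variants$contig)
  for (nm in names(excluded)) {
    ids <- excluded[[nm]]
    unknown <- setdiff(ids, known)
    if (length(unknown))
      warning(length(unknown), " unknown contig ids in exclusion list '",
              nm, "' ignored")
    hit <- vs$variants$contig %in% ids
    ledger$tags[hit, "ExcludedContig"] <- TRUE
    for (ctg in intersect(ids, known))
      ledger$exclusion_reasons[[ctg]] <-
        union(ledger$exclusion_reasons[[ctg]], nm)
  }
  ledger
}

#' Run all ascertainment filters on a variant set
#'
#' Applies confidence nulling then every tag operation. The tag steps are
#' simultaneous and order-independent: each inspects the variant set, not
#' the ledger, so a variant can accumulate several tags.
#'
#' @param vs a [variant_set()].
#' @param reference named character vector of contig sequences; needed for
#'   the flank-length tag and, when `mask` is NULL, for mask detection.
#' @param cfg an [ascertainment_config()].
#' @param mask optional mask data.frame (e.g. from [read_mask_bed()]);
#'   detected from the reference when NULL and a reference is given.
#' @param excluded named list of contig exclusion lists.
#' @param haploid_sample haploid sample name, or NULL to skip the test.
#' @return an `ascertainment_result`: list with `variants` (post-nulling),
#'   `ledger`, `removed`, `n_nulled` and `source`.
#' @export
ascertain_variants <- function(vs, reference = NULL,
                               cfg = ascertainment_config(), mask = NULL,
                               excluded = list(),
                               haploid_sample = "single_haploid") {
  nul <- null_low_confidence_calls(vs, cfg)
  v <- nul$variants
  ledger <- new_filter_ledger(v)
  ledger <- tag_indels_and_gap(v, ledger, cfg)
  ledger <- tag_snp_clusters(v, ledger, cfg)
  if (is.null(mask) && !is.null(reference))
    mask <- detect_masked_intervals(reference, cfg)
  ledger <- tag_low_complexity(v, ledger, mask, cfg)
  ledger <- tag_hard_filter(v, ledger, cfg)
  if (!is.null(haploid_sample))
    ledger <- tag_haploid_inconsistency(v, ledger, haploid_sample)
  ledger <- tag_allele_compatibility(v, ledger, cfg)
  if (!is.null(reference))
    ledger <- tag_short_flanks(v, ledger, nchar(reference), cfg)
  ledger <- tag_excluded_contigs(v, ledger, excluded)
  structure(list(variants = v, ledger = ledger, removed = nul$removed,
                 n_nulled = nul$n_nulled, source = vs$source),
            class = "ascertainment_result")
}

#' Summarize the filter ledger as a per-tag count table
#'
#' One row per tag with the number of variants carrying it; rows are not
#' disjoint because filters are simultaneous and tags additive. Sites
#' removed for lacking any confident genotype are reported under
#' `LowConfidenceNulled`. `retained` counts tag-free SNPs.
#'
#' @param res an `ascertainment_result` from [ascertain_variants()].
#' @return data.frame with columns `item` and `count`.
#' @export
summarize_filter_ledger <- function(res) {
  stopifnot(inherits(res, "ascertainment_result"))
  tg <- res$ledger$tags
  tg[, "LowConfidenceNulled"] <- FALSE   # removed sites counted separately
  counts <- colSums(tg)
  counts["LowConfidenceNulled"] <- nrow(res$removed)
  is_snp <- res$variants$variants$type == "SNP"
  retained <- sum(is_snp & rowSums(res$ledger$tags) == 0)
  data.frame(
    item = c("total_raw_variants", names(counts), "retained"),
    count = c(nrow(res$removed) + length(res$variants),
              unname(counts), retained),
    stringsAsFactors = FALSE)
}

#' Select the catalog of assayable SNPs
#'
#' Keeps only tag-free SNPs and computes per-contig SNP counts (the basis
#' of the mean-SNPs-per-contig statistic for the retained catalog).
#'
#' @param res an `ascertainment_result`.
#' @return data.frame catalog (snp_id, contig, pos, ref, alt, source,
#'   status, tags) with attributes `contig_counts` and
#'   `mean_snps_per_contig`.
#' @export
select_catalog <- function(res) {
  stopifnot(inherits(res, "ascertainment_result"))
  v <- res$variants$variants
  pass <- v$type == "SNP" & rowSums(res$ledger$tags) == 0
  cat_df <- data.frame(snp_id = v$variant_id[pass],
                       contig = v$contig[pass], pos = v$pos[pass],
                       ref = v$ref[pass], alt = v$alt[pass],
                       source = res$source, status = "PASS", tags = "",
                       stringsAsFactors = FALSE)
  cc <- table(cat_df$contig)
  attr(cat_df, "contig_counts") <- cc
  attr(cat_df, "mean_snps_per_contig") <-
    if (length(cc)) round(nrow(cat_df) / length(cc), 2) else NA_real_
  cat_df
}
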