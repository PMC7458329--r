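#' Array QC configuration
#'
#' Thresholds of the two performance-criteria sets used to classify
#' genotyped SNPs and samples. Sample QC requires dish QC strictly above
#' `dqc_min` and sample call rate strictly above `sample_cr_min`. The
#' Axiom-style SNP criteria use a strict call-rate threshold (`CR < 97%`
#' fails as CRBT) and polymorphism measured by the minor allele appearing
#' in at least `min_minor_samples` samples; the conventional criteria use
#' an inclusive `CR >= 90%` and `MAF >= 0.005`.
#'
#' @param dqc_min dish-QC floor (strict, default 0.82).
#' @param sample_cr_min sample call-rate floor (strict, default 0.97).
#' @param axiom_snp_cr_min Axiom SNP call-rate threshold (default 0.97).
#' @param conventional_cr_min conventional call-rate threshold (inclusive,
#'   default 0.90).
#' @param maf_min conversion MAF threshold (inclusive, default 0.005).
#' @param min_minor_samples samples carrying the minor allele required for
#'   polymorphism (default 2).
#' @return an `array_qc_config` list.
#' @export
array_qc_config <- function(dqc_min = 0.82, sample_cr_min = 0.97,
                            axiom_snp_cr_min = 0.97,
                            conventional_cr_min = 0.90, maf_min = 0.005,
                            min_minor_samples = 2) {
  cfg <- as.list(environment())
  stopifnot_cfg("thresholds must lie in [0, 1]" = all(
    unlist(cfg[c("dqc_min", "sample_cr_min", "axiom_snp_cr_min",
                 "conventional_cr_min", "maf_min")]) >= 0 &
      unlist(cfg[c("dqc_min", "sample_cr_min", "axiom_snp_cr_min",
                   "conventional_cr_min", "maf_min")]) <= 1))
  class(cfg) <- "array_qc_config"
  cfg
}

#' Per-sample quality control
#'
#' A sample passes iff its dish QC exceeds `dqc_min` and its call rate
#' exceeds `sample_cr_min`, both strictly. Failing samples are meant to be
#' excluded before computing SNP metrics.
#'
#' @param gm a [genotype_matrix()] with `dqc` in the sample metadata.
#' @param cfg an [array_qc_config()].
#' @return data.frame `sample_id`, `dqc`, `call_rate`, `pass`.
#' @export
sample_qc <- function(gm, cfg = array_qc_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$samples$dqc) || all(is.na(gm$samples$dqc)))
    stop("sample metadata lacks dqc values", call. = FALSE)
  cr <- rowMeans(!is.na(gm$calls))
  data.frame(sample_id = gm$samples$sample_id, dqc = gm$samples$dqc,
             call_rate = cr,
             pass = gm$samples$dqc > cfg$dqc_min & cr > cfg$sample_cr_min,
             stringsAsFactors = FALSE)
}

#' Per-SNP call metrics
#'
#' Computes, per SNP over the supplied samples: call rate, allele-count
#' minor allele frequency among called genotypes, the number of samples
#' carrying at least one copy of the minor allele, and whether a minor
#' homozygote is observed. All-NoCall SNPs get `NA` metrics rather than an
#' error. On a 50/50 allele tie the B allele is treated as minor.
#'
#' @param gm a [genotype_matrix()] (typically already restricted to
#'   QC-passing samples).
#' @return data.frame `snp_id`, `call_rate`, `maf`, `minor_sample_count`,
#'   `has_minor_homozygote`, plus the SNP `source` if available.
#' @export
snp_call_metrics <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  calls <- gm$calls
  n_called <- colSums(!is.na(calls))
  cr <- n_called / nrow(calls)
  p_b <- colSums(calls, na.rm = TRUE) / (2 * n_called)  # freq of B allele
  minor_is_b <- p_b <= 0.5
  maf <- ifelse(minor_is_b, p_b, 1 - p_b)
  maf[n_called == 0] <- NA_real_
  carriers_b <- colSums(calls >= 1, na.rm = TRUE)
  carriers_a <- colSums(calls <= 1, na.rm = TRUE)
  hom_b <- colSums(calls == 2, na.rm = TRUE)
  hom_a <- colSums(calls == 0, na.rm = TRUE)
  msc <- ifelse(minor_is_b, carriers_b, carriers_a)
  hmh <- ifelse(minor_is_b, hom_b, hom_a) > 0
  msc[n_called == 0] <- NA_integer_
  hmh[n_called == 0] <- NA
  out <- data.frame(snp_id = colnames(calls), call_rate = cr, maf = maf,
                    minor_sample_count = msc,
                    has_minor_homozygote = hmh,
                    stringsAsFactors = FALSE)
  if (!is.null(gm$snps$source)) out$source <- gm$snps$source
  out
}

#' Axiom-style SNP classification
#'
#' Classifies each SNP by precedence: `CRBT` when call rate is below the
#' strict threshold; else `MHR` when fewer than `min_minor_samples`
#' samples carry the minor allele (monomorphic, or a single-sample minor
#' allele — a SNP that passes everything except polymorphism); else `NMH`
#' when the minor allele is present in enough samples but no minor
#' homozygote is observed (only two genotype clusters); else `PHR`.
#' Intensity-dependent classes (OTV/OTH) require signal data this pipeline
#' never sees and are never emitted; all-NoCall SNPs fall in `Other`.
#'
#' @param metrics data.frame from [snp_call_metrics()].
#' @param cfg an [array_qc_config()].
#' @return factor of categories `PHR`, `MHR`, `NMH`, `CRBT`, `Other`.
#' @export
classify_axiom <- function(metrics, cfg = array_qc_config()) {
  cat <- rep("Other", nrow(metrics))
  defined <- !is.na(metrics$maf)
  cat[defined & metrics$call_rate < cfg$axiom_snp_cr_min] <- "CRBT"
  rest <- defined & metrics$call_rate >= cfg$axiom_snp_cr_min
  cat[rest & metrics$minor_sample_count < cfg$min_minor_samples] <- "MHR"
  poly <- rest & metrics$minor_sample_count >= cfg$min_minor_samples
  cat[poly & !metrics$has_minor_homozygote] <- "NMH"
  cat[poly & metrics$has_minor_homozygote] <- "PHR"
  factor(cat, levels = c("PHR", "MHR", "NMH", "CRBT", "OTV", "Other"))
}

#' Conventional success and conversion flags
#'
#' The liberal criteria common in plant and animal genotyping: success iff
#' call rate is at least `conventional_cr_min` (inclusive); converted iff
#' additionally the MAF is at least `maf_min`.
#'
#' @param metrics data.frame from [snp_call_metrics()].
#' @param cfg an [array_qc_config()].
#' @return data.frame `success`, `converted` (logical, one row per SNP).
#' @export
classify_conventional <- function(metrics, cfg = array_qc_config()) {
  success <- metrics$call_rate >= cfg$conventional_cr_min
  converted <- success & !is.na(metrics$maf) & metrics$maf >= cfg$maf_min
  data.frame(success = success, converted = converted)
}

#' Duplicate-pair reproducibility
#'
#' For each duplicated sample, concordance is the fraction of matching
#' calls over SNPs where both members of the pair have a call. Pairs with
#' zero co-called SNPs are skipped with a warning.
#'
#' @param gm a [genotype_matrix()] whose sample metadata has
#'   `duplicate_of` set for duplicate samples.
#' @return list with `pairs` (data.frame sample, source, n_co_called,
#'   concordance) and `mean` concordance over pairs.
#' @export
duplicate_concordance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  dup <- which(!is.na(gm$samples$duplicate_of))
  if (length(dup) == 0) stop("no duplicate pairs in matrix", call. = FALSE)
  rows <- lapply(dup, function(i) {
    src <- gm$samples$duplicate_of[i]
    a <- gm$calls[i, ]
    b <- gm$calls[match(src, gm$samples$sample_id), ]
    co <- !is.na(a) & !is.na(b)
    if (!any(co)) {
      warning("duplicate pair ", gm$samples$sample_id[i],
              " has no co-called SNPs; skipped")
      return(NULL)
    }
    data.frame(sample = gm$samples$sample_id[i], source = src,
               n_co_called = sum(co),
               concordance = mean(a[co] == b[co]),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  list(pairs = pairs, mean = mean(pairs$concordance))
}

#' Build the percentage block of a performance summary
#'
#' Given per-source counts and assayed totals, produces counts plus
#' percentages of assayed at one decimal, with a Total column — the rate
#' arithmetic of an array performance table. Exposed separately so the
#' arithmetic can be driven by externally supplied counts as well as by
#' [performance_summary()].
#'
#' @param counts named numeric vector or matrix (rows = items, cols =
#'   sources) of counts.
#' @param assayed numeric vector of assayed totals per source.
#' @return data.frame with interleaved `n_<source>` / `pct_<source>`
#'   columns and totals.
#' @export
rate_table <- function(counts, assayed) {
  counts <- rbind(counts)
  total_n <- rowSums(counts)
  total_assayed <- sum(assayed)
  out <- data.frame(item = rownames(counts) %||%
                      sprintf("item%d", seq_len(nrow(counts))))
  for (j in seq_len(ncol(counts))) {
    src <- colnames(counts)[j] %||% sprintf("src%d", j)
    out[[paste0("n_", src)]] <- counts[, j]
    out[[paste0("pct_", src)]] <- pct1(counts[, j], assayed[j])
  }
  out$n_total <- total_n
  out$pct_total <- pct1(total_n, total_assayed)
  out
}

#' Performance summary by SNP source
#'
#' Applies sample QC, computes SNP metrics over passing samples, both
#' classification schemes, and tabulates counts and one-decimal
#' percentages per source and in total: assayed SNPs, conventional
#' success (CR >= 90%) and conversion (plus MAF >= 0.005), the Axiom
#' global success (PHR + MHR + NMH) and each Axiom category.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg an [array_qc_config()].
#' @return list with `table` (the rate table), `metrics`, `axiom`
#'   (per-SNP categories), `conventional`, `sample_qc`.
#' @export
performance_summary <- function(gm, cfg = array_qc_config()) {
  sq <- sample_qc(gm, cfg)
  gmp <- subset_samples(gm, sq$pass)
  metrics <- snp_call_metrics(gmp)
  ax <- classify_axiom(metrics, cfg)
  cv <- classify_conventional(metrics, cfg)
  src <- factor(metrics$source %||% rep("all", nrow(metrics)))
  assayed <- as.vector(table(src))
  names(assayed) <- levels(src)
  tab <- function(flag) tapply(flag, src, sum)
  counts <- rbind(
    assayed = assayed,
    conventional_success = tab(cv$success),
    conventional_converted = tab(cv$converted),
    axiom_global_success = tab(ax %in% c("PHR", "MHR", "NMH")),
    PHR = tab(ax == "PHR"),
    MHR = tab(ax == "MHR"),
    NMH = tab(ax == "NMH"),
    CRBT = tab(ax == "CRBT"),
    OTV = tab(ax == "OTV"),
    Other = tab(ax == "Other"))
  counts[is.na(counts)] <- 0
  list(table = rate_table(counts, assayed), metrics = metrics,
       axiom = ax, conventional = cv, sample_qc = sq)
}
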