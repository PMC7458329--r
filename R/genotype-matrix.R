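#' Genotype matrix container
#'
#' Bundles a samples-by-SNPs biallelic call matrix with the sample and SNP
#' metadata the downstream QC and population-genetic routines need. Calls are
#' stored as minor-allele dosage style integers: 0 = AA, 1 = AB, 2 = BB and
#' `NA` = NoCall (A/B are the two array alleles, not necessarily ref/alt).
#'
#' @param calls integer matrix, samples in rows, SNPs in columns, values in
#'   \{0, 1, 2, NA\}. Row names are sample ids, column names SNP ids.
#' @param samples data.frame with at least `sample_id`; optional columns
#'   `population`, `region`, `duplicate_of` (NA for originals) and `dqc`.
#' @param snps data.frame with at least `snp_id`; optional `source`
#'   ("RAD"/"RNA") and any per-SNP annotation.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, samples, snps = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) rownames(calls) <- samples$sample_id
  if (is.null(snps)) {
    snps <- data.frame(snp_id = colnames(calls) %||%
                         sprintf("snp%05d", seq_len(ncol(calls))),
                       stringsAsFactors = FALSE)
  }
  if (is.null(colnames(calls))) colnames(calls) <- snps$snp_id
  stopifnot_cfg(
    "calls values must be 0, 1, 2 or NA" =
      all(calls %in% c(0L, 1L, 2L) | is.na(calls)),
    "nrow(calls) must match nrow(samples)" = nrow(calls) == nrow(samples),
    "ncol(calls) must match nrow(snps)" = ncol(calls) == nrow(snps),
    "sample_id column required" = "sample_id" %in% names(samples)
  )
  if (!is.null(samples$duplicate_of)) {
    dups <- samples$duplicate_of[!is.na(samples$duplicate_of)]
    if (!all(dups %in% samples$sample_id))
      stop("duplicate_of references unknown sample ids", call. = FALSE)
  }
  structure(list(calls = calls, samples = samples, snps = snps),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$calls), ncol(x$calls)))
  if (!is.null(x$samples$population))
    cat(sprintf("  %d populations", length(unique(x$samples$population))))
  if (!is.null(x$samples$region))
    cat(sprintf(" in %d regions", length(unique(x$samples$region))))
  ndup <- sum(!is.na(x$samples$duplicate_of %||% NA))
  cat(sprintf("\n  duplicates: %d; missing calls: %.2f%%\n",
              ndup, 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

## subset loci (columns) keeping metadata in step
subset_loci <- function(gm, idx) {
  genotype_matrix(gm$calls[, idx, drop = FALSE], gm$samples,
                  gm$snps[idx, , drop = FALSE])
}

## drop samples (rows); duplicate_of pointers to dropped samples are cleared
subset_samples <- function(gm, keep) {
  s <- gm$samples[keep, , drop = FALSE]
  if (!is.null(s$duplicate_of))
    s$duplicate_of[!(s$duplicate_of %in% s$sample_id)] <- NA
  genotype_matrix(gm$calls[keep, , drop = FALSE], s, gm$snps)
}
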