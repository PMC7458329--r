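#' Variant set container
#'
#' One discovery variant per row with per-sample genotype calls and
#' confidences. Calls are stored as characters in
#' \{"hom_ref", "het", "hom_alt"\} with `NA` for NULLed/absent calls;
#' confidences are the RAD genotype confidence (GT_CONF) or the GQ of an
#' RNA-seq caller, depending on `source`.
#'
#' @param variants data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, `type` ("SNP"/"InDel"); a `variant_id` column is added when
#'   absent.
#' @param calls character matrix variants x samples.
#' @param conf numeric matrix variants x samples.
#' @param source "RAD" or "RNA"; decides which confidence threshold applies.
#' @param info optional data.frame of site annotations (QD, FS, MQ,
#'   MQRankSum, ReadPosRankSum, SOR) aligned with `variants`.
#' @return an object of class `variant_set`.
#' @export
variant_set <- function(variants, calls, conf, source = c("RAD", "RNA"),
                        info = NULL) {
  source <- match.arg(source)
  variants <- as.data.frame(variants)
  stopifnot_cfg(
    "variants needs contig/pos/ref/alt/type columns" =
      all(c("contig", "pos", "ref", "alt", "type") %in% names(variants)),
    "pos must be >= 1" = all(variants$pos >= 1),
    "calls rows must match variants" = nrow(calls) == nrow(variants),
    "conf dims must match calls" = all(dim(conf) == dim(calls)),
    "SNP iff single-base ref and alt" =
      all((variants$type == "SNP") ==
            (nchar(variants$ref) == 1 & nchar(variants$alt) == 1))
  )
  if (is.null(variants$variant_id))
    variants$variant_id <- sprintf("%s:%d", variants$contig, variants$pos)
  ok <- is.na(calls) | calls %in% c("hom_ref", "het", "hom_alt")
  if (!all(ok)) stop("invalid genotype call strings", call. = FALSE)
  structure(list(variants = variants, calls = as.matrix(calls),
                 conf = as.matrix(conf), source = source, info = info),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set (%s): %d variants (%d SNP, %d InDel), samples: %s\n",
              x$source, nrow(x$variants), sum(x$variants$type == "SNP"),
              sum(x$variants$type == "InDel"),
              paste(colnames(x$calls), collapse = ", ")))
  invisible(x)
}

#' @export
length.variant_set <- function(x) nrow(x$variants)

## row subset keeping all slots aligned
subset_variants <- function(vs, idx) {
  variant_set(vs$variants[idx, , drop = FALSE],
              vs$calls[idx, , drop = FALSE],
              vs$conf[idx, , drop = FALSE],
              vs$source,
              if (!is.null(vs$info)) vs$info[idx, , drop = FALSE])
}
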