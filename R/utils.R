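`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement character k-mers
#'
#' Vectorised reverse complement for plain character vectors of equal-length
#' DNA words. Non-ACGT characters are preserved (complemented to themselves).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp_chr <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## stop unless all conditions hold; msgs are sprintf-ready
stopifnot_cfg <- function(...) {
  conds <- list(...)
  nms <- names(conds)
  for (i in seq_along(conds)) {
    if (!isTRUE(all(conds[[i]]))) stop(nms[i], call. = FALSE)
  }
  invisible(TRUE)
}

#' Percentage at one-decimal precision
#'
#' The convention used in array performance summaries: `100 * num / den`
#' rounded to one decimal place. Returns `NA` for a zero denominator rather
#' than erroring, so empty strata produce empty rows.
#'
#' @param num numerator count.
#' @param den denominator count.
#' @param digits decimal places (default 1).
#' @return numeric percentage.
#' @export
pct1 <- function(num, den, digits = 1) {
  out <- round(100 * num / den, digits)
  out[rep_len(den, length(out)) <= 0] <- NA_real_
  out
}

## deterministic child seed streams: one parent seed -> k reproducible
## sub-seeds, each < 2^31
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
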