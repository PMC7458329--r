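#' Detect low-complexity and homopolymer intervals in a reference
#'
#' A DUST-style scorer: every window of `dust_window` bases is scored by its
#' overlapping-triplet composition, `score = 10 * sum(c_t * (c_t - 1) / 2) /
#' (k - 1)` where `c_t` counts occurrences of triplet `t` and `k` is the
#' number of scoreable triplets in the window. Windows with
#' `score >= dust_threshold` are masked and overlapping masked windows
#' merged. Independently, homopolymer runs of `homopolymer_min_run` or more
#' identical bases are reported as their own interval type. Non-ACGT
#' characters break runs and make the affected triplets unscoreable.
#'
#' @param reference named character vector of contig sequences.
#' @param cfg an [ascertainment_config()]; uses `dust_window`,
#'   `dust_threshold` and `homopolymer_min_run`.
#' @return data.frame with columns `contig`, `start`, `end` (1-based
#'   closed) and `type` in \{"lcr", "homopolymer"\}.
#' @export
detect_masked_intervals <- function(reference, cfg = ascertainment_config()) {
  out <- list()
  for (nm in names(reference)) {
    ch <- strsplit(reference[[nm]], "")[[1]]
    n <- length(ch)
    code <- match(ch, c("A", "C", "G", "T"))  # NA for ambiguous bases

    ## homopolymer runs
    r <- rle(ch)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hp <- which(r$lengths >= cfg$homopolymer_min_run &
                  r$values %in% c("A", "C", "G", "T"))
    if (length(hp))
      out[[length(out) + 1]] <- data.frame(
        contig = nm, start = starts[hp], end = ends[hp],
        type = "homopolymer", stringsAsFactors = FALSE)

    ## DUST-style windows
    if (n >= 3) {
      trip <- (code[1:(n - 2)] - 1) * 16 + (code[2:(n - 1)] - 1) * 4 +
        code[3:n]                      # NA propagates from ambiguous bases
      w <- min(cfg$dust_window, n)
      nt <- n - 2                      # number of triplet start positions
      counts <- integer(64)
      score_sum <- 0
      k <- 0
      add <- function(t) {
        if (!is.na(t)) {
          score_sum <<- score_sum + counts[t]
          counts[t] <<- counts[t] + 1L
          k <<- k + 1
        }
      }
      rem <- function(t) {
        if (!is.na(t)) {
          counts[t] <<- counts[t] - 1L
          score_sum <<- score_sum - counts[t]
          k <<- k - 1
        }
      }
      wt <- w - 2                      # triplets per full window
      for (i in seq_len(min(wt, nt))) add(trip[i])
      flagged <- logical(n - w + 1)
      flagged[1] <- k >= 2 && 10 * score_sum / (k - 1) >= cfg$dust_threshold
      if (n > w) {
        for (s in 2:(n - w + 1)) {
          rem(trip[s - 1])
          add(trip[s + wt - 1])
          flagged[s] <- k >= 2 &&
            10 * score_sum / (k - 1) >= cfg$dust_threshold
        }
      }
      if (any(flagged)) {
        iv <- IRanges::reduce(IRanges::IRanges(start = which(flagged),
                                               width = w))
        out[[length(out) + 1]] <- data.frame(
          contig = nm, start = IRanges::start(iv),
          end = pmin(IRanges::end(iv), n), type = "lcr",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(0), start = integer(0),
               end = integer(0), type = character(0))
}
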