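#' Call CNV segments by dense breakpoint seeding and backward elimination
#'
#' A documented stand-in for genome-alteration detection by sparse
#' piecewise-constant fitting.  It mirrors that architecture in two
#' stages without reproducing the original sparse Bayesian learning:
#'
#' 1. *Dense candidate breakpoints*: every position whose standardized
#'    local jump statistic (difference of the `minseglen`-probe means
#'    flanking the position) exceeds `qnorm(1 - alpha/2)` and is a
#'    local maximum seeds a breakpoint.  Smaller `alpha` admits more
#'    candidates (a sparsity dial).
#' 2. *Backward elimination*: breakpoints whose between-segment
#'    t-statistic (pooled, with a robust first-difference noise scale)
#'    falls below `T` are removed iteratively, weakest first.
#'
#' Segments with at least `minseglen` probes whose |mean| exceeds the
#' caller's noise floor (`T * s / sqrt(n_probes)`) are emitted, with
#' state the sign of the mean and score the segment z-score against
#' the chromosome background.
#'
#' @param samples normalized [acgh_set()].
#' @param probes a `probe_set`.
#' @param alpha candidate-seeding sparsity parameter (default 0.2).
#' @param T t-statistic threshold for backward elimination (default 4.5).
#' @param minseglen minimal segment length in probes (default 5).
#' @return `data.frame` of segment calls: one row per segment with
#'   `individual_id`, `chrom`, probe/bp bounds, `state`, `mean_log2`,
#'   `n_probes`, `method = "gada_like"`, `score` (segment z-score).
#' @export
call_gada_like <- function(samples, probes, alpha = 0.2, T = 4.5,
                           minseglen = 5L) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  t0 <- stats::qnorm(1 - alpha / 2)
  call_by_chrom(samples, probes, function(y) {
    n <- length(y)
    s <- floor_sd(diff_sd(y))
    w <- as.integer(minseglen)
    if (n < 2L * w + 1L) return(NULL)
    ## stage 1: standardized local jump at each possible breakpoint
    S <- c(0, cumsum(y))
    k <- (w + 1L):(n - w + 1L)           # breakpoint before position k
    jump <- ((S[k + w] - S[k]) - (S[k] - S[k - w])) / w
    jz <- abs(jump) / (s * sqrt(2 / w))
    cand <- k[jz > t0]
    if (length(cand)) {                   # keep local maxima only
      jzc <- jz[match(cand, k)]
      keep <- vapply(seq_along(cand), function(q) {
        near <- abs(cand - cand[q]) <= w & seq_along(cand) != q
        all(jzc[q] >= jzc[near])
      }, logical(1))
      cand <- cand[keep]
    }
    if (!length(cand)) return(NULL)
    ## stage 2: backward elimination of weak breakpoints
    breaks <- backward_eliminate(y, sort(cand), s, T)
    if (!length(breaks)) return(NULL)
    seg <- segments_from_breaks(y, breaks)
    seg <- seg[seg$n >= minseglen &
                 abs(seg$mean) > T * s / sqrt(seg$n), , drop = FALSE]
    if (!nrow(seg)) return(NULL)
    data.frame(a = seg$a, b = seg$b,
               score = segment_z(seg$mean, y))
  }, minseglen, "gada_like")
}

# Remove, weakest first, every breakpoint whose between-segment
# t-statistic is below T.  Recomputes only the neighbours of each
# removed breakpoint.
backward_eliminate <- function(y, breaks, s, T) {
  repeat {
    if (!length(breaks)) return(breaks)
    seg <- segments_from_breaks(y, breaks)
    nl <- seg$n[-nrow(seg)]; nr <- seg$n[-1]
    tt <- abs(seg$mean[-nrow(seg)] - seg$mean[-1]) /
      (s * sqrt(1 / nl + 1 / nr))
    if (min(tt) >= T) return(breaks)
    breaks <- breaks[-which.min(tt)]
  }
}
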