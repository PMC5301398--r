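#' Call CNV segments by sliding-window scan with carrier probabilities
#'
#' A documented stand-in for window-based CNV detection.  A window of
#' `r` consecutive probes slides along each chromosome; windows whose
#' standardized mean exceeds `T` seed candidate regions.  Overlapping
#' same-sign significant windows are merged, each candidate is expanded
#' by one window width and its boundaries refined to the local optimum
#' of the arc statistic.  The carrier probability of a refined region
#' is the posterior probability of a two-component Gaussian contrast:
#' non-carrier probes ~ N(0, s^2) versus carrier probes ~ N(0, (a s)^2)
#' (copy-number deviations of scale `a` noise units), with prior
#' carrier probability `P`:
#' \deqn{\Pr(carrier \mid x) = \frac{P \, L_1(x)}{P \, L_1(x) + (1 - P) L_0(x)}}
#' Regions with at least `m` probes are emitted with the carrier
#' probability as score; downstream filtering requires score >= 0.8.
#'
#' @param samples normalized [acgh_set()].
#' @param probes a `probe_set`.
#' @param r window size in probes (default 20).
#' @param T window-score threshold (default 4).
#' @param m minimal region size in probes (default 5).
#' @param a carrier-component scale in noise-sd units (default 2.1).
#' @param P prior carrier probability per region (default 0.001).
#' @return `data.frame` of segment calls with `method = "window_like"`
#'   and `score` the carrier probability.
#' @export
call_window_like <- function(samples, probes, r = 20L, T = 4, m = 5L,
                             a = 2.1, P = 0.001) {
  if (a <= 1) stop("'a' must exceed 1 (carrier scale in noise units)")
  if (P <= 0 || P >= 1) stop("'P' must be in (0, 1)")
  call_by_chrom(samples, probes, function(y) {
    n <- length(y)
    if (n < r) return(NULL)
    s <- floor_sd(diff_sd(y))
    S <- c(0, cumsum(y))
    wm <- (S[(r + 1L):(n + 1L)] - S[1:(n - r + 1L)]) / r   # window means
    z <- wm / (s / sqrt(r))
    sig <- which(abs(z) > T)
    if (!length(sig)) return(NULL)
    ## merge overlapping same-sign significant windows
    grp <- cumsum(c(TRUE, diff(sig) > r | diff(sign(z[sig])) != 0))
    segs <- lapply(split(sig, grp), function(ix) {
      lo <- max(1L, min(ix) - r)
      hi <- min(n, max(ix) + 2L * r)       # windows cover [ix, ix + r - 1]
      yy <- y[lo:hi]
      ## refine edges within the expanded candidate
      i0 <- min(ix) - lo + 1L
      j0 <- min(max(ix) + r, hi) - lo + 1L
      edges <- refine_arc(yy, i0, max(j0, i0 + 1L), s)
      a1 <- lo + edges[1] - 1L
      b1 <- lo + edges[2] - 1L             # half-open in y coordinates
      if (b1 - a1 < m) return(NULL)
      x <- y[a1:(b1 - 1L)]
      ll1 <- sum(stats::dnorm(x, 0, a * s, log = TRUE))
      ll0 <- sum(stats::dnorm(x, 0, s, log = TRUE))
      post <- 1 / (1 + exp(log((1 - P) / P) + ll0 - ll1))
      data.frame(a = a1, b = b1, score = post)
    })
    segs <- do.call(rbind, segs)
    if (is.null(segs) || !nrow(segs)) return(NULL)
    ## drop duplicates if two seed groups refined to the same region
    segs[!duplicated(segs[, c("a", "b")]), , drop = FALSE]
  }, m, "window_like")
}
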