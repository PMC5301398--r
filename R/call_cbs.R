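#' Call CNV segments by recursive arc-based binary segmentation
#'
#' A documented stand-in for circular binary segmentation.  Each
#' chromosome is segmented recursively: within the current segment the
#' maximal standardized arc statistic (contrast of a candidate
#' sub-interval against the rest of the segment, scanned over all
#' positions and a dense-then-geometric width grid) is compared with
#' its permutation reference — the same scan on `n_perm` random
#' shuffles of the segment values; the change is accepted when the
#' permutation p-value is below `p_accept` (default 0.01 with >= 100
#' permutations).  Accepted arcs are refined to the local optimum of
#' the arc statistic and split the segment in three.
#'
#' After segmentation, splits whose between-segment mean difference is
#' below `undo_sd` times the robust noise sd are undone (weakest
#' first), and remaining breakpoints whose removal increases the total
#' within-segment sum of squares by less than a fraction `undo_prune`
#' are pruned.  When `smooth = TRUE`, single-probe outliers more than
#' 3 noise-sd away from the local 3-probe median are shrunk to that
#' median before segmentation, so isolated spikes never seed calls.
#'
#' @param samples normalized [acgh_set()].
#' @param probes a `probe_set`.
#' @param minseglen minimal emitted segment length in probes.
#' @param undo_sd undo threshold in noise-sd units (default 3).
#' @param undo_prune relative SSE-increase threshold for pruning
#'   (default 0.05).
#' @param smooth smooth single-probe outliers first (default TRUE).
#' @param n_perm permutations per split test (default 100).
#' @param p_accept permutation p-value below which a split is accepted.
#' @return `data.frame` of segment calls with `method = "cbs_like"`.
#' @export
call_cbs_like <- function(samples, probes, minseglen = 5L, undo_sd = 3,
                          undo_prune = 0.05, smooth = TRUE,
                          n_perm = 100L, p_accept = 0.01) {
  if (n_perm < 10L) stop("'n_perm' must be >= 10")
  call_by_chrom(samples, probes, function(y) {
    s <- floor_sd(diff_sd(y))
    if (smooth) y <- smooth_outliers(y, s)
    breaks <- cbs_segment(y, s, minseglen, n_perm, p_accept)
    breaks <- undo_splits(y, breaks, s, undo_sd)
    breaks <- prune_splits(y, breaks, undo_prune)
    if (!length(breaks)) return(NULL)
    seg <- segments_from_breaks(y, breaks)
    seg <- seg[seg$n >= minseglen &
                 abs(seg$mean) > 3 * s / sqrt(seg$n), , drop = FALSE]
    if (!nrow(seg)) return(NULL)
    data.frame(a = seg$a, b = seg$b, score = segment_z(seg$mean, y))
  }, minseglen, "cbs_like")
}

# Shrink single-probe outliers (> 3 s from the running 3-probe median)
# to that median.
smooth_outliers <- function(y, s) {
  n <- length(y)
  if (n < 3L) return(y)
  med3 <- y
  med3[2:(n - 1)] <- vapply(2:(n - 1), function(i)
    stats::median(y[(i - 1):(i + 1)]), numeric(1))
  out <- abs(y - med3) > 3 * s
  y[out] <- med3[out]
  y
}

# Recursive arc-splitting with a permutation reference.  Returns
# breakpoint positions (2 .. n) relative to y.
cbs_segment <- function(y, s, minseglen, n_perm, p_accept) {
  n <- length(y)
  breaks <- integer(0)
  stack <- list(c(1L, n + 1L))            # segments [a, b) to test
  max_reject <- ceiling(p_accept * (n_perm + 1)) - 1L
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- seg[1]; b <- seg[2]
    m <- b - a
    if (m < 2L * minseglen) next
    yy <- y[a:(b - 1L)]
    widths <- scan_widths(m, w_min = 2L)
    if (!length(widths)) next
    ## observed scan + permutation reference (compiled kernel, early
    ## rejection once the p-value cannot fall below p_accept)
    obs <- .cbs_perm_test(yy, widths, s, n_perm, max_reject)
    if (!is.finite(obs$t)) next
    if (obs$count > max_reject) next      # p >= p_accept: stop splitting
    edges <- refine_arc(yy, obs$i, obs$i + obs$w, s)
    i <- edges[1]; j <- edges[2]
    new_breaks <- c(if (i > 1L) a + i - 1L, if (j <= m) a + j - 1L)
    if (!length(new_breaks)) next
    breaks <- c(breaks, new_breaks)
    bounds <- sort(unique(c(a, new_breaks, b)))
    for (k in seq_len(length(bounds) - 1L))
      stack[[length(stack) + 1L]] <- c(bounds[k], bounds[k + 1L])
  }
  sort(unique(breaks))
}

# Undo splits whose adjacent-mean difference is below undo_sd * s,
# weakest first.
undo_splits <- function(y, breaks, s, undo_sd) {
  repeat {
    if (!length(breaks)) return(breaks)
    seg <- segments_from_breaks(y, breaks)
    d <- abs(diff(seg$mean))
    if (min(d) >= undo_sd * s) return(breaks)
    breaks <- breaks[-which.min(d)]
  }
}

# Prune breakpoints whose removal grows the total within-segment SSE
# by less than a fraction `undo_prune`.
prune_splits <- function(y, breaks, undo_prune) {
  sse <- function(brk) {
    seg <- segments_from_breaks(y, brk)
    sum(vapply(seq_len(nrow(seg)), function(k) {
      v <- y[seg$a[k]:(seg$b[k] - 1L)]
      sum((v - mean(v))^2)
    }, numeric(1)))
  }
  repeat {
    if (!length(breaks)) return(breaks)
    base <- sse(breaks)
    rel <- vapply(seq_along(breaks), function(q)
      (sse(breaks[-q]) - base) / max(base, .Machine$double.eps),
      numeric(1))
    if (min(rel) >= undo_prune) return(breaks)
    breaks <- breaks[-which.min(rel)]
  }
}
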