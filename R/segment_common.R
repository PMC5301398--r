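## Internals shared by the three segmentation stand-ins.  Each caller
## works chromosome-by-chromosome on the finite log2 values of one
## array; `idx_map` maps positions in that working vector back to rows
## of the probe table.

# Iterate over (individual, chromosome), collect calls.
call_by_chrom <- function(samples, probes, fun, minseglen, method) {
  stop_if_not_acgh(samples)
  stop_if_not_probe_set(probes)
  res <- list()
  for (j in seq_len(ncol(samples$log2))) {
    ind <- samples$info$individual_id[j]
    for (ch in unique(probes$chrom)) {
      idx <- which(probes$chrom == ch)
      yy <- samples$log2[idx, j]
      ok <- is.finite(yy)
      if (sum(ok) < minseglen) {
        message(method, ": chromosome ", ch, " of ", ind, " has fewer than ",
                minseglen, " usable probes; no calls")
        next
      }
      y <- yy[ok]
      idx_map <- idx[ok]
      segs <- fun(y)
      if (!is.null(segs) && nrow(segs))
        res[[length(res) + 1L]] <-
          emit_segments(segs, y, idx_map, probes, ind, ch, method)
    }
  }
  if (!length(res)) return(empty_calls())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  data.frame(individual_id = character(), chrom = character(),
             start_probe = integer(), end_probe = integer(),
             start_bp = numeric(), end_bp = numeric(),
             state = character(), mean_log2 = numeric(),
             n_probes = integer(), method = character(),
             score = numeric(), stringsAsFactors = FALSE)
}

# segs: data.frame(a, b, score) with [a, b) positions in the working
# vector; emitted segments carry global probe indices and bp bounds.
emit_segments <- function(segs, y, idx_map, probes, ind, ch, method) {
  m <- vapply(seq_len(nrow(segs)),
              function(k) mean(y[segs$a[k]:(segs$b[k] - 1L)]), numeric(1))
  data.frame(
    individual_id = ind, chrom = ch,
    start_probe = idx_map[segs$a], end_probe = idx_map[segs$b - 1L] + 1L,
    start_bp = probes$start[idx_map[segs$a]],
    end_bp = probes$end[idx_map[segs$b - 1L]],
    state = ifelse(m > 0, "gain", "loss"),
    mean_log2 = m, n_probes = segs$b - segs$a,
    method = method, score = segs$score,
    stringsAsFactors = FALSE
  )
}

# Segment means/lengths from a sorted breakpoint vector b (positions
# 1 < b < n+1; segments are [c(1,b), c(b,n+1)) half-open).
segments_from_breaks <- function(y, breaks) {
  bounds <- c(1L, sort(breaks), length(y) + 1L)
  a <- bounds[-length(bounds)]
  b <- bounds[-1]
  S <- c(0, cumsum(y))
  data.frame(a = a, b = b, n = b - a, mean = (S[b] - S[a]) / (b - a))
}

# Arc statistic: standardized contrast of [i, j) against the rest of
# [1, n].  Used by the binary-segmentation and window callers.
arc_t <- function(S, n, i, j, s) {
  w <- j - i
  mean_in <- (S[j] - S[i]) / w
  mean_out <- (S[n + 1L] - (S[j] - S[i])) / (n - w)
  (mean_in - mean_out) / (s * sqrt(1 / w + 1 / (n - w)))
}

# Refine arc edges to the local optimum of |arc_t| by coordinate
# ascent (exact on noise-free steps).  y is the working vector of one
# segment; returns c(i, j) with [i, j) half-open, i >= 1, j <= n + 1.
refine_arc <- function(y, i, j, s, max_iter = 4L) {
  n <- length(y)
  S <- c(0, cumsum(y))
  for (it in seq_len(max_iter)) {
    i_old <- i; j_old <- j
    ii <- seq_len(j - 1L)                       # candidate left edges
    w <- j - ii
    keep <- w < n
    ii <- ii[keep]; w <- w[keep]
    tv <- ((S[j] - S[ii]) / w - (S[n + 1L] - (S[j] - S[ii])) / (n - w)) /
      (s * sqrt(1 / w + 1 / (n - w)))
    i <- ii[which.max(abs(tv))]
    jj <- seq(i + 1L, n + 1L)                   # candidate right edges
    w <- jj - i
    keep <- w < n
    jj <- jj[keep]; w <- w[keep]
    tv <- ((S[jj] - S[i]) / w - (S[n + 1L] - (S[jj] - S[i])) / (n - w)) /
      (s * sqrt(1 / w + 1 / (n - w)))
    j <- jj[which.max(abs(tv))]
    if (i == i_old && j == j_old) break
  }
  c(i, j)
}

# Width grid for arc scans: exhaustive over small widths, geometric
# above, capped at half the segment.
scan_widths <- function(n, w_min = 2L, w_cap = 5000L) {
  half <- floor(n / 2)
  if (half < w_min) return(integer(0))
  small <- w_min:min(12L, half)
  w <- max(small)
  geo <- integer(0)
  while (w < min(half, w_cap)) {
    w <- min(ceiling(w * 1.8), half, w_cap)
    geo <- c(geo, w)
  }
  unique(c(small, geo))
}

# Max |arc_t| over all start positions and the width grid.
# Returns list(t, i, w) or NULL when the segment is too short.
max_arc_stat <- function(y, s, widths) {
  n <- length(y)
  if (!length(widths)) return(NULL)
  S <- c(0, cumsum(y))
  best <- list(t = -Inf, i = NA_integer_, w = NA_integer_)
  for (w in widths) {
    i <- 0:(n - w)                     # arc [i+1, i+w] in 1-based values
    mean_in <- (S[i + w + 1L] - S[i + 1L]) / w
    mean_out <- (S[n + 1L] - (S[i + w + 1L] - S[i + 1L])) / (n - w)
    tv <- abs(mean_in - mean_out) / (s * sqrt(1 / w + 1 / (n - w)))
    k <- which.max(tv)
    if (tv[k] > best$t) best <- list(t = tv[k], i = i[k] + 1L, w = w)
  }
  best
}

# z-score of a segment mean against its chromosome background:
# robust center (median) and scale (1.4826 * MAD) of all probes on the
# chromosome.  The basis is configurable in apply_call_filters().
segment_z <- function(mean_log2, chrom_values) {
  md <- stats::median(chrom_values, na.rm = TRUE)
  sc <- floor_sd(robust_sd(chrom_values))
  (mean_log2 - md) / sc
}
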