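## Internal helpers shared across modules.

# Derive a per-stage RNG seed from one master seed so that independent
# simulation stages draw from distinct, reproducible substreams.
# Kept strictly below 2^31 - 1 (R integer range).
derive_seed <- function(seed, stream) {
  offsets <- c(
    probes = 101, cnv = 211, acgh = 307, expr = 401,
    perm = 503, genes = 601, misc = 701
  )
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  as.integer((abs(as.numeric(seed)) * 1009 + offsets[[stream]]) %% 2147483647)
}

# Robust per-chromosome noise-level estimate from first differences.
# diff(y) ~ N(0, 2*sigma^2) for locally flat signal, so
# sigma = median(|diff|) / (sqrt(2) * qnorm(3/4)); the qnorm(3/4)
# factor makes the estimator consistent for Gaussian noise.  CNV
# segments contribute only O(#breakpoints) outlying differences, so
# the median is essentially unaffected by the CNVs themselves.
diff_sd <- function(y) {
  y <- y[is.finite(y)]
  if (length(y) < 3L) return(NA_real_)
  stats::median(abs(diff(y))) / (sqrt(2) * stats::qnorm(0.75))
}

# Robust scale used for z-score filtering: 1.4826 * MAD (mad() default).
robust_sd <- function(y) stats::mad(y, na.rm = TRUE)

# Guard against exactly-zero noise estimates on noise-free input.
floor_sd <- function(s, eps = 1e-10) max(s, eps, na.rm = TRUE)

# Half-open [start, end) bp intervals -> IRanges (1-based, closed).
# Intervals overlap in half-open coordinates iff they share >= 1 bp,
# which maps exactly to IRanges overlap after this shift.
as_iranges <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

# Single-linkage clustering of half-open intervals on one chromosome:
# returns an integer cluster id per interval (connected components of
# the any-overlap graph, computed via IRanges::reduce).
overlap_clusters <- function(start, end) {
  ir <- as_iranges(start, end)
  # min.gapwidth = 0: merge only truly overlapping ranges, never
  # abutting ones (touching half-open intervals share no bp)
  red <- IRanges::reduce(ir, min.gapwidth = 0L)
  hits <- IRanges::findOverlaps(ir, red, type = "any")
  cl <- integer(length(start))
  cl[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  cl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_probe_set <- function(probes) {
  need <- c("probe_id", "chrom", "start", "end", "gc")
  if (!is.data.frame(probes) || !all(need %in% names(probes)))
    stop("'probes' must be a probe set data.frame with columns ",
         paste(need, collapse = ", "))
  invisible(probes)
}

stop_if_not_acgh <- function(samples) {
  if (!inherits(samples, "acgh_set"))
    stop("'samples' must be an 'acgh_set' (see simulate_acgh / acgh_set)")
  invisible(samples)
}
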