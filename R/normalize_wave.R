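#' Correct chromosomal wave artifacts by local regression
#'
#' Per chromosome and array, fits a locally linear LOESS model of
#' log2-ratio on probe position (tricube weights, one robustness
#' iteration) and subtracts the fitted trend.  The smoothing window is
#' parameterized as an absolute number of probes per local fit
#' (`span_probes`), not a proportion, so the effective genomic
#' bandwidth does not depend on chromosome size.
#'
#' Chromosomes with fewer probes than `span_probes` fall back to
#' subtracting the chromosome median (with a message).  Probe order,
#' count and coordinates are never altered.
#'
#' @param samples an [acgh_set()] (typically GC-residualized).
#' @param probes a `probe_set` aligned with `samples`.
#' @param span_probes window size in probes per local fit (>= 10).
#' @return a wave-corrected [acgh_set()].
#' @export
wave_correct <- function(samples, probes, span_probes = 4000L) {
  stop_if_not_acgh(samples)
  stop_if_not_probe_set(probes)
  if (span_probes < 10L) stop("'span_probes' must be >= 10")
  y <- samples$log2
  out <- y
  for (ch in unique(probes$chrom)) {
    idx <- which(probes$chrom == ch)
    n <- length(idx)
    pos <- probes$start[idx]
    if (n < span_probes) {
      message("wave_correct: chromosome ", ch, " has ", n,
              " probes < span ", span_probes, "; subtracting the median")
      for (j in seq_len(ncol(y)))
        out[idx, j] <- y[idx, j] - stats::median(y[idx, j], na.rm = TRUE)
      next
    }
    for (j in seq_len(ncol(y))) {
      yj <- y[idx, j]
      ok <- is.finite(yj)
      if (sum(ok) < 10L) {
        out[idx, j] <- yj - stats::median(yj, na.rm = TRUE)
        next
      }
      fit <- stats::loess(
        yj[ok] ~ pos[ok], span = min(1, span_probes / sum(ok)), degree = 1,
        family = "symmetric",
        control = stats::loess.control(surface = "interpolate",
                                       iterations = 2L))
      res <- yj
      res[ok] <- yj[ok] - stats::fitted(fit)
      out[idx, j] <- res
    }
  }
  acgh_set(out, samples$info)
}

#' Choose the wave-correction span by median SNR improvement
#'
#' Applies [wave_correct()] at each candidate span, measures each
#' array's mean signal-to-noise ratio over a CNV test set before and
#' after correction ([compute_snr()]), and summarizes each span by the
#' median across arrays of the relative improvement
#' `(after - before) / before`.  The span with the largest median
#' improvement is chosen; ties go to the smaller span.  If every span
#' degrades the median SNR the chosen span is `NA` ("no correction"),
#' with the full improvement table still returned.
#'
#' @param samples an [acgh_set()] (GC-residualized, wave-uncorrected).
#' @param probes a `probe_set`.
#' @param candidate_spans integer vector of window sizes in probes.
#' @param test_set CNV test intervals, `data.frame(chrom, start, end)`,
#'   e.g. from [build_snr_test_set()].
#' @return list with `span` (chosen, or `NA_integer_`) and `table`
#'   (`data.frame(span_probes, median_improvement)`).
#' @export
select_wave_span <- function(samples, probes,
                             candidate_spans = c(1000L, 2000L, 4000L,
                                                 8000L, 16000L),
                             test_set) {
  stop_if_not_acgh(samples)
  if (length(candidate_spans) < 1L)
    stop("at least one candidate span is required")
  candidate_spans <- sort(unique(as.integer(candidate_spans)))
  before <- compute_snr(samples, probes, test_set)$mean_snr
  impr <- vapply(candidate_spans, function(sp) {
    after <- compute_snr(wave_correct(samples, probes, sp),
                         probes, test_set)$mean_snr
    stats::median((after - before) / before)
  }, numeric(1))
  tab <- data.frame(span_probes = candidate_spans,
                    median_improvement = impr)
  best <- which(impr == max(impr))[1]  # spans sorted: first max = smallest
  span <- if (max(impr) > 0) candidate_spans[best] else NA_integer_
  list(span = span, table = tab)
}
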