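#' Filter raw segment calls by z-score or carrier probability
#'
#' Applies the per-method confidence filters to raw segmentation
#' output.  For `gada_like` and `cbs_like` calls a z-score is computed
#' for each call as the segment mean log2-ratio centred by the
#' chromosome median and scaled by the robust chromosome sd
#' (1.4826 x MAD), and only calls with `z > z_cut` or `z < -z_cut` are
#' retained.  For `window_like` calls a carrier probability of at
#' least `min_carrier_prob` is required (inclusive).  A minimal
#' segment length of `minseglen` probes is re-enforced for all
#' methods.
#'
#' @param calls `data.frame` of segment calls from the callers.
#' @param samples the [acgh_set()] the calls were made on (for the
#'   chromosome background of the z-scores).
#' @param probes a `probe_set`.
#' @param z_cut z-score threshold (default 1.5, strict inequality).
#' @param min_carrier_prob carrier-probability threshold (default 0.8,
#'   inclusive).
#' @param minseglen minimal probes per call (default 5).
#' @return the filtered calls, with `score` replaced by the recomputed
#'   z-score for `gada_like`/`cbs_like` calls.
#' @export
apply_call_filters <- function(calls, samples, probes, z_cut = 1.5,
                               min_carrier_prob = 0.8, minseglen = 5L) {
  if (is.null(calls) || nrow(calls) == 0L) return(empty_calls())
  known <- c("gada_like", "cbs_like", "window_like")
  bad <- setdiff(unique(calls$method), known)
  if (length(bad)) stop("unknown calling method tag(s): ",
                        paste(bad, collapse = ", "))
  stop_if_not_acgh(samples)
  ## per-(individual, chromosome) robust background, computed once
  key <- paste(calls$individual_id, calls$chrom)
  stats_for <- new.env(parent = emptyenv())
  for (kk in unique(key)) {
    k1 <- which(key == kk)[1]
    j <- match(calls$individual_id[k1], samples$info$individual_id)
    chv <- samples$log2[probes$chrom == calls$chrom[k1], j]
    assign(kk, c(stats::median(chv, na.rm = TRUE),
                 floor_sd(robust_sd(chv))), envir = stats_for)
  }
  keep <- logical(nrow(calls))
  score <- calls$score
  for (k in seq_len(nrow(calls))) {
    if (calls$n_probes[k] < minseglen) next
    if (calls$method[k] == "window_like") {
      keep[k] <- calls$score[k] >= min_carrier_prob
    } else {
      ms <- get(key[k], envir = stats_for)
      z <- (calls$mean_log2[k] - ms[1]) / ms[2]
      score[k] <- z
      keep[k] <- z > z_cut || z < -z_cut
    }
  }
  out <- calls
  out$score <- score
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run all three callers and the confidence filters
#'
#' Convenience wrapper: calls [call_gada_like()], [call_cbs_like()]
#' and [call_window_like()] with their default (study) parameters and
#' applies [apply_call_filters()] to the combined call list.
#'
#' @param samples normalized [acgh_set()].
#' @param probes a `probe_set`.
#' @param methods subset of the three method names to run.
#' @param ... passed on to [apply_call_filters()].
#' @return filtered combined `data.frame` of calls.
#' @export
call_cnvs <- function(samples, probes,
                      methods = c("gada_like", "cbs_like", "window_like"),
                      ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  calls <- list()
  if ("gada_like" %in% methods)
    calls$gada <- call_gada_like(samples, probes)
  if ("cbs_like" %in% methods)
    calls$cbs <- call_cbs_like(samples, probes)
  if ("window_like" %in% methods)
    calls$win <- call_window_like(samples, probes)
  apply_call_filters(do.call(rbind, calls), samples, probes, ...)
}
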