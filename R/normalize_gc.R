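#' Remove probe GC-content bias by quadratic residualization
#'
#' Fits, per array, the linear model
#' \deqn{\log_2(R_i) = \alpha + \beta_1 GC_i + \beta_2 GC_i^2 + \varepsilon_i}
#' of probe log2-ratio on probe GC content and subtracts the fitted
#' effect (including the intercept), i.e. residualizes each array.
#' Probes with missing log2-ratio are excluded from the fit and
#' re-inserted as missing in the output.
#'
#' Refitting the same model on the returned data yields coefficients
#' numerically indistinguishable from zero.
#'
#' @param samples an [acgh_set()].
#' @param probes a `probe_set` aligned with `samples`.
#' @return list with `samples` (residualized `acgh_set`) and `fits`,
#'   a `data.frame(individual_id, alpha, beta1, beta2, residual_sd)`.
#' @export
gc_residualize <- function(samples, probes) {
  stop_if_not_acgh(samples)
  stop_if_not_probe_set(probes)
  if (nrow(samples$log2) != nrow(probes))
    stop("'samples' and 'probes' have different probe counts")
  gc <- probes$gc
  if (length(unique(gc[is.finite(gc)])) < 3L)
    stop("GC content is (near-)constant: quadratic GC design matrix ",
         "is rank deficient; cannot residualize")
  X <- cbind(1, gc, gc^2)
  y <- samples$log2
  out <- y
  fits <- data.frame(individual_id = samples$info$individual_id,
                     alpha = NA_real_, beta1 = NA_real_, beta2 = NA_real_,
                     residual_sd = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(y))) {
    ok <- is.finite(y[, j]) & is.finite(gc)
    b <- qr.coef(qr(X[ok, , drop = FALSE]), y[ok, j])
    r <- y[ok, j] - X[ok, , drop = FALSE] %*% b
    out[ok, j] <- r
    out[!ok, j] <- NA_real_
    fits[j, 2:5] <- c(b, stats::sd(r))
  }
  list(samples = acgh_set(out, samples$info), fits = fits)
}
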