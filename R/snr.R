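#' Signal-to-noise ratio of CNV test-set probes
#'
#' For every probe `i` inside a test-set CNV interval,
#' \deqn{SNR_i = |\log_2(R_i)| / \sigma_{Ci}}
#' where `sigma_Ci` is the standard deviation of *all* probes on probe
#' `i`'s chromosome for that array (CNV probes are not masked).  The
#' per-array summary is the mean (and median) SNR over all test-set
#' probes; the mean is the metric used for normalization evaluation.
#'
#' @param samples an [acgh_set()].
#' @param probes a `probe_set`.
#' @param test_set `data.frame(chrom, start, end)` of CNV intervals
#'   (0-based half-open bp).
#' @return `data.frame(individual_id, n_probes, mean_snr, median_snr)`
#'   with the per-probe SNR vectors in attribute `"per_probe"` (a list
#'   of numeric vectors, one per array).
#' @export
compute_snr <- function(samples, probes, test_set) {
  stop_if_not_acgh(samples)
  stop_if_not_probe_set(probes)
  if (is.null(test_set) || nrow(test_set) == 0L)
    stop("empty CNV test set: SNR is undefined")
  sel <- unique(unlist(lapply(seq_len(nrow(test_set)), function(k)
    probes_in_interval(probes, test_set$chrom[k],
                       test_set$start[k], test_set$end[k]))))
  if (!length(sel))
    stop("no probes fall inside the CNV test set")
  sel <- sort(sel)
  y <- samples$log2
  per_probe <- vector("list", ncol(y))
  out <- data.frame(individual_id = samples$info$individual_id,
                    n_probes = length(sel), mean_snr = NA_real_,
                    median_snr = NA_real_, stringsAsFactors = FALSE)
  chrom_of <- probes$chrom
  for (j in seq_len(ncol(y))) {
    sig <- vapply(unique(chrom_of), function(ch)
      stats::sd(y[chrom_of == ch, j], na.rm = TRUE), numeric(1))
    snr <- abs(y[sel, j]) / sig[chrom_of[sel]]
    per_probe[[j]] <- unname(snr)
    out$mean_snr[j] <- mean(snr, na.rm = TRUE)
    out$median_snr[j] <- stats::median(snr, na.rm = TRUE)
  }
  attr(out, "per_probe") <- per_probe
  out
}

#' Build the CNV test set used for SNR-based span selection
#'
#' Calls CNVs on (GC-normalized, wave-uncorrected) arrays with all
#' three segmentation methods at default parameters, applies the
#' z-score / carrier-probability filters, forms two-of-three consensus
#' CNVs per individual and merges them into regions; regions detected
#' in at least `min_individuals` individuals form the test set.
#'
#' @param samples GC-residualized [acgh_set()].
#' @param probes a `probe_set`.
#' @param min_individuals minimal number of carrier individuals.
#' @return `data.frame(chrom, start, end)` of test intervals.
#' @export
build_snr_test_set <- function(samples, probes, min_individuals = 2L) {
  calls <- call_cnvs(samples, probes)
  cons <- consensus_per_individual(calls)
  cnvrs <- build_cnvrs(cons)
  keep <- cnvrs$n_carriers >= min_individuals
  cnvrs[keep, c("chrom", "start", "end"), drop = FALSE]
}
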