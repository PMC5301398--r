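#' Quantitative CNVR genotypes as median log2-ratios
#'
#' The genotype of individual `i` at a CNVR is the median of `i`'s
#' normalized log2-ratios over all probes inside the CNVR — computed
#' for every individual, carrier or not (non-carrier values hover near
#' zero).  Quantitative genotypes side-step discrete copy-number
#' mis-assignments by the callers.  Ties at even probe counts take the
#' mean of the two middle values (`stats::median` convention).
#'
#' @param cnvrs CNVR table from [build_cnvrs()] / [filter_cnvrs()].
#' @param samples normalized [acgh_set()].
#' @param probes a `probe_set`.
#' @return numeric matrix, CNVRs x individuals, dimnames
#'   (`cnvr_id`, `individual_id`).
#' @export
quantitative_genotypes <- function(cnvrs, samples, probes) {
  stop_if_not_acgh(samples)
  stop_if_not_probe_set(probes)
  G <- matrix(NA_real_, nrow(cnvrs), ncol(samples$log2),
              dimnames = list(cnvrs$cnvr_id, samples$info$individual_id))
  for (k in seq_len(nrow(cnvrs))) {
    idx <- probes_in_interval(probes, cnvrs$chrom[k],
                              cnvrs$start[k], cnvrs$end[k])
    if (!length(idx))
      stop("CNVR ", cnvrs$cnvr_id[k], " contains no probes; cannot genotype")
    G[k, ] <- apply(samples$log2[idx, , drop = FALSE], 2,
                    stats::median, na.rm = TRUE)
  }
  G
}
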