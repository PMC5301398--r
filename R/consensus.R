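#' Two-of-three consensus CNVs per individual
#'
#' For each individual and chromosome, calls from the different
#' methods are grouped by single-linkage interval overlap (any shared
#' bp).  A group supported by at least `min_methods` distinct methods
#' with a unique copy-number state becomes one consensus CNV spanning
#' the union of its member intervals; groups containing both gain and
#' loss calls are dropped entirely (conflicting states), as are groups
#' supported by fewer methods.
#'
#' @param calls filtered segment calls (all methods, all individuals).
#' @param min_methods minimal number of distinct supporting methods
#'   (default 2).
#' @return `data.frame(individual_id, chrom, start, end, state,
#'   n_methods, mean_log2)` with 0-based half-open bp intervals;
#'   `mean_log2` is the probe-count-weighted mean of member segment
#'   means.
#' @export
consensus_per_individual <- function(calls, min_methods = 2L) {
  empty <- data.frame(individual_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      state = character(), n_methods = integer(),
                      mean_log2 = numeric(), stringsAsFactors = FALSE)
  if (is.null(calls) || nrow(calls) == 0L) return(empty)
  out <- list()
  for (ind in unique(calls$individual_id)) {
    for (ch in unique(calls$chrom[calls$individual_id == ind])) {
      cc <- calls[calls$individual_id == ind & calls$chrom == ch, ,
                  drop = FALSE]
      cl <- overlap_clusters(cc$start_bp, cc$end_bp)
      for (g in unique(cl)) {
        gg <- cc[cl == g, , drop = FALSE]
        if (length(unique(gg$method)) < min_methods) next
        if (length(unique(gg$state)) > 1L) next  # gain/loss conflict
        out[[length(out) + 1L]] <- data.frame(
          individual_id = ind, chrom = ch,
          start = min(gg$start_bp), end = max(gg$end_bp),
          state = gg$state[1],
          n_methods = length(unique(gg$method)),
          mean_log2 = sum(gg$mean_log2 * gg$n_probes) / sum(gg$n_probes),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$individual_id, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Convert a simulated CNV truth table to consensus-CNV form
#'
#' Ground-truth planted CNVs rendered as if they were perfect
#' consensus calls (all three methods agreeing), for testing the
#' region-building, genotyping and association stages independently of
#' the segmentation stage.
#'
#' @param truth output of [simulate_cnv_truth()].
#' @return consensus `data.frame` as from [consensus_per_individual()].
#' @export
truth_as_consensus <- function(truth) {
  data.frame(individual_id = truth$individual_id, chrom = truth$chrom,
             start = truth$start, end = truth$end, state = truth$state,
             n_methods = 3L, mean_log2 = truth$effect,
             stringsAsFactors = FALSE)
}
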