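#' Merge consensus CNVs across individuals into CNV regions
#'
#' Single-linkage merge of overlapping consensus CNVs across all
#' individuals: each connected component of the any-overlap graph
#' becomes one CNVR spanning the union of its members.  Carrier
#' individuals and their states are recorded; an individual
#' contributing more than one consensus CNV to a CNVR marks it as a
#' complex locus.
#'
#' @param consensus consensus CNVs from [consensus_per_individual()]
#'   (or [truth_as_consensus()]).
#' @return `data.frame(cnvr_id, chrom, start, end, n_carriers,
#'   complex_flag, has_deletion, has_duplication)`, sorted by
#'   coordinate, with attribute `"carriers"`: a
#'   `data.frame(cnvr_id, individual_id, state, n_cnv, mean_log2)`.
#' @export
build_cnvrs <- function(consensus) {
  empty <- data.frame(cnvr_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_carriers = integer(), complex_flag = logical(),
                      has_deletion = logical(), has_duplication = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(consensus) || nrow(consensus) == 0L) {
    attr(empty, "carriers") <- data.frame(
      cnvr_id = character(), individual_id = character(),
      state = character(), n_cnv = integer(), mean_log2 = numeric(),
      stringsAsFactors = FALSE)
    return(empty)
  }
  regions <- list()
  carriers <- list()
  for (ch in unique(consensus$chrom)) {
    cc <- consensus[consensus$chrom == ch, , drop = FALSE]
    cl <- overlap_clusters(cc$start, cc$end)
    for (g in unique(cl)) {
      gg <- cc[cl == g, , drop = FALSE]
      ncnv <- table(gg$individual_id)
      carr <- do.call(rbind, lapply(names(ncnv), function(ind) {
        gi <- gg[gg$individual_id == ind, , drop = FALSE]
        data.frame(individual_id = ind,
                   state = if (length(unique(gi$state)) == 1L)
                     gi$state[1] else "mixed",
                   n_cnv = nrow(gi),
                   mean_log2 = mean(gi$mean_log2),
                   stringsAsFactors = FALSE)
      }))
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = min(gg$start), end = max(gg$end),
        n_carriers = length(ncnv),
        complex_flag = any(ncnv > 1L),
        has_deletion = any(gg$state == "loss"),
        has_duplication = any(gg$state == "gain"),
        stringsAsFactors = FALSE)
      carriers[[length(carriers) + 1L]] <- carr
    }
  }
  reg <- do.call(rbind, regions)
  ord <- order(reg$chrom, reg$start)
  reg <- reg[ord, , drop = FALSE]
  carriers <- carriers[ord]
  reg <- cbind(cnvr_id = sprintf("CNVR_%05d", seq_len(nrow(reg))), reg,
               stringsAsFactors = FALSE)
  carr <- do.call(rbind, lapply(seq_along(carriers), function(k)
    cbind(cnvr_id = reg$cnvr_id[k], carriers[[k]],
          stringsAsFactors = FALSE)))
  rownames(reg) <- rownames(carr) <- NULL
  attr(reg, "carriers") <- carr
  reg
}

#' Filter CNV regions by locus-level exclusion rules
#'
#' Removes CNVRs that are (i) complex loci (one individual carrying
#' more than one CNV in the region), (ii) located on a sex chromosome,
#' or (iii) located within `gap_margin_bp` of an inter-probe gap
#' larger than `gap_bp` (e.g. centromeres and assembly gaps, where
#' calls are unreliable).  Removal reasons are logged per CNVR in the
#' `"removed"` attribute of the result; counts always reconcile:
#' every input CNVR is either returned or logged.
#'
#' @param cnvrs CNVR table from [build_cnvrs()].
#' @param probes a `probe_set` (defines gap positions and known
#'   chromosomes).
#' @param sex_chrom_names chromosome names treated as sex chromosomes.
#' @param gap_bp minimal inter-probe distance that defines a gap
#'   (default 500 kb).
#' @param gap_margin_bp exclusion margin around such gaps
#'   (default 250 kb).
#' @return the retained CNVRs (carriers attribute subset accordingly)
#'   with attribute `"removed"`: `data.frame(cnvr_id, reason)`.
#' @export
filter_cnvrs <- function(cnvrs, probes,
                         sex_chrom_names = c("chrX", "chrY", "X", "Y"),
                         gap_bp = 5e5, gap_margin_bp = 2.5e5) {
  stop_if_not_probe_set(probes)
  known <- c(unique(probes$chrom), sex_chrom_names)
  bad <- setdiff(unique(cnvrs$chrom), known)
  if (length(bad))
    stop("CNVRs on unknown chromosome(s): ", paste(bad, collapse = ", "))

  ## exclusion zones: inter-probe gaps > gap_bp, widened by the margin
  zones <- do.call(rbind, lapply(unique(probes$chrom), function(ch) {
    pp <- probes[probes$chrom == ch, , drop = FALSE]
    if (nrow(pp) < 2L) return(NULL)
    gap_start <- pp$end[-nrow(pp)]
    gap_end <- pp$start[-1]
    big <- which(gap_end - gap_start > gap_bp)
    if (!length(big)) return(NULL)
    data.frame(chrom = ch,
               start = pmax(0, gap_start[big] - gap_margin_bp),
               end = gap_end[big] + gap_margin_bp,
               stringsAsFactors = FALSE)
  }))

  in_gap_zone <- function(k) {
    if (is.null(zones)) return(FALSE)
    any(zones$chrom == cnvrs$chrom[k] &
          zones$start < cnvrs$end[k] & zones$end > cnvrs$start[k])
  }
  reasons <- character(nrow(cnvrs))
  for (k in seq_len(nrow(cnvrs))) {
    r <- c(if (cnvrs$complex_flag[k]) "complex",
           if (cnvrs$chrom[k] %in% sex_chrom_names) "sex_chromosome",
           if (in_gap_zone(k)) "probe_gap")
    reasons[k] <- paste(r, collapse = ",")
  }
  keep <- reasons == ""
  removed <- data.frame(cnvr_id = cnvrs$cnvr_id[!keep],
                        reason = reasons[!keep], stringsAsFactors = FALSE)
  out <- cnvrs[keep, , drop = FALSE]
  rownames(out) <- NULL
  carr <- attr(cnvrs, "carriers")
  if (!is.null(carr))
    attr(out, "carriers") <- carr[carr$cnvr_id %in% out$cnvr_id, ,
                                  drop = FALSE]
  attr(out, "removed") <- removed
  out
}
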