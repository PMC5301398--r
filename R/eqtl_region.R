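#' Region-level secondary association scan around significant eQTLs
#'
#' Significant eQTLs of one tissue whose 1 Mb TSS windows overlap are
#' collapsed into non-overlapping regions (single linkage); the lead
#' eQTL of a region is the one with the smallest permutation p-value
#' (ties: smallest nominal p).  Every gene whose TSS lies within
#' `window_bp` of the lead gene's TSS is then tested against the lead
#' CNVR with the same linear model (PC1 covariate included), and the
#' nominal p-values are Bonferroni-corrected by the number of genes
#' tested in the region.  `same_direction` records whether the
#' association sign matches the lead eQTL's.
#'
#' @param significant significant rows of [qvalue_fdr()] output.
#' @param genotypes CNVR x individual genotype matrix.
#' @param study the `expression_study`.
#' @param window_bp region half-width around the lead TSS (default 1 Mb).
#' @param include_lead keep the lead gene itself among the tested
#'   (and counted) associations (default TRUE).
#' @return `data.frame(region_id, tissue, gene_id, cnvr_id, beta1,
#'   nominal_p, m, bonferroni_p, same_direction, is_lead,
#'   significant)`; `bonferroni_p = min(1, m * nominal_p)` and
#'   significance requires `bonferroni_p < 0.05`.
#' @export
region_secondary_scan <- function(significant, genotypes, study,
                                  window_bp = 1e6, include_lead = TRUE) {
  empty <- data.frame(region_id = character(), tissue = character(),
                      gene_id = character(), cnvr_id = character(),
                      beta1 = numeric(), nominal_p = numeric(),
                      m = integer(), bonferroni_p = numeric(),
                      same_direction = logical(), is_lead = logical(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (is.null(significant) || !nrow(significant)) return(empty)
  genes <- study$genes
  individuals <- study$individuals
  out <- list()
  for (tt in unique(significant$tissue)) {
    ss <- significant[significant$tissue == tt, , drop = FALSE]
    tss <- genes$tss[match(ss$gene_id, genes$gene_id)]
    chrom <- genes$chrom[match(ss$gene_id, genes$gene_id)]
    E <- study$values[[tt]][, individuals, drop = FALSE]
    cov <- expression_pc1(E)
    for (ch in unique(chrom)) {
      k <- which(chrom == ch)
      cl <- overlap_clusters(pmax(0, tss[k] - window_bp),
                             tss[k] + window_bp)
      for (g in unique(cl)) {
        members <- ss[k[cl == g], , drop = FALSE]
        ord <- order(members$perm_p, members$min_nominal_p)
        lead <- members[ord[1], ]
        lead_tss <- genes$tss[match(lead$gene_id, genes$gene_id)]
        cand <- which(genes$chrom == ch &
                        abs(genes$tss - lead_tss) <= window_bp)
        if (!include_lead)
          cand <- cand[genes$gene_id[cand] != lead$gene_id]
        if (!length(cand)) next
        gt <- genotypes[lead$cnvr_id, individuals]
        Y <- t(E[genes$gene_id[cand], , drop = FALSE])
        f <- ols_assoc(cbind(1, gt, cov), Y)
        m <- length(cand)
        bon <- pmin(1, m * f$p)
        out[[length(out) + 1L]] <- data.frame(
          region_id = lead$gene_id, tissue = tt,
          gene_id = genes$gene_id[cand], cnvr_id = lead$cnvr_id,
          beta1 = unname(f$beta), nominal_p = unname(f$p), m = m,
          bonferroni_p = unname(bon),
          same_direction = sign(f$beta) == sign(lead$beta1),
          is_lead = genes$gene_id[cand] == lead$gene_id,
          significant = bon < 0.05,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summary statistics of a significant eQTL set
#'
#' Per tissue, a two-sided Wilcoxon rank-sum test (normal
#' approximation with tie correction) compares the mean expression of
#' eQTL genes with that of all other genes of the tissue.  Across
#' tissues, a two-sided exact binomial test asks whether eQTL CNVRs
#' fall upstream of the TSS more or less often than the 50% expected
#' under no positional preference, and the signed TSS-distance table
#' is returned for density summaries.
#'
#' @param significant significant rows of [qvalue_fdr()] output
#'   (must carry `tss_distance`).
#' @param study the `expression_study`.
#' @return list with `wilcoxon` (`data.frame(tissue, n_eqtl, p)`),
#'   `binomial` (`list(n_upstream, n_downstream, p)`), and
#'   `distances` (`data.frame(gene_id, cnvr_id, tissue,
#'   tss_distance)`).
#' @export
eqtl_summaries <- function(significant, study) {
  if (is.null(significant) || !nrow(significant))
    stop("no significant eQTLs to summarize")
  wil <- list()
  for (tt in study$tissues) {
    ss <- significant[significant$tissue == tt, , drop = FALSE]
    if (!nrow(ss)) {
      message("eqtl_summaries: no eQTLs in tissue ", tt, "; skipped")
      next
    }
    E <- study$values[[tt]]
    gm <- rowMeans(E)
    is_eqtl <- rownames(E) %in% ss$gene_id
    p <- stats::wilcox.test(gm[is_eqtl], gm[!is_eqtl],
                            exact = FALSE, correct = TRUE)$p.value
    wil[[length(wil) + 1L]] <- data.frame(tissue = tt,
                                          n_eqtl = sum(is_eqtl), p = p,
                                          stringsAsFactors = FALSE)
  }
  n_up <- sum(significant$tss_distance < 0)
  n_down <- sum(significant$tss_distance >= 0)
  bin <- stats::binom.test(n_up, n_up + n_down, p = 0.5)
  list(
    wilcoxon = do.call(rbind, wil),
    binomial = list(n_upstream = n_up, n_downstream = n_down,
                    p = bin$p.value),
    distances = significant[, c("gene_id", "cnvr_id", "tissue",
                                "tss_distance")]
  )
}
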