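#' Gene-level permutation correction for multiple cis variants
#'
#' For each (gene, tissue) the observed statistic is the minimum
#' nominal p over the gene's cis CNVRs.  Individual labels of the
#' expression vector are permuted `n_perm` times (genotypes and the
#' covariate stay aligned with each other), the minimum nominal p is
#' recomputed each time, and the gene-level empirical p-value is
#' \deqn{p_{perm} = \frac{1 + \#\{ \min p^{(b)} \le \min p^{(obs)} \}}{n_{perm} + 1}}
#' which is bounded below by `1/(n_perm + 1)`.
#'
#' @param pairs nominal cis results from [map_cis_eqtls()].
#' @param genotypes CNVR x individual genotype matrix.
#' @param study the `expression_study` the pairs were mapped on.
#' @param n_perm number of permutations (default 1000; fewer than 100
#'   triggers a warning about unstable tail estimates).
#' @param seed integer seed for the permutation stream.
#' @return `data.frame(gene_id, tissue, cnvr_id, beta1, tss_distance,
#'   n_cis, min_nominal_p, perm_p)`, one row per tested (gene,
#'   tissue); `cnvr_id`/`beta1` describe the lead (smallest nominal p)
#'   CNVR.
#' @export
permutation_correct <- function(pairs, genotypes, study, n_perm = 1000L,
                                seed = 1L) {
  if (n_perm < 100L)
    warning("n_perm < 100 gives unstable permutation p-values")
  if (!nrow(pairs)) {
    return(data.frame(gene_id = character(), tissue = character(),
                      cnvr_id = character(), beta1 = numeric(),
                      tss_distance = numeric(), n_cis = integer(),
                      min_nominal_p = numeric(), perm_p = numeric(),
                      stringsAsFactors = FALSE))
  }
  set.seed(derive_seed(seed, "perm"))
  individuals <- study$individuals
  n <- length(individuals)
  out <- list()
  for (tt in unique(pairs$tissue)) {
    E <- study$values[[tt]][, individuals, drop = FALSE]
    cov <- expression_pc1(E)
    ## one shared permutation set per tissue
    perm_idx <- replicate(n_perm, sample.int(n))
    pp <- pairs[pairs$tissue == tt, , drop = FALSE]
    for (g in unique(pp$gene_id)) {
      pg <- pp[pp$gene_id == g, , drop = FALSE]
      obs_min <- min(pg$nominal_p)
      y <- E[g, ]
      Yp <- matrix(y[perm_idx], n, n_perm)
      pmin_perm <- rep(Inf, n_perm)
      for (r in seq_len(nrow(pg))) {
        gt <- genotypes[pg$cnvr_id[r], individuals]
        X <- cbind(1, gt, cov)
        pv <- ols_assoc(X, Yp)$p
        pmin_perm <- pmin(pmin_perm, pv)
      }
      lead <- which.min(pg$nominal_p)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, tissue = tt, cnvr_id = pg$cnvr_id[lead],
        beta1 = pg$beta1[lead], tss_distance = pg$tss_distance[lead],
        n_cis = nrow(pg), min_nominal_p = obs_min,
        perm_p = (1 + sum(pmin_perm <= obs_min)) / (n_perm + 1),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Storey q-values
#'
#' Estimates the proportion of true nulls as
#' \eqn{\hat\pi_0 = \#\{p > \lambda\} / (m (1 - \lambda))} at a single
#' `lambda` (default 0.5), clamped to (0, 1]; when the estimate is
#' unstable (no p-values above `lambda`) it falls back to
#' \eqn{\pi_0 = 1}, which reduces the q-values to Benjamini-Hochberg.
#' Step-up monotonicity is enforced.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param lambda tuning parameter for the `pi0` estimate.
#' @return numeric vector of q-values, same order as `p`.
#' @export
storey_qvalue <- function(p, lambda = 0.5) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  pi0 <- sum(p > lambda) / (m * (1 - lambda))
  if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1
  pi0 <- min(pi0, 1)
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  res <- numeric(m)
  res[o] <- q
  res
}

#' Per-tissue FDR control of gene-level permutation p-values
#'
#' Computes Storey q-values independently within each tissue and
#' flags eQTLs with `q_value < fdr` (default 10%) as significant.
#'
#' @param gene_results output of [permutation_correct()].
#' @param fdr FDR threshold (default 0.10).
#' @param lambda passed to [storey_qvalue()].
#' @return `gene_results` with `q_value` and `significant` columns.
#' @export
qvalue_fdr <- function(gene_results, fdr = 0.10, lambda = 0.5) {
  if (!nrow(gene_results)) {
    gene_results$q_value <- numeric(0)
    gene_results$significant <- logical(0)
    return(gene_results)
  }
  gene_results$q_value <- NA_real_
  for (tt in unique(gene_results$tissue)) {
    sel <- gene_results$tissue == tt
    gene_results$q_value[sel] <- storey_qvalue(gene_results$perm_p[sel],
                                               lambda)
  }
  gene_results$significant <- gene_results$q_value < fdr
  gene_results
}
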