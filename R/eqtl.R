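#' First-principal-component expression covariate
#'
#' Computes each individual's score on the first principal component
#' of the gene-centred expression matrix of one tissue.  This single
#' covariate absorbs global transcriptome shifts (batch effects,
#' population stratification, physiological state) that would
#' otherwise produce spurious genotype-expression associations.  The
#' sign is fixed by making the covariate positively correlated with
#' per-individual mean expression (an arbitrary but reproducible
#' convention).
#'
#' @param expression genes x individuals matrix, or an
#'   `expression_study` together with `tissue`.
#' @param tissue tissue name when `expression` is a study.
#' @return named numeric vector, one score per individual.
#' @export
expression_pc1 <- function(expression, tissue = NULL) {
  if (inherits(expression, "expression_study")) {
    if (is.null(tissue)) stop("'tissue' required for an expression_study")
    expression <- expression$values[[tissue]]
    if (is.null(expression)) stop("unknown tissue: ", tissue)
  }
  E <- as.matrix(expression)
  if (ncol(E) < 3L) stop("need at least 3 individuals")
  rv <- apply(E, 1, stats::var)
  if (sum(rv > 0, na.rm = TRUE) < 2L)
    stop("need at least 2 genes with non-zero variance")
  Ec <- E - rowMeans(E)
  sv <- svd(Ec, nu = 0, nv = 1)
  v1 <- sv$v[, 1] * sv$d[1]
  cc <- suppressWarnings(stats::cor(v1, colMeans(E)))
  if (is.finite(cc) && cc < 0) v1 <- -v1
  stats::setNames(v1, colnames(E))
}

# Vectorized OLS of many response vectors on one design matrix.
# X: n x p (p includes intercept); Y: n x k.  Returns the coefficient,
# t-statistic and two-sided p-value for column `which` of X, per
# response.
ols_assoc <- function(X, Y, which = 2L) {
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) stop("rank-deficient association design matrix")
  coefs <- qr.coef(qx, Y)
  res <- Y - X %*% coefs
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtxi <- chol2inv(qr.R(qx))[which, which]
  se <- sqrt(sigma2 * xtxi)
  tt <- coefs[which, ] / se
  list(beta = coefs[which, ], t = tt,
       p = 2 * stats::pt(-abs(tt), df),
       coefs = coefs, df = df)
}

#' Single gene-CNVR association fit
#'
#' Ordinary least squares fit of the eQTL model
#' \deqn{E_{it} = \alpha + \beta_1 C_i + \beta_2 G_{it} + \varepsilon_{it}}
#' with `C` the quantitative CNVR genotype and `G` the PC1 expression
#' covariate; the nominal p-value is the two-sided t-test on `beta1`.
#'
#' @param expr numeric expression vector (one gene, one tissue).
#' @param genotype numeric genotype vector, same individuals.
#' @param covariate numeric covariate vector (e.g. from
#'   [expression_pc1()]); `NULL` fits without the covariate.
#' @return list `beta1`, `beta2`, `nominal_p`; when the genotype is
#'   constant the fit is skipped and the list carries `reason`.
#' @export
fit_association <- function(expr, genotype, covariate = NULL) {
  n <- length(expr)
  if (length(genotype) != n ||
      (!is.null(covariate) && length(covariate) != n))
    stop("expression, genotype and covariate lengths differ")
  if (n < 4L) stop("need at least 4 individuals (residual df >= 1)")
  if (stats::sd(genotype) == 0)
    return(list(beta1 = NA_real_, beta2 = NA_real_, nominal_p = NA_real_,
                reason = "constant_genotype"))
  X <- if (is.null(covariate)) cbind(1, genotype)
  else cbind(1, genotype, covariate)
  f <- ols_assoc(X, matrix(expr, ncol = 1))
  list(beta1 = unname(f$beta[1]),
       beta2 = if (is.null(covariate)) NA_real_ else unname(f$coefs[3, 1]),
       nominal_p = unname(f$p[1]))
}

#' Map cis associations between CNVR genotypes and gene expression
#'
#' For every gene and tissue, tests the gene's expression against all
#' eligible CNVRs whose nearest boundary lies within `window_bp` of
#' the gene's TSS (inclusive), with the tissue's PC1 covariate.
#' Eligible CNVRs are non-complex and carried by at least
#' `min_carriers` individuals; pairs with a constant genotype vector
#' are skipped and logged in the `"skipped"` attribute, genes with no
#' eligible cis CNVR are recorded in `"untested"`.
#'
#' @param genotypes CNVR x individual genotype matrix.
#' @param cnvrs CNVR table (filtered) with carrier attribute.
#' @param study an `expression_study` (or a compatible list).
#' @param window_bp cis window from the TSS (default 1 Mb, inclusive).
#' @param min_carriers minimal carrier count (default 2).
#' @return `data.frame(gene_id, cnvr_id, tissue, beta1, beta2,
#'   nominal_p, tss_distance)`; `tss_distance` is the signed,
#'   strand-oriented distance from TSS to CNVR midpoint (positive =
#'   downstream).
#' @export
map_cis_eqtls <- function(genotypes, cnvrs, study, window_bp = 1e6,
                          min_carriers = 2L) {
  genes <- study$genes
  individuals <- study$individuals
  if (!all(individuals %in% colnames(genotypes)))
    stop("genotype matrix lacks some study individuals")
  G <- genotypes[, individuals, drop = FALSE]

  elig <- cnvrs[!cnvrs$complex_flag & cnvrs$n_carriers >= min_carriers &
                  cnvrs$cnvr_id %in% rownames(G), , drop = FALSE]
  out <- list(); skipped <- list(); untested <- character(0)

  ## cis pairs by boundary distance (inclusive window)
  pair_list <- lapply(seq_len(nrow(genes)), function(g) {
    same <- elig$chrom == genes$chrom[g]
    d <- pmax(0, elig$start - genes$tss[g], genes$tss[g] - elig$end)
    which(same & d <= window_bp)
  })

  for (tt in study$tissues) {
    E <- study$values[[tt]][, individuals, drop = FALSE]
    cov <- expression_pc1(E)
    for (g in seq_len(nrow(genes))) {
      rs <- pair_list[[g]]
      if (!length(rs)) {
        if (tt == study$tissues[1])
          untested <- c(untested, genes$gene_id[g])
        next
      }
      y <- E[genes$gene_id[g], ]
      for (r in rs) {
        gt <- G[elig$cnvr_id[r], ]
        if (stats::sd(gt) == 0) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            gene_id = genes$gene_id[g], cnvr_id = elig$cnvr_id[r],
            tissue = tt, reason = "constant_genotype",
            stringsAsFactors = FALSE)
          next
        }
        f <- fit_association(y, gt, cov)
        mid <- (elig$start[r] + elig$end[r]) / 2
        sgn <- if (genes$strand[g] == "-") -1 else 1
        out[[length(out) + 1L]] <- data.frame(
          gene_id = genes$gene_id[g], cnvr_id = elig$cnvr_id[r],
          tissue = tt, beta1 = f$beta1, beta2 = f$beta2,
          nominal_p = f$nominal_p,
          tss_distance = sgn * (mid - genes$tss[g]),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), cnvr_id = character(),
               tissue = character(), beta1 = numeric(), beta2 = numeric(),
               nominal_p = numeric(), tss_distance = numeric(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "untested") <- untested
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
  else NULL
  res
}
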