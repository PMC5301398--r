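#' Population structure from CNVR genotypes
#'
#' Principal component analysis of the individuals x CNVRs genotype
#' matrix (columns centred, not scaled, covariance convention with
#' divisor n as in `princomp`, computed via SVD so that more CNVRs
#' than individuals is not a limitation) together with hierarchical
#' clustering of individuals on the distance
#' `1 - Pearson correlation` between their genotype vectors.
#'
#' `subset` restricts the analysis to CNVRs containing deletions or
#' duplications, the comparison showing that deletion genotypes
#' segregate populations more accurately than duplication genotypes.
#'
#' @param genotypes CNVR x individual matrix from
#'   [quantitative_genotypes()].
#' @param cnvrs CNVR table carrying `has_deletion`/`has_duplication`
#'   flags; required when `subset != "all"`.
#' @param subset `"all"`, `"deletions_only"` or `"duplications_only"`.
#' @param linkage hierarchical clustering linkage (default
#'   `"average"`).
#' @return list of class `cnv_structure`: `scores` (individuals x PC),
#'   `loadings`, `sdev` (divisor-n standard deviations), `hclust`, and
#'   `subset`.
#' @export
population_structure <- function(genotypes, cnvrs = NULL,
                                 subset = c("all", "deletions_only",
                                            "duplications_only"),
                                 linkage = "average") {
  subset <- match.arg(subset)
  if (ncol(genotypes) < 3L) stop("need at least 3 individuals")
  if (subset != "all") {
    if (is.null(cnvrs)) stop("'cnvrs' is required for subset = ", subset)
    flag <- if (subset == "deletions_only") cnvrs$has_deletion
    else cnvrs$has_duplication
    ids <- cnvrs$cnvr_id[flag]
    ids <- intersect(rownames(genotypes), ids)
    if (!length(ids)) stop("no CNVRs match subset = ", subset)
    genotypes <- genotypes[ids, , drop = FALSE]
  }
  X <- t(genotypes)                       # individuals x CNVRs
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < .Machine$double.eps^0.5))
    stop("genotype matrix has no variance; cannot analyse structure")
  n <- nrow(Xc)
  sv <- svd(Xc)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(ncol(scores))))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(X), colnames(scores))
  ## correlation distance between individuals' genotype vectors
  cm <- stats::cor(genotypes)
  hc <- stats::hclust(stats::as.dist(1 - cm), method = linkage)
  structure(list(scores = scores, loadings = loadings,
                 sdev = sv$d / sqrt(n), hclust = hc, subset = subset),
            class = "cnv_structure")
}

#' @export
print.cnv_structure <- function(x, ...) {
  cat("cnv_structure (subset:", x$subset, ")\n")
  v <- x$sdev^2
  cat("  PC1/PC2 variance explained:",
      paste0(round(100 * v[1:2] / sum(v), 1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' Export the clustering dendrogram as a Newick string
#'
#' @param x a `cnv_structure`.
#' @param file optional path; when given the tree is written there.
#' @return the Newick string, invisibly when writing to file.
#' @export
structure_newick <- function(x, file = NULL) {
  tr <- ape::as.phylo(x$hclust)
  txt <- ape::write.tree(tr)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
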