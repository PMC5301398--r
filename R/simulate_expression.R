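#' Simulate gene models on the simulated genome
#'
#' Places gene transcription start sites uniformly along each
#' chromosome of the probe set with random strand.
#'
#' @param probes a `probe_set`.
#' @param n_genes total number of genes.
#' @param seed integer seed.
#' @return `data.frame(gene_id, chrom, tss, strand)`.
#' @export
make_gene_models <- function(probes, n_genes = 300L, seed = 1L) {
  stop_if_not_probe_set(probes)
  set.seed(derive_seed(seed, "genes"))
  chroms <- unique(probes$chrom)
  chr_len <- vapply(chroms, function(ch) max(probes$end[probes$chrom == ch]),
                    numeric(1))
  ch <- sample(chroms, n_genes, replace = TRUE, prob = chr_len)
  genes <- data.frame(
    gene_id = sprintf("G%05d", seq_len(n_genes)),
    chrom = ch,
    tss = floor(runif(n_genes, 0, chr_len[ch])),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
  genes[order(genes$chrom, genes$tss), , drop = FALSE]
}

#' Simulate multi-tissue expression with planted cis-CNV effects
#'
#' Generates log2 expression per tissue as
#' \deqn{E_{it} = \alpha_g + \beta \, C_i + \gamma_{gt} u_i + \varepsilon_{it}}
#' where `C_i` is the individual's quantitative CNVR genotype for the
#' planted cis CNVR (zero `beta` for all non-eQTL genes), `u_i` a
#' per-individual global confounder (batch / physiological state)
#' shared across tissues and entering every gene with its own loading
#' `gamma ~ N(0, 1)` — so the first expression principal component
#' captures it — and Gaussian noise.  All planted non-zero effects are
#' recorded in the returned truth table per tissue.
#'
#' @param genes gene annotation from [make_gene_models()].
#' @param cnvrs CNVR table (`cnvr_id`, `chrom`, `start`, `end`), e.g.
#'   from [build_cnvrs()] or a truth-derived stand-in.
#' @param genotypes CNVR x individual quantitative genotype matrix.
#' @param tissues character vector of tissue names.
#' @param eqtl_truth optional `data.frame(gene_id, cnvr_id, tissue,
#'   beta)` of effects to plant; pairs farther than `window_bp` from
#'   TSS to nearest CNVR boundary are rejected with an error.  When
#'   `NULL`, `n_eqtl` eligible (gene, CNVR) pairs are sampled and each
#'   assigned one random tissue with effect `beta`.
#' @param n_eqtl number of auto-planted eQTLs when `eqtl_truth` is NULL.
#' @param beta planted genotype effect (log2 expression per genotype
#'   unit); 0 gives a null simulation.
#' @param confounder_sd standard deviation of the global confounder
#'   `u_i` (0 disables it).
#' @param confounder optional explicit per-individual confounder vector
#'   (named by individual, or in genotype column order), e.g. a
#'   population-aligned batch effect emulating stratification;
#'   overrides the random `u_i`.
#' @param noise_sd residual standard deviation.
#' @param baseline_mean,baseline_sd distribution of gene baselines
#'   `alpha_g`.
#' @param window_bp maximal TSS-to-CNVR distance of a planted pair.
#' @param seed integer seed.
#'
#' @return object of class `expression_study`: list with `genes`,
#'   `tissues`, `individuals`, `values` (named list of genes x
#'   individuals matrices), `truth`, and `confounder` (the simulated
#'   `u_i`, for diagnostics).
#' @export
simulate_expression <- function(genes, cnvrs, genotypes,
                                tissues = paste0("tissue", 1:5),
                                eqtl_truth = NULL, n_eqtl = 10L, beta = 1,
                                confounder_sd = 1, confounder = NULL,
                                noise_sd = 0.5,
                                baseline_mean = 8, baseline_sd = 2,
                                window_bp = 1e6, seed = 1L) {
  if (noise_sd <= 0) stop("'noise_sd' must be > 0")
  individuals <- colnames(genotypes)
  if (is.null(individuals)) stop("'genotypes' must have individual columns")
  set.seed(derive_seed(seed, "expr"))

  dist_gene_cnvr <- function(g, r)  # TSS to nearest CNVR boundary, bp
    ifelse(genes$chrom[g] != cnvrs$chrom[r], Inf,
           pmax(0, cnvrs$start[r] - genes$tss[g],
                genes$tss[g] - cnvrs$end[r]))

  if (is.null(eqtl_truth)) {
    ## all eligible cis pairs, then sample
    pairs <- do.call(rbind, lapply(seq_len(nrow(genes)), function(g) {
      r <- which(cnvrs$chrom == genes$chrom[g] &
                   pmax(0, cnvrs$start - genes$tss[g],
                        genes$tss[g] - cnvrs$end) <= window_bp)
      if (!length(r)) return(NULL)
      data.frame(gene_id = genes$gene_id[g], cnvr_id = cnvrs$cnvr_id[r],
                 stringsAsFactors = FALSE)
    }))
    if (beta != 0 && n_eqtl > 0L) {
      if (is.null(pairs) || nrow(pairs) == 0L)
        stop("no gene lies within 'window_bp' of any CNVR")
      take <- pairs[sample(nrow(pairs), min(n_eqtl, nrow(pairs))), ,
                    drop = FALSE]
      ## at most one planted CNVR per gene keeps the truth unambiguous
      take <- take[!duplicated(take$gene_id), , drop = FALSE]
      eqtl_truth <- data.frame(take,
                               tissue = sample(tissues, nrow(take),
                                               replace = TRUE),
                               beta = beta, stringsAsFactors = FALSE)
    } else {
      eqtl_truth <- data.frame(gene_id = character(), cnvr_id = character(),
                               tissue = character(), beta = numeric(),
                               stringsAsFactors = FALSE)
    }
  } else {
    gi <- match(eqtl_truth$gene_id, genes$gene_id)
    ri <- match(eqtl_truth$cnvr_id, cnvrs$cnvr_id)
    if (anyNA(gi) || anyNA(ri))
      stop("eqtl_truth references unknown genes or CNVRs")
    d <- mapply(dist_gene_cnvr, gi, ri)
    if (any(d > window_bp))
      stop("eqtl_truth pair(s) farther than 'window_bp' from the TSS: ",
           paste(eqtl_truth$gene_id[d > window_bp], collapse = ", "))
  }

  nG <- nrow(genes); nI <- length(individuals)
  alpha <- rnorm(nG, baseline_mean, baseline_sd)
  if (is.null(confounder)) {
    u <- rnorm(nI, 0, confounder_sd)
  } else {
    if (!is.null(names(confounder))) confounder <- confounder[individuals]
    if (length(confounder) != nI || anyNA(confounder))
      stop("'confounder' must provide one value per individual")
    u <- as.numeric(confounder)
  }
  values <- setNames(vector("list", length(tissues)), tissues)
  for (tt in tissues) {
    gamma <- rnorm(nG)
    E <- matrix(alpha, nG, nI) + outer(gamma, u) +
      matrix(rnorm(nG * nI, 0, noise_sd), nG, nI)
    tr <- eqtl_truth[eqtl_truth$tissue == tt, , drop = FALSE]
    if (nrow(tr)) for (k in seq_len(nrow(tr))) {
      g <- match(tr$gene_id[k], genes$gene_id)
      E[g, ] <- E[g, ] + tr$beta[k] * genotypes[tr$cnvr_id[k], individuals]
    }
    dimnames(E) <- list(genes$gene_id, individuals)
    values[[tt]] <- E
  }
  structure(list(genes = genes, tissues = tissues, individuals = individuals,
                 values = values, truth = eqtl_truth,
                 confounder = setNames(u, individuals)),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$genes), "genes x", length(x$individuals),
      "individuals x", length(x$tissues), "tissues;",
      nrow(x$truth), "planted eQTL effect(s)\n")
  invisible(x)
}
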