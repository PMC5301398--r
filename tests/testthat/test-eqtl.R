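# A compact study used across the eQTL tests: one chromosome, CNVRs
# with known genotypes, genes at controlled TSS distances.
mk_study <- function(n_ind = 21, seed = 1) {
  set.seed(seed)
  ids <- sprintf("I%02d", seq_len(n_ind))
  cnvrs <- data.frame(
    cnvr_id = c("R1", "R2", "R3"), chrom = "chr1",
    start = c(1e6, 4e6, 8e6), end = c(1.02e6, 4.05e6, 8.01e6),
    n_carriers = c(5L, 4L, 1L), complex_flag = FALSE,
    has_deletion = c(TRUE, FALSE, TRUE),
    has_duplication = c(FALSE, TRUE, FALSE), stringsAsFactors = FALSE)
  G <- rbind(
    R1 = c(rep(-1, 5), rep(0, n_ind - 5)) + rnorm(n_ind, 0, 0.05),
    R2 = c(rep(0, 5), rep(0.58, 4), rep(0, n_ind - 9)) +
      rnorm(n_ind, 0, 0.05),
    R3 = c(rep(-1, 1), rep(0, n_ind - 1)) + rnorm(n_ind, 0, 0.05))
  colnames(G) <- ids
  genes <- data.frame(
    gene_id = c("G1", "G2", "G3", "G4"), chrom = "chr1",
    ## G1 near R1; G2 exactly 1 Mb from R2's start; G3 far from all;
    ## G4 near R3 (single carrier)
    tss = c(1.5e6, 3e6, 1.5e7, 8.2e6),
    strand = c("+", "-", "+", "+"), stringsAsFactors = FALSE)
  list(cnvrs = cnvrs, G = G, genes = genes, ids = ids)
}

test_that("expression PC1 recovers a planted factor and is equivariant", {
  set.seed(2)
  u <- rnorm(15)
  gamma <- rnorm(40)
  E <- outer(gamma, u) + matrix(rnorm(600, 0, 0.01), 40, 15)
  colnames(E) <- sprintf("I%02d", 1:15)
  v <- expression_pc1(E)
  expect_gt(abs(cor(v, u)), 0.99)
  ## permuting individuals permutes the covariate identically
  perm <- sample(15)
  v2 <- expression_pc1(E[, perm])
  expect_equal(abs(unname(v2)), abs(unname(v[perm])), tolerance = 1e-6)
  ## duplicating every gene changes scores only by the scale convention
  v3 <- expression_pc1(rbind(E, E))
  expect_equal(abs(cor(v3, v)), 1, tolerance = 1e-10)
  expect_error(expression_pc1(E[, 1:2]), "3 individuals")
  expect_error(expression_pc1(matrix(5, 4, 10)), "variance")
})

test_that("association fits match lm() and handle exact relations", {
  set.seed(3)
  gt <- rnorm(5)
  cov <- rnorm(5)
  y <- 1 + 2 * gt - 0.5 * cov + rnorm(5, 0, 0.01)
  f <- fit_association(y, gt, cov)
  ref <- summary(lm(y ~ gt + cov))
  expect_equal(f$beta1, unname(coef(ref)[2, 1]))
  expect_equal(f$beta2, unname(coef(ref)[3, 1]))
  expect_equal(f$nominal_p, unname(coef(ref)[2, 4]))
  ## exact linear case
  gt2 <- c(-1, -1, 0, 0, 0, 0, 1)
  f2 <- fit_association(2 * gt2, gt2, NULL)
  expect_equal(f2$beta1, 2)
  expect_lt(f2$nominal_p, 1e-10)
  ## constant genotype is a skip, not an error
  f3 <- fit_association(rnorm(6), rep(1, 6), rnorm(6))
  expect_equal(f3$reason, "constant_genotype")
  expect_error(fit_association(rnorm(3), rnorm(3), NULL), "4 individuals")
})

test_that("cis pairing respects window boundary and carrier filters", {
  s <- mk_study()
  study <- list(genes = s$genes, tissues = "liver", individuals = s$ids,
                values = list(liver = {
                  set.seed(4)
                  E <- matrix(rnorm(4 * 21, 8, 0.5), 4, 21,
                              dimnames = list(s$genes$gene_id, s$ids))
                  E
                }))
  pairs <- map_cis_eqtls(s$G, s$cnvrs, study)
  ## G2 is exactly 1 Mb from R2's nearest boundary: inclusive
  expect_true(any(pairs$gene_id == "G2" & pairs$cnvr_id == "R2"))
  ## R3 has one carrier: excluded everywhere
  expect_false(any(pairs$cnvr_id == "R3"))
  ## G3 has no cis CNVR: recorded as untested
  expect_true("G3" %in% attr(pairs, "untested"))
  ## brute-force distance scan reproduces the pair list
  want <- NULL
  for (g in seq_len(nrow(s$genes))) for (r in 1:2) {
    d <- max(0, s$cnvrs$start[r] - s$genes$tss[g],
             s$genes$tss[g] - s$cnvrs$end[r])
    if (d <= 1e6)
      want <- rbind(want, data.frame(gene_id = s$genes$gene_id[g],
                                     cnvr_id = s$cnvrs$cnvr_id[r]))
  }
  expect_equal(pairs[, c("gene_id", "cnvr_id")],
               want[order(match(want$gene_id, s$genes$gene_id)), ],
               ignore_attr = TRUE)
  ## signed distance uses the midpoint, strand-oriented
  mid <- (s$cnvrs$start[2] + s$cnvrs$end[2]) / 2
  d2 <- pairs$tss_distance[pairs$gene_id == "G2" & pairs$cnvr_id == "R2"]
  expect_equal(d2, -(mid - s$genes$tss[2]))   # G2 on the minus strand
})

test_that("permutation p-values hit the lower bound for strong effects", {
  s <- mk_study()
  set.seed(5)
  ## enough background genes that PC1 does not chase the planted effect
  extra <- data.frame(gene_id = sprintf("N%02d", 1:30), chrom = "chr2",
                      tss = seq(1e6, 3e6, length.out = 30), strand = "+",
                      stringsAsFactors = FALSE)
  genes <- rbind(s$genes, extra)
  E <- matrix(rnorm(34 * 21, 8, 1), 34, 21,
              dimnames = list(genes$gene_id, s$ids))
  E["G1", ] <- 8 + 2 * s$G["R1", ] + rnorm(21, 0, 0.1)
  study <- list(genes = genes, tissues = "liver", individuals = s$ids,
                values = list(liver = E))
  pairs <- map_cis_eqtls(s$G, s$cnvrs, study)
  res <- permutation_correct(pairs, s$G, study, n_perm = 200, seed = 6)
  g1 <- res[res$gene_id == "G1", ]
  expect_equal(g1$perm_p, 1 / 201)
  expect_equal(g1$cnvr_id, "R1")
  expect_true(all(res$perm_p >= 1 / 201))
  expect_true(all(res$perm_p <= 1))
  expect_warning(permutation_correct(pairs, s$G, study, n_perm = 50,
                                     seed = 1), "unstable")
})

test_that("Storey q-values reduce to Benjamini-Hochberg at pi0 = 1", {
  set.seed(7)
  p <- c(rep(0.0005, 10), runif(990))
  q <- storey_qvalue(p, lambda = 0.5)
  pi0 <- min(1, sum(p > 0.5) / (length(p) * 0.5))
  bh <- p.adjust(p, "BH")              # independent step-up oracle
  expect_equal(q, pmin(1, pi0 * bh), tolerance = 1e-12)
  ## monotone in sorted p
  expect_true(all(diff(q[order(p)]) >= 0))
  ## degenerate cases
  expect_equal(storey_qvalue(rep(1, 5)), rep(1, 5))
  expect_error(storey_qvalue(c(0.5, 1.2)), "0, 1")
  ## per-tissue control and the 10% significance rule
  res <- data.frame(gene_id = sprintf("g%d", 1:20),
                    tissue = rep(c("a", "b"), each = 10),
                    perm_p = c(rep(0.001, 3), runif(7, 0.5, 1),
                               runif(10, 0.5, 1)),
                    stringsAsFactors = FALSE)
  out <- qvalue_fdr(res)
  expect_true(all(out$significant[1:3]))
  expect_false(any(out$significant[11:20]))
  expect_equal(out$significant, out$q_value < 0.10)
})

test_that("region scan applies per-region Bonferroni and directionality", {
  set.seed(8)
  n_ind <- 21
  ids <- sprintf("I%02d", seq_len(n_ind))
  gt <- c(rep(1, 6), rep(0, 15)) + rnorm(n_ind, 0, 0.05)
  G <- matrix(gt, 1, dimnames = list("R1", ids))
  ## 10 genes inside the lead window; gene 1 is the lead eQTL, gene 2
  ## co-regulated by the same CNVR with the same sign
  genes <- rbind(
    data.frame(gene_id = sprintf("G%02d", 1:10), chrom = "chr1",
               tss = seq(1e6, 1.9e6, length.out = 10),
               strand = "+", stringsAsFactors = FALSE),
    ## distant background genes keep PC1 away from the planted effect
    data.frame(gene_id = sprintf("N%03d", 1:200), chrom = "chr2",
               tss = seq(1e6, 2e7, length.out = 200),
               strand = "+", stringsAsFactors = FALSE))
  E <- matrix(rnorm(210 * n_ind, 8, 1), 210, n_ind,
              dimnames = list(genes$gene_id, ids))
  E[1:10, ] <- matrix(rnorm(10 * n_ind, 8, 0.4), 10, n_ind)
  E["G01", ] <- E["G01", ] + 3 * gt
  E["G02", ] <- E["G02", ] + 2 * gt
  study <- list(genes = genes, tissues = "liver", individuals = ids,
                values = list(liver = E))
  sig <- data.frame(gene_id = "G01", tissue = "liver", cnvr_id = "R1",
                    beta1 = 3, tss_distance = 1e5, n_cis = 1L,
                    min_nominal_p = 1e-8, perm_p = 0.001,
                    q_value = 0.001, significant = TRUE,
                    stringsAsFactors = FALSE)
  out <- region_secondary_scan(sig, G, study)
  expect_equal(unique(out$m), 10L)
  expect_equal(out$bonferroni_p, pmin(1, out$m * out$nominal_p))
  g2 <- out[out$gene_id == "G02", ]
  expect_true(g2$significant)
  expect_true(g2$same_direction)
  expect_true(out$is_lead[out$gene_id == "G01"])
  ## a lead-only region yields exactly one (lead) row
  genes1 <- genes[-(2:10), , drop = FALSE]       # lead + distant genes
  study1 <- list(genes = genes1, tissues = "liver", individuals = ids,
                 values = list(liver = E))
  out1 <- region_secondary_scan(sig, G, study1)
  expect_equal(nrow(out1), 1L)
  expect_equal(out1$m, 1L)
  expect_true(out1$is_lead)
})

test_that("eQTL summaries compute Wilcoxon, binomial and distances", {
  set.seed(9)
  ids <- sprintf("I%02d", 1:10)
  genes <- data.frame(gene_id = sprintf("G%02d", 1:30), chrom = "chr1",
                      tss = seq(1e6, 3e6, length.out = 30), strand = "+",
                      stringsAsFactors = FALSE)
  E <- matrix(rnorm(300, 8, 1), 30, 10,
              dimnames = list(genes$gene_id, ids))
  study <- list(genes = genes, tissues = c("liver", "spleen"),
                individuals = ids,
                values = list(liver = E, spleen = E))
  sig <- data.frame(gene_id = sprintf("G%02d", 1:10), tissue = "liver",
                    cnvr_id = "R1", beta1 = 1,
                    tss_distance = c(rep(-1e4, 5), rep(2e4, 5)),
                    n_cis = 1L, min_nominal_p = 1e-4, perm_p = 0.001,
                    q_value = 0.01, significant = TRUE,
                    stringsAsFactors = FALSE)
  expect_message(summ <- eqtl_summaries(sig, study), "spleen")
  ## 5 upstream vs 5 downstream: exact binomial p = 1
  expect_equal(summ$binomial$p, 1.0)
  expect_equal(summ$binomial$n_upstream, 5L)
  ## Wilcoxon matches a direct recomputation
  gm <- rowMeans(E)
  sel <- rownames(E) %in% sig$gene_id
  ref <- wilcox.test(gm[sel], gm[!sel], exact = FALSE)$p.value
  expect_equal(summ$wilcoxon$p, ref)
  expect_equal(nrow(summ$distances), 10L)
  expect_error(eqtl_summaries(sig[0, ], study), "no significant")
})
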