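mk_call <- function(ind, chrom, start, end, state, method,
                    mean_log2 = ifelse(state == "gain", 0.6, -1)) {
  data.frame(individual_id = ind, chrom = chrom,
             start_probe = NA_integer_, end_probe = NA_integer_,
             start_bp = start, end_bp = end, state = state,
             mean_log2 = mean_log2,
             n_probes = as.integer((end - start) / 100),
             method = method, score = 2, stringsAsFactors = FALSE)
}

test_that("two-method overlapping gains merge into one consensus CNV", {
  calls <- rbind(mk_call("I1", "chr1", 100, 200, "gain", "gada_like"),
                 mk_call("I1", "chr1", 150, 250, "gain", "cbs_like"))
  cons <- consensus_per_individual(calls)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start, 100)
  expect_equal(cons$end, 250)
  expect_equal(cons$n_methods, 2L)
  expect_equal(cons$state, "gain")
})

test_that("single-method and state-conflicting groups are dropped", {
  one <- mk_call("I1", "chr1", 100, 200, "gain", "gada_like")
  expect_equal(nrow(consensus_per_individual(one)), 0L)
  conflict <- rbind(mk_call("I1", "chr1", 100, 200, "gain", "gada_like"),
                    mk_call("I1", "chr1", 150, 250, "loss", "cbs_like"))
  expect_equal(nrow(consensus_per_individual(conflict)), 0L)
  ## same method twice does not count as two methods
  dup <- rbind(mk_call("I1", "chr1", 100, 200, "gain", "gada_like"),
               mk_call("I1", "chr1", 150, 250, "gain", "gada_like"))
  expect_equal(nrow(consensus_per_individual(dup)), 0L)
})

test_that("consensus matches the brute-force oracle on random inputs", {
  for (s in 1:25) {
    calls <- random_calls(sample(3:30, 1), n_ind = 3, seed = s)
    got <- consensus_per_individual(calls)
    want <- oracle_consensus(calls)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, want$start, info = paste("seed", s))
      expect_equal(got$end, want$end)
      expect_equal(got$state, want$state)
      expect_equal(got$n_methods, want$n_methods)
    }
  }
})

mk_cons <- function(ind, chrom, start, end, state, mean_log2 = 0.5) {
  data.frame(individual_id = ind, chrom = chrom, start = start,
             end = end, state = state, n_methods = 2L,
             mean_log2 = mean_log2, stringsAsFactors = FALSE)
}

test_that("single-linkage chains merge across individuals", {
  ## A overlaps B, B overlaps C, A does not overlap C -> one CNVR
  cons <- rbind(mk_cons("I1", "chr1", 100, 200, "gain"),
                mk_cons("I2", "chr1", 180, 300, "gain"),
                mk_cons("I3", "chr1", 280, 400, "gain"))
  cnvrs <- build_cnvrs(cons)
  expect_equal(nrow(cnvrs), 1L)
  expect_equal(cnvrs$start, 100)
  expect_equal(cnvrs$end, 400)
  expect_equal(cnvrs$n_carriers, 3L)
  ## disjoint CNVs in different individuals stay apart
  cons2 <- rbind(mk_cons("I1", "chr1", 100, 200, "gain"),
                 mk_cons("I2", "chr1", 500, 600, "loss"))
  expect_equal(nrow(build_cnvrs(cons2)), 2L)
})

test_that("complex loci and state flags are recorded", {
  cons <- rbind(mk_cons("I1", "chr1", 100, 200, "gain"),
                mk_cons("I1", "chr1", 250, 350, "gain"),
                mk_cons("I2", "chr1", 150, 300, "loss"))
  cnvrs <- build_cnvrs(cons)
  expect_equal(nrow(cnvrs), 1L)
  expect_true(cnvrs$complex_flag)        # I1 contributes two CNVs
  expect_true(cnvrs$has_deletion)
  expect_true(cnvrs$has_duplication)
  carr <- attr(cnvrs, "carriers")
  expect_equal(sort(carr$individual_id), c("I1", "I2"))
  expect_equal(carr$n_cnv[carr$individual_id == "I1"], 2L)
})

test_that("CNVR construction matches the transitive-closure oracle", {
  for (s in 1:25) {
    calls <- random_calls(sample(5:40, 1), n_ind = 4, seed = 100 + s)
    cons <- data.frame(individual_id = calls$individual_id,
                       chrom = calls$chrom, start = calls$start_bp,
                       end = calls$end_bp, state = calls$state,
                       n_methods = 2L, mean_log2 = calls$mean_log2,
                       stringsAsFactors = FALSE)
    got <- build_cnvrs(cons)
    want <- oracle_cnvr_spans(cons)
    expect_equal(got$start, want$start, info = paste("seed", s))
    expect_equal(got$end, want$end)
    expect_equal(got$n_carriers, want$n_carriers)
    expect_equal(got$complex_flag, want$complex_flag)
    expect_equal(got$has_deletion, want$has_deletion)
    ## conservation: every consensus CNV inside exactly one CNVR
    for (k in seq_len(nrow(cons))) {
      inside <- sum(got$chrom == cons$chrom[k] &
                      got$start <= cons$start[k] &
                      got$end >= cons$end[k])
      expect_gte(inside, 1L)
    }
  }
})

test_that("locus filters remove sex-chromosome, gap and complex CNVRs", {
  ## probe set with a ~600 kb gap on chr1 after 400 kb of probes
  left <- toy_probes(400, spacing = 1000, chrom = "chr1")
  right <- toy_probes(400, spacing = 1000, chrom = "chr1")
  right$start <- right$start + 400 * 1000 + 6e5
  right$end <- right$end + 400 * 1000 + 6e5
  ps <- rbind(left, right)
  class(ps) <- c("probe_set", "data.frame")

  cnvrs <- data.frame(
    cnvr_id = c("R1", "R2", "R3", "R4"),
    chrom = c("chr1", "chr1", "chrX", "chr1"),
    ## R1 safe; R2 ends ~90 kb before the gap (inside the 250 kb margin);
    ## R4 complex
    start = c(0, 3e5, 0, 10000),
    end = c(20000, 3.1e5, 5000, 30000),
    n_carriers = c(2L, 2L, 2L, 2L),
    complex_flag = c(FALSE, FALSE, FALSE, TRUE),
    has_deletion = TRUE, has_duplication = FALSE,
    stringsAsFactors = FALSE)
  out <- filter_cnvrs(cnvrs, ps)
  removed <- attr(out, "removed")
  expect_equal(out$cnvr_id, "R1")
  expect_setequal(removed$cnvr_id, c("R2", "R3", "R4"))
  expect_match(removed$reason[removed$cnvr_id == "R2"], "probe_gap")
  expect_match(removed$reason[removed$cnvr_id == "R3"], "sex_chromosome")
  expect_match(removed$reason[removed$cnvr_id == "R4"], "complex")
  ## counts reconcile exactly
  expect_equal(nrow(out) + nrow(removed), nrow(cnvrs))
  ## unknown chromosome -> error
  bad <- cnvrs; bad$chrom[1] <- "chr99"
  expect_error(filter_cnvrs(bad, ps), "unknown chromosome")
})

test_that("gap margin arithmetic matches a direct distance computation", {
  left <- toy_probes(50, spacing = 1000, chrom = "chr1")
  right <- toy_probes(50, spacing = 1000, chrom = "chr1")
  gap_start <- left$end[50]
  gap_end <- gap_start + 7e5          # 700 kb gap ( > 500 kb )
  right$start <- right$start + gap_end
  right$end <- right$end + gap_end
  ps <- rbind(left, right)
  class(ps) <- c("probe_set", "data.frame")
  mk <- function(id, s, e) data.frame(
    cnvr_id = id, chrom = "chr1", start = s, end = e, n_carriers = 2L,
    complex_flag = FALSE, has_deletion = TRUE, has_duplication = FALSE,
    stringsAsFactors = FALSE)
  ## within 250 kb of the gap edge -> removed; beyond -> kept
  near <- mk("N", gap_end + 2e5, gap_end + 2.2e5)
  far <- mk("F", gap_end + 2.6e5, gap_end + 2.8e5)
  out <- filter_cnvrs(rbind(near, far), ps)
  expect_equal(out$cnvr_id, "F")
  expect_equal(attr(out, "removed")$cnvr_id, "N")
})

test_that("quantitative genotypes are exact medians", {
  ps <- toy_probes(10, spacing = 1000)
  y <- matrix(0, 10, 2)
  y[3:5, 1] <- c(0.1, 0.5, 0.9)
  y[3:4, 2] <- c(0.2, 0.4)
  cnvrs <- data.frame(cnvr_id = c("Ra", "Rb"), chrom = "chr1",
                      start = c(2000, 2000), end = c(4100, 3100),
                      n_carriers = 1L, complex_flag = FALSE,
                      has_deletion = FALSE, has_duplication = TRUE,
                      stringsAsFactors = FALSE)
  G <- quantitative_genotypes(cnvrs, toy_acgh(y), ps)
  expect_equal(G["Ra", 1], median(c(0.1, 0.5, 0.9)))  # 0.5
  expect_equal(G["Rb", 2], 0.3)                        # mean of middle two
  ## zero-probe CNVR errors
  bad <- cnvrs[1, ]; bad$start <- 5e6; bad$end <- 5.01e6
  expect_error(quantitative_genotypes(bad, toy_acgh(y), ps), "no probes")
})

test_that("genotype matrices match the brute-force oracle", {
  ps <- toy_probes(60, spacing = 1000)
  set.seed(11)
  y <- matrix(rnorm(60 * 4, 0, 0.3), 60, 4)
  cnvrs <- data.frame(cnvr_id = sprintf("R%d", 1:5), chrom = "chr1",
                      start = c(0, 5000, 20000, 30500, 50000),
                      end = c(4000, 15000, 30000, 40000, 59000),
                      n_carriers = 2L, complex_flag = FALSE,
                      has_deletion = TRUE, has_duplication = FALSE,
                      stringsAsFactors = FALSE)
  samples <- toy_acgh(y)
  expect_equal(quantitative_genotypes(cnvrs, samples, ps),
               oracle_genotypes(cnvrs, samples, ps))
})
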