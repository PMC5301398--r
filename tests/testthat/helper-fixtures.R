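# Small in-code fixtures and independent brute-force oracles used
# across the suite.

# Probe set with exact, regular geometry (no RNG) for constructed cases.
toy_probes <- function(n, spacing = 1000, chrom = "chr1", gc = NULL,
                       probe_len = 50) {
  start <- (seq_len(n) - 1L) * spacing
  d <- data.frame(
    probe_id = sprintf("%s_p%06d", chrom, seq_len(n)),
    chrom = chrom, start = start, end = start + probe_len,
    gc = gc %||% rep(seq(0.3, 0.7, length.out = 25), length.out = n),
    stringsAsFactors = FALSE
  )
  class(d) <- c("probe_set", "data.frame")
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One- or multi-sample acgh_set from a vector/matrix.
toy_acgh <- function(y, ids = NULL, population = "POP") {
  y <- as.matrix(y)
  ids <- ids %||% sprintf("I%02d", seq_len(ncol(y)))
  acgh_set(y, data.frame(individual_id = ids,
                         population = rep_len(population, ncol(y)),
                         sex = "F", stringsAsFactors = FALSE))
}

# A planted-CNV single-sample dataset on a regular probe grid.
planted_sample <- function(n = 2000, cnvs = NULL, noise_sd = 0.15,
                           seed = 1, spacing = 598) {
  ps <- toy_probes(n, spacing = spacing)
  set.seed(seed)
  y <- rnorm(n, 0, noise_sd)
  if (!is.null(cnvs)) {
    for (k in seq_len(nrow(cnvs)))
      y[cnvs$from[k]:cnvs$to[k]] <- y[cnvs$from[k]:cnvs$to[k]] +
        cnvs$effect[k]
  }
  list(probes = ps, samples = toy_acgh(y))
}

## ---- independent oracles -------------------------------------------------

# Transitive closure of the any-overlap relation by repeated pairwise
# scanning (quadratic, obviously correct).
oracle_overlap_clusters <- function(start, end) {
  n <- length(start)
  cl <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && start[i] < end[j] && end[i] > start[j] &&
          cl[i] != cl[j]) {
        cl[cl == cl[j]] <- cl[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(cl, unique(cl))
}

# Per-individual consensus by explicit looping over overlap groups.
oracle_consensus <- function(calls, min_methods = 2L) {
  out <- NULL
  for (ind in unique(calls$individual_id)) {
    for (ch in unique(calls$chrom)) {
      cc <- calls[calls$individual_id == ind & calls$chrom == ch, ,
                  drop = FALSE]
      if (!nrow(cc)) next
      cl <- oracle_overlap_clusters(cc$start_bp, cc$end_bp)
      for (g in unique(cl)) {
        gg <- cc[cl == g, , drop = FALSE]
        if (length(unique(gg$method)) < min_methods) next
        if (length(unique(gg$state)) > 1) next
        out <- rbind(out, data.frame(
          individual_id = ind, chrom = ch, start = min(gg$start_bp),
          end = max(gg$end_bp), state = gg$state[1],
          n_methods = length(unique(gg$method)),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) return(out)
  out <- out[order(out$individual_id, out$chrom, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Cross-individual CNVR bounds by explicit transitive closure.
oracle_cnvr_spans <- function(consensus) {
  out <- NULL
  for (ch in unique(consensus$chrom)) {
    cc <- consensus[consensus$chrom == ch, , drop = FALSE]
    cl <- oracle_overlap_clusters(cc$start, cc$end)
    for (g in unique(cl)) {
      gg <- cc[cl == g, , drop = FALSE]
      out <- rbind(out, data.frame(
        chrom = ch, start = min(gg$start), end = max(gg$end),
        n_carriers = length(unique(gg$individual_id)),
        complex_flag = any(table(gg$individual_id) > 1),
        has_deletion = any(gg$state == "loss"),
        has_duplication = any(gg$state == "gain"),
        stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Genotype matrix by probe-by-probe looping.
oracle_genotypes <- function(cnvrs, samples, probes) {
  G <- matrix(NA_real_, nrow(cnvrs), ncol(samples$log2),
              dimnames = list(cnvrs$cnvr_id, samples$info$individual_id))
  for (k in seq_len(nrow(cnvrs))) {
    sel <- c()
    for (i in seq_len(nrow(probes))) {
      if (probes$chrom[i] == cnvrs$chrom[k] &&
          probes$start[i] < cnvrs$end[k] &&
          probes$end[i] > cnvrs$start[k]) sel <- c(sel, i)
    }
    for (j in seq_len(ncol(samples$log2)))
      G[k, j] <- median(samples$log2[sel, j])
  }
  G
}

# SNR by an explicit probe-by-probe loop.
oracle_snr <- function(samples, probes, test_set) {
  res <- NULL
  for (j in seq_len(ncol(samples$log2))) {
    snrs <- c()
    seen <- c()
    for (k in seq_len(nrow(test_set))) {
      for (i in seq_len(nrow(probes))) {
        if (probes$chrom[i] == test_set$chrom[k] &&
            probes$start[i] < test_set$end[k] &&
            probes$end[i] > test_set$start[k] && !(i %in% seen)) {
          sdc <- sd(samples$log2[probes$chrom == probes$chrom[i], j])
          snrs <- c(snrs, abs(samples$log2[i, j]) / sdc)
          seen <- c(seen, i)
        }
      }
    }
    res <- rbind(res, data.frame(mean_snr = mean(snrs),
                                 median_snr = median(snrs)))
  }
  res
}

# Random carrier-call table for oracle comparisons.
random_calls <- function(n, n_ind = 3, n_methods = 3, seed) {
  set.seed(seed)
  start <- sample(0:500, n, replace = TRUE) * 100
  len <- sample(1:40, n, replace = TRUE) * 100
  data.frame(
    individual_id = sprintf("I%02d", sample(n_ind, n, replace = TRUE)),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start_bp = start, end_bp = start + len,
    state = sample(c("gain", "loss"), n, replace = TRUE),
    mean_log2 = rnorm(n, 0, 0.5), n_probes = pmax(5L, len %/% 100),
    method = sample(c("gada_like", "cbs_like", "window_like"), n,
                    replace = TRUE),
    score = runif(n, 0.5, 5), stringsAsFactors = FALSE
  )
}
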