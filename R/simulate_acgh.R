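#' Construct an aCGH sample set
#'
#' Bundles a probes x individuals log2-ratio matrix with individual
#' metadata.  All normalization and calling functions operate on this
#' container; a single array is just a one-column set.
#'
#' @param log2 numeric matrix, probes in rows (aligned with the probe
#'   set), individuals in columns.
#' @param info `data.frame` with columns `individual_id`, `population`,
#'   `sex`; row order must match the columns of `log2`.
#' @return object of class `acgh_set`.
#' @export
acgh_set <- function(log2, info) {
  if (!is.matrix(log2)) log2 <- as.matrix(log2)
  if (nrow(info) != ncol(log2))
    stop("nrow(info) must equal ncol(log2)")
  colnames(log2) <- info$individual_id
  structure(list(log2 = log2, info = info), class = "acgh_set")
}

#' @export
print.acgh_set <- function(x, ...) {
  cat("acgh_set:", nrow(x$log2), "probes x", ncol(x$log2), "individuals\n")
  cat("  populations:", paste(unique(x$info$population), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate aCGH log2-ratio arrays with GC and wave artifacts
#'
#' Generates per-individual probe log2-ratios as the sum of the planted
#' CNV effects, a quadratic GC-content bias, a sinusoidal chromosomal
#' wave with random phase per (individual, chromosome), and i.i.d.
#' Gaussian noise:
#'
#' \deqn{y_i = effect_i + \beta_1 GC_i + \beta_2 GC_i^2 +
#'   A \sin(2\pi pos_i / T + \phi) + \varepsilon_i}
#'
#' This is the generative inverse of the normalization model: the GC
#' term is what quadratic residualization removes and the sinusoid is
#' the simplest wave a local-regression correction must remove.
#'
#' @param probes a `probe_set`.
#' @param truth CNV truth table from [simulate_cnv_truth()] (may be
#'   `NULL` for CNV-free arrays).
#' @param individuals `data.frame(individual_id, population, sex)`;
#'   defaults to the individual table attached to `truth`.
#' @param gc_coefs length-2 numeric `(beta1, beta2)` of the GC bias.
#' @param wave_amplitude,wave_period_bp sinusoidal wave parameters.
#' @param noise_sd probe-level Gaussian noise standard deviation (> 0
#'   unless explicitly set to 0 for noise-free checks).
#' @param seed integer seed.
#' @return an [acgh_set()].
#' @export
simulate_acgh <- function(probes, truth = NULL, individuals = NULL,
                          gc_coefs = c(0.5, -0.3),
                          wave_amplitude = 0.1, wave_period_bp = 5e6,
                          noise_sd = 0.15, seed = 1L) {
  stop_if_not_probe_set(probes)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (is.null(individuals)) {
    individuals <- attr(truth, "individuals")
    if (is.null(individuals) && !is.null(truth))
      individuals <- data.frame(
        individual_id = sort(unique(truth$individual_id)),
        population = "POP", sex = "F", stringsAsFactors = FALSE)
    if (is.null(individuals))
      stop("'individuals' must be given when 'truth' is NULL")
  }
  if (is.character(individuals))
    individuals <- data.frame(individual_id = individuals,
                              population = "POP", sex = "F",
                              stringsAsFactors = FALSE)
  if (!is.null(truth) &&
      !all(truth$individual_id %in% individuals$individual_id))
    stop("truth table references individuals absent from 'individuals'")
  set.seed(derive_seed(seed, "acgh"))

  n <- nrow(probes)
  chroms <- unique(probes$chrom)
  gc_bias <- gc_coefs[1] * probes$gc + gc_coefs[2] * probes$gc^2
  y <- matrix(0, n, nrow(individuals),
              dimnames = list(probes$probe_id, individuals$individual_id))
  for (j in seq_len(nrow(individuals))) {
    yj <- gc_bias
    for (ch in chroms) {
      idx <- which(probes$chrom == ch)
      phase <- runif(1, 0, 2 * pi)
      yj[idx] <- yj[idx] + wave_amplitude *
        sin(2 * pi * probes$start[idx] / wave_period_bp + phase)
    }
    if (!is.null(truth)) {
      tj <- truth[truth$individual_id == individuals$individual_id[j], ,
                  drop = FALSE]
      if (nrow(tj)) for (k in seq_len(nrow(tj))) {
        idx <- probes_in_interval(probes, tj$chrom[k], tj$start[k], tj$end[k])
        yj[idx] <- yj[idx] + tj$effect[k]
      }
    }
    y[, j] <- yj + rnorm(n, 0, noise_sd)
  }
  acgh_set(y, individuals)
}
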