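#' Simulate a tiling aCGH probe set
#'
#' Generates an ordered genomic probe set emulating a high-density
#' oligonucleotide tiling design: probes tile each chromosome at a
#' jittered spacing whose realized median is close to
#' `target_spacing_bp`, and probe GC content follows a smooth bounded
#' AR(1) profile along the chromosome (correlation length
#' `gc_autocorr_bp`), mimicking isochore-scale GC structure.
#'
#' Coordinates are 0-based, half-open (BED convention) throughout.
#'
#' @param n_chrom number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length_bp length of every chromosome in bp.
#' @param target_spacing_bp target median inter-probe spacing in bp.
#' @param gc_autocorr_bp correlation length of the GC profile in bp.
#' @param probe_length_bp probe footprint in bp.
#' @param seed integer seed; identical seeds give identical probe sets.
#'
#' @return A `data.frame` of class `probe_set` with columns
#'   `probe_id`, `chrom`, `start`, `end`, `gc`, sorted by
#'   (`chrom`, `start`); `gc` lies in `[0.2, 0.8]`.
#' @examples
#' ps <- make_probe_set(n_chrom = 1, chrom_length_bp = 1e5,
#'                      target_spacing_bp = 598, seed = 1)
#' median(diff(ps$start))
#' @export
make_probe_set <- function(n_chrom = 1L, chrom_length_bp = 1e6,
                           target_spacing_bp = 598L, gc_autocorr_bp = 5e4,
                           probe_length_bp = 50L, seed = 1L) {
  if (n_chrom < 1L) stop("'n_chrom' must be >= 1")
  if (target_spacing_bp < 1L) stop("'target_spacing_bp' must be >= 1")
  if (chrom_length_bp < 10 * target_spacing_bp)
    stop("'chrom_length_bp' must be at least 10 x the target spacing")
  if (gc_autocorr_bp <= 0) stop("'gc_autocorr_bp' must be positive")
  set.seed(derive_seed(seed, "probes"))

  out <- vector("list", n_chrom)
  for (ci in seq_len(n_chrom)) {
    chrom <- paste0("chr", ci)
    n <- floor(chrom_length_bp / target_spacing_bp)
    base <- (seq_len(n) - 1) * chrom_length_bp / n
    # Jitter clamped to +/- 45% of the spacing keeps starts strictly
    # increasing and the realized median spacing near the target.
    jit <- rnorm(n, 0, 0.12 * target_spacing_bp)
    lim <- 0.45 * target_spacing_bp
    start <- floor(base + pmin(pmax(jit, -lim), lim))
    start <- pmax(start, 0)
    end <- pmin(start + probe_length_bp, chrom_length_bp)

    # GC: stationary AR(1) around 0.5, step correlation decaying with
    # physical distance, clamped to the plausible probe-design range.
    sp <- diff(c(start[1], start))
    rho <- exp(-pmax(sp, 1) / gc_autocorr_bp)
    z <- rnorm(n)
    g <- numeric(n)
    g[1] <- 0.1 * z[1]
    for (k in seq_len(n)[-1])
      g[k] <- rho[k] * g[k - 1] + sqrt(1 - rho[k]^2) * 0.1 * z[k]
    gc <- pmin(pmax(0.5 + g, 0.2), 0.8)

    out[[ci]] <- data.frame(
      probe_id = sprintf("%s_p%06d", chrom, seq_len(n)),
      chrom = chrom, start = start, end = end, gc = gc,
      stringsAsFactors = FALSE
    )
  }
  probes <- do.call(rbind, out)
  rownames(probes) <- NULL
  class(probes) <- c("probe_set", "data.frame")
  probes
}

#' @export
print.probe_set <- function(x, ...) {
  cat("probe_set:", nrow(x), "probes on", length(unique(x$chrom)),
      "chromosome(s)\n")
  sp <- unlist(tapply(x$start, x$chrom, function(s) diff(sort(s))))
  if (length(sp)) cat("  median spacing:", stats::median(sp), "bp\n")
  cat("  GC range:", paste(signif(range(x$gc), 3), collapse = " - "), "\n")
  invisible(x)
}

# Row indices of probes overlapping the half-open interval
# [start_bp, end_bp) on `chrom`.
probes_in_interval <- function(probes, chrom, start_bp, end_bp) {
  which(probes$chrom == chrom & probes$start < end_bp & probes$end > start_bp)
}
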