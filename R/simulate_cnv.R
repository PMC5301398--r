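#' Simulate a ground-truth CNV landscape across populations
#'
#' Plants duplication/deletion loci on a probe set and assigns carriers
#' within (and, for recurrent duplications, across) populations.  Each
#' locus has fixed coordinates reused identically by all its carriers,
#' so sharing fractions can be recounted exactly from the truth table.
#'
#' The carrier model per locus and population is: one "founder"
#' individual always carries the locus, and every other individual of
#' the population carries it independently with probability `sharing`.
#' `sharing = 0` therefore makes every CNV private to one individual and
#' `sharing = 1` (single population) makes every CNV carried by all.
#' A fraction `recurrent_dup_prob` of duplication loci recurs
#' independently in two or more populations (same coordinates, separate
#' carrier draws), emulating the recurrent-mutation behaviour that makes
#' duplications weaker population markers than deletions.
#'
#' Locus lengths are log-normal (median `exp(size_meanlog)`) clamped to
#' `size_range_bp`; loci that cannot cover at least `min_probes` probes
#' after several placement attempts are skipped with a warning, never
#' silently shrunk.
#'
#' @param probes a `probe_set`.
#' @param populations character vector of population names.
#' @param individuals_per_pop individuals simulated per population.
#' @param n_cnv_per_ind target mean number of CNVs per individual.
#' @param size_meanlog,size_sdlog log-normal parameters of locus length.
#' @param size_range_bp length-2 clamp for locus length in bp.
#' @param dup_fraction probability that a locus is a duplication.
#' @param sharing within-population carrier probability (see Details).
#' @param recurrent_dup_prob probability that a duplication locus recurs
#'   in more than one population.
#' @param min_probes minimum probes a locus must span.
#' @param effect_gain,effect_loss expected log2-ratio shift of carriers
#'   (defaults `+0.58` = log2(3/2), single-copy gain, and `-1.0`,
#'   heterozygous deletion).
#' @param seed integer seed.
#'
#' @return `data.frame` with one row per (locus, carrier): `locus_id`,
#'   `individual_id`, `population`, `chrom`, `start`, `end`, `state`
#'   (`"gain"`/`"loss"`), `effect`.  The attribute `"individuals"` holds
#'   the full individual table (including non-carriers of any locus).
#' @export
simulate_cnv_truth <- function(probes,
                               populations = c("POP1", "POP2", "POP3", "POP4"),
                               individuals_per_pop = 5L,
                               n_cnv_per_ind = 30,
                               size_meanlog = log(8400), size_sdlog = 1.1,
                               size_range_bp = c(2300, 693000),
                               dup_fraction = 0.6,
                               sharing = 0.3,
                               recurrent_dup_prob = 0.25,
                               min_probes = 5L,
                               effect_gain = 0.58, effect_loss = -1.0,
                               seed = 1L) {
  stop_if_not_probe_set(probes)
  if (dup_fraction <= 0 || dup_fraction >= 1)
    stop("'dup_fraction' must be in (0, 1)")
  if (sharing < 0 || sharing > 1) stop("'sharing' must be in [0, 1]")
  if (effect_gain <= 0) stop("'effect_gain' must be positive (gain)")
  if (effect_loss >= 0) stop("'effect_loss' must be negative (loss)")
  set.seed(derive_seed(seed, "cnv"))

  chroms <- unique(probes$chrom)
  chr_len <- vapply(chroms, function(ch) max(probes$end[probes$chrom == ch]),
                    numeric(1))
  inds <- data.frame(
    individual_id = unlist(lapply(seq_along(populations), function(p)
      sprintf("%s_i%02d", populations[p], seq_len(individuals_per_pop)))),
    population = rep(populations, each = individuals_per_pop),
    sex = rep_len(c("M", "F"), length(populations) * individuals_per_pop),
    stringsAsFactors = FALSE
  )

  target_total <- round(nrow(inds) * n_cnv_per_ind)
  rows <- list()
  total <- 0L
  locus_k <- 0L
  n_skipped <- 0L
  max_loci <- max(10L, 50L * target_total)  # hard stop for safety

  while (total < target_total && locus_k < max_loci) {
    locus_k <- locus_k + 1L
    is_gain <- runif(1) < dup_fraction
    size <- round(min(max(rlnorm(1, size_meanlog, size_sdlog),
                          size_range_bp[1]), size_range_bp[2]))
    ## place the locus so it spans >= min_probes probes
    placed <- FALSE
    for (try in 1:20) {
      ch <- sample(chroms, 1L, prob = chr_len)
      if (chr_len[[ch]] <= size) next
      start <- floor(runif(1, 0, chr_len[[ch]] - size))
      end <- start + size
      if (length(probes_in_interval(probes, ch, start, end)) >= min_probes) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      n_skipped <- n_skipped + 1L
      next
    }
    ## which populations harbour the locus
    pops_here <- sample(populations, 1L)
    if (is_gain && length(populations) > 1L &&
        runif(1) < recurrent_dup_prob) {
      k <- sample(2:length(populations), 1L)
      pops_here <- sample(populations, k)
    }
    lid <- sprintf("L%05d", locus_k)
    for (pp in pops_here) {
      members <- inds$individual_id[inds$population == pp]
      founder <- sample(members, 1L)
      others <- setdiff(members, founder)
      carriers <- c(founder,
                    others[runif(length(others)) < sharing])
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = lid, individual_id = carriers, population = pp,
        chrom = ch, start = start, end = end,
        state = if (is_gain) "gain" else "loss",
        effect = if (is_gain) effect_gain else effect_loss,
        stringsAsFactors = FALSE
      )
      total <- total + length(carriers)
    }
  }
  if (n_skipped > 0L)
    warning(n_skipped, " CNV locus(es) could not span >= ", min_probes,
            " probes and were skipped")
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  attr(truth, "individuals") <- inds
  truth
}

#' Fraction of CNV loci observed in exactly one population
#'
#' Recounts the carrier table by locus identity; used to check the
#' sharing structure of simulated landscapes.
#'
#' @param truth output of [simulate_cnv_truth()].
#' @return named numeric: fraction of loci found in 1, 2, ... populations.
#' @export
locus_population_spectrum <- function(truth) {
  npop <- tapply(truth$population, truth$locus_id,
                 function(p) length(unique(p)))
  tab <- table(factor(npop, levels = seq_len(max(npop))))
  as.numeric(tab) / sum(tab)
}
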