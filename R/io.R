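## Plain-text readers/writers for the pipeline's on-disk formats.
## Probes and CNVRs travel as BED-like TSV (0-based half-open), the
## log2-ratio and genotype matrices as TSV with a probe/CNVR id column.

#' Write / read a probe set as BED-like TSV
#'
#' Columns: chrom, start, end, probe_id, gc (no header, BED order).
#' @param probes a `probe_set`.
#' @param file path.
#' @return `read_probes_bed` returns a `probe_set`.
#' @export
write_probes_bed <- function(probes, file) {
  stop_if_not_probe_set(probes)
  utils::write.table(probes[, c("chrom", "start", "end", "probe_id", "gc")],
                     file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_probes_bed
#' @export
read_probes_bed <- function(file) {
  d <- utils::read.delim(file, header = FALSE,
                         col.names = c("chrom", "start", "end",
                                       "probe_id", "gc"),
                         stringsAsFactors = FALSE)
  d <- d[, c("probe_id", "chrom", "start", "end", "gc")]
  class(d) <- c("probe_set", "data.frame")
  d
}

#' Write / read an aCGH sample set as TSV
#'
#' The matrix file has a `probe_id` column followed by one column per
#' individual; the companion `<file>.info` holds the individual table.
#' @param samples an [acgh_set()].
#' @param file path of the matrix TSV.
#' @return `read_acgh_tsv` returns an [acgh_set()].
#' @export
write_acgh_tsv <- function(samples, file) {
  stop_if_not_acgh(samples)
  d <- data.frame(probe_id = rownames(samples$log2), samples$log2,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(samples$info, paste0(file, ".info"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_acgh_tsv
#' @export
read_acgh_tsv <- function(file) {
  d <- utils::read.delim(file, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  info <- utils::read.delim(paste0(file, ".info"),
                            stringsAsFactors = FALSE)
  acgh_set(m, info)
}

#' Write CNVRs as BED-like TSV
#'
#' Columns: chrom, start, end, cnvr_id, n_carriers, states (a
#' compact `del`/`dup`/`del,dup` tag).
#' @param cnvrs CNVR table.
#' @param file path.
#' @export
write_cnvr_bed <- function(cnvrs, file) {
  states <- paste0(ifelse(cnvrs$has_deletion, "del", ""),
                   ifelse(cnvrs$has_deletion & cnvrs$has_duplication,
                          ",", ""),
                   ifelse(cnvrs$has_duplication, "dup", ""))
  d <- data.frame(cnvrs$chrom, cnvrs$start, cnvrs$end, cnvrs$cnvr_id,
                  cnvrs$n_carriers, states)
  utils::write.table(d, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write / read a genotype matrix as TSV
#'
#' @param genotypes CNVR x individual matrix.
#' @param file path.
#' @return `read_genotypes_tsv` returns the matrix.
#' @export
write_genotypes_tsv <- function(genotypes, file) {
  d <- data.frame(cnvr_id = rownames(genotypes), genotypes,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(file) {
  d <- utils::read.delim(file, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}
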