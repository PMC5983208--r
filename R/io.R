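# Readers/writers for the plain-text formats the pipeline consumes and
# emits. Coordinates inside the package are 1-based inclusive; BED files
# are 0-based half-open, and only these two functions convert.

#' Read / write a BED interval file
#'
#' `read_bed()` loads at least the first three BED columns and converts to
#' the package's 1-based inclusive convention (`start = start0 + 1`);
#' `write_bed()` converts back. Extra columns are preserved by position
#' (name, score, strand, ...).
#'
#' @param path File path.
#' @return `read_bed()`: tibble with `chrom`, `start`, `end` and any extra
#'   columns.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       comment = "#")
  names(x)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  k <- ncol(x) - 3
  if (k > 0) names(x)[4:(3 + k)] <- c(extra, paste0("V", seq_len(max(0, k - 3))))[seq_len(k)]
  x$start <- as.integer(x$start) + 1L
  x$end <- as.integer(x$end)
  x
}

#' @rdname read_bed
#' @param x Interval tibble (1-based inclusive `start`, `end`).
#' @export
write_bed <- function(x, path) {
  out <- x
  out$start <- as.integer(out$start) - 1L
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write DMRs as BED6+
#'
#' Columns: chrom, 0-based start, end, dmr_id, n_probes, direction,
#' mean_delta_beta, max_run.
#'
#' @param dmrs DMR tibble from [merge_windows()].
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  out <- dplyr::select(dmrs, "chrom", "start", "end", "dmr_id",
                       "n_probes", "direction", "mean_delta_beta", "max_run")
  write_bed(out, path)
}

#' Read / write the tabular pipeline inputs
#'
#' TSV dialects: the manifest has columns `probe_id`, `chrom`, `pos`
#' (1-based), `cgi_member` and `snp_flag` (0/1 or logical); beta and
#' detection-p matrices have `probe_id` followed by one column per sample;
#' the sample sheet has `sample_id`, `group`, `cell_type`; the expression
#' table has `gene_id`, `rpkm`.
#'
#' @param path File path.
#' @param x Tibble to write.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name meth_io
NULL

#' @rdname meth_io
#' @export
read_manifest_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  x$cgi_member <- as.logical(x$cgi_member)
  x$snp_flag <- as.logical(x$snp_flag)
  x$pos <- as.integer(x$pos)
  check_manifest_sorted(x)
  x
}

#' @rdname meth_io
#' @export
write_manifest_tsv <- function(x, path) {
  out <- dplyr::mutate(x, cgi_member = as.integer(.data$cgi_member),
                       snp_flag = as.integer(.data$snp_flag))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname meth_io
#' @export
read_matrix_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname meth_io
#' @export
write_matrix_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname meth_io
#' @export
read_samples_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Write a full synthetic cohort to a directory
#'
#' Emits manifest, beta and detection-p TSVs, the sample sheet, and the
#' implanted-region truth set as a 0-based half-open BED (name = truth id,
#' score = probe count, strand column carries the direction).
#'
#' @param cohort A `meth_cohort` from [simulate_beta_cohort()].
#' @param manifest The matching manifest.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest_tsv(manifest, file.path(dir, "manifest.tsv"))
  write_matrix_tsv(cohort$beta, file.path(dir, "beta.tsv"))
  write_matrix_tsv(cohort$detp, file.path(dir, "detection_p.tsv"))
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  truth <- dplyr::select(cohort$truth, "chrom", "start", "end",
                         name = "dmr_id", score = "n_probes",
                         strand = "direction")
  write_bed(truth, file.path(dir, "truth.bed"))
  invisible(dir)
}
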