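#' Mask beta-values that failed detection
#'
#' Sets a beta-value to `NA` wherever its detection p-value exceeds the
#' threshold (a high detection p-value means the signal was not reliably
#' above background for that probe in that sample). All other values are
#' returned unchanged.
#'
#' @param beta Tibble `probe_id` + one numeric column per sample.
#' @param detp Detection p-value tibble, congruent with `beta`.
#' @param detection_p_threshold Values with detection p strictly greater
#'   than this are masked (default 0.01).
#' @return `beta` with failed cells set to `NA`.
#' @export
#' @examples
#' b <- tibble::tibble(probe_id = "cg1", s1 = 0.5, s2 = 0.6)
#' p <- tibble::tibble(probe_id = "cg1", s1 = 0.001, s2 = 0.02)
#' mask_failed_values(b, p)
mask_failed_values <- function(beta, detp, detection_p_threshold = 0.01) {
  check_congruent(beta, detp)
  if (detection_p_threshold <= 0 || detection_p_threshold >= 1) {
    abort("detection_p_threshold must lie in (0, 1)")
  }
  b <- as_value_matrix(beta)
  p <- as_value_matrix(detp)
  b[p > detection_p_threshold] <- NA_real_
  value_matrix_to_tibble(b)
}

#' Filter probes by missingness, SNP flags, and sex chromosomes
#'
#' Applies the probe-level quality rules of an HM450K analysis, in order:
#' probes whose post-masking missing fraction across the cohort is
#' *strictly greater* than `max_missing_fraction` are dropped; then
#' SNP-flagged probes (common variant in the probe's last 5 bp or at the
#' CpG site, precomputed in the manifest); then chrX/chrY probes. A probe
#' removed by an earlier rule is not recounted by a later one, so the
#' ledger counts sum to the number of probes removed. Retained probes keep
#' manifest order, and the filter is idempotent.
#'
#' @param beta Beta tibble, typically after [mask_failed_values()].
#' @param manifest Probe manifest covering every probe in `beta`.
#' @param max_missing_fraction Missing-fraction cutoff (strict inequality;
#'   default 0.05).
#' @param drop_snp_probes,drop_sex_chromosomes Toggle those rules.
#' @return Filtered beta tibble; the removal ledger is attached as
#'   attribute `"ledger"` and readable with [qc_ledger()].
#' @export
filter_probes <- function(beta, manifest,
                          max_missing_fraction = 0.05,
                          drop_snp_probes = TRUE,
                          drop_sex_chromosomes = TRUE) {
  if (max_missing_fraction <= 0 || max_missing_fraction >= 1) {
    abort("max_missing_fraction must lie in (0, 1)")
  }
  miss <- setdiff(beta$probe_id, manifest$probe_id)
  if (length(miss) > 0) {
    abort(sprintf("%d probes in the matrix are absent from the manifest",
                  length(miss)))
  }
  b <- as_value_matrix(beta)
  info <- manifest[match(beta$probe_id, manifest$probe_id), ]

  missing_frac <- rowMeans(is.na(b))
  drop_missing <- missing_frac > max_missing_fraction
  drop_snp <- drop_snp_probes & info$snp_flag & !drop_missing
  drop_sex <- drop_sex_chromosomes & is_sex_chrom(info$chrom) &
    !drop_missing & !drop_snp
  keep <- !(drop_missing | drop_snp | drop_sex)

  out <- beta[keep, , drop = FALSE]
  # restore manifest order among retained probes
  out <- out[order(match(out$probe_id, manifest$probe_id)), , drop = FALSE]
  attr(out, "ledger") <- tibble(
    rule = c("missing", "snp", "sex"),
    n_removed = c(sum(drop_missing), sum(drop_snp), sum(drop_sex))
  )
  out
}

#' Removal ledger of a [filter_probes()] result
#'
#' @param x Tibble returned by [filter_probes()].
#' @return Tibble with columns `rule` and `n_removed`.
#' @export
qc_ledger <- function(x) {
  ledger <- attr(x, "ledger")
  if (is.null(ledger)) abort("no QC ledger attached; run filter_probes() first")
  ledger
}
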