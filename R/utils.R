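# Internal helpers shared across modules. Coordinates are 1-based inclusive
# everywhere inside the package; BED readers/writers convert at the boundary.

# sample columns of a beta/detp tibble (everything except probe_id)
sample_cols <- function(x) setdiff(names(x), "probe_id")

# beta/detp tibble -> numeric matrix with probe_id rownames
as_value_matrix <- function(x) {
  stopifnot(is.data.frame(x), "probe_id" %in% names(x))
  m <- as.matrix(x[sample_cols(x)])
  if (!is.numeric(m)) abort("value columns must be numeric")
  rownames(m) <- x$probe_id
  m
}

value_matrix_to_tibble <- function(m) {
  dplyr::bind_cols(tibble(probe_id = rownames(m)), as_tibble(m))
}

check_congruent <- function(beta, detp) {
  if (!identical(dim(beta), dim(detp)) ||
      !identical(beta$probe_id, detp$probe_id) ||
      !identical(sample_cols(beta), sample_cols(detp))) {
    abort("`beta` and `detp` must have identical probes and sample columns")
  }
  invisible(TRUE)
}

is_sex_chrom <- function(chrom) {
  toupper(sub("^chr", "", chrom, ignore.case = TRUE)) %in% c("X", "Y")
}

check_manifest_sorted <- function(manifest) {
  ord <- order(manifest$chrom, manifest$pos)
  if (!identical(ord, seq_len(nrow(manifest)))) {
    abort("manifest must be sorted by (chrom, pos)")
  }
  if (anyDuplicated(manifest$probe_id)) abort("probe ids must be unique")
  invisible(TRUE)
}

# generic interval tibble (chrom, start, end; 1-based inclusive) -> GRanges
as_granges <- function(x) {
  if (nrow(x) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start, end = x$end)
  )
}

# which rows of `x` overlap any interval of `y` by >= min_overlap bases
overlaps_any <- function(x, y, min_overlap = 1L) {
  if (nrow(x) == 0) return(logical(0))
  if (is.null(y) || nrow(y) == 0) return(rep(FALSE, nrow(x)))
  IRanges::overlapsAny(as_granges(x), as_granges(y),
                       minoverlap = min_overlap)
}

check_intervals <- function(x, what = "interval table") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    abort(paste0(what, " must have columns chrom, start, end"))
  }
  if (nrow(x) > 0 && any(x$end < x$start)) {
    abort(paste0(what, " has end < start"))
  }
  invisible(TRUE)
}
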