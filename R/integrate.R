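#' Candidate repressed / expressed genes from promoter DMRs and expression
#'
#' Crosses promoter-DMR overlap with baseline expression in the healthy
#' reference tissue: a gene expressed there (`rpkm > rpkm_threshold`)
#' whose promoter overlaps a hypermethylated DMR is a
#' `candidate_repressed` gene (its expression could be lost upon
#' hypermethylation); a repressed gene (`rpkm < rpkm_threshold`) whose
#' promoter overlaps a hypomethylated DMR is a `candidate_expressed` gene
#' (it could be ectopically activated). Genes exactly at the threshold are
#' left unclassified, a gene is reported once even when several of its
#' promoters qualify, and genes absent from the expression table are
#' excluded (their count is attached as attribute `n_missing_expression`).
#'
#' @param dmrs DMR tibble from [merge_windows()] (needs `chrom`, `start`,
#'   `end`, `direction`, `dmr_id`).
#' @param gene_models Gene models (see [promoters_from_genes()]).
#' @param expression Tibble `gene_id`, `rpkm`.
#' @param rpkm_threshold Expressed/repressed cutoff (default 1, strict on
#'   both sides).
#' @param promoter_halfwidth Promoter flank in bp (default 1000).
#' @param min_overlap_bp Minimum promoter-DMR overlap (default 1).
#' @return Tibble `gene_id`, `class`, `rpkm`, `promoters` (list of
#'   transcript ids whose promoter overlaps a qualifying DMR), `dmr_ids`
#'   (list).
#' @export
classify_candidates <- function(dmrs, gene_models, expression,
                                rpkm_threshold = 1,
                                promoter_halfwidth = 1000,
                                min_overlap_bp = 1) {
  overlaps <- promoter_dmr_overlaps(dmrs, gene_models, promoter_halfwidth,
                                    min_overlap_bp)
  missing <- setdiff(unique(overlaps$gene_id), expression$gene_id)
  if (length(missing) > 0) {
    message(sprintf("%d genes with promoter-DMR overlap lack expression data; excluded",
                    length(missing)))
  }
  merged <- dplyr::inner_join(overlaps, expression, by = "gene_id")
  merged <- dplyr::mutate(merged, class = dplyr::case_when(
    .data$rpkm > rpkm_threshold & .data$direction == "hyper" ~ "candidate_repressed",
    .data$rpkm < rpkm_threshold & .data$direction == "hypo" ~ "candidate_expressed",
    TRUE ~ NA_character_
  ))
  merged <- dplyr::filter(merged, !is.na(.data$class))
  out <- dplyr::summarise(
    dplyr::group_by(merged, .data$gene_id, .data$class, .data$rpkm),
    promoters = list(unique(.data$transcript_id)),
    dmr_ids = list(unique(.data$dmr_id)),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$gene_id)
  attr(out, "n_missing_expression") <- length(missing)
  out
}

# long table of every (promoter, DMR) overlap with direction
promoter_dmr_overlaps <- function(dmrs, gene_models, promoter_halfwidth,
                                  min_overlap_bp) {
  promoters <- promoters_from_genes(gene_models, promoter_halfwidth)
  if (nrow(dmrs) == 0 || nrow(promoters) == 0) {
    return(tibble(gene_id = character(), transcript_id = character(),
                  dmr_id = character(), direction = character()))
  }
  hits <- GenomicRanges::findOverlaps(as_granges(promoters), as_granges(dmrs),
                                      minoverlap = min_overlap_bp)
  tibble(
    gene_id = promoters$gene_id[S4Vectors::queryHits(hits)],
    transcript_id = promoters$transcript_id[S4Vectors::queryHits(hits)],
    dmr_id = dmrs$dmr_id[S4Vectors::subjectHits(hits)],
    direction = dmrs$direction[S4Vectors::subjectHits(hits)]
  )
}

#' Restrict candidates to one cell type
#'
#' Keeps a candidate gene only when none of its supporting promoters
#' overlaps a same-direction DMR in the other cell type's DMR set, i.e.,
#' the promoter methylation defect is private to the cell subset the
#' candidates came from.
#'
#' @param candidates Output of [classify_candidates()] for the focal cell
#'   type.
#' @param dmrs_other DMR tibble of the other cell type.
#' @param gene_models Gene models (to rebuild promoter intervals).
#' @param promoter_halfwidth,min_overlap_bp As in [classify_candidates()].
#' @return Subset of `candidates` with a `cell_type_specific = TRUE`
#'   column appended.
#' @export
cell_type_specific_candidates <- function(candidates, dmrs_other, gene_models,
                                          promoter_halfwidth = 1000,
                                          min_overlap_bp = 1) {
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates, cell_type_specific = logical(0)))
  }
  other <- promoter_dmr_overlaps(dmrs_other, gene_models,
                                 promoter_halfwidth, min_overlap_bp)
  dir_of <- c(candidate_repressed = "hyper", candidate_expressed = "hypo")
  shared <- purrr::map2_lgl(candidates$promoters,
                            dir_of[candidates$class],
                            function(tx, dir) {
    any(other$transcript_id %in% tx & other$direction == dir)
  })
  dplyr::mutate(candidates[!shared, , drop = FALSE],
                cell_type_specific = TRUE)
}

#' Concordance between array beta-values and WGBS methylation
#'
#' Matches array probes to whole-genome bisulfite sequencing CpG sites on
#' (chrom, pos), drops sites sequenced below `min_coverage` reads, and
#' reports the squared Pearson correlation between the array beta-values
#' and the WGBS methylation fractions.
#'
#' @param array_means Tibble `chrom`, `pos`, `beta` (e.g., control-group
#'   mean beta per probe).
#' @param wgbs Tibble `chrom`, `pos`, `meth` (fraction), `coverage`
#'   (read count).
#' @param min_coverage Minimum WGBS read coverage (default 5).
#' @return One-row tibble `n_sites`, `r_squared`.
#' @export
wgbs_concordance <- function(array_means, wgbs, min_coverage = 5) {
  wgbs <- dplyr::filter(wgbs, .data$coverage >= min_coverage)
  matched <- dplyr::inner_join(array_means, wgbs, by = c("chrom", "pos"))
  matched <- matched[complete.cases(matched[c("beta", "meth")]), ]
  if (nrow(matched) < 3) {
    abort("fewer than 3 matched sites after the coverage filter")
  }
  tibble(n_sites = nrow(matched),
         r_squared = cor(matched$beta, matched$meth)^2)
}

#' qPCR relative expression
#'
#' Efficiency-corrected relative expression of a target transcript against
#' a housekeeping panel:
#' `E_t^(-Ct_t) / geometric_mean_i(E_i^(-Ct_i))`.
#'
#' @param e_target Amplification efficiency of the target (typically
#'   near 2; must be positive, and a warning is issued outside (1, 2.2]).
#' @param ct_target Target cycle threshold (> 0).
#' @param housekeeping Tibble (or data frame) with columns `e` and `ct`,
#'   one row per housekeeping gene (at least one).
#' @return Relative expression level (numeric scalar).
#' @export
#' @examples
#' hk <- tibble::tibble(e = c(2, 2), ct = c(20, 20))
#' relative_expression(2, 19, hk)  # 2
relative_expression <- function(e_target, ct_target, housekeeping) {
  es <- c(e_target, housekeeping$e)
  if (any(es <= 0)) abort("amplification efficiencies must be positive")
  if (any(es <= 1 | es > 2.2)) {
    warn("amplification efficiency outside the usual (1, 2.2] range")
  }
  if (nrow(housekeeping) < 1) abort("at least one housekeeping gene required")
  if (any(c(ct_target, housekeeping$ct) <= 0)) abort("Ct values must be positive")
  target_level <- e_target^(-ct_target)
  hk_levels <- housekeeping$e^(-housekeeping$ct)
  target_level / exp(mean(log(hk_levels)))
}
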