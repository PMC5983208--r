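#' Promoter intervals from gene models
#'
#' One promoter per transcript TSS, spanning `tss - halfwidth` to
#' `tss + halfwidth` (1-based inclusive, clipped at 1). A gene may own
#' several promoters.
#'
#' @param gene_models Tibble with `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `tss` (1-based TSS position).
#' @param halfwidth Flank size in bp (default 1000, i.e., TSS +/- 1 kb).
#' @return Tibble `gene_id`, `transcript_id`, `chrom`, `start`, `end`.
#' @export
promoters_from_genes <- function(gene_models, halfwidth = 1000) {
  tibble(
    gene_id = gene_models$gene_id,
    transcript_id = gene_models$transcript_id,
    chrom = gene_models$chrom,
    start = pmax(1L, as.integer(gene_models$tss - halfwidth)),
    end = as.integer(gene_models$tss + halfwidth)
  )
}

#' Assign genomic feature labels to intervals
#'
#' Labels each query interval `promoter`, `gene_body` or `intergenic`
#' (mutually exclusive; promoter wins over gene body), and independently
#' flags overlap with CpG islands and enhancers. Probes can be annotated
#' by passing 1-bp intervals (`start = end = pos`).
#'
#' @param x Query tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @param gene_models Gene models as in [promoters_from_genes()], with
#'   gene-body `start`/`end` columns.
#' @param cgis,enhancers Optional interval tibbles (`chrom`, `start`,
#'   `end`); `NULL` means the corresponding flag is `FALSE` everywhere.
#' @param promoter_halfwidth Promoter flank in bp (default 1000).
#' @return `x` with columns `feature` (character), `cgi`, `enhancer`
#'   (logical) appended.
#' @export
assign_feature <- function(x, gene_models, cgis = NULL, enhancers = NULL,
                           promoter_halfwidth = 1000) {
  check_intervals(x, "query")
  promoters <- promoters_from_genes(gene_models, promoter_halfwidth)
  bodies <- dplyr::select(gene_models, "chrom", "start", "end")
  in_prom <- overlaps_any(x, promoters)
  in_body <- overlaps_any(x, bodies)
  dplyr::mutate(
    x,
    feature = dplyr::case_when(in_prom ~ "promoter",
                               in_body ~ "gene_body",
                               TRUE ~ "intergenic"),
    cgi = overlaps_any(x, cgis),
    enhancer = overlaps_any(x, enhancers)
  )
}

# per-window CpG-density statistics over one DNA string; windows slide by
# `step`, plus a final tail window so the 3' end is always covered
promoter_window_stats <- function(seq, window = 500L, step = 5L) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  is_c <- chars == "C"
  is_g <- chars == "G"
  is_n <- !(chars %in% c("A", "C", "G", "T"))
  # overlapping CpG dinucleotide starts
  cpg_start <- c(is_c[-L] & is_g[-1], FALSE)
  if (L < window) {
    warn("sequence shorter than the sliding window; classifying on the full sequence")
    starts <- 1L
    window <- L
  } else {
    starts <- seq.int(1L, L - window + 1L, by = step)
    if (starts[length(starts)] != L - window + 1L) {
      starts <- c(starts, L - window + 1L)
    }
  }
  cum <- function(v) c(0, cumsum(v))
  cc <- cum(is_c); cg <- cum(is_g); cn <- cum(is_n); cp <- cum(cpg_start)
  ends <- starts + window - 1L
  n_c <- cc[ends + 1L] - cc[starts]
  n_g <- cg[ends + 1L] - cg[starts]
  n_n <- cn[ends + 1L] - cn[starts]
  # dinucleotide must lie fully inside the window
  n_cpg <- cp[ends] - cp[starts]
  eff_len <- window - n_n
  oe <- ifelse(n_c * n_g > 0, n_cpg * eff_len / (n_c * n_g), 0)
  gc <- ifelse(eff_len > 0, (n_c + n_g) / eff_len, 0)
  tibble(start = starts, oe = oe, gc = gc)
}

#' Classify promoter CpG density (HCP / ICP / LCP)
#'
#' Weber-style classification on 500-bp windows sliding in 5-bp steps
#' across the promoter sequence: **HCP** if any window has CpG
#' observed/expected ratio >= 0.75 *and* GC fraction >= 0.55; **LCP** if no
#' window reaches o/e >= 0.48; **ICP** otherwise. Within a window,
#' `o/e = (#CpG * L) / (#C * #G)` with overlapping CpG dinucleotide
#' counts; N bases are excluded from all counts and from the effective
#' length. Sequences shorter than the window are classified on the full
#' sequence with a warning. The statistics are reverse-complement
#' symmetric, so the class does not depend on strand.
#'
#' @param seq Character vector of promoter sequences over `{A,C,G,T,N}`.
#' @param hcp_oe,hcp_gc,lcp_oe Class thresholds (defaults 0.75, 0.55, 0.48).
#' @param window,step Sliding-window size and offset in bp (500 / 5).
#' @return Character vector of classes `"HCP"`, `"ICP"`, `"LCP"`.
#' @export
#' @examples
#' classify_promoter(strrep("CG", 250))   # "HCP"
#' classify_promoter(strrep("A", 1000))   # "LCP"
classify_promoter <- function(seq, hcp_oe = 0.75, hcp_gc = 0.55,
                              lcp_oe = 0.48, window = 500L, step = 5L) {
  vapply(seq, function(s) {
    st <- promoter_window_stats(s, window = window, step = step)
    if (any(st$oe >= hcp_oe & st$gc >= hcp_gc)) {
      "HCP"
    } else if (all(st$oe < lcp_oe)) {
      "LCP"
    } else {
      "ICP"
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Classify chromatin state by histone-mark peak overlap
#'
#' An interval overlapping both an H3K4me3 and an H3K27me3 peak carries
#' the bivalent signature; overlap with a single mark gives the
#' corresponding single-mark state; no overlap gives `none`.
#'
#' @param x Query interval tibble (`chrom`, `start`, `end`).
#' @param k4_peaks,k27_peaks Peak interval tibbles for H3K4me3 and
#'   H3K27me3.
#' @return `x` with a `chromatin_state` column in
#'   `{bivalent, H3K4me3_only, H3K27me3_only, none}`.
#' @export
classify_chromatin_state <- function(x, k4_peaks, k27_peaks) {
  check_intervals(x, "query")
  k4 <- overlaps_any(x, k4_peaks)
  k27 <- overlaps_any(x, k27_peaks)
  dplyr::mutate(x, chromatin_state = dplyr::case_when(
    k4 & k27 ~ "bivalent",
    k4 ~ "H3K4me3_only",
    k27 ~ "H3K27me3_only",
    TRUE ~ "none"
  ))
}

#' Category distribution of a probe set against its background
#'
#' Tabulates the percentage of probes per category for a focal set and for
#' the background it was drawn from (e.g., chromatin states of probes in
#' hypermethylated CGI-associated DMRs vs all array probes). Both
#' percentage vectors sum to 100.
#'
#' @param focal Tibble of focal probes; must be a subset of `background`
#'   (checked on `probe_id` when present).
#' @param background Tibble of background probes.
#' @param category Name of the category column (string), present in both.
#' @return Tibble `category`, `focal_pct`, `background_pct`.
#' @export
category_distribution <- function(focal, background, category) {
  if (nrow(focal) == 0) abort("focal set is empty")
  if (!category %in% names(focal) || !category %in% names(background)) {
    abort(sprintf("column '%s' must exist in both sets", category))
  }
  if ("probe_id" %in% names(focal) && "probe_id" %in% names(background) &&
      !all(focal$probe_id %in% background$probe_id)) {
    abort("focal probes must be a subset of the background")
  }
  levels <- union(unique(background[[category]]), unique(focal[[category]]))
  pct <- function(x) {
    counts <- table(factor(x[[category]], levels = levels))
    100 * as.numeric(counts) / nrow(x)
  }
  tibble(category = levels, focal_pct = pct(focal),
         background_pct = pct(background))
}

#' Report a percentage from a count pair
#'
#' The reporting helper used for headline ratios (e.g., the share of
#' differentially methylated probes that are hypomethylated, or of
#' promoter-DMR genes that pass an expression cutoff): a numerator and
#' denominator produce a percentage rounded to the requested number of
#' digits.
#'
#' @param numerator,denominator Non-negative counts (`denominator > 0`).
#' @param digits Decimal places of the reported percentage (default 1).
#' @return Numeric percentage in `[0, 100]`.
#' @export
#' @examples
#' report_fraction(46379, 68164, digits = 0)  # 68
#' report_fraction(70, 177)                   # 39.5
report_fraction <- function(numerator, denominator, digits = 1) {
  if (any(denominator <= 0)) abort("denominator must be positive")
  if (any(numerator < 0 | numerator > denominator)) {
    abort("numerator must lie in [0, denominator]")
  }
  round(100 * numerator / denominator, digits)
}
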