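#' Simulation configuration for a synthetic HM450K-style cohort
#'
#' Bundles every tunable of the synthetic-data generator into a validated
#' list. The defaults emulate a small two-group array study: a bimodal
#' baseline methylation profile, log-normal inter-probe spacing, a ~5.5%
#' SNP-flagged probe rate and ~2.5% sex-chromosome probes (the approximate
#' rates on the HM450K array), sporadic detection failures, and implanted
#' differentially methylated regions described by [dmr_target()].
#'
#' @param n_probes Number of array probes to simulate.
#' @param n_chromosomes Number of autosomes (`chr1`..`chrN`); sex-chromosome
#'   probes are placed on `chrX`/`chrY` in addition when
#'   `sex_chromosome_fraction > 0`.
#' @param median_gap Median inter-probe spacing in bp.
#' @param gap_dispersion Log-scale standard deviation of the spacing
#'   distribution (gaps are log-normal).
#' @param n_samples_per_group Samples per group (case and control each get
#'   this many, per cell type).
#' @param baseline_profile Named numeric vector of mixture proportions
#'   `c(low, mid, high)` for near-0, intermediate and near-1 baseline
#'   methylation; must sum to 1.
#' @param dmr_spec Tibble of regions to implant, built with [dmr_target()]
#'   (one row per region), or `NULL` for none.
#' @param noise_sd Beta-scale standard deviation of measurement noise
#'   (applied on the logit scale and mapped back, so values stay in (0,1)).
#' @param detection_fail_rate Per probe-by-sample probability of a detection
#'   failure (detection p-value forced above 0.01).
#' @param snp_probe_rate Probability a probe is SNP-flagged.
#' @param sex_chromosome_fraction Fraction of probes placed on chrX/chrY.
#' @param cgi_fraction Fraction of probes inside simulated CpG islands.
#' @param seed Integer seed; the seed and config fully determine all output.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_manifest()], [simulate_beta_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(n_probes = 500, seed = 1)
sim_config <- function(n_probes = 10000,
                       n_chromosomes = 5,
                       median_gap = 500,
                       gap_dispersion = 1.2,
                       n_samples_per_group = 5,
                       baseline_profile = c(low = 0.40, mid = 0.15, high = 0.45),
                       dmr_spec = NULL,
                       noise_sd = 0.05,
                       detection_fail_rate = 0.002,
                       snp_probe_rate = 0.055,
                       sex_chromosome_fraction = 0.025,
                       cgi_fraction = 0.31,
                       seed = 1L) {
  if (n_probes < 0 || n_chromosomes < 1 || n_samples_per_group < 0) {
    abort("counts must be non-negative (and n_chromosomes >= 1)")
  }
  probs <- c(detection_fail_rate, snp_probe_rate,
             sex_chromosome_fraction, cgi_fraction)
  if (any(probs < 0 | probs > 1)) abort("all rates must lie in [0, 1]")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (abs(sum(baseline_profile) - 1) > 1e-8 || any(baseline_profile < 0)) {
    abort("baseline_profile proportions must be non-negative and sum to 1")
  }
  if (!is.null(dmr_spec)) {
    stopifnot(is.data.frame(dmr_spec))
    if (any(dmr_spec$effect_size <= 0 | dmr_spec$effect_size > 1)) {
      abort("effect sizes must lie in (0, 1]")
    }
    if (any(dmr_spec$n_probes < 1)) abort("dmr_spec n_probes must be >= 1")
  }
  structure(
    list(n_probes = as.integer(n_probes),
         n_chromosomes = as.integer(n_chromosomes),
         median_gap = median_gap,
         gap_dispersion = gap_dispersion,
         n_samples_per_group = as.integer(n_samples_per_group),
         baseline_profile = baseline_profile,
         dmr_spec = dmr_spec,
         noise_sd = noise_sd,
         detection_fail_rate = detection_fail_rate,
         snp_probe_rate = snp_probe_rate,
         sex_chromosome_fraction = sex_chromosome_fraction,
         cgi_fraction = cgi_fraction,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Describe one region to implant in a synthetic cohort
#'
#' @param direction `"hyper"` (cases gain methylation) or `"hypo"`.
#' @param n_probes Number of consecutive probes in the region (>= 1).
#' @param effect_size Group-mean beta difference implanted before noise,
#'   in (0, 1].
#' @param max_gap Largest allowed gap (bp) between adjacent member probes
#'   when placing the region.
#' @param undetectable If `TRUE`, the region is deliberately placed across
#'   at least one gap larger than 1 kb, so a 1 kb-gap window caller must
#'   split or drop it; useful for specificity benchmarks. Requires
#'   `max_gap > 1000`.
#'
#' @return One-row tibble suitable for `dmr_spec` in [sim_config()].
#' @export
#' @examples
#' dmr_target("hyper", n_probes = 5, effect_size = 0.3)
dmr_target <- function(direction = c("hyper", "hypo"), n_probes = 5,
                       effect_size = 0.3, max_gap = 1000,
                       undetectable = FALSE) {
  direction <- match.arg(direction)
  if (undetectable && max_gap <= 1000) {
    abort("undetectable regions need max_gap > 1000")
  }
  tibble(direction = direction, n_probes = as.integer(n_probes),
         effect_size = effect_size, max_gap = max_gap,
         undetectable = undetectable)
}

#' Simulate an ordered probe manifest
#'
#' Produces the genomic catalogue the rest of the pipeline keys on: probes
#' strictly ordered by (chromosome, position) with unique ids, CpG-island
#' membership for roughly `cgi_fraction` of probes (islands are short runs
#' of adjacent probes, as on the array), SNP flags drawn per probe at
#' `snp_probe_rate`, and a `sex_chromosome_fraction` share of probes on
#' chrX/chrY. Given the same config the output is byte-identical.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `probe_id`, `chrom`, `pos`, `cgi_member`,
#'   `snp_flag`, sorted by (chrom, pos).
#' @export
#' @examples
#' simulate_manifest(sim_config(n_probes = 10, seed = 7))
simulate_manifest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_probes
  if (n == 0) {
    return(tibble(probe_id = character(), chrom = character(),
                  pos = integer(), cgi_member = logical(),
                  snp_flag = logical()))
  }
  manifest <- withr::with_seed(config$seed, {
    n_sex <- round(n * config$sex_chromosome_fraction)
    n_x <- floor(n_sex / 2)
    n_y <- n_sex - n_x
    n_auto <- n - n_sex
    # spread autosomal probes over chromosomes, keep every chromosome nonempty
    auto_counts <- as.vector(stats::rmultinom(1, n_auto,
                                              rep(1, config$n_chromosomes)))
    chroms <- c(paste0("chr", seq_len(config$n_chromosomes)), "chrX", "chrY")
    counts <- c(auto_counts, n_x, n_y)
    per_chrom <- purrr::map2(chroms, counts, function(ch, k) {
      if (k == 0) return(NULL)
      gaps <- pmax(2, round(rlnorm(k, meanlog = log(config$median_gap),
                                   sdlog = config$gap_dispersion)))
      tibble(chrom = ch, pos = as.integer(1000L + cumsum(gaps)))
    })
    out <- dplyr::bind_rows(per_chrom)
    out <- dplyr::arrange(out, .data$chrom, .data$pos)
    # CpG islands: short runs of adjacent probes flagged together
    cgi <- rep(FALSE, nrow(out))
    target <- round(config$cgi_fraction * nrow(out))
    while (sum(cgi) < target) {
      len <- stats::rpois(1, 4) + 2
      start <- sample.int(max(1, nrow(out) - len), 1)
      cgi[start:min(nrow(out), start + len - 1)] <- TRUE
    }
    out$cgi_member <- cgi
    out
  })
  # SNP flags in an isolated stream so the draw is reproducible on its own
  manifest$snp_flag <- withr::with_seed(
    config$seed + 1L, runif(nrow(manifest)) < config$snp_probe_rate
  )
  manifest$probe_id <- sprintf("cg%08d", seq_len(nrow(manifest)))
  dplyr::select(manifest, "probe_id", "chrom", "pos", "cgi_member", "snp_flag")
}

# pick non-overlapping probe runs satisfying each dmr_target's gap rule;
# a one-probe buffer keeps implanted regions from abutting each other
place_truth_regions <- function(manifest, spec) {
  n <- nrow(manifest)
  taken <- rep(FALSE, n)
  gaps <- c(diff(manifest$pos), Inf)
  gaps[c(diff(as.integer(factor(manifest$chrom))) != 0, TRUE)] <- Inf
  out <- vector("list", nrow(spec))
  ord <- order(-spec$n_probes)
  for (row in ord) {
    k <- spec$n_probes[row]
    ok_start <- logical(n)
    for (i in seq_len(max(0, n - k + 1))) {
      idx <- i:(i + k - 1)
      run_gaps <- gaps[idx[-k]]
      if (k > 1 && any(run_gaps > spec$max_gap[row])) next
      if (k > 1 && isTRUE(spec$undetectable[row]) && all(run_gaps <= 1000)) next
      buf <- max(1, i - 1):min(n, i + k)
      if (any(taken[buf])) next
      if (is_sex_chrom(manifest$chrom[i])) next
      ok_start[i] <- TRUE
    }
    cand <- which(ok_start)
    if (length(cand) == 0) {
      abort(sprintf("cannot place implanted region %d (%d probes, max_gap %g)",
                    row, k, spec$max_gap[row]))
    }
    i <- cand[sample.int(length(cand), 1)]
    idx <- i:(i + k - 1)
    taken[idx] <- TRUE
    out[[row]] <- tibble(
      dmr_id = sprintf("truth_%03d", row),
      chrom = manifest$chrom[i],
      start = manifest$pos[i],
      end = manifest$pos[i + k - 1],
      direction = spec$direction[row],
      n_probes = k,
      effect_size = spec$effect_size[row],
      detectable = if (k > 1) all(gaps[idx[-k]] <= 1000) else TRUE,
      probe_ids = list(manifest$probe_id[idx])
    )
  }
  dplyr::bind_rows(out)
}

#' Simulate a two-group beta-value cohort with implanted DMRs
#'
#' Builds a probes-by-samples beta matrix for a case and a control group.
#' Each probe gets a baseline methylation level drawn from the configured
#' near-0 / intermediate / near-1 mixture. Regions listed in
#' `config$dmr_spec` are realized as runs of consecutive manifest probes
#' whose case-group mean is shifted by exactly the configured effect size
#' before noise (baselines at implanted probes are drawn away from the
#' boundary so the shift never clips). Measurement noise is added on the
#' logit scale, scaled so its beta-scale standard deviation is
#' approximately `noise_sd`, and mapped back, keeping values inside (0,1).
#' Detection failures are independent Bernoulli events per probe-by-sample
#' cell; failed cells get a detection p-value above 0.01, all others below.
#'
#' @param manifest Probe manifest from [simulate_manifest()] (non-empty).
#' @param config The same [sim_config()] used for the manifest.
#' @param cell_type Cell-type label written into the sample sheet.
#' @param groups Length-2 character: case label then control label.
#'
#' @return List of class `meth_cohort` with tibbles `beta` (probe_id +
#'   one column per sample), `detp` (same shape), `samples` (sample_id,
#'   group, cell_type) and `truth` (implanted regions with member probes
#'   and a `detectable` flag).
#' @export
#' @examples
#' cfg <- sim_config(n_probes = 200, dmr_spec = dmr_target("hyper", 5, 0.3),
#'                   seed = 2)
#' cohort <- simulate_beta_cohort(simulate_manifest(cfg), cfg)
#' names(cohort)
simulate_beta_cohort <- function(manifest, config,
                                 cell_type = "CD34+CD15-",
                                 groups = c("CML", "HD")) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(manifest) == 0) abort("manifest must be non-empty")
  check_manifest_sorted(manifest)
  n <- nrow(manifest)
  n_per <- config$n_samples_per_group
  spec <- config$dmr_spec

  withr::with_seed(config$seed + 2L, {
    truth <- if (!is.null(spec) && nrow(spec) > 0) {
      place_truth_regions(manifest, spec)
    } else {
      tibble(dmr_id = character(), chrom = character(), start = integer(),
             end = integer(), direction = character(), n_probes = integer(),
             effect_size = numeric(), detectable = logical(),
             probe_ids = list())
    }

    comp <- sample(names(config$baseline_profile), n, replace = TRUE,
                   prob = config$baseline_profile)
    mu <- numeric(n)
    mu[comp == "low"] <- runif(sum(comp == "low"), 0.02, 0.15)
    mu[comp == "mid"] <- runif(sum(comp == "mid"), 0.30, 0.70)
    mu[comp == "high"] <- runif(sum(comp == "high"), 0.85, 0.98)

    # per-probe case-group shift; baselines at implanted probes re-drawn so
    # mu + shift stays strictly inside [0, 1]
    shift <- numeric(n)
    if (nrow(truth) > 0) {
      for (r in seq_len(nrow(truth))) {
        idx <- match(truth$probe_ids[[r]], manifest$probe_id)
        d <- truth$effect_size[r]
        if (truth$direction[r] == "hyper") {
          mu[idx] <- runif(length(idx), 0.03, min(0.35, 1 - d - 0.02))
          shift[idx] <- d
        } else {
          mu[idx] <- runif(length(idx), max(0.65, d + 0.02), 0.97)
          shift[idx] <- -d
        }
      }
    }

    sample_ids <- c(paste0(groups[1], "_", seq_len(n_per)),
                    paste0(groups[2], "_", seq_len(n_per)))
    group <- rep(groups, each = n_per)
    means <- outer(shift, as.numeric(group == groups[1])) + mu

    if (config$noise_sd > 0) {
      m0 <- pmin(pmax(means, 1e-3), 1 - 1e-3)
      sd_logit <- config$noise_sd / (m0 * (1 - m0))
      beta <- plogis(qlogis(m0) +
                     rnorm(length(m0)) * sd_logit)
      dim(beta) <- dim(means)
    } else {
      beta <- means
    }
    rownames(beta) <- manifest$probe_id
    colnames(beta) <- sample_ids

    fail <- matrix(runif(length(beta)) < config$detection_fail_rate,
                   nrow = n)
    detp <- matrix(runif(length(beta), 0, 0.005), nrow = n)
    detp[fail] <- runif(sum(fail), 0.02, 0.6)
    rownames(detp) <- manifest$probe_id
    colnames(detp) <- sample_ids

    structure(
      list(beta = value_matrix_to_tibble(beta),
           detp = value_matrix_to_tibble(detp),
           samples = tibble(sample_id = sample_ids, group = group,
                            cell_type = cell_type),
           truth = truth),
      class = "meth_cohort"
    )
  })
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf("<meth_cohort> %d probes x %d samples (%s), %d implanted regions\n",
              nrow(x$beta), nrow(x$samples),
              paste(unique(x$samples$group), collapse = " vs "),
              nrow(x$truth)))
  invisible(x)
}

#' Simulate an expression table
#'
#' Assigns each gene an rpkm value: a configurable fraction of genes is
#' expressed (rpkm strictly > 1, log-normal above the threshold) and the
#' rest repressed (rpkm strictly < 1).
#'
#' @param genes Data frame with a `gene_id` column (or a character vector
#'   of gene ids); must be non-empty.
#' @param fraction_expressed Fraction of genes with rpkm > 1.
#' @param seed Integer seed.
#' @return Tibble with `gene_id` and `rpkm`.
#' @export
#' @examples
#' simulate_expression(tibble::tibble(gene_id = paste0("g", 1:4)), 0.5, seed = 1)
simulate_expression <- function(genes, fraction_expressed = 0.4, seed = 1L) {
  ids <- if (is.data.frame(genes)) genes$gene_id else genes
  if (length(ids) == 0) abort("gene list must be non-empty")
  if (fraction_expressed < 0 || fraction_expressed > 1) {
    abort("fraction_expressed must lie in [0, 1]")
  }
  withr::with_seed(as.integer(seed), {
    expressed <- runif(length(ids)) < fraction_expressed
    rpkm <- numeric(length(ids))
    rpkm[expressed] <- 1 + rlnorm(sum(expressed), meanlog = 1, sdlog = 1)
    rpkm[!expressed] <- runif(sum(!expressed), 0, 0.999)
    tibble(gene_id = ids, rpkm = rpkm)
  })
}

#' Simulate gene models anchored on the manifest
#'
#' Places genes on the simulated genome, one transcript each by default,
#' with TSSs drawn near probe positions so promoter intervals (TSS +/- 1 kb)
#' have a realistic chance of containing probes and overlapping called DMRs.
#'
#' @param manifest Probe manifest.
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param width_range Gene-body length range in bp.
#' @return Tibble with `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `tss`, `start`, `end` (gene body, 1-based inclusive).
#' @export
simulate_gene_models <- function(manifest, n_genes = 100, seed = 1L,
                                 width_range = c(2000, 20000)) {
  if (nrow(manifest) == 0) abort("manifest must be non-empty")
  withr::with_seed(as.integer(seed), {
    anchor <- sample.int(nrow(manifest), n_genes, replace = TRUE)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    tss <- manifest$pos[anchor] + sample(-500:500, n_genes, replace = TRUE)
    tss <- pmax(tss, 1L)
    width <- round(runif(n_genes, width_range[1], width_range[2]))
    start <- ifelse(strand == "+", tss, pmax(1, tss - width))
    end <- ifelse(strand == "+", tss + width, tss)
    tibble(gene_id = sprintf("gene%04d", seq_len(n_genes)),
           transcript_id = sprintf("tx%04d", seq_len(n_genes)),
           chrom = manifest$chrom[anchor], strand = strand,
           tss = as.integer(tss), start = as.integer(start),
           end = as.integer(end))
  })
}
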