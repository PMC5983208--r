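#' Per-probe two-group summary statistics
#'
#' Computes, for each probe, the group-mean beta difference
#' (case minus control), the pooled within-group variance, the residual
#' degrees of freedom, and the per-group counts of usable (non-missing)
#' values. Probes with fewer than two usable values in either group are
#' untestable: they are returned with `NA` statistics and flagged, and
#' downstream steps exclude them.
#'
#' @param beta Beta tibble (`probe_id` + sample columns), typically the
#'   output of [filter_probes()].
#' @param samples Sample sheet with `sample_id` and `group`.
#' @param contrast Length-2 character: case group then control group;
#'   `delta_beta = mean(case) - mean(control)`.
#' @return Tibble with `probe_id`, `delta_beta`, `s2`, `df`, `n_a`, `n_b`,
#'   `testable`.
#' @export
fit_group_model <- function(beta, samples, contrast = c("CML", "HD")) {
  stopifnot(length(contrast) == 2)
  b <- as_value_matrix(beta)
  grp <- samples$group[match(colnames(b), samples$sample_id)]
  if (anyNA(grp)) abort("every beta column must appear in the sample sheet")
  a_cols <- which(grp == contrast[1])
  b_cols <- which(grp == contrast[2])
  if (length(a_cols) == 0 || length(b_cols) == 0) {
    abort("both contrast groups must be present in the sample sheet")
  }
  A <- b[, a_cols, drop = FALSE]
  B <- b[, b_cols, drop = FALSE]
  n_a <- rowSums(!is.na(A))
  n_b <- rowSums(!is.na(B))
  mean_a <- rowMeans(A, na.rm = TRUE)
  mean_b <- rowMeans(B, na.rm = TRUE)
  ss_a <- rowSums((A - mean_a)^2, na.rm = TRUE)
  ss_b <- rowSums((B - mean_b)^2, na.rm = TRUE)
  df <- n_a + n_b - 2
  testable <- n_a >= 2 & n_b >= 2
  out <- tibble(
    probe_id = beta$probe_id,
    delta_beta = unname(ifelse(testable, mean_a - mean_b, NA_real_)),
    s2 = unname(ifelse(testable, (ss_a + ss_b) / df, NA_real_)),
    df = unname(ifelse(testable, as.numeric(df), NA_real_)),
    n_a = unname(n_a), n_b = unname(n_b), testable = unname(testable)
  )
  if (any(!testable)) {
    message(sprintf("%d probes untestable (<2 usable values in a group)",
                    sum(!testable)))
  }
  out
}

# Newton inversion of trigamma(y) = x, as needed by the moment matching;
# trigamma is convex decreasing on (0, Inf) so the update converges fast.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    y <- 0.5 + 1 / xi
    for (i in 1:60) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) < 1e-10 * y) break
    }
    y
  }, numeric(1))
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square prior of the moderated t-statistic by
#' matching the first two moments of `log(s2)` to the marginal scaled-F
#' distribution: with residual variances `s2` on `df` degrees of freedom,
#' `e = log(s2) - digamma(df/2) + log(df/2)` has mean
#' `log(s0_sq) - digamma(d0/2) + log(d0/2)` and excess variance
#' `trigamma(d0/2)` beyond the chi-square contribution `trigamma(df/2)`.
#' The prior degrees of freedom `d0` are recovered by trigamma inversion;
#' when the observed variance of `log(s2)` does not exceed the chi-square
#' contribution (e.g., all `s2` equal), `d0 = Inf` and `s0_sq` is the
#' geometric-mean-based variance estimate.
#'
#' @param s2 Vector of residual variances (non-negative).
#' @param df Residual degrees of freedom, scalar or vector.
#' @return List of class `eb_prior` with elements `d0` and `s0_sq`.
#' @export
estimate_eb_prior <- function(s2, df) {
  if (any(s2 < 0, na.rm = TRUE)) abort("s2 must be non-negative")
  ok <- is.finite(s2) & is.finite(df) & df > 0
  s2 <- s2[ok]
  df <- rep_len(df, length(ok))[ok]
  if (length(s2) == 0) abort("no usable variances")
  # zeros have no finite log; nudge them to a tiny positive value
  if (any(s2 == 0)) {
    floor_val <- if (any(s2 > 0)) min(s2[s2 > 0]) * 1e-3 else 1e-12
    s2 <- pmax(s2, floor_val)
  }
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- if (n > 1) sum((e - emean)^2) / (n - 1) else 0
  excess <- evar - mean(trigamma(df / 2))
  if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    # exactly degenerate input (all s2 equal) lies outside the sampling
    # model: report that common value rather than the bias-corrected mean
    s0_sq <- if (evar == 0) exp(mean(z)) else exp(emean)
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "eb_prior")
}

#' @export
print.eb_prior <- function(x, ...) {
  cat(sprintf("<eb_prior> d0 = %s, s0_sq = %.4g\n",
              format(x$d0, digits = 4), x$s0_sq))
  invisible(x)
}

#' @rdname estimate_eb_prior
#' @param x An `eb_prior` object.
#' @param ... Unused.
#' @method tidy eb_prior
#' @export
tidy.eb_prior <- function(x, ...) {
  tibble(term = c("d0", "s0_sq"), estimate = c(x$d0, x$s0_sq))
}

#' Moderated t-statistic and two-sided p-value
#'
#' Shrinks each probe's variance toward the prior,
#' `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)`, and forms
#' `t = delta_beta / sqrt(s2_post * (1/n_a + 1/n_b))`, referred to a
#' t-distribution on `d0 + df` degrees of freedom (normal in the
#' `d0 = Inf` limit). With `d0 = 0` this is exactly the ordinary pooled
#' two-sample t-test. A zero posterior variance cannot yield `p = 0`; such
#' probes get the smallest representable positive p-value with a warning.
#'
#' @param delta_beta,s2,df Per-probe statistics from [fit_group_model()].
#' @param prior An [estimate_eb_prior()] fit (or `list(d0 =, s0_sq =)`).
#' @param n_a,n_b Usable sample counts per group.
#' @return Tibble with `t_mod` and `p`.
#' @export
moderated_t <- function(delta_beta, s2, df, prior, n_a, n_b) {
  d0 <- prior$d0
  s0 <- prior$s0_sq
  if (is.infinite(d0)) {
    s2_post <- rep_len(s0, length(s2))
    df_total <- rep_len(Inf, length(s2))
  } else {
    s2_post <- (d0 * s0 + df * s2) / (d0 + df)
    df_total <- d0 + df
  }
  se <- sqrt(s2_post * (1 / n_a + 1 / n_b))
  t_mod <- delta_beta / se
  t_mod[delta_beta == 0] <- 0
  p <- 2 * pt(-abs(t_mod), df = df_total)
  degenerate <- is.finite(delta_beta) & delta_beta != 0 & se == 0
  if (any(degenerate, na.rm = TRUE)) {
    warn("zero posterior variance at some probes; p set to smallest positive value")
    p[degenerate] <- .Machine$double.xmin
    t_mod[degenerate] <- sign(delta_beta[degenerate]) * Inf
  }
  tibble(t_mod = t_mod, p = p)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: `q_i = min over j with rank >= rank(i) of
#' m * p_(j) / j`, capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]` (`NA` allowed, propagated).
#' @return Vector of q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Apply the dual-threshold differential methylation call
#'
#' A probe is called `hyper` when `fdr < alpha` and
#' `delta_beta > +delta`, `hypo` when `fdr < alpha` and
#' `delta_beta < -delta`, and `none` otherwise. Both inequalities are
#' strict, so a probe at exactly `delta_beta = delta` is not called.
#'
#' @param diff Tibble with `delta_beta` and `fdr` columns.
#' @param alpha FDR cutoff (default 0.05).
#' @param delta Beta-difference cutoff (default 0.15).
#' @return `diff` with a `call` column added (character).
#' @export
call_dm_probes <- function(diff, alpha = 0.05, delta = 0.15) {
  dplyr::mutate(diff, call = dplyr::case_when(
    is.na(.data$fdr) | is.na(.data$delta_beta) ~ "none",
    .data$fdr < alpha & .data$delta_beta > delta ~ "hyper",
    .data$fdr < alpha & .data$delta_beta < -delta ~ "hypo",
    TRUE ~ "none"
  ))
}

#' Full per-probe differential methylation analysis
#'
#' Chains [fit_group_model()], [estimate_eb_prior()] (on testable probes),
#' [moderated_t()], [bh_fdr()] and [call_dm_probes()]. Tests are run on
#' beta-values directly (matching the beta-scale call threshold); pass
#' `use_m_values = TRUE` to moderate on the logit (M-value) scale instead,
#' in which case the reported `delta_beta` and the delta gate remain on
#' the beta scale.
#'
#' @inheritParams fit_group_model
#' @param cell_type If given, samples are first restricted to this
#'   `cell_type` in the sample sheet.
#' @param alpha,delta Call thresholds, see [call_dm_probes()].
#' @param manifest Optional manifest; when given, `chrom` and `pos` are
#'   joined onto the result and rows follow manifest order.
#' @param use_m_values Moderate on M-values (`log2(beta/(1-beta))`)
#'   instead of beta-values (default `FALSE`).
#' @return Tibble of class `dm_table`: `probe_id`, (`chrom`, `pos`,)
#'   `delta_beta`, `s2`, `df`, `t_mod`, `p`, `fdr`, `call`. The fitted
#'   prior and the untestable-probe count are attached as attributes and
#'   surfaced by [glance.dm_table()].
#' @export
diff_methylation <- function(beta, samples, contrast = c("CML", "HD"),
                             cell_type = NULL, alpha = 0.05, delta = 0.15,
                             manifest = NULL, use_m_values = FALSE) {
  if (!is.null(cell_type)) {
    samples <- dplyr::filter(samples, .data$cell_type %in% !!cell_type)
    keep <- c("probe_id", intersect(sample_cols(beta), samples$sample_id))
    beta <- beta[keep]
  }
  fit <- fit_group_model(beta, samples, contrast)
  if (use_m_values) {
    eps <- 1e-6
    m <- beta
    m[sample_cols(m)] <- lapply(m[sample_cols(m)], function(v) {
      v <- pmin(pmax(v, eps), 1 - eps)
      log2(v / (1 - v))
    })
    fit_m <- fit_group_model(m, samples, contrast)
    stat <- fit_m
  } else {
    stat <- fit
  }
  testable <- which(stat$testable)
  if (length(testable) < 2) abort("need at least 2 testable probes")
  prior <- estimate_eb_prior(stat$s2[testable], stat$df[testable])
  mt <- moderated_t(stat$delta_beta[testable], stat$s2[testable],
                    stat$df[testable], prior,
                    stat$n_a[testable], stat$n_b[testable])
  out <- fit
  out$t_mod <- NA_real_
  out$p <- NA_real_
  out$t_mod[testable] <- mt$t_mod
  out$p[testable] <- mt$p
  out$fdr <- NA_real_
  out$fdr[testable] <- bh_fdr(out$p[testable])
  out <- call_dm_probes(out, alpha = alpha, delta = delta)
  if (!is.null(manifest)) {
    out <- dplyr::left_join(out,
                            dplyr::select(manifest, "probe_id", "chrom", "pos"),
                            by = "probe_id")
    out <- out[order(match(out$probe_id, manifest$probe_id)), , drop = FALSE]
    out <- dplyr::relocate(out, "probe_id", "chrom", "pos")
  }
  out <- dplyr::select(out, -"testable")
  class(out) <- c("dm_table", class(out))
  attr(out, "prior") <- prior
  attr(out, "n_untestable") <- sum(!fit$testable)
  attr(out, "thresholds") <- c(alpha = alpha, delta = delta)
  out
}

#' @rdname diff_methylation
#' @param x A `dm_table`.
#' @param ... Unused.
#' @method tidy dm_table
#' @export
tidy.dm_table <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  attr(out, "prior") <- NULL
  attr(out, "n_untestable") <- NULL
  attr(out, "thresholds") <- NULL
  out
}

#' @rdname diff_methylation
#' @method glance dm_table
#' @export
glance.dm_table <- function(x, ...) {
  prior <- attr(x, "prior")
  tibble(
    n_probes = nrow(x),
    n_hyper = sum(x$call == "hyper", na.rm = TRUE),
    n_hypo = sum(x$call == "hypo", na.rm = TRUE),
    n_untestable = attr(x, "n_untestable") %||% NA_integer_,
    d0 = prior$d0, s0_sq = prior$s0_sq
  )
}
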