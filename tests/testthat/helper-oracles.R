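# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (loops, enumeration, closed
# forms), never via the package's own code paths.

# classic pooled two-sample t-test
oracle_pooled_t <- function(x, y) {
  na <- length(x)
  nb <- length(y)
  s2 <- ((na - 1) * var(x) + (nb - 1) * var(y)) / (na + nb - 2)
  tt <- (mean(x) - mean(y)) / sqrt(s2 * (1 / na + 1 / nb))
  c(t = tt, p = 2 * pt(-abs(tt), df = na + nb - 2))
}

# BH step-up by explicit enumeration: q_i = min over ranks >= rank(i)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- m * p[o] / seq_len(m)
  q <- vapply(seq_len(m), function(k) min(1, min(adj[k:m])), numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# masking by naive double loop
oracle_mask <- function(b, p, thr = 0.01) {
  out <- b
  for (i in seq_len(nrow(b))) {
    for (j in seq_len(ncol(b))) {
      if (p[i, j] > thr) out[i, j] <- NA_real_
    }
  }
  out
}

# maximal same-direction runs by exhaustive subsequence enumeration:
# a window is any contiguous index range that is valid (single direction,
# single chromosome, adjacent gaps <= max_gap, no "none" inside) and
# cannot be extended on either side without breaking a rule
oracle_windows <- function(chrom, pos, call, min_probes = 2, max_gap = 1000) {
  n <- length(call)
  res <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < min_probes) next
      idx <- i:j
      dir <- call[i]
      if (dir == "none") next
      if (any(call[idx] != dir)) next
      if (any(chrom[idx] != chrom[i])) next
      if (length(idx) > 1 && any(diff(pos[idx]) > max_gap)) next
      ext_l <- i > 1 && call[i - 1] == dir && chrom[i - 1] == chrom[i] &&
        (pos[i] - pos[i - 1]) <= max_gap
      ext_r <- j < n && call[j + 1] == dir && chrom[j + 1] == chrom[j] &&
        (pos[j + 1] - pos[j]) <= max_gap
      if (ext_l || ext_r) next
      res[[length(res) + 1]] <- idx
    }
  }
  res
}

# 1-based inclusive interval overlap length
overlap_len <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2) + 1)

# quadratic all-pairs scan: does row i of x overlap any row of y
oracle_overlaps_any <- function(x, y, min_overlap = 1) {
  vapply(seq_len(nrow(x)), function(i) {
    if (nrow(y) == 0) return(FALSE)
    any(vapply(seq_len(nrow(y)), function(j) {
      x$chrom[i] == y$chrom[j] &&
        overlap_len(x$start[i], x$end[i], y$start[j], y$end[j]) >= min_overlap
    }, logical(1)))
  }, logical(1))
}

# sliding-window promoter statistics recomputed with substring counting
oracle_promoter_class <- function(seq, window = 500, step = 5) {
  s <- toupper(seq)
  L <- nchar(s)
  starts <- if (L < window) 1 else {
    st <- seq(1, L - window + 1, by = step)
    if (st[length(st)] != L - window + 1) st <- c(st, L - window + 1)
    st
  }
  w <- if (L < window) L else window
  any_hcp <- FALSE
  all_lcp <- TRUE
  for (st in starts) {
    sub <- substr(s, st, st + w - 1)
    chars <- strsplit(sub, "")[[1]]
    n_c <- sum(chars == "C")
    n_g <- sum(chars == "G")
    n_n <- sum(!chars %in% c("A", "C", "G", "T"))
    n_cpg <- sum(chars[-length(chars)] == "C" & chars[-1] == "G")
    eff <- w - n_n
    oe <- if (n_c * n_g > 0) n_cpg * eff / (n_c * n_g) else 0
    gc <- if (eff > 0) (n_c + n_g) / eff else 0
    if (oe >= 0.75 && gc >= 0.55) any_hcp <- TRUE
    if (oe >= 0.48) all_lcp <- FALSE
  }
  if (any_hcp) "HCP" else if (all_lcp) "LCP" else "ICP"
}

# random manifest-like probe layout for toy tests
toy_manifest <- function(pos, chrom = "chr1", cgi = FALSE, snp = FALSE) {
  tibble::tibble(
    probe_id = sprintf("p%03d", seq_along(pos)),
    chrom = rep_len(chrom, length(pos)),
    pos = as.integer(pos),
    cgi_member = rep_len(cgi, length(pos)),
    snp_flag = rep_len(snp, length(pos))
  )
}

# dm_table-like tibble for the window caller
toy_calls <- function(manifest, call, delta = NULL) {
  tibble::tibble(
    probe_id = manifest$probe_id,
    delta_beta = delta %||% ifelse(call == "hyper", 0.3,
                                   ifelse(call == "hypo", -0.3, 0)),
    call = call
  )
}

# random interval tibble
random_intervals <- function(n, max_pos = 10000, max_width = 500,
                             chroms = c("chr1", "chr2")) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_width, n, replace = TRUE) - 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
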