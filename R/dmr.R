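# Core run finder shared by find_windows() and kept lean so exhaustive
# grid comparisons stay cheap. `call` is "hyper"/"hypo"/"none" per probe in
# manifest order; returns a list of integer index vectors (maximal runs of
# same-direction called probes, adjacent gaps <= max_gap, never crossing a
# chromosome or an intervening retained non-called probe).
run_windows_core <- function(chrom, pos, call, min_probes = 2L,
                             max_gap = 1000) {
  n <- length(call)
  runs <- list()
  cur <- integer(0)
  flush <- function() {
    if (length(cur) >= min_probes) runs[[length(runs) + 1L]] <<- cur
    cur <<- integer(0)
  }
  for (i in seq_len(n)) {
    if (call[i] == "none") {
      flush()
      next
    }
    if (length(cur) > 0) {
      j <- cur[length(cur)]
      same <- chrom[i] == chrom[j] && call[i] == call[j] &&
        (pos[i] - pos[j]) <= max_gap
      if (!same) flush()
    }
    cur <- c(cur, i)
  }
  flush()
  runs
}

#' Find windows of consecutive same-direction differentially methylated probes
#'
#' Scans called probes in manifest order and emits every maximal run of at
#' least `min_probes` probes sharing a direction (`hyper` or `hypo`) in
#' which each adjacent pair of member probes lies at most `max_gap` bp
#' apart. "Consecutive" is evaluated on the retained (post-QC) probe order:
#' an intervening retained probe that is not called breaks a run, while
#' probes removed by QC (absent from the table) do not. Runs never cross a
#' chromosome. The gap rule constrains *adjacent* probes, not the total
#' span, so downstream merged regions may exceed `max_gap` in size.
#'
#' @param diff A `dm_table` (or tibble with `probe_id` and `call`)
#'   restricted to retained probes.
#' @param manifest Probe manifest; probes in `diff` must appear in it, and
#'   `diff` must be sorted in manifest order.
#' @param min_probes Minimum run length emitted as a window (default 2).
#' @param max_gap Maximum distance in bp between adjacent member probes
#'   (default 1000).
#' @return Tibble with `window_id`, `chrom`, `start`, `end` (first/last
#'   member-probe coordinates, 1-based inclusive), `direction`,
#'   `n_probes`, `probe_ids` (list-column), `mean_delta_beta` (when
#'   `diff` carries `delta_beta`).
#' @export
find_windows <- function(diff, manifest, min_probes = 2, max_gap = 1000) {
  idx <- match(diff$probe_id, manifest$probe_id)
  if (anyNA(idx)) abort("all probes in `diff` must appear in the manifest")
  if (is.unsorted(idx, strictly = TRUE)) {
    abort("`diff` must be sorted in manifest order")
  }
  chrom <- manifest$chrom[idx]
  pos <- manifest$pos[idx]
  call <- diff$call
  runs <- run_windows_core(chrom, pos, call, min_probes, max_gap)
  if (length(runs) == 0) {
    return(tibble(window_id = character(), chrom = character(),
                  start = integer(), end = integer(), direction = character(),
                  n_probes = integer(), probe_ids = list(),
                  mean_delta_beta = numeric()))
  }
  has_delta <- "delta_beta" %in% names(diff)
  purrr::imap_dfr(runs, function(r, i) {
    tibble(
      window_id = sprintf("win_%04d", i),
      chrom = chrom[r[1]],
      start = pos[r[1]],
      end = pos[r[length(r)]],
      direction = call[r[1]],
      n_probes = length(r),
      probe_ids = list(diff$probe_id[r]),
      mean_delta_beta = if (has_delta) mean(diff$delta_beta[r]) else NA_real_
    )
  })
}

#' Merge windows into differentially methylated regions (DMRs)
#'
#' Same-direction windows that overlap, share probes, or are book-ended
#' (gap between their nearest member probes at most `max_gap`) are merged
#' into one region; hyper and hypo windows never merge even when their
#' coordinates overlap. The merged span may exceed `max_gap`. Each DMR
#' records the union of member probes, the mean member-probe delta-beta,
#' and `max_run`: the longest run of probes that were consecutive within a
#' single window or a chain of probe-sharing windows (windows joined only
#' by a book-end gap had a retained non-called probe or a super-threshold
#' gap between them, so their runs do not concatenate).
#'
#' @param windows Output of [find_windows()] for one contrast/cell type.
#' @param max_gap Book-end merge distance in bp (default 1000).
#' @param diff Optional per-probe table with `probe_id` and `delta_beta`;
#'   when given, each DMR's `mean_delta_beta` is the exact mean over its
#'   distinct member probes. Otherwise it is the probe-count-weighted mean
#'   of the window means (identical for non-overlapping windows).
#' @return Tibble with `dmr_id`, `chrom`, `start`, `end`, `direction`,
#'   `n_probes`, `probe_ids`, `mean_delta_beta`, `max_run`. Same-direction
#'   DMRs are non-overlapping.
#' @export
merge_windows <- function(windows, max_gap = 1000, diff = NULL) {
  empty <- tibble(dmr_id = character(), chrom = character(),
                  start = integer(), end = integer(), direction = character(),
                  n_probes = integer(), probe_ids = list(),
                  mean_delta_beta = numeric(), max_run = integer())
  if (nrow(windows) == 0) return(empty)
  windows <- dplyr::arrange(windows, .data$direction, .data$chrom, .data$start)
  out <- list()
  for (dir in unique(windows$direction)) {
    w <- dplyr::filter(windows, .data$direction == dir)
    for (ch in unique(w$chrom)) {
      wc <- dplyr::filter(w, .data$chrom == ch)
      # cluster: merge while next window starts within max_gap of current end
      cluster_id <- integer(nrow(wc))
      cid <- 1L
      cur_end <- wc$end[1]
      cluster_id[1] <- cid
      for (i in seq_len(nrow(wc))[-1]) {
        if (wc$start[i] - cur_end <= max_gap) {
          cluster_id[i] <- cid
          cur_end <- max(cur_end, wc$end[i])
        } else {
          cid <- cid + 1L
          cluster_id[i] <- cid
          cur_end <- wc$end[i]
        }
      }
      for (cl in unique(cluster_id)) {
        members <- wc[cluster_id == cl, , drop = FALSE]
        probes <- unique(unlist(members$probe_ids))
        out[[length(out) + 1L]] <- tibble(
          chrom = ch,
          start = min(members$start),
          end = max(members$end),
          direction = dir,
          n_probes = length(probes),
          probe_ids = list(probes),
          mean_delta_beta = if (!is.null(diff)) {
            mean(diff$delta_beta[match(probes, diff$probe_id)])
          } else if (all(is.na(members$mean_delta_beta))) {
            NA_real_
          } else {
            sum(members$mean_delta_beta * members$n_probes) /
              sum(members$n_probes)
          },
          max_run = max_run_of(members$probe_ids)
        )
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::arrange(res, .data$chrom, .data$start, .data$direction)
  res$dmr_id <- sprintf("dmr_%04d", seq_len(nrow(res)))
  dplyr::relocate(res, "dmr_id")
}

# longest consecutive probe run across a set of windows: windows sharing at
# least one probe chain into a single run (their probe unions are one
# uninterrupted consecutive stretch); disjoint windows keep separate runs
max_run_of <- function(probe_lists) {
  k <- length(probe_lists)
  if (k == 1) return(length(probe_lists[[1]]))
  comp <- seq_len(k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (length(intersect(probe_lists[[i]], probe_lists[[j]])) > 0) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  max(vapply(unique(comp), function(cc) {
    length(unique(unlist(probe_lists[comp == cc])))
  }, integer(1)))
}

#' Extract hotspot DMRs
#'
#' A hotspot is a DMR containing at least `hotspot_min_run` consecutive
#' differentially methylated probes (a single uninterrupted same-direction
#' run, not merely that many member probes).
#'
#' @param dmrs Output of [merge_windows()].
#' @param hotspot_min_run Minimum run length (default 5).
#' @return Subset of `dmrs` (same columns).
#' @export
find_hotspots <- function(dmrs, hotspot_min_run = 5) {
  dplyr::filter(dmrs, .data$max_run >= hotspot_min_run)
}

#' Intersect two DMR sets
#'
#' A DMR is "common" when it overlaps a same-direction DMR of the other
#' set by at least `min_overlap_bp` bases; otherwise it is specific to its
#' own set. The four outputs partition the two inputs.
#'
#' @param set_a,set_b DMR tibbles on the same genome coordinate system.
#' @param min_overlap_bp Minimum overlap in bp (default 1).
#' @return Named list of tibbles `common_a`, `specific_a`, `common_b`,
#'   `specific_b`.
#' @export
intersect_dmr_sets <- function(set_a, set_b, min_overlap_bp = 1) {
  common_in <- function(x, y) {
    if (nrow(x) == 0) return(logical(0))
    res <- rep(FALSE, nrow(x))
    for (dir in c("hyper", "hypo")) {
      xi <- which(x$direction == dir)
      if (length(xi) == 0) next
      yd <- y[y$direction == dir, , drop = FALSE]
      res[xi] <- overlaps_any(x[xi, , drop = FALSE], yd,
                              min_overlap = min_overlap_bp)
    }
    res
  }
  in_b <- common_in(set_a, set_b)
  in_a <- common_in(set_b, set_a)
  list(common_a = set_a[in_b, , drop = FALSE],
       specific_a = set_a[!in_b, , drop = FALSE],
       common_b = set_b[in_a, , drop = FALSE],
       specific_b = set_b[!in_a, , drop = FALSE])
}

#' Score recovered DMRs against an implanted truth set
#'
#' A truth region counts as recovered when a called DMR of the same
#' direction overlaps it by at least `min_overlap_bp`; a called DMR counts
#' as false when it overlaps no same-direction truth region. Sensitivity
#' is computed over truth regions with at least `min_truth_probes` probes
#' flagged `detectable` (placed with all internal gaps within the window
#' rule), the population a 1 kb-gap caller can possibly recover.
#'
#' @param dmrs Called DMR tibble.
#' @param truth Truth tibble from [simulate_beta_cohort()].
#' @param min_overlap_bp Minimum overlap (default 1).
#' @param min_truth_probes Smallest truth region scored (default 2).
#' @return One-row tibble: `n_truth`, `n_recovered`, `sensitivity`,
#'   `n_called`, `n_false`.
#' @export
evaluate_dmr_recovery <- function(dmrs, truth, min_overlap_bp = 1,
                                  min_truth_probes = 2) {
  scored <- truth[truth$n_probes >= min_truth_probes &
                    (truth$detectable %||% TRUE), , drop = FALSE]
  hit <- function(x, y) {
    if (nrow(x) == 0) return(logical(0))
    res <- rep(FALSE, nrow(x))
    for (dir in c("hyper", "hypo")) {
      xi <- which(x$direction == dir)
      if (length(xi) == 0) next
      res[xi] <- overlaps_any(x[xi, , drop = FALSE],
                              y[y$direction == dir, , drop = FALSE],
                              min_overlap = min_overlap_bp)
    }
    res
  }
  recovered <- hit(scored, dmrs)
  false_call <- if (nrow(dmrs) > 0) !hit(dmrs, truth) else logical(0)
  tibble(
    n_truth = nrow(scored),
    n_recovered = sum(recovered),
    sensitivity = if (nrow(scored) > 0) mean(recovered) else NA_real_,
    n_called = nrow(dmrs),
    n_false = sum(false_call)
  )
}

#' Run the window/merge/hotspot chain in one call
#'
#' Convenience wrapper: [find_windows()] then [merge_windows()] then
#' [find_hotspots()], with shared `max_gap`.
#'
#' @inheritParams find_windows
#' @param hotspot_min_run Passed to [find_hotspots()].
#' @return List with `windows`, `dmrs`, `hotspots`.
#' @export
call_dmrs <- function(diff, manifest, min_probes = 2, max_gap = 1000,
                      hotspot_min_run = 5) {
  windows <- find_windows(diff, manifest, min_probes, max_gap)
  dmrs <- merge_windows(windows, max_gap, diff = diff)
  list(windows = windows, dmrs = dmrs,
       hotspots = find_hotspots(dmrs, hotspot_min_run))
}
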