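test_that("window calling follows the gap, direction and consecutiveness rules", {
  # hyper probes at 100, 400, 900, 2500: the 1600 bp gap excludes the last
  man <- toy_manifest(c(100, 400, 900, 2500))
  d <- toy_calls(man, rep("hyper", 4))
  w <- find_windows(d, man)
  expect_equal(nrow(w), 1)
  expect_equal(w$start, 100)
  expect_equal(w$end, 900)
  expect_equal(w$n_probes, 3)
  expect_equal(w$probe_ids[[1]], c("p001", "p002", "p003"))

  # a single called probe yields no window
  man1 <- toy_manifest(c(100, 400))
  expect_equal(nrow(find_windows(toy_calls(man1, c("hyper", "none")), man1)), 0)

  # alternating directions break every run
  man3 <- toy_manifest(c(100, 300, 500))
  expect_equal(nrow(find_windows(toy_calls(man3, c("hyper", "hypo", "hyper")),
                                 man3)), 0)

  # an intervening retained non-called probe breaks a run
  man4 <- toy_manifest(c(100, 300, 500, 700))
  w4 <- find_windows(toy_calls(man4, c("hyper", "hyper", "none", "hyper")), man4)
  expect_equal(nrow(w4), 1)
  expect_equal(w4$n_probes, 2)

  # runs never cross chromosomes even at small coordinate gaps
  man5 <- toy_manifest(c(100, 200, 100, 200), chrom = c("chr1", "chr1", "chr2", "chr2"))
  w5 <- find_windows(toy_calls(man5, rep("hyper", 4)), man5)
  expect_equal(nrow(w5), 2)
  expect_equal(w5$chrom, c("chr1", "chr2"))

  expect_error(find_windows(toy_calls(man, rep("hyper", 4))[c(2, 1, 3, 4), ], man),
               "sorted")
})

test_that("windows are maximal: random layouts match exhaustive enumeration", {
  withr::with_seed(55, {
    for (rep in 1:40) {
      n <- sample(3:12, 1)
      man <- toy_manifest(cumsum(sample(c(200, 600, 1500), n, replace = TRUE)),
                          chrom = sort(sample(c("chr1", "chr2"), n, replace = TRUE)))
      call <- sample(c("hyper", "hypo", "none"), n, replace = TRUE)
      w <- find_windows(toy_calls(man, call), man)
      expected <- oracle_windows(man$chrom, man$pos, call)
      expect_equal(nrow(w), length(expected))
      if (length(expected) > 0) {
        expect_equal(unname(purrr::map(w$probe_ids, ~ match(.x, man$probe_id))),
                     expected)
      }
    }
  })
})

test_that("window merging unions probes, respects direction, and spans past 1 kb", {
  win <- function(id, start, end, dir, probes, delta = 0.3) {
    tibble::tibble(window_id = id, chrom = "chr1", start = start, end = end,
                   direction = dir, n_probes = length(probes),
                   probe_ids = list(probes), mean_delta_beta = delta)
  }
  # two hyper windows sharing a probe collapse to one DMR with the probe union
  shared <- dplyr::bind_rows(
    win("w1", 100, 600, "hyper", c("p001", "p002", "p003")),
    win("w2", 400, 900, "hyper", c("p003", "p004"))
  )
  m <- merge_windows(shared)
  expect_equal(nrow(m), 1)
  expect_equal(sort(m$probe_ids[[1]]), paste0("p00", 1:4))
  expect_equal(m$n_probes, 4)
  expect_equal(m$max_run, 4)  # chained through the shared probe

  # overlapping hyper and hypo windows are never merged
  opposed <- dplyr::bind_rows(
    win("w1", 100, 600, "hyper", c("p001", "p002")),
    win("w2", 300, 800, "hypo", c("p005", "p006"))
  )
  expect_equal(nrow(merge_windows(opposed)), 2)

  # a chain of three windows pairwise within 1 kb forms one DMR of 2.3 kb
  chain <- dplyr::bind_rows(
    win("w1", 1000, 1700, "hyper", c("p001", "p002")),
    win("w2", 2100, 2500, "hyper", c("p003", "p004")),
    win("w3", 3000, 3300, "hyper", c("p005", "p006"))
  )
  m <- merge_windows(chain)
  expect_equal(nrow(m), 1)
  expect_equal(m$end - m$start + 1, 2301)
  expect_equal(m$n_probes, 6)
  expect_equal(m$max_run, 2)  # book-ended windows do not concatenate runs

  # windows farther apart than max_gap stay separate
  far <- dplyr::bind_rows(
    win("w1", 1000, 1500, "hyper", c("p001", "p002")),
    win("w2", 2600, 3000, "hyper", c("p003", "p004"))
  )
  expect_equal(nrow(merge_windows(far)), 2)

  expect_equal(nrow(merge_windows(merge_windows(far)[0, ])), 0)
})

test_that("same-direction DMRs are non-overlapping and probes are called probes", {
  withr::with_seed(91, {
    n <- 60
    man <- toy_manifest(cumsum(sample(c(150, 400, 1200), n, replace = TRUE)))
    call <- sample(c("hyper", "hypo", "none"), n, replace = TRUE,
                   prob = c(0.4, 0.3, 0.3))
  })
  d <- toy_calls(man, call)
  res <- call_dmrs(d, man)
  dmrs <- res$dmrs
  for (dir in c("hyper", "hypo")) {
    dd <- dmrs[dmrs$direction == dir, ]
    if (nrow(dd) > 1) {
      dd <- dd[order(dd$start), ]
      expect_true(all(dd$start[-1] > dd$end[-nrow(dd)]))
    }
  }
  member <- unlist(dmrs$probe_ids)
  expect_true(all(d$call[match(member, d$probe_id)] != "none"))
  expect_gte(sum(res$windows$n_probes), length(unique(member)))
  # every hotspot is a DMR
  expect_true(all(res$hotspots$dmr_id %in% dmrs$dmr_id))
})

test_that("hotspots require a single uninterrupted run of called probes", {
  # 6-probe run qualifies
  man <- toy_manifest(seq(100, by = 300, length.out = 6))
  res <- call_dmrs(toy_calls(man, rep("hyper", 6)), man)
  expect_equal(nrow(find_hotspots(res$dmrs)), 1)

  # runs of 4 and 3 split by a retained non-called probe merge into one DMR
  # (book-end gap under 1 kb) but max_run stays 4: not a hotspot
  man2 <- toy_manifest(seq(100, by = 200, length.out = 8))
  call2 <- c(rep("hyper", 4), "none", rep("hyper", 3))
  res2 <- call_dmrs(toy_calls(man2, call2), man2)
  expect_equal(nrow(res2$dmrs), 1)
  expect_equal(res2$dmrs$max_run, 4)
  expect_equal(nrow(find_hotspots(res2$dmrs)), 0)
  expect_equal(nrow(find_hotspots(res2$dmrs, hotspot_min_run = 4)), 1)

  expect_equal(nrow(find_hotspots(res2$dmrs[0, ])), 0)
})

test_that("DMR set intersection partitions both sets and matches a quadratic scan", {
  reg <- function(start, end, dir, chrom = "chr1") {
    tibble::tibble(dmr_id = sprintf("d%04d", start), chrom = chrom,
                   start = start, end = end, direction = dir)
  }
  a <- dplyr::bind_rows(reg(100, 300, "hyper"), reg(1000, 1200, "hypo"))
  same <- intersect_dmr_sets(a, a)
  expect_equal(nrow(same$common_a), 2)
  expect_equal(nrow(same$specific_a), 0)

  b <- dplyr::bind_rows(reg(5000, 5100, "hyper"))
  disj <- intersect_dmr_sets(a, b)
  expect_equal(nrow(disj$common_a), 0)
  expect_equal(nrow(disj$specific_b), 1)

  # direction must match for commonality
  c2 <- dplyr::bind_rows(reg(100, 300, "hypo"))
  opp <- intersect_dmr_sets(a, c2)
  expect_equal(nrow(opp$common_a), 0)

  withr::with_seed(77, {
    for (rep in 1:10) {
      xa <- random_intervals(10)
      xa$direction <- sample(c("hyper", "hypo"), 10, replace = TRUE)
      xa$dmr_id <- sprintf("a%02d", 1:10)
      xb <- random_intervals(10)
      xb$direction <- sample(c("hyper", "hypo"), 10, replace = TRUE)
      xb$dmr_id <- sprintf("b%02d", 1:10)
      res <- intersect_dmr_sets(xa, xb)
      for (dir in c("hyper", "hypo")) {
        ya <- xa[xa$direction == dir, ]
        yb <- xb[xb$direction == dir, ]
        expect_equal(sort(res$common_a$dmr_id[res$common_a$direction == dir]),
                     sort(ya$dmr_id[oracle_overlaps_any(ya, yb)]))
        expect_equal(sort(res$specific_b$dmr_id[res$specific_b$direction == dir]),
                     sort(yb$dmr_id[!oracle_overlaps_any(yb, ya)]))
      }
      # partition property
      expect_equal(sort(c(res$common_a$dmr_id, res$specific_a$dmr_id)),
                   sort(xa$dmr_id))
    }
  })
})

test_that("implanted regions are recovered and super-kb gaps are never bridged", {
  spec <- dplyr::bind_rows(
    dmr_target("hyper", 5, 0.3),
    dmr_target("hypo", 3, 0.3),
    dmr_target("hyper", 4, 0.3, max_gap = 6000, undetectable = TRUE)
  )
  cfg <- sim_config(n_probes = 3000, noise_sd = 0.02, dmr_spec = spec,
                    median_gap = 600, gap_dispersion = 1.0, seed = 77)
  man <- simulate_manifest(cfg)
  co <- simulate_beta_cohort(man, cfg)
  b <- filter_probes(mask_failed_values(co$beta, co$detp), man)
  dm <- diff_methylation(b, co$samples, manifest = man)
  res <- call_dmrs(dm, man)
  score <- evaluate_dmr_recovery(res$dmrs, co$truth)
  expect_equal(score$sensitivity, 1)
  expect_equal(score$n_false, 0)

  # no emitted window may span the deliberate >1 kb internal gap
  truth_gap <- co$truth[!co$truth$detectable, ]
  idx <- match(truth_gap$probe_ids[[1]], man$probe_id)
  gap_after <- man$pos[idx][which(diff(man$pos[idx]) > 1000)]
  for (g in gap_after) {
    spanning <- res$windows$start <= g & res$windows$end > g &
      res$windows$chrom == truth_gap$chrom[1]
    expect_false(any(spanning))
  }
})
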