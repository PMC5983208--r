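toy_dmr <- function(id, start, end, dir, chrom = "chr1") {
  tibble::tibble(dmr_id = id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), direction = dir)
}

toy_gene <- function(gene, tx, tss, chrom = "chr1") {
  tibble::tibble(gene_id = gene, transcript_id = tx, chrom = chrom,
                 strand = "+", tss = as.integer(tss),
                 start = as.integer(tss), end = as.integer(tss + 5000))
}

test_that("candidate classification matches hand enumeration on a toy locus", {
  dmrs <- dplyr::bind_rows(
    toy_dmr("hyperA", 10000, 10400, "hyper"),
    toy_dmr("hypoB", 30000, 30400, "hypo"),
    toy_dmr("hyperC", 50000, 50400, "hyper")
  )
  genes <- dplyr::bind_rows(
    toy_gene("g1", "t1", 10200),  # hyper promoter, expressed -> repressed
    toy_gene("g2", "t2", 30200),  # hypo promoter, repressed -> expressed
    toy_gene("g3", "t3", 30300),  # hypo promoter, expressed -> no class
    toy_gene("g4", "t4", 50200),  # hyper promoter, rpkm exactly 1 -> none
    toy_gene("g5", "t5", 90000),  # no DMR overlap
    toy_gene("g6", "t6", 10500),  # second promoter of g1's locus? distinct gene,
                                  # hyper overlap via flank, expressed
    toy_gene("g7", "t7", 10300)   # hyper overlap but missing expression
  )
  expr <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    rpkm = c(5, 0.5, 5, 1, 8, 2)
  )
  expect_message(
    out <- classify_candidates(dmrs, genes, expr),
    "lack expression"
  )
  expect_equal(attr(out, "n_missing_expression"), 1)
  expect_equal(out$class[out$gene_id == "g1"], "candidate_repressed")
  expect_equal(out$class[out$gene_id == "g2"], "candidate_expressed")
  expect_equal(out$gene_id, c("g1", "g2", "g6"))
  expect_equal(out$dmr_ids[[which(out$gene_id == "g1")]], "hyperA")

  # candidate classes are mutually exclusive by construction
  expect_equal(anyDuplicated(out$gene_id), 0)
})

test_that("a gene with several qualifying promoters is reported once", {
  dmrs <- toy_dmr("h1", 10000, 12000, "hyper")
  genes <- dplyr::bind_rows(
    toy_gene("g1", "t1a", 10100),
    toy_gene("g1", "t1b", 11500)
  )
  expr <- tibble::tibble(gene_id = "g1", rpkm = 4)
  out <- classify_candidates(dmrs, genes, expr)
  expect_equal(nrow(out), 1)
  expect_setequal(out$promoters[[1]], c("t1a", "t1b"))
})

test_that("cell-type-specific candidates require all supporting promoters private", {
  dmrs_imm <- dplyr::bind_rows(
    toy_dmr("i1", 10000, 10400, "hyper"),
    toy_dmr("i2", 30000, 30400, "hyper"),
    toy_dmr("i3", 50000, 50400, "hyper")
  )
  genes <- dplyr::bind_rows(
    toy_gene("shared", "ts", 10200),   # same promoter also hyper in mature
    toy_gene("private", "tp", 30200),  # DMR private to immature cells
    toy_gene("flipped", "tf", 50200)   # mature set has only a hypo DMR here
  )
  expr <- tibble::tibble(gene_id = c("shared", "private", "flipped"),
                         rpkm = c(5, 5, 5))
  cand <- classify_candidates(dmrs_imm, genes, expr)
  expect_setequal(cand$gene_id, c("shared", "private", "flipped"))

  dmrs_mat <- dplyr::bind_rows(
    toy_dmr("m1", 10000, 10400, "hyper"),
    toy_dmr("m2", 50000, 50400, "hypo")
  )
  spec <- cell_type_specific_candidates(cand, dmrs_mat, genes)
  # "shared" drops (same-direction overlap in the other set); "flipped"
  # survives because the overlapping mature DMR has the opposite direction
  expect_setequal(spec$gene_id, c("private", "flipped"))
  expect_true(all(spec$cell_type_specific))
  expect_true(all(spec$gene_id %in% cand$gene_id))

  none <- cell_type_specific_candidates(cand[0, ], dmrs_mat, genes)
  expect_equal(nrow(none), 0)
})

test_that("wgbs concordance filters on coverage and returns squared correlation", {
  arr <- tibble::tibble(chrom = "chr1", pos = 1:100,
                        beta = seq(0, 1, length.out = 100))
  wgbs <- tibble::tibble(chrom = "chr1", pos = 1:100,
                         meth = seq(0, 1, length.out = 100),
                         coverage = 10L)
  out <- wgbs_concordance(arr, wgbs)
  expect_equal(out$n_sites, 100)
  expect_equal(out$r_squared, 1)

  low <- dplyr::mutate(wgbs, coverage = 4L)
  expect_error(wgbs_concordance(arr, low), "fewer than 3")

  # affine rescaling of either vector leaves R^2 unchanged; swap is symmetric
  withr::with_seed(8, {
    z <- rnorm(100)
    x <- plogis(z)
    y <- plogis(0.9 * z + sqrt(1 - 0.81) * rnorm(100))
  })
  a2 <- tibble::tibble(chrom = "chr1", pos = 1:100, beta = x)
  w2 <- tibble::tibble(chrom = "chr1", pos = 1:100, meth = y, coverage = 10L)
  r1 <- wgbs_concordance(a2, w2)$r_squared
  r2 <- wgbs_concordance(
    tibble::tibble(chrom = "chr1", pos = 1:100, beta = y),
    tibble::tibble(chrom = "chr1", pos = 1:100, meth = x, coverage = 10L)
  )$r_squared
  expect_equal(r1, r2)
  r3 <- wgbs_concordance(dplyr::mutate(a2, beta = 3 * beta - 1), w2)$r_squared
  expect_equal(r1, r3)

  # known latent correlation rho = 0.9 gives R^2 near 0.81
  withr::with_seed(15, {
    z <- rnorm(400)
    sim_arr <- tibble::tibble(chrom = "chr1", pos = 1:400, beta = z)
    sim_wgbs <- tibble::tibble(chrom = "chr1", pos = 1:400,
                               meth = 0.9 * z + sqrt(1 - 0.81) * rnorm(400),
                               coverage = 10L)
  })
  expect_equal(wgbs_concordance(sim_arr, sim_wgbs)$r_squared, 0.81,
               tolerance = 0.12)
})

test_that("relative expression follows the efficiency-corrected ratio", {
  hk3 <- tibble::tibble(e = c(2, 2, 2), ct = c(20, 20, 20))
  expect_equal(relative_expression(2, 20, hk3), 1)
  hk2 <- tibble::tibble(e = c(2, 2), ct = c(20, 20))
  expect_equal(relative_expression(2, 19, hk2), 2)
  # single housekeeping gene with equal Ct: unity for any efficiency
  expect_equal(relative_expression(1.9, 25, tibble::tibble(e = 1.9, ct = 25)), 1)
  # geometric mean across an unequal panel
  hk <- tibble::tibble(e = c(2, 2), ct = c(18, 22))
  expect_equal(relative_expression(2, 20, hk),
               2^-20 / sqrt(2^-18 * 2^-22))
  expect_error(relative_expression(-1, 20, hk2), "positive")
  expect_warning(relative_expression(2.5, 20, hk2), "range")
})

test_that("noiseless end-to-end run recovers every planted candidate gene", {
  spec <- dplyr::bind_rows(
    dmr_target("hyper", 4, 0.3),
    dmr_target("hypo", 4, 0.3)
  )
  cfg <- sim_config(n_probes = 1500, noise_sd = 0.02, dmr_spec = spec,
                    detection_fail_rate = 0, seed = 19)
  man <- simulate_manifest(cfg)
  co <- simulate_beta_cohort(man, cfg)
  dm <- diff_methylation(co$beta, co$samples, manifest = man)
  dmrs <- call_dmrs(dm, man)$dmrs

  truth <- co$truth
  # one gene with its TSS at each truth region, plus unaffected bystanders
  genes <- dplyr::bind_rows(
    toy_gene("gHyper", "tH", truth$start[truth$direction == "hyper"][1],
             chrom = truth$chrom[truth$direction == "hyper"][1]),
    toy_gene("gHypo", "tL", truth$start[truth$direction == "hypo"][1],
             chrom = truth$chrom[truth$direction == "hypo"][1]),
    toy_gene("gFar", "tF", 10L, chrom = "chr1")
  )
  expr <- tibble::tibble(gene_id = c("gHyper", "gHypo", "gFar"),
                         rpkm = c(6, 0.2, 6))
  out <- classify_candidates(dmrs, genes, expr)
  expect_setequal(out$gene_id, c("gHyper", "gHypo"))
  expect_equal(out$class[out$gene_id == "gHyper"], "candidate_repressed")
  expect_equal(out$class[out$gene_id == "gHypo"], "candidate_expressed")
})
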