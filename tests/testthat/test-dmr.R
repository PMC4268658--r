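# DMR calling: exact test, BH correction, selection/retention filters,
# matched control sampling and persistence.

test_that("two-sided Fisher p matches hypergeometric enumeration", {
  expect_equal(fisher_two_sided(5, 5, 5, 5), 1)
  # fully discordant table: only the two extreme tables are as improbable
  p_expected <- 2 * choose(10, 0) * choose(10, 10) / choose(20, 10)
  expect_equal(fisher_two_sided(0, 10, 10, 0), p_expected, tolerance = 1e-12)
  expect_equal(fisher_two_sided(2, 38, 36, 4), oracle_fisher(2, 38, 36, 4),
               tolerance = 1e-12)
  # random tables against the enumeration oracle and stats::fisher.test
  withr::local_seed(21)
  for (i in 1:50) {
    tb <- sample(0:30, 4, replace = TRUE)
    ours <- suppressMessages(fisher_two_sided(tb[1], tb[2], tb[3], tb[4]))
    expect_equal(ours, oracle_fisher(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    if (all(rowSums(matrix(tb, 2, byrow = TRUE)) > 0) &&
        all(colSums(matrix(tb, 2, byrow = TRUE)) > 0)) {
      expect_equal(ours,
                   stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                   tolerance = 1e-9)
    }
  }
})

test_that("Fisher handles zero margins and rejects negatives", {
  expect_message(p <- fisher_two_sided(0, 0, 3, 4), "zero margin")
  expect_equal(p, 1)
  expect_equal(suppressMessages(fisher_two_sided(0, 5, 0, 7)), 1)
  expect_error(fisher_two_sided(-1, 2, 3, 4), "negative")
})

test_that("bh_adjust equals the naive step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               naive_bh(c(0.01, 0.02, 0.03, 0.04)))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  withr::local_seed(13)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, naive_bh(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))                 # q >= raw p
    expect_true(all(diff(q[order(p)]) >= -1e-15))    # monotone in p order
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

make_bin_pair <- function(mc_case, uc_case, mc_ctrl, uc_ctrl,
                          n_cg = 5L) {
  bins <- tile_bins(c(chr1 = 500 * length(mc_case)))
  case <- bins
  case$n_sites <- n_cg
  case$n_sites_min_cov <- n_cg
  case$mc <- mc_case
  case$uc <- uc_case
  case$level <- ifelse(mc_case + uc_case > 0,
                       mc_case / (mc_case + uc_case), NA_real_)
  case$empty <- case$n_sites == 0
  ctrl <- case
  ctrl$mc <- mc_ctrl
  ctrl$uc <- uc_ctrl
  ctrl$level <- ifelse(mc_ctrl + uc_ctrl > 0,
                       mc_ctrl / (mc_ctrl + uc_ctrl), NA_real_)
  list(case = case, control = ctrl)
}

test_that("call_dmrs applies delta, FDR and retention filters", {
  # identical counts: nothing called
  b <- make_bin_pair(c(40L, 10L), c(10L, 40L), c(40L, 10L), c(10L, 40L))
  expect_equal(nrow(call_dmrs(b$case, b$control)), 0)
  # the worked single-bin example: case (2,38) vs control (36,4)
  b <- make_bin_pair(2L, 38L, 36L, 4L)
  d <- call_dmrs(b$case, b$control)
  expect_equal(nrow(d), 1)
  expect_equal(d$delta, 2 / 40 - 36 / 40)
  expect_equal(d$p, oracle_fisher(2, 38, 36, 4), tolerance = 1e-12)
  expect_equal(d$direction, "hypo")
  # retention: same counts but too few qualifying CGs in one genotype
  b2 <- make_bin_pair(2L, 38L, 36L, 4L, n_cg = 3L)
  expect_equal(nrow(call_dmrs(b2$case, b2$control)), 0)
  expect_equal(nrow(call_dmrs(b2$case, b2$control,
                              dmr_params(min_cg = 3))), 1)
  # a large but sub-threshold difference is not called
  b3 <- make_bin_pair(30L, 70L, 70L, 30L)  # |delta| = 0.4 < 0.5
  expect_equal(nrow(call_dmrs(b3$case, b3$control)), 0)
  expect_error(call_dmrs(b$case, b$control[c(1, 1), ]), "tilings")
})

test_that("swapping case and control flips direction, preserves p and q", {
  withr::local_seed(31)
  g <- sim_genome(3, n_chroms = 1, chrom_length = 30000, repeat_density = 0,
                  n_genes = 0)
  bins <- tile_bins(g$chrom_sizes)
  m <- sim_methylome(g$genome, 17, planted_hypo = bins[c(3, 40), ],
                     mean_coverage = 15)
  cb <- aggregate_bins(m$case, bins)
  tb <- aggregate_bins(m$control, bins)
  d1 <- call_dmrs(cb, tb)
  d2 <- call_dmrs(tb, cb)
  expect_equal(nrow(d1), nrow(d2))
  expect_gt(nrow(d1), 0)
  expect_equal(d1$p, d2$p)
  expect_equal(d1$q, d2$q)
  expect_equal(d1$delta, -d2$delta)
  expect_true(all(d1$direction != d2$direction))
})

test_that("prefiltering the universe changes BH m but not the statistics", {
  b <- make_bin_pair(c(2L, 5L, 40L), c(38L, 3L, 10L),
                     c(36L, 5L, 40L), c(4L, 3L, 10L),
                     n_cg = c(5L, 2L, 5L))
  d_post <- call_dmrs(b$case, b$control)
  d_pre <- call_dmrs(b$case, b$control, prefilter_universe = TRUE)
  expect_equal(attr(d_post, "n_tested"), 3L)
  expect_equal(attr(d_pre, "n_tested"), 2L)
  expect_equal(d_post$p, d_pre$p)   # same bin survives, same raw p
  expect_gte(d_post$q, d_pre$q)     # larger universe, larger q
})

test_that("control sampling matches chromosome, CG count and level exactly", {
  # pool where every non-DMR bin matches the DMRs' coverage and level
  bins <- tile_bins(c(chr1 = 5000, chr2 = 5000))
  ctrl <- bins
  ctrl$n_sites <- 6L
  ctrl$n_sites_min_cov <- 6L
  ctrl$mc <- 80L
  ctrl$uc <- 20L
  ctrl$level <- 0.8
  ctrl$empty <- FALSE
  dmrs <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(0L, 500L, 0L), end = c(500L, 1000L, 500L),
    bin_id = c("chr1:0-500", "chr1:500-1000", "chr2:0-500"),
    level_control = 0.8, direction = "hypo",
    n_cg_control = 6L
  )
  picks <- sample_control_regions(dmrs, ctrl, seed = 5)
  expect_equal(nrow(picks), 3)
  expect_equal(table(picks$chrom), table(dmrs$chrom))
  expect_true(all(picks$n_cg_sites_min_cov == dmrs$n_cg_control))
  expect_true(all(abs(picks$level_control - dmrs$level_control) < 0.05))
  expect_false(any(picks$bin_id %in% dmrs$bin_id))    # never a DMR bin
  expect_false(any(duplicated(picks$bin_id)))         # one use per bin
  # deterministic under the seed
  expect_equal(picks, sample_control_regions(dmrs, ctrl, seed = 5))
  expect_false(identical(picks$bin_id,
                         sample_control_regions(dmrs, ctrl, seed = 6)$bin_id))
  # impossible matching fails loudly
  bad <- dplyr::mutate(dmrs, n_cg_control = 99L)
  expect_error(suppressWarnings(sample_control_regions(bad, ctrl, seed = 1)),
               "unmatched")
})

test_that("DMR persistence pairs overlapping same-direction bins", {
  a <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L),
                      end = c(500L, 1500L), direction = c("hypo", "hyper"))
  same <- dmr_persistence(a, a)
  expect_equal(nrow(same$shared), 2)
  expect_equal(nrow(same$only_a), 0)
  disjoint <- dmr_persistence(a, dplyr::mutate(a, start = start + 5000L,
                                               end = end + 5000L))
  expect_equal(nrow(disjoint$shared), 0)
  expect_equal(nrow(disjoint$only_a), 2)
  shifted <- dmr_persistence(a, dplyr::mutate(a, start = start + 250L,
                                              end = end + 250L))
  expect_equal(nrow(shifted$shared), 2)   # 250 bp overlap is enough
  # same interval, opposite direction: not shared
  flipped <- dmr_persistence(a, dplyr::mutate(
    a, direction = c("hyper", "hypo")))
  expect_equal(nrow(flipped$shared), 0)
})
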