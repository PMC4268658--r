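# The synthetic-data generators: determinism, ground-truth fidelity, and
# the statistical properties downstream stages rely on.

test_that("sim_genome is deterministic and hits the requested density", {
  g1 <- sim_genome(1, n_chroms = 1, chrom_length = 20000, repeat_density = 0.2)
  g2 <- sim_genome(1, n_chroms = 1, chrom_length = 20000, repeat_density = 0.2)
  expect_identical(g1, g2)
  g3 <- sim_genome(2, n_chroms = 1, chrom_length = 20000, repeat_density = 0.2)
  expect_false(identical(g1$genome, g3$genome))

  g0 <- sim_genome(1, n_chroms = 1, chrom_length = 20000, repeat_density = 0)
  expect_equal(nrow(g0$repeats), 0)

  big <- sim_genome(5, n_chroms = 1, chrom_length = 1e6, repeat_density = 0.25)
  covered <- sum(big$repeats$end - big$repeats$start) / 1e6
  expect_lt(abs(covered - 0.25), 0.05)
  # copies never overlap and genes stay repeat-free
  r <- dplyr::arrange(big$repeats, chrom, start)
  same_chrom <- r$chrom[-1] == r$chrom[-nrow(r)]
  expect_true(all(r$start[-1][same_chrom] >= r$end[-nrow(r)][same_chrom]))
  expect_false(any(brute_overlap_any(big$transcripts, big$repeats)))
})

test_that("repeat copies diverge from consensus at about the mutation rate", {
  g <- sim_genome(4, n_chroms = 1, chrom_length = 50000, repeat_density = 0.2,
                  mutation_rate = 0.02)
  fwd <- g$repeats[g$repeats$strand == "+", ]
  skip_if(nrow(fwd) == 0)
  r <- fwd[1, ]
  copy <- substring(g$genome[[r$chrom]], r$start + 1, r$end)
  cons <- g$consensus[[r$repeat_family]]
  mism <- mean(strsplit(copy, "")[[1]] != strsplit(cons, "")[[1]])
  expect_gt(mism, 0)
  expect_lt(mism, 0.06)
})

test_that("sim_methylome plants the requested signal and respects coverage", {
  g <- sim_genome(3, n_chroms = 1, chrom_length = 50000, repeat_density = 0)
  bins <- tile_bins(g$chrom_sizes)
  planted <- bins[c(10, 50), ]
  m <- sim_methylome(g$genome, 11, planted_hypo = planted, mean_coverage = 20,
                     baseline_mCG = 0.85, delta = 0.7)
  agg <- aggregate_bins(m$case, bins)
  inside <- agg[agg$bin_id %in% planted$bin_id, ]
  pooled <- sum(inside$mc) / (sum(inside$mc) + sum(inside$uc))
  n_tot <- sum(inside$mc) + sum(inside$uc)
  se <- sqrt(0.15 * 0.85 / n_tot)
  expect_lt(abs(pooled - 0.15), 3 * se)   # case level = baseline - delta
  outside <- agg[!agg$bin_id %in% planted$bin_id, ]
  pooled_out <- sum(outside$mc) / (sum(outside$mc) + sum(outside$uc))
  expect_lt(abs(pooled_out - 0.85), 0.02)
  # control genotype is untouched inside hypo bins
  agg_c <- aggregate_bins(m$control, bins)
  inc <- agg_c[agg_c$bin_id %in% planted$bin_id, ]
  expect_lt(abs(sum(inc$mc) / (sum(inc$mc) + sum(inc$uc)) - 0.85), 0.05)

  expect_equal(nrow(sim_methylome(g$genome, 1, mean_coverage = 0)$case), 0)
  expect_error(sim_methylome(g$genome, 1, delta = 0.9, baseline_mCG = 0.8,
                             floor_at_zero = FALSE), "flooring disabled")
  # observed coverage is Poisson-like: mean of retained sites near target
  cov <- m$case$count_methylated + m$case$count_unmethylated
  expect_lt(abs(mean(cov) - 20), 0.5)
})

test_that("sim_rna reports true placement counts as n_hits", {
  g <- sim_genome(6, n_chroms = 1, chrom_length = 60000, repeat_density = 0.15)
  counts <- table(g$repeats$repeat_family)
  # all reads from a single-copy family map uniquely
  single <- names(counts)[counts == 1][1]
  skip_if(is.na(single))
  lv <- setNames(20000, single)
  rna <- sim_rna(g, lv, 2, n_reads = 500, multimap_fraction = 0)
  fam_hits <- rna$alignments[!grepl("^bg", rna$alignments$read_id), ]
  expect_true(all(rna$alignments$n_hits == 1))
  # full multimapping: n_hits equals the family copy number
  multi_fam <- names(counts)[which.max(counts)]
  lv2 <- setNames(20000, multi_fam)
  rna2 <- sim_rna(g, lv2, 2, n_reads = 500, multimap_fraction = 1)
  placed <- rna2$alignments[rna2$alignments$n_hits > 1, ]
  skip_if(nrow(placed) == 0)
  expect_true(all(placed$n_hits == counts[[multi_fam]]))
  tab <- table(placed$read_id)
  expect_true(all(tab == counts[[multi_fam]]))
})

test_that("sim_rna expression ranking follows 10x-separated truth", {
  g <- sim_genome(6, n_chroms = 2, chrom_length = 60000, repeat_density = 0.15)
  truth <- c(L1Md = 20000, L1Alt = 2000, ERVK10 = 200)
  rna <- sim_rna(g, truth, 9, n_reads = 20000)
  hits <- suppressMessages(fractional_weights(rna$alignments))
  fe <- family_expression(hits, g$repeats, total_mapped_reads = 20000)
  est <- setNames(fe$expression, fe$repeat_family)[names(truth)]
  expect_equal(order(est), order(truth))
})

test_that("sim_smallrna honours its planted fractions", {
  feats <- tibble::tibble(chrom = "chr1", start = c(0L, 5000L),
                          end = c(2000L, 8000L), strand = c("+", "-"),
                          category = "transposon")
  all_long <- sim_smallrna(pirna_params(frac_long = 1), feats, 3,
                           n_reads = 300)
  expect_true(all(nchar(all_long$reads$seq) >= 25))
  pure <- sim_smallrna(pirna_params(u1 = 1, a10 = 0), feats, 3, n_reads = 300)
  expect_true(all(substr(pure$reads$seq, 1, 1) == "T"))
  cls <- ping_pong_class(pure$reads$seq,
                         classify_size(nchar(pure$reads$seq)))
  expect_true(all(cls[!is.na(cls)] == "primary"))

  sm <- sim_smallrna(pirna_params(), feats, 7, n_reads = 10000)
  u1_hat <- mean(substr(sm$reads$seq, 1, 1) == "T")
  p <- pirna_params()
  se <- sqrt(p$u1 * (1 - p$u1) / 10000)
  expect_lt(abs(u1_hat - p$u1), 3 * se)
  long_hat <- mean(nchar(sm$reads$seq) > 24)
  expect_lt(abs(long_hat - p$frac_long),
            3 * sqrt(p$frac_long * (1 - p$frac_long) / 10000))
})

test_that("sim_atac fragments respect open regions and shift inverses", {
  open <- tibble::tibble(chrom = "chr1", start = c(2000L, 7000L),
                         end = c(2600L, 7600L))
  at <- sim_atac(open, c(chr1 = 20000L), 5, n_fragments = 400,
                 background_rate = 0)
  cuts <- shift_cut_sites(at$alignments)
  in_open <- brute_overlap_any(
    tibble::tibble(chrom = cuts$chrom, start = cuts$pos, end = cuts$pos + 1L),
    open)
  expect_true(all(in_open))
  # the corrected positions reproduce the simulated cut sites exactly
  plus <- cuts[cuts$strand == "+", ]
  expect_equal(sort(plus$pos), sort(at$truth$cut1))
  minus <- cuts[cuts$strand == "-", ]
  expect_equal(sort(minus$pos), sort(at$truth$cut2))
})

test_that("sim_chip duplicates are exact and fold=1 is uniform", {
  open <- tibble::tibble(chrom = "chr1", start = 5000L, end = 7000L)
  ch <- sim_chip(open, c(chr1 = 50000L), 8, fold = 5, n_reads = 4000,
                 dup_rate = 0.25)
  dd <- suppressMessages(deduplicate(ch$alignments))
  expect_equal(nrow(dd), ch$truth$n_unique)
  ch0 <- sim_chip(open, c(chr1 = 50000L), 8, fold = 5, n_reads = 4000,
                  dup_rate = 0)
  expect_equal(nrow(suppressMessages(deduplicate(ch0$alignments))),
               nrow(ch0$alignments))
  # fold = 1: positions indistinguishable from uniform (KS test)
  flat <- sim_chip(open, c(chr1 = 50000L), 9, fold = 1, n_reads = 5000,
                   dup_rate = 0)
  ks <- suppressWarnings(
    stats::ks.test(flat$alignments$pos / 50000, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("all simulators are reproducible under a fixed seed", {
  g <- sim_genome(2, n_chroms = 1, chrom_length = 20000, repeat_density = 0.1)
  expect_identical(sim_methylome(g$genome, 4, mean_coverage = 5),
                   sim_methylome(g$genome, 4, mean_coverage = 5))
  lv <- setNames(rep(10000, length(unique(g$repeats$repeat_family))),
                 unique(g$repeats$repeat_family))
  expect_identical(sim_rna(g, lv, 4, n_reads = 300),
                   sim_rna(g, lv, 4, n_reads = 300))
  feats <- tibble::tibble(chrom = "chr1", start = 0L, end = 2000L,
                          strand = "+", category = "transposon")
  expect_identical(sim_smallrna(pirna_params(), feats, 4, n_reads = 200),
                   sim_smallrna(pirna_params(), feats, 4, n_reads = 200))
  expect_identical(sim_atac(feats, c(chr1 = 20000L), 4, n_fragments = 100),
                   sim_atac(feats, c(chr1 = 20000L), 4, n_fragments = 100))
  expect_identical(sim_chip(feats, c(chr1 = 20000L), 4, n_reads = 200),
                   sim_chip(feats, c(chr1 = 20000L), 4, n_reads = 200))
})
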