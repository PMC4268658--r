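# Repeat expression: rRNA filtering, 1/n weighting, the family expression
# statistic, fold changes, RPKM and consensus methylation profiles.

test_that("filter_rrna removes reads within the mismatch ceiling", {
  withr::local_seed(14)
  rrna <- c(r18S = paste(sample(c("A", "C", "G", "T"), 600, TRUE),
                         collapse = ""))
  exact <- substr(rrna, 101, 150)
  three_mm <- exact
  substr(three_mm, 5, 5) <- "N"   # N mismatches everything
  substr(three_mm, 15, 15) <- "N"
  substr(three_mm, 25, 25) <- "N"
  four_mm <- three_mm
  substr(four_mm, 35, 35) <- "N"
  other <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  reads <- tibble::tibble(read_id = c("a", "b", "c", "d"),
                          seq = c(exact, three_mm, four_mm, other))
  expect_message(kept <- filter_rrna(reads, rrna), "removed 2 of 4")
  expect_equal(kept$read_id, c("c", "d"))
  expect_warning(filter_rrna(reads, character(0)), "empty rRNA")
})

test_that("filter_rrna catches reverse-complement matches and planted fractions", {
  withr::local_seed(15)
  rrna <- c(r5S = paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                        collapse = ""))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(rrna, 51, 100))))
  n_clean <- 90
  clean <- vapply(seq_len(n_clean), function(i)
    paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""),
    character(1))
  reads <- tibble::tibble(
    read_id = sprintf("x%03d", seq_len(n_clean + 10)),
    seq = c(clean, rep(rc, 10))
  )
  expect_message(kept <- filter_rrna(reads, rrna), "removed 10 of 100")
  expect_equal(nrow(kept), 90)
})

test_that("fractional weights are 1/n and conserve read mass", {
  aln <- tibble::tibble(
    read_id = c("u", rep("m", 4), rep("h", 3)),
    chrom = "chr1", pos = 0:7 * 100L, strand = "+", length = 50L,
    n_hits = c(1L, rep(4L, 4), rep(3L, 3))
  )
  w <- fractional_weights(aln)
  expect_equal(w$weight[w$read_id == "u"], 1)
  expect_equal(w$weight[w$read_id == "m"], rep(0.25, 4))
  expect_equal(sum(w$weight), 3)  # three retained reads
  # cap: the whole read disappears, not just excess hits
  expect_message(w2 <- fractional_weights(aln, max_sites = 3), "discarded 4")
  expect_equal(sort(unique(w2$read_id)), c("h", "u"))
  expect_equal(sum(w2$weight), 2)
})

test_that("family expression follows the score / (millions x kb) formula", {
  repeats <- tibble::tibble(chrom = "chr1", start = 1000L, end = 2000L,
                            strand = "+", repeat_name = "fam1_c1",
                            repeat_class = "LTR", repeat_family = "fam1")
  hits <- tibble::tibble(chrom = "chr1",
                         pos = as.integer(seq(1100, 1900, length.out = 10)),
                         strand = "+", length = 50L, weight = 1)
  fe <- family_expression(hits, repeats, total_mapped_reads = 1e6)
  expect_equal(fe$expression, 10 / (1 * 1))
  expect_equal(fe$score_sum, 10)
  # no hits: expression 0, family still present
  fe0 <- family_expression(hits[0, ], repeats, total_mapped_reads = 1e6)
  expect_equal(fe0$expression, 0)
  expect_error(family_expression(hits, repeats, total_mapped_reads = 0),
               "positive")
  # consensus-length mode
  fe_c <- family_expression(hits, repeats, total_mapped_reads = 1e6,
                            length_from = "consensus",
                            consensus_lengths = c(fam1 = 2000))
  expect_equal(fe_c$expression, 10 / (1 * 2))
})

test_that("hit-in-body rule uses the 5' base and never double counts", {
  repeats <- tibble::tibble(
    chrom = "chr1", start = c(1000L, 1400L), end = c(2000L, 1600L),
    strand = "+", repeat_name = c("outer", "inner"),
    repeat_class = c("LINE", "SINE"),
    repeat_family = c("famO", "famI"))
  hits <- tibble::tibble(
    chrom = "chr1",
    pos = c(980L, 1500L, 1990L),
    strand = c("+", "+", "+"),
    length = 50L, weight = 1)
  # read 1: 5' base at 980, outside both despite overlapping the body
  # read 2: 5' base inside both; assigned to the smaller (inner) only
  # read 3: 5' base inside outer, read runs past the end; still counted
  fe <- family_expression(hits, repeats, total_mapped_reads = 1e6)
  expect_equal(fe$score_sum[fe$repeat_family == "famI"], 1)
  expect_equal(fe$score_sum[fe$repeat_family == "famO"], 1)
  expect_equal(sum(fe$score_sum), 2)
  # minus-strand 5' base is the rightmost aligned base
  hits_m <- tibble::tibble(chrom = "chr1", pos = 980L, strand = "-",
                           length = 50L, weight = 1)
  fe_m <- family_expression(hits_m, repeats, total_mapped_reads = 1e6)
  expect_equal(sum(fe_m$score_sum), 1)  # 5' end at 1029, inside outer
})

test_that("family expression is invariant under library duplication", {
  withr::local_seed(16)
  g <- sim_genome(7, n_chroms = 1, chrom_length = 60000, repeat_density = 0.15)
  lv <- c(L1Md = 20000, ERVK10 = 4000)
  rna <- sim_rna(g, lv, 3, n_reads = 5000)
  hits <- fractional_weights(rna$alignments)
  fe1 <- family_expression(hits, g$repeats, total_mapped_reads = 5000)
  hits2 <- dplyr::bind_rows(hits, dplyr::mutate(hits, read_id = paste0(read_id, "_dup")))
  fe2 <- family_expression(hits2, g$repeats, total_mapped_reads = 10000)
  expect_equal(fe1$expression, fe2$expression)
})

test_that("expression ratios use a pseudo-expression floor", {
  fe <- function(e) tibble::tibble(repeat_family = names(e), expression = unname(e))
  r <- expression_ratio(fe(c(a = 5, b = 0, c = 10)),
                        fe(c(a = 5, b = 0, c = 5)))
  expect_equal(r$fold_change[r$repeat_family == "a"], 1)
  expect_equal(r$fold_change[r$repeat_family == "b"], 1)  # 0/0 pseudo-dominated
  expect_equal(r$fold_change[r$repeat_family == "c"],
               (10 + 1e-3) / (5 + 1e-3))
})

test_that("rpkm is count / (kb x millions) and scale-invariant", {
  expect_equal(rpkm(100, 2000, 1e7), 5)
  expect_equal(rpkm(0, 2000, 1e7), 0)
  withr::local_seed(17)
  cnt <- rpois(20, 50)
  len <- sample(500:5000, 20)
  expect_equal(rpkm(cnt, len, 2e6), rpkm(2 * cnt, len, 4e6))
})

test_that("consensus profiles report per-CG levels with a 5' exclusion flag", {
  withr::local_seed(18)
  cons <- c(el1 = paste(rep("TACGAT", 100), collapse = ""))
  # fully methylated reads: read sequence equals the consensus
  starts <- seq(0L, 550L, by = 5L)
  aln <- tibble::tibble(read_id = paste0("r", starts), chrom = "el1",
                        pos = starts, strand = "+", length = 50L,
                        seq = substring(cons, starts + 1L, starts + 50L))
  pr <- consensus_meth_profile(aln, cons)
  expect_true(all(pr$level == 1))
  expect_true(all(pr$pos[pr$plot_excluded] < 50))
  expect_false(any(pr$pos[!pr$plot_excluded] < 50))
  expect_gt(sum(pr$plot_excluded), 0)  # early positions present but flagged
  # a planted 5' hypomethylation gradient comes back monotone
  bs <- sim_consensus_bs(cons, 4, coverage = 20, low = 0.05, high = 0.95)
  pr2 <- consensus_meth_profile(bs, cons)
  expect_gt(cor(pr2$pos, pr2$level, method = "spearman"), 0.5)
  expect_warning(
    consensus_meth_profile(aln[0, ][seq_len(0), ],
                           c(noCG = "ATATATAT")), NA)
})

test_that("LTR orientation averaging pools a profile with its mirror", {
  # consensus with one CG near each end; methylated only at the left CG
  cons <- c(ltr = paste0("AACGTT", strrep("A", 88), "AACGTT"))
  L <- nchar(cons)
  aln <- tibble::tibble(
    read_id = c("a", "b"), chrom = "ltr", pos = c(0L, L - 50L),
    strand = "+", length = 50L,
    seq = c(substr(cons, 1, 50),
            chartr("C", "T", substr(cons, L - 49, L))))
  pr <- consensus_meth_profile(aln, cons, min_skip = 0)
  plus <- pr[pr$strand == "+", ]
  expect_equal(plus$level[plus$pos == 2], 1)
  expect_equal(plus$level[plus$pos == L - 4], 0)
  pra <- consensus_meth_profile(aln, cons, min_skip = 0,
                                average_orientations = "ltr")
  # dyad 2 pools with its mirrored partner dyad (L - 2 - 96 = 2): level 0.5
  merged <- pra[pra$pos == 2 & pra$strand == "*", ]
  expect_equal(merged$level, 0.5)
  expect_equal(merged$coverage, 2L)
})
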