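# Binned DMR calling: two-sided Fisher exact test on pooled CpG counts per
# 500-bp bin, Benjamini-Hochberg correction across the testable universe,
# a 50-percentage-point level-difference filter, and a final >=4 CpG /
# >=4-read retention step. Matched control regions are drawn randomly under
# exact per-chromosome, covered-CpG and methylation-level constraints.

#' DMR-calling parameters
#'
#' Defaults follow the binned WGBS procedure: a methylation-level difference
#' of at least 0.50 between genotypes, FDR < 0.05 (Fisher exact test,
#' Benjamini-Hochberg corrected), and final retention of bins containing at
#' least four CG-context cytosines each covered by at least four reads in
#' both genotypes, on 500-bp bins.
#'
#' @param delta_min Minimum absolute methylation-level difference.
#' @param fdr_max Benjamini-Hochberg FDR ceiling.
#' @param min_cg Minimum qualifying CG cytosines per retained bin.
#' @param min_cov Per-cytosine read-coverage floor for a qualifying CG.
#' @param bin_width Bin width in bp.
#' @return A named list of class `dmr_params`.
#' @export
dmr_params <- function(delta_min = 0.50, fdr_max = 0.05, min_cg = 4,
                       min_cov = 4, bin_width = 500) {
  stopifnot(delta_min > 0, delta_min <= 1, fdr_max > 0, min_cg > 0,
            min_cov > 0, bin_width > 0)
  structure(list(delta_min = delta_min, fdr_max = fdr_max, min_cg = min_cg,
                 min_cov = min_cov, bin_width = bin_width),
            class = "dmr_params")
}

fisher_two_sided_1 <- function(a, b, c, d, rel_tol) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- probs[a - lo + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
}

#' Two-sided Fisher exact test p-value for a 2x2 table
#'
#' Computes the exact two-sided p-value of the table `[[a, b], [c, d]]` with
#' fixed margins: the sum of hypergeometric probabilities of all tables whose
#' probability does not exceed that of the observed table. Tables whose
#' probability is within a relative tolerance of the observed one are counted
#' as ties and included, making the sum reproducible across floating-point
#' implementations. A table with any zero margin has p = 1 by convention
#' (reported via a message).
#'
#' All four arguments are vectorized in parallel.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param rel_tol Relative tie tolerance (default 1e-7).
#' @return Numeric vector of p-values.
#' @export
fisher_two_sided <- function(a, b, c, d, rel_tol = 1e-7) {
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) {
    abort("fisher_two_sided: negative cell count")
  }
  n_deg <- sum((a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0)
  if (n_deg > 0) {
    inform(sprintf("fisher_two_sided: %d table(s) with a zero margin; p = 1",
                   n_deg))
  }
  unlist(Map(fisher_two_sided_1, a, b, c, d, rel_tol), use.names = FALSE)
}

#' Benjamini-Hochberg step-up adjusted values
#'
#' The classic step-up procedure: with p-values sorted ascending,
#' `q(i) = min over j >= i of p(j) * m / j`, clipped at 1, returned in the
#' original input order.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("bh_adjust: p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  o <- order(pvalues)
  q_sorted <- pmin(1, rev(cummin(rev(pvalues[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Call differentially methylated bins between two genotypes
#'
#' The testing universe is every bin with at least one covered CG cytosine in
#' both genotypes. Each universe bin is tested with a two-sided Fisher exact
#' test on pooled counts `[[mC_case, uC_case], [mC_control, uC_control]]`;
#' Benjamini-Hochberg correction runs across the universe. Bins with
#' `|delta| >= delta_min` and `q < fdr_max` are selected, then only bins with
#' at least `min_cg` CG cytosines each covered by at least `min_cov` reads in
#' both genotypes are retained. Direction is `hypo` when the case level is
#' below control, `hyper` otherwise; adjacent significant bins are not
#' merged (one bin = one DMR).
#'
#' @param case_bins,control_bins [aggregate_bins()] output for the two
#'   genotypes over the same tiling (case = mutant).
#' @param params A [dmr_params()] list.
#' @param prefilter_universe If `TRUE`, the `min_cg`/`min_cov` retention
#'   filter is applied before testing, shrinking the BH universe, instead of
#'   after selection (the default, which follows the procedure literally).
#' @return A tibble of class `epigerm_dmr` with bin coordinates, per-genotype
#'   levels, `delta`, `p`, `q` and `direction`; the number of tested bins is
#'   attached as attribute `n_tested`.
#' @export
call_dmrs <- function(case_bins, control_bins, params = dmr_params(),
                      prefilter_universe = FALSE) {
  if (nrow(case_bins) != nrow(control_bins) ||
      !identical(case_bins$bin_id, control_bins$bin_id)) {
    abort("call_dmrs: case and control were aggregated over different tilings")
  }
  qualifies <- case_bins$n_sites_min_cov >= params$min_cg &
    control_bins$n_sites_min_cov >= params$min_cg
  universe <- case_bins$n_sites > 0 & control_bins$n_sites > 0
  if (prefilter_universe) universe <- universe & qualifies
  idx <- which(universe)
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    bin_id = character(), level_case = numeric(), level_control = numeric(),
    delta = numeric(), p = numeric(), q = numeric(), direction = character(),
    n_cg_case = integer(), n_cg_control = integer()
  )
  if (length(idx) == 0) {
    return(structure(empty, class = c("epigerm_dmr", class(empty)),
                     params = params, n_tested = 0L))
  }
  mc1 <- case_bins$mc[idx]; uc1 <- case_bins$uc[idx]
  mc0 <- control_bins$mc[idx]; uc0 <- control_bins$uc[idx]
  lvl1 <- mc1 / (mc1 + uc1)
  lvl0 <- mc0 / (mc0 + uc0)
  delta <- lvl1 - lvl0
  p <- suppressMessages(fisher_two_sided(mc1, uc1, mc0, uc0))
  q <- bh_adjust(p)
  sel <- abs(delta) >= params$delta_min & q < params$fdr_max
  if (!prefilter_universe) sel <- sel & qualifies[idx]
  keep <- which(sel)
  delta_keep <- delta[keep]
  out <- tibble(
    chrom = case_bins$chrom[idx][keep],
    start = case_bins$start[idx][keep],
    end = case_bins$end[idx][keep],
    bin_id = case_bins$bin_id[idx][keep],
    level_case = lvl1[keep], level_control = lvl0[keep],
    delta = delta_keep, p = p[keep], q = q[keep],
    direction = ifelse(delta_keep < 0, "hypo", "hyper"),
    n_cg_case = case_bins$n_sites_min_cov[idx][keep],
    n_cg_control = control_bins$n_sites_min_cov[idx][keep]
  )
  structure(out, class = c("epigerm_dmr", class(empty)),
            params = params, n_tested = length(idx))
}

#' Sample matched random control regions for a DMR set
#'
#' Draws one non-DMR bin per DMR, uniformly at random among bins that (1) lie
#' on the same chromosome (so per-chromosome counts match the DMR set), (2)
#' carry exactly the same number of qualifying CG cytosines in the control
#' genotype, and (3) have a control-genotype methylation level within
#' `level_tol` of the DMR's. Each bin is used at most once. DMRs with no
#' qualifying candidate are reported unmatched; the run fails only when more
#' than `max_unmatched_frac` of DMRs are unmatched.
#'
#' @param dmrs An [call_dmrs()] result.
#' @param control_bins [aggregate_bins()] output for the control genotype.
#' @param params [dmr_params()] (supplies `min_cov`/`min_cg` semantics of the
#'   qualifying-CG tally).
#' @param seed Integer seed; sampling is deterministic given it.
#' @param level_tol Methylation-level matching tolerance (default 0.05).
#' @param max_unmatched_frac Maximum tolerated unmatched fraction.
#' @return A tibble of control bins with `matched_dmr_id`,
#'   `n_cg_sites_min_cov` and `level_control`; unmatched DMR ids are attached
#'   as attribute `unmatched`.
#' @export
sample_control_regions <- function(dmrs, control_bins, params = dmr_params(),
                                   seed = 1, level_tol = 0.05,
                                   max_unmatched_frac = 0.1) {
  pool <- control_bins
  if (nrow(dmrs) > 0) {
    hit <- overlap_pairs(pool, dmrs)
    if (nrow(hit) > 0) pool <- pool[-unique(hit$query), ]
  }
  pool <- pool[!pool$empty & !is.na(pool$level), ]
  taken <- logical(nrow(pool))
  picks <- integer(nrow(dmrs))
  with_substream(seed, "control_regions", {
    for (i in seq_len(nrow(dmrs))) {
      cand <- which(
        !taken &
          pool$chrom == dmrs$chrom[i] &
          pool$n_sites_min_cov == dmrs$n_cg_control[i] &
          abs(pool$level - dmrs$level_control[i]) < level_tol
      )
      if (length(cand) == 0) {
        picks[i] <- NA_integer_
      } else {
        picks[i] <- cand[sample.int(length(cand), 1L)]
        taken[picks[i]] <- TRUE
      }
    }
  })
  unmatched <- dmrs$bin_id[is.na(picks)]
  if (length(unmatched) > nrow(dmrs) * max_unmatched_frac) {
    abort(sprintf(
      "sample_control_regions: %d of %d DMRs unmatched (limit %.0f%%)",
      length(unmatched), nrow(dmrs), 100 * max_unmatched_frac))
  }
  if (length(unmatched) > 0) {
    warn(sprintf("sample_control_regions: %d DMR(s) left unmatched",
                 length(unmatched)))
  }
  ok <- !is.na(picks)
  out <- tibble(
    chrom = pool$chrom[picks[ok]],
    start = pool$start[picks[ok]],
    end = pool$end[picks[ok]],
    bin_id = pool$bin_id[picks[ok]],
    matched_dmr_id = dmrs$bin_id[ok],
    n_cg_sites_min_cov = pool$n_sites_min_cov[picks[ok]],
    level_control = pool$level[picks[ok]]
  )
  attr(out, "unmatched") <- unmatched
  out
}

#' Compare two DMR sets for persistence
#'
#' A DMR from one set is shared with the other when the two intervals overlap
#' by at least one basepair and have the same direction.
#'
#' @param dmrs_a,dmrs_b DMR tibbles (need `chrom`, `start`, `end`,
#'   `direction`).
#' @return A list with `shared` (tibble of index pairs `a`, `b`), `only_a`
#'   and `only_b` (row subsets of the inputs).
#' @export
dmr_persistence <- function(dmrs_a, dmrs_b) {
  pairs <- overlap_pairs(dmrs_a, dmrs_b)
  if (nrow(pairs) > 0) {
    same_dir <- dmrs_a$direction[pairs$query] == dmrs_b$direction[pairs$subject]
    pairs <- pairs[same_dir, ]
  }
  list(
    shared = tibble(a = pairs$query, b = pairs$subject),
    only_a = dmrs_a[setdiff(seq_len(nrow(dmrs_a)), pairs$query), ],
    only_b = dmrs_b[setdiff(seq_len(nrow(dmrs_b)), pairs$subject), ]
  )
}
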