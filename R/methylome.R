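# Per-cytosine methylation calling and bin-level summaries.
#
# A methylation level is always #C / (#C + #T): the fraction of bisulfite
# reads reporting cytosine (methylated) among reads reporting C or T at a
# reference cytosine. Strand-specific cytosines are kept as separate records
# (no symmetric-CpG merging), so coverage filters act per cytosine.

#' Locate cytosines in a genome with their sequence context
#'
#' Scans both strands: a plus-strand cytosine's context is the dinucleotide
#' starting at it on the top strand; a minus-strand cytosine (a `G` on the
#' top strand) takes its context from the reverse complement. Terminal bases
#' with no downstream neighbour are dropped.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param contexts `"CG"` (default) to report CpG cytosines only, or
#'   `"all"` for CG/CA/CC/CT.
#' @return A tibble `chrom`, `pos` (0-based, position of the cytosine on its
#'   strand as a top-strand offset), `strand`, `context`.
#' @export
find_cytosines <- function(genome, contexts = c("CG", "all")) {
  contexts <- match.arg(contexts)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- purrr::map(names(genome), function(ch) {
    s <- strsplit(genome[[ch]], "")[[1]]
    L <- length(s)
    if (L < 2) {
      return(tibble(chrom = character(), pos = integer(),
                    strand = character(), context = character()))
    }
    cpos <- which(s == "C")
    cpos <- cpos[cpos < L]
    ctx_plus <- paste0("C", s[cpos + 1L])
    gpos <- which(s == "G")
    gpos <- gpos[gpos > 1]
    ctx_minus <- paste0("C", unname(comp[s[gpos - 1L]]))
    res <- tibble(
      chrom = ch,
      pos = c(cpos, gpos) - 1L,
      strand = rep(c("+", "-"), c(length(cpos), length(gpos))),
      context = c(ctx_plus, ctx_minus)
    )
    res[res$context %in% c("CG", "CA", "CC", "CT"), ]
  })
  out <- bind_rows(out)
  if (contexts == "CG") out <- out[out$context == "CG", ]
  arrange(out, .data$chrom, .data$pos)
}

#' Extract per-cytosine methylation calls from bisulfite alignments
#'
#' Reads are given in reference-forward orientation (SAM convention). For a
#' plus-strand read, reference `C` positions are scored: read base `C`
#' increments the methylated count, `T` the unmethylated count, anything else
#' is ignored. For a minus-strand read the converted strand is the bottom
#' strand, so reference `G` positions are scored with read `G` as methylated
#' and `A` as unmethylated. Context comes from the reference top strand
#' (reverse-complemented for minus-strand cytosines). Reads running past the
#' contig end are skipped with a message.
#'
#' @param alignments Alignment tibble with `chrom`, `pos`, `strand`,
#'   `length`, `seq` columns.
#' @param genome Named character vector of reference sequences.
#' @return A cytosine tibble as from [read_cytosine_report()].
#' @export
extract_methylation <- function(alignments, genome) {
  stopifnot(all(c("chrom", "pos", "strand", "seq") %in% names(alignments)))
  glen <- vapply(genome, nchar, integer(1))
  rl <- nchar(alignments$seq)
  ok <- alignments$chrom %in% names(genome) &
    alignments$pos + rl <= glen[alignments$chrom]
  if (any(!ok)) {
    inform(sprintf("extract_methylation: skipped %d read(s) outside contig bounds",
                   sum(!ok)))
    alignments <- alignments[ok, ]
    rl <- rl[ok]
  }
  if (nrow(alignments) == 0) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  context = character(), count_methylated = integer(),
                  count_unmethylated = integer()))
  }
  events <- purrr::pmap(
    list(alignments$chrom, alignments$pos, alignments$strand, alignments$seq),
    function(ch, p0, st, sq) {
      ref <- strsplit(substr(genome[[ch]], p0 + 1L, p0 + nchar(sq)), "")[[1]]
      rd <- strsplit(sq, "")[[1]]
      if (st == "+") {
        at <- which(ref == "C")
        meth <- rd[at] == "C"
        unmeth <- rd[at] == "T"
      } else {
        at <- which(ref == "G")
        meth <- rd[at] == "G"
        unmeth <- rd[at] == "A"
      }
      keep <- meth | unmeth
      tibble(chrom = ch, pos = p0 + at[keep] - 1L, strand = st,
             m = meth[keep])
    }
  )
  calls <- bind_rows(events)
  if (nrow(calls) == 0) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  context = character(), count_methylated = integer(),
                  count_unmethylated = integer()))
  }
  counts <- calls |>
    group_by(.data$chrom, .data$pos, .data$strand) |>
    summarise(count_methylated = sum(.data$m),
              count_unmethylated = sum(!.data$m), .groups = "drop")
  ctx <- bind_rows(purrr::map(unique(counts$chrom), function(ch) {
    find_cytosines(setNames(genome[ch], ch), contexts = "all")
  }))
  out <- inner_join(counts, ctx, by = c("chrom", "pos", "strand"))
  arrange(out[, c("chrom", "pos", "strand", "context",
                  "count_methylated", "count_unmethylated")],
          .data$chrom, .data$pos)
}

#' Genome-wide methylation level for a context
#'
#' Count-weighted by default: total #C over total (#C + #T) across all
#' records of the context, i.e. the bulk level of pooled counts. The
#' per-site mean (`weighting = "site"`) is exposed as an alternative.
#'
#' @param records Cytosine tibble.
#' @param context `"CG"` or `"CA"`.
#' @param weighting `"count"` (default) or `"site"`.
#' @return A single fraction in \[0, 1\]; `NA` with a warning when the
#'   context has no records.
#' @export
genome_level <- function(records, context = c("CG", "CA"),
                         weighting = c("count", "site")) {
  context <- match.arg(context)
  weighting <- match.arg(weighting)
  x <- records[records$context == context, ]
  if (nrow(x) == 0) {
    warn(paste0("genome_level: no records in context ", context,
                "; level undefined"))
    return(NA_real_)
  }
  if (weighting == "count") {
    pooled_level(x$count_methylated, x$count_unmethylated)
  } else {
    tot <- x$count_methylated + x$count_unmethylated
    mean((x$count_methylated / tot)[tot > 0])
  }
}

#' Bisulfite conversion rate from an unmethylated spike-in
#'
#' One minus the pooled methylation level over all contexts of the spike-in
#' contig (every retained C call on an unmethylated genome reflects failed
#' conversion). Warns when the rate falls below the QC threshold.
#'
#' @param spikein_records Cytosine tibble restricted to the spike-in contig.
#' @param qc_threshold Minimum acceptable conversion rate (default 0.98).
#' @return Conversion rate in \[0, 1\]; `NA` with a warning when no spike-in
#'   records are present.
#' @export
conversion_rate <- function(spikein_records, qc_threshold = 0.98) {
  if (nrow(spikein_records) == 0) {
    warn("conversion_rate: no spike-in records; conversion QC unavailable")
    return(NA_real_)
  }
  rate <- 1 - pooled_level(spikein_records$count_methylated,
                           spikein_records$count_unmethylated)
  if (!is.na(rate) && rate < qc_threshold) {
    warn(sprintf("conversion rate %.4f below QC threshold %.2f",
                 rate, qc_threshold))
  }
  rate
}

#' Tile chromosomes into fixed-width bins
#'
#' Adjacent non-overlapping bins in genome order; the terminal partial bin
#' is retained, so bin widths always sum to the genome length.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param width Bin width in bp (default 500).
#' @return An interval tibble with a `bin_id` column.
#' @export
tile_bins <- function(chrom_sizes, width = 500) {
  stopifnot(width >= 1, all(chrom_sizes >= 1))
  bind_rows(purrr::map(names(chrom_sizes), function(ch) {
    L <- as.integer(chrom_sizes[[ch]])
    starts <- seq.int(0L, L - 1L, by = as.integer(width))
    tibble(chrom = ch, start = starts,
           end = pmin(starts + as.integer(width), L))
  })) |>
    mutate(bin_id = paste0(.data$chrom, ":", .data$start, "-", .data$end))
}

#' Pool cytosine counts into bins
#'
#' Assigns CG-context records to bins by position, pools methylated and
#' unmethylated counts, and tallies covered sites and sites reaching the
#' coverage floor. Bins with no covered cytosine are flagged `empty` and are
#' excluded from the DMR testing universe downstream.
#'
#' @param records Cytosine tibble.
#' @param bins Bin tibble from [tile_bins()].
#' @param min_cov Per-site coverage floor for the qualifying-site tally
#'   (default 4 reads).
#' @param context Context pooled (default `"CG"`).
#' @return `bins` with `n_sites`, `n_sites_min_cov`, `mc`, `uc`, `level`,
#'   `empty` columns.
#' @export
aggregate_bins <- function(records, bins, min_cov = 4, context = "CG") {
  validate_intervals(bins, "bins")
  x <- records[records$context == context &
                 records$count_methylated + records$count_unmethylated > 0, ]
  if (nrow(x) > 0) {
    pr <- tibble(chrom = x$chrom, start = x$pos, end = x$pos + 1L)
    pairs <- overlap_pairs(pr, bins)
    per_bin <- tibble(
      bin = pairs$subject,
      mc = x$count_methylated[pairs$query],
      uc = x$count_unmethylated[pairs$query]
    ) |>
      group_by(.data$bin) |>
      summarise(
        n_sites = dplyr::n(),
        n_sites_min_cov = sum(.data$mc + .data$uc >= min_cov),
        mc = sum(.data$mc), uc = sum(.data$uc), .groups = "drop"
      )
  } else {
    per_bin <- tibble(bin = integer(), n_sites = integer(),
                      n_sites_min_cov = integer(), mc = integer(),
                      uc = integer())
  }
  out <- bins
  out$n_sites <- 0L
  out$n_sites_min_cov <- 0L
  out$mc <- 0L
  out$uc <- 0L
  out$n_sites[per_bin$bin] <- per_bin$n_sites
  out$n_sites_min_cov[per_bin$bin] <- per_bin$n_sites_min_cov
  out$mc[per_bin$bin] <- per_bin$mc
  out$uc[per_bin$bin] <- per_bin$uc
  out$level <- ifelse(out$mc + out$uc > 0, out$mc / (out$mc + out$uc), NA_real_)
  out$empty <- out$n_sites == 0L
  out
}
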