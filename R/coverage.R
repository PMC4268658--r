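# ATAC cut-site correction, read deduplication, and library-size-normalized
# coverage matrices over anchored regions (metaplots, per-region abundance).

#' Correct ATAC-seq reads to Tn5 insertion points
#'
#' The Tn5 transposase dimer inserts two adaptors 9 bp apart, so the true
#' insertion point sits inside the read: plus-strand reads are offset by
#' +4 bp from their leftmost base, minus-strand reads by -5 bp from their
#' rightmost base. Calling this on an already-shifted result is an error
#' (the output carries a `shifted` marker).
#'
#' @param alignments Alignment tibble (`chrom`, `pos`, `strand`, `length`).
#' @return Tibble of cut sites (`chrom`, `pos`, `strand`); positions shifted
#'   below 0 are clipped to 0 with a warning.
#' @export
shift_cut_sites <- function(alignments) {
  if (isTRUE(attr(alignments, "shifted"))) {
    abort("shift_cut_sites: input is already cut-site corrected")
  }
  pos <- ifelse(alignments$strand == "-",
                alignments$pos + alignments$length - 1L - 5L,
                alignments$pos + 4L)
  if (any(pos < 0)) {
    warn(sprintf("shift_cut_sites: %d position(s) clipped at 0", sum(pos < 0)))
    pos <- pmax(pos, 0L)
  }
  out <- tibble(chrom = alignments$chrom, pos = as.integer(pos),
                strand = alignments$strand)
  attr(out, "shifted") <- TRUE
  out
}

#' Collapse reads mapping to the same location
#'
#' One record is kept per (chromosome, 5' position, strand); the collapsed
#' multiplicity is reported via a message. Idempotent.
#'
#' @param alignments Alignment tibble (`chrom`, `pos`, `strand`; `length`
#'   used for minus-strand 5' ends when present).
#' @return The deduplicated tibble.
#' @export
deduplicate <- function(alignments) {
  p5 <- if ("length" %in% names(alignments)) {
    five_prime_pos(alignments)
  } else {
    alignments$pos
  }
  key <- paste(alignments$chrom, p5, alignments$strand)
  keep <- !duplicated(key)
  if (any(!keep)) {
    inform(sprintf("deduplicate: collapsed %d duplicate read(s)", sum(!keep)))
  }
  alignments[keep, ]
}

anchor_positions <- function(regions, anchor) {
  switch(anchor,
    midpoint = (regions$start + regions$end) %/% 2L,
    start = regions$start,
    point = if ("tss" %in% names(regions)) regions$tss else regions$start
  )
}

site_positions <- function(x) {
  if ("length" %in% names(x)) five_prime_pos(x) else x$pos
}

#' Library-normalized coverage matrix over anchored regions
#'
#' Counts cut sites (or read 5' ends) in fixed-width offset bins around each
#' region's anchor, scaled to reads per million by `library_size`. Offset 0
#' is the anchor; for minus-strand regions offsets are flipped so that
#' positive offsets always point downstream of a stranded anchor (TSS
#' metaplots).
#'
#' @param sites Cut-site or alignment tibble.
#' @param regions Interval tibble; `strand` and `tss` columns honoured.
#' @param anchor `"midpoint"` (default), `"start"`, or `"point"` (uses the
#'   `tss` column when present).
#' @param flank Half-window in bp (default 2000).
#' @param binsize Offset-bin width in bp (default 50).
#' @param library_size Total mapped reads used for the per-million scaling;
#'   defaults to `nrow(sites)`.
#' @return An object of class `epigerm_profile`: a list with `matrix`
#'   (regions x offset bins, RPM), `offsets` (bin left edges), `region_id`,
#'   and the call parameters.
#' @export
normalized_coverage <- function(sites, regions,
                                anchor = c("midpoint", "start", "point"),
                                flank = 2000, binsize = 50,
                                library_size = nrow(sites)) {
  anchor <- match.arg(anchor)
  stopifnot(flank > 0, binsize > 0)
  n_bins <- ceiling(flank / binsize)
  offsets <- seq.int(-n_bins, n_bins - 1L) * binsize
  rid <- if ("bin_id" %in% names(regions)) {
    regions$bin_id
  } else if ("name" %in% names(regions)) {
    regions$name
  } else {
    paste0(regions$chrom, ":", regions$start, "-", regions$end)
  }
  mat <- matrix(0, nrow = nrow(regions), ncol = 2 * n_bins,
                dimnames = list(rid, offsets))
  if (nrow(sites) > 0 && nrow(regions) > 0 && library_size > 0) {
    apos <- anchor_positions(regions, anchor)
    win <- tibble(chrom = regions$chrom,
                  start = pmax(0L, apos - n_bins * binsize),
                  end = apos + n_bins * binsize)
    clipped <- win$start != apos - n_bins * binsize
    if (any(clipped)) {
      warn(sprintf("normalized_coverage: %d window(s) clipped at contig start",
                   sum(clipped)))
    }
    sp <- site_positions(sites)
    pts <- tibble(chrom = sites$chrom, start = sp, end = sp + 1L)
    pairs <- overlap_pairs(pts, win)
    if (nrow(pairs) > 0) {
      off <- sp[pairs$query] - apos[pairs$subject]
      if ("strand" %in% names(regions)) {
        neg <- regions$strand[pairs$subject] == "-"
        off[neg] <- -off[neg] - 1L
      }
      bin <- floor(off / binsize) + n_bins + 1L
      ok <- bin >= 1 & bin <= 2 * n_bins
      idx <- cbind(pairs$subject[ok], bin[ok])
      counts <- table(paste(idx[, 1], idx[, 2]))
      ij <- do.call(rbind, strsplit(names(counts), " "))
      mat[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] <-
        as.numeric(counts) * 1e6 / library_size
    }
  }
  structure(
    list(matrix = mat, offsets = offsets, region_id = rid, anchor = anchor,
         flank = flank, binsize = binsize, library_size = library_size),
    class = "epigerm_profile"
  )
}

#' @export
print.epigerm_profile <- function(x, ...) {
  cat(sprintf(
    "<epigerm_profile> %d regions x %d bins (anchor %s, flank %d, binsize %d)\n",
    nrow(x$matrix), ncol(x$matrix), x$anchor, x$flank, x$binsize))
  invisible(x)
}

#' Per-region normalized read abundance
#'
#' Reads per million whose cut site / 5' end lies inside each region.
#'
#' @param sites Cut-site or alignment tibble.
#' @param regions Interval tibble.
#' @param library_size Total mapped reads (defaults to `nrow(sites)`).
#' @return `regions` with `n_reads` and `rpm` columns.
#' @export
region_abundance <- function(sites, regions, library_size = nrow(sites)) {
  validate_intervals(regions, "regions")
  sp <- site_positions(sites)
  pts <- tibble(chrom = sites$chrom, start = sp, end = sp + 1L)
  pairs <- overlap_pairs(pts, regions)
  out <- regions
  out$n_reads <- 0L
  if (nrow(pairs) > 0) {
    cnt <- table(pairs$subject)
    out$n_reads[as.integer(names(cnt))] <- as.integer(cnt)
  }
  out$rpm <- if (library_size > 0) out$n_reads * 1e6 / library_size else 0
  out
}

#' Rank correlation between TSS-proximal density and expression
#'
#' Spearman correlation between per-gene read density around the TSS (row
#' sums of a TSS-anchored profile, or any numeric density vector) and
#' matched expression values.
#'
#' @param tss_density An `epigerm_profile` over TSSs, or a numeric vector.
#' @param expression Numeric expression values, same order/length as the
#'   profile rows.
#' @return Spearman's rho.
#' @export
tss_expression_concordance <- function(tss_density, expression) {
  dens <- if (inherits(tss_density, "epigerm_profile")) {
    rowSums(tss_density$matrix)
  } else {
    tss_density
  }
  stopifnot(length(dens) == length(expression))
  cor(dens, expression, method = "spearman")
}
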