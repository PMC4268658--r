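# Internal helpers: interval validation, GRanges bridging, seed substreams.

# All genomic coordinates inside the package are 0-based half-open [start, end).
# 1-based on-disk formats are converted at the I/O boundary only.

validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(what, " table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    abort(paste0(what, ": chrom must be nonempty"))
  }
  if (any(x$start < 0)) abort(paste0(what, ": negative start coordinate"))
  if (any(x$end <= x$start)) abort(paste0(what, ": end must exceed start"))
  invisible(x)
}

# 0-based half-open tibble -> GRanges (1-based closed internally to Bioconductor)
as_granges0 <- function(x, strand_col = "strand", seqlevels = NULL) {
  strand <- if (strand_col %in% names(x)) {
    s <- x[[strand_col]]
    s[is.na(s) | !(s %in% c("+", "-"))] <- "*"
    s
  } else {
    "*"
  }
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlevels %||% unique(x$chrom)),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# Overlap pairs between two 0-based half-open interval tables.
# Returns tibble(query = i, subject = j) of row indices with >= 1 bp overlap.
overlap_pairs <- function(queries, subjects) {
  if (nrow(queries) == 0 || nrow(subjects) == 0) {
    return(tibble(query = integer(), subject = integer()))
  }
  lev <- union(unique(queries$chrom), unique(subjects$chrom))
  hits <- GenomicRanges::findOverlaps(
    as_granges0(queries, seqlevels = lev),
    as_granges0(subjects, seqlevels = lev),
    ignore.strand = TRUE
  )
  tibble(
    query = S4Vectors::queryHits(hits),
    subject = S4Vectors::subjectHits(hits)
  )
}

# FNV-1a 32-bit hash of a character scalar, returned as hex string.
# Used for provenance headers (config fingerprints), nothing cryptographic.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low 16 bits (b < 256); keep h as a double since
    # it exceeds R's 32-bit signed integer range
    h <- (h %/% 65536) * 65536 + bitwXor(h %% 65536, b)
    # 32-bit modular multiply by 16777619 without overflow: split into halves
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Derive a named substream seed from a root seed
#'
#' All randomness in the package flows from one root seed; each stage draws
#' from its own substream so adding or reordering stages does not perturb the
#' others. The substream seed is a deterministic mix of the root seed and the
#' stream name, kept below 2^31.
#'
#' @param seed Integer root seed.
#' @param name Character stream name (e.g. `"methylome"`).
#' @return A single integer seed.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- strtoi(substr(fnv1a32(name), 1, 7), base = 16L)
  as.integer((abs(seed) * 2654435761 + h) %% (2^31 - 1))
}

with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

# pooled level = sum(mC)/sum(mC + uC); NA when no coverage
pooled_level <- function(mc, uc) {
  tot <- sum(mc) + sum(uc)
  if (tot == 0) return(NA_real_)
  sum(mc) / tot
}
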