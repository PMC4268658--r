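# Readers and writers for the on-disk formats the pipeline touches.
#
# Coordinate policy: everything in memory is 0-based half-open; 1-based
# formats (cytosine reports, RepeatMasker tables, SAM) are shifted at this
# boundary and nowhere else.

#' Read a per-cytosine methylation report
#'
#' The report is a headerless tab-separated file with columns
#' chrom, position (1-based), strand, context, methylated count, total count
#' (a CGmap-like interchange schema). Positions are converted to 0-based;
#' the unmethylated count is `total - methylated`.
#'
#' @param path File path.
#' @return A tibble with columns `chrom`, `pos` (0-based), `strand`,
#'   `context` (one of CG, CA, CC, CT), `count_methylated`,
#'   `count_unmethylated`.
#' @export
read_cytosine_report <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "pos1", "strand", "context", "mc", "total"),
    col_types = readr::cols(
      chrom = readr::col_character(), pos1 = readr::col_integer(),
      strand = readr::col_character(), context = readr::col_character(),
      mc = readr::col_integer(), total = readr::col_integer()
    ),
    progress = FALSE
  )
  bad <- readr::problems(x)
  if (nrow(bad) > 0) {
    abort(sprintf("cytosine report parse error at line %d of %s",
                  bad$row[1], path))
  }
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  context = character(), count_methylated = integer(),
                  count_unmethylated = integer()))
  }
  if (any(is.na(x$pos1)) || any(x$pos1 < 1)) {
    abort(sprintf("cytosine report: invalid position at line %d",
                  which(is.na(x$pos1) | x$pos1 < 1)[1]))
  }
  if (any(!x$context %in% c("CG", "CA", "CC", "CT"))) {
    abort(sprintf("cytosine report: unknown context at line %d",
                  which(!x$context %in% c("CG", "CA", "CC", "CT"))[1]))
  }
  if (any(x$total < x$mc)) {
    abort(sprintf("cytosine report: total < methylated at line %d",
                  which(x$total < x$mc)[1]))
  }
  tibble(
    chrom = x$chrom, pos = x$pos1 - 1L, strand = x$strand,
    context = x$context, count_methylated = x$mc,
    count_unmethylated = x$total - x$mc
  )
}

#' Write a per-cytosine methylation report
#'
#' Inverse of [read_cytosine_report()]: emits the 1-based six-column
#' tab-separated schema.
#'
#' @param records Cytosine tibble as returned by [read_cytosine_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  out <- tibble(
    chrom = records$chrom, pos1 = records$pos + 1L, strand = records$strand,
    context = records$context, mc = records$count_methylated,
    total = records$count_methylated + records$count_unmethylated
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a RepeatMasker-style repeat annotation table
#'
#' Expects a headerless TSV with columns chrom, start (1-based), end, strand,
#' repeat name, class/family (e.g. `LTR/ERVK`). The class/family string is
#' split on `/`; a bare class (no slash) is used for both fields. Strand `C`
#' (RepeatMasker's complement mark) is read as `-`.
#'
#' @param path File path.
#' @return A tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `repeat_name`, `repeat_class`, `repeat_family`.
#' @export
read_repeat_table <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start1", "end", "strand", "repeat_name", "class_family"),
    col_types = "ciiccc", progress = FALSE
  )
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), repeat_name = character(),
                  repeat_class = character(), repeat_family = character()))
  }
  if (any(!x$strand %in% c("+", "-", "C"))) {
    abort(sprintf("repeat table: unknown strand symbol '%s'",
                  x$strand[!x$strand %in% c("+", "-", "C")][1]))
  }
  split <- stringr::str_split_fixed(x$class_family, "/", 2)
  fam <- ifelse(split[, 2] == "", split[, 1], split[, 2])
  out <- tibble(
    chrom = x$chrom, start = x$start1 - 1L, end = x$end,
    strand = ifelse(x$strand == "C", "-", x$strand),
    repeat_name = x$repeat_name,
    repeat_class = split[, 1], repeat_family = fam
  )
  validate_intervals(out, "repeat table")
  if (any(!nzchar(out$repeat_name)) || any(!nzchar(out$repeat_class))) {
    abort("repeat table: empty repeat name or class")
  }
  out
}

#' Write a repeat annotation table
#'
#' Inverse of [read_repeat_table()] (1-based starts, class/family rejoined
#' with `/`).
#'
#' @param repeats Repeat tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_table <- function(repeats, path) {
  cf <- ifelse(repeats$repeat_family == repeats$repeat_class,
               repeats$repeat_class,
               paste0(repeats$repeat_class, "/", repeats$repeat_family))
  out <- tibble(
    chrom = repeats$chrom, start1 = repeats$start + 1L, end = repeats$end,
    strand = repeats$strand, repeat_name = repeats$repeat_name,
    class_family = cf
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# reference span consumed by a CIGAR string (M/D/N/=/X advance the reference)
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- stringr::str_match_all(cg, "(\\d+)([MIDNSHP=X])")[[1]]
    sum(as.integer(ops[ops[, 3] %in% c("M", "D", "N", "=", "X"), 2]))
  }, integer(1), USE.NAMES = FALSE)
}

#' Read an alignment table
#'
#' Two formats are supported. `"tabular"` is a TSV with header columns
#' `read_id, chrom, pos, strand, length, mismatches, n_hits` (0-based `pos`;
#' `n_hits` and `mismatches` optional, defaulting to 1 and 0; an optional
#' `seq` column is carried through for bisulfite extraction). `"sam-subset"`
#' is plain-text SAM restricted to the mandatory columns plus optional
#' `NH:i:` (hit count) and `NM:i:` (mismatch) tags; flag 16 maps to strand
#' `-`, flag-4 (unmapped) records are skipped with a message.
#'
#' @param path File path.
#' @param format `"tabular"` or `"sam-subset"`.
#' @param sort Sort records by (chrom, pos)?
#' @return A tibble of alignment records with 0-based `pos` and `n_hits >= 1`.
#' @export
read_alignments <- function(path, format = c("tabular", "sam-subset"),
                            sort = FALSE) {
  format <- match.arg(format)
  if (format == "tabular") {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    req <- c("read_id", "chrom", "pos", "strand")
    if (!all(req %in% names(x))) {
      abort(paste0("alignment table missing mandatory column(s): ",
                   paste(setdiff(req, names(x)), collapse = ", ")))
    }
    if (!"length" %in% names(x)) x$length <- 50L
    if (!"mismatches" %in% names(x)) x$mismatches <- 0L
    if (!"n_hits" %in% names(x)) x$n_hits <- 1L
    x$n_hits[is.na(x$n_hits)] <- 1L
    out <- as_tibble(x)
  } else {
    lines <- readr::read_lines(path, progress = FALSE)
    lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
    if (length(lines) == 0) {
      out <- tibble(read_id = character(), chrom = character(),
                    pos = integer(), strand = character(), length = integer(),
                    mismatches = integer(), n_hits = integer(),
                    seq = character())
    } else {
      fields <- stringr::str_split(lines, "\t")
      n_col <- lengths(fields)
      if (any(n_col < 11)) {
        abort(sprintf("SAM parse error: line %d has %d fields (need >= 11)",
                      which(n_col < 11)[1], min(n_col)))
      }
      get <- function(i) vapply(fields, `[[`, character(1), i)
      flag <- as.integer(get(2))
      unmapped <- bitwAnd(flag, 4L) > 0L
      if (any(unmapped)) {
        inform(sprintf("read_alignments: skipped %d unmapped record(s)",
                       sum(unmapped)))
      }
      tag_value <- function(f, tag) {
        extra <- f[-(1:11)]
        hit <- extra[startsWith(extra, paste0(tag, ":i:"))]
        if (length(hit) == 0) NA_integer_ else as.integer(sub(".*:", "", hit[1]))
      }
      out <- tibble(
        read_id = get(1),
        chrom = get(3),
        pos = as.integer(get(4)) - 1L,
        strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
        length = cigar_ref_span(get(6)),
        mismatches = vapply(fields, tag_value, integer(1), tag = "NM"),
        n_hits = vapply(fields, tag_value, integer(1), tag = "NH"),
        seq = get(10)
      )[!unmapped, ]
      out$length[is.na(out$length)] <- 50L
      out$mismatches[is.na(out$mismatches)] <- 0L
      out$n_hits[is.na(out$n_hits)] <- 1L
    }
  }
  if (nrow(out) > 0) {
    if (any(out$pos < 0)) abort("alignments: negative position")
    if (any(out$n_hits < 1)) abort("alignments: n_hits must be >= 1")
    if (any(out$length < 1)) abort("alignments: length must be >= 1")
  }
  if (sort) out <- arrange(out, .data$chrom, .data$pos)
  out
}

#' Write an alignment table (tabular format)
#'
#' @param alignments Alignment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path) {
  readr::write_tsv(alignments, path, progress = FALSE)
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' Emits BED3, or BED6 when `name`/`strand` columns are present (missing
#' names become `.`; the score column is taken from `score_field` when
#' given, else 0). Coordinates are already 0-based half-open, BED's native
#' convention.
#'
#' @param regions Interval tibble (`chrom`, `start`, `end`, optionally
#'   `name`, `strand`).
#' @param path Output path.
#' @param score_field Optional name of a numeric column to use as BED score.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path, score_field = NULL) {
  validate_intervals(regions, "BED regions")
  bed6 <- !is.null(score_field) || any(c("name", "strand") %in% names(regions))
  if (bed6) {
    out <- tibble(
      chrom = regions$chrom, start = regions$start, end = regions$end,
      name = if ("name" %in% names(regions)) regions$name else ".",
      score = if (!is.null(score_field)) regions[[score_field]] else 0,
      strand = if ("strand" %in% names(regions)) {
        ifelse(regions$strand %in% c("+", "-"), regions$strand, ".")
      } else "."
    )
  } else {
    out <- regions[, c("chrom", "start", "end")]
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' @param path File path.
#' @return An interval tibble (0-based half-open); BED6 adds `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  names(x)[1:3] <- c("chrom", "start", "end")
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (ncol(x) >= 6) {
    names(x)[4:6] <- c("name", "score", "strand")
  }
  validate_intervals(x, "BED")
  as_tibble(x)
}

#' Read a FASTA file as a named character vector
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 80L
  )
  invisible(path)
}

#' Read transcript models from a BED-like TSV
#'
#' A lightweight transcript table: `chrom, start, end, gene_id,
#' transcript_id, strand` (0-based half-open span). The TSS is the `start`
#' for `+` transcripts and `end - 1` for `-` transcripts.
#'
#' @param path File path.
#' @return A tibble with the columns above plus a derived `tss` column.
#' @export
read_transcripts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("chrom", "start", "end", "gene_id", "transcript_id", "strand")
  if (!all(req %in% names(x))) {
    abort(paste0("transcript table missing column(s): ",
                 paste(setdiff(req, names(x)), collapse = ", ")))
  }
  validate_intervals(x, "transcripts")
  mutate(as_tibble(x),
         tss = if_else(.data$strand == "-", .data$end - 1L, .data$start))
}

#' Write transcript models
#'
#' @param transcripts Transcript tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  cols <- c("chrom", "start", "end", "gene_id", "transcript_id", "strand")
  readr::write_tsv(transcripts[, cols], path, progress = FALSE)
  invisible(path)
}
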