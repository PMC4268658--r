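# Transposon-family expression from multi-mapped RNA-seq reads.
#
# Each read carries unit mass split evenly over its n genomic alignments
# (weight 1/n per hit, reads mapping to more than 10,000 sites discarded).
# Family expression is the weight sum inside annotated repeat bodies divided
# by (total million mapped reads x mean copy length in kb).

#' Discard reads matching ribosomal RNA
#'
#' A read is removed when it aligns anywhere within any of the supplied rRNA
#' reference sequences (either strand) with at most `max_mismatches`
#' mismatches (ungapped). The removal count is reported via a message.
#'
#' @param reads Tibble with `read_id` and `seq` columns.
#' @param rrna_sequences Named character vector of rRNA references.
#' @param max_mismatches Mismatch ceiling (default 3).
#' @return The filtered `reads` tibble.
#' @export
filter_rrna <- function(reads, rrna_sequences, max_mismatches = 3) {
  if (length(rrna_sequences) == 0) {
    warn("filter_rrna: empty rRNA reference set; no reads removed")
    return(reads)
  }
  if (nrow(reads) == 0) return(reads)
  # concatenate references with an N spacer so a single scan suffices;
  # N never matches, so the spacer cannot create spurious sub-threshold hits
  spacer <- strrep("N", max_mismatches + 1 + max(nchar(reads$seq)))
  subject <- Biostrings::DNAString(
    paste(rrna_sequences, collapse = spacer))
  subject_rc <- Biostrings::reverseComplement(subject)
  # seed prefilter: a read of length L with <= max_mismatches mismatches
  # must share an exact k-mer of k = floor(L / (max_mismatches + 1)) with
  # the reference (pigeonhole); only seeded reads get the full scan
  k <- max(8L, min(nchar(reads$seq)) %/% (max_mismatches + 1L))
  ref_kmers <- unique(unlist(lapply(
    c(as.character(subject), as.character(subject_rc)),
    function(s) substring(s, seq_len(nchar(s) - k + 1L),
                          seq_len(nchar(s) - k + 1L) + k - 1L))))
  has_seed <- vapply(reads$seq, function(s) {
    n_k <- nchar(s) - k + 1L
    if (n_k < 1) return(TRUE)
    any(substring(s, seq_len(n_k), seq_len(n_k) + k - 1L) %in% ref_kmers)
  }, logical(1), USE.NAMES = FALSE)
  is_rrna <- logical(nrow(reads))
  is_rrna[has_seed] <- vapply(reads$seq[has_seed], function(s) {
    p <- Biostrings::DNAString(s)
    length(Biostrings::matchPattern(p, subject,
                                    max.mismatch = max_mismatches)) > 0 ||
      length(Biostrings::matchPattern(p, subject_rc,
                                      max.mismatch = max_mismatches)) > 0
  }, logical(1), USE.NAMES = FALSE)
  inform(sprintf("filter_rrna: removed %d of %d read(s)",
                 sum(is_rrna), nrow(reads)))
  reads[!is_rrna, ]
}

#' Fractional 1/n weights for multi-mapped alignments
#'
#' Drops reads whose reported hit count exceeds `max_sites`, then assigns
#' every retained hit the weight `1 / n_hits`, so each retained read
#' contributes total mass 1 across its alignments.
#'
#' @param alignments Alignment tibble (one row per hit, `n_hits` column).
#' @param max_sites Maximum genomic alignment count kept (default 10,000).
#' @return `alignments` with a `weight` column.
#' @export
fractional_weights <- function(alignments, max_sites = 10000) {
  dropped <- sum(alignments$n_hits > max_sites)
  if (dropped > 0) {
    inform(sprintf(
      "fractional_weights: discarded %d hit row(s) from reads mapping to > %d sites",
      dropped, max_sites))
  }
  out <- alignments[alignments$n_hits <= max_sites, ]
  out$weight <- 1 / out$n_hits
  out
}

# 5'-most aligned base of each record (leftmost for +, rightmost for -)
five_prime_pos <- function(alignments) {
  ifelse(alignments$strand == "-",
         alignments$pos + alignments$length - 1L,
         alignments$pos)
}

#' Repeat-family expression from weighted hits
#'
#' A hit belongs to a repeat body when its 5'-most aligned base lies inside
#' the repeat interval; a hit whose 5' base falls inside several (nested)
#' repeats is assigned to the smallest one only, so a single hit is never
#' counted twice. Family expression is
#' `score_sum / (mapped_millions * mean_length_kb)` with `mean_length_kb`
#' the mean genomic copy length of the family in kb (set
#' `length_from = "consensus"` with a `consensus_lengths` vector to use
#' consensus lengths instead). Families with annotated copies but no hits
#' score 0; families without annotated copies are absent.
#'
#' @param hits Weighted hit tibble from [fractional_weights()].
#' @param repeats Repeat annotation tibble ([read_repeat_table()] schema).
#' @param total_mapped_reads Total fractional mapped reads in the library.
#' @param length_from `"copies"` (default) or `"consensus"`.
#' @param consensus_lengths Named numeric vector of consensus lengths (bp),
#'   required for `length_from = "consensus"`.
#' @return A tibble of class `epigerm_famexpr`: `repeat_family`, `n_copies`,
#'   `mean_length_kb`, `score_sum`, `expression`.
#' @export
family_expression <- function(hits, repeats, total_mapped_reads,
                              length_from = c("copies", "consensus"),
                              consensus_lengths = NULL) {
  length_from <- match.arg(length_from)
  if (total_mapped_reads <= 0) {
    abort("family_expression: total_mapped_reads must be positive")
  }
  fam <- repeats |>
    group_by(.data$repeat_family) |>
    summarise(n_copies = dplyr::n(),
              mean_length_kb = mean(.data$end - .data$start) / 1000,
              .groups = "drop")
  if (length_from == "consensus") {
    if (is.null(consensus_lengths)) {
      abort("family_expression: consensus_lengths required")
    }
    fam$mean_length_kb <- unname(consensus_lengths[fam$repeat_family]) / 1000
  }
  if (nrow(hits) > 0) {
    pts <- tibble(chrom = hits$chrom, start = five_prime_pos(hits))
    pts$end <- pts$start + 1L
    pairs <- overlap_pairs(pts, repeats)
    if (nrow(pairs) > 0) {
      # nested repeats: keep the smallest containing repeat per hit
      width <- (repeats$end - repeats$start)[pairs$subject]
      pairs <- pairs[order(pairs$query, width), ]
      pairs <- pairs[!duplicated(pairs$query), ]
    }
    scores <- tibble(
      repeat_family = repeats$repeat_family[pairs$subject],
      weight = hits$weight[pairs$query]
    ) |>
      group_by(.data$repeat_family) |>
      summarise(score_sum = sum(.data$weight), .groups = "drop")
  } else {
    scores <- tibble(repeat_family = character(), score_sum = numeric())
  }
  out <- left_join(fam, scores, by = "repeat_family")
  out$score_sum[is.na(out$score_sum)] <- 0
  out$expression <- out$score_sum /
    ((total_mapped_reads / 1e6) * out$mean_length_kb)
  structure(arrange(out, .data$repeat_family),
            class = c("epigerm_famexpr", class(out)),
            total_mapped_reads = total_mapped_reads)
}

#' Fold change of family expression between two samples
#'
#' `(case + pseudo) / (control + pseudo)`; the pseudo-expression keeps
#' ratios defined when a family is silent in one sample and is recorded in
#' the output attribute `pseudo`.
#'
#' @param case,control [family_expression()] tibbles.
#' @param pseudo Pseudo-expression added to both (default 1e-3).
#' @return Tibble `repeat_family`, `expression_case`, `expression_control`,
#'   `fold_change`.
#' @export
expression_ratio <- function(case, control, pseudo = 1e-3) {
  joined <- inner_join(
    tibble(repeat_family = case$repeat_family, expression_case = case$expression),
    tibble(repeat_family = control$repeat_family,
           expression_control = control$expression),
    by = "repeat_family"
  )
  joined$fold_change <- (joined$expression_case + pseudo) /
    (joined$expression_control + pseudo)
  attr(joined, "pseudo") <- pseudo
  joined
}

#' Reads per kilobase per million mapped reads
#'
#' `count / (exonic kb x mapped millions)`, for uniquely mapping reads.
#' Vectorized over features.
#'
#' @param count Unique-read count per feature.
#' @param length_bp Feature (exonic) length in bp.
#' @param total_mapped Library size (uniquely mapped reads).
#' @return Numeric RPKM values.
#' @export
rpkm <- function(count, length_bp, total_mapped) {
  stopifnot(all(length_bp > 0), total_mapped > 0)
  count / ((length_bp / 1000) * (total_mapped / 1e6))
}

#' Methylation profile along repeat consensus sequences
#'
#' Pools bisulfite calls from reads aligned uniquely to a consensus
#' "microgenome" and reports #C/(#C+#T) at every CG-context cytosine of each
#' consensus. Positions before `min_skip` are flagged `plot_excluded` (kept
#' in the data, omitted from plots, since element starts often have low
#' coverage). For elements named in `average_orientations` (LTRs whose read
#' orientation is ambiguous) the profile is averaged with its own reverse
#' complement by pooling counts of each CG with its mirror CG at position
#' `L - 1 - pos` on the opposite strand.
#'
#' @param alignments Bisulfite alignment tibble (`chrom` = consensus name,
#'   `pos`, `strand`, `seq`), uniquely mapping.
#' @param consensus Named character vector of consensus sequences.
#' @param min_skip Leading bases flagged for plot exclusion (default 50).
#' @param average_orientations Character vector of element names to
#'   orientation-average. For these, calls are first collapsed to CpG-dyad
#'   coordinates (the plus-strand C position of each CG), each dyad is
#'   pooled with its mirror dyad at `L - 2 - pos`, and strand is reported
#'   as `*`.
#' @return Tibble `element_name`, `pos`, `strand`, `level`, `coverage`,
#'   `plot_excluded`.
#' @export
consensus_meth_profile <- function(alignments, consensus, min_skip = 50,
                                   average_orientations = character()) {
  calls <- extract_methylation(alignments, consensus)
  calls <- calls[calls$context == "CG", ]
  no_cg <- setdiff(names(consensus), unique(calls$chrom))
  if (length(no_cg) > 0 && nrow(alignments) > 0) {
    warn(paste0("consensus_meth_profile: no CG calls for: ",
                paste(no_cg, collapse = ", ")))
  }
  out <- tibble(
    element_name = calls$chrom, pos = calls$pos, strand = calls$strand,
    mc = calls$count_methylated, uc = calls$count_unmethylated
  )
  for (el in intersect(average_orientations, unique(out$element_name))) {
    L <- nchar(consensus[[el]])
    sel <- out$element_name == el
    # collapse to CpG-dyad coordinates (plus-strand C of each CG), then
    # pool every dyad with its reverse-complement partner at L - 2 - pos
    x <- mutate(out[sel, ],
                pos = if_else(.data$strand == "-", .data$pos - 1L, .data$pos),
                strand = "*")
    mirror <- mutate(x, pos = L - 2L - .data$pos)
    pooled <- bind_rows(x, mirror) |>
      group_by(.data$element_name, .data$pos, .data$strand) |>
      summarise(mc = sum(.data$mc), uc = sum(.data$uc), .groups = "drop")
    out <- bind_rows(out[!sel, ], pooled)
  }
  out <- out |>
    mutate(level = .data$mc / (.data$mc + .data$uc),
           coverage = .data$mc + .data$uc,
           plot_excluded = .data$pos < min_skip) |>
    select("element_name", "pos", "strand", "level", "coverage",
           "plot_excluded") |>
    arrange(.data$element_name, .data$pos)
  out
}
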