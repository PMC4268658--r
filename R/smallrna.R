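# Small-RNA classification: size gate, random-subset majority-vote
# annotation with a fixed tie-break hierarchy, sense/antisense orientation,
# and the 1U/10A primary/secondary piRNA signature.

default_hierarchy <- c("exon", "intron", "transposon", "other_repeat",
                       "intergenic")

#' Size class of small-RNA reads
#'
#' Reads longer than 24 nt are piRNA candidates; 19-24 nt reads are the
#' putative-miRNA size class (the gel-excised small-RNA window starts at
#' 19 nt); everything else is `other`.
#'
#' @param length Integer read lengths (vectorized).
#' @return Character vector in
#'   `{piRNA_candidate, miRNA_sized, other}`.
#' @export
classify_size <- function(length) {
  dplyr::case_when(
    length > 24 ~ "piRNA_candidate",
    length >= 19 ~ "miRNA_sized",
    TRUE ~ "other"
  )
}

#' Primary/secondary ping-pong signature
#'
#' A piRNA candidate with U (T in DNA space) at position 1 from the 5' end is
#' primary; otherwise A at position 10 makes it secondary; otherwise it is
#' unclassified. Reads carrying both signatures are called primary (1U
#' precedence, the convention of ping-pong analyses); set
#' `precedence = "10A"` for the symmetric alternative. Non-candidates get
#' `NA`.
#'
#' @param seq Read sequences, 5' to 3' (vectorized).
#' @param size_class Size classes from [classify_size()].
#' @param precedence `"1U"` (default) or `"10A"`.
#' @return Character vector in `{primary, secondary, unclassified, NA}`.
#' @export
ping_pong_class <- function(seq, size_class, precedence = c("1U", "10A")) {
  precedence <- match.arg(precedence)
  u1 <- substr(seq, 1, 1) == "T"
  a10 <- substr(seq, 10, 10) == "A"
  cls <- if (precedence == "1U") {
    dplyr::case_when(u1 ~ "primary", a10 ~ "secondary", TRUE ~ "unclassified")
  } else {
    dplyr::case_when(a10 ~ "secondary", u1 ~ "primary", TRUE ~ "unclassified")
  }
  n_both <- sum(u1 & a10 & size_class == "piRNA_candidate")
  if (n_both > 0) {
    inform(sprintf(
      "ping_pong_class: %d read(s) carry both 1U and 10A; %s precedence applied",
      n_both, precedence))
  }
  ifelse(size_class == "piRNA_candidate", cls, NA_character_)
}

# annotate one read's alignments: returns c(category, orientation)
annotate_one <- function(cat, feat_strand, read_strand, k, hierarchy) {
  n <- length(cat)
  pick <- if (n > k) sample.int(n, k) else seq_len(n)
  cat <- cat[pick]
  feat_strand <- feat_strand[pick]
  read_strand <- read_strand[pick]
  tab <- table(cat)
  winners <- names(tab)[tab == max(tab)]
  category <- hierarchy[min(match(winners, hierarchy))]
  on_cat <- cat == category & !is.na(feat_strand)
  if (!any(on_cat)) return(c(category, "ambiguous"))
  sense <- read_strand[on_cat] == feat_strand[on_cat]
  orientation <- if (sum(sense) > sum(!sense)) {
    "sense"
  } else if (sum(sense) < sum(!sense)) {
    "antisense"
  } else {
    "ambiguous"
  }
  c(category, orientation)
}

#' Annotate small-RNA reads by majority vote over sampled alignments
#'
#' Each alignment is annotated by the feature overlapping its 5'-most base
#' (ties among overlapping features resolved by the hierarchy); alignments
#' hitting nothing are `intergenic`. For a read with more than `k`
#' alignments, `k` are sampled without replacement under the seed; the
#' strict majority category wins, ties break by the fixed hierarchy.
#' Orientation (sense iff read strand equals feature strand) is the majority
#' over the sampled alignments carrying the winning category; ties and
#' intergenic winners are `ambiguous`. Reads with no alignments are excluded
#' with a message.
#'
#' @param alignments Alignment tibble (`read_id`, `chrom`, `pos`, `strand`,
#'   `length`).
#' @param features Feature tibble (`chrom`, `start`, `end`, `strand`,
#'   `category` using the hierarchy vocabulary).
#' @param seed Integer seed for the alignment subsampling.
#' @param k Alignments sampled per read (default 10).
#' @param hierarchy Tie-break order, most to least preferred.
#' @param reads Optional reads tibble (`read_id`, ...) used to detect and
#'   report alignment-less reads.
#' @return Tibble `read_id`, `category`, `orientation`.
#' @export
annotate_reads <- function(alignments, features, seed = 1, k = 10,
                           hierarchy = default_hierarchy, reads = NULL) {
  stopifnot(all(features$category %in% hierarchy))
  if (!is.null(reads)) {
    n_lost <- sum(!reads$read_id %in% alignments$read_id)
    if (n_lost > 0) {
      inform(sprintf("annotate_reads: excluded %d read(s) with no alignments",
                     n_lost))
    }
  }
  if (nrow(alignments) == 0) {
    return(tibble(read_id = character(), category = character(),
                  orientation = character()))
  }
  pts <- tibble(chrom = alignments$chrom, start = five_prime_pos(alignments))
  pts$end <- pts$start + 1L
  pairs <- overlap_pairs(pts, features)
  aln_cat <- rep("intergenic", nrow(alignments))
  aln_fstrand <- rep(NA_character_, nrow(alignments))
  if (nrow(pairs) > 0) {
    # several features can cover one 5' base: prefer by hierarchy
    rank <- match(features$category[pairs$subject], hierarchy)
    pairs <- pairs[order(pairs$query, rank), ]
    pairs <- pairs[!duplicated(pairs$query), ]
    aln_cat[pairs$query] <- features$category[pairs$subject]
    aln_fstrand[pairs$query] <- features$strand[pairs$subject]
  }
  ord <- order(alignments$read_id)
  by_read <- split(ord, alignments$read_id[ord])
  res <- with_substream(seed, "annotate_reads", {
    vapply(by_read, function(ix) {
      annotate_one(aln_cat[ix], aln_fstrand[ix], alignments$strand[ix],
                   k, hierarchy)
    }, character(2))
  })
  tibble(read_id = names(by_read), category = unname(res[1, ]),
         orientation = unname(res[2, ]))
}

#' Full per-read small-RNA call table
#'
#' Combines [classify_size()], [annotate_reads()] and [ping_pong_class()]
#' into one call tibble.
#'
#' @param reads Tibble with `read_id`, `seq`.
#' @param alignments Alignment tibble for those reads.
#' @param features Annotation features (see [annotate_reads()]).
#' @inheritParams annotate_reads
#' @return Tibble `read_id`, `length`, `size_class`, `category`,
#'   `orientation`, `ping_pong`.
#' @export
classify_smallrna <- function(reads, alignments, features, seed = 1, k = 10,
                              hierarchy = default_hierarchy) {
  ann <- annotate_reads(alignments, features, seed = seed, k = k,
                        hierarchy = hierarchy, reads = reads)
  out <- inner_join(reads[, c("read_id", "seq")], ann, by = "read_id")
  out$length <- nchar(out$seq)
  out$size_class <- classify_size(out$length)
  out$ping_pong <- suppressMessages(
    ping_pong_class(out$seq, out$size_class))
  select(out, "read_id", "length", "size_class", "category", "orientation",
         "ping_pong")
}

#' Summary ratios of a small-RNA call table
#'
#' The three headline ratios of a piRNA population: piRNA candidates over
#' miRNA-sized reads, and sense/antisense and primary/secondary among piRNA
#' candidates. A zero denominator yields `NA` with a warning.
#'
#' @param calls Call tibble from [classify_smallrna()].
#' @return A one-row tibble of class `epigerm_smallrna_summary` with
#'   `pirna_over_mirna`, `sense_over_antisense`, `primary_over_secondary`
#'   and the underlying counts.
#' @export
summary_ratios <- function(calls) {
  ratio <- function(num, den, what) {
    if (den == 0) {
      warn(paste0("summary_ratios: ", what, " undefined (zero denominator)"))
      return(NA_real_)
    }
    num / den
  }
  pi <- calls[calls$size_class == "piRNA_candidate", ]
  n_pi <- nrow(pi)
  n_mi <- sum(calls$size_class == "miRNA_sized")
  n_sense <- sum(pi$orientation == "sense")
  n_anti <- sum(pi$orientation == "antisense")
  n_pri <- sum(pi$ping_pong == "primary")
  n_sec <- sum(pi$ping_pong == "secondary")
  out <- tibble(
    pirna_over_mirna = ratio(n_pi, n_mi, "piRNA/miRNA"),
    sense_over_antisense = ratio(n_sense, n_anti, "sense/antisense"),
    primary_over_secondary = ratio(n_pri, n_sec, "primary/secondary"),
    n_pirna = n_pi, n_mirna = n_mi, n_sense = n_sense, n_antisense = n_anti,
    n_primary = n_pri, n_secondary = n_sec
  )
  structure(out, class = c("epigerm_smallrna_summary", class(out)))
}
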