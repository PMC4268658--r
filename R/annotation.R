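# Overlap statistics between region sets (DMRs, controls) and genomic
# features, and TSS-window gene association.

#' Fraction of query regions overlapping each feature class
#'
#' A query counts as overlapping a class when it shares at least one basepair
#' with any feature of that class (region-level counting: several features of
#' one class under one query still count once). Combined classes (e.g.
#' "LTR or LINE") count a query once if it overlaps any member class.
#'
#' @param queries Interval tibble.
#' @param features Interval tibble with a class column.
#' @param class_col Name of the feature-class column (default
#'   `"repeat_class"`, falling back to `"category"` / `"class"` if absent).
#' @param combine Optional named list of character vectors; each entry adds a
#'   combined class, e.g. `list(LTR_or_LINE = c("LTR", "LINE"))`.
#' @return Tibble `class`, `n_overlapping`, `fraction`, `n_queries`.
#' @export
overlap_fraction <- function(queries, features, class_col = NULL,
                             combine = NULL) {
  validate_intervals(queries, "queries")
  validate_intervals(features, "features")
  if (is.null(class_col)) {
    class_col <- intersect(c("repeat_class", "category", "class"),
                           names(features))[1]
    if (is.na(class_col)) abort("overlap_fraction: no feature class column")
  }
  classes <- sort(unique(features[[class_col]]))
  pairs <- overlap_pairs(queries, features)
  pair_class <- features[[class_col]][pairs$subject]
  nq <- nrow(queries)
  one <- function(cls_members, label) {
    hit <- unique(pairs$query[pair_class %in% cls_members])
    tibble(class = label, n_overlapping = length(hit),
           fraction = if (nq > 0) length(hit) / nq else NA_real_,
           n_queries = nq)
  }
  out <- bind_rows(purrr::map(classes, function(cl) one(cl, cl)))
  if (!is.null(combine)) {
    combined <- purrr::map2(combine, names(combine),
                            function(members, label) one(members, label))
    out <- bind_rows(out, bind_rows(unname(combined)))
  }
  out
}

#' Genes whose TSS lies within a window of any region
#'
#' Distance is from the single-base TSS to the nearest region edge,
#' unstranded: 0 when the TSS falls inside a region, otherwise the gap in
#' bp. A gene is associated when its minimum TSS distance over all its
#' transcripts and all regions is at most `window`.
#'
#' @param regions Interval tibble.
#' @param transcripts Transcript tibble with `gene_id`, `transcript_id`,
#'   `chrom`, `tss`.
#' @param window Association window in bp (default 1000).
#' @return Tibble of associated transcripts: `gene_id`, `transcript_id`,
#'   `chrom`, `tss`, `distance`, `status` (`inside` / `within_window`).
#' @export
genes_near_regions <- function(regions, transcripts, window = 1000) {
  validate_intervals(regions, "regions")
  if (nrow(transcripts) == 0 || nrow(regions) == 0) {
    return(tibble(gene_id = character(), transcript_id = character(),
                  chrom = character(), tss = integer(), distance = integer(),
                  status = character()))
  }
  win <- tibble(chrom = transcripts$chrom,
                start = pmax(0L, transcripts$tss - as.integer(window)),
                end = transcripts$tss + as.integer(window) + 1L)
  pairs <- overlap_pairs(win, regions)
  if (nrow(pairs) == 0) return(genes_near_regions(regions, transcripts[0, ], window))
  tss <- transcripts$tss[pairs$query]
  rs <- regions$start[pairs$subject]
  re <- regions$end[pairs$subject]
  dist <- pmax(0L, pmax(rs - tss, tss - (re - 1L)))
  out <- tibble(
    gene_id = transcripts$gene_id[pairs$query],
    transcript_id = transcripts$transcript_id[pairs$query],
    chrom = transcripts$chrom[pairs$query],
    tss = tss, distance = dist
  ) |>
    filter(.data$distance <= window) |>
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$tss) |>
    summarise(distance = min(.data$distance), .groups = "drop") |>
    mutate(status = if_else(.data$distance == 0L, "inside", "within_window")) |>
    arrange(.data$gene_id, .data$transcript_id)
  out
}

#' Feature-class overlap enrichment of DMRs relative to controls
#'
#' Computes [overlap_fraction()] for the DMR and control sets and reports the
#' per-class fraction ratio. A class absent under controls gives an `NA`
#' ratio with a warning.
#'
#' @param dmrs,controls Interval tibbles.
#' @param features Feature tibble with a class column.
#' @inheritParams overlap_fraction
#' @return Tibble `class`, `fraction_dmr`, `fraction_control`, `ratio`.
#' @export
enrichment_vs_controls <- function(dmrs, controls, features,
                                   class_col = NULL, combine = NULL) {
  fd <- overlap_fraction(dmrs, features, class_col, combine)
  fc <- overlap_fraction(controls, features, class_col, combine)
  out <- inner_join(
    tibble(class = fd$class, fraction_dmr = fd$fraction),
    tibble(class = fc$class, fraction_control = fc$fraction),
    by = "class"
  )
  out$ratio <- ifelse(out$fraction_control > 0,
                      out$fraction_dmr / out$fraction_control, NA_real_)
  if (any(is.na(out$ratio))) {
    warn("enrichment_vs_controls: ratio undefined for class(es) with zero control overlap")
  }
  out
}
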