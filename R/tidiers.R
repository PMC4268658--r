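# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a DMR call result
#'
#' @param x An `epigerm_dmr` object from [call_dmrs()].
#' @param ... Unused.
#' @return The per-bin DMR tibble without the class attributes.
#' @method tidy epigerm_dmr
#' @export
tidy.epigerm_dmr <- function(x, ...) {
  as_tibble(unclass_keep(x))
}

#' One-row summary of a DMR call result
#'
#' @param x An `epigerm_dmr` object.
#' @param ... Unused.
#' @return Tibble with tested-bin and per-direction DMR counts and the
#'   calling parameters.
#' @method glance epigerm_dmr
#' @export
glance.epigerm_dmr <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    n_tested = attr(x, "n_tested"),
    n_dmrs = nrow(x),
    n_hypo = sum(x$direction == "hypo"),
    n_hyper = sum(x$direction == "hyper"),
    delta_min = p$delta_min, fdr_max = p$fdr_max,
    min_cg = p$min_cg, min_cov = p$min_cov, bin_width = p$bin_width
  )
}

#' Tidy a coverage profile into long format
#'
#' @param x An `epigerm_profile` from [normalized_coverage()].
#' @param ... Unused.
#' @return Tibble `region_id`, `offset`, `rpm`.
#' @method tidy epigerm_profile
#' @export
tidy.epigerm_profile <- function(x, ...) {
  profile_to_tsv(x)
}

#' One-row summary of a coverage profile
#'
#' @param x An `epigerm_profile`.
#' @param ... Unused.
#' @return Tibble with dimensions, total RPM in the profiled windows and the
#'   window parameters.
#' @method glance epigerm_profile
#' @export
glance.epigerm_profile <- function(x, ...) {
  tibble(
    n_regions = nrow(x$matrix), n_bins = ncol(x$matrix),
    total_rpm = sum(x$matrix), anchor = x$anchor,
    flank = x$flank, binsize = x$binsize, library_size = x$library_size
  )
}

#' Tidy a family-expression result
#'
#' @param x An `epigerm_famexpr` from [family_expression()].
#' @param ... Unused.
#' @return The per-family tibble.
#' @method tidy epigerm_famexpr
#' @export
tidy.epigerm_famexpr <- function(x, ...) {
  as_tibble(unclass_keep(x))
}

#' One-row summary of a family-expression result
#'
#' @param x An `epigerm_famexpr`.
#' @param ... Unused.
#' @return Tibble with family count, total fractional score and library
#'   size.
#' @method glance epigerm_famexpr
#' @export
glance.epigerm_famexpr <- function(x, ...) {
  tibble(
    n_families = nrow(x),
    total_score = sum(x$score_sum),
    total_mapped_reads = attr(x, "total_mapped_reads")
  )
}

# drop the package's head class but keep the tibble classes
unclass_keep <- function(x) {
  class(x) <- setdiff(class(x),
                      c("epigerm_dmr", "epigerm_famexpr",
                        "epigerm_smallrna_summary"))
  x
}
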