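# End-to-end orchestration on synthetic or user data: simulate a study,
# then run methylome -> DMR -> controls -> annotation, repeat expression,
# small RNA, and chromatin profiles, writing provenance-stamped TSVs.

pkg_version <- function() {
  as.character(utils::packageVersion("epigerm"))
}

write_tsv_prov <- function(df, path, hash, seed) {
  header <- c(
    paste0("# epigerm ", pkg_version()),
    paste0("# config_hash ", hash),
    paste0("# seed ", seed)
  )
  readr::write_lines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read a provenance-stamped pipeline TSV
#'
#' @param path File path.
#' @return A tibble (provenance header lines skipped).
#' @export
read_pipeline_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Default study-simulation parameters
#'
#' Desk-scale study conditions: a 2 x 250-kb genome at 20% repeat density,
#' pooled case/control bisulfite data at 20x mean coverage with baseline CpG
#' methylation 0.85 and planted hypomethylated bins at `delta` 0.7 (1% of
#' bins hypo, plus two hyper bins), RNA reads over four repeat families with
#' two families upregulated 5x in the case, a small-RNA population with the
#' [pirna_params()] signature fractions, and ATAC/ChIP reads enriched over
#' the planted hypomethylated bins (DMRs are open, transcribed promoters in
#' this design).
#'
#' @return Named list of simulation parameters.
#' @export
sim_study_params <- function() {
  list(
    n_chroms = 2, chrom_length = 250000, repeat_density = 0.2,
    bin_width = 500, n_hypo_bins = 10, n_hyper_bins = 2,
    mean_coverage = 20, baseline_mCG = 0.85, delta = 0.7,
    rna_expression_case = c(L1Md = 25000, L1Alt = 5000, ERVK10 = 12000,
                            B1Sine = 3000),
    rna_expression_control = c(L1Md = 5000, L1Alt = 5000, ERVK10 = 2400,
                               B1Sine = 3000),
    n_rna_reads = 8000, rrna_fraction = 0.05,
    pirna = pirna_params(), n_smallrna_reads = 20000,
    n_atac_fragments = 5000, atac_background = 0.2,
    chip_fold = 5, n_chip_reads = 10000, chip_dup_rate = 0.1
  )
}

# small-RNA annotation features from the simulated genome: repeat copies of
# mobile classes are transposons, everything else repeat-like is
# other_repeat, gene spans are exons
study_features <- function(repeats, transcripts) {
  bind_rows(
    tibble(chrom = repeats$chrom, start = repeats$start, end = repeats$end,
           strand = repeats$strand,
           category = if_else(repeats$repeat_class %in%
                                c("LINE", "LTR", "SINE"),
                              "transposon", "other_repeat")),
    tibble(chrom = transcripts$chrom, start = transcripts$start,
           end = transcripts$end, strand = transcripts$strand,
           category = "exon")
  )
}

#' Simulate a complete synthetic study to disk
#'
#' Generates a genome, annotations, case/control methylomes with planted
#' DMR bins, RNA/small-RNA/ATAC/ChIP read sets and truth files, all under
#' one root seed, into `dir` using the formats the pipeline readers consume.
#'
#' @param dir Output directory (created if missing).
#' @param seed Root seed.
#' @param params Parameter list as from [sim_study_params()].
#' @return `dir`, invisibly; files are listed in the return attribute
#'   `files`.
#' @export
simulate_study <- function(dir, seed, params = sim_study_params()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- params
  sim <- sim_genome(seed, n_chroms = p$n_chroms,
                    chrom_length = p$chrom_length,
                    repeat_density = p$repeat_density)
  bins <- tile_bins(sim$chrom_sizes, width = p$bin_width)
  planted <- with_substream(seed, "plant_bins", {
    ix <- sample.int(nrow(bins), p$n_hypo_bins + p$n_hyper_bins)
    list(hypo = bins[ix[seq_len(p$n_hypo_bins)], ],
         hyper = bins[ix[p$n_hypo_bins + seq_len(p$n_hyper_bins)], ])
  })
  meth <- sim_methylome(sim$genome, seed, planted_hypo = planted$hypo,
                        planted_hyper = planted$hyper,
                        mean_coverage = p$mean_coverage,
                        baseline_mCG = p$baseline_mCG, delta = p$delta)
  rrna <- with_substream(seed, "rrna_ref", {
    setNames(c(random_dna(1800), random_dna(350)), c("rRNA_large", "rRNA_small"))
  })
  rna_case <- sim_rna(sim, p$rna_expression_case,
                      substream_seed(seed, "rna_case"),
                      n_reads = p$n_rna_reads,
                      rrna_fraction = p$rrna_fraction,
                      rrna_sequences = rrna)
  rna_ctrl <- sim_rna(sim, p$rna_expression_control,
                      substream_seed(seed, "rna_control"),
                      n_reads = p$n_rna_reads,
                      rrna_fraction = p$rrna_fraction,
                      rrna_sequences = rrna)
  feats <- study_features(sim$repeats, sim$transcripts)
  sm <- sim_smallrna(p$pirna, feats[feats$category == "transposon", ],
                     seed, n_reads = p$n_smallrna_reads)
  atac <- sim_atac(planted$hypo, sim$chrom_sizes, seed,
                   n_fragments = p$n_atac_fragments,
                   background_rate = p$atac_background)
  chip <- sim_chip(planted$hypo, sim$chrom_sizes, seed,
                   fold = p$chip_fold, n_reads = p$n_chip_reads,
                   dup_rate = p$chip_dup_rate)
  fp <- function(x) file.path(dir, x)
  write_fasta(sim$genome, fp("genome.fa"))
  write_fasta(sim$consensus, fp("consensus.fa"))
  write_fasta(rrna, fp("rrna.fa"))
  write_repeat_table(sim$repeats, fp("repeats.tsv"))
  write_transcripts(sim$transcripts, fp("transcripts.tsv"))
  write_cytosine_report(meth$case, fp("meth_case.tsv"))
  write_cytosine_report(meth$control, fp("meth_control.tsv"))
  readr::write_tsv(rna_case$reads, fp("rna_case_reads.tsv"), progress = FALSE)
  readr::write_tsv(rna_ctrl$reads, fp("rna_control_reads.tsv"), progress = FALSE)
  write_alignments(rna_case$alignments, fp("rna_case_alignments.tsv"))
  write_alignments(rna_ctrl$alignments, fp("rna_control_alignments.tsv"))
  readr::write_tsv(sm$reads, fp("smallrna_reads.tsv"), progress = FALSE)
  write_alignments(sm$alignments, fp("smallrna_alignments.tsv"))
  write_alignments(atac$alignments, fp("atac_alignments.tsv"))
  write_alignments(chip$alignments, fp("chip_alignments.tsv"))
  write_bed(planted$hypo[, c("chrom", "start", "end")], fp("truth_hypo.bed"))
  write_bed(planted$hyper[, c("chrom", "start", "end")], fp("truth_hyper.bed"))
  readr::write_tsv(
    tibble(repeat_family = names(p$rna_expression_case),
           expression_case = unname(p$rna_expression_case),
           expression_control = unname(p$rna_expression_control)),
    fp("truth_family_expression.tsv"), progress = FALSE)
  readr::write_tsv(
    tibble(param = names(unlist(p$pirna)), value = unlist(p$pirna)),
    fp("truth_pirna_params.tsv"), progress = FALSE)
  invisible(structure(dir, files = list.files(dir)))
}

#' Assemble and validate a pipeline configuration
#'
#' @param input_dir Directory holding the study inputs (as written by
#'   [simulate_study()]).
#' @param out_dir Output directory for result TSVs.
#' @param seed Root seed for the pipeline's own random steps (control-region
#'   sampling, small-RNA alignment subsampling).
#' @param dmr [dmr_params()] list.
#' @param smallrna_k Alignments sampled per small-RNA read.
#' @param hierarchy Small-RNA annotation tie-break hierarchy.
#' @param flank,binsize Profile window half-width and bin size (bp).
#' @param level_tol Control-region methylation matching tolerance.
#' @return A list of class `epigerm_config`.
#' @export
pipeline_config <- function(input_dir, out_dir, seed = 1,
                            dmr = dmr_params(), smallrna_k = 10,
                            hierarchy = default_hierarchy,
                            flank = 2000, binsize = 50, level_tol = 0.05) {
  required <- c("genome.fa", "consensus.fa", "rrna.fa", "repeats.tsv",
                "transcripts.tsv", "meth_case.tsv", "meth_control.tsv",
                "rna_case_reads.tsv", "rna_control_reads.tsv",
                "rna_case_alignments.tsv", "rna_control_alignments.tsv",
                "smallrna_reads.tsv", "smallrna_alignments.tsv",
                "atac_alignments.tsv", "chip_alignments.tsv")
  missing <- required[!file.exists(file.path(input_dir, required))]
  if (length(missing) > 0) {
    abort(paste0("pipeline_config: missing input file(s): ",
                 paste(missing, collapse = ", ")))
  }
  structure(
    list(input_dir = input_dir, out_dir = out_dir, seed = seed, dmr = dmr,
         smallrna_k = smallrna_k, hierarchy = hierarchy, flank = flank,
         binsize = binsize, level_tol = level_tol),
    class = "epigerm_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — methylome summaries, DMR
#' calling, matched control sampling, feature-overlap annotation; repeat
#' expression and case/control ratios; consensus methylation profiles;
#' small-RNA classification and summary ratios; ATAC cut-site correction,
#' ChIP deduplication and DMR-anchored profiles — and writes each result as
#' a TSV stamped with the package version, a configuration hash and the
#' seed. Reruns with an identical configuration produce byte-identical
#' outputs.
#'
#' @param config An [pipeline_config()] object.
#' @return Invisibly, a named list of the in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "epigerm_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- fnv1a32(paste(deparse(config[setdiff(names(config), "out_dir")]),
                        collapse = ""))
  seed <- config$seed
  inp <- function(x) file.path(config$input_dir, x)
  outp <- function(x) file.path(config$out_dir, x)
  emit <- function(df, name) write_tsv_prov(df, outp(name), hash, seed)
  res <- list()

  # --- methylome ---------------------------------------------------------
  genome <- read_fasta(inp("genome.fa"))
  chrom_sizes <- vapply(genome, nchar, integer(1))
  meth_case <- read_cytosine_report(inp("meth_case.tsv"))
  meth_ctrl <- read_cytosine_report(inp("meth_control.tsv"))
  res$genome_level <- tibble(
    genotype = c("case", "control"),
    cg_level = c(genome_level(meth_case, "CG"),
                 genome_level(meth_ctrl, "CG"))
  )
  emit(res$genome_level, "genome_methylation.tsv")
  bins <- tile_bins(chrom_sizes, width = config$dmr$bin_width)
  case_bins <- aggregate_bins(meth_case, bins, min_cov = config$dmr$min_cov)
  ctrl_bins <- aggregate_bins(meth_ctrl, bins, min_cov = config$dmr$min_cov)

  # --- DMRs, controls, annotation ---------------------------------------
  res$dmrs <- call_dmrs(case_bins, ctrl_bins, config$dmr)
  emit(as_tibble(res$dmrs), "dmrs.tsv")
  write_bed(mutate(as_tibble(res$dmrs), name = .data$bin_id),
            outp("dmrs.bed"), score_field = "q")
  # control regions and enrichment follow the hypomethylated DMR set, the
  # set whose feature overlap is benchmarked against matched controls
  hypo <- filter(as_tibble(res$dmrs), .data$direction == "hypo")
  res$controls <- sample_control_regions(
    hypo, ctrl_bins, config$dmr,
    seed = substream_seed(seed, "pipeline_controls"),
    level_tol = config$level_tol)
  emit(res$controls, "controls.tsv")
  repeats <- read_repeat_table(inp("repeats.tsv"))
  transcripts <- read_transcripts(inp("transcripts.tsv"))
  res$enrichment <- enrichment_vs_controls(
    hypo, res$controls, repeats, class_col = "repeat_class",
    combine = list(LTR_or_LINE = c("LTR", "LINE")))
  emit(res$enrichment, "dmr_feature_enrichment.tsv")
  res$dmr_genes <- genes_near_regions(res$dmrs, transcripts, window = 1000)
  emit(res$dmr_genes, "dmr_genes.tsv")

  # --- repeat expression -------------------------------------------------
  rrna <- read_fasta(inp("rrna.fa"))
  quant <- function(which) {
    reads <- readr::read_tsv(inp(paste0("rna_", which, "_reads.tsv")),
                             show_col_types = FALSE, progress = FALSE)
    aln <- read_alignments(inp(paste0("rna_", which, "_alignments.tsv")))
    kept <- suppressMessages(filter_rrna(reads, rrna))
    aln <- aln[aln$read_id %in% kept$read_id, ]
    hits <- suppressMessages(fractional_weights(aln))
    family_expression(hits, repeats,
                      total_mapped_reads = length(unique(hits$read_id)))
  }
  fe_case <- quant("case")
  fe_ctrl <- quant("control")
  res$family_expression <- fe_case
  emit(as_tibble(fe_case), "family_expression_case.tsv")
  emit(as_tibble(fe_ctrl), "family_expression_control.tsv")
  res$expression_ratio <- expression_ratio(fe_case, fe_ctrl)
  emit(res$expression_ratio, "family_expression_ratio.tsv")

  # --- consensus methylation profile ------------------------------------
  consensus <- read_fasta(inp("consensus.fa"))
  cons_reads <- sim_consensus_bs(consensus,
                                 substream_seed(seed, "consensus_reads"))
  res$consensus_profile <- suppressMessages(
    consensus_meth_profile(cons_reads, consensus))
  emit(res$consensus_profile, "consensus_methylation.tsv")

  # --- small RNA ---------------------------------------------------------
  sm_reads <- readr::read_tsv(inp("smallrna_reads.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  sm_aln <- read_alignments(inp("smallrna_alignments.tsv"))
  feats <- study_features(repeats, transcripts)
  res$smallrna_calls <- suppressMessages(classify_smallrna(
    sm_reads, sm_aln, feats,
    seed = substream_seed(seed, "pipeline_smallrna"),
    k = config$smallrna_k, hierarchy = config$hierarchy))
  emit(res$smallrna_calls, "smallrna_calls.tsv")
  res$smallrna_summary <- suppressMessages(
    summary_ratios(res$smallrna_calls))
  emit(as_tibble(res$smallrna_summary), "smallrna_summary.tsv")

  # --- chromatin profiles -----------------------------------------------
  atac <- read_alignments(inp("atac_alignments.tsv"))
  atac <- suppressMessages(deduplicate(atac))
  cuts <- suppressWarnings(shift_cut_sites(atac))
  res$atac_profile <- normalized_coverage(
    cuts, as_tibble(res$dmrs), anchor = "midpoint",
    flank = config$flank, binsize = config$binsize)
  emit(profile_to_tsv(res$atac_profile), "atac_dmr_profile.tsv")
  res$atac_abundance <- bind_rows(
    mutate(region_abundance(cuts, as_tibble(res$dmrs),
                            library_size = nrow(cuts))[, c("chrom", "start", "end", "n_reads", "rpm")],
           set = "dmr"),
    mutate(region_abundance(cuts, res$controls,
                            library_size = nrow(cuts))[, c("chrom", "start", "end", "n_reads", "rpm")],
           set = "control")
  )
  emit(res$atac_abundance, "atac_dmr_abundance.tsv")
  chip <- read_alignments(inp("chip_alignments.tsv"))
  chip <- suppressMessages(deduplicate(chip))
  res$chip_profile <- normalized_coverage(
    chip, as_tibble(res$dmrs), anchor = "midpoint",
    flank = config$flank, binsize = config$binsize)
  emit(profile_to_tsv(res$chip_profile), "chip_dmr_profile.tsv")

  invisible(res)
}

# long-format TSV rendering of a profile matrix
profile_to_tsv <- function(profile) {
  m <- profile$matrix
  tibble(
    region_id = rep(rownames(m), times = ncol(m)),
    offset = rep(profile$offsets, each = nrow(m)),
    rpm = as.vector(m)
  ) |>
    arrange(.data$region_id, .data$offset)
}
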