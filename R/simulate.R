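# Seeded synthetic genomes, annotations and read sets with known ground
# truth. The generators emit exactly the tabular schemas the readers in
# io.R consume, so every downstream stage can be scored without external
# data. All draws are wrapped in named substreams of one root seed.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(s)) < rate)
  if (length(hit) > 0) {
    subst <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
    s[hit] <- vapply(s[hit], function(b) sample(subst[[b]], 1), character(1))
  }
  paste(s, collapse = "")
}

#' Simulate a genome with repeat copies, genes and consensus sequences
#'
#' Background sequence is uniform random DNA. Each repeat family gets a
#' consensus sequence; genomic copies are the consensus with point mutations
#' (default 2%, enough to exercise both unique mapping and <=2-mismatch
#' consensus mapping) pasted at non-overlapping positions until the requested
#' repeat density is reached. Gene models are placed in repeat-free space.
#' Deterministic given the seed.
#'
#' @param seed Root seed.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (>= 10,000 bp).
#' @param repeat_density Target fraction of the genome covered by repeats,
#'   in \[0, 1).
#' @param families Tibble describing families (`repeat_family`,
#'   `repeat_class`, `length`); defaults to two LINE-like, one LTR-like and
#'   one SINE-like family.
#' @param mutation_rate Per-base substitution rate when copying a consensus
#'   into the genome (default 0.02).
#' @param n_genes Gene models to place (default 20).
#' @param gene_length Gene span in bp (default 2000).
#' @return List with `genome` (named character), `repeats` (repeat tibble),
#'   `transcripts`, `consensus` (named character), `chrom_sizes`.
#' @export
sim_genome <- function(seed, n_chroms = 2, chrom_length = 1e5,
                       repeat_density = 0.2, families = NULL,
                       mutation_rate = 0.02, n_genes = 20,
                       gene_length = 2000) {
  stopifnot(chrom_length >= 10000, repeat_density >= 0, repeat_density < 1)
  if (is.null(families)) {
    families <- tibble(
      repeat_family = c("L1Md", "L1Alt", "ERVK10", "B1Sine"),
      repeat_class = c("LINE", "LINE", "LTR", "SINE"),
      length = c(3000L, 2500L, 1500L, 300L)
    )
  }
  with_substream(seed, "genome", {
    chroms <- paste0("chr", seq_len(n_chroms))
    seqs <- setNames(
      vapply(chroms, function(x) random_dna(chrom_length), character(1)),
      chroms)
    consensus <- setNames(
      vapply(families$length, random_dna, character(1)),
      families$repeat_family)
    target <- repeat_density * n_chroms * chrom_length
    placed <- 0
    rows <- list()
    occ <- lapply(setNames(chroms, chroms), function(x) integer(0))
    guard <- 0
    # seed one copy of every family first so each is represented, then fill
    # randomly until the target density is reached
    pending <- if (repeat_density > 0) seq_len(nrow(families)) else integer(0)
    while ((repeat_density > 0 && placed < target) || length(pending) > 0) {
      guard <- guard + 1
      if (guard > 50 * (target / mean(families$length) + nrow(families) + 1)) {
        abort("sim_genome: repeat density unattainable without overlaps")
      }
      fi <- if (length(pending) > 0) {
        pending[1]
      } else {
        sample.int(nrow(families), 1)
      }
      L <- families$length[fi]
      ch <- sample(chroms, 1)
      start <- sample.int(chrom_length - L, 1) - 1L
      block_lo <- start %/% 1000L
      block_hi <- (start + L) %/% 1000L
      if (any((block_lo:block_hi) %in% occ[[ch]])) next
      occ[[ch]] <- c(occ[[ch]], block_lo:block_hi)
      copy <- mutate_sequence(consensus[[families$repeat_family[fi]]],
                              mutation_rate)
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "-") {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(copy)))
      } else {
        copy
      }
      substr(seqs[[ch]], start + 1L, start + L) <- ins
      rows[[length(rows) + 1]] <- tibble(
        chrom = ch, start = start, end = start + L, strand = strand,
        repeat_name = paste0(families$repeat_family[fi], "_c", length(rows) + 1),
        repeat_class = families$repeat_class[fi],
        repeat_family = families$repeat_family[fi]
      )
      placed <- placed + L
      if (length(pending) > 0) pending <- pending[-1]
    }
    repeats <- if (length(rows) > 0) {
      arrange(bind_rows(rows), .data$chrom, .data$start)
    } else {
      tibble(chrom = character(), start = integer(), end = integer(),
             strand = character(), repeat_name = character(),
             repeat_class = character(), repeat_family = character())
    }
    # genes in repeat-free space: sample directly from the gap list so
    # placement stays cheap even on dense genomes
    gaps <- bind_rows(purrr::map(chroms, function(ch) {
      r <- repeats[repeats$chrom == ch, ]
      bounds <- sort(c(0L, r$start, r$end, chrom_length))
      tibble(chrom = ch,
             start = bounds[seq(1, length(bounds), by = 2)],
             end = bounds[seq(2, length(bounds), by = 2)])
    }))
    gaps <- gaps[gaps$end - gaps$start >= gene_length, ]
    genes <- list()
    while (length(genes) < n_genes && nrow(gaps) > 0) {
      gi <- sample.int(nrow(gaps), 1)
      room <- gaps$end[gi] - gaps$start[gi] - gene_length
      gstart <- gaps$start[gi] +
        if (room > 0) sample.int(room + 1L, 1) - 1L else 0L
      genes[[length(genes) + 1]] <- tibble(
        chrom = gaps$chrom[gi], start = gstart, end = gstart + gene_length,
        strand = sample(c("+", "-"), 1))
      # split the used gap so genes never overlap each other
      left <- tibble(chrom = gaps$chrom[gi], start = gaps$start[gi],
                     end = gstart)
      right <- tibble(chrom = gaps$chrom[gi], start = gstart + gene_length,
                      end = gaps$end[gi])
      gaps <- bind_rows(gaps[-gi, ], left, right)
      gaps <- gaps[gaps$end - gaps$start >= gene_length, ]
    }
    transcripts <- if (length(genes) > 0) {
      g <- bind_rows(genes)
      g$gene_id <- sprintf("gene%03d", seq_len(nrow(g)))
      g$transcript_id <- paste0(g$gene_id, ".1")
      mutate(arrange(g, .data$chrom, .data$start),
             tss = if_else(.data$strand == "-", .data$end - 1L, .data$start))
    } else {
      tibble(chrom = character(), start = integer(), end = integer(),
             strand = character(), gene_id = character(),
             transcript_id = character(), tss = integer())
    }
    list(genome = seqs, repeats = repeats, transcripts = transcripts,
         consensus = consensus,
         chrom_sizes = setNames(rep(chrom_length, n_chroms), chroms))
  })
}

#' Simulate case/control pooled bisulfite methylomes with planted DMRs
#'
#' Per-cytosine coverage is Poisson with mean `mean_coverage`; methylated
#' counts are binomial given coverage. All cytosines share `baseline_mCG`
#' (CG context; non-CG contexts use `baseline_mCH` when `contexts = "all"`),
#' except inside planted bins: hypo bins lower the case methylation
#' probability to `baseline_mCG - delta` (floored at 0 unless `floor_at_zero`
#' is `FALSE`, in which case a negative probability is an error) and hyper
#' bins lower the control probability by the same amount, so the case sits
#' `+delta` above control. Sites drawing zero coverage are omitted, as a
#' mapper would omit them.
#'
#' @param genome Named character vector of chromosome sequences (e.g. from
#'   [sim_genome()]).
#' @param seed Root seed.
#' @param planted_hypo,planted_hyper Interval tibbles of planted bins
#'   (aligned to the tiling used downstream); `NULL` for none.
#' @param mean_coverage Mean per-cytosine read coverage.
#' @param baseline_mCG Baseline CG methylation probability.
#' @param delta Planted methylation difference.
#' @param baseline_mCH Baseline non-CG methylation (default 0.03).
#' @param contexts `"CG"` (default) or `"all"`.
#' @param floor_at_zero Floor `baseline - delta` at 0 (default `TRUE`).
#' @param cytosines Optional precomputed [find_cytosines()] table, to avoid
#'   rescanning the genome across replicate simulations.
#' @return List with `case` and `control` cytosine tibbles and `truth`
#'   (planted bins and the parameters).
#' @export
sim_methylome <- function(genome, seed, planted_hypo = NULL,
                          planted_hyper = NULL, mean_coverage = 20,
                          baseline_mCG = 0.85, delta = 0.7,
                          baseline_mCH = 0.03, contexts = c("CG", "all"),
                          floor_at_zero = TRUE, cytosines = NULL) {
  contexts <- match.arg(contexts)
  stopifnot(baseline_mCG >= 0, baseline_mCG <= 1, delta >= 0, delta <= 1)
  if (!floor_at_zero && baseline_mCG - delta < 0) {
    abort("sim_methylome: baseline_mCG - delta < 0 with flooring disabled")
  }
  cy <- cytosines %||% find_cytosines(genome, contexts = contexts)
  empty <- cy[0, ]
  empty$count_methylated <- integer(0)
  empty$count_unmethylated <- integer(0)
  if (mean_coverage == 0) {
    return(list(case = empty, control = empty,
                truth = list(planted_hypo = planted_hypo,
                             planted_hyper = planted_hyper,
                             baseline_mCG = baseline_mCG, delta = delta,
                             seed = seed)))
  }
  base_p <- ifelse(cy$context == "CG", baseline_mCG, baseline_mCH)
  in_set <- function(set) {
    flag <- logical(nrow(cy))
    if (!is.null(set) && nrow(set) > 0) {
      pts <- tibble(chrom = cy$chrom, start = cy$pos, end = cy$pos + 1L)
      flag[unique(overlap_pairs(pts, set)$query)] <- TRUE
    }
    flag
  }
  hypo <- in_set(planted_hypo)
  hyper <- in_set(planted_hyper)
  p_case <- base_p
  p_case[hypo & cy$context == "CG"] <-
    max(0, baseline_mCG - delta)
  p_ctrl <- base_p
  p_ctrl[hyper & cy$context == "CG"] <-
    max(0, baseline_mCG - delta)
  draw <- function(p, stream) {
    with_substream(seed, stream, {
      cov <- rpois(nrow(cy), mean_coverage)
      mc <- rbinom(nrow(cy), cov, p)
      keep <- cov > 0
      out <- cy[keep, ]
      out$count_methylated <- mc[keep]
      out$count_unmethylated <- cov[keep] - mc[keep]
      out
    })
  }
  list(
    case = draw(p_case, "methylome_case"),
    control = draw(p_ctrl, "methylome_control"),
    truth = list(planted_hypo = planted_hypo, planted_hyper = planted_hyper,
                 baseline_mCG = baseline_mCG, delta = delta, seed = seed)
  )
}

#' Simulate multi-mapped RNA-seq alignments over repeat families
#'
#' `n_reads` is the library size. Each family contributes
#' `Poisson(expression * mean_length_kb * n_reads / 1e6)` reads from its
#' genomic copies, so the family-expression statistic (score / (mapped
#' millions x kb)) recovers the planted level in absolute units; the
#' remaining reads are background transcription placed uniquely in
#' repeat-free space. A `multimap_fraction` of repeat reads map to the
#' homologous offset in every copy of their family (`n_hits` = copy
#' number); the rest map uniquely. Optionally a fraction of additional
#' reads are drawn from rRNA references (no genomic placements), to
#' exercise the rRNA filter.
#'
#' @param sim Genome list from [sim_genome()].
#' @param family_expression Named numeric vector: planted expression level
#'   per repeat family, in reads per kb per million mapped reads.
#' @param seed Root seed.
#' @param n_reads Library size (repeat + background reads, before rRNA
#'   contamination).
#' @param read_length Read length (default 50).
#' @param multimap_fraction Fraction of repeat reads mapping to all family
#'   copies (default 0.5).
#' @param rrna_fraction Fraction of additional rRNA reads (default 0).
#' @param rrna_sequences Named character rRNA references (required when
#'   `rrna_fraction > 0`).
#' @return List with `reads` (read_id, seq, is_rrna), `alignments` (one row
#'   per placement, with `n_hits`), and `truth`.
#' @export
sim_rna <- function(sim, family_expression, seed, n_reads = 10000,
                    read_length = 50, multimap_fraction = 0.5,
                    rrna_fraction = 0, rrna_sequences = NULL) {
  repeats <- sim$repeats
  fams <- names(family_expression)
  stopifnot(all(fams %in% repeats$repeat_family))
  fam_len <- repeats |>
    group_by(.data$repeat_family) |>
    summarise(len_kb = mean(.data$end - .data$start) / 1000, .groups = "drop")
  w <- family_expression *
    fam_len$len_kb[match(fams, fam_len$repeat_family)]
  with_substream(seed, "rna", {
    n_fam_reads <- rpois(length(fams), w * n_reads / 1e6)
    if (sum(n_fam_reads) > n_reads) {
      abort("sim_rna: planted expression exceeds the library size")
    }
    n_total_repeat <- sum(n_fam_reads)
    fam_of_read <- rep(fams, n_fam_reads)
    multi <- runif(n_total_repeat) < multimap_fraction
    copies_by_fam <- split(seq_len(nrow(repeats)), repeats$repeat_family)
    ids <- sprintf("r%06d", seq_len(n_reads))
    seqs <- character(n_reads)
    aln <- vector("list", length(fams))
    for (fi in seq_along(fams)) {
      f <- fams[fi]
      rix <- which(fam_of_read == f)
      if (length(rix) == 0) next
      copies <- copies_by_fam[[f]]
      nc <- length(copies)
      L <- repeats$end[copies[1]] - repeats$start[copies[1]]
      off <- sample.int(L - read_length, length(rix), replace = TRUE) - 1L
      is_multi <- multi[rix]
      # multi-mapping reads place at the homologous offset in every copy
      n_place <- ifelse(is_multi, nc, 1L)
      place <- integer(sum(n_place))
      place[rep(is_multi, n_place)] <- rep(copies, sum(is_multi))
      place[rep(!is_multi, n_place)] <-
        copies[sample.int(nc, sum(!is_multi), replace = TRUE)]
      ridx <- rep(rix, n_place)
      roff <- rep(off, n_place)
      aln[[fi]] <- tibble(
        read_id = ids[ridx],
        chrom = repeats$chrom[place],
        pos = repeats$start[place] + roff,
        strand = repeats$strand[place],
        length = read_length, mismatches = 0L,
        n_hits = rep(n_place, n_place)
      )
      first <- ifelse(is_multi, copies[1],
                      place[cumsum(n_place) - n_place + 1L])
      seqs[rix] <- substring(
        sim$genome[repeats$chrom[first]],
        repeats$start[first] + off + 1L,
        repeats$start[first] + off + read_length)
    }
    # background transcription: unique reads in repeat-free space
    n_bg <- n_reads - n_total_repeat
    if (n_bg > 0) {
      chroms <- names(sim$genome)
      clen <- vapply(sim$genome, nchar, integer(1))
      bg_chrom <- character(0)
      bg_pos <- integer(0)
      while (length(bg_pos) < n_bg) {
        need <- n_bg - length(bg_pos)
        ch <- sample(chroms, 2 * need + 10, replace = TRUE)
        p0 <- floor(runif(length(ch)) * (clen[ch] - read_length))
        cand <- tibble(chrom = ch, start = as.integer(p0),
                       end = as.integer(p0) + read_length)
        if (nrow(repeats) > 0) {
          bad <- unique(overlap_pairs(cand, repeats)$query)
          if (length(bad) > 0) cand <- cand[-bad, ]
        }
        take <- head(seq_len(nrow(cand)), need)
        bg_chrom <- c(bg_chrom, cand$chrom[take])
        bg_pos <- c(bg_pos, cand$start[take])
      }
      bg_ix <- n_total_repeat + seq_len(n_bg)
      aln[[length(aln) + 1]] <- tibble(
        read_id = ids[bg_ix], chrom = bg_chrom, pos = bg_pos,
        strand = sample(c("+", "-"), n_bg, replace = TRUE),
        length = read_length, mismatches = 0L, n_hits = 1L
      )
      seqs[bg_ix] <- substring(sim$genome[bg_chrom], bg_pos + 1L,
                               bg_pos + read_length)
    }
    aln <- arrange(bind_rows(aln), .data$read_id)
    reads <- tibble(read_id = ids, seq = seqs, is_rrna = FALSE)
    if (rrna_fraction > 0) {
      stopifnot(!is.null(rrna_sequences))
      n_rrna <- round(n_reads * rrna_fraction / (1 - rrna_fraction))
      rref <- unname(rrna_sequences[
        sample.int(length(rrna_sequences), n_rrna, replace = TRUE)])
      roff <- vapply(nchar(rref) - read_length,
                     function(m) sample.int(m, 1), integer(1))
      reads <- bind_rows(reads, tibble(
        read_id = sprintf("rr%06d", seq_len(n_rrna)),
        seq = substr(rref, roff + 1L, roff + read_length),
        is_rrna = TRUE
      ))
    }
    list(reads = reads, alignments = bind_rows(aln),
         truth = list(family_expression = family_expression, seed = seed,
                      multimap_fraction = multimap_fraction))
  })
}

#' piRNA population parameters
#'
#' Defaults are chosen to emulate an E16.5 germline small-RNA population:
#' the long (>24 nt) fraction, 5'-U fraction, position-10-A fraction and
#' sense fraction reproduce piRNA/miRNA = 0.55, primary/secondary = 4.43 and
#' sense/antisense = 1.34 in expectation.
#'
#' @param frac_long P(length > 24).
#' @param u1 P(first base is T).
#' @param a10 P(tenth base is A), independent of `u1`.
#' @param sense_fraction P(read strand equals feature strand).
#' @return Named list.
#' @export
pirna_params <- function(frac_long = 0.55 / 1.55, u1 = 0.75,
                         a10 = 0.75 / (4.43 * 0.25),
                         sense_fraction = 1.34 / 2.34) {
  p <- list(frac_long = frac_long, u1 = u1, a10 = a10,
            sense_fraction = sense_fraction)
  stopifnot(all(unlist(p) >= 0), all(unlist(p) <= 1))
  p
}

#' Simulate a small-RNA read population with controlled signatures
#'
#' Lengths: >24 nt with probability `frac_long` (25-30 uniform), otherwise
#' 19-24 uniform. The first base is T with probability `u1`; the tenth is A
#' with probability `a10` (independently). Each read gets one alignment
#' placed uniformly inside a random feature, on the feature strand with
#' probability `sense_fraction`.
#'
#' @param params [pirna_params()] list.
#' @param features Feature tibble (`chrom`, `start`, `end`, `strand`,
#'   `category`) reads are placed into.
#' @param seed Root seed.
#' @param n_reads Number of reads.
#' @return List with `reads` (`read_id`, `seq`), `alignments`, and `truth`
#'   (the parameters).
#' @export
sim_smallrna <- function(params, features, seed, n_reads = 20000) {
  stopifnot(nrow(features) > 0)
  with_substream(seed, "smallrna", {
    long <- runif(n_reads) < params$frac_long
    len <- ifelse(long, sample(25:30, n_reads, replace = TRUE),
                  sample(19:24, n_reads, replace = TRUE))
    base1 <- ifelse(runif(n_reads) < params$u1, "T",
                    sample(c("A", "C", "G"), n_reads, replace = TRUE))
    base10 <- ifelse(runif(n_reads) < params$a10, "A",
                     sample(c("C", "G", "T"), n_reads, replace = TRUE))
    seqs <- vapply(len, random_dna, character(1))
    substr(seqs, 1, 1) <- base1
    substr(seqs, 10, 10) <- base10
    fi <- sample.int(nrow(features), n_reads, replace = TRUE)
    width <- features$end[fi] - features$start[fi]
    pos <- features$start[fi] +
      floor(runif(n_reads) * pmax(1, width - len))
    sense <- runif(n_reads) < params$sense_fraction
    flip <- c("+" = "-", "-" = "+")
    strand <- ifelse(sense, features$strand[fi],
                     flip[features$strand[fi]])
    ids <- sprintf("s%06d", seq_len(n_reads))
    list(
      reads = tibble(read_id = ids, seq = seqs),
      alignments = tibble(read_id = ids, chrom = features$chrom[fi],
                          pos = as.integer(pos), strand = unname(strand),
                          length = len, mismatches = 0L, n_hits = 1L),
      truth = c(params, list(seed = seed, n_reads = n_reads))
    )
  })
}

#' Simulate ATAC-seq fragments concentrated in open regions
#'
#' Each fragment yields two Tn5 cut sites `c1 < c2`; reads are emitted so
#' that the standard +4/-5 correction recovers the cut sites exactly (plus
#' read leftmost = c1 - 4, minus read rightmost = c2 + 5). With probability
#' `1 - background_rate` both cut sites lie inside a random open region;
#' otherwise the fragment is placed uniformly on the genome.
#'
#' @param open_regions Interval tibble of accessible regions.
#' @param chrom_sizes Named chromosome lengths.
#' @param seed Root seed.
#' @param n_fragments Number of fragments.
#' @param background_rate Fraction of background fragments.
#' @param read_length Read length (default 50).
#' @return List with `alignments` (two reads per fragment), `truth`
#'   (fragment cut sites and their open/background label).
#' @export
sim_atac <- function(open_regions, chrom_sizes, seed, n_fragments = 5000,
                     background_rate = 0.1, read_length = 50) {
  with_substream(seed, "atac", {
    bg <- runif(n_fragments) < background_rate
    d <- sample(60:150, n_fragments, replace = TRUE)
    chrom <- character(n_fragments)
    c1 <- integer(n_fragments)
    ri <- sample.int(nrow(open_regions), n_fragments, replace = TRUE)
    for (i in seq_len(n_fragments)) {
      if (!bg[i]) {
        r <- ri[i]
        room <- open_regions$end[r] - open_regions$start[r] - d[i] - 1L
        if (room < 1) room <- 1L
        chrom[i] <- open_regions$chrom[r]
        c1[i] <- open_regions$start[r] + sample.int(room, 1) - 1L
      } else {
        chrom[i] <- sample(names(chrom_sizes), 1)
        c1[i] <- sample.int(chrom_sizes[[chrom[i]]] - d[i] - read_length - 10L,
                            1) + read_length
      }
    }
    c2 <- c1 + d
    ids <- sprintf("f%06d", seq_len(n_fragments))
    alignments <- bind_rows(
      tibble(read_id = ids, chrom = chrom, pos = c1 - 4L, strand = "+",
             length = read_length, mismatches = 0L, n_hits = 1L),
      tibble(read_id = ids, chrom = chrom,
             pos = c2 + 5L - read_length + 1L, strand = "-",
             length = read_length, mismatches = 0L, n_hits = 1L)
    )
    list(alignments = arrange(alignments, .data$read_id),
         truth = tibble(read_id = ids, chrom = chrom, cut1 = c1, cut2 = c2,
                        background = bg))
  })
}

#' Simulate ChIP-seq reads with fold enrichment and duplicates
#'
#' Unique read positions fall inside enriched regions with the probability
#' implied by `fold` enrichment of per-bp density over background; exact
#' duplicates are then added at rate `dup_rate` by resampling unique reads,
#' so the distinct-key count is known truth for deduplication.
#'
#' @param enriched_regions Interval tibble.
#' @param chrom_sizes Named chromosome lengths.
#' @param seed Root seed.
#' @param fold Per-bp density fold enrichment (1 = none).
#' @param n_reads Total reads including duplicates.
#' @param dup_rate Fraction of reads that are duplicates of another read.
#' @param read_length Read length (default 50).
#' @return List with `alignments` and `truth` (`n_unique` distinct keys).
#' @export
sim_chip <- function(enriched_regions, chrom_sizes, seed, fold = 5,
                     n_reads = 10000, dup_rate = 0.1, read_length = 50) {
  stopifnot(fold >= 1, dup_rate >= 0, dup_rate < 1)
  with_substream(seed, "chip", {
    area <- sum(enriched_regions$end - enriched_regions$start)
    gsize <- sum(unlist(chrom_sizes))
    frac <- area / gsize
    p_enr <- fold * frac / (fold * frac + (1 - frac))
    n_unique <- max(1L, round(n_reads * (1 - dup_rate)))
    enr <- runif(n_unique) < p_enr
    chrom <- character(n_unique)
    pos <- integer(n_unique)
    n_enr <- sum(enr)
    if (n_enr > 0) {
      ri <- sample.int(nrow(enriched_regions), n_enr, replace = TRUE)
      width <- pmax(1L, enriched_regions$end[ri] -
                      enriched_regions$start[ri] - read_length)
      chrom[enr] <- enriched_regions$chrom[ri]
      pos[enr] <- enriched_regions$start[ri] +
        as.integer(floor(runif(n_enr) * width))
    }
    # background reads live strictly outside the enriched regions, so the
    # in-region density ratio equals the requested fold
    n_bg <- n_unique - n_enr
    bg_chrom <- character(0)
    bg_pos <- integer(0)
    while (length(bg_pos) < n_bg) {
      need <- n_bg - length(bg_pos)
      ch <- sample(names(chrom_sizes), 2 * need + 10, replace = TRUE)
      p0 <- as.integer(floor(runif(length(ch)) *
                               (unlist(chrom_sizes)[ch] - read_length)))
      cand <- tibble(chrom = ch, start = p0, end = p0 + 1L)
      bad <- unique(overlap_pairs(cand, enriched_regions)$query)
      if (length(bad) > 0) cand <- cand[-bad, ]
      take <- head(seq_len(nrow(cand)), need)
      bg_chrom <- c(bg_chrom, cand$chrom[take])
      bg_pos <- c(bg_pos, cand$start[take])
    }
    chrom[!enr] <- bg_chrom
    pos[!enr] <- bg_pos
    strand <- sample(c("+", "-"), n_unique, replace = TRUE)
    uniq <- tibble(chrom = chrom, pos = pos, strand = strand)
    uniq <- uniq[!duplicated(paste(uniq$chrom, uniq$pos, uniq$strand)), ]
    n_dup <- round(n_reads * dup_rate)
    dups <- uniq[sample.int(nrow(uniq), n_dup, replace = TRUE), ]
    all <- bind_rows(uniq, dups)
    all$read_id <- sprintf("c%06d", seq_len(nrow(all)))
    all$length <- read_length
    all$mismatches <- 0L
    all$n_hits <- 1L
    list(
      alignments = all[, c("read_id", "chrom", "pos", "strand", "length",
                           "mismatches", "n_hits")],
      truth = list(n_unique = nrow(uniq), fold = fold, dup_rate = dup_rate)
    )
  })
}

#' Simulate bisulfite reads over consensus sequences with a planted profile
#'
#' Emits plus-strand reads tiled across each consensus; at each CG cytosine
#' the read shows C with the probability given by `level_fun(pos, length)`
#' (default: a 5' hypomethylation gradient rising from `low` to `high`),
#' and non-CG cytosines are always converted (read T).
#'
#' @param consensus Named character vector of consensus sequences.
#' @param seed Root seed.
#' @param coverage Reads per start position spacing (mean coverage ~
#'   coverage).
#' @param read_length Read length (default 50).
#' @param level_fun Function of (position, consensus length) returning the
#'   methylation probability; default linear 5'-low gradient.
#' @param low,high Gradient endpoints for the default `level_fun`.
#' @return Alignment tibble with `seq` suitable for
#'   [consensus_meth_profile()].
#' @export
sim_consensus_bs <- function(consensus, seed, coverage = 10,
                             read_length = 50, level_fun = NULL,
                             low = 0.1, high = 0.9) {
  if (is.null(level_fun)) {
    level_fun <- function(pos, L) low + (high - low) * pos / L
  }
  with_substream(seed, "consensus_bs", {
    out <- purrr::map(names(consensus), function(el) {
      S <- consensus[[el]]
      L <- nchar(S)
      if (L < read_length) return(NULL)
      step <- max(1L, round(read_length / coverage))
      starts <- seq.int(0L, L - read_length, by = step)
      purrr::map(starts, function(p0) {
        ref <- strsplit(substr(S, p0 + 1L, p0 + read_length), "")[[1]]
        nxt <- c(ref[-1], substr(S, p0 + read_length + 1L,
                                 p0 + read_length + 1L))
        rd <- ref
        is_c <- ref == "C"
        is_cg <- is_c & nxt == "G"
        p_meth <- level_fun(p0 + which(is_c) - 1L, L)
        meth <- runif(sum(is_c)) < ifelse(is_cg[is_c], p_meth, 0)
        rd[which(is_c)[!meth]] <- "T"
        tibble(read_id = paste0(el, "_", p0), chrom = el, pos = p0,
               strand = "+", length = read_length, mismatches = 0L,
               n_hits = 1L, seq = paste(rd, collapse = ""))
      })
    })
    bind_rows(purrr::flatten(out))
  })
}
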