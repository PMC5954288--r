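#' Pipeline configuration with standard thresholds
#'
#' Collects every tunable threshold of the workflow in one flat list.
#' Defaults are the standard analysis values: sRNA QC drops reads with
#' more than 5 nucleotides below Q25; inserts of 18-30 nt are kept;
#' homolog search allows 2 mismatches; hairpin candidates use 80/130/180
#' nt flanks and novel-candidate loci a 300-nt extension; novel hairpins
#' need >= 18 duplex pairs and energy < -40 kcal/mol; phasing windows
#' have m = 10 cycles (210/240 nt), are extended 100 bp, and loci need
#' phase score > 5, corrected P < 0.05 and >= 4 unique phasiRNAs;
#' clusters chain loci < 2000 bp apart; expression filters are 5 RPTM in
#' >= 2 libraries with sd >= 1. Unknown keys are rejected.
#'
#' @param ... Overrides of the default values.
#' @return A `phasr_config` list.
#' @export
phasr_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_dir = "phasr_out",
    # preprocess
    qc_min_q = 25L, qc_max_low = 5L,
    insert_min = 18L, insert_max = 30L,
    adapter = "TGGAATTCTCGGGTGCCAAGG",
    degradome_min_q = 20L,
    # miRNA discovery
    homolog_max_mismatch = 2L,
    flanks = c(80L, 130L, 180L),
    novel_extension = 300L,
    min_paired = 18L, max_energy = -40,
    mature_only_max_mismatch = 2L,
    # PHAS detection
    phase_lengths = c(21L, 24L), m = 10L,
    window_alpha = 0.05, window_extend = 100L, fdr_method = "BH",
    score_threshold = 5, q_threshold = 0.05, min_unique = 4L,
    cluster_gap = 2000L,
    # targets
    conserved_max_mismatch = 4, gu_penalty = 0.5,
    tas3_flank = 250L, tas3_max_mismatch = 2L,
    # expression
    rptm_min = 5, rptm_min_libraries = 2L, rptm_min_sd = 1,
    pca_min_mean = 5)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "phasr_config")
}

#' Run a pipeline stage on a synthetic study
#'
#' Orchestrates the simulate -> preprocess -> map -> detect workflow on
#' the synthetic study defined by the configuration seed, writing each
#' stage's artifacts under `config$out_dir` together with a JSON run
#' manifest recording the seed and every threshold.
#'
#' @param stage One of `"simulate"`, `"preprocess"`, `"phas"`, `"all"`.
#' @param config A [phasr_config()].
#' @param sim Optional simulation (list with `reference`, `truth`) to
#'   reuse; by default a small two-locus study is generated from
#'   `config$seed`.
#' @return A list of in-memory results; artifacts are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "preprocess", "phas"),
                         config = phasr_config(), sim = NULL) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "phasr_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(unclass(config), manifest, auto_unbox = TRUE,
                       digits = NA)
  if (is.null(sim)) {
    cfg <- sim_config(
      seed = config$seed, chrom_length = 20000L,
      phas_plan = data.frame(
        phase_length = 21L, cycles = 10L, chrom = "Chr1",
        start = c(5001L, 12001L), strand = "+", abundance = 3,
        noise_rate = 0.1),
      library_plan = data.frame(library_id = "L1", depth = 1000L,
                                background_rate = 0.3))
    sim <- make_genome(cfg)
    sim$config <- cfg
  }
  res <- list(sim = sim)
  write_fasta(sim$reference$sequences,
              file.path(config$out_dir, "genome.fa"))
  write_ground_truth(sim$truth, config$out_dir)
  if (stage == "simulate") return(invisible(res))

  reads <- simulate_srna_library(sim$reference, sim$truth,
                                 library_id = "L1", depth = 1000L,
                                 background_rate = 0.3)
  write_fastq(reads, file.path(config$out_dir, "srna_L1.fastq"))
  keep <- filter_srna_read(reads, min_q = config$qc_min_q,
                           max_low = config$qc_max_low)
  tags <- collapse_unique(data.frame(library = "L1",
                                     seq = reads$seq[keep],
                                     stringsAsFactors = FALSE))
  utils::write.table(tags, file.path(config$out_dir, "tags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$tags <- tags
  if (stage == "preprocess") return(invisible(res))

  counts <- structure(as.numeric(tags$L1), names = tags$seq)
  aln <- map_tags(tags$seq, sim$reference, max_mismatch = 0L)
  write_alignments_tsv(aln, file.path(config$out_dir, "alignments.tsv"))
  phas <- detect_phas(aln, sim$reference, p = 21L, counts = counts,
                      m = config$m, alpha = config$window_alpha,
                      extend = config$window_extend,
                      fdr_method = config$fdr_method,
                      score_threshold = config$score_threshold,
                      q_threshold = config$q_threshold,
                      min_unique = config$min_unique,
                      gap = config$cluster_gap)
  write_phas_bed(phas$loci, file.path(config$out_dir, "phas_loci.bed"))
  write_phas_gff3(phas$loci, file.path(config$out_dir, "phas_loci.gff3"))
  utils::write.table(phas$loci, file.path(config$out_dir, "phas_loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (NROW(phas$phasirna) > 0L) {
    ps <- phas$phasirna$seq
    names(ps) <- phas$phasirna$name
    write_fasta(ps, file.path(config$out_dir, "phasirna.fa"))
  }
  res$phas <- phas
  invisible(res)
}
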