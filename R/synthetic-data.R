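#' Simulation configuration for synthetic small RNA studies
#'
#' Describes a toy study: a random genome, planted phased siRNA ladders
#' (PHAS loci), planted miRNA hairpins, small RNA libraries and a
#' degradome library. The generator exists so that every pipeline stage
#' can be exercised and calibrated on data with known ground truth.
#'
#' @param seed Integer seed; a fixed seed yields byte-identical outputs.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in nt (at least 2000).
#' @param phas_plan data.frame with columns `phase_length` (21 or 24),
#'   `cycles`, `chrom`, `start`, `strand` (`"+"`, `"-"` or `"both"`),
#'   `abundance` (reads per cycle per library) and `noise_rate`
#'   (off-phase reads as a fraction of phased reads).
#' @param hairpin_plan data.frame with columns `mature` (20-22 nt
#'   sequence), `chrom`, `start`, `strand`, `flank`,
#'   `mature_abundance`, `star_abundance`.
#' @param library_plan data.frame with columns `library_id`, `depth`,
#'   `background_rate`; each library receives
#'   `round(depth * background_rate)` random background reads drawn
#'   uniformly from the genome with lengths sampled from
#'   21:0.35, 22:0.10, 23:0.10, 24:0.45 (mimicking the 21/24-nt length
#'   peaks of real plant sRNA libraries) in addition to the planted reads.
#' @param degradome_plan data.frame with columns `transcript`, `position`,
#'   `count`.
#' @return A `phasr_sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chrom = 1L, chrom_length = 20000L,
                       phas_plan = NULL, hairpin_plan = NULL,
                       library_plan = NULL, degradome_plan = NULL) {
  if (chrom_length < 2000L) stop("chrom_length must be >= 2000")
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 chrom_length = as.integer(chrom_length),
                 phas_plan = phas_plan, hairpin_plan = hairpin_plan,
                 library_plan = library_plan,
                 degradome_plan = degradome_plan),
            class = "phasr_sim_config")
}

# evaluate `code` under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a random genome with planted PHAS loci and hairpins
#'
#' Builds a uniform-random background genome, records the planted phased
#' ladders from `phas_plan` (ladders are intervals of the background
#' sequence from which phased reads will be sampled) and inserts the
#' hairpin precursors from `hairpin_plan` via [plant_hairpin()].
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `reference` (a [reference()]) and `truth`
#'   (a `phasr_ground_truth` list with data.frames `phas` and `hairpins`).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "phasr_sim_config"))
  with_seed(config$seed, {
    seqs <- vapply(seq_len(config$n_chrom),
                   function(i) random_dna(config$chrom_length), character(1))
    names(seqs) <- sprintf("Chr%d", seq_len(config$n_chrom))
    ref <- reference(seqs, name = "synthetic")
    phas <- empty_phas_truth()
    if (!is.null(config$phas_plan) && nrow(config$phas_plan) > 0L) {
      pp <- config$phas_plan
      end <- pp$start + pp$phase_length * pp$cycles - 1L
      for (i in seq_len(nrow(pp))) {
        L <- nchar(ref$sequences[[pp$chrom[i]]])
        if (pp$start[i] < 3L || end[i] > L)
          stop(sprintf("planted PHAS %d at %s:%d-%d outside genome",
                       i, pp$chrom[i], pp$start[i], end[i]))
      }
      phas <- data.frame(chrom = pp$chrom, start = as.integer(pp$start),
                         end = as.integer(end),
                         phase_length = as.integer(pp$phase_length),
                         cycles = as.integer(pp$cycles),
                         strand = pp$strand, abundance = pp$abundance,
                         noise_rate = pp$noise_rate,
                         stringsAsFactors = FALSE)
    }
    hairpins <- empty_hairpin_truth()
    if (!is.null(config$hairpin_plan) && nrow(config$hairpin_plan) > 0L) {
      hp <- config$hairpin_plan
      for (i in seq_len(nrow(hp))) {
        res <- plant_hairpin(ref, hp$mature[i], chrom = hp$chrom[i],
                             start = hp$start[i], strand = hp$strand[i],
                             flank = hp$flank[i])
        ref <- res$reference
        row <- res$hairpin
        row$mature_abundance <- hp$mature_abundance[i]
        row$star_abundance <- hp$star_abundance[i]
        hairpins <- rbind(hairpins, row)
      }
    }
    check_no_overlap(phas, hairpins)
    truth <- structure(list(phas = phas, hairpins = hairpins,
                            seed = config$seed),
                       class = "phasr_ground_truth")
    list(reference = ref, truth = truth)
  })
}

empty_phas_truth <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             phase_length = integer(), cycles = integer(),
             strand = character(), abundance = numeric(),
             noise_rate = numeric(), stringsAsFactors = FALSE)
}

empty_hairpin_truth <- function() {
  data.frame(chrom = character(), precursor_start = integer(),
             precursor_end = integer(), strand = character(),
             mature = character(), star = character(),
             mature_start = integer(), mature_end = integer(),
             star_start = integer(), star_end = integer(),
             mature_abundance = numeric(), star_abundance = numeric(),
             stringsAsFactors = FALSE)
}

check_no_overlap <- function(phas, hairpins) {
  iv <- rbind(
    if (nrow(phas)) data.frame(chrom = phas$chrom, start = phas$start,
                               end = phas$end,
                               id = sprintf("PHAS#%d", seq_len(nrow(phas))),
                               stringsAsFactors = FALSE),
    if (nrow(hairpins)) data.frame(chrom = hairpins$chrom,
                                   start = hairpins$precursor_start,
                                   end = hairpins$precursor_end,
                                   id = sprintf("hairpin#%d",
                                                seq_len(nrow(hairpins))),
                                   stringsAsFactors = FALSE))
  if (is.null(iv) || nrow(iv) < 2L) return(invisible(TRUE))
  iv <- iv[order(iv$chrom, iv$start), ]
  for (i in seq_len(nrow(iv) - 1L)) {
    if (iv$chrom[i] == iv$chrom[i + 1L] && iv$end[i] >= iv$start[i + 1L])
      stop(sprintf("planted features overlap: %s and %s", iv$id[i],
                   iv$id[i + 1L]))
  }
  invisible(TRUE)
}

#' Insert a miRNA hairpin precursor into a genome
#'
#' Writes `mature + 8-nt loop + reverse complement of mature` into the
#' reference at `start`, producing a perfect fold-back stem. The recorded
#' miRNA* spans the 3' arm shifted by two positions so that the
#' mature:star duplex carries the canonical 2-nt 3' overhangs on both
#' ends: for a mature of length L the star sequence equals
#' `revcomp(mature[1..L-2])` followed by the two genomic nucleotides
#' downstream of the arm.
#'
#' @param genome A [reference()].
#' @param mature Mature miRNA sequence, 20-22 nt.
#' @param chrom Chromosome id to plant into.
#' @param start 1-based insertion position of the mature 5' end.
#' @param strand `"+"` or `"-"`; on `"-"` the reverse complement of the
#'   construct is written, so the mature is recovered after
#'   reverse-complementing the locus.
#' @param flank Flanking context (nt) recorded with the precursor
#'   interval; must be non-negative.
#' @return A list with the updated `reference` and a one-row `hairpin`
#'   truth data.frame (coordinates of precursor, mature and star).
#' @export
plant_hairpin <- function(genome, mature, chrom = names(genome$sequences)[1],
                          start = 1000L, strand = "+", flank = 20L) {
  stopifnot(inherits(genome, "phasr_reference"))
  mature <- toupper(chartr("U", "T", mature))
  L <- nchar(mature)
  if (L < 20L || L > 22L) stop("mature must be 20-22 nt")
  if (flank < 0L) stop("flank must be non-negative")
  loop <- "AACAAACA"  # 8-nt loop, weakly pairing
  construct <- paste0(mature, loop, revcomp(mature))
  clen <- nchar(construct)
  s <- genome$sequences[[chrom]]
  Lc <- nchar(s)
  if (start < 3L || start + clen + 1L > Lc)
    stop("hairpin construct does not fit inside the chromosome")
  if (strand == "-") {
    # write the reverse complement of the construct at the same interval
    ins <- revcomp(construct)
  } else ins <- construct
  substr(s, start, start + clen - 1L) <- ins
  genome$sequences[[chrom]] <- s
  # plus-strand geometry (positions relative to construct start):
  # mature [1, L]; 3' arm [L+9, 2L+8]; star [L+11, 2L+10]
  if (strand == "+") {
    m_start <- start; m_end <- start + L - 1L
    s_start <- start + L + 10L; s_end <- start + 2L * L + 9L
    star <- substr(s, s_start, s_end)
  } else {
    # mirror: construct occupies [start, start+clen-1] reverse-complemented
    m_end <- start + clen - 1L; m_start <- m_end - L + 1L
    s_end <- start + clen - 1L - (L + 10L); s_start <- start + clen - 2L * L - 10L
    star <- revcomp(substr(s, s_start, s_end))
  }
  hairpin <- data.frame(chrom = chrom,
                        precursor_start = max(1L, start - as.integer(flank)),
                        precursor_end = min(Lc, start + clen - 1L +
                                              as.integer(flank)),
                        strand = strand, mature = mature, star = star,
                        mature_start = m_start, mature_end = m_end,
                        star_start = s_start, star_end = s_end,
                        mature_abundance = 100, star_abundance = 5,
                        stringsAsFactors = FALSE)
  list(reference = genome, hairpin = hairpin)
}

#' Simulate one small RNA library from planted ground truth
#'
#' Emits, per planted PHAS locus, `abundance` phased reads at each cycle
#' position (plus-strand reads start at the register; minus-strand reads
#' are the duplex partners whose leftmost coordinate plus two equals the
#' plus register), off-phase noise reads at `noise_rate`, mature and star
#' reads for each planted hairpin, and random background reads. Quality
#' strings are constant `"I"` (Phred 40).
#'
#' @param genome A [reference()] from [make_genome()].
#' @param truth Matching `phasr_ground_truth`.
#' @param library_id Library identifier (used in read ids).
#' @param depth Background sampling depth.
#' @param background_rate Fraction of `depth` emitted as background reads.
#' @param adapter Optional 3' adapter sequence appended to every read.
#' @param seed Integer seed for this library; defaults to a value derived
#'   from the ground-truth seed and the library id.
#' @return data.frame of reads (`id`, `seq`, `qual`), writable with
#'   [write_fastq()].
#' @export
simulate_srna_library <- function(genome, truth, library_id = "L1",
                                  depth = 1000L, background_rate = 0.3,
                                  adapter = NULL, seed = NULL) {
  stopifnot(inherits(genome, "phasr_reference"))
  if (is.null(seed))
    seed <- (truth$seed * 1000L +
               sum(utf8ToInt(library_id))) %% 2147483647L
  with_seed(seed, {
    seqs <- character(0)
    labs <- character(0)
    phas <- truth$phas
    for (i in seq_len(NROW(phas))) {
      p <- phas$phase_length[i]
      cyc_pos <- phas$start[i] + (seq_len(phas$cycles[i]) - 1L) * p
      chrseq <- genome$sequences[[phas$chrom[i]]]
      ab <- phas$abundance[i]
      emit_plus <- phas$strand[i] %in% c("+", "both")
      emit_minus <- phas$strand[i] %in% c("-", "both")
      n_phased <- 0L
      if (emit_plus) {
        tags <- substring(chrseq, cyc_pos, cyc_pos + p - 1L)
        seqs <- c(seqs, rep(tags, each = ab))
        n_phased <- n_phased + length(tags) * ab
      }
      if (emit_minus) {
        tags <- revcomp(substring(chrseq, cyc_pos - 2L, cyc_pos + p - 3L))
        seqs <- c(seqs, rep(tags, each = ab))
        n_phased <- n_phased + length(tags) * ab
      }
      labs <- c(labs, rep(sprintf("phas%d", i), n_phased))
      n_noise <- round(phas$noise_rate[i] * n_phased)
      if (n_noise > 0L) {
        off <- sample(seq_len(p - 1L), n_noise, replace = TRUE)
        cyc <- sample(cyc_pos, n_noise, replace = TRUE)
        pos <- pmin(cyc + off, nchar(chrseq) - p + 1L)
        seqs <- c(seqs, substring(chrseq, pos, pos + p - 1L))
        labs <- c(labs, rep(sprintf("phas%d_off", i), n_noise))
      }
    }
    hp <- truth$hairpins
    for (i in seq_len(NROW(hp))) {
      seqs <- c(seqs, rep(hp$mature[i], hp$mature_abundance[i]),
                rep(hp$star[i], hp$star_abundance[i]))
      labs <- c(labs, rep(sprintf("mir%d", i), hp$mature_abundance[i]),
                rep(sprintf("mir%d_star", i), hp$star_abundance[i]))
    }
    n_bg <- round(depth * background_rate)
    if (n_bg > 0L) {
      lens <- sample(c(21L, 22L, 23L, 24L), n_bg, replace = TRUE,
                     prob = c(0.35, 0.10, 0.10, 0.45))
      chroms <- sample(names(genome$sequences), n_bg, replace = TRUE)
      Ls <- nchar(genome$sequences)[chroms]
      pos <- 1L + floor(stats::runif(n_bg) * (Ls - lens))
      bg <- substring(genome$sequences[chroms], pos, pos + lens - 1L)
      flip <- stats::runif(n_bg) < 0.5
      bg[flip] <- revcomp(bg[flip])
      seqs <- c(seqs, bg)
      labs <- c(labs, rep("bg", n_bg))
    }
    if (!is.null(adapter)) seqs <- paste0(seqs, toupper(adapter))
    data.frame(id = sprintf("%s_%s_%d", library_id, labs, seq_along(seqs)),
               seq = seqs,
               qual = strrep("I", nchar(seqs)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a degradome (PARE) library over a transcript set
#'
#' Each planned cleavage site yields `count` tags whose 5' ends start
#' exactly at the cleavage position (length 25 nt or up to the transcript
#' end, never below 20), plus uniform background tags.
#'
#' @param transcripts A [reference()] of transcript sequences.
#' @param plan data.frame with columns `transcript`, `position`, `count`.
#' @param background Number of uniform background tags.
#' @param seed Integer seed.
#' @return data.frame of reads (`id`, `seq`, `qual`).
#' @export
simulate_degradome <- function(transcripts, plan, background = 0L,
                               seed = 1L) {
  stopifnot(inherits(transcripts, "phasr_reference"))
  with_seed(seed, {
    seqs <- character(0)
    if (!is.null(plan) && NROW(plan) > 0L) {
      for (i in seq_len(nrow(plan))) {
        tx <- transcripts$sequences[[plan$transcript[i]]]
        if (is.null(tx)) stop("unknown transcript: ", plan$transcript[i])
        pos <- plan$position[i]
        if (pos < 1L || pos + 20L > nchar(tx) + 1L)
          stop(sprintf("cleavage position %d out of range for %s", pos,
                       plan$transcript[i]))
        len <- min(25L, nchar(tx) - pos + 1L)
        seqs <- c(seqs, rep(substr(tx, pos, pos + len - 1L), plan$count[i]))
      }
    }
    if (background > 0L) {
      ids <- sample(names(transcripts$sequences), background, replace = TRUE)
      Ls <- nchar(transcripts$sequences)[ids]
      pos <- 1L + floor(stats::runif(background) * (Ls - 24L))
      seqs <- c(seqs, substring(transcripts$sequences[ids], pos, pos + 24L))
    }
    data.frame(id = sprintf("deg_%d", seq_along(seqs)),
               seq = seqs, qual = strrep("I", nchar(seqs)),
               stringsAsFactors = FALSE)
  })
}

#' Export planted ground truth as GFF3 and JSON
#'
#' @param truth A `phasr_ground_truth` from [make_genome()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(dir, "truth.gff3")
  rows <- character(0)
  ph <- truth$phas
  for (i in seq_len(NROW(ph)))
    rows <- c(rows, sprintf(
      "%s\tphasr_sim\tPHAS_locus\t%d\t%d\t.\t%s\t.\tID=planted_phas_%d;phase_length=%d",
      ph$chrom[i], ph$start[i], ph$end[i],
      if (ph$strand[i] == "both") "." else ph$strand[i], i,
      ph$phase_length[i]))
  hp <- truth$hairpins
  for (i in seq_len(NROW(hp)))
    rows <- c(rows, sprintf(
      "%s\tphasr_sim\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=planted_mir_%d",
      hp$chrom[i], hp$precursor_start[i], hp$precursor_end[i], hp$strand[i],
      i))
  writeLines(c("##gff-version 3", rows), gff)
  js <- file.path(dir, "truth.json")
  jsonlite::write_json(list(seed = truth$seed, phas = truth$phas,
                            hairpins = truth$hairpins),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(gff, js))
}
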