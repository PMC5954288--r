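# shared fixture builders (all fixtures are generated in code)

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a one-library study with planted 21-nt phased ladders
ladder_study <- function(seed, starts = 5001L, strand = "+", cycles = 10L,
                         abundance = 3, noise_rate = 0.1,
                         chrom_length = 20000L, depth = 1000L,
                         background_rate = 0.3) {
  cfg <- sim_config(
    seed = seed, chrom_length = chrom_length,
    phas_plan = if (length(starts) > 0)
      data.frame(phase_length = 21L, cycles = cycles, chrom = "Chr1",
                 start = starts, strand = strand, abundance = abundance,
                 noise_rate = noise_rate),
    library_plan = data.frame(library_id = "L1", depth = depth,
                              background_rate = background_rate))
  sim <- make_genome(cfg)
  reads <- simulate_srna_library(sim$reference, sim$truth, "L1",
                                 depth = depth,
                                 background_rate = background_rate)
  tags <- collapse_unique(data.frame(library = "L1", seq = reads$seq,
                                     stringsAsFactors = FALSE))
  aln <- map_tags(tags$seq, sim$reference, max_mismatch = 0L)
  counts <- structure(as.numeric(tags$L1), names = tags$seq)
  list(sim = sim, reads = reads, tags = tags, aln = aln, counts = counts)
}

# brute-force all-positions Hamming scan, the mapping oracle
brute_force_map <- function(tags, ref, max_mm) {
  out <- list()
  for (tg in unique(tags)) {
    L <- nchar(tg)
    for (rid in names(ref$sequences)) {
      s <- ref$sequences[[rid]]
      n <- nchar(s)
      if (n < L) next
      sv <- strsplit(s, "")[[1]]
      for (std in c("+", "-")) {
        pat <- strsplit(if (std == "+") tg else revcomp(tg), "")[[1]]
        for (i in seq_len(n - L + 1L)) {
          mm <- sum(sv[i:(i + L - 1L)] != pat)
          if (mm <= max_mm)
            out[[length(out) + 1L]] <-
              data.frame(tag = tg, ref = rid, start = i, strand = std,
                         mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(tag = character(), ref = character(),
                      start = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$ref, res$start, res$strand, res$tag), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# a planted hairpin with expressed mature and star tags
make_hairpin_study <- function(seed = 5, strand = "+", flank = 10L) {
  mature <- rand_dna(21, seed = seed + 100)
  cfg <- sim_config(seed = seed, chrom_length = 4000L,
                    hairpin_plan = data.frame(mature = mature, chrom = "Chr1",
                                              start = 2001L, strand = strand,
                                              flank = flank,
                                              mature_abundance = 100,
                                              star_abundance = 5))
  sim <- make_genome(cfg)
  hp <- sim$truth$hairpins
  pre <- substr(sim$reference$sequences[["Chr1"]], hp$precursor_start,
                hp$precursor_end)
  tags <- data.frame(seq = c(hp$mature, hp$star),
                     start = c(hp$mature_start, hp$star_start) -
                       hp$precursor_start + 1L,
                     count = c(hp$mature_abundance, hp$star_abundance),
                     stringsAsFactors = FALSE)
  list(sim = sim, hp = hp, pre = pre, tags = tags, mature = mature)
}

# detect planted ladders and compute recovery of the planted truth
phas_recovery <- function(study, p = 21L) {
  res <- detect_phas(study$aln, study$sim$reference, p = p,
                     counts = study$counts)
  truth <- study$sim$truth$phas
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(res$loci$ref == truth$chrom[i] &
          res$loci$start <= truth$end[i] &
          res$loci$end >= truth$start[i] &
          res$loci$register == truth$start[i] %% p)
  }, logical(1))
  list(result = res, recovered = hit)
}

# plant `n_sub` substitutions into a sequence at distinct positions
mutate_seq <- function(s, positions) {
  sv <- strsplit(s, "")[[1]]
  for (i in positions) {
    sv[i] <- setdiff(c("A", "C", "G", "T"), sv[i])[1]
  }
  paste(sv, collapse = "")
}
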