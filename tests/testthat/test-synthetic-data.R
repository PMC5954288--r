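test_that("planted ladder occupies the expected interval", {
  cfg <- sim_config(seed = 7, chrom_length = 20000L,
                    phas_plan = data.frame(phase_length = 21L, cycles = 10L,
                                           chrom = "Chr1", start = 5001L,
                                           strand = "+", abundance = 1,
                                           noise_rate = 0))
  sim <- make_genome(cfg)
  expect_equal(sim$truth$phas$start, 5001L)
  expect_equal(sim$truth$phas$end, 5210L)  # 10 cycles x 21 nt
})

test_that("genome generation is byte-deterministic", {
  cfg <- sim_config(seed = 3, chrom_length = 5000L)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(make_genome(cfg)$reference$sequences, f1)
  write_fasta(make_genome(cfg)$reference$sequences, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("features planted outside the genome are rejected", {
  cfg <- sim_config(seed = 1, chrom_length = 2000L,
                    phas_plan = data.frame(phase_length = 21L, cycles = 10L,
                                           chrom = "Chr1", start = 1990L,
                                           strand = "+", abundance = 1,
                                           noise_rate = 0))
  expect_error(make_genome(cfg), "outside genome")
})

test_that("overlapping planted features are rejected by name", {
  cfg <- sim_config(seed = 1, chrom_length = 5000L,
                    phas_plan = data.frame(phase_length = 21L, cycles = 10L,
                                           chrom = "Chr1",
                                           start = c(1001L, 1100L),
                                           strand = "+", abundance = 1,
                                           noise_rate = 0))
  expect_error(make_genome(cfg), "overlap.*PHAS#1.*PHAS#2")
})

test_that("hairpin star has 2-nt 3' overhang duplex geometry", {
  mature <- rand_dna(21, seed = 21)
  cfg <- sim_config(seed = 5, chrom_length = 3000L,
                    hairpin_plan = data.frame(mature = mature, chrom = "Chr1",
                                              start = 1001L, strand = "+",
                                              flank = 10L,
                                              mature_abundance = 50,
                                              star_abundance = 5))
  sim <- make_genome(cfg)
  hp <- sim$truth$hairpins
  expect_equal(substr(hp$star, 1, 19), revcomp(substr(mature, 1, 19)))
  # the planted precursor folds back with at least 18 pairs
  pre <- substr(sim$reference$sequences[["Chr1"]], hp$precursor_start,
                hp$precursor_end)
  expect_gte(fold(pre)$pairs, 18L)
})

test_that("minus-strand hairpin is recovered after reverse-complementing", {
  mature <- rand_dna(21, seed = 22)
  cfg <- sim_config(seed = 6, chrom_length = 3000L,
                    hairpin_plan = data.frame(mature = mature, chrom = "Chr1",
                                              start = 1001L, strand = "-",
                                              flank = 0L,
                                              mature_abundance = 50,
                                              star_abundance = 5))
  sim <- make_genome(cfg)
  hp <- sim$truth$hairpins
  genome_mature <- substr(sim$reference$sequences[["Chr1"]],
                          hp$mature_start, hp$mature_end)
  expect_equal(revcomp(genome_mature), mature)
})

test_that("hairpin planting rejects negative flank", {
  ref <- reference(c(Chr1 = rand_dna(3000, seed = 1)))
  expect_error(plant_hairpin(ref, rand_dna(21, seed = 2), start = 100L,
                             flank = -1L), "non-negative")
})

test_that("phased read counts follow the plan", {
  cfg <- sim_config(seed = 9, chrom_length = 5000L,
                    phas_plan = data.frame(phase_length = 21L, cycles = 10L,
                                           chrom = "Chr1", start = 1001L,
                                           strand = "+", abundance = 5,
                                           noise_rate = 0))
  sim <- make_genome(cfg)
  reads <- simulate_srna_library(sim$reference, sim$truth, "L1", depth = 0,
                                 background_rate = 0)
  expect_equal(nrow(reads), 50L)  # 5 reads x 10 cycles, plus strand only
  # with no noise and no background, every read lies inside the ladder
  starts <- vapply(reads$seq, function(s)
    as.integer(regexpr(s, sim$reference$sequences[["Chr1"]], fixed = TRUE)),
    integer(1))
  expect_true(all(starts >= 1001L & starts + 20L <= 5210L))
})

test_that("library simulation is deterministic for a fixed seed", {
  st <- ladder_study(31)
  r2 <- simulate_srna_library(st$sim$reference, st$sim$truth, "L1",
                              depth = 1000L, background_rate = 0.3)
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  write_fastq(st$reads, f1); write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("degradome simulation plants 5' ends at cleavage positions", {
  tx <- reference(c(t1 = rand_dna(500, seed = 4)))
  plan <- data.frame(transcript = "t1", position = 111L, count = 30L)
  reads <- simulate_degradome(tx, plan, background = 0, seed = 8)
  expect_equal(nrow(reads), 30L)
  expect_true(all(substr(reads$seq, 1, 20) ==
                    substr(tx$sequences[["t1"]], 111, 130)))
  # background only
  bg <- simulate_degradome(tx, NULL, background = 100L, seed = 8)
  expect_equal(nrow(bg), 100L)
  # determinism
  again <- simulate_degradome(tx, plan, background = 0, seed = 8)
  expect_identical(reads, again)
  # out-of-range position
  expect_error(simulate_degradome(
    tx, data.frame(transcript = "t1", position = 490L, count = 1L)),
    "out of range")
})

test_that("ground truth export writes GFF3 and JSON", {
  st <- ladder_study(17)
  d <- tempfile()
  paths <- write_ground_truth(st$sim$truth, d)
  expect_true(all(file.exists(paths)))
  gff <- readLines(paths[1])
  expect_equal(gff[1], "##gff-version 3")
  expect_true(any(grepl("PHAS_locus", gff)))
  js <- jsonlite::read_json(paths[2])
  expect_equal(js$seed, 17L)
})
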