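test_that("find_sites scores perfect, wobble and mismatched sites", {
  q <- "TGACAGAAGAGAGTGAGCACA"  # 21 nt
  tx <- paste0(rand_dna(99, seed = 71), revcomp(q), rand_dna(80, seed = 72))
  ref <- reference(c(t1 = tx))
  s <- find_sites(q, ref, query_id = "q")
  expect_equal(s$start, 100L)
  expect_equal(s$end, 120L)
  expect_equal(s$score, 0)
  # G:U wobble scores 0.5: query G pairing transcript T (query
  # position 9 pairs site position end - 8 = 112)
  qv <- strsplit(q, "")[[1]]
  stopifnot(qv[9] == "G")
  txv <- strsplit(tx, "")[[1]]
  txv[112] <- "T"
  ref2 <- reference(c(t1 = paste(txv, collapse = "")))
  s2 <- find_sites(q, ref2, query_id = "q")
  s2 <- s2[s2$start == 100L, ]
  expect_equal(s2$score, 0.5)
  # with wobble penalty 1 the same site scores 1
  s2b <- find_sites(q, ref2, gu_penalty = 1, query_id = "q")
  expect_equal(s2b[s2b$start == 100L, ]$score, 1)
  # a site scoring above the cap is excluded
  txv5 <- strsplit(tx, "")[[1]]
  # five pure mismatches (avoid accidental wobbles)
  for (i in c(101, 103, 105, 107, 109)) {
    qpos <- 120 - i + 1
    comp <- c(A = "T", C = "G", G = "C", T = "A")[[qv[qpos]]]
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(comp, if (qv[qpos] == "G") "T",
                     if (qv[qpos] == "T") "G"))
    txv5[i] <- bad[1]
  }
  ref3 <- reference(c(t1 = paste(txv5, collapse = "")))
  s3 <- find_sites(q, ref3, max_mismatch = 4, query_id = "q")
  expect_false(any(s3$start == 100L))
})

test_that("mismatch score is invariant under joint reverse complement", {
  q <- rand_dna(21, seed = 73)
  site <- mutate_seq(revcomp(q), c(3, 11))
  ref_f <- reference(c(t = paste0("AAAA", site, "TTTT")))
  ref_r <- reference(c(t = paste0("AAAA", revcomp(site), "TTTT")))
  sf <- find_sites(q, ref_f, max_mismatch = 21)
  sr <- find_sites(revcomp(q), ref_r, max_mismatch = 21)
  expect_equal(sf$score[sf$start == 5], sr$score[sr$start == 5])
})

test_that("valid reads are counted only at positions pairing query 9-11", {
  q <- rand_dna(21, seed = 74)
  tx <- paste0(rand_dna(99, seed = 75), revcomp(q), rand_dna(100, seed = 76))
  ref <- reference(c(t1 = tx))
  site <- find_sites(q, ref, query_id = "q")
  expect_equal(c(site$start, site$end), c(100L, 120L))
  # positions pairing query 9, 10, 11 are 112, 111, 110
  deg <- data.frame(transcript = "t1", start = c(110L, 111L, 112L),
                    count = c(10, 20, 30))
  expect_equal(count_valid_reads(site, deg), 60)
  # positions pairing query 5-8 (113-116) and 12-15 (106-109) are invalid
  deg2 <- data.frame(transcript = "t1",
                     start = c(106L, 107L, 108L, 109L, 113L, 114L, 115L,
                               116L), count = 5)
  expect_equal(count_valid_reads(site, deg2), 0)
  # a planted cleavage opposite query position 10/11 via the simulator
  plan <- data.frame(transcript = "t1", position = 111L, count = 30L)
  reads <- simulate_degradome(ref, plan, seed = 3)
  tags <- collapse_unique(data.frame(library = "D1",
                                     seq = substr(reads$seq, 1, 20)))
  mapped <- map_degradome(data.frame(seq = tags$seq, count = tags$D1), ref)
  expect_equal(count_valid_reads(site, mapped), 30)
})

test_that("class rules decide the constructed truth table", {
  # scenarios: (score, valid) -> expected decision per class
  cases <- expand.grid(score = c(0, 2, 3, 3.5, 4, 5),
                       valid = c(0, 2))
  sites <- data.frame(query = "q", transcript = "t", start = 1L, end = 21L,
                      score = cases$score, valid_reads = cases$valid)
  cons <- call_targets(sites, "conserved")
  expect_equal(cons$accepted, cases$score <= 4)
  nov <- call_targets(sites, "novel")
  expect_equal(nov$accepted, cases$valid >= 1 & cases$score < 4)
  pha <- call_targets(sites, "phasiRNA")
  expect_equal(pha$accepted,
               cases$score == 0 | (cases$valid >= 1 & cases$score <= 3))
  trig <- call_targets(sites, "phas_trigger")
  expect_equal(trig$accepted, cases$valid >= 1 | cases$score < 4)
  # spot checks from the rules' boundary rows
  expect_true(cons$accepted[cases$score == 4 & cases$valid == 0])
  expect_false(nov$accepted[cases$score == 2 & cases$valid == 0])
  expect_true(pha$accepted[cases$score == 0 & cases$valid == 0])
  expect_error(call_targets(sites, "unknown"))
})

test_that("T-plot conserves mapped degradome reads", {
  tx <- reference(c(t1 = rand_dna(600, seed = 77)))
  deg <- data.frame(transcript = "t1", start = c(111L, 500L, 111L),
                    count = c(10, 2, 20))
  v <- tplot_data("t1", tx, deg)
  expect_equal(length(v), 600L)
  expect_equal(v[111], 30)
  expect_equal(v[500], 2)
  expect_equal(sum(v), sum(deg$count))
  expect_true(all(v[-c(111, 500)] == 0))
  # empty degradome
  expect_equal(sum(tplot_data("t1", tx, deg[0, ])), 0)
  f <- tempfile(fileext = ".tsv")
  write_tplot_tsv(v, f)
  back <- utils::read.delim(f)
  expect_equal(back$reads, unname(v))
})

test_that("TAS3 calling requires miR390 sites on both sides", {
  set.seed(81)
  mir390 <- "AAGCTCAGGAGGGATAGCGCC"
  tasiarf <- "TTCTTGACCTTGTAAGACCCC"
  site <- revcomp(mir390)
  mk_locus <- function(five = TRUE, three = TRUE) {
    paste0(rand_dna(300), if (five) site else rand_dna(21),
           rand_dna(30), tasiarf, rand_dna(30),
           if (three) site else rand_dna(21), rand_dna(300))
  }
  g <- reference(c(Chr1 = mk_locus()))
  tas <- find_tas3(c(arf = tasiarf), g, mir390)
  expect_equal(nrow(tas), 1L)
  expect_equal(tas$name, "TAS3a")
  expect_equal(c(tas$site5_start, tas$site5_end), c(301L, 321L))
  expect_equal(c(tas$site3_start, tas$site3_end), c(403L, 423L))
  expect_equal(c(tas$tasi_start, tas$tasi_end), c(352L, 372L))
  # removing either site removes the call
  expect_equal(nrow(find_tas3(c(arf = tasiarf),
                              reference(c(Chr1 = mk_locus(five = FALSE))),
                              mir390)), 0L)
  expect_equal(nrow(find_tas3(c(arf = tasiarf),
                              reference(c(Chr1 = mk_locus(three = FALSE))),
                              mir390)), 0L)
  # a tasiARF copy with 3 substitutions is not even mapped
  g3 <- reference(c(Chr1 = paste0(rand_dna(300), site, rand_dna(30),
                                  mutate_seq(tasiarf, c(3, 9, 15)),
                                  rand_dna(30), site, rand_dna(300))))
  expect_equal(nrow(find_tas3(c(arf = tasiarf), g3, mir390)), 0L)
})

test_that("a minus-strand TAS3 locus is found with genomic coordinates", {
  set.seed(82)
  mir390 <- "AAGCTCAGGAGGGATAGCGCC"
  tasiarf <- "TTCTTGACCTTGTAAGACCCC"
  site <- revcomp(mir390)
  fwd <- paste0(site, rand_dna(30), tasiarf, rand_dna(30), site)
  g <- reference(c(Chr1 = paste0(rand_dna(300), revcomp(fwd),
                                 rand_dna(300))))
  tas <- find_tas3(c(arf = tasiarf), g, mir390)
  expect_equal(nrow(tas), 1L)
  expect_equal(tas$strand, "-")
  expect_equal(tas$start, 301L)
  expect_equal(tas$end, 301L + nchar(fwd) - 1L)
})

test_that("predict_targets chains site search, validation and rules", {
  q <- rand_dna(21, seed = 78)
  tx <- paste0(rand_dna(99, seed = 79), revcomp(q), rand_dna(100, seed = 80))
  ref <- reference(c(t1 = tx))
  deg <- data.frame(transcript = "t1", start = 111L, count = 12)
  res <- predict_targets(c(myq = q), ref, deg, class = "novel",
                         max_mismatch = 4)
  hit <- res[res$start == 100L, ]
  expect_equal(hit$valid_reads, 12)
  expect_true(hit$accepted)
})
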