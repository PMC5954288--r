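test_that("phase positions and registers follow the 2-nt duplex offset", {
  expect_equal(phase_position(5001L, "+"), 5001L)
  expect_equal(phase_position(4999L, "-"), 5001L)
  expect_equal(phase_register(phase_position(5001L, "+"), 5001L, 21L), 0)
  expect_equal(phase_register(phase_position(4999L, "-"), 5001L, 21L), 0)
  expect_equal(phase_register(5003L, 5001L, 21L), 2)
})

test_that("phasing p-value has exact boundary values", {
  # k = 0: the full tail sums to 1 (Vandermonde identity)
  for (n in c(1, 5, 17, 30)) expect_identical(phasing_pvalue(n, 0), 1)
  # n = k = m: single surviving term
  expect_equal(phasing_pvalue(10, 10, m = 10, p = 21),
               exp(-lchoose(210, 10)), tolerance = 1e-12)
  expect_error(phasing_pvalue(5, 6), "exceed n")
  expect_error(phasing_pvalue(3, 11), "\\[0, m\\]")
})

test_that("phasing p-value matches the exact big-integer tail oracle", {
  worst <- 0
  for (p in c(21L, 24L)) {
    for (n in 0:30) {
      for (k in 0:min(n, 10L)) {
        got <- phasing_pvalue(n, k, m = 10L, p = p)
        want <- oracle_phasing_tail(n, k, m = 10L, p = p)
        rel <- if (want == 0) abs(got) else abs(got - want) / want
        worst <- max(worst, rel)
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("phasing p-value agrees with the hypergeometric tail in stats", {
  for (p in c(21L, 24L)) {
    for (n in c(4L, 9L, 15L, 28L)) {
      for (k in 0:min(n, 10L)) {
        expect_equal(phasing_pvalue(n, k, m = 10L, p = p),
                     stats::phyper(k - 1, 10, (p - 1) * 10, n,
                                   lower.tail = FALSE),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("the exact pmf sums to one (Vandermonde, integer arithmetic)", {
  for (p in c(21L, 24L)) {
    for (n in c(7L, 19L, 30L)) {
      total <- 0
      for (j in 0:min(n, 10L)) {
        term <- big_mul_small(big_choose((p - 1) * 10, n - j),
                              big_to_double(big_choose(10, j)))
        total <- big_add(total, term)
      }
      expect_true(big_eq(total, big_choose(p * 10, n)))
    }
  }
})

test_that("p-value is non-increasing in k at fixed n", {
  for (n in c(6L, 12L, 25L)) {
    pv <- phasing_pvalue(rep(n, min(n, 10L) + 1L), 0:min(n, 10L))
    expect_true(all(diff(pv) <= 1e-15))
  }
})

test_that("phase score matches its closed form and monotonicity", {
  expect_equal(phase_score(10, 0, 3), log(101))
  expect_equal(phase_score(5, 9, 4), 2 * log(6))
  expect_equal(phase_score(0, 7, 5), 0)      # no phased reads
  expect_true(is.na(phase_score(10, 0, 2)))  # k < 3: no score
  # accepts per-cycle vectors too
  expect_equal(phase_score(c(4, 3, 3), c(0, 0, 0), 3), log(101))
  grid <- expand.grid(P = c(1, 5, 20), U = c(0, 3, 10), k = 3:6)
  s <- mapply(phase_score, grid$P, grid$U, grid$k)
  expect_true(all(s >= 0))
  # increasing in P, decreasing in U, linear in k
  expect_true(all(diff(sapply(c(1, 5, 20), phase_score, U = 2, k = 4)) > 0))
  expect_true(all(diff(sapply(c(0, 3, 10),
                              function(u) phase_score(5, u, 4))) < 0))
  s3 <- phase_score(5, 2, 3); s5 <- phase_score(5, 2, 5)
  expect_equal(s5 / s3, 3)
})

test_that("window scan counts n and k on a constructed ladder", {
  g <- rand_dna(2000, seed = 51)
  ref <- reference(c(Chr1 = g))
  starts <- 501L + (0:9) * 21L
  ladder <- data.frame(tag = substring(g, starts, starts + 20L), ref = "Chr1",
                       start = starts, strand = "+", mismatches = 0L,
                       stringsAsFactors = FALSE)
  w <- scan_phase_windows(ladder, ref, p = 21L)
  at <- w[w$start == 501L, ]
  expect_equal(at$n, 10L)
  expect_equal(at$k, 10L)
  expect_equal(at$phased_reads, 10)
  expect_equal(at$unphased_reads, 0)
  # adding 5 off-register tags: n = 15, k stays 10
  offs <- 503L + (0:4) * 21L
  noise <- data.frame(tag = substring(g, offs, offs + 20L), ref = "Chr1",
                      start = offs, strand = "+", mismatches = 0L,
                      stringsAsFactors = FALSE)
  w2 <- scan_phase_windows(rbind(ladder, noise), ref, p = 21L)
  at2 <- w2[w2$start == 501L, ]
  expect_equal(at2$n, 15L)
  expect_equal(at2$k, 10L)
  # empty region yields no windows
  expect_equal(nrow(scan_phase_windows(ladder[0, ], ref, p = 21L)), 0L)
})

test_that("window extension and merging follow interval arithmetic", {
  g <- rand_dna(3000, seed = 52)
  ref <- reference(c(Chr1 = g))
  windows <- data.frame(ref = "Chr1", start = c(1000L, 1250L),
                        end = c(1209L, 1459L), n = 10L, k = 10L,
                        phased_reads = 20, unphased_reads = 0,
                        pvalue = c(0.01, 0.02), score = c(10, 12),
                        stringsAsFactors = FALSE)
  reg <- merge_phase_windows(windows, ref)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 900L)
  expect_equal(reg$end, 1559L)
  expect_equal(reg$pvalue, 0.01)   # minimum member p
  expect_equal(reg$max_score, 12)
  # single window clipped at the chromosome start
  w1 <- windows[1, ]; w1$start <- 50L; w1$end <- 259L
  reg1 <- merge_phase_windows(w1, ref)
  expect_equal(c(reg1$start, reg1$end), c(1L, 359L))
})

test_that("BH correction reproduces hand-computed values", {
  g <- rand_dna(21000, seed = 53)
  ref <- reference(c(Chr1 = g))
  windows <- data.frame(ref = "Chr1", start = c(1000L, 8000L, 15000L),
                        end = c(1209L, 8209L, 15209L), n = 10L, k = 10L,
                        phased_reads = 20, unphased_reads = 0,
                        pvalue = c(0.01, 0.02, 0.04), score = 10,
                        stringsAsFactors = FALSE)
  reg <- merge_phase_windows(windows, ref)
  expect_equal(reg$padj, c(0.03, 0.03, 0.04))
  # the q-value alternative is monotone and bounded by 1
  regq <- merge_phase_windows(windows, ref, method = "qvalue")
  expect_true(all(regq$padj <= 1 & regq$padj >= reg$padj - 1e-12))
})

test_that("locus calling applies score, q and uniqueness gates", {
  st <- ladder_study(61, starts = c(5001L, 12001L), abundance = 3,
                     noise_rate = 0.1)
  res <- detect_phas(st$aln, st$sim$reference, p = 21L, counts = st$counts)
  expect_equal(nrow(res$loci), 2L)
  expect_equal(res$loci$anchor, c(5001L, 12001L))
  expect_equal(res$loci$name, c("P21_Chr1_1", "P21_Chr1_2"))
  expect_true(all(res$loci$max_score > 5 & res$loci$padj < 0.05 &
                    res$loci$n_phasirna >= 4))
  expect_true(all(grepl("^P21_Chr1_\\d+_siR\\d+$", res$phasirna$name)))
  # phasiRNAs are numbered by position within each locus
  p1 <- res$phasirna[res$phasirna$locus == "P21_Chr1_1", ]
  expect_true(all(diff(p1$effective) > 0))
  # a region whose max score is below threshold is not called
  reg <- res$regions
  fake <- reg[1, ]; fake$max_score <- 4.2
  called <- call_phas_loci(fake, st$aln, p = 21L)
  expect_equal(nrow(called$loci), 0L)
})

test_that("loci with fewer than 4 unique phased tags are not reported", {
  g <- rand_dna(2000, seed = 54)
  ref <- reference(c(Chr1 = g))
  starts <- 501L + (0:2) * 21L  # only 3 unique phased tags
  aln <- data.frame(tag = substring(g, starts, starts + 20L), ref = "Chr1",
                    start = starts, strand = "+", mismatches = 0L,
                    stringsAsFactors = FALSE)
  counts <- structure(rep(50, 3), names = aln$tag)
  res <- detect_phas(aln, ref, p = 21L, counts = counts)
  expect_equal(nrow(res$loci), 0L)
})

test_that("a minus-strand ladder mirrors its plus-strand twin exactly", {
  plus <- ladder_study(71, starts = 3001L, strand = "+", noise_rate = 0,
                       depth = 0, background_rate = 0, chrom_length = 10000L)
  minus <- ladder_study(71, starts = 3001L, strand = "-", noise_rate = 0,
                        depth = 0, background_rate = 0,
                        chrom_length = 10000L)
  rp <- detect_phas(plus$aln, plus$sim$reference, p = 21L,
                    counts = plus$counts)
  rm_ <- detect_phas(minus$aln, minus$sim$reference, p = 21L,
                     counts = minus$counts)
  expect_equal(rm_$loci$start, rp$loci$start)
  expect_equal(rm_$loci$end, rp$loci$end)
  expect_equal(rm_$loci$anchor, rp$loci$anchor)
  expect_equal(rm_$loci$register, rp$loci$register)
  # the minus-strand phasiRNAs occupy the same effective registers
  expect_setequal(rm_$phasirna$effective %% 21L,
                  rp$phasirna$effective %% 21L)
})

test_that("clusters chain loci closer than 2000 bp", {
  loci <- data.frame(name = c("P21_Chr1_1", "P21_Chr1_2", "P21_Chr1_3"),
                     ref = "Chr1", start = c(8000L, 11500L, 20000L),
                     end = c(10000L, 12000L, 21000L), phase_length = 21L,
                     stringsAsFactors = FALSE)
  cl <- cluster_phas_loci(loci, gap = 2000L)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$n_loci, c(2L, 1L))
  # a gap of exactly 2000 bp separates clusters
  loci2 <- loci[1:2, ]; loci2$start[2] <- 12000L; loci2$end[1] <- 10000L
  expect_equal(nrow(cluster_phas_loci(loci2, gap = 2000L)), 2L)
  # singleton
  expect_equal(cluster_phas_loci(loci[1, ], gap = 2000L)$n_loci, 1L)
})

test_that("BED export is 0-based half-open", {
  loci <- data.frame(name = "P21_Chr1_1", ref = "Chr1", start = 101L,
                     end = 310L, phase_length = 21L, max_score = 12.5,
                     stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".bed")
  write_phas_bed(loci, f)
  fields <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(as.integer(fields[2:3]), c(100L, 310L))
})
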