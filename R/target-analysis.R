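#' Find complementary sites of a small RNA on transcripts
#'
#' Ungapped reverse-complement scan: query position `q` (counted from the
#' query 5' end, length L) pairs transcript position `end - q + 1` of a
#' site `[start, end]` with `end - start + 1 = L`. Each site is scored by
#' its number of mispaired positions; the G:U wobble (query G against
#' transcript T, or query T against transcript G) counts `gu_penalty`
#' (default 0.5). Sites with score at most `max_mismatch` are returned.
#'
#' @param query Small RNA sequence, 20-24 nt (U converted to T).
#' @param transcripts A [reference()] of transcript sequences.
#' @param max_mismatch Maximum (inclusive) mismatch score.
#' @param gu_penalty Penalty per G:U pair (0.5 or 1).
#' @param query_id Identifier recorded in the output.
#' @return data.frame with columns `query`, `transcript`, `start`, `end`,
#'   `score`.
#' @export
find_sites <- function(query, transcripts, max_mismatch = 4,
                       gu_penalty = 0.5, query_id = "query") {
  stopifnot(inherits(transcripts, "phasr_reference"))
  q <- toupper(chartr("U", "T", query))
  L <- nchar(q)
  if (L < 20L || L > 24L) stop("query must be 20-24 nt")
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  for (tid in names(transcripts$sequences)) {
    tx <- transcripts$sequences[[tid]]
    n <- nchar(tx)
    if (n < L) next
    tv <- strsplit(tx, "", fixed = TRUE)[[1]]
    starts <- seq_len(n - L + 1L)
    score <- numeric(length(starts))
    for (i in seq_len(L)) {
      # site position pairing query position i is start + L - i
      tb <- tv[starts + L - i]
      qb <- qv[i]
      pen <- ifelse(tb == comp[[qb]], 0,
                    ifelse((qb == "G" & tb == "T") |
                             (qb == "T" & tb == "G"), gu_penalty, 1))
      score <- score + pen
    }
    keep <- score <= max_mismatch
    if (any(keep))
      out[[tid]] <- data.frame(query = query_id, transcript = tid,
                               start = starts[keep],
                               end = starts[keep] + L - 1L,
                               score = score[keep],
                               stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(query = character(), transcript = character(),
                      start = integer(), end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count valid degradome reads at a target site
#'
#' A degradome read is valid for a site when its 5' end lies at one of
#' the transcript positions pairing query positions 9, 10 or 11 (counted
#' from the query 5' end) - the canonical slicing window. For a site
#' `[start, end]` these are positions `end - 8`, `end - 9`, `end - 10`.
#'
#' @param site One-row data.frame from [find_sites()] (or a list with
#'   `transcript`, `start`, `end`).
#' @param degradome data.frame of degradome tag placements on
#'   transcripts: columns `transcript`, `start` (5'-end position),
#'   `count`.
#' @param positions Query positions defining the valid window.
#' @return Total valid read count (numeric).
#' @export
count_valid_reads <- function(site, degradome, positions = 9:11) {
  valid_pos <- site$end - (positions - 1L)
  sel <- degradome$transcript == site$transcript &
    degradome$start %in% valid_pos
  sum(degradome$count[sel])
}

#' Apply class-specific target acceptance rules
#'
#' Decision rules by query class:
#' \itemize{
#'   \item `conserved`: mismatch score <= 4 (degradome support optional);
#'   \item `novel`: at least 1 valid read and score < 4;
#'   \item `phasiRNA`: score 0, or at least 1 valid read and score <= 3;
#'   \item `phas_trigger`: at least 1 valid read, or score < 4 (the rule
#'     used when searching miRNA triggers on PHAS transcripts).
#' }
#'
#' @param sites data.frame from [find_sites()] with a `valid_reads`
#'   column (see [count_valid_reads()]).
#' @param class One of `"conserved"`, `"novel"`, `"phasiRNA"`,
#'   `"phas_trigger"`.
#' @return The input with a logical `accepted` column.
#' @export
call_targets <- function(sites, class = c("conserved", "novel", "phasiRNA",
                                          "phas_trigger")) {
  class <- match.arg(class)
  acc <- switch(class,
    conserved = sites$score <= 4,
    novel = sites$valid_reads >= 1 & sites$score < 4,
    phasiRNA = sites$score == 0 |
      (sites$valid_reads >= 1 & sites$score <= 3),
    phas_trigger = sites$valid_reads >= 1 | sites$score < 4)
  sites$accepted <- acc
  sites$class <- class
  sites
}

#' Map 20-nt degradome tags to transcripts (sense, exact)
#'
#' @param tags data.frame with columns `seq` and `count` (collapsed
#'   20-nt degradome tags), or a character vector (count 1 each).
#' @param transcripts A [reference()].
#' @return data.frame with columns `transcript`, `start`, `seq`, `count`.
#' @export
map_degradome <- function(tags, transcripts) {
  if (!is.data.frame(tags))
    tags <- data.frame(seq = tags, count = 1L, stringsAsFactors = FALSE)
  hits <- map_tags(tags$seq, transcripts, max_mismatch = 0L)
  hits <- hits[hits$strand == "+", , drop = FALSE]
  cnt <- structure(tags$count, names = tags$seq)
  data.frame(transcript = hits$ref, start = hits$start, seq = hits$tag,
             count = as.numeric(cnt[hits$tag]), stringsAsFactors = FALSE)
}

#' Per-position degradome read-count profile of a transcript (T-plot)
#'
#' @param transcript_id Transcript to profile.
#' @param transcripts A [reference()].
#' @param degradome data.frame from [map_degradome()].
#' @return Numeric vector of 5'-end read counts, one per transcript
#'   position; its sum equals the mapped read count on the transcript.
#' @export
tplot_data <- function(transcript_id, transcripts, degradome) {
  L <- nchar(transcripts$sequences[[transcript_id]])
  v <- numeric(L)
  d <- degradome[degradome$transcript == transcript_id, , drop = FALSE]
  if (nrow(d) > 0L) {
    s <- tapply(d$count, d$start, sum)
    v[as.integer(names(s))] <- s
  }
  v
}

#' Write a T-plot profile as TSV
#'
#' @param tplot Numeric vector from [tplot_data()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tplot_tsv <- function(tplot, path) {
  utils::write.table(data.frame(position = seq_along(tplot),
                                reads = tplot),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Identify TAS3 loci by tasiARF homology and dual miR390 sites
#'
#' Maps known tasiARF sequences to the genome (at most `max_mismatch`
#' substitutions), cuts `flank` nt of sequence on both sides of each hit,
#' and reports a TAS3 locus when miR390 complementary sites are found on
#' both the 5' and the 3' side of the tasiRNA region (on the strand of
#' the tasiARF hit). Loci are named TAS3a, TAS3b, ... in genomic order.
#'
#' @param tasiarfs Named character vector of known tasiARF sequences (or
#'   FASTA path).
#' @param genome A [reference()].
#' @param mir390 miR390 sequence (~21 nt).
#' @param flank Cut-out size on each side (default 250 nt).
#' @param max_mismatch Mismatch cap for tasiARF mapping.
#' @param site_max_mismatch Score cap for miR390 site prediction.
#' @return data.frame with columns `name`, `ref`, `start`, `end`,
#'   `strand`, `tasi_start`, `tasi_end`, `site5_start`, `site5_end`,
#'   `site3_start`, `site3_end` (site coordinates are genomic).
#' @export
find_tas3 <- function(tasiarfs, genome, mir390, flank = 250L,
                      max_mismatch = 2L, site_max_mismatch = 4) {
  if (is.character(tasiarfs) && length(tasiarfs) == 1L &&
      file.exists(tasiarfs))
    tasiarfs <- read_fasta(tasiarfs)
  tasiarfs <- toupper(chartr("U", "T", tasiarfs))
  hits <- map_tags(tasiarfs, genome, max_mismatch = max_mismatch)
  if (nrow(hits) == 0L)
    return(empty_tas3())
  # collapse hits into candidate tasiRNA regions (overlapping hits on the
  # same strand belong to one locus)
  out <- list()
  hits <- hits[order(hits$ref, hits$start), , drop = FALSE]
  grp <- cumsum(c(TRUE, hits$ref[-1] != hits$ref[-nrow(hits)] |
                    hits$start[-1] > hits$start[-nrow(hits)] +
                    nchar(hits$tag[-nrow(hits)]) + 50L))
  for (g in unique(grp)) {
    h <- hits[grp == g, , drop = FALSE]
    rid <- h$ref[1]
    strand <- names(sort(table(h$strand), decreasing = TRUE))[1]
    L <- nchar(genome$sequences[[rid]])
    t_start <- min(h$start); t_end <- max(h$start + nchar(h$tag) - 1L)
    c_start <- max(1L, t_start - flank); c_end <- min(L, t_end + flank)
    cut <- substr(genome$sequences[[rid]], c_start, c_end)
    if (strand == "-") cut <- revcomp(cut)
    cutref <- reference(c(cutout = cut), name = "tas3-cutout")
    sites <- find_sites(mir390, cutref, max_mismatch = site_max_mismatch,
                        query_id = "miR390")
    if (nrow(sites) == 0L) next
    # tasiRNA region in cut-out coordinates (strand orientation)
    if (strand == "+") {
      r_start <- t_start - c_start + 1L; r_end <- t_end - c_start + 1L
    } else {
      r_start <- c_end - t_end + 1L; r_end <- c_end - t_start + 1L
    }
    five <- sites[sites$end < r_start, , drop = FALSE]
    three <- sites[sites$start > r_end, , drop = FALSE]
    if (nrow(five) == 0L || nrow(three) == 0L) next
    s5 <- five[which.min(five$score), ]
    s3 <- three[which.min(three$score), ]
    to_genomic <- function(a, b) {
      if (strand == "+") c(c_start + a - 1L, c_start + b - 1L)
      else c(c_end - b + 1L, c_end - a + 1L)
    }
    g5 <- to_genomic(s5$start, s5$end)
    g3 <- to_genomic(s3$start, s3$end)
    out[[length(out) + 1L]] <-
      data.frame(ref = rid, start = min(g5[1], g3[1]),
                 end = max(g5[2], g3[2]), strand = strand,
                 tasi_start = t_start, tasi_end = t_end,
                 site5_start = g5[1], site5_end = g5[2],
                 site3_start = g3[1], site3_end = g3[2],
                 stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty_tas3())
  res <- do.call(rbind, out)
  res <- res[order(res$ref, res$start), , drop = FALSE]
  res <- data.frame(name = paste0("TAS3", letters[seq_len(nrow(res))]), res,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

empty_tas3 <- function() {
  data.frame(name = character(), ref = character(), start = integer(),
             end = integer(), strand = character(), tasi_start = integer(),
             tasi_end = integer(), site5_start = integer(),
             site5_end = integer(), site3_start = integer(),
             site3_end = integer(), stringsAsFactors = FALSE)
}

#' Predict and validate targets for a set of queries
#'
#' Convenience wrapper: runs [find_sites()] for each query, counts valid
#' degradome reads per site, and applies the class rule via
#' [call_targets()].
#'
#' @param queries Named character vector of small RNA sequences.
#' @param transcripts A [reference()].
#' @param degradome data.frame from [map_degradome()].
#' @param class Query class (see [call_targets()]).
#' @param max_mismatch Site score cap passed to [find_sites()].
#' @param gu_penalty G:U wobble penalty.
#' @return data.frame of scored, validated sites.
#' @export
predict_targets <- function(queries, transcripts, degradome,
                            class = "conserved", max_mismatch = 4,
                            gu_penalty = 0.5) {
  out <- list()
  for (qn in names(queries)) {
    sites <- find_sites(queries[[qn]], transcripts,
                        max_mismatch = max_mismatch,
                        gu_penalty = gu_penalty, query_id = qn)
    if (nrow(sites) == 0L) next
    sites$valid_reads <- vapply(seq_len(nrow(sites)), function(i)
      count_valid_reads(sites[i, ], degradome), numeric(1))
    out[[qn]] <- call_targets(sites, class = class)
  }
  if (length(out) == 0L)
    return(data.frame(query = character(), transcript = character(),
                      start = integer(), end = integer(), score = numeric(),
                      valid_reads = numeric(), accepted = logical(),
                      class = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
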