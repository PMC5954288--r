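#' Effective plus-strand phase position of an aligned small RNA
#'
#' Plus-strand reads keep their leftmost coordinate; minus-strand reads
#' receive a two-nucleotide positive offset, because the two strands of a
#' phased siRNA duplex carry 2-nt 3' overhangs, so the duplex partner of a
#' plus-strand siRNA starts two nucleotides upstream on the minus strand.
#' With this offset, duplex partners fall in the same phase register.
#'
#' @param start Leftmost plus-strand coordinate(s).
#' @param strand `"+"` or `"-"` (vectorized).
#' @return Effective position(s) in the shared register space.
#' @export
phase_position <- function(start, strand) {
  ifelse(strand == "-", start + 2L, as.integer(start))
}

#' Phase register of an effective position within a window
#'
#' @param effective Effective position(s) from [phase_position()].
#' @param window_start Window anchor position.
#' @param p Phase length (21 or 24).
#' @return Register(s) in `0:(p-1)`; register 0 is in phase.
#' @export
phase_register <- function(effective, window_start, p) {
  (effective - window_start) %% p
}

#' Hypergeometric phasing P-value
#'
#' For a window of `m` phase cycles of length `p` (so `p*m` positions, of
#' which `m` are in register), containing `n` unique p-nt small RNAs of
#' which `k` occupy phased positions, the P-value is the hypergeometric
#' upper tail
#' \deqn{P = \sum_{j=k}^{m} \frac{\binom{(p-1)m}{n-j}\binom{m}{j}}
#'   {\binom{pm}{n}}.}
#' Terms with `n - j < 0` or `n - j > (p-1)m` are zero. The sum is
#' computed term-wise in log space (no cancellation occurs: all terms are
#' positive), which reproduces an exact rational evaluation to close to
#' machine precision.
#'
#' @param n Number of unique p-nt sRNAs in the window (vectorized).
#' @param k Number of occupied phased positions (vectorized with `n`).
#' @param m Number of phase cycles (default 10).
#' @param p Phase length, 21 or 24.
#' @return P-value(s) in (0, 1]; `k = 0` gives exactly 1.
#' @export
phasing_pvalue <- function(n, k, m = 10L, p = 21L) {
  stopifnot(length(n) == length(k))
  if (any(k < 0 | k > m)) stop("k must lie in [0, m]")
  if (any(k > n)) stop("k must not exceed n")
  if (any(n < 0 | n > p * m)) stop("n must lie in [0, p*m]")
  vapply(seq_along(n), function(i) {
    if (k[i] == 0) return(1)
    j <- seq.int(k[i], m)
    j <- j[n[i] - j >= 0 & n[i] - j <= (p - 1) * m]
    if (length(j) == 0L) return(0)
    lt <- lchoose((p - 1) * m, n[i] - j) + lchoose(m, j) -
      lchoose(p * m, n[i])
    sum(exp(lt))
  }, numeric(1))
}

#' Phase score of a window position
#'
#' For a window starting at a position with `k >= 3` occupied phased
#' positions, the score is
#' \deqn{(k-2)\,\ln\left(1 + 10\frac{\sum_i P_i}{1+\sum_i U_i}\right),}
#' where `P_i` and `U_i` are the phased and non-phased read counts at the
#' i-th phase cycle. Positions with `k < 3` receive no score (`NA`).
#'
#' @param P Phased read counts: per-cycle vector, or the precomputed sum.
#' @param U Non-phased read counts, likewise.
#' @param k Number of unique phased positions in the window.
#' @return The score, or `NA_real_` when `k < 3`.
#' @export
phase_score <- function(P, U, k) {
  sP <- sum(P); sU <- sum(U)
  if (sP < 0 || sU < 0) stop("read counts must be non-negative")
  if (k < 3) return(NA_real_)
  (k - 2) * log1p(10 * sP / (1 + sU))
}

#' Scan a reference for phased siRNA windows
#'
#' Slides a window of `m` phase cycles (210 nt for 21-nt phasing, 240 nt
#' for 24-nt) in 1-nt steps over every reference sequence and computes,
#' for each window containing at least one p-nt tag: `n` (unique p-nt
#' tags in the window, by effective position), `k` (occupied phased
#' positions, i.e. positions congruent to the window start modulo `p`),
#' the summed phased/non-phased read counts, the hypergeometric P-value
#' and - where `k >= 3` - the phase score. Alignments should be
#' restricted to p-nt tags not annotated as repeats before calling.
#'
#' @param alignments data.frame from [map_tags()] (columns `tag`, `ref`,
#'   `start`, `strand`); only tags of length `p` are used.
#' @param reference The [reference()] that was scanned.
#' @param p Phase length (21 or 24).
#' @param counts Optional named vector of read counts per tag sequence
#'   (default: 1 per alignment).
#' @param m Number of phase cycles per window.
#' @return data.frame of windows: `ref`, `start`, `end`, `n`, `k`,
#'   `phased_reads`, `unphased_reads`, `pvalue`, `score`.
#' @export
scan_phase_windows <- function(alignments, reference, p = 21L,
                               counts = NULL, m = 10L) {
  stopifnot(inherits(reference, "phasr_reference"))
  p <- as.integer(p); m <- as.integer(m)
  wlen <- p * m
  aln <- alignments[nchar(alignments$tag) == p, , drop = FALSE]
  out <- list()
  for (rid in unique(aln$ref)) {
    a <- aln[aln$ref == rid, , drop = FALSE]
    L <- nchar(reference$sequences[[rid]])
    eff <- phase_position(a$start, a$strand)
    ok <- eff >= 1L & eff <= L
    a <- a[ok, , drop = FALSE]; eff <- eff[ok]
    if (nrow(a) == 0L) next
    cnt <- if (is.null(counts)) rep(1, nrow(a)) else {
      cv <- counts[a$tag]; cv[is.na(cv)] <- 1; as.numeric(cv)
    }
    # per-position unique-tag and read-count tracks; a tag sequence is one
    # unique sRNA per effective position (plus- and minus-strand tags are
    # distinct sequences)
    key <- paste(a$tag, eff)
    first <- !duplicated(key)
    uniq_track <- numeric(L); read_track <- numeric(L)
    ut <- tapply(rep(1, sum(first)), eff[first], sum)
    uniq_track[as.integer(names(ut))] <- ut
    rt <- tapply(cnt, eff, sum)
    read_track[as.integer(names(rt))] <- rt
    occupied <- sort(unique(eff))
    # candidate window starts: any start whose window covers a tag
    starts <- unique(unlist(lapply(occupied, function(x)
      max(1L, x - wlen + 1L):x)))
    starts <- sort(starts[starts >= 1L & starts + wlen - 1L <= L])
    if (length(starts) == 0L) next
    cu <- c(0, cumsum(uniq_track)); cr <- c(0, cumsum(read_track))
    n <- cu[starts + wlen] - cu[starts]
    tot_reads <- cr[starts + wlen] - cr[starts]
    idx <- outer(starts, (seq_len(m) - 1L) * p, `+`)
    k <- rowSums(matrix(uniq_track[idx] > 0, nrow = length(starts)))
    phased <- rowSums(matrix(read_track[idx], nrow = length(starts)))
    unphased <- tot_reads - phased
    keep <- n > 0
    w <- data.frame(ref = rid, start = starts, end = starts + wlen - 1L,
                    n = pmin(as.integer(round(n)), p * m),
                    k = as.integer(k),
                    phased_reads = phased, unphased_reads = unphased,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
    # P-values on the distinct (n, k) pairs only
    nk <- unique(w[, c("n", "k")])
    nk$pvalue <- phasing_pvalue(nk$n, nk$k, m = m, p = p)
    w <- merge(w, nk, by = c("n", "k"), sort = FALSE)
    w$score <- ifelse(w$k >= 3,
                      (w$k - 2) * log1p(10 * w$phased_reads /
                                          (1 + w$unphased_reads)),
                      NA_real_)
    out[[rid]] <- w
  }
  if (length(out) == 0L)
    return(data.frame(ref = character(), start = integer(), end = integer(),
                      n = integer(), k = integer(), phased_reads = numeric(),
                      unphased_reads = numeric(), pvalue = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$ref, res$start),
             c("ref", "start", "end", "n", "k", "phased_reads",
               "unphased_reads", "pvalue", "score")]
  rownames(res) <- NULL
  res
}

#' Merge significant windows and correct for multiple testing
#'
#' Windows with raw P-value below `alpha` are extended by `extend` bp on
#' both sides, transitively overlapping extensions are merged (per
#' reference sequence), each merged region inherits the minimum member
#' P-value, and region P-values are corrected across all regions
#' (Benjamini-Hochberg by default, or Storey-style q-values).
#'
#' Only score-bearing windows - those with at least `min_k` occupied
#' phased positions, the same gate the phase score itself uses - seed
#' region building. A window holding a single isolated tag already has
#' P < 0.05 (for n = k = 1 the tail is m/(pm) ~ 0.048), so without this
#' gate sparse background reads blanket the reference with extended
#' significant windows and chain unrelated loci into one region;
#' windows below `min_k` can never supply the phase score a reported
#' locus needs, so excluding them changes no locus calls, only region
#' boundaries.
#'
#' @param windows data.frame from [scan_phase_windows()].
#' @param reference The scanned [reference()] (for end clipping).
#' @param alpha Raw P-value cutoff for window selection.
#' @param extend Extension in bp at both ends.
#' @param method `"BH"` or `"qvalue"`.
#' @param min_k Minimum occupied phased positions for a window to seed a
#'   region (default 3, matching the phase-score support).
#' @return data.frame of regions: `ref`, `start`, `end`, `pvalue`,
#'   `padj`, `max_score`, `n_windows`, plus `anchor` (start of the
#'   maximal-score member window).
#' @export
merge_phase_windows <- function(windows, reference, alpha = 0.05,
                                extend = 100L, method = c("BH", "qvalue"),
                                min_k = 3L) {
  method <- match.arg(method)
  sig <- windows[!is.na(windows$pvalue) & windows$pvalue < alpha &
                   windows$k >= min_k, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(ref = character(), start = integer(), end = integer(),
                      pvalue = numeric(), padj = numeric(),
                      max_score = numeric(), n_windows = integer(),
                      anchor = integer(), stringsAsFactors = FALSE))
  out <- list()
  for (rid in unique(sig$ref)) {
    s <- sig[sig$ref == rid, , drop = FALSE]
    L <- nchar(reference$sequences[[rid]])
    ext <- IRanges::IRanges(start = pmax(1L, s$start - extend),
                            end = pmin(L, s$end + extend))
    red <- IRanges::reduce(ext)
    hit <- IRanges::findOverlaps(ext, red)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    agg <- lapply(split(seq_len(nrow(s)), grp), function(ix) {
      sc <- s$score[ix]
      best <- if (all(is.na(sc))) NA_integer_ else ix[which.max(sc)]
      data.frame(pvalue = min(s$pvalue[ix]),
                 max_score = if (all(is.na(sc))) NA_real_ else
                   max(sc, na.rm = TRUE),
                 n_windows = length(ix),
                 anchor = if (is.na(best)) s$start[ix[which.min(s$pvalue[ix])]]
                 else s$start[best])
    })
    out[[rid]] <- data.frame(ref = rid,
                             start = IRanges::start(red),
                             end = IRanges::end(red),
                             do.call(rbind, agg),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$padj <- if (method == "BH") stats::p.adjust(res$pvalue, method = "BH")
  else qvalue_storey(res$pvalue)
  res <- res[order(res$ref, res$start),
             c("ref", "start", "end", "pvalue", "padj", "max_score",
               "n_windows", "anchor")]
  rownames(res) <- NULL
  res
}

# Storey-style q-values with the conservative pi0 = 1 estimate, suitable
# for the small region counts typical here.
qvalue_storey <- function(p, pi0 = 1) {
  n <- length(p)
  o <- order(p)
  q <- pmin(1, pi0 * p[o] * n / seq_len(n))
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- q
  out
}

#' Call PHAS loci from merged regions
#'
#' A merged region is reported as a PHAS locus when its maximal phase
#' score exceeds `score_threshold`, its corrected P-value is below
#' `q_threshold`, and it contains at least `min_unique` unique phased
#' p-nt tags (tags whose effective position is congruent to the region's
#' anchor register). Loci are named `P{p}_{ref}_{serial}` with serials
#' assigned by position within each reference sequence; their phased tags
#' are extracted as phasiRNAs named `{locus}_siR{serial}` by position.
#'
#' @param regions data.frame from [merge_phase_windows()].
#' @param alignments The alignment table used for scanning.
#' @param p Phase length.
#' @param score_threshold Minimum (exclusive) maximal phase score.
#' @param q_threshold Maximum (exclusive) corrected P-value.
#' @param min_unique Minimum unique phasiRNA count for reporting.
#' @return A list with data.frames `loci` (name, ref, start, end,
#'   phase_length, anchor, register, pvalue, padj, max_score,
#'   n_phasirna) and `phasirna` (name, locus, seq, ref, start, strand,
#'   effective).
#' @export
call_phas_loci <- function(regions, alignments, p = 21L,
                           score_threshold = 5, q_threshold = 0.05,
                           min_unique = 4L) {
  aln <- alignments[nchar(alignments$tag) == p, , drop = FALSE]
  eff <- phase_position(aln$start, aln$strand)
  keep <- !is.na(regions$max_score) & regions$max_score > score_threshold &
    regions$padj < q_threshold
  cand <- regions[keep, , drop = FALSE]
  loci <- list(); phasi <- list()
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, ]
    reg <- r$anchor %% p
    sel <- aln$ref == r$ref & eff >= r$start & eff <= r$end &
      (eff %% p) == reg
    sub <- aln[sel, , drop = FALSE]
    sub$effective <- eff[sel]
    sub <- sub[!duplicated(paste(sub$tag, sub$effective)), , drop = FALSE]
    if (length(unique(sub$tag)) < min_unique) next
    sub <- sub[order(sub$effective, sub$strand), , drop = FALSE]
    loci[[length(loci) + 1L]] <-
      data.frame(ref = r$ref, start = r$start, end = r$end,
                 phase_length = p, anchor = r$anchor, register = reg,
                 pvalue = r$pvalue, padj = r$padj, max_score = r$max_score,
                 n_phasirna = length(unique(sub$tag)),
                 stringsAsFactors = FALSE)
    phasi[[length(phasi) + 1L]] <- sub
  }
  if (length(loci) == 0L)
    return(list(loci = data.frame(name = character(), ref = character(),
                                  start = integer(), end = integer(),
                                  phase_length = integer(), anchor = integer(),
                                  register = integer(), pvalue = numeric(),
                                  padj = numeric(), max_score = numeric(),
                                  n_phasirna = integer(),
                                  stringsAsFactors = FALSE),
                phasirna = data.frame()))
  ldf <- do.call(rbind, loci)
  ord <- order(ldf$ref, ldf$start)
  ldf <- ldf[ord, , drop = FALSE]; phasi <- phasi[ord]
  serial <- stats::ave(seq_len(nrow(ldf)), ldf$ref, FUN = seq_along)
  ldf <- data.frame(name = sprintf("P%d_%s_%d", p, ldf$ref, serial), ldf,
                    stringsAsFactors = FALSE)
  pdf <- do.call(rbind, lapply(seq_len(nrow(ldf)), function(i) {
    s <- phasi[[i]]
    first <- !duplicated(s$tag)
    s <- s[first, , drop = FALSE]
    data.frame(name = sprintf("%s_siR%d", ldf$name[i], seq_len(nrow(s))),
               locus = ldf$name[i], seq = s$tag, ref = s$ref,
               start = s$start, strand = s$strand, effective = s$effective,
               stringsAsFactors = FALSE)
  }))
  rownames(ldf) <- rownames(pdf) <- NULL
  list(loci = ldf, phasirna = pdf)
}

#' Group neighboring PHAS loci into clusters
#'
#' Single-linkage chaining of loci on the same reference sequence with the
#' same phase length whose gap is strictly smaller than `gap` bp.
#'
#' @param loci Loci data.frame from [call_phas_loci()].
#' @param gap Maximum (exclusive) inter-locus distance in bp.
#' @return data.frame with columns `cluster`, `ref`, `start`, `end`,
#'   `phase_length`, `n_loci`, `members` (comma-separated names).
#' @export
cluster_phas_loci <- function(loci, gap = 2000L) {
  if (NROW(loci) == 0L)
    return(data.frame(cluster = character(), ref = character(),
                      start = integer(), end = integer(),
                      phase_length = integer(), n_loci = integer(),
                      members = character(), stringsAsFactors = FALSE))
  loci <- loci[order(loci$ref, loci$phase_length, loci$start), , drop = FALSE]
  grp <- integer(nrow(loci)); g <- 0L
  for (i in seq_len(nrow(loci))) {
    if (i == 1L || loci$ref[i] != loci$ref[i - 1L] ||
        loci$phase_length[i] != loci$phase_length[i - 1L] ||
        loci$start[i] - loci$end[i - 1L] >= gap) g <- g + 1L
    grp[i] <- g
  }
  do.call(rbind, lapply(split(seq_len(nrow(loci)), grp), function(ix) {
    data.frame(cluster = sprintf("C%d_%s_%d", loci$phase_length[ix[1]],
                                 loci$ref[ix[1]], grp[ix[1]]),
               ref = loci$ref[ix[1]], start = min(loci$start[ix]),
               end = max(loci$end[ix]),
               phase_length = loci$phase_length[ix[1]],
               n_loci = length(ix),
               members = paste(loci$name[ix], collapse = ","),
               stringsAsFactors = FALSE)
  })) -> res
  rownames(res) <- NULL
  res
}

#' Detect PHAS loci end to end
#'
#' Convenience wrapper chaining [scan_phase_windows()],
#' [merge_phase_windows()], [call_phas_loci()] and
#' [cluster_phas_loci()] with the standard thresholds (window P < 0.05,
#' 100-bp extension, BH correction, phase score > 5, corrected P < 0.05,
#' at least 4 unique phasiRNAs, 2000-bp cluster gap).
#'
#' @param alignments data.frame from [map_tags()].
#' @param reference The scanned [reference()].
#' @param p Phase length (21 or 24).
#' @param counts Optional named read-count vector per tag sequence.
#' @param m Phase cycles per window.
#' @param alpha,extend,fdr_method,score_threshold,q_threshold,min_unique,gap
#'   Stage thresholds, see the stage functions.
#' @return A list with `windows`, `regions`, `loci`, `phasirna`,
#'   `clusters`.
#' @export
detect_phas <- function(alignments, reference, p = 21L, counts = NULL,
                        m = 10L, alpha = 0.05, extend = 100L,
                        fdr_method = "BH", score_threshold = 5,
                        q_threshold = 0.05, min_unique = 4L, gap = 2000L) {
  windows <- scan_phase_windows(alignments, reference, p = p,
                                counts = counts, m = m)
  regions <- merge_phase_windows(windows, reference, alpha = alpha,
                                 extend = extend, method = fdr_method)
  called <- call_phas_loci(regions, alignments, p = p,
                           score_threshold = score_threshold,
                           q_threshold = q_threshold,
                           min_unique = min_unique)
  clusters <- cluster_phas_loci(called$loci, gap = gap)
  list(windows = windows, regions = regions, loci = called$loci,
       phasirna = called$phasirna, clusters = clusters)
}

#' Export PHAS loci as BED (0-based half-open)
#'
#' @param loci Loci data.frame from [call_phas_loci()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phas_bed <- function(loci, path) {
  if (NROW(loci) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t.", loci$ref, loci$start - 1L,
                   loci$end, loci$name, loci$max_score)
  writeLines(lines, path)
  invisible(path)
}

#' Export PHAS loci as GFF3
#'
#' @param loci Loci data.frame from [call_phas_loci()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phas_gff3 <- function(loci, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(NROW(loci)))
    lines <- c(lines, sprintf(
      "%s\tphasr\tsiRNA_locus\t%d\t%d\t%g\t.\t.\tID=%s;phase_length=%d;padj=%g",
      loci$ref[i], loci$start[i], loci$end[i], loci$max_score[i],
      loci$name[i], loci$phase_length[i], loci$padj[i]))
  writeLines(lines, path)
  invisible(path)
}
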