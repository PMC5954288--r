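#' Reference sequence set
#'
#' Validates and wraps a set of reference sequences (a genome or a
#' transcript set). Coordinates everywhere in the package are 1-based and
#' inclusive on the plus strand; BED export converts to 0-based half-open.
#'
#' @param sequences Named character vector or `DNAStringSet` of sequences
#'   over the alphabet ACGTN (case-insensitive).
#' @param name Identifier for the reference set.
#' @return An object of class `phasr_reference`: a list with elements
#'   `name` and `sequences` (named uppercase character vector).
#' @export
reference <- function(sequences, name = "reference") {
  if (inherits(sequences, "DNAStringSet"))
    sequences <- structure(as.character(sequences), names = names(sequences))
  if (length(sequences) == 0L) stop("no sequences")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("reference sequence ids must be present and unique")
  sequences <- toupper(sequences)
  if (any(nchar(sequences) < 1L)) stop("reference sequences must be non-empty")
  if (any(grepl("[^ACGTN]", sequences)))
    stop("reference alphabet restricted to ACGTN")
  structure(list(name = name, sequences = sequences),
            class = "phasr_reference")
}

#' @export
print.phasr_reference <- function(x, ...) {
  cat(sprintf("<phasr_reference '%s': %d sequence(s), %s nt total>\n",
              x$name, length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ",")))
  invisible(x)
}

ref_lengths <- function(reference) nchar(reference$sequences)

as_dss <- function(reference) {
  x <- Biostrings::DNAStringSet(unname(reference$sequences))
  names(x) <- names(reference$sequences)
  x
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (ACGTN).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build an exact-word seed index over a reference
#'
#' Indexes every overlapping word of length `word_size` on the plus strand
#' of every reference sequence; minus-strand occurrences are retrieved by
#' querying the reverse complement of a word. The index also carries the
#' reference itself and is the handle passed to [map_tags()].
#'
#' @param reference A [reference()] object.
#' @param word_size Seed word length, between 8 and 14.
#' @return An object of class `phasr_seed_index`.
#' @export
build_index <- function(reference, word_size = 10L) {
  stopifnot(inherits(reference, "phasr_reference"))
  word_size <- as.integer(word_size)
  if (word_size < 8L || word_size > 14L)
    stop("word_size must be between 8 and 14")
  if (length(reference$sequences) == 0L) stop("no sequences")
  env <- new.env(parent = emptyenv(), hash = TRUE)
  for (rid in names(reference$sequences)) {
    s <- reference$sequences[[rid]]
    L <- nchar(s)
    if (L < word_size) next
    starts <- seq_len(L - word_size + 1L)
    words <- substring(s, starts, starts + word_size - 1L)
    keep <- !grepl("N", words, fixed = TRUE)
    sp <- split(starts[keep], words[keep])
    for (w in names(sp)) {
      prev <- if (exists(w, envir = env, inherits = FALSE))
        get(w, envir = env) else NULL
      hit <- list(ref = rid, pos = sp[[w]])
      assign(w, c(prev, list(hit)), envir = env)
    }
  }
  structure(list(reference = reference, word_size = word_size, words = env),
            class = "phasr_seed_index")
}

#' Look up exact occurrences of a word in a seed index
#'
#' @param index A `phasr_seed_index` from [build_index()].
#' @param word A word of the index's word size.
#' @param strand `"+"` for plus-strand occurrences of `word`, `"-"` for
#'   occurrences of its reverse complement (reported, as everywhere, by
#'   leftmost plus-strand coordinate).
#' @return data.frame with columns `ref`, `start`, `strand`.
#' @export
lookup_word <- function(index, word, strand = "+") {
  stopifnot(inherits(index, "phasr_seed_index"))
  word <- toupper(word)
  if (nchar(word) != index$word_size)
    stop("word length must equal the index word size")
  key <- if (strand == "+") word else revcomp(word)
  if (!exists(key, envir = index$words, inherits = FALSE))
    return(data.frame(ref = character(), start = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  hits <- get(key, envir = index$words)
  do.call(rbind, lapply(hits, function(h)
    data.frame(ref = h$ref, start = h$pos, strand = strand,
               stringsAsFactors = FALSE)))
}

#' Map short tags to a reference with bounded substitution mismatches
#'
#' Ungapped, exhaustive short-tag mapping: every placement of every tag on
#' either strand with at most `max_mismatch` substitutions is reported
#' (all hits, not best hits). Minus-strand alignments are reported by the
#' leftmost coordinate on the plus strand. The substitution-only scan is
#' performed by Biostrings' pattern matcher, which is exhaustive over all
#' positions.
#'
#' @param tags Character vector of tag sequences (15-30 nt), or a
#'   data.frame with a `seq` column.
#' @param index A `phasr_seed_index` (or a `phasr_reference`).
#' @param max_mismatch Maximum substitutions allowed (at most 3).
#' @return data.frame with columns `tag`, `ref`, `start`, `strand`,
#'   `mismatches`. Tags containing non-ACGT characters are skipped; the
#'   number skipped is attached as attribute `n_skipped` and a warning is
#'   emitted.
#' @export
map_tags <- function(tags, index, max_mismatch = 2L) {
  if (is.data.frame(tags)) tags <- tags$seq
  if (inherits(index, "phasr_seed_index")) index <- index$reference
  stopifnot(inherits(index, "phasr_reference"))
  max_mismatch <- as.integer(max_mismatch)
  if (max_mismatch > 3L) stop("max_mismatch must be <= 3")
  tags <- toupper(tags)
  bad <- grepl("[^ACGT]", tags)
  if (any(bad)) warning(sprintf("skipped %d tag(s) with non-ACGT characters",
                                sum(bad)))
  tags <- unique(tags[!bad])
  subject <- as_dss(index)
  if (max_mismatch == 0L && length(tags) > 0L) {
    res <- map_tags_exact(tags, index, subject)
    attr(res, "n_skipped") <- sum(bad)
    return(res)
  }
  out <- vector("list", 2L * length(tags))
  j <- 0L
  for (tg in tags) {
    for (std in c("+", "-")) {
      pat <- if (std == "+") tg else revcomp(tg)
      m <- Biostrings::vmatchPattern(pat, subject, max.mismatch = max_mismatch,
                                     fixed = TRUE)
      nh <- S4Vectors::elementNROWS(m)
      if (sum(nh) == 0L) next
      rids <- rep(names(subject), nh)
      starts <- unlist(lapply(m, IRanges::start), use.names = FALSE)
      mm <- mapply(function(rid, st) {
        ref_sub <- substr(index$sequences[[rid]], st, st + nchar(tg) - 1L)
        hamming(ref_sub, pat)
      }, rids, starts, USE.NAMES = FALSE)
      j <- j + 1L
      out[[j]] <- data.frame(tag = tg, ref = rids, start = as.integer(starts),
                             strand = std, mismatches = as.integer(mm),
                             stringsAsFactors = FALSE)
    }
  }
  res <- if (j == 0L)
    data.frame(tag = character(), ref = character(), start = integer(),
               strand = character(), mismatches = integer(),
               stringsAsFactors = FALSE)
  else do.call(rbind, out[seq_len(j)])
  res <- res[order(res$ref, res$start, res$strand, res$tag), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_skipped") <- sum(bad)
  res
}

# exact-match fast path: constant-width dictionaries per tag length
map_tags_exact <- function(tags, index, subject) {
  out <- list()
  for (w in sort(unique(nchar(tags)))) {
    tg <- tags[nchar(tags) == w]
    for (std in c("+", "-")) {
      pats <- if (std == "+") tg else revcomp(tg)
      pd <- Biostrings::PDict(pats)
      for (rid in names(subject)) {
        m <- Biostrings::matchPDict(pd, subject[[rid]])
        nh <- S4Vectors::elementNROWS(m)
        if (sum(nh) == 0L) next
        out[[length(out) + 1L]] <- data.frame(
          tag = rep(tg, nh), ref = rid,
          start = unlist(lapply(m, IRanges::start), use.names = FALSE),
          strand = std, mismatches = 0L, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out) == 0L)
    data.frame(tag = character(), ref = character(), start = integer(),
               strand = character(), mismatches = integer(),
               stringsAsFactors = FALSE)
  else do.call(rbind, out)
  res <- res[order(res$ref, res$start, res$strand, res$tag), , drop = FALSE]
  rownames(res) <- NULL
  res
}

hamming <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(av) == length(bv))
  sum(av != bv)
}

#' Write an alignment table as TSV
#'
#' @param alignments data.frame from [map_tags()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(alignments, path) {
  utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
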