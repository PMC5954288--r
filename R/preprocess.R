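#' Quality-filter small RNA reads
#'
#' A raw read is dropped when it contains more than `max_low` nucleotides
#' with a Phred quality below `min_q` (defaults: more than 5 nucleotides
#' below Q25).
#'
#' @param reads data.frame with columns `seq` and `qual` (Phred+33).
#' @param min_q Quality threshold.
#' @param max_low Maximum tolerated number of low-quality positions.
#' @return Logical vector: `TRUE` for reads to keep.
#' @export
filter_srna_read <- function(reads, min_q = 25L, max_low = 5L) {
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence/quality length mismatch")
  vapply(phred_scores(reads$qual),
         function(q) sum(q < min_q) <= max_low, logical(1))
}

#' Trim the 3' adapter and length-select inserts
#'
#' Locates the leftmost adapter match in each read: either an exact match
#' of the first `min_prefix` adapter nucleotides, or a full-length
#' adapter match with at most one mismatch. The 5' insert is returned
#' when its length lies in `[min_insert, max_insert]`.
#'
#' @param seqs Character vector of read sequences.
#' @param adapter 3' adapter sequence (at least 8 nt).
#' @param min_insert,max_insert Retained insert length bounds (18-30 nt).
#' @param min_prefix Length of the exact adapter prefix match.
#' @return data.frame with columns `insert` (NA when rejected) and
#'   `reason` (`"ok"`, `"no-adapter"`, `"too-short"`, `"too-long"`).
#' @export
trim_adapter <- function(seqs, adapter, min_insert = 18L, max_insert = 30L,
                         min_prefix = 8L) {
  adapter <- toupper(adapter)
  if (nchar(adapter) < 8L) stop("adapter must be at least 8 nt")
  prefix <- substr(adapter, 1L, min_prefix)
  find_one <- function(s) {
    hit <- regexpr(prefix, s, fixed = TRUE)[1]
    full <- locate_approx(s, adapter, max_mm = 1L)
    pos <- suppressWarnings(min(c(if (hit > 0) hit, if (!is.na(full)) full)))
    if (!is.finite(pos)) return(NA_integer_)
    as.integer(pos)
  }
  pos <- vapply(toupper(seqs), find_one, integer(1), USE.NAMES = FALSE)
  ins <- ifelse(is.na(pos), NA_character_, substr(seqs, 1L, pos - 1L))
  len <- nchar(ins)
  reason <- ifelse(is.na(pos), "no-adapter",
                   ifelse(len < min_insert, "too-short",
                          ifelse(len > max_insert, "too-long", "ok")))
  ins[reason != "ok"] <- NA_character_
  data.frame(insert = ins, reason = reason, stringsAsFactors = FALSE)
}

# leftmost start of `pattern` in `s` with <= max_mm substitutions, full
# pattern only (no truncation at the read end); NA when absent
locate_approx <- function(s, pattern, max_mm = 1L) {
  n <- nchar(s); m <- nchar(pattern)
  if (m > n) return(NA_integer_)
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  pv <- strsplit(pattern, "", fixed = TRUE)[[1]]
  for (i in seq_len(n - m + 1L)) {
    if (sum(sv[i:(i + m - 1L)] != pv) <= max_mm) return(i)
  }
  NA_integer_
}

#' Collapse reads to unique tags with per-library counts
#'
#' @param reads data.frame with columns `library` and `seq` (QC-passed,
#'   trimmed inserts).
#' @return data.frame with one row per distinct sequence: column `seq`
#'   plus one integer count column per library. Total counts equal the
#'   number of input reads.
#' @export
collapse_unique <- function(reads) {
  if (NROW(reads) == 0L)
    return(data.frame(seq = character(), stringsAsFactors = FALSE))
  tab <- table(reads$seq, reads$library)
  libs <- colnames(tab)
  out <- data.frame(seq = rownames(tab), stringsAsFactors = FALSE)
  for (l in libs) out[[l]] <- as.integer(tab[, l])
  out <- out[order(out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-library and total counts of a collapsed tag table
#'
#' @param tags data.frame from [collapse_unique()].
#' @return Numeric vector of per-library totals.
#' @export
library_totals <- function(tags) {
  libs <- setdiff(names(tags), "seq")
  vapply(libs, function(l) sum(tags[[l]]), numeric(1))
}

#' Filter and truncate degradome reads
#'
#' A degradome read is dropped when it is shorter than 20 nt or when any
#' of its first 20 positions has a Phred quality below 20; otherwise
#' exactly its first 20 nucleotides are retained.
#'
#' @param reads data.frame with columns `seq` and `qual`.
#' @return data.frame with columns `tag` (20-nt tag or NA) and `reason`
#'   (`"ok"`, `"too-short"`, `"low-quality"`).
#' @export
filter_degradome_read <- function(reads) {
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence/quality length mismatch")
  n <- NROW(reads)
  reason <- character(n); tag <- rep(NA_character_, n)
  scores <- phred_scores(reads$qual)
  for (i in seq_len(n)) {
    if (nchar(reads$seq[i]) < 20L) { reason[i] <- "too-short"; next }
    if (any(scores[[i]][1:20] < 20L)) { reason[i] <- "low-quality"; next }
    reason[i] <- "ok"; tag[i] <- substr(reads$seq[i], 1L, 20L)
  }
  data.frame(tag = tag, reason = reason, stringsAsFactors = FALSE)
}

#' Annotate collapsed tags against ordered reference categories
#'
#' Each tag receives the label of the first reference set it maps to, in
#' the given priority order (exact match for category assignment unless
#' `max_mismatch` is raised). Tags mapping to none of the categorical
#' references but to the genome get `"genome-only"`; the rest are
#' `"unmapped"`. Tags labeled `repeat` or `other-ncRNA` are conventionally
#' excluded from downstream miRNA and PHAS discovery.
#'
#' @param tags data.frame from [collapse_unique()] (or character vector).
#' @param refs Named list of [reference()] objects in priority order,
#'   e.g. `list("other-ncRNA" = ..., "repeat" = ..., "mRNA" = ...)`.
#' @param genome Optional genome [reference()] for the `"genome-only"`
#'   fallback.
#' @param max_mismatch Mismatches tolerated for category assignment
#'   (default 0, exact).
#' @return data.frame with columns `seq` and `category`.
#' @export
annotate_categories <- function(tags, refs, genome = NULL,
                                max_mismatch = 0L) {
  seqs <- if (is.data.frame(tags)) tags$seq else tags
  category <- rep("unmapped", length(seqs))
  unassigned <- rep(TRUE, length(seqs))
  for (label in names(refs)) {
    if (!any(unassigned)) break
    hits <- map_tags(seqs[unassigned], refs[[label]],
                     max_mismatch = max_mismatch)
    hit_seqs <- unique(hits$tag)
    sel <- unassigned & seqs %in% hit_seqs
    category[sel] <- label
    unassigned <- unassigned & !sel
  }
  if (!is.null(genome) && any(unassigned)) {
    hits <- map_tags(seqs[unassigned], genome, max_mismatch = max_mismatch)
    sel <- unassigned & seqs %in% unique(hits$tag)
    category[sel] <- "genome-only"
  }
  data.frame(seq = seqs, category = category, stringsAsFactors = FALSE)
}

#' Write collapsed tags as FASTA with abundance headers
#'
#' Headers follow the `>tagN_xCOUNT` convention, where COUNT is the total
#' read count of the tag over all libraries.
#'
#' @param tags data.frame from [collapse_unique()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tags_fasta <- function(tags, path) {
  total <- rowSums(as.matrix(tags[, setdiff(names(tags), "seq"),
                                  drop = FALSE]))
  seqs <- tags$seq
  names(seqs) <- sprintf("tag%d_x%d", seq_along(seqs), as.integer(total))
  write_fasta(seqs, path)
}
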