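#' Find genomic homologs of known mature miRNAs
#'
#' Maps a catalog of known mature miRNAs (from any species) to the genome
#' allowing at most `max_mismatch` substitutions on either strand.
#'
#' @param known_matures Named character vector of mature sequences
#'   (20-24 nt; U is converted to T), or a path readable by
#'   [read_fasta()].
#' @param genome A [reference()].
#' @param max_mismatch Mismatch cap (default 2).
#' @return Alignment data.frame as from [map_tags()], plus a `query`
#'   column naming the catalog entry.
#' @export
find_homolog_loci <- function(known_matures, genome, max_mismatch = 2L) {
  if (is.character(known_matures) && length(known_matures) == 1L &&
      file.exists(known_matures))
    known_matures <- read_fasta(known_matures)
  if (length(known_matures) == 0L) stop("empty miRNA catalog")
  seqs <- toupper(chartr("U", "T", known_matures))
  lens <- nchar(seqs)
  if (any(lens < 20L | lens > 24L))
    stop("known matures must be 20-24 nt")
  hits <- map_tags(seqs, genome, max_mismatch = max_mismatch)
  lut <- split(names(seqs), seqs)
  if (nrow(hits) == 0L) { hits$query <- character(0); return(hits) }
  hits$query <- vapply(hits$tag, function(s) lut[[s]][1], character(1),
                       USE.NAMES = FALSE)
  hits
}

#' Extract hairpin candidate windows around a homolog hit
#'
#' For each flank size, two windows are produced: one extended upstream
#' of the mature hit and one extended downstream, both containing the
#' mature. Windows truncated by a chromosome end are flagged `clipped`.
#'
#' @param hit One-row alignment data.frame (columns `ref`, `start`,
#'   `strand`, `tag`).
#' @param genome A [reference()].
#' @param flanks Flank sizes in nt (default 80, 130, 180).
#' @return data.frame with columns `ref`, `start`, `end`, `strand`,
#'   `side`, `flank`, `clipped`, `seq`, `mature_offset` (1-based position
#'   of the mature within the window sequence, in window orientation).
#' @export
extract_candidates <- function(hit, genome, flanks = c(80L, 130L, 180L)) {
  stopifnot(nrow(hit) == 1L)
  L <- nchar(genome$sequences[[hit$ref]])
  tag_len <- nchar(hit$tag)
  hit_end <- hit$start + tag_len - 1L
  rows <- list()
  for (f in flanks) {
    for (side in c("upstream", "downstream")) {
      s <- if (side == "upstream") hit$start - f else hit$start
      e <- if (side == "upstream") hit_end else hit_end + f
      clipped <- s < 1L || e > L
      s2 <- max(1L, s); e2 <- min(L, e)
      seq <- substr(genome$sequences[[hit$ref]], s2, e2)
      off <- hit$start - s2 + 1L
      if (hit$strand == "-") {
        seq <- revcomp(seq)
        off <- e2 - hit_end + 1L
      }
      rows[[length(rows) + 1L]] <-
        data.frame(ref = hit$ref, start = s2, end = e2, strand = hit$strand,
                   side = side, flank = f, clipped = clipped, seq = seq,
                   mature_offset = off, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Pairs between the mature and star intervals of a folded precursor.
duplex_pairs <- function(pairtable, mature, star) {
  i <- mature[1]:mature[2]
  partners <- pairtable[i]
  sum(!is.na(partners) & partners >= star[1] & partners <= star[2])
}

#' Screen a candidate precursor for a novel miRNA annotation
#'
#' Applies the standard evidence-based gates for annotating a novel plant
#' miRNA from an expressed hairpin: (a) at least `min_paired` base pairs
#' in the mature:miRNA* duplex, (b) folding energy below `max_energy`
#' kcal/mol, and (c) presence of the miRNA* - the most abundant tag on
#' the precursor is taken as the mature, and some other expressed tag
#' must sit on the opposite arm forming a duplex with 2-nt 3' overhangs
#' on both ends. The first failed criterion is reported.
#'
#' @param precursor Precursor sequence (candidate from a +/-300-nt
#'   extension of an expressed tag locus).
#' @param tags data.frame of tags expressed on the precursor: columns
#'   `seq`, `start` (1-based on the precursor), `count`.
#' @param folded Optional result of [fold()] on the precursor (computed
#'   with the baseline engine when omitted).
#' @param min_paired Minimum duplex base pairs (default 18).
#' @param max_energy Maximum folding energy in kcal/mol (default -40).
#' @param overhang_tol Tolerance in nt on the 2-nt overhang geometry.
#' @return A list with `status` (`"accepted"` or `"rejected"`), `reason`
#'   (`"ok"`, `"no-expression"`, `"pairing"`, `"energy"`, `"no-star"`),
#'   and for accepted calls `mature`, `star`, `mature_interval`,
#'   `star_interval`, `arm`.
#' @export
screen_novel_precursor <- function(precursor, tags, folded = NULL,
                                   min_paired = 18L, max_energy = -40,
                                   overhang_tol = 1L) {
  if (NROW(tags) == 0L)
    return(list(status = "rejected", reason = "no-expression"))
  if (is.null(folded)) folded <- fold(precursor)
  pt <- folded$pairtable
  tags <- tags[order(-tags$count), , drop = FALSE]
  m_start <- tags$start[1]
  m_end <- m_start + nchar(tags$seq[1]) - 1L
  # (c) candidates for the star among the remaining expressed tags
  star_row <- NULL
  for (i in seq_len(nrow(tags))[-1]) {
    s_start <- tags$start[i]
    s_end <- s_start + nchar(tags$seq[i]) - 1L
    if (is_star_duplex(pt, c(m_start, m_end), c(s_start, s_end),
                       tol = overhang_tol)) { star_row <- i; break }
  }
  # (a) duplex pairing, evaluated over the mature:star duplex when a star
  # exists, otherwise over the mature's pairing to anywhere
  paired <- if (!is.null(star_row)) {
    duplex_pairs(pt, c(m_start, m_end),
                 c(tags$start[star_row],
                   tags$start[star_row] + nchar(tags$seq[star_row]) - 1L))
  } else sum(!is.na(pt[m_start:m_end]))
  if (paired < min_paired)
    return(list(status = "rejected", reason = "pairing"))
  if (!(folded$energy < max_energy))
    return(list(status = "rejected", reason = "energy"))
  if (is.null(star_row))
    return(list(status = "rejected", reason = "no-star"))
  list(status = "accepted", reason = "ok",
       mature = tags$seq[1], star = tags$seq[star_row],
       mature_interval = c(m_start, m_end),
       star_interval = c(tags$start[star_row],
                         tags$start[star_row] +
                           nchar(tags$seq[star_row]) - 1L),
       arm = if (m_start < tags$start[star_row]) "5p" else "3p")
}

# Dicer duplex geometry on the folded precursor: the partner of the
# mature 5' end must fall 2 nt inside the star 3' end and the partner of
# the star 5' end 2 nt inside the mature 3' end (2-nt 3' overhangs on
# both strands of the duplex), within `tol` nt of slack for folding
# ambiguity.
is_star_duplex <- function(pairtable, mature, star, tol = 1L) {
  p1 <- pairtable[mature[1]]
  p2 <- pairtable[star[1]]
  if (is.na(p1) || is.na(p2)) {
    # fall back to the nearest paired position inside either 5' end
    p1 <- first_partner(pairtable, mature[1], mature[2])
    p2 <- first_partner(pairtable, star[1], star[2])
    if (is.na(p1) || is.na(p2)) return(FALSE)
  }
  abs(p1 - (star[2] - 2L)) <= tol && abs(p2 - (mature[2] - 2L)) <= tol
}

first_partner <- function(pt, from, to) {
  step <- if (from <= to) 1L else -1L
  for (i in seq(from, to, by = step)) {
    if (!is.na(pt[i])) {
      # extrapolate back to the 5' end assuming a contiguous helix
      return(pt[i] + (i - from))
    }
  }
  NA_integer_
}

#' Screen a conserved-miRNA hairpin candidate
#'
#' MIRcheck-style structural screen of the mature within a folded
#' hairpin: at most `max_mismatch` unpaired mature positions, at most
#' `max_bulge` bulged or asymmetrically unpaired nucleotides, and no run
#' of more than `max_consecutive` consecutive unpaired mature positions.
#' A mature spanning the terminal loop fails outright.
#'
#' Unpaired runs are classified by the enclosing helix: a run of length
#' `a` facing a gap of length `b` on the opposing arm contributes
#' `min(a, b)` mismatch positions and `|a - b|` bulged/asymmetric
#' positions.
#'
#' @param folded Result of [fold()] on the precursor.
#' @param mature_interval Integer vector `c(start, end)` of the mature on
#'   the precursor.
#' @param max_mismatch,max_bulge,max_consecutive Criterion caps
#'   (defaults 5, 2, 3).
#' @return A list with `pass` (logical), `reason`, `mismatches`,
#'   `bulged`, `longest_run`.
#' @export
screen_conserved_precursor <- function(folded, mature_interval,
                                       max_mismatch = 5L, max_bulge = 2L,
                                       max_consecutive = 3L) {
  pt <- folded$pairtable
  i0 <- mature_interval[1]; i1 <- mature_interval[2]
  partners <- pt[i0:i1]
  if (any(!is.na(partners) & partners >= i0 & partners <= i1))
    return(list(pass = FALSE, reason = "loop-spanning",
                mismatches = NA_integer_, bulged = NA_integer_,
                longest_run = NA_integer_))
  unpaired <- is.na(partners)
  runs <- rle(unpaired)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  # walk unpaired runs and compare with the opposing-arm gap
  mism <- 0L; bulge <- 0L
  pos <- i0
  idx <- 1L
  run_bounds <- cumsum(runs$lengths)
  run_starts <- c(1L, utils::head(run_bounds, -1L) + 1L)
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r]) next
    a <- runs$lengths[r]
    left <- i0 + run_starts[r] - 2L   # last position before the run
    right <- i0 + run_bounds[r]       # first position after the run
    jl <- if (left >= i0) pt[left] else NA_integer_
    jr <- if (right <= i1) pt[right] else NA_integer_
    if (!is.na(jl) && !is.na(jr)) {
      b <- abs(jl - jr) - 1L
      mism <- mism + min(a, b)
      bulge <- bulge + abs(a - b)
    } else {
      # run at the mature boundary: treat as asymmetric (opposing side
      # unknown/absent)
      bulge <- bulge + a
    }
  }
  pass <- mism <= max_mismatch && bulge <= max_bulge &&
    longest <= max_consecutive
  reason <- if (pass) "ok"
  else if (longest > max_consecutive) "consecutive-mismatches"
  else if (mism > max_mismatch) "mismatches"
  else "bulged"
  list(pass = pass, reason = reason, mismatches = mism, bulged = bulge,
       longest_run = longest)
}

#' Match tags directly against a mature-miRNA catalog
#'
#' Identifies conserved mature miRNAs without a detectable precursor by
#' matching expressed tags against catalog sequences with a bounded
#' number of substitutions (the tag must align within the catalog entry,
#' ungapped).
#'
#' @param tags Character vector of tag sequences.
#' @param catalog Named character vector of known mature sequences.
#' @param max_mismatch Substitution cap (default 2).
#' @return data.frame with columns `seq`, `catalog_name`, `mismatches`
#'   (best match per tag).
#' @export
match_mature_only <- function(tags, catalog, max_mismatch = 2L) {
  catalog <- toupper(chartr("U", "T", catalog))
  cat_ref <- reference(catalog, name = "mature-catalog")
  hits <- map_tags(tags, cat_ref, max_mismatch = max_mismatch)
  hits <- hits[hits$strand == "+", , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(seq = character(), catalog_name = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  hits <- hits[order(hits$tag, hits$mismatches), , drop = FALSE]
  best <- hits[!duplicated(hits$tag), , drop = FALSE]
  data.frame(seq = best$tag, catalog_name = best$ref,
             mismatches = best$mismatches, stringsAsFactors = FALSE)
}

#' Assign names to miRNA annotations
#'
#' Matures identical in sequence to a prior catalog entry inherit the
#' prior name. Remaining conserved annotations are named
#' `MIR<family><letter>` with lowercase letters assigned in genomic
#' order within each family; novel annotations get sequential
#' `novel-miR-N` identifiers in genomic order. Name collisions are
#' resolved by deterministic numeric suffixing.
#'
#' @param annotations data.frame with columns `mature` (sequence),
#'   `family` (character; NA for novel), `status` (`"conserved"` or
#'   `"novel"`), `ref`, `start`.
#' @param prior Optional named character vector of previously reported
#'   mature sequences (names are the published miRNA names).
#' @return The input with a `name` column added.
#' @export
assign_names <- function(annotations, prior = NULL) {
  ann <- annotations[order(annotations$ref, annotations$start), ,
                     drop = FALSE]
  n <- nrow(ann)
  name <- rep(NA_character_, n)
  if (!is.null(prior)) {
    prior <- toupper(chartr("U", "T", prior))
    lut <- structure(names(prior), names = unname(prior))
    hit <- lut[toupper(chartr("U", "T", ann$mature))]
    name[!is.na(hit)] <- hit[!is.na(hit)]
  }
  todo <- which(is.na(name) & ann$status == "conserved")
  for (fam in unique(ann$family[todo])) {
    ix <- todo[ann$family[todo] == fam]
    name[ix] <- sprintf("MIR%s%s", fam, letters[seq_along(ix)])
  }
  novel <- which(is.na(name) & ann$status == "novel")
  name[novel] <- sprintf("novel-miR-%d", seq_along(novel))
  # deterministic collision suffixing
  dup <- duplicated(name)
  while (any(dup)) {
    for (i in which(dup)) {
      j <- 2L
      while (paste0(name[i], ".", j) %in% name) j <- j + 1L
      name[i] <- paste0(name[i], ".", j)
    }
    dup <- duplicated(name)
  }
  ann$name <- name
  rownames(ann) <- NULL
  ann
}
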