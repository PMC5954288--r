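#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that uppercases the
#' sequences and returns plain character strings keyed by the first word of
#' each header, the representation used throughout the package.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to a 4-line-record FASTQ file (Sanger/Phred+33).
#' @return A data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = if (is.null(names(x))) sprintf("read%d", seq_along(x)) else names(x),
             seq = toupper(as.character(x)),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads A data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param qual Character vector of quality strings.
#' @return List of integer vectors.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}
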