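#' Predict RNA secondary structure for a hairpin candidate
#'
#' Folds a candidate precursor sequence and returns the dot-bracket
#' structure, a folding energy, the number of paired nucleotides and a
#' 1-based pair table.
#'
#' Two engines are available. The default `"baseline"` engine is a
#' built-in maximum base-pairing folder (minimum hairpin loop of 3
#' unpaired bases, Watson-Crick plus G:U pairs) whose energy is a simple
#' stacking sum (-3 kcal/mol per stacked G:C, -2 per A:U, -1 per G:U);
#' these energies are *not* thermodynamic free energies and thresholds on
#' them are calibrated only on synthetic constructs. The `"rnafold"`
#' engine shells out to ViennaRNA's `RNAfold` binary when it is on the
#' PATH and returns true minimum-free-energy structures.
#'
#' @param seq A nucleotide sequence (ACGU or ACGT; at most 1000 nt).
#' @param engine `"baseline"` or `"rnafold"`.
#' @param min_loop Minimum hairpin loop size for the baseline engine.
#' @return A list with elements `structure` (dot-bracket string), `energy`
#'   (kcal/mol), `pairs` (number of base pairs) and `pairtable` (integer
#'   vector; `pairtable[i]` is the partner of position i or `NA`).
#' @export
fold <- function(seq, engine = c("baseline", "rnafold"), min_loop = 3L) {
  engine <- match.arg(engine)
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  if (nchar(seq) > 1000L) stop("sequence longer than 1000 nt")
  if (grepl("[^ACGT]", seq)) stop("sequence contains non-ACGU characters")
  if (engine == "baseline") {
    res <- .nussinov_fold(seq, as.integer(min_loop))
    res$pairtable <- as.integer(res$pairtable)
    return(res)
  }
  fold_rnafold(seq)
}

fold_rnafold <- function(seq) {
  bin <- Sys.which("RNAfold")
  if (!nzchar(bin)) stop("RNAfold binary not found on PATH")
  out <- system2(bin, c("--noPS"), input = chartr("T", "U", seq),
                 stdout = TRUE)
  line <- out[length(out)]
  db <- sub("^([.()]+).*$", "\\1", line)
  energy <- as.numeric(sub("^[.()]+\\s+\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1",
                           line))
  pt <- pairtable_from_db(db)
  list(structure = db, energy = energy,
       pairs = sum(!is.na(pt)) %/% 2L, pairtable = pt)
}

#' Convert a dot-bracket string to a 1-based pair table
#'
#' @param db Dot-bracket structure string.
#' @return Integer vector of partners (`NA` for unpaired positions).
#' @export
pairtable_from_db <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  pt <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced brackets")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced brackets")
  pt
}
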