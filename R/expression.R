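#' Normalize raw counts to reads per ten million (RPTM)
#'
#' `RPTM = count / library_total * 1e7`. By default library totals are
#' the column sums of the supplied count matrix, i.e. all sequencing tags
#' that entered the matrix; pass explicit `totals` to normalize by, e.g.,
#' QC-passed trimmed read totals or mapped-only totals.
#'
#' @param counts Numeric matrix (rows = small RNAs, columns = libraries).
#' @param totals Optional named vector of per-library tag totals.
#' @return Matrix of RPTM values with the same dimnames.
#' @export
rptm <- function(counts, totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(totals)) totals <- colSums(counts)
  if (any(totals <= 0)) stop("library totals must be positive")
  sweep(counts, 2, totals, "/") * 1e7
}

#' Select small RNAs for clustering
#'
#' Keeps rows with at least `min_rptm` RPTM in at least `min_libraries`
#' libraries and a sample standard deviation of at least `min_sd`
#' (defaults 5, 2, 1).
#'
#' @param mat RPTM matrix from [rptm()].
#' @param min_rptm,min_libraries,min_sd Filter thresholds.
#' @return Row-subset of `mat`.
#' @export
select_for_clustering <- function(mat, min_rptm = 5, min_libraries = 2L,
                                  min_sd = 1) {
  keep <- rowSums(mat >= min_rptm) >= min_libraries &
    apply(mat, 1, stats::sd) >= min_sd
  mat[keep, , drop = FALSE]
}

#' Correlate libraries and cluster them hierarchically
#'
#' Transforms RPTM values by `ln(x + 1)`, computes Pearson correlations
#' between library columns, and clusters libraries on distance
#' `1 - correlation` with complete linkage. Zero-variance columns are
#' excluded with a warning (their correlations are undefined).
#'
#' @param mat RPTM matrix (rows = small RNAs, columns = libraries).
#' @return A list with `correlation` (matrix), `hclust` (an
#'   [stats::hclust] object) and `excluded` (column names dropped).
#' @export
correlate_and_cluster <- function(mat) {
  if (nrow(mat) < 2L) stop("need at least 2 rows")
  lx <- log1p(mat)
  v <- apply(lx, 2, stats::sd)
  excluded <- colnames(lx)[v == 0]
  if (length(excluded) > 0L)
    warning("excluding zero-variance column(s): ",
            paste(excluded, collapse = ", "))
  lx <- lx[, v > 0, drop = FALSE]
  cc <- stats::cor(lx)
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "complete")
  list(correlation = cc, hclust = hc, excluded = excluded)
}

#' Principal component analysis of library profiles
#'
#' Rows with mean RPTM of at least `min_mean` are retained, values are
#' `ln(x + 1)` transformed, and libraries (columns) are treated as
#' observations: the transformed matrix is transposed, column-centered
#' and decomposed by SVD.
#'
#' @param mat RPTM matrix (rows = small RNAs, columns = libraries).
#' @param min_mean Minimum row mean RPTM (default 5).
#' @return A list with `coordinates` (libraries x components) and
#'   `explained` (non-increasing variance fractions summing to 1).
#' @export
expression_pca <- function(mat, min_mean = 5) {
  if (ncol(mat) < 3L) stop("need at least 3 libraries")
  mat <- mat[rowMeans(mat) >= min_mean, , drop = FALSE]
  if (nrow(mat) < 2L) stop("fewer than 2 rows pass the mean-RPTM filter")
  pc <- stats::prcomp(t(log1p(mat)), center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = pc$x, explained = expl)
}

#' Export a library dendrogram in Newick format
#'
#' @param hc An [stats::hclust] object from [correlate_and_cluster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
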