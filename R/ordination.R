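#' Pairwise distances between samples on binary methylation calls
#'
#' Computes sample-by-sample dissimilarities over the differentially
#' methylated universe.  The default metric is Euclidean distance on the 0/1
#' call vectors, i.e. the square root of the Hamming (mismatch) count — the
#' canonical input for classical scaling.  `"hamming"` (mismatch proportion)
#' and `"jaccard"` are available as alternatives.
#'
#' @param calls Call matrix from [call_methylation()].
#' @param universe Locus ids to restrict to (default: the differential
#'   universe of `calls`).
#' @param metric One of `"euclidean"`, `"hamming"`, `"jaccard"`.
#' @return A [stats::dist] object with sample labels.
#' @export
binary_distance <- function(calls, universe = differential_universe(calls),
                            metric = c("euclidean", "hamming", "jaccard")) {
  metric <- match.arg(metric)
  if (!length(universe)) abort("empty differential universe")
  m <- wide_to_matrix(calls)
  missing_loci <- setdiff(universe, rownames(m))
  if (length(missing_loci)) abort("`universe` contains loci absent from `calls`")
  x <- t(m[universe, , drop = FALSE])
  if (ncol(t(x)) < 2 && nrow(x) < 2) abort("need at least 2 samples")
  switch(metric,
    euclidean = stats::dist(x, method = "euclidean"),
    hamming = stats::dist(x, method = "manhattan") / ncol(x),
    jaccard = stats::dist(x, method = "binary")
  )
}

#' Classical multidimensional scaling (principal coordinates)
#'
#' Double-centers the squared distance matrix, eigendecomposes it and scales
#' the eigenvectors by the square roots of the top positive eigenvalues.  The
#' percentage of variation per axis is its eigenvalue over the sum of the
#' positive eigenvalues (negative eigenvalues, which can arise for
#' non-Euclidean metrics, are excluded from the denominator so percentages
#' stay in \[0, 100\]).
#'
#' @param d A [stats::dist] object or symmetric distance matrix.
#' @param k Number of axes requested (default 2).
#' @return Object of class `epirad_mds`: `$points` (tibble `sample_id`,
#'   `axis1`, `axis2`, ...), `$eigenvalues`, `$percent_variance` (one entry
#'   per returned axis), `$k`.
#' @export
classical_mds <- function(d, k = 2) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isTRUE(all.equal(m, t(m))) || any(diag(m) != 0) || any(m < 0)) {
      abort("`d` must be a symmetric non-negative matrix with zero diagonal")
    }
    d <- stats::as.dist(m)
  }
  if (k < 1) abort("`k` must be >= 1")
  n <- attr(d, "Size")
  fit <- stats::cmdscale(d, k = min(k, n - 1), eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > 0]
  pts <- fit$points
  if (is.null(rownames(pts))) {
    rownames(pts) <- attr(d, "Labels") %||% paste0("s", seq_len(n))
  }
  avail <- ncol(pts)
  # cmdscale can return fewer columns than requested when the spectrum runs
  # out of positive eigenvalues
  if (avail < k) {
    warn(paste0("only ", avail, " positive axes available (", k, " requested)"))
  }
  colnames(pts) <- paste0("axis", seq_len(avail))
  points <- dplyr::bind_cols(tibble(sample_id = rownames(pts)), as_tibble(pts))
  structure(
    list(
      points = points,
      eigenvalues = eig,
      percent_variance = 100 * eig[seq_len(avail)] / sum(pos),
      k = avail
    ),
    class = "epirad_mds"
  )
}

#' @export
print.epirad_mds <- function(x, ...) {
  cat(sprintf("<epirad_mds> %d samples, %d axes\n", nrow(x$points), x$k))
  cat("  % variance per axis:",
      paste(sprintf("%.1f", x$percent_variance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.epirad_mds <- function(x, ...) x$points

#' @export
glance.epirad_mds <- function(x, ...) {
  tibble(n_samples = nrow(x$points), n_axes = x$k,
         pct_axis1 = x$percent_variance[1],
         pct_axis2 = if (x$k >= 2) x$percent_variance[2] else NA_real_)
}
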