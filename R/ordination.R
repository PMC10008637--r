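#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of `-d^2 / 2`,
#' eigendecomposition, and coordinates `v_k * sqrt(lambda_k)` on the axes
#' with positive eigenvalues. Chord-mean matrices need not be Euclidean;
#' axes with negative eigenvalues carry no coordinates and their total
#' magnitude is reported. Axis signs are fixed deterministically (first
#' loading of largest absolute size made positive) so repeated runs give
#' identical coordinates.
#'
#' @param dm a [distance_matrix()] result, `dist` or symmetric matrix with
#'   zero diagonal.
#' @param n_axes number of axes to return (capped at the number of
#'   positive eigenvalues).
#' @return a `pcoa_result`: `coordinates` (accession x axis),
#'   `eigenvalues` (all, descending), `proportion_explained` (per positive
#'   axis, relative to the positive eigenvalue total) and
#'   `negative_magnitude`.
#' @export
pcoa <- function(dm, n_axes = 2) {
  m <- as_dist_matrix(dm)
  if (n_axes < 1) stop("n_axes must be >= 1")
  n <- nrow(m)
  a <- -0.5 * m^2
  centred <- a - matrix(rowMeans(a), n, n) -
    matrix(colMeans(a), n, n, byrow = TRUE) + mean(a)
  eig <- eigen((centred + t(centred)) / 2, symmetric = TRUE)
  vals <- eig$values
  pos <- which(vals > max(vals[1], 0) * 1e-12 & vals > 0)
  keep <- pos[seq_len(min(n_axes, length(pos)))]
  coords <- if (length(keep)) {
    sweep(eig$vectors[, keep, drop = FALSE], 2, sqrt(vals[keep]), `*`)
  } else {
    matrix(0, n, 0)
  }
  for (k in seq_len(ncol(coords))) {        # deterministic sign convention
    j <- which.max(abs(coords[, k]))
    if (coords[j, k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(m)
  if (ncol(coords))
    colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  pos_total <- sum(vals[vals > 0])
  structure(list(coordinates = coords,
                 eigenvalues = vals,
                 proportion_explained = if (pos_total > 0 && length(keep))
                   vals[keep] / pos_total else numeric(0),
                 negative_magnitude = -sum(vals[vals < 0])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("pcoa_result:", nrow(x$coordinates), "points,",
      ncol(x$coordinates), "axes")
  if (length(x$proportion_explained))
    cat(sprintf(" (%s explained)",
                paste0(sprintf("%.1f%%", 100 * x$proportion_explained),
                       collapse = ", ")))
  cat("\n")
  invisible(x)
}
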