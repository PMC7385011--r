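#' Principal component analysis of an aligned coordinate ensemble
#'
#' Flattens every member of a pre-superposed family into a 3C-vector over
#' the aligned columns and eigen-decomposes the (mean-centred, unscaled)
#' coordinate covariance. The number of retained components is
#' min(S - 1, 3C). The sign of each component is fixed so its
#' largest-magnitude loading is positive, making projections reproducible
#' (up to that documented reflection convention).
#'
#' @param ensemble an `aligned_ensemble` ([superpose_ensemble()]) or an
#'   S x C x 3 array.
#' @param columns optional subset of column indices (positions within the
#'   ensemble's column set) to analyse, e.g. an invariant core.
#' @return An object of class `coord_pca`: `components` (3C' x k
#'   orthonormal), `eigenvalues` (descending), `variance_fractions`
#'   (summing to 1), `projections` (S x k member scores), `center`,
#'   `n_coordinates` and `n_columns`.
#' @export
coordinate_pca <- function(ensemble, columns = NULL) {
  coords <- if (inherits(ensemble, "aligned_ensemble")) ensemble$coords
            else ensemble
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  S <- dim(coords)[1]
  if (S < 3L) stop("precondition error: at least 3 structures are required")
  if (!is.null(columns)) coords <- coords[, columns, , drop = FALSE]
  C <- dim(coords)[2]
  X <- matrix(coords, nrow = S)   # S x 3C (all x, then all y, then all z)
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(S - 1L, 3L * C)
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  ## deterministic sign: largest-|loading| coordinate positive
  for (j in seq_len(k)) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  lam <- p$sdev^2
  lam <- lam[seq_len(k)]
  vf <- lam / sum(lam)
  structure(list(components = rot, eigenvalues = lam,
                 variance_fractions = vf, projections = scores,
                 center = p$center, n_coordinates = 3L * C,
                 n_columns = C),
            class = "coord_pca")
}

#' @export
print.coord_pca <- function(x, ...) {
  cat(sprintf(
    "<coord_pca> %d members x %d coordinates; PC1 %.1f%%, PC2 %.1f%%\n",
    nrow(x$projections), x$n_coordinates,
    100 * x$variance_fractions[1],
    if (length(x$variance_fractions) > 1) 100 * x$variance_fractions[2] else NA))
  invisible(x)
}

#' Quadrant clustering on a pair of principal components
#'
#' Labels each family member by the signs of its projections on two chosen
#' components: `(-,-)`, `(-,+)`, `(+,-)` or `(+,+)`. Zero projections are
#' assigned to the positive side (tie rule). The component pair (1, 3) is
#' the default axis choice for structure families of class C enzymes, where
#' it has been observed to resolve the groups best.
#'
#' @param p a [coordinate_pca()] result.
#' @param axis_x,axis_y component indices (defaults 1 and 3).
#' @return Character vector of quadrant labels, one per member.
#' @export
quadrant_cluster <- function(p, axis_x = 1L, axis_y = 3L) {
  stopifnot(inherits(p, "coord_pca"))
  k <- ncol(p$projections)
  if (axis_x > k || axis_y > k)
    stop("requested component does not exist (only ", k, " components)")
  sgn <- function(v) ifelse(v >= 0, "+", "-")
  paste0("(", sgn(p$projections[, axis_x]), ",",
         sgn(p$projections[, axis_y]), ")")
}
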