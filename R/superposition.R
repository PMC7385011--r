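#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation R and translation t minimizing the RMSD between
#' `mobile %*% R + t` and `reference` (SVD solution; a reflection in the
#' optimum is corrected by flipping the smallest singular direction).
#'
#' @param mobile N x 3 coordinate matrix to move.
#' @param reference N x 3 coordinate matrix to fit onto.
#' @return An object of class `superposition` with fields `rotation`
#'   (3 x 3, det +1), `translation` (length-3, Angstrom) and `rmsd`
#'   (Angstrom, the minimized value). Apply with [apply_superposition()].
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L ||
      ncol(reference) != 3L)
    stop("point sets must be N x 3 with equal N")
  n <- nrow(mobile)
  if (n < 3L) stop("geometry error: at least 3 points are required")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (qr(A)$rank < 2L || qr(B)$rank < 2L)
    stop("geometry error: collinear or degenerate point configuration")
  H <- crossprod(A, B)                  # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)           # mobile %*% R aligns onto B frame
  fit <- A %*% R
  rmsd <- sqrt(mean(rowSums((fit - B)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cr - cm %*% R),
                 rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' @param sp a [kabsch_superpose()] result.
#' @param xyz N x 3 coordinate matrix.
#' @return The transformed N x 3 matrix.
#' @export
apply_superposition <- function(sp, xyz) {
  stopifnot(inherits(sp, "superposition"))
  sweep(as.matrix(xyz) %*% sp$rotation, 2, sp$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f Angstrom\n", x$rmsd))
  invisible(x)
}

#' Superpose a structure family on alignment columns
#'
#' All structures are rigidly fitted onto the reference (the first by
#' default) using the coordinates at `fit_columns` only; the returned block
#' covers the ungapped columns of the alignment.
#'
#' @param structures list of [ca_structure()] objects.
#' @param map an `alignment_map` covering all structures.
#' @param fit_columns 1-based alignment columns used for the fit; must be a
#'   subset of `map$ungapped_columns` with at least 3 members. Default: all
#'   ungapped columns.
#' @param reference index of the reference structure (default 1).
#' @return An object of class `aligned_ensemble`: list with `coords`
#'   (S x C x 3 array over ungapped columns), `columns` (the ungapped
#'   column indices), `fit_columns`, `names` and `res_id` (C x S matrix of
#'   the residue numbers behind each column).
#' @export
superpose_ensemble <- function(structures, map, fit_columns = NULL,
                               reference = 1L) {
  stopifnot(inherits(map, "alignment_map"))
  cols <- map$ungapped_columns
  if (is.null(fit_columns)) fit_columns <- cols
  if (length(fit_columns) == 0L)
    stop("precondition error: empty fit column set")
  if (!all(fit_columns %in% cols))
    stop("fit_columns must be a subset of the ungapped columns")
  if (length(fit_columns) < 3L)
    stop("at least 3 fit columns are required")
  S <- length(structures); C <- length(cols)
  coords <- array(NA_real_, dim = c(S, C, 3))
  block <- function(s, v, which_cols) {
    idx <- match(v[which_cols], s$res_id)
    s$xyz[idx, , drop = FALSE]
  }
  ref_s <- structures[[reference]]
  ref_map <- map$maps[[ref_s$name]]
  ref_fit <- block(ref_s, ref_map, fit_columns)
  for (i in seq_len(S)) {
    s <- structures[[i]]
    v <- map$maps[[s$name]]
    sp <- kabsch_superpose(block(s, v, fit_columns), ref_fit)
    coords[i, , ] <- apply_superposition(sp, block(s, v, cols))
  }
  res_id <- vapply(structures, function(s) map$maps[[s$name]][cols],
                   integer(C))
  if (C == 1L) res_id <- matrix(res_id, nrow = 1L)
  structure(list(coords = coords, columns = cols,
                 fit_columns = fit_columns,
                 names = vapply(structures, function(s) s$name, character(1)),
                 res_id = res_id),
            class = "aligned_ensemble")
}

#' Ellipsoid volume of a positional scatter
#'
#' The spread of a set of aligned C-alpha positions is summarised as the
#' volume of the ellipsoid whose semi-axes are the square roots of the
#' eigenvalues of the positional covariance (population form, 1/n):
#' V = (4/3) * pi * sqrt(lambda1 * lambda2 * lambda3). V is zero iff the
#' points coincide or are coplanar/collinear.
#'
#' @param points M x 3 matrix of positions (M >= 2).
#' @return Volume in cubic Angstrom (>= 0).
#' @export
column_ellipsoid_volume <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stop("precondition error: at least 2 points are required")
  centred <- sweep(points, 2, colMeans(points))
  covm <- crossprod(centred) / nrow(points)   # population covariance
  lam <- pmax(eigen(covm, symmetric = TRUE, only.values = TRUE)$values, 0)
  (4 / 3) * pi * sqrt(prod(lam))
}

#' Iterative invariant-core analysis of a structure family
#'
#' The invariant core is the set of aligned positions whose positional
#' ellipsoid volumes across the family fall below a cutoff. Starting from
#' all ungapped columns, the family is superposed on the current candidate
#' set, per-column ellipsoid volumes are computed, and the single
#' largest-volume column is removed (ties broken towards the lowest column
#' index); this repeats until every remaining column is below `cutoff` or
#' only `min_core` columns remain.
#'
#' @param structures list of [ca_structure()] objects (>= 3).
#' @param map an `alignment_map`.
#' @param cutoff per-column volume cutoff in cubic Angstrom (default 1.0).
#' @param min_core minimum number of surviving columns (>= 3).
#' @param reference reference structure index for superposition.
#' @param resuperpose re-fit the family on the surviving set after every
#'   elimination (default TRUE); FALSE fits once on all columns.
#' @param criterion `"per_column"` stops when all surviving volumes are
#'   below `cutoff`; `"total"` stops when their sum is.
#' @return An object of class `core_result`: `volumes` (per ungapped column,
#'   at the final iteration), `core_columns`, `removal_order`, `cutoff` and
#'   `columns` (the ungapped column universe).
#' @export
find_invariant_core <- function(structures, map, cutoff = 1.0,
                                min_core = 3L, reference = 1L,
                                resuperpose = TRUE,
                                criterion = c("per_column", "total")) {
  criterion <- match.arg(criterion)
  if (min_core < 3L) stop("precondition error: min_core must be >= 3")
  if (length(structures) < 3L)
    stop("at least 3 structures are required")
  cols <- map$ungapped_columns
  if (length(cols) < min_core)
    stop("fewer ungapped columns than min_core")
  candidate <- seq_along(cols)       # indices into cols
  removal <- integer(0)
  ens <- superpose_ensemble(structures, map, fit_columns = cols,
                            reference = reference)
  vols <- col_volumes(ens$coords)
  repeat {
    if (resuperpose) {
      ens <- superpose_ensemble(structures, map,
                                fit_columns = cols[candidate],
                                reference = reference)
      vols <- col_volumes(ens$coords)
    }
    v_cand <- vols[candidate]
    done <- if (criterion == "per_column") all(v_cand < cutoff)
            else sum(v_cand) < cutoff
    if (done || length(candidate) <= min_core) break
    worst <- candidate[which.max(v_cand)]    # which.max: first max => lowest index
    removal <- c(removal, worst)
    candidate <- setdiff(candidate, worst)
  }
  structure(list(volumes = setNames(vols, cols),
                 core_columns = cols[candidate],
                 removal_order = cols[removal],
                 cutoff = cutoff,
                 columns = cols),
            class = "core_result")
}

col_volumes <- function(coords) {
  vapply(seq_len(dim(coords)[2]),
         function(j) column_ellipsoid_volume(coords[, j, ]),
         numeric(1))
}

#' @export
print.core_result <- function(x, ...) {
  cat(sprintf(
    "<core_result> %d/%d columns in core (cutoff %.3g A^3), %d removed\n",
    length(x$core_columns), length(x$columns), x$cutoff,
    length(x$removal_order)))
  invisible(x)
}

#' Tabulate a core analysis
#'
#' @param x a [find_invariant_core()] result.
#' @return data.frame with `column` (1-based), `volume_A3`, `in_core` (0/1)
#'   and `removal_rank` (NA for core columns).
#' @export
core_table <- function(x) {
  stopifnot(inherits(x, "core_result"))
  rank <- match(x$columns, x$removal_order)
  data.frame(column = x$columns,
             volume_A3 = unname(x$volumes),
             in_core = as.integer(x$columns %in% x$core_columns),
             removal_rank = rank)
}
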