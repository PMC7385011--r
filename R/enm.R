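#' Anisotropic elastic-network Hessian of a C-alpha structure
#'
#' Builds the 3N x 3N Hessian of the anisotropic network model (ANM): every
#' pair of C-alpha atoms within `cutoff` is joined by a harmonic spring of
#' stiffness `gamma`, giving off-diagonal superblocks
#' H_ij = -gamma * d d^T / |d|^2 (d = x_j - x_i) and diagonal superblocks
#' minus the sum of the off-diagonals in their row. The result is symmetric
#' and positive semi-definite with translation-invariant rows.
#'
#' @param s a [ca_structure()] or an N x 3 coordinate matrix.
#' @param cutoff contact distance cutoff in Angstrom (default 15).
#' @param gamma spring constant (dimensionless scale; default 1).
#' @return A 3N x 3N numeric matrix with attributes `cutoff`, `gamma` and
#'   `isolated` (indices of atoms without contacts, if any; a connectivity
#'   warning is raised and carried on to [normal_modes()]).
#' @export
build_hessian <- function(s, cutoff = 15, gamma = 1) {
  xyz <- if (inherits(s, "ca_structure")) s$xyz else as.matrix(s)
  n <- nrow(xyz)
  if (n < 2L) stop("at least 2 residues are required")
  if (cutoff <= 0 || gamma <= 0) stop("cutoff and gamma must be positive")
  d2 <- as.matrix(dist(xyz))^2
  contact <- d2 <= cutoff^2 & upper.tri(d2)
  pairs <- which(contact, arr.ind = TRUE)
  H <- matrix(0, 3 * n, 3 * n)
  if (nrow(pairs)) {
    i <- pairs[, 1]; j <- pairs[, 2]
    d <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
    w <- -gamma / rowSums(d^2)
    ## 3x3 superblock entries for every contact pair, fully vectorized;
    ## diagonal superblocks are minus the per-atom sum of the off-diagonals
    ## (collapsed with rowsum so repeated atoms accumulate correctly)
    for (a in 1:3) for (b in 1:3) {
      val <- w * d[, a] * d[, b]
      H[cbind(3 * (i - 1) + a, 3 * (j - 1) + b)] <- val
      H[cbind(3 * (j - 1) + a, 3 * (i - 1) + b)] <- val
      acc <- rowsum(c(-val, -val), group = c(i, j))
      atom <- as.integer(rownames(acc))
      H[cbind(3 * (atom - 1) + a, 3 * (atom - 1) + b)] <- acc[, 1]
    }
  }
  deg <- tabulate(c(pairs), nbins = n)
  isolated <- which(deg == 0L)
  if (length(isolated))
    warning("connectivity: ", length(isolated),
            " atom(s) have no contacts at cutoff ", cutoff)
  attr(H, "cutoff") <- cutoff
  attr(H, "gamma") <- gamma
  attr(H, "isolated") <- isolated
  H
}

#' Elastic-network normal modes
#'
#' Diagonalises a symmetric Hessian and returns ascending eigenpairs.
#' Modes are indexed 1-based; for a connected, non-collinear structure the
#' first six are the zero-frequency rigid-body motions, so the k-th
#' non-trivial mode is mode 6+k ([nontrivial_mode()]). Frequencies are
#' omega_k = sqrt(max(lambda_k, 0)) in arbitrary units.
#'
#' @param H Hessian from [build_hessian()] (3N x 3N symmetric).
#' @param n_modes number of lowest modes to keep (default: all).
#' @param zero_tol relative tolerance for zero modes,
#'   lambda < zero_tol * max(lambda) (default 1e-8).
#' @return An object of class `mode_set`: `eigenvalues` (ascending),
#'   `eigenvectors` (3N x k, orthonormal columns), `frequencies`, `n_atoms`,
#'   `n_zero`, `cutoff`, `gamma`.
#' @export
normal_modes <- function(H, n_modes = NULL, zero_tol = 1e-8) {
  H <- as.matrix(H)
  if (nrow(H) != ncol(H) || max(abs(H - t(H))) > 1e-8 * max(1, max(abs(H))))
    stop("H must be a symmetric square matrix")
  eig <- eigen(H, symmetric = TRUE)
  lam <- rev(eig$values)
  vec <- eig$vectors[, rev(seq_along(lam)), drop = FALSE]
  n_zero <- sum(lam < zero_tol * max(lam))
  if (n_zero > 6L)
    stop("disconnected-structure error: ", n_zero,
         " near-zero modes (expected 6); the contact graph is disconnected")
  if (!is.null(n_modes)) {
    n_modes <- min(n_modes, length(lam))
    lam <- lam[seq_len(n_modes)]
    vec <- vec[, seq_len(n_modes), drop = FALSE]
  }
  structure(list(eigenvalues = lam,
                 eigenvectors = vec,
                 frequencies = sqrt(pmax(lam, 0)),
                 n_atoms = nrow(H) / 3L,
                 n_zero = n_zero,
                 cutoff = attr(H, "cutoff"),
                 gamma = attr(H, "gamma")),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf(
    "<mode_set> %d atoms, %d modes (%d zero); omega7 = %.4g\n",
    x$n_atoms, length(x$eigenvalues), x$n_zero,
    if (length(x$frequencies) >= 7) x$frequencies[7] else NA))
  invisible(x)
}

#' Index of the k-th non-trivial mode
#'
#' @param k non-trivial mode number (1 = first internal mode).
#' @return The 1-based mode index `6 + k`.
#' @export
nontrivial_mode <- function(k) 6L + as.integer(k)

#' Fluctuation profile container
#'
#' @param rmsf per-residue fluctuation (>= 0).
#' @param source `"modes"` (relative units) or `"ensemble"` (Angstrom).
#' @return Class `fluctuation_profile` with `rmsf`, `source`,
#'   `delta` = max - min and `sigma` = standard deviation — the summary
#'   scores used to compare full-length and truncated enzyme forms.
#' @export
fluctuation_profile <- function(rmsf, source = c("modes", "ensemble")) {
  source <- match.arg(source)
  stopifnot(all(rmsf >= 0))
  structure(list(rmsf = as.numeric(rmsf), source = source,
                 delta = max(rmsf) - min(rmsf), sigma = sd(rmsf)),
            class = "fluctuation_profile")
}

#' @export
print.fluctuation_profile <- function(x, ...) {
  cat(sprintf(
    "<fluctuation_profile> %d residues (%s); delta = %.4g, sigma = %.4g\n",
    length(x$rmsf), x$source, x$delta, x$sigma))
  invisible(x)
}

#' Mode-derived residue fluctuations
#'
#' rmsf_i = sqrt( sum_k (1/lambda_k) * |v_{k,i}|^2 ) over the selected
#' modes, where v_{k,i} is the 3-vector of mode k on residue i. The default
#' window 7:18 is the set of low-frequency non-trivial modes customarily
#' inspected for multi-domain flexibility.
#'
#' @param m a [normal_modes()] result.
#' @param mode_range integer mode indices; must exclude modes 1-6.
#' @return A [fluctuation_profile()] (source `"modes"`, relative units).
#' @export
mode_rmsf <- function(m, mode_range = 7:18) {
  stopifnot(inherits(m, "mode_set"))
  mode_range <- as.integer(mode_range)
  if (any(mode_range <= 6L))
    stop("precondition error: mode_range must exclude the six rigid-body modes")
  if (max(mode_range) > length(m$eigenvalues))
    stop("mode_range exceeds the number of computed modes")
  lam <- m$eigenvalues[mode_range]
  if (any(lam <= 0))
    stop("precondition error: selected mode has non-positive eigenvalue")
  V <- m$eigenvectors[, mode_range, drop = FALSE]
  n <- m$n_atoms
  per_res <- matrix(0, n, length(mode_range))
  for (a in 1:3)
    per_res <- per_res + V[seq(a, 3 * n, by = 3), , drop = FALSE]^2
  msf <- as.numeric(per_res %*% (1 / lam))
  fluctuation_profile(sqrt(msf), source = "modes")
}

#' Ensemble-derived residue fluctuations
#'
#' rmsf_i = sqrt( mean_frames |x_i - <x_i>|^2 ) in Angstrom. Frames must be
#' pre-superposed (e.g. with [superpose_frames()]).
#'
#' @param ensemble S x N x 3 array of frames, or an `aligned_ensemble`.
#' @return A [fluctuation_profile()] (source `"ensemble"`, Angstrom).
#' @export
ensemble_rmsf <- function(ensemble) {
  coords <- if (inherits(ensemble, "aligned_ensemble")) ensemble$coords
            else ensemble
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (dim(coords)[1] < 2L)
    stop("precondition error: at least 2 frames are required")
  mean_xyz <- apply(coords, c(2, 3), mean)
  dev2 <- sweep(coords, c(2, 3), mean_xyz)^2
  msf <- apply(dev2, 2, mean) * 3    # mean over frames and axes, x3 axes
  fluctuation_profile(sqrt(msf), source = "ensemble")
}

#' Superpose ensemble frames onto a reference frame
#'
#' Convenience for raw frame stacks (all frames share the residue order):
#' every frame is Kabsch-fitted onto the first (or given) frame using
#' `fit_idx` residues.
#'
#' @param coords S x N x 3 array.
#' @param fit_idx residue indices used for the fit (default all).
#' @param reference reference frame index (default 1).
#' @return S x N x 3 array of superposed frames.
#' @export
superpose_frames <- function(coords, fit_idx = NULL, reference = 1L) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (is.null(fit_idx)) fit_idx <- seq_len(dim(coords)[2])
  ref <- coords[reference, fit_idx, , drop = TRUE]
  out <- coords
  for (f in seq_len(dim(coords)[1])) {
    sp <- kabsch_superpose(coords[f, fit_idx, ], ref)
    out[f, , ] <- apply_superposition(sp, coords[f, , ])
  }
  out
}

#' Dynamic cross-correlation map
#'
#' C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>), the normalized covariance
#' of residue displacement vectors; entries lie in [-1, 1] with unit
#' diagonal. Two sources are supported: an elastic-network `mode_set`
#' (covariance from the pseudo-inverse over the selected modes,
#' <dr_i . dr_j> = sum_k (1/lambda_k) v_{k,i} . v_{k,j}) or a pre-superposed
#' frame ensemble (covariance about the frame mean).
#'
#' @param source a `mode_set` or an S x N x 3 array / `aligned_ensemble`.
#' @param mode_range modes used when `source` is a `mode_set` (default 7:18).
#' @param labels optional residue labels for the matrix dimnames.
#' @return An object of class `correlation_map`: `matrix` (N x N) and
#'   `labels`.
#' @export
dccm_map <- function(source, mode_range = 7:18, labels = NULL) {
  if (inherits(source, "mode_set")) {
    m <- source
    mode_range <- as.integer(mode_range)
    if (any(mode_range <= 6L))
      stop("mode_range must exclude the six rigid-body modes")
    lam <- m$eigenvalues[mode_range]
    if (any(lam <= 0)) stop("selected mode has non-positive eigenvalue")
    V <- m$eigenvectors[, mode_range, drop = FALSE]
    n <- m$n_atoms
    cross <- matrix(0, n, n)
    for (a in 1:3) {
      Va <- V[seq(a, 3 * n, by = 3), , drop = FALSE]
      cross <- cross + Va %*% (t(Va) * (1 / lam))
    }
  } else {
    coords <- if (inherits(source, "aligned_ensemble")) source$coords
              else source
    stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
    S <- dim(coords)[1]; n <- dim(coords)[2]
    if (S < 2L) stop("at least 2 frames are required")
    mean_xyz <- apply(coords, c(2, 3), mean)
    cross <- matrix(0, n, n)
    for (a in 1:3) {
      D <- sweep(coords[, , a, drop = TRUE], 2, mean_xyz[, a])
      cross <- cross + crossprod(D) / S
    }
  }
  v <- diag(cross)
  zero <- which(v <= 0 | v < 1e-300)
  if (length(zero))
    stop("undefined-correlation error: zero-variance residue ", zero[1L])
  C <- cross / sqrt(outer(v, v))
  C <- (C + t(C)) / 2
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  if (!is.null(labels)) dimnames(C) <- list(labels, labels)
  structure(list(matrix = C, labels = labels), class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %d x %d, range [%.3f, %.3f]\n",
              nrow(x$matrix), ncol(x$matrix),
              min(x$matrix), max(x$matrix)))
  invisible(x)
}
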