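#' Specification for the synthetic structure generators
#'
#' The generators emulate the architecture of plant class C GH9
#' endoglucanases: a compact catalytic GH9 domain (about 450 residues), an
#' extended linker (under 100 residues) and a compact CBM49 module (about
#' 40-200 residues), with the linker and CBM49 substantially more mobile
#' than the GH9 core. Defaults are the conditions under which the pipeline
#' is validated; all outputs are pure functions of (spec, seed).
#'
#' @param n_gh9,n_linker,n_cbm residue counts per domain (450, 60, 110).
#' @param linker_rise linker extension in Angstrom per residue (3.5).
#' @param min_dist minimum inter-bead distance in the packed domains,
#'   Angstrom (3.5).
#' @param mobility named per-domain fluctuation sigma in Angstrom per axis
#'   for ensembles, `c(GH9 = 0.3, L = 1.5, CBM49 = 1.5)` — a 5:1 ratio of
#'   linker/CBM to core mobility.
#' @param n_frames ensemble frames (500).
#' @param n_members family size (40).
#' @param n_clusters planted cluster count, 1-4 (4).
#' @param cluster_shift two rigid CBM49 displacement magnitudes in Angstrom
#'   along orthogonal directions, `c(8, 5)`; the magnitudes are distinct so
#'   that the two between-cluster principal components have distinct
#'   eigenvalues and a reproducible order.
#' @param core_sigma,mobile_sigma per-axis coordinate noise (Angstrom) on
#'   the rigid core (GH9, 0.05) and the variable periphery (linker+CBM49,
#'   3.0) of family members.
#' @param seed integer random seed (0).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_gh9 = 450L, n_linker = 60L, n_cbm = 110L,
                           linker_rise = 3.5, min_dist = 3.5,
                           mobility = c(GH9 = 0.3, L = 1.5, CBM49 = 1.5),
                           n_frames = 500L, n_members = 40L,
                           n_clusters = 4L, cluster_shift = c(8, 5),
                           core_sigma = 0.05, mobile_sigma = 3.0,
                           seed = 0L) {
  stopifnot(n_gh9 > 0, n_linker > 0, n_cbm > 0, all(mobility >= 0),
            n_clusters >= 1L, n_clusters <= 4L,
            length(cluster_shift) == 2L)
  structure(list(n_gh9 = as.integer(n_gh9), n_linker = as.integer(n_linker),
                 n_cbm = as.integer(n_cbm), linker_rise = linker_rise,
                 min_dist = min_dist, mobility = mobility,
                 n_frames = as.integer(n_frames),
                 n_members = as.integer(n_members),
                 n_clusters = as.integer(n_clusters),
                 cluster_shift = cluster_shift,
                 core_sigma = core_sigma, mobile_sigma = mobile_sigma,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

## One global seed drives a named substream per generator, so adding a
## generator never perturbs the draws of another. The RNG state is restored
## on exit.
with_substream <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 2654435761) %% 1000000007
  set.seed((as.numeric(seed) * 7919 + h) %% 2147483647)
  force(expr)
}

## Random sequential packing of n beads in a sphere, min pairwise distance
## min_dist. The radius is sized for a packing fraction safely below the
## random sequential adsorption limit.
pack_cloud <- function(n, min_dist, max_tries = 400L * n) {
  vol_per <- (4 / 3) * pi * (min_dist / 2)^3 / 0.22
  R <- (3 * n * vol_per / (4 * pi))^(1 / 3)
  pts <- matrix(NA_real_, n, 3)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("generation error: infeasible packing after ", max_tries,
           " attempts")
    dir <- rnorm(3)
    p <- dir / sqrt(sum(dir^2)) * R * runif(1)^(1 / 3)
    if (placed > 0L) {
      d2 <- colSums((t(pts[seq_len(placed), , drop = FALSE]) - p)^2)
      if (min(d2) < min_dist^2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- p
  }
  attr(pts, "radius") <- R
  pts
}

random_rotation <- function() {
  ## uniform rotation via normalized quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

#' Generate a synthetic multi-domain C-alpha structure
#'
#' GH9 and CBM49 are compact self-avoiding bead clouds (minimum inter-bead
#' distance `min_dist`) joined by an extended, lightly jittered linker of
#' `n_linker` beads at `linker_rise` spacing, mirroring the elongated
#' architecture of class C enzymes. Residues are numbered 1..N on chain A
#' with a seeded random amino-acid sequence.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `structure` (a [ca_structure()]) and `annotation`
#'   (a [domain_annotation()] covering all residues).
#' @export
make_multidomain_structure <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_substream(spec$seed, "structure", {
    gh9 <- pack_cloud(spec$n_gh9, spec$min_dist)
    cbm <- pack_cloud(spec$n_cbm, spec$min_dist)
    R_g <- attr(gh9, "radius")
    R_c <- attr(cbm, "radius")
    x0 <- R_g + spec$min_dist
    ## the linker is a semi-extended helical path (axial rise 2 A/residue,
    ## radius 3 A, contour spacing linker_rise) plus a small jitter: a
    ## straight bead chain would be a first-order mechanism of the
    ## anisotropic network (free transverse bending), injecting spurious
    ## near-zero modes; a helix has first-order bending stiffness
    i <- seq_len(spec$n_linker) - 1L
    rise_ax <- 2.0
    r_h <- 3.0
    chord <- sqrt(max(spec$linker_rise^2 - rise_ax^2, 1)) / 2
    omega <- 2 * asin(min(chord / r_h, 1))
    link <- cbind(x0 + rise_ax * i,
                  r_h * cos(omega * i),
                  r_h * sin(omega * i)) +
      matrix(rnorm(3L * spec$n_linker, 0, 0.3), ncol = 3)
    cbm_center <- c(max(link[, 1]) + spec$min_dist + R_c, 0, 0)
    cbm <- sweep(cbm, 2, cbm_center, "+")
    xyz <- rbind(gh9, link, cbm)
    n <- nrow(xyz)
    aa <- sample(VALID_AA, n, replace = TRUE)
    s <- ca_structure("A", seq_len(n), aa, xyz, name = "synthetic_fl")
    ann <- domain_annotation(list(
      GH9 = c(1L, spec$n_gh9),
      L = c(spec$n_gh9 + 1L, spec$n_gh9 + spec$n_linker),
      CBM49 = c(spec$n_gh9 + spec$n_linker + 1L, n)), s = s)
    list(structure = s, annotation = ann)
  })
}

#' Generate a conformational ensemble with elevated linker/CBM mobility
#'
#' Frames are the base structure plus independent Gaussian displacements
#' with per-domain sigma (`spec$mobility`), then a random rigid rotation
#' and translation per frame so that downstream superposition is genuinely
#' exercised.
#'
#' @param s base [ca_structure()].
#' @param annotation its [domain_annotation()].
#' @param spec a [synthetic_spec()] (uses `mobility`, `n_frames`, `seed`).
#' @return S x N x 3 array of frames (S = `n_frames`), with attribute
#'   `res_id`.
#' @export
make_ensemble <- function(s, annotation, spec = synthetic_spec()) {
  stopifnot(inherits(s, "ca_structure"), inherits(spec, "synthetic_spec"))
  dom <- domain_of(annotation, s$res_id)
  if (anyNA(dom)) stop("ensemble generation requires full annotation")
  sig <- spec$mobility[dom]
  n <- length(s$res_id)
  with_substream(spec$seed, "ensemble", {
    coords <- array(NA_real_, dim = c(spec$n_frames, n, 3))
    for (f in seq_len(spec$n_frames)) {
      disp <- matrix(rnorm(3L * n, 0, rep(sig, 3L)), n, 3)
      Rm <- random_rotation()
      tv <- runif(3, -10, 10)
      coords[f, , ] <- sweep((s$xyz + disp) %*% Rm, 2, tv, "+")
    }
    attr(coords, "res_id") <- s$res_id
    coords
  })
}

#' Sample an ensemble from elastic-network modes
#'
#' Draws frames from the Gaussian distribution implied by the selected
#' modes at unit thermal energy: x = x0 + sum_k eta_k v_k with
#' eta_k ~ N(0, 1/lambda_k). The ensemble DCCM of a large sample converges
#' to the mode DCCM, which is how the two routes cross-validate.
#'
#' @param s base [ca_structure()] (or N x 3 matrix).
#' @param modes a [normal_modes()] result for `s`.
#' @param mode_range modes to excite (default 7:18).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return S x N x 3 array of frames.
#' @export
sample_mode_ensemble <- function(s, modes, mode_range = 7:18,
                                 n_frames = 1000L, seed = 0L) {
  xyz <- if (inherits(s, "ca_structure")) s$xyz else as.matrix(s)
  stopifnot(inherits(modes, "mode_set"))
  mode_range <- as.integer(mode_range)
  lam <- modes$eigenvalues[mode_range]
  if (any(lam <= 0)) stop("selected mode has non-positive eigenvalue")
  V <- modes$eigenvectors[, mode_range, drop = FALSE]
  n <- nrow(xyz)
  with_substream(seed, "mode_ensemble", {
    eta <- matrix(rnorm(n_frames * length(lam)), n_frames) %*%
      diag(1 / sqrt(lam), nrow = length(lam))
    disp <- eta %*% t(V)                     # frames x 3N (x1 y1 z1 ...)
    coords <- array(NA_real_, dim = c(n_frames, n, 3))
    for (a in 1:3)
      coords[, , a] <- sweep(disp[, seq(a, 3 * n, by = 3), drop = FALSE],
                             2, xyz[, a], "+")
    coords
  })
}

#' Generate a structure family with a rigid core and planted clusters
#'
#' Family members share the base structure's sequence (gap-free alignment)
#' and differ by small Gaussian noise on the rigid GH9 core
#' (`core_sigma`), large noise on the linker and CBM49 periphery
#' (`mobile_sigma`), a per-cluster rigid displacement of the whole CBM49
#' block along cluster-specific directions (magnitudes `cluster_shift`),
#' and a random rigid transform of every member.
#'
#' @param s base [ca_structure()] from [make_multidomain_structure()].
#' @param annotation its [domain_annotation()].
#' @param spec a [synthetic_spec()].
#' @return List with `structures` (length `n_members`), `map` (gap-free
#'   `alignment_map`), `core_columns` (planted rigid columns = GH9
#'   positions, 1-based), `cluster` (planted labels 1..n_clusters) and
#'   `msa` (named aligned sequences).
#' @export
make_family <- function(s, annotation, spec = synthetic_spec()) {
  stopifnot(inherits(s, "ca_structure"), inherits(spec, "synthetic_spec"))
  if (spec$n_members < 4L) stop("n_members must be at least 4")
  dom <- domain_of(annotation, s$res_id)
  if (anyNA(dom)) stop("family generation requires full annotation")
  n <- length(s$res_id)
  is_core <- dom == "GH9"
  is_cbm <- dom == "CBM49"
  sig <- ifelse(is_core, spec$core_sigma, spec$mobile_sigma)
  signs <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  with_substream(spec$seed, "family", {
    ## two fixed orthonormal cluster-shift directions
    u1 <- rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- rnorm(3); u2 <- u2 - sum(u2 * u1) * u1; u2 <- u2 / sqrt(sum(u2^2))
    cluster <- rep_len(seq_len(spec$n_clusters), spec$n_members)
    structures <- vector("list", spec$n_members)
    for (m in seq_len(spec$n_members)) {
      q <- cluster[m]
      shift <- signs[q, 1] * spec$cluster_shift[1] * u1 +
               signs[q, 2] * spec$cluster_shift[2] * u2
      xyz <- s$xyz + matrix(rnorm(3L * n, 0, rep(sig, 3L)), n, 3)
      xyz[is_cbm, ] <- sweep(xyz[is_cbm, , drop = FALSE], 2, shift, "+")
      Rm <- random_rotation()
      tv <- runif(3, -20, 20)
      xyz <- sweep(xyz %*% Rm, 2, tv, "+")
      structures[[m]] <- ca_structure(s$chain, s$res_id, s$aa, xyz,
                                      name = sprintf("member_%03d", m))
    }
    seqs <- setNames(rep(paste(s$aa, collapse = ""), spec$n_members),
                     vapply(structures, function(x) x$name, character(1)))
    map <- alignment_map_from_strings(seqs, structures)
    list(structures = structures, map = map,
         core_columns = which(is_core), cluster = cluster, msa = seqs)
  })
}
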