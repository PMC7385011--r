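## Independent oracles and small fixture builders shared across the suite.
## These deliberately use naive algorithms (grids, exhaustive scans, finite
## differences) so they stay independent of the implementation paths they
## check.

## Rigid-fit RMSD by brute force over quaternion space: coarse random scan
## followed by shrinking local perturbation rounds. Translation is optimal
## in closed form (centroid match) for any fixed rotation.
oracle_rigid_rmsd <- function(mobile, reference, n_coarse = 4000,
                              n_refine = 12, n_local = 400) {
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
    matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
             2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
             2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
           3, 3, byrow = TRUE)
  }
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  score <- function(q) sqrt(mean(rowSums((A %*% quat_rot(q) - B)^2)))
  best_q <- c(1, 0, 0, 0); best <- score(best_q)
  for (i in seq_len(n_coarse)) {
    q <- rnorm(4)
    s <- score(q)
    if (s < best) { best <- s; best_q <- q / sqrt(sum(q^2)) }
  }
  sigma <- 0.3
  for (r in seq_len(n_refine)) {
    for (i in seq_len(n_local)) {
      q <- best_q + rnorm(4, 0, sigma)
      s <- score(q)
      if (s < best) { best <- s; best_q <- q / sqrt(sum(q^2)) }
    }
    sigma <- sigma / 2.5
  }
  best
}

## Columns occupied in every sequence of a character-matrix MSA.
oracle_ungapped <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  which(apply(mat, 2, function(col) all(!col %in% c("-", "."))))
}

## ENM potential energy restricted to the contact set of x0.
enm_energy <- function(x, x0, cutoff, gamma = 1) {
  n <- nrow(x0)
  d0 <- as.matrix(dist(x0))
  contacts <- which(d0 <= cutoff & upper.tri(d0), arr.ind = TRUE)
  d <- sqrt(rowSums((x[contacts[, 1], , drop = FALSE] -
                     x[contacts[, 2], , drop = FALSE])^2))
  r0 <- d0[contacts]
  sum(gamma / 2 * (d - r0)^2)
}

## Central-difference Hessian of the ENM energy around x0 (3N x 3N).
oracle_numeric_hessian <- function(x0, cutoff, gamma = 1, h = 1e-4) {
  n3 <- 3L * nrow(x0)
  f <- function(v) enm_energy(matrix(v, ncol = 3), x0, cutoff, gamma)
  v0 <- as.vector(x0)
  H <- matrix(0, n3, n3)
  ## flatten order must match build_hessian: (x,y,z) per atom
  idx <- as.vector(t(matrix(seq_len(n3), ncol = 3)))
  for (a in seq_len(n3)) for (b in a:n3) {
    ea <- eb <- numeric(n3)
    ea[idx[a]] <- h; eb[idx[b]] <- h
    val <- (f(v0 + ea + eb) - f(v0 + ea - eb) -
            f(v0 - ea + eb) + f(v0 - ea - eb)) / (4 * h^2)
    H[a, b] <- H[b, a] <- val
  }
  H
}

## Exhaustive maximal-block scan over a thresholded correlation matrix,
## restricted to domain-pure row/column runs. O(N^4); fixtures only.
oracle_block_scan <- function(C, dom, r_min, min_len, min_sep) {
  n <- nrow(C)
  B <- C >= r_min & abs(outer(1:n, 1:n, "-")) >= min_sep
  ok <- function(I, J) {
    all(B[I, J]) &&
      length(unique(dom[I])) == 1L && !anyNA(dom[I]) &&
      length(unique(dom[J])) == 1L && !anyNA(dom[J])
  }
  active <- which(rowSums(B) > 0)   # rows that can participate at all
  res <- list()
  for (i1 in active) for (i2 in active[active >= i1 + min_len - 1]) {
    for (j1 in active) for (j2 in active[active >= j1 + min_len - 1]) {
      I <- i1:i2; J <- j1:j2
      if (!ok(I, J)) next
      ## maximality: every one-step extension (within the same domain run)
      ## must fail
      ext <- (i1 > 1 && ok((i1 - 1):i2, J)) ||
             (i2 < n && ok(i1:(i2 + 1), J)) ||
             (j1 > 1 && ok(I, (j1 - 1):j2)) ||
             (j2 < n && ok(I, j1:(j2 + 1)))
      if (ext) next
      if (i1 > j1) next            # one orientation per unordered pair
      res[[length(res) + 1L]] <- c(i1, i2, j1, j2)
    }
  }
  if (!length(res)) return(matrix(integer(0), ncol = 4))
  unique(do.call(rbind, res))
}

## Best label agreement between planted and inferred 4-way labels over all
## permutations (the assignment-problem optimum at this size).
match_accuracy <- function(planted, inferred) {
  pl <- as.integer(factor(planted))
  inf <- as.integer(factor(inferred))
  k <- max(pl, inf)
  if (k > 4) stop("match_accuracy supports up to 4 labels")
  perms <- list()
  for (a in 1:k) for (b in 1:k) for (c in 1:k) for (d in 1:k) {
    p <- c(a, b, c, d)[1:k]
    if (length(unique(p)) == k) perms[[length(perms) + 1L]] <- p
  }
  best <- 0
  for (p in perms) best <- max(best, mean(p[inf] == pl))
  best
}

## Hollow cube of shell spheres leaving an inner void of side `side` after
## probe inflation; analytic void volume ~ side^3.
make_hollow_shell <- function(side = 10, radius = 2, probe = 1.4,
                              spacing = 2) {
  L <- side + 2 * (radius + probe)
  g <- unique(c(seq(0, L, by = spacing), L))   # ensure the far walls exist
  pts <- as.matrix(expand.grid(g, g, g))
  keep <- apply(pts, 1, function(p) any(p == 0 | p == L))
  pts <- pts[keep, ]
  ca_structure("A", seq_len(nrow(pts)), rep("G", nrow(pts)), pts,
               name = "hollow_shell")
}

## Small multi-domain fixture at reduced size (fast ENM/core tests).
small_multidomain <- function(seed = 3, n_gh9 = 40, n_linker = 10,
                              n_cbm = 20, ...) {
  sp <- synthetic_spec(n_gh9 = n_gh9, n_linker = n_linker, n_cbm = n_cbm,
                       seed = seed, ...)
  c(make_multidomain_structure(sp), list(spec = sp))
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}
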