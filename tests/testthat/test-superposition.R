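test_that("superposing identical point sets gives zero rmsd and the identity rotation", {
  set.seed(1)
  P <- matrix(rnorm(30), 10)
  sp <- kabsch_superpose(P, P)
  expect_lt(sp$rmsd, 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-10)
  expect_lt(abs(det(sp$rotation) - 1), 1e-8)
})

test_that("a rigid motion is removed exactly", {
  set.seed(2)
  P <- matrix(rnorm(45), 15)
  Q <- sweep(P %*% rotation_z(pi / 2), 2, c(5, 0, 0), "+")
  sp <- kabsch_superpose(P, Q)
  expect_lt(sp$rmsd, 1e-10)
  expect_lt(max(abs(apply_superposition(sp, P) - Q)), 1e-8)
})

test_that("kabsch rmsd matches a quaternion-grid brute-force minimizer", {
  set.seed(3)
  A <- matrix(rnorm(60), 20)
  B <- matrix(rnorm(60), 20)
  sp <- kabsch_superpose(A, B)
  expect_lt(abs(sp$rmsd - oracle_rigid_rmsd(A, B)), 1e-3)
})

test_that("rmsd is invariant to rigid pre-transforms of the mobile set", {
  set.seed(4)
  A <- matrix(rnorm(36), 12)
  B <- matrix(rnorm(36), 12)
  base <- kabsch_superpose(A, B)$rmsd
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi)
    A2 <- sweep(A %*% rotation_z(th), 2, rnorm(3, sd = 10), "+")
    expect_lt(abs(kabsch_superpose(A2, B)$rmsd - base), 1e-8)
  }
})

test_that("degenerate configurations are geometry errors", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear|degenerate")
})

test_that("ellipsoid volume has the closed form, eigen oracle and rotation invariance", {
  expect_equal(column_ellipsoid_volume(matrix(1, 5, 3)), 0)
  expect_error(column_ellipsoid_volume(matrix(1, 1, 3)), "at least 2")

  ## population covariance exactly the identity -> V = 4/3 pi
  P <- rbind(diag(3), -diag(3)) * sqrt(3)   # cov = I with 1/n denominator
  expect_equal(column_ellipsoid_volume(P), 4 / 3 * pi, tolerance = 1e-12)

  set.seed(5)
  X <- matrix(rnorm(30), 10)
  lam <- eigen(crossprod(sweep(X, 2, colMeans(X))) / 10,
               symmetric = TRUE, only.values = TRUE)$values
  expect_equal(column_ellipsoid_volume(X), 4 / 3 * pi * sqrt(prod(lam)),
               tolerance = 1e-12)
  for (i in 1:3) {
    XR <- X %*% rotation_z(runif(1, 0, 2 * pi))
    expect_lt(abs(column_ellipsoid_volume(XR) / column_ellipsoid_volume(X) - 1),
              1e-9)
  }

  ## coplanar points have a zero eigenvalue hence zero volume
  expect_equal(column_ellipsoid_volume(cbind(rnorm(6), rnorm(6), 0)), 0)
})

test_that("ensembles of rigid copies superpose to machine precision", {
  set.seed(6)
  base <- ca_structure("A", 1:20, rep("A", 20), matrix(rnorm(60, sd = 5), 20),
                       name = "m1")
  structs <- list(base)
  for (i in 2:4) {
    xyz <- sweep(base$xyz %*% rotation_z(i), 2, c(i, -i, 2 * i), "+")
    structs[[i]] <- ca_structure("A", 1:20, base$aa, xyz,
                                 name = sprintf("m%d", i))
  }
  seqs <- setNames(rep(paste(base$aa, collapse = ""), 4),
                   sapply(structs, `[[`, "name"))
  m <- alignment_map_from_strings(seqs, structs)
  ens <- superpose_ensemble(structs, m)
  for (i in 2:4)
    expect_lt(max(abs(ens$coords[i, , ] - ens$coords[1, , ])), 1e-8)
  expect_error(superpose_ensemble(structs, m, fit_columns = integer(0)),
               "empty fit")
})

test_that("per-column spread of a noisy ensemble matches direct covariance", {
  set.seed(7)
  n <- 12; S <- 30
  base <- matrix(rnorm(3 * n, sd = 8), n)
  structs <- lapply(seq_len(S), function(i) {
    ca_structure("A", 1:n, rep("G", n), base + matrix(rnorm(3 * n, sd = 0.3), n),
                 name = sprintf("m%02d", i))
  })
  seqs <- setNames(rep(paste(rep("G", n), collapse = ""), S),
                   sapply(structs, `[[`, "name"))
  m <- alignment_map_from_strings(seqs, structs)
  ens <- superpose_ensemble(structs, m)
  vols <- sapply(seq_len(n), function(j) column_ellipsoid_volume(ens$coords[, j, ]))
  direct <- sapply(seq_len(n), function(j) {
    X <- ens$coords[, j, ]
    lam <- eigen(crossprod(sweep(X, 2, colMeans(X))) / S,
                 symmetric = TRUE, only.values = TRUE)$values
    4 / 3 * pi * sqrt(prod(pmax(lam, 0)))
  })
  expect_equal(vols, direct, tolerance = 1e-10)
})

test_that("invariant core keeps everything for identical structures or infinite cutoff", {
  base <- ca_structure("A", 1:15, rep("A", 15),
                       matrix(seq_len(45) + rnorm(45), 15), name = "m1")
  structs <- lapply(1:4, function(i) {
    s <- base; s$name <- sprintf("m%d", i); s
  })
  seqs <- setNames(rep(paste(base$aa, collapse = ""), 4),
                   sapply(structs, `[[`, "name"))
  m <- alignment_map_from_strings(seqs, structs)
  core <- find_invariant_core(structs, m, cutoff = 1.0, min_core = 3)
  expect_equal(core$core_columns, 1:15)
  expect_true(all(core$volumes < 1e-12))
  expect_length(core$removal_order, 0)

  set.seed(8)
  noisy <- lapply(seq_along(structs), function(i) {
    s <- structs[[i]]
    s$xyz <- s$xyz + matrix(rnorm(45, sd = 2), 15)
    s
  })
  core2 <- find_invariant_core(noisy, m, cutoff = Inf, min_core = 3)
  expect_equal(core2$core_columns, 1:15)
  expect_length(core2$removal_order, 0)
  expect_error(find_invariant_core(noisy, m, min_core = 2), "min_core")
})

test_that("planted rigid columns are recovered and mobile columns eliminated", {
  set.seed(9)
  n <- 40; S <- 8
  base <- matrix(rnorm(3 * n, sd = 10), n)
  structs <- lapply(seq_len(S), function(i) {
    sig <- c(rep(0.05, 30), rep(3, 10))
    xyz <- base + matrix(rnorm(3 * n, 0, rep(sig, 3)), n)
    xyz <- sweep(xyz %*% rotation_z(i / 2), 2, rnorm(3, sd = 5), "+")
    ca_structure("A", 1:n, rep("A", n), xyz, name = sprintf("m%d", i))
  })
  seqs <- setNames(rep(paste(rep("A", n), collapse = ""), S),
                   sapply(structs, `[[`, "name"))
  m <- alignment_map_from_strings(seqs, structs)
  core <- find_invariant_core(structs, m, cutoff = 1.0, min_core = 5)
  expect_true(all(1:30 %in% core$core_columns))
  expect_length(intersect(core$core_columns, 31:40), 0)

  ## determinism of the removal order
  core2 <- find_invariant_core(structs, m, cutoff = 1.0, min_core = 5)
  expect_identical(core$removal_order, core2$removal_order)

  ## core volumes do not grow between first and final superposition
  ens0 <- superpose_ensemble(structs, m)
  v0 <- sapply(core$core_columns, function(j)
    column_ellipsoid_volume(ens0$coords[, j, ]))
  ensF <- superpose_ensemble(structs, m, fit_columns = core$core_columns)
  vF <- sapply(core$core_columns, function(j)
    column_ellipsoid_volume(ensF$coords[, j, ]))
  expect_true(all(vF <= v0 + 1e-9))

  tab <- core_table(core)
  expect_equal(sum(tab$in_core), length(core$core_columns))
  expect_equal(sort(tab$removal_rank[!is.na(tab$removal_rank)]),
               seq_along(core$removal_order))
})

test_that("superposition agrees with an independent structural library", {
  set.seed(10)
  A <- matrix(rnorm(60, sd = 4), 20)
  B <- matrix(rnorm(60, sd = 4), 20)
  sp <- kabsch_superpose(A, B)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(B)),
                   mobile = matrix(as.vector(t(A)), nrow = 1)))
  ref_rmsd <- bio3d::rmsd(as.vector(t(B)), fitted)
  expect_equal(sp$rmsd, ref_rmsd, tolerance = 1e-3)
})
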