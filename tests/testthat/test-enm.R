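test_that("the two-atom network has the closed-form spectrum", {
  H <- build_hessian(rbind(c(0, 0, 0), c(1, 0, 0)), cutoff = 2, gamma = 1)
  ## only the xx block couples a bond along x
  nz <- which(H != 0, arr.ind = TRUE)
  expect_true(all(nz[, 1] %in% c(1, 4) & nz[, 2] %in% c(1, 4)))
  ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev, c(0, 0, 0, 0, 0, 2), tolerance = 1e-12)
  m <- normal_modes(H)
  expect_equal(m$frequencies[6], sqrt(2), tolerance = 1e-10)
})

test_that("a cutoff below all pair distances yields the zero matrix", {
  xyz <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0), 3, byrow = TRUE)
  expect_warning(H <- build_hessian(xyz, cutoff = 1), "connectivity")
  expect_true(all(H == 0))
})

test_that("the analytic Hessian matches a finite-difference oracle", {
  set.seed(12)
  xyz <- matrix(rnorm(30, sd = 3), 10)
  cutoff <- 8
  H <- build_hessian(xyz, cutoff = cutoff, gamma = 1)
  Hnum <- oracle_numeric_hessian(xyz, cutoff = cutoff, gamma = 1)
  expect_lt(max(abs(H - Hnum)), 1e-5)
})

test_that("Hessian superblock rows sum to zero (translation invariance)", {
  set.seed(13)
  s <- small_multidomain(seed = 13)$structure
  H <- build_hessian(s, cutoff = 15)
  expect_lt(max(abs(rowSums(H))), 1e-10)
  expect_lt(max(abs(H - t(H))), 1e-12)
})

test_that("connected structures have exactly six zero modes; disconnected ones error", {
  md <- small_multidomain(seed = 14)
  H <- build_hessian(md$structure, cutoff = 15)
  m <- normal_modes(H)
  expect_equal(m$n_zero, 6L)
  lam <- m$eigenvalues
  expect_lt(lam[6], 1e-8 * max(lam))
  expect_gt(lam[7], 1e-8 * max(lam))
  expect_equal(nontrivial_mode(1), 7L)
  ## orthonormality of the eigenvector matrix
  V <- m$eigenvectors
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)

  ## two trimers far apart: block-diagonal Hessian, 12 zero modes
  tri <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 1))
  far <- rbind(tri, sweep(tri, 2, c(100, 0, 0), "+"))
  H2 <- build_hessian(far, cutoff = 5)
  expect_error(normal_modes(H2), "disconnected-structure")
})

test_that("mode eigenvalues agree with an independent dense solver", {
  set.seed(15)
  md <- small_multidomain(seed = 15, n_gh9 = 15, n_linker = 5, n_cbm = 10)
  H <- build_hessian(md$structure, cutoff = 15)
  m <- normal_modes(H)
  ## SVD of the PSD matrix as the independent route
  sv <- svd(H)$d
  expect_equal(sort(m$eigenvalues), sort(sv), tolerance = 1e-8)
})

test_that("mode rmsf concentrates on a planted floppy tail and ignores sign flips", {
  ## the tail contrast grows with the rigid-core size; 200/30/50 keeps the
  ## packed GH9 dense at the 15 A cutoff while the tail stays sparse
  md <- small_multidomain(seed = 16, n_gh9 = 200, n_linker = 30, n_cbm = 50)
  dom <- domain_of(md$annotation, md$structure$res_id)
  H <- build_hessian(md$structure, cutoff = 15)
  m <- normal_modes(H)
  prof <- mode_rmsf(m, 7:18)
  ## the thin linker + CBM tail is far floppier than the packed GH9 cloud
  expect_gt(mean(prof$rmsf[dom != "GH9"]), 2 * mean(prof$rmsf[dom == "GH9"]))
  expect_equal(prof$delta, max(prof$rmsf) - min(prof$rmsf))
  expect_equal(prof$sigma, sd(prof$rmsf))

  m_flip <- m
  m_flip$eigenvectors <- -m_flip$eigenvectors
  expect_equal(mode_rmsf(m_flip, 7:18)$rmsf, prof$rmsf, tolerance = 1e-12)

  expect_error(mode_rmsf(m, 5:10), "rigid-body")
})

test_that("a single-mode rmsf localises on the loaded residue; constant profiles have zero delta", {
  ## hand-built mode set: mode 7 displaces residue 3 only
  n <- 5
  V <- diag(3 * n)[, 1:8]
  V[, 7] <- 0; V[7, 7] <- 1   # residue 3, x-axis
  fake <- structure(list(eigenvalues = c(rep(0, 6), 2, 3),
                         eigenvectors = V,
                         frequencies = sqrt(c(rep(0, 6), 2, 3)),
                         n_atoms = n, n_zero = 6L), class = "mode_set")
  prof <- mode_rmsf(fake, 7)
  expect_equal(which(prof$rmsf > 0), 3L)
  const <- fluctuation_profile(rep(2, 10), "modes")
  expect_equal(const$delta, 0)
})

test_that("ensemble rmsf reproduces two-point and Gaussian closed forms", {
  ## identical frames -> zero
  one <- matrix(rnorm(30), 10)
  frames <- array(rep(one, each = 4), dim = c(4, 10, 3))
  expect_equal(ensemble_rmsf(frames)$rmsf, rep(0, 10))
  expect_error(ensemble_rmsf(frames[1, , , drop = FALSE]), "at least 2")

  ## residue oscillating +-1 A along x in half the frames each
  fr2 <- array(0, dim = c(10, 2, 3))
  fr2[, 1, 1] <- rep(c(1, -1), 5)
  expect_equal(ensemble_rmsf(fr2)$rmsf[1], 1.0)

  ## isotropic Gaussian sigma = 0.5 per axis -> rmsf = sqrt(3)*0.5 within 2%
  set.seed(17)
  S <- 1e4
  fr3 <- array(rnorm(S * 5 * 3, 0, 0.5), dim = c(S, 5, 3))
  expect_equal(mean(ensemble_rmsf(fr3)$rmsf), sqrt(3) * 0.5,
               tolerance = 0.02)
})

test_that("dccm trivial limits: rigid ensembles are fully correlated, antiphase pairs are -1", {
  base <- matrix(rnorm(24), 8)
  frames <- array(NA_real_, dim = c(6, 8, 3))
  for (f in 1:6) frames[f, , ] <- base + f   # rigid translations
  C <- dccm_map(frames)
  expect_true(all(abs(C$matrix - 1) < 1e-10))

  fr2 <- array(0, dim = c(50, 2, 3))
  disp <- rnorm(50)
  fr2[, 1, 1] <- disp; fr2[, 2, 1] <- -disp
  C2 <- dccm_map(fr2)
  expect_equal(C2$matrix[1, 2], -1, tolerance = 1e-10)
})

test_that("dccm satisfies its structural invariants and is rotation invariant", {
  md <- small_multidomain(seed = 18)
  H <- build_hessian(md$structure, cutoff = 15)
  m <- normal_modes(H)
  C <- dccm_map(m, 7:18)
  M <- C$matrix
  expect_lt(max(abs(M - t(M))), 1e-10)
  expect_lt(max(abs(diag(M) - 1)), 1e-10)
  expect_true(all(M >= -1 & M <= 1))

  set.seed(18)
  frames <- sample_mode_ensemble(md$structure, m, 7:12, n_frames = 200,
                                 seed = 5)
  C1 <- dccm_map(frames)
  R <- rotation_z(0.83)
  rot <- frames
  for (f in seq_len(dim(frames)[1])) rot[f, , ] <- frames[f, , ] %*% R
  C2 <- dccm_map(rot)
  expect_lt(max(abs(C1$matrix - C2$matrix)), 1e-8)

  ## zero-variance residue is reported by index
  frz <- frames
  frz[, 4, ] <- rep(frames[1, 4, ], each = dim(frames)[1])
  expect_error(dccm_map(frz), "zero-variance residue 4")
})

test_that("ensemble dccm agrees with the independent structural library on the same frames", {
  md <- small_multidomain(seed = 19, n_gh9 = 12, n_linker = 5, n_cbm = 8)
  m <- normal_modes(build_hessian(md$structure, cutoff = 15))
  frames <- sample_mode_ensemble(md$structure, m, 7:12, n_frames = 300,
                                 seed = 9)
  C <- dccm_map(frames)
  ## bio3d consumes frames as an S x 3N matrix in (x1,y1,z1,...) order
  S <- dim(frames)[1]; n <- dim(frames)[2]
  xyz <- matrix(NA_real_, S, 3 * n)
  for (a in 1:3) xyz[, seq(a, 3 * n, by = 3)] <- frames[, , a]
  ref <- bio3d::dccm.xyz(xyz)
  expect_equal(unclass(C$matrix), unclass(ref), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("linker and CBM residues out-fluctuate the GH9 core in rank (planted mobility)", {
  md <- small_multidomain(seed = 0, n_gh9 = 60, n_linker = 15, n_cbm = 30)
  dom <- domain_of(md$annotation, md$structure$res_id)
  H <- build_hessian(md$structure, cutoff = 15)
  prof <- mode_rmsf(normal_modes(H), 7:18)
  wt <- wilcox.test(prof$rmsf[dom != "GH9"], prof$rmsf[dom == "GH9"],
                    alternative = "greater", exact = FALSE)
  expect_lt(wt$p.value, 0.01)
})
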