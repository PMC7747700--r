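test_that("Kabsch superposition recovers constructed transforms and excludes reflections", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  # identity on identical sets
  fit0 <- kabsch_superpose(X, X)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)

  # rotating 90 degrees about z and translating: recovered exactly
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  Y <- X %*% Rz + matrix(c(5, -2, 1), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(X, Y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, Rz, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  # a mirrored cloud cannot be matched by a proper rotation
  Ym <- X %*% diag(c(-1, 1, 1))
  fitm <- kabsch_superpose(X, Ym)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-10)
  expect_gt(fitm$rmsd, 0.1)

  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "at least 3")
  expect_error(kabsch_superpose(cbind(1:5, 0, 0), cbind(1:5, 0, 0)),
               "degenerate")
})

test_that("superposed RMSD never exceeds the unsuperposed RMSD and matches a rotation-grid oracle", {
  set.seed(2)
  for (rep in 1:20) {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    fit <- kabsch_superpose(A, B)
    raw <- sqrt(mean(rowSums((A - B)^2)))
    expect_lte(fit$rmsd, raw + 1e-12)
  }
  # planar (z = 0) clouds: brute-force search over in-plane rotations
  for (rep in 1:5) {
    A <- cbind(matrix(rnorm(16), 8, 2), 0)
    B <- cbind(matrix(rnorm(16), 8, 2), 0)
    fit <- kabsch_superpose(A, B)
    Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
    grid <- sapply(seq(0, 359.9, by = 0.25) * pi / 180, function(th) {
      Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
      sqrt(mean(rowSums((Ac %*% Rz - Bc)^2)))
    })
    expect_equal(fit$rmsd, min(grid), tolerance = 1e-3)
  }
})

test_that("rmsd series is zero for static trajectories and ignores rigid motion", {
  e <- toy_ensemble(n = 1)
  coords <- array(rep(e$coords[, , 1], 5), c(6, 3, 5))
  static <- ensemble(e$atoms, coords)
  expect_equal(rmsd_series(static), rep(0, 5), tolerance = 1e-10)

  # a rigidly shifted/rotated frame reads as zero after superposition
  set.seed(3)
  moved <- apply_rigid_to_model(static, 3, random_rigid_motion())
  expect_equal(rmsd_series(moved), rep(0, 5), tolerance = 1e-8)

  # isotropic noise with per-axis sd 0.5 against the noiseless mean
  # structure: mean RMSD near 0.5 * sqrt(3)
  tr <- make_correlated_trajectory(trajectory_spec(
    n_residues = 40, n_frames = 400, displacement_sd = 0.5, seed = 8))
  ref <- get_model(tr, 1)
  ref$coords <- attr(tr, "mean_structure")
  s <- rmsd_series(tr, ref)
  expect_equal(mean(s), sqrt(3) * 0.5, tolerance = 0.1)
})

test_that("rmsf is zero only for static selections and recovers the isotropic closed form", {
  e <- toy_ensemble(n = 1)
  static <- ensemble(e$atoms, array(rep(e$coords[, , 1], 4), c(6, 3, 4)))
  expect_equal(rmsf(static)$rmsf, rep(0, 6), tolerance = 1e-10)
  expect_error(rmsf(toy_ensemble(n = 1)), "single frame")

  sigma <- 0.3
  tr <- make_correlated_trajectory(trajectory_spec(
    n_residues = 50, n_frames = 5000, displacement_sd = sigma, seed = 4))
  prof <- rmsf(tr)
  expect_equal(mean(prof$rmsf), sigma * sqrt(3), tolerance = 0.05 * sigma * sqrt(3))
  expect_true(all(prof$rmsf >= 0))

  # two-block displacement scale: RMSF ratio tracks the planted sd ratio
  sp <- trajectory_spec(n_residues = 20, n_frames = 3000, seed = 6)
  tr2 <- make_correlated_trajectory(sp)
  mref <- as.vector(attr(tr2, "mean_structure")[1:10, ])
  tr2$coords[1:10, , ] <- mref + (tr2$coords[1:10, , ] - mref) * 4
  prof2 <- rmsf(tr2)
  ratio <- mean(prof2$rmsf[1:10]) / mean(prof2$rmsf[11:20])
  expect_equal(ratio, 4, tolerance = 0.5)
})

test_that("rmsf and rmsd are invariant under one global rigid motion of the whole trajectory", {
  tr <- make_correlated_trajectory(trajectory_spec(
    n_residues = 15, n_frames = 100, seed = 10))
  set.seed(11)
  mo <- random_rigid_motion()
  tr2 <- tr
  for (m in seq_len(n_models(tr2))) tr2 <- apply_rigid_to_model(tr2, m, mo)
  expect_equal(rmsf(tr2)$rmsf, rmsf(tr)$rmsf, tolerance = 1e-6)
  expect_equal(rmsd_series(tr2), rmsd_series(tr), tolerance = 1e-6)
})

test_that("correlation matrices are symmetric unit-diagonal and capture exact co/anti-movement", {
  tr <- make_correlated_trajectory(trajectory_spec(
    n_residues = 6, n_frames = 300, seed = 13))
  # duplicate residue 2's displacements onto residue 5, mirror onto residue 6
  mean_xyz <- attr(tr, "mean_structure")
  dev2 <- sweep(tr$coords[2, , ], 1, mean_xyz[2, ])
  tr$coords[5, , ] <- mean_xyz[5, ] + dev2
  tr$coords[6, , ] <- mean_xyz[6, ] - dev2
  C <- correlation_matrix(tr, superpose = FALSE)
  expect_equal(C$C, t(C$C))
  expect_equal(diag(C$C), rep(1, 6))
  expect_true(all(C$C >= -1 & C$C <= 1))
  expect_equal(C$C[2, 5], 1, tolerance = 1e-10)
  expect_equal(C$C[2, 6], -1, tolerance = 1e-10)
})

test_that("zero-variance residues yield zero correlations with a warning", {
  tr <- make_correlated_trajectory(trajectory_spec(
    n_residues = 5, n_frames = 50, seed = 14))
  tr$coords[3, , ] <- c(1, 2, 3)  # frozen residue
  expect_warning(C <- correlation_matrix(tr, superpose = FALSE),
                 "zero-variance")
  expect_equal(C$C[3, -3], rep(0, 4))
  expect_equal(C$C[3, 3], 1)
})

test_that("B-factor ratios are occupancy-weighted and reproduce the refinement-table worked example", {
  e <- toy_ensemble(n = 1)
  m <- get_model(e, 1)
  cls <- classify_entities(e, quiet = TRUE)
  # uniform B: ratio 1
  r <- bfactor_ratio(m, cls$ligand, cls$protein)
  expect_equal(r$ratio, 1.0)
  # ligand B doubled: ratio 2
  m2 <- m; m2$bfactor[cls$ligand] <- 100
  expect_equal(bfactor_ratio(m2, cls$ligand, cls$protein)$ratio, 2.0)
  # refinement-table means 61.5 (ligand) / 37.7 (protein) -> 1.63 at 2 d.p.
  m3 <- m
  m3$bfactor[cls$protein] <- 37.7
  m3$bfactor[cls$ligand] <- 61.5
  expect_equal(round(bfactor_ratio(m3, cls$ligand, cls$protein)$ratio, 2), 1.63)
  # occupancy weighting: a zero-occupancy atom cannot move the mean
  m4 <- m3
  m4$atoms$occupancy[cls$protein[1]] <- 0
  m4$bfactor[cls$protein[1]] <- 1000
  expect_equal(bfactor_ratio(m4, cls$ligand, cls$protein)$mean_protein_B, 37.7)
  expect_error(bfactor_ratio(m, integer(0), cls$protein), "empty")
})

test_that("the two-sample ratio comparison matches the textbook t formula", {
  a <- c(1.9, 2.3, 2.1, 2.5, 1.7)
  b <- c(1.55, 1.7, 1.63, 1.58, 1.72)
  res <- compare_bfactor_ratios(a, b)
  oracle <- student_t_oracle(a, b)
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  res0 <- compare_bfactor_ratios(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$t, 0); expect_equal(res0$p, 1)
  # strong separation
  expect_lt(compare_bfactor_ratios(c(1, 2, 3), c(11, 12, 13))$p, 1e-3)
  expect_error(compare_bfactor_ratios(c(1, 1), c(1, 1)), "degenerate")
})
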