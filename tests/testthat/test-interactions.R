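test_that("hydrogen-bond detection is a strict distance threshold and symmetric in atom order", {
  e <- toy_ensemble()
  place <- function(d) {
    e$coords[4, , 1] <- e$coords[3, , 1] + c(d, 0, 0)
    get_model(e, 1)
  }
  crit <- hbond_criterion(donor = list(name = "O1"), acceptor = list(name = "SD"))
  rev_crit <- hbond_criterion(donor = list(name = "SD"), acceptor = list(name = "O1"))

  r0 <- hbond_satisfied(place(0), crit)          # coincident atoms
  expect_true(r0$satisfied); expect_equal(r0$distance, 0)
  r_in <- hbond_satisfied(place(3.49), crit)
  expect_true(r_in$satisfied); expect_equal(r_in$distance, 3.49)
  r_out <- hbond_satisfied(place(3.51), crit)
  expect_false(r_out$satisfied); expect_equal(r_out$distance, 3.51)
  expect_equal(hbond_satisfied(place(2.9), rev_crit)$satisfied,
               hbond_satisfied(place(2.9), crit)$satisfied)
  # ambiguous selection: two atoms match
  bad <- hbond_criterion(donor = list(element = "O"), acceptor = list(name = "SD"))
  expect_error(hbond_satisfied(place(3), bad), "exactly 1")
})

test_that("ring geometry reports constructed plane angles and centroid distances", {
  # parallel coplanar-normal rings: angle 0 (mod 180)
  m <- two_ring_model(c(0, 0, 0), c(0, 0, 1), c(0, 0, 3.5), c(0, 0, 1))
  g <- ring_geometry(m, aromatic_ring(ring1_sel()), aromatic_ring(ring2_sel()))
  expect_equal(fold90(g$plane_angle), 0, tolerance = 1e-8)
  expect_equal(g$centroid_distance, 3.5, tolerance = 1e-8)

  # perpendicular rings, centroids 4 A apart
  m <- two_ring_model(c(0, 0, 0), c(0, 0, 1), c(4, 0, 0), c(1, 0, 0))
  g <- ring_geometry(m, aromatic_ring(ring1_sel()), aromatic_ring(ring2_sel()))
  expect_equal(fold90(g$plane_angle), 90, tolerance = 1e-8)
  expect_equal(g$centroid_distance, 4, tolerance = 1e-8)

  # T-shaped at 75 degrees, 5 A: satisfies the edge-to-face rule
  n2 <- c(sin(75 * pi / 180), 0, cos(75 * pi / 180))
  m <- two_ring_model(c(0, 0, 0), c(0, 0, 1), c(5, 0, 0), n2)
  r <- edge_to_face_satisfied(m, aromatic_ring(ring1_sel()), aromatic_ring(ring2_sel()))
  expect_true(r$satisfied)
  expect_equal(fold90(r$plane_angle), 75, tolerance = 1e-8)

  # collinear "ring" atoms: no plane
  atoms <- data.frame(serial = 1:12, name = paste0("C", 1:12), element = "C",
                      resname = rep(c("RNG", "RNH"), each = 6),
                      resid = rep(1:2, each = 6), chain = "X", altloc = "",
                      occupancy = 1, type = "HETATM")
  xyz <- rbind(cbind(1:6, 0, 0), hex_ring(c(4, 0, 0), c(1, 0, 0)))
  bad <- get_model(ensemble(atoms, array(xyz, c(12, 3, 1))), 1)
  expect_error(ring_geometry(bad, aromatic_ring(ring1_sel()),
                             aromatic_ring(ring2_sel())), "degenerate")
})

test_that("edge-to-face acceptance follows both the angle window and the centroid cutoff", {
  mk <- function(angle_deg, d) {
    n2 <- c(sin(angle_deg * pi / 180), 0, cos(angle_deg * pi / 180))
    two_ring_model(c(0, 0, 0), c(0, 0, 1), c(d, 0, 0), n2)
  }
  ok <- function(m) edge_to_face_satisfied(m, aromatic_ring(ring1_sel()),
                                           aromatic_ring(ring2_sel()))$satisfied
  expect_false(ok(mk(0, 3.5)))    # parallel stack: face-to-face, angle fails
  expect_false(ok(mk(90, 5.6)))   # distance just outside
  expect_true(ok(mk(90, 5.4)))    # distance just inside
  expect_true(ok(mk(60, 5.0)))    # window edge included
  expect_false(ok(mk(59, 5.0)))
  # symmetry in the two rings
  m <- mk(75, 5)
  expect_equal(ok(m),
               edge_to_face_satisfied(m, aromatic_ring(ring2_sel()),
                                      aromatic_ring(ring1_sel()))$satisfied)
})

test_that("water-network counting follows connected components through waters", {
  # anchor - w1 - w2 - w3 - w4 chained at 2.8 A: all four in the network
  at <- data.frame(serial = 1:5, name = c("OG1", rep("O", 4)),
                   element = "O", resname = c("THR", rep("HOH", 4)),
                   resid = c(352L, 601:604), chain = c("A", rep("W", 4)),
                   altloc = "", occupancy = 1,
                   type = c("ATOM", rep("HETATM", 4)))
  xyz <- cbind(2.8 * (0:4), 0, 0)
  m <- get_model(ensemble(at, array(xyz, c(5, 3, 1))), 1)
  spec <- water_network_spec(anchors = list(name = "OG1"))
  st <- water_network_state(m, spec)
  expect_equal(st$n_waters, 4L); expect_true(st$intact)

  # displace the second water to 6 A: chain breaks after w1
  xyz2 <- xyz; xyz2[3, 1] <- xyz2[2, 1] + 6
  m2 <- get_model(ensemble(at, array(xyz2, c(5, 3, 1))), 1)
  st2 <- water_network_state(m2, spec)
  expect_lt(st2$n_waters, 4L); expect_false(st2$intact)

  # no waters at all
  m3 <- get_model(ensemble(at[1, , drop = FALSE],
                           array(xyz[1, , drop = FALSE], c(1, 3, 1))), 1)
  expect_equal(water_network_state(m3, spec),
               list(n_waters = 0L, intact = FALSE))

  # the simple radius rule counts only first-shell waters
  st_r <- water_network_state(m, water_network_spec(
    anchors = list(name = "OG1"), rule = "radius"))
  expect_equal(st_r$n_waters, 1L)
})

test_that("persistence matches a naive per-model loop and its reported summaries", {
  e <- make_interaction_ensemble(ensemble_spec(
    n_models = 35, hbond_true_count = 5, stack_true_count = 20, seed = 1))
  crit <- synthetic_criteria()$hbond
  p <- persistence(e, crit)
  expect_equal(p$fraction,
               persistence_oracle(e, function(m) hbond_satisfied(m, crit)$satisfied))
  expect_equal(p$n_true, sum(p$per_model))
  expect_equal(p$percent_rounded, 14)

  all_true <- persistence(e, function(m) TRUE)
  expect_equal(all_true$fraction, 1.0)

  # planted 581-of-1000 frames mirrors a 58.1% trajectory persistence
  e2 <- make_interaction_ensemble(ensemble_spec(
    n_models = 40, hbond_true_count = 23, stack_true_count = 0, seed = 2))
  p2 <- persistence(e2, crit)
  expect_equal(p2$fraction, 23 / 40)

  # evaluator failure names the offending model
  e3 <- toy_ensemble(n = 3)
  expect_error(persistence(e3, function(m) {
    if (m$model_id == 2) stop("boom") else TRUE
  }), "model 2")
})

test_that("detections are invariant under random rigid motions of each model", {
  set.seed(77)
  e <- make_interaction_ensemble(ensemble_spec(
    n_models = 8, hbond_true_count = 4, stack_true_count = 5, seed = 12))
  cr <- synthetic_criteria()
  stack_eval <- function(m) edge_to_face_satisfied(m, cr$ring_ligand,
                                                   cr$ring_protein, cr$stacking)
  before <- list(persistence(e, cr$hbond)$per_model,
                 persistence(e, stack_eval)$per_model,
                 persistence(e, cr$water)$per_model)
  for (m in seq_len(8)) e <- apply_rigid_to_model(e, m, random_rigid_motion())
  after <- list(persistence(e, cr$hbond)$per_model,
                persistence(e, stack_eval)$per_model,
                persistence(e, cr$water)$per_model)
  expect_identical(before, after)
})

test_that("persistence percent rounding is half-up", {
  expect_equal(round_half_up(14.5), 15)
  expect_equal(round_half_up(14.49), 14)
  expect_equal(round_half_up(100 * 5 / 35), 14)
  expect_equal(round_half_up(100 * 36 / 38), 95)
})
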