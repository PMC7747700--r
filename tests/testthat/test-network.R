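test_that("contact fractions count frames inside the cutoff exactly", {
  # two C-alpha atoms fixed 3 A apart: full contact
  atoms <- data.frame(serial = 1:2, name = "CA", element = "C",
                      resname = "ALA", resid = 1:2, chain = "A", altloc = "",
                      occupancy = 1, type = "ATOM")
  mk <- function(dists) {
    coords <- array(0, c(2, 3, length(dists)))
    for (m in seq_along(dists)) coords[2, 1, m] <- dists[m]
    ensemble(atoms, coords)
  }
  expect_equal(contact_fractions(mk(rep(3, 10)))$F[1, 2], 1.0)
  expect_equal(contact_fractions(mk(rep(10, 10)))$F[1, 2], 0.0)
  # inside the cutoff in exactly 750 of 1000 frames: F = 0.75, edge admitted
  d <- c(rep(4.0, 750), rep(6.0, 250))
  cmap <- contact_fractions(mk(d))
  expect_equal(cmap$F[1, 2], 0.75)
})

test_that("network edges require both the contact threshold and nonzero correlation", {
  labels <- 1:3
  mkmap <- function(f12, f13, f23) {
    Fm <- diag(3); Fm[1, 2] <- Fm[2, 1] <- f12
    Fm[1, 3] <- Fm[3, 1] <- f13; Fm[2, 3] <- Fm[3, 2] <- f23
    structure(list(labels = labels, F = Fm, cutoff = 4.5, mode = "calpha"),
              class = "contact_map")
  }
  mkC <- function(c12, c13, c23) {
    C <- diag(3); C[1, 2] <- C[2, 1] <- c12
    C[1, 3] <- C[3, 1] <- c13; C[2, 3] <- C[3, 2] <- c23
    structure(list(labels = labels, C = C), class = "correlation_matrix")
  }
  # perfect correlation on a contact: zero-length edge
  net <- build_network(mkmap(1, 1, 1), mkC(1, 0.5, 0.5),
                       exclude_neighbors = FALSE)
  expect_equal(net$W[1, 2], 0)
  # |C| = 0.5 -> length log 2
  expect_equal(net$W[1, 3], log(2), tolerance = 1e-12)
  # F = 0.74 just below threshold: no edge even at |C| = 0.99
  net2 <- build_network(mkmap(0.74, 1, 1), mkC(0.99, 0.5, 0.5),
                        exclude_neighbors = FALSE)
  expect_false(is.finite(net2$W[1, 2]))
  # zero correlation on a contact: edge dropped with a warning
  expect_warning(net3 <- build_network(mkmap(1, 1, 1), mkC(0, 0.5, 0.5),
                                       exclude_neighbors = FALSE),
                 "zero correlation")
  expect_false(is.finite(net3$W[1, 2]))
  # label mismatch
  bad <- mkC(1, 1, 1); bad$labels <- 4:6
  expect_error(build_network(mkmap(1, 1, 1), bad), "mismatch")
  # negative correlations use |C|: same length as positive
  net4 <- build_network(mkmap(1, 1, 1), mkC(-0.5, 0.5, 0.5),
                        exclude_neighbors = FALSE)
  expect_equal(net4$W[1, 2], log(2), tolerance = 1e-12)
})

test_that("Floyd-Warshall distances are exact on hand-enumerated graphs and match Dijkstra", {
  # single edge
  W <- matrix(Inf, 2, 2); diag(W) <- 0; W[1, 2] <- W[2, 1] <- 1
  net <- structure(list(labels = 1:2, W = W), class = "dynamical_network")
  expect_equal(optimal_paths(net)$dist[1, 2], 1)
  # triangle: A-C direct 3 vs 2 via B
  W <- matrix(Inf, 3, 3); diag(W) <- 0
  W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1; W[1, 3] <- W[3, 1] <- 3
  net <- structure(list(labels = c("A", "B", "C"), W = W),
                   class = "dynamical_network")
  fw <- optimal_paths(net)
  expect_equal(fw$dist[1, 3], 2)
  expect_equal(get_optimal_path(fw, "A", "C"), c("A", "B", "C"))

  set.seed(31)
  for (rep in 1:25) {
    net <- random_network(sample(4:8, 1), p_edge = runif(1, 0.3, 0.9))
    fw <- optimal_paths(net)
    g <- igraph::graph_from_data_frame(
      data.frame(from = net$edges$i, to = net$edges$j,
                 weight = net$edges$length),
      directed = FALSE, vertices = data.frame(name = net$labels))
    D <- igraph::distances(g, algorithm = "dijkstra")
    ord <- match(net$labels, as.integer(rownames(D)))
    expect_equal(unname(fw$dist), unname(D[ord, ord]), tolerance = 1e-10)
  }
})

test_that("suboptimal path enumeration equals the exhaustive oracle on all small random graphs", {
  set.seed(57)
  for (rep in 1:200) {
    n <- sample(4:8, 1)
    net <- random_network(n, p_edge = runif(1, 0.25, 0.9))
    st <- sample(n, 2)
    k <- sample(c(1, 3, 10, 1000), 1)
    got <- suboptimal_paths(net, st[1], st[2], k = k)
    want <- enumerate_paths_oracle(net$W, st[1], st[2])
    keep <- seq_len(min(k, length(want$paths)))
    expect_equal(got$lengths, want$lengths[keep], tolerance = 1e-10)
    expect_identical(lapply(got$paths, as.integer),
                     lapply(want$paths[keep], as.integer))
  }
})

test_that("suboptimal paths are simple, sorted, start at the optimum, and flag unreachable sinks", {
  set.seed(73)
  net <- random_network(7, p_edge = 0.5)
  ps <- suboptimal_paths(net, 1, 7, k = 50)
  expect_true(all(diff(ps$lengths) >= -1e-12))
  expect_equal(ps$lengths[1], optimal_paths(net)$dist[1, 7], tolerance = 1e-12)
  for (p in ps$paths) {
    expect_false(anyDuplicated(p) > 0)
    expect_equal(p[1], 1); expect_equal(p[length(p)], 7)
  }
  # k = 1 reduces to the Floyd-Warshall optimum
  p1 <- suboptimal_paths(net, 1, 7, k = 1)
  fw <- optimal_paths(net)
  expect_equal(p1$paths[[1]], get_optimal_path(fw, 1, 7))

  # two-component graph: unreachable status
  W <- matrix(Inf, 4, 4); diag(W) <- 0
  W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
  net2 <- structure(list(labels = 1:4, W = W), class = "dynamical_network")
  ps2 <- suboptimal_paths(net2, 1, 4)
  expect_equal(ps2$status, "unreachable")
  expect_length(ps2$paths, 0)
})

test_that("parallel routes are returned in ascending length order", {
  # 1-2-4 (length 2) and 1-3-4 (length 3)
  W <- matrix(Inf, 4, 4); diag(W) <- 0
  W[1, 2] <- W[2, 1] <- 1; W[2, 4] <- W[4, 2] <- 1
  W[1, 3] <- W[3, 1] <- 1.5; W[3, 4] <- W[4, 3] <- 1.5
  net <- structure(list(labels = 1:4, W = W), class = "dynamical_network")
  ps <- suboptimal_paths(net, 1, 4, k = 2)
  expect_equal(ps$lengths, c(2, 3))
  expect_equal(ps$paths, list(c(1, 2, 4), c(1, 3, 4)))
})

test_that("the network stage recovers a planted correlation corridor end to end", {
  corridor <- c(1, 5, 9, 13, 17, 20)
  tr <- make_correlated_trajectory(trajectory_spec(
    n_residues = 20, n_frames = 2000, corridor = corridor,
    rho_corridor = 0.9, seed = 17))
  cmap <- contact_fractions(tr)
  C <- correlation_matrix(tr)
  net <- build_network(cmap, C)
  fw <- optimal_paths(net)
  expect_equal(get_optimal_path(fw, 1, 20), corridor)
  ps <- suboptimal_paths(net, 1, 20, k = 5)
  expect_equal(ps$paths[[1]], corridor)
})

test_that("path histograms cover every path and support shared-bin comparison", {
  W <- matrix(Inf, 4, 4); diag(W) <- 0
  W[1, 2] <- W[2, 1] <- 1; W[2, 4] <- W[4, 2] <- 1
  W[1, 3] <- W[3, 1] <- 1.5; W[3, 4] <- W[4, 3] <- 1.5
  net <- structure(list(labels = 1:4, W = W), class = "dynamical_network")
  ps <- suboptimal_paths(net, 1, 4, k = 3)
  h1 <- path_histogram(ps, nbins = 1)
  expect_equal(sum(h1$paths), length(ps$paths))
  expect_error(path_histogram(ps, breaks = c(0, 1)), "cover")
  h2 <- path_histogram(list(a = ps, b = ps), nbins = 4)
  expect_equal(sum(h2$a), length(ps$paths))
  expect_equal(h2$a, h2$b)
})
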