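# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: geometry from first principles, paths by
# exhaustive enumeration, statistics from textbook formulas.

dist3 <- function(a, b) sqrt(sum((a - b)^2))

# plane normal of a planar ring from the cross product of two ring chords
# (independent of the package's least-squares plane fit)
ring_normal_oracle <- function(xyz) {
  v1 <- xyz[2, ] - xyz[1, ]
  v2 <- xyz[3, ] - xyz[1, ]
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  n / sqrt(sum(n^2))
}

ring_angle_oracle <- function(xyz1, xyz2) {
  n1 <- ring_normal_oracle(xyz1)
  n2 <- ring_normal_oracle(xyz2)
  acos(min(1, max(-1, abs(sum(n1 * n2))))) * 180 / pi  # folded to [0,90]
}

# fold an angle in [0,180] onto [0,90] for comparisons that ignore normal
# orientation
fold90 <- function(a) ifelse(a > 90, 180 - a, a)

# naive per-model persistence loop (oracle for persistence())
persistence_oracle <- function(e, eval_fn) {
  hits <- 0L
  for (i in seq_len(n_models(e))) if (isTRUE(eval_fn(get_model(e, i)))) hits <- hits + 1L
  hits / n_models(e)
}

# random proper rotation matrix + translation
random_rigid_motion <- function() {
  A <- matrix(rnorm(9), 3)
  qr_d <- qr(A)
  R <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 10))
}

apply_rigid_to_model <- function(e, m, motion) {
  e$coords[, , m] <- e$coords[, , m] %*% motion$R +
    matrix(motion$t, nrow(e$atoms), 3, byrow = TRUE)
  e
}

# exhaustive enumeration of ALL simple paths s->t in a weight matrix W
# (Inf = no edge), returning lengths and node sequences sorted by
# (length, lexicographic node order)
enumerate_paths_oracle <- function(W, s, t) {
  n <- nrow(W)
  out_paths <- list(); out_lens <- numeric(0)
  rec <- function(v, visited, len, path) {
    if (v == t) {
      out_paths[[length(out_paths) + 1L]] <<- path
      out_lens[length(out_lens) + 1L] <<- len
      return()
    }
    for (u in seq_len(n)) {
      if (!visited[u] && is.finite(W[v, u]) && u != v) {
        visited[u] <- TRUE
        rec(u, visited, len + W[v, u], c(path, u))
        visited[u] <- FALSE
      }
    }
  }
  visited <- logical(n); visited[s] <- TRUE
  rec(s, visited, 0, s)
  ord <- order(out_lens, vapply(out_paths, function(p)
    paste(sprintf("%06d", p), collapse = ""), character(1)))
  list(paths = out_paths[ord], lengths = out_lens[ord])
}

# random connected weighted graph as a dynamical_network-shaped object
random_network <- function(n, p_edge = 0.5) {
  repeat {
    W <- matrix(Inf, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < p_edge) W[i, j] <- W[j, i] <- runif(1, 0.1, 3)
    }
    # force connectivity along a random spanning chain
    perm <- sample(n)
    for (k in seq_len(n - 1)) {
      i <- perm[k]; j <- perm[k + 1]
      if (!is.finite(W[i, j])) W[i, j] <- W[j, i] <- runif(1, 0.1, 3)
    }
    diag(W) <- 0
    if (all(is.finite(W[1, ]))) {} # no-op; connectivity ensured by chain
    break
  }
  ut <- which(is.finite(W) & upper.tri(W), arr.ind = TRUE)
  structure(list(labels = seq_len(n), W = W,
                 edges = data.frame(i = ut[, 1], j = ut[, 2],
                                    correlation = exp(-W[ut]),
                                    length = W[ut]),
                 cutoff_fraction = 0.75, exclude_neighbors = FALSE),
            class = "dynamical_network")
}

# textbook paired / two-sample t statistics
paired_t_oracle <- function(a, b) {
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  list(t = tstat, p = 2 * pt(-abs(tstat), length(d) - 1))
}
student_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tstat, p = 2 * pt(-abs(tstat), n1 + n2 - 2))
}
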