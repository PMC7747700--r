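# Dynamical network construction (contact-filtered, correlation-weighted)
# and optimal/suboptimal path enumeration between source and sink residues.

#' Residue-residue contact fractions over a trajectory
#'
#' `F_ij` is the fraction of frames in which the two residues are within
#' `cutoff`. The pair distance is the closest heavy-atom distance between
#' the residues (`mode = "heavy"`, the contact-map convention of dynamical
#' network tools); `mode = "calpha"` restricts both residues to their
#' C-alpha atoms.
#'
#' @param traj ensemble.
#' @param cutoff contact distance cutoff in Angstrom (default 4.5).
#' @param mode `"heavy"` or `"calpha"`.
#' @return list of class `contact_map` with `labels` (residue ids) and `F`
#'   (symmetric matrix in `[0,1]`, unit diagonal).
#' @export
contact_fractions <- function(traj, cutoff = 4.5,
                              mode = c("heavy", "calpha")) {
  mode <- match.arg(mode)
  at <- traj$atoms
  keep <- if (mode == "calpha") which(at$name == "CA") else
    which(!(at$element %in% "H"))
  rid <- paste(at$chain[keep], at$resid[keep], sep = "|")
  labels <- unique(at$resid[keep])
  ulab <- unique(rid)
  grp <- match(rid, ulab)
  n <- length(ulab)
  acc <- matrix(0, n, n)
  one_atom <- all(tabulate(grp) == 1L)
  for (m in seq_len(n_models(traj))) {
    xyz <- matrix(traj$coords[keep, , m], ncol = 3)
    dm <- as.matrix(dist(xyz))
    if (one_atom) {
      rd <- dm[order(grp), order(grp)]
    } else {
      # residue-pair minimum over atom-pair distances
      rd <- matrix(Inf, n, n)
      sp <- split(seq_along(grp), grp)
      for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
        rd[i, j] <- rd[j, i] <- min(dm[sp[[i]], sp[[j]]])
      }
      diag(rd) <- 0
    }
    acc <- acc + (rd < cutoff)
  }
  Fm <- acc / n_models(traj)
  diag(Fm) <- 1
  structure(list(labels = labels, F = Fm, cutoff = cutoff, mode = mode),
            class = "contact_map")
}

#' Build a dynamical network from contacts and correlations
#'
#' Nodes are residues (one C-alpha each); an undirected edge joins residues
#' whose contact fraction reaches `cutoff_fraction`, with length
#' `w_ij = -log|C_ij|` so that strongly correlated contacts are short.
#' Contacts with exactly zero correlation would have infinite length and
#' are dropped with a warning. Sequence-neighbour pairs (|i-j| = 1) are
#' excluded by default to forbid trivial backbone shortcuts.
#'
#' @param cmap a `contact_map` from [contact_fractions()].
#' @param C a `correlation_matrix` from [correlation_matrix()] (same labels).
#' @param cutoff_fraction contact persistence threshold (default 0.75).
#' @param exclude_neighbors drop sequence-neighbour edges (default TRUE).
#' @return list of class `dynamical_network` with `labels`, `W` (matrix of
#'   edge lengths, `Inf` where no edge), `edges` (data.frame `i`, `j`,
#'   `correlation`, `length`), and the parameters used.
#' @export
build_network <- function(cmap, C, cutoff_fraction = 0.75,
                          exclude_neighbors = TRUE) {
  if (!identical(cmap$labels, C$labels))
    stop("contact map and correlation matrix label mismatch")
  n <- length(cmap$labels)
  keep <- cmap$F >= cutoff_fraction
  diag(keep) <- FALSE
  if (exclude_neighbors) {
    nb <- abs(outer(seq_len(n), seq_len(n), "-")) == 1L
    keep <- keep & !nb
  }
  zeroC <- keep & abs(C$C) == 0
  if (any(zeroC))
    warning(sum(zeroC) / 2, " contact(s) with zero correlation dropped (infinite length)")
  keep <- keep & !zeroC
  W <- matrix(Inf, n, n)
  W[keep] <- -log(abs(C$C[keep]))
  diag(W) <- 0
  ut <- which(keep & upper.tri(keep), arr.ind = TRUE)
  edges <- data.frame(
    i = cmap$labels[ut[, 1]], j = cmap$labels[ut[, 2]],
    correlation = C$C[ut], length = W[ut]
  )
  structure(list(labels = cmap$labels, W = W, edges = edges,
                 cutoff_fraction = cutoff_fraction,
                 exclude_neighbors = exclude_neighbors),
            class = "dynamical_network")
}

#' Write a dynamical network as an edge-list TSV
#' @param net `dynamical_network`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_network_tsv <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' All-pairs shortest path lengths (Floyd-Warshall)
#'
#' Exact all-pairs shortest communication lengths over the network's
#' non-negative edge lengths, with a successor structure for path
#' reconstruction. Unreachable pairs keep length `Inf`.
#'
#' @param net `dynamical_network`.
#' @return list of class `fw_paths` with `dist` (matrix), `nxt` (successor
#'   index matrix), `labels`.
#' @export
optimal_paths <- function(net) {
  D <- net$W
  n <- nrow(D)
  nxt <- matrix(NA_integer_, n, n)
  fin <- is.finite(D)
  nxt[fin] <- col(D)[fin]
  diag(nxt) <- seq_len(n)
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    upd <- Dk < D
    if (any(upd)) {
      D[upd] <- Dk[upd]
      nxt[upd] <- nxt[, k][row(D)[upd]]
    }
  }
  structure(list(dist = D, nxt = nxt, labels = net$labels),
            class = "fw_paths")
}

#' Reconstruct one optimal path from a Floyd-Warshall result
#' @param fw `fw_paths` from [optimal_paths()].
#' @param source,sink residue labels.
#' @return Vector of residue labels along the shortest path, or NULL when
#'   the sink is unreachable.
#' @export
get_optimal_path <- function(fw, source, sink) {
  s <- match(source, fw$labels); t <- match(sink, fw$labels)
  if (is.na(s) || is.na(t)) stop("source/sink not in network")
  if (!is.finite(fw$dist[s, t])) return(NULL)
  path <- s
  while (path[length(path)] != t)
    path <- c(path, fw$nxt[path[length(path)], t])
  fw$labels[path]
}

# depth-first enumeration of all simple source->sink paths with total
# length <= bound, pruned by the exact shortest distance-to-sink.
# Returns list(paths, lengths, pruned): pruned = TRUE when the bound cut
# anything off (so the enumeration below the bound is complete either way,
# but pruned = FALSE means ALL simple paths were seen).
.bounded_paths <- function(W, s, t, bound, dist_to_sink, max_paths = 2e5) {
  n <- nrow(W)
  paths <- vector("list", 0); lens <- numeric(0)
  pruned <- FALSE
  visited <- logical(n)
  stack_path <- integer(0)
  recurse <- function(v, len) {
    if (length(paths) >= max_paths) { pruned <<- TRUE; return() }
    if (v == t) {
      paths[[length(paths) + 1L]] <<- c(stack_path, v)
      lens[length(lens) + 1L] <<- len
      return()
    }
    visited[v] <<- TRUE
    stack_path <<- c(stack_path, v)
    nb <- which(is.finite(W[v, ]) & !visited & seq_len(n) != v)
    nb <- nb[order(nb)]
    for (u in nb) {
      nl <- len + W[v, u]
      if (nl + dist_to_sink[u] <= bound + 1e-12) {
        recurse(u, nl)
      } else pruned <<- TRUE
    }
    visited[v] <<- FALSE
    stack_path <<- stack_path[-length(stack_path)]
  }
  recurse(s, 0)
  list(paths = paths, lengths = lens, pruned = pruned)
}

#' Top-k suboptimal paths between source and sink
#'
#' Enumerates the `k` distinct simple paths of smallest total length,
#' ascending, using bounded depth-first search: the length cap starts at
#' the optimal path length and is raised until `k` paths fit under it (the
#' length-offset strategy of classical suboptimal-path tools). Exact
#' shortest distances to the sink prune the search. Equal-length paths are
#' ordered lexicographically by node sequence, making the output
#' deterministic.
#'
#' @param net `dynamical_network`.
#' @param source,sink residue labels.
#' @param k number of paths requested (default 1000).
#' @return list of class `path_set` with `source`, `sink`, `paths` (list of
#'   label vectors), `lengths` (ascending), `k_requested`, `status`
#'   (`"ok"` or `"unreachable"`).
#' @export
suboptimal_paths <- function(net, source, sink, k = 1000) {
  s <- match(source, net$labels); t <- match(sink, net$labels)
  if (is.na(s) || is.na(t)) stop("source/sink not in network")
  fw <- optimal_paths(net)
  d_opt <- fw$dist[s, t]
  if (!is.finite(d_opt)) {
    return(structure(list(source = source, sink = sink, paths = list(),
                          lengths = numeric(0), k_requested = k,
                          status = "unreachable"),
                     class = "path_set"))
  }
  dist_to_sink <- fw$dist[, t]
  step <- max(d_opt, 1) * 0.25
  bound <- d_opt
  repeat {
    res <- .bounded_paths(net$W, s, t, bound, dist_to_sink)
    if (length(res$paths) >= k || !res$pruned) break
    bound <- bound + step
  }
  ord <- order(res$lengths,
               vapply(res$paths, function(p)
                 paste(sprintf("%06d", p), collapse = ""), character(1)))
  ord <- head(ord, k)
  structure(
    list(source = source, sink = sink,
         paths = lapply(res$paths[ord], function(p) net$labels[p]),
         lengths = res$lengths[ord], k_requested = k, status = "ok"),
    class = "path_set"
  )
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("<path_set> %s -> %s: %d path(s) [%s]\n", x$source, x$sink,
              length(x$paths), x$status))
  if (length(x$paths))
    cat(sprintf("  optimal length %.4f: %s\n", x$lengths[1],
                paste(x$paths[[1]], collapse = " -> ")))
  invisible(x)
}

#' Histogram of suboptimal path lengths
#'
#' @param ps a `path_set` (non-empty), or a named list of `path_set`s to
#'   overlay on shared bins.
#' @param breaks bin edges covering all path lengths, or NULL to derive
#'   `nbins` equal-width bins.
#' @param nbins number of bins when `breaks` is NULL.
#' @return data.frame with `bin_lo`, `bin_hi`, and one count column per
#'   path set; counts in each column sum to that set's path count.
#' @export
path_histogram <- function(ps, breaks = NULL, nbins = 30) {
  sets <- if (inherits(ps, "path_set")) list(paths = ps) else ps
  if (any(!vapply(sets, inherits, logical(1), "path_set")))
    stop("inputs must be path_set objects")
  lens <- lapply(sets, `[[`, "lengths")
  if (any(lengths(lens) == 0L)) stop("empty path set")
  all_l <- unlist(lens)
  if (is.null(breaks)) {
    rng <- range(all_l)
    pad <- max(diff(rng), 1e-9) * 1e-6
    breaks <- seq(rng[1] - pad, rng[2] + pad, length.out = nbins + 1)
  }
  if (min(all_l) < min(breaks) || max(all_l) > max(breaks))
    stop("bin edges do not cover all path lengths")
  out <- data.frame(bin_lo = head(breaks, -1), bin_hi = tail(breaks, -1))
  for (nm in names(sets)) {
    cnt <- table(cut(lens[[nm]], breaks, include.lowest = TRUE))
    out[[nm]] <- as.integer(cnt)
  }
  out
}
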