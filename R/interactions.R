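# Geometric interaction criteria evaluated per model, and their persistence
# over an ensemble or trajectory.

.dist3 <- function(a, b) sqrt(sum((a - b)^2))

# resolve a selection spec (list of select_atoms arguments, or bare integer
# indices) against an ensemble; used by the criterion constructors
.resolve_sel <- function(e, sel) {
  if (is.numeric(sel)) return(as.integer(sel))
  if (!is.list(sel)) stop("selection must be an index vector or a list of select_atoms() arguments")
  do.call(select_atoms, c(list(e), sel))
}

.resolve_single <- function(e, sel, what) {
  idx <- .resolve_sel(e, sel)
  if (length(idx) != 1L)
    stop(sprintf("%s selection must resolve to exactly 1 atom, got %d",
                 what, length(idx)))
  idx
}

#' Hydrogen-bond distance criterion
#'
#' Heavy-atom donor-acceptor criterion: satisfied when the Euclidean
#' distance between the two atoms is below `dmax`. No angle term is used;
#' the criterion is symmetric in donor/acceptor.
#'
#' @param donor,acceptor each a single atom: integer index, or a list of
#'   [select_atoms()] arguments resolving to exactly one atom.
#' @param dmax distance cutoff in Angstrom (default 3.5).
#' @return An object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(donor, acceptor, dmax = 3.5) {
  stopifnot(dmax > 0)
  structure(list(donor = donor, acceptor = acceptor, dmax = dmax),
            class = "hbond_criterion")
}

#' Evaluate a hydrogen-bond criterion on one model
#' @param model a `structure_model` from [get_model()].
#' @param crit an [hbond_criterion()].
#' @return list with `satisfied` (logical) and `distance` (Angstrom).
#' @export
hbond_satisfied <- function(model, crit) {
  i <- .resolve_single(model, crit$donor, "donor")
  j <- .resolve_single(model, crit$acceptor, "acceptor")
  d <- .dist3(model$coords[i, ], model$coords[j, ])
  list(satisfied = d < crit$dmax, distance = d)
}

#' Aromatic ring defined by its member atoms
#'
#' @param atoms 5 or 6 atoms: integer indices or a [select_atoms()] argument
#'   list. Five-membered rings (imidazole) are supported because the plane
#'   is a least-squares fit.
#' @return Object of class `aromatic_ring`.
#' @export
aromatic_ring <- function(atoms) structure(list(atoms = atoms), class = "aromatic_ring")

# least-squares plane of a point set: centroid + unit normal.
# Errors when points are (near-)collinear so no plane is defined.
.plane_fit <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate ring geometry: atoms are collinear")
  list(centroid = ctr, normal = sv$v[, 3])
}

#' Plane angle and centroid distance between two rings
#'
#' Planes are least-squares fits through the ring atoms; the angle between
#' the plane normals is reported raw in `[0, 180)` degrees (no folding --
#' the edge-to-face window 60--120 degrees is symmetric under folding).
#'
#' @param model a `structure_model`.
#' @param ring1,ring2 [aromatic_ring()] objects.
#' @return list with `plane_angle` (degrees) and `centroid_distance`
#'   (Angstrom).
#' @export
ring_geometry <- function(model, ring1, ring2) {
  i1 <- .resolve_sel(model, ring1$atoms)
  i2 <- .resolve_sel(model, ring2$atoms)
  if (length(i1) < 5 || length(i1) > 6 || length(i2) < 5 || length(i2) > 6)
    stop("each ring must resolve to 5 or 6 atoms")
  p1 <- .plane_fit(model$coords[i1, , drop = FALSE])
  p2 <- .plane_fit(model$coords[i2, , drop = FALSE])
  cosang <- sum(p1$normal * p2$normal)
  ang <- acos(min(1, max(-1, cosang))) * 180 / pi
  if (ang >= 180) ang <- 0
  list(plane_angle = ang,
       centroid_distance = .dist3(p1$centroid, p2$centroid))
}

#' Edge-to-face pi-pi stacking criterion
#'
#' Satisfied when the angle between ring planes lies in `angle_window`
#' (default 60--120 degrees, i.e. roughly perpendicular rings) and the ring
#' centroids are within `centroid_dmax` (default 5.5 Angstrom).
#'
#' @param angle_window length-2 numeric, degrees.
#' @param centroid_dmax Angstrom.
#' @return Object of class `stacking_criterion`.
#' @export
stacking_criterion <- function(angle_window = c(60, 120), centroid_dmax = 5.5) {
  stopifnot(length(angle_window) == 2, angle_window[1] >= 0,
            angle_window[2] <= 180, angle_window[1] < angle_window[2])
  structure(list(angle_window = angle_window, centroid_dmax = centroid_dmax),
            class = "stacking_criterion")
}

#' Evaluate edge-to-face stacking on one model
#' @param model a `structure_model`.
#' @param ring1,ring2 [aromatic_ring()] objects.
#' @param crit a [stacking_criterion()].
#' @return list with `satisfied`, `plane_angle`, `centroid_distance`.
#' @export
edge_to_face_satisfied <- function(model, ring1, ring2,
                                   crit = stacking_criterion()) {
  g <- ring_geometry(model, ring1, ring2)
  # fold so that the window test sees the acute-equivalent representative
  ang <- g$plane_angle
  ok <- ang >= crit$angle_window[1] & ang <= crit$angle_window[2] &
    g$centroid_distance <= crit$centroid_dmax
  list(satisfied = ok, plane_angle = g$plane_angle,
       centroid_distance = g$centroid_distance)
}

#' Water-network specification
#'
#' The pocket water network is the set of water oxygens connected -- directly
#' or through other network waters -- to at least one anchor atom, with links
#' shorter than `link_dmax`. The network is "intact" when it contains at
#' least `expected_count` waters.
#'
#' @param anchors anchor (polar pocket) atoms: indices or [select_atoms()]
#'   argument list.
#' @param expected_count waters required for an intact network (default 4).
#' @param link_dmax link distance cutoff in Angstrom (default 3.5).
#' @param rule `"component"` (connected component through waters, default)
#'   or `"radius"` (simple count of waters within `link_dmax` of an anchor).
#' @return Object of class `water_network_spec`.
#' @export
water_network_spec <- function(anchors, expected_count = 4, link_dmax = 3.5,
                               rule = c("component", "radius")) {
  stopifnot(expected_count >= 1, link_dmax > 0)
  structure(list(anchors = anchors, expected_count = expected_count,
                 link_dmax = link_dmax, rule = match.arg(rule)),
            class = "water_network_spec")
}

#' Count network waters in one model
#'
#' @param model a `structure_model`.
#' @param spec a [water_network_spec()].
#' @param water_resnames residue names recognised as water.
#' @return list with `n_waters` and `intact`.
#' @export
water_network_state <- function(model, spec,
                                water_resnames = c("HOH", "WAT")) {
  anchors <- .resolve_sel(model, spec$anchors)
  if (length(anchors) == 0L) stop("no anchor atoms resolvable")
  wat <- which(model$atoms$resname %in% water_resnames &
                 model$atoms$element %in% c("O", "") &
                 grepl("^O", model$atoms$name))
  if (length(wat) == 0L)
    return(list(n_waters = 0L, intact = FALSE))
  if (spec$rule == "radius") {
    d <- sapply(wat, function(w) min(sapply(anchors, function(a)
      .dist3(model$coords[w, ], model$coords[a, ]))))
    n <- sum(d < spec$link_dmax)
  } else {
    nodes <- c(anchors, wat)
    xyz <- model$coords[nodes, , drop = FALSE]
    dm <- as.matrix(dist(xyz))
    adj <- dm < spec$link_dmax
    # BFS from the anchor nodes through the adjacency graph
    seen <- seq_along(anchors)
    queue <- seen
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & !(seq_along(nodes) %in% seen))
      seen <- c(seen, nb)
      queue <- c(queue, nb)
    }
    n <- sum(seen > length(anchors))
  }
  list(n_waters = as.integer(n), intact = n >= spec$expected_count)
}

#' Persistence of a criterion over an ensemble
#'
#' Applies a per-model evaluator to every model and summarises the fraction
#' of models in which the criterion holds (the interaction "persistence").
#'
#' @param e ensemble.
#' @param evaluator function taking a `structure_model` and returning either
#'   a logical or a list with a `satisfied` element; convenience dispatch is
#'   provided for [hbond_criterion()] and [water_network_spec()] objects.
#' @return Object of class `persistence_result`: list with `per_model`
#'   (logical), `values` (numeric distances/angles when the evaluator reports
#'   one), `n_true`, `fraction`, `percent_rounded` (half-up integer percent),
#'   `model_ids`.
#' @export
persistence <- function(e, evaluator) {
  stopifnot(n_models(e) >= 1)
  f <- evaluator
  if (inherits(evaluator, "hbond_criterion"))
    f <- function(m) hbond_satisfied(m, evaluator)
  if (inherits(evaluator, "water_network_spec"))
    f <- function(m) water_network_state(m, evaluator)
  per_model <- logical(n_models(e))
  values <- rep(NA_real_, n_models(e))
  for (i in seq_len(n_models(e))) {
    r <- tryCatch(f(get_model(e, i)), error = function(err)
      stop(sprintf("evaluator failed on model %d: %s",
                   e$model_ids[i], conditionMessage(err))))
    if (is.list(r)) {
      per_model[i] <- isTRUE(r$satisfied) || isTRUE(r$intact)
      num <- r$distance %||% r$centroid_distance %||% r$n_waters
      if (!is.null(num)) values[i] <- as.numeric(num)
    } else per_model[i] <- isTRUE(r)
  }
  n_true <- sum(per_model)
  fraction <- n_true / length(per_model)
  structure(
    list(per_model = per_model, values = values, n_true = n_true,
         fraction = fraction, percent_rounded = round_half_up(100 * fraction),
         model_ids = e$model_ids),
    class = "persistence_result"
  )
}

#' @export
print.persistence_result <- function(x, ...) {
  cat(sprintf("<persistence> %d/%d models (%.1f%%, reported %d%%)\n",
              x$n_true, length(x$per_model), 100 * x$fraction,
              x$percent_rounded))
  invisible(x)
}

#' Write a persistence result as a per-model TSV
#' @param x `persistence_result`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_persistence_tsv <- function(x, path) {
  write.table(
    data.frame(model_id = x$model_ids, satisfied = x$per_model,
               value = x$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero to integer percent
#'
#' `round()` in R rounds half to even; interaction persistences are reported
#' with the conventional half-up rule (14.49 -> 14, 14.5 -> 15).
#' @param x numeric.
#' @return numeric of the same length.
#' @export
round_half_up <- function(x) floor(x + 0.5)
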