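# Superposition, RMSD/RMSF, C-alpha correlation matrices, and B-factor
# ratio statistics.

#' Kabsch least-squares rigid superposition
#'
#' Optimal proper rotation and translation mapping `mobile` onto
#' `reference` in the least-squares sense (SVD solution; reflections are
#' excluded).
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (Angstrom, after superposition). The transform maps a row
#'   vector `x` to `x %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 || ncol(reference) != 3)
    stop("coordinate sets must be n x 3 with equal n")
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 points for superposition")
  w <- if (is.null(weights)) rep(1, n) else {
    stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
    weights
  }
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  if (sv$d[2] < 1e-12)
    stop("degenerate (rank-deficient) coordinate set")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  moved <- P %*% R
  rmsd <- sqrt(sum(w * rowSums((moved - Q)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% R), rmsd = rmsd)
}

.apply_transform <- function(xyz, fit) {
  sweep(xyz %*% fit$rotation, 2, -fit$translation)
}

#' Per-frame RMSD against a reference model
#'
#' Each frame is superposed onto the reference over the selection before the
#' RMSD over that selection is computed, so global rigid motion does not
#' register.
#'
#' @param traj ensemble (trajectory).
#' @param reference a `structure_model` (e.g. `get_model(traj, 1)`), or NULL
#'   for the first frame.
#' @param sel integer atom indices (default: all atoms).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = NULL, sel = NULL) {
  if (is.null(sel)) sel <- seq_len(nrow(traj$atoms))
  if (length(sel) == 0L) stop("empty selection")
  ref <- if (is.null(reference)) get_model(traj, 1)$coords else reference$coords
  refc <- ref[sel, , drop = FALSE]
  vapply(seq_len(n_models(traj)), function(m) {
    kabsch_superpose(traj$coords[sel, , m], refc)$rmsd
  }, numeric(1))
}

# superpose every frame of traj onto ref coords over sel; returns the
# coordinate array restricted to sel
.superpose_all <- function(traj, sel, ref) {
  out <- array(NA_real_, c(length(sel), 3L, n_models(traj)))
  for (m in seq_len(n_models(traj))) {
    fit <- kabsch_superpose(traj$coords[sel, , m], ref)
    out[, , m] <- .apply_transform(traj$coords[sel, , m], fit)
  }
  out
}

# iterated mean-structure superposition: fit to frame 1, take the mean,
# refit to the mean once (the usual RMSF reference choice)
.fit_to_mean <- function(traj, sel) {
  a <- .superpose_all(traj, sel, traj$coords[sel, , 1])
  mean1 <- apply(a, c(1, 2), mean)
  tmp <- ensemble(traj$atoms[sel, , drop = FALSE], a)
  a2 <- .superpose_all(tmp, seq_along(sel), mean1)
  list(coords = a2, mean = apply(a2, c(1, 2), mean))
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto the mean structure (one refinement iteration)
#' before fluctuations about the mean are measured:
#' `rmsf_i = sqrt(mean_t |r_i(t) - <r_i>|^2)`.
#'
#' @param traj ensemble with at least 2 frames.
#' @param sel integer atom indices (default: all atoms).
#' @return data.frame with columns `resid`, `rmsf` (Angstrom), plus the
#'   mean structure as attribute `"reference"`.
#' @export
rmsf <- function(traj, sel = NULL) {
  if (n_models(traj) < 2) stop("RMSF undefined for a single frame")
  if (is.null(sel)) sel <- seq_len(nrow(traj$atoms))
  ft <- .fit_to_mean(traj, sel)
  dev2 <- apply((ft$coords - array(ft$mean, dim(ft$coords)))^2, c(1, 3), sum)
  out <- data.frame(resid = traj$atoms$resid[sel],
                    rmsf = sqrt(rowMeans(dev2)))
  attr(out, "reference") <- ft$mean
  out
}

#' Normalized displacement-vector correlation matrix
#'
#' The dynamical cross-correlation
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` with
#' `dr = r - <r>_t`, computed after superposing all frames onto the mean
#' structure. Residues with zero displacement variance get zero
#' off-diagonal entries (with a warning) and a unit diagonal.
#'
#' @param traj ensemble with at least 2 frames.
#' @param sel integer atom indices, typically one C-alpha per residue
#'   (default: atoms named `"CA"`, else all).
#' @param superpose superpose frames onto the mean structure first
#'   (default TRUE). Required for trajectories containing global
#'   rigid-body motion; for coordinates already sharing a lab frame (e.g.
#'   the synthetic generators) the superposition absorbs six degrees of
#'   freedom of genuine correlated motion and can be turned off.
#' @return list of class `correlation_matrix` with `labels` (residue ids)
#'   and `C` (symmetric, unit diagonal, entries in `[-1, 1]`).
#' @export
correlation_matrix <- function(traj, sel = NULL, superpose = TRUE) {
  if (n_models(traj) < 2) stop("need at least 2 frames")
  if (is.null(sel)) {
    sel <- which(traj$atoms$name == "CA")
    if (length(sel) == 0L) sel <- seq_len(nrow(traj$atoms))
  }
  ft <- if (superpose) .fit_to_mean(traj, sel) else {
    a <- traj$coords[sel, , , drop = FALSE]
    list(coords = a, mean = apply(a, c(1, 2), mean))
  }
  n <- length(sel); TT <- n_models(traj)
  dev <- ft$coords - array(ft$mean, dim(ft$coords))  # n x 3 x T
  num <- matrix(0, n, n)
  for (ax in 1:3) {
    A <- dev[, ax, , drop = TRUE]            # n x T
    if (is.null(dim(A))) A <- matrix(A, n, TT)
    num <- num + A %*% t(A)
  }
  num <- num / TT
  v <- diag(num)
  zero <- v < 1e-12
  if (any(zero)) warning(sum(zero), " zero-variance residue(s); correlations set to 0")
  denom <- sqrt(pmax(v, 1e-300))
  C <- num / outer(denom, denom)
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  C <- (C + t(C)) / 2
  C[C > 1] <- 1; C[C < -1] <- -1
  structure(list(labels = traj$atoms$resid[sel], C = C),
            class = "correlation_matrix")
}

#' Ligand/protein B-factor ratio statistics for one model
#'
#' Occupancy-weighted mean B over the ligand and protein selections, their
#' ratio, and the per-atom ligand ratio sample (each ligand atom's B divided
#' by the mean protein B) used to compare refinement variants.
#'
#' @param model a `structure_model`.
#' @param ligand_sel,protein_sel integer atom indices.
#' @return list with `mean_ligand_B`, `mean_protein_B`, `ratio`,
#'   `per_atom_ligand_ratios`, `ratio_sd` (SD of the per-atom ratios).
#' @export
bfactor_ratio <- function(model, ligand_sel, protein_sel) {
  if (length(ligand_sel) == 0L || length(protein_sel) == 0L)
    stop("empty selection")
  wmean <- function(idx) {
    w <- model$atoms$occupancy[idx]
    sum(w * model$bfactor[idx]) / sum(w)
  }
  mL <- wmean(ligand_sel); mP <- wmean(protein_sel)
  per_atom <- model$bfactor[ligand_sel] / mP
  list(mean_ligand_B = mL, mean_protein_B = mP, ratio = mL / mP,
       per_atom_ligand_ratios = per_atom, ratio_sd = sd(per_atom))
}

#' Two-sample t-test on B-factor ratio samples
#'
#' Classical two-tailed unpaired test comparing per-atom ligand/protein
#' B-factor ratios between two refinement variants. Equal-variance
#' (Student) by default; Welch behind `welch = TRUE`.
#'
#' @param sample_a,sample_b numeric ratio samples (each n >= 2).
#' @param welch use the Welch correction instead of pooled variance.
#' @return list with `t`, `df`, `p`.
#' @export
compare_bfactor_ratios <- function(sample_a, sample_b, welch = FALSE) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("each sample needs n >= 2")
  if (sd(c(sample_a - mean(sample_a), sample_b - mean(sample_b))) < 1e-15)
    stop("degenerate input: zero pooled variance")
  ht <- t.test(sample_a, sample_b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
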