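# Binding and stability assay models: competition fluorescence-polarization
# curves with probe-corrected Ki, and Boltzmann thermal melts.

#' Competition FP dataset container
#'
#' @param conc_M competitor concentrations (molar), one per dose.
#' @param Y polarization readings (mP): matrix with one row per dose and
#'   one column per replicate (a vector is treated as one replicate).
#' @param probe_conc_nM,probe_Kd_nM fluorescent-probe concentration and
#'   its dissociation constant for the receptor, in nM. The probe Kd is an
#'   input (measured separately), never re-fit.
#' @param label free-text receptor/ligand label.
#' @return list of class `competition_dataset` with `X = log10(conc_M)`.
#' @export
competition_dataset <- function(conc_M, Y, probe_conc_nM, probe_Kd_nM,
                                label = "") {
  Y <- as.matrix(Y)
  stopifnot(length(conc_M) == nrow(Y), all(conc_M > 0),
            probe_conc_nM > 0, probe_Kd_nM > 0)
  if (length(unique(conc_M)) < 4)
    stop("need at least 4 distinct concentrations spanning the transition")
  structure(list(X = log10(conc_M), Y = Y, probe_conc_nM = probe_conc_nM,
                 probe_Kd_nM = probe_Kd_nM, label = label),
            class = "competition_dataset")
}

#' Read a competition FP CSV (`conc_M, rep1, rep2, ...`)
#' @param path CSV path.
#' @param probe_conc_nM,probe_Kd_nM probe parameters (see
#'   [competition_dataset()]).
#' @param label dataset label.
#' @return A [competition_dataset()].
#' @export
read_competition_csv <- function(path, probe_conc_nM, probe_Kd_nM,
                                 label = basename(path)) {
  tab <- read.table(path, header = TRUE, sep = ",")
  competition_dataset(tab[[1]], as.matrix(tab[, -1, drop = FALSE]),
                      probe_conc_nM, probe_Kd_nM, label)
}

# one-site displacement curve, unit Hill slope as printed
.eq1 <- function(X, Top, Bottom, LogEC50, slope = 1) {
  Bottom + (Top - Bottom) / (1 + 10^(slope * (X - LogEC50)))
}

#' Convert a fitted log EC50 to log Ki via the probe correction
#'
#' The competition-curve midpoint overestimates the competitor affinity by
#' the probe occupancy factor:
#' `logEC50 = log10(10^logKi * (1 + probe_conc/probe_Kd))`, hence
#' `logKi = logEC50 - log10(1 + probe_conc/probe_Kd)` (exact inversion).
#'
#' @param logEC50 log10 molar midpoint of the displacement curve.
#' @param probe_conc_nM,probe_Kd_nM probe concentration and Kd (nM; only
#'   their ratio enters).
#' @return logKi in log10 molar.
#' @export
logec50_to_logki <- function(logEC50, probe_conc_nM, probe_Kd_nM) {
  stopifnot(probe_conc_nM >= 0, probe_Kd_nM > 0)
  logEC50 - log10(1 + probe_conc_nM / probe_Kd_nM)
}

#' Inverse of [logec50_to_logki()]
#' @param logKi log10 molar inhibition constant.
#' @param probe_conc_nM,probe_Kd_nM probe parameters.
#' @return logEC50 in log10 molar.
#' @export
logki_to_logec50 <- function(logKi, probe_conc_nM, probe_Kd_nM) {
  logKi + log10(1 + probe_conc_nM / probe_Kd_nM)
}

#' Fit the one-site displacement curve to a competition dataset
#'
#' Least-squares fit of
#' `Y = Bottom + (Top - Bottom)/(1 + 10^(X - LogEC50))` on all replicate
#' points jointly, with multi-start initialisation of `LogEC50` over the
#' dose range. The Hill slope is fixed at 1 (as the model is written);
#' `variable_slope = TRUE` frees it.
#'
#' @param ds a [competition_dataset()].
#' @param variable_slope free the Hill slope.
#' @return list of class `logistic_fit` with `Top`, `Bottom`, `LogEC50`
#'   (and `HillSlope` when freed), standard errors `se`, `residual_se`,
#'   `converged`.
#' @export
fit_logistic_competition <- function(ds, variable_slope = FALSE) {
  X <- rep(ds$X, ncol(ds$Y))
  Y <- as.vector(ds$Y)
  ok <- is.finite(Y)
  X <- X[ok]; Y <- Y[ok]
  if (diff(range(Y)) < 1e-9) stop("degenerate fit: flat data")
  dat <- data.frame(X = X, Y = Y)
  top0 <- max(Y); bot0 <- min(Y)
  starts <- unique(c(
    X[which.min(abs(Y - (top0 + bot0) / 2))],
    as.numeric(quantile(ds$X, c(0.25, 0.5, 0.75)))
  ))
  best <- NULL
  for (s0 in starts) {
    st <- list(Top = top0, Bottom = bot0, LogEC50 = s0)
    fml <- Y ~ Bottom + (Top - Bottom) / (1 + 10^(X - LogEC50))
    if (variable_slope) {
      st$HillSlope <- 1
      fml <- Y ~ Bottom + (Top - Bottom) / (1 + 10^(HillSlope * (X - LogEC50)))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = dat, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("competition fit did not converge from any start")
  cf <- coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(cf)), names(cf)))
  out <- list(Top = unname(cf["Top"]), Bottom = unname(cf["Bottom"]),
              LogEC50 = unname(cf["LogEC50"]),
              HillSlope = if (variable_slope) unname(cf["HillSlope"]) else 1,
              se = se,
              residual_se = sqrt(best$rss / max(1, length(Y) - length(cf))),
              converged = TRUE)
  if (out$LogEC50 < min(ds$X) || out$LogEC50 > max(ds$X))
    warning("fitted LogEC50 lies outside the dose range")
  structure(out, class = "logistic_fit")
}

#' Fit Ki for a competition dataset
#'
#' Fits the displacement curve, converts the midpoint to an inhibition
#' constant with the probe correction, and (for paired tests) fits each
#' replicate column separately to give a per-replicate logKi sample.
#'
#' @param ds a [competition_dataset()].
#' @return list of class `ki_result` with `logKi`, `Ki` (molar), `CI95`
#'   (molar), `fit` (the joint [fit_logistic_competition()] result),
#'   `per_replicate_logKi`.
#' @export
fit_ki <- function(ds) {
  fit <- fit_logistic_competition(ds)
  logKi <- logec50_to_logki(fit$LogEC50, ds$probe_conc_nM, ds$probe_Kd_nM)
  se <- fit$se["LogEC50"]
  ci <- if (is.finite(se)) logKi + c(-1, 1) * 1.96 * se else c(NA_real_, NA_real_)
  per_rep <- rep(NA_real_, ncol(ds$Y))
  for (r in seq_len(ncol(ds$Y))) {
    f <- tryCatch(fit_logistic_competition(
      competition_dataset(10^ds$X, ds$Y[, r], ds$probe_conc_nM,
                          ds$probe_Kd_nM)),
      error = function(e) NULL)
    if (!is.null(f))
      per_rep[r] <- logec50_to_logki(f$LogEC50, ds$probe_conc_nM, ds$probe_Kd_nM)
  }
  structure(list(logKi = logKi, Ki = 10^logKi, CI95 = 10^ci, fit = fit,
                 per_replicate_logKi = per_rep, label = ds$label),
            class = "ki_result")
}

#' Paired t-test on log Ki values from parallel experiments
#'
#' @param logki_a,logki_b equal-length numeric vectors: per-experiment
#'   logKi for the two ligands, paired by experiment.
#' @return list with `t`, `df`, `p`, `mean_difference`, `degenerate`
#'   (TRUE when within-pair variance is zero, in which case `p` is NA).
#' @export
compare_logki <- function(logki_a, logki_b) {
  if (length(logki_a) != length(logki_b))
    stop("paired test needs equal-length samples")
  if (length(logki_a) < 2) stop("need at least 2 paired experiments")
  d <- logki_a - logki_b
  if (sd(d) < 1e-12) {
    if (all(abs(d) < 1e-12))
      return(list(t = 0, df = length(d) - 1, p = 1,
                  mean_difference = 0, degenerate = FALSE))
    return(list(t = NA_real_, df = length(d) - 1, p = NA_real_,
                mean_difference = mean(d), degenerate = TRUE))
  }
  ht <- t.test(logki_a, logki_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_difference = mean(d), degenerate = FALSE)
}

#' Thermal melt curve container
#' @param T_C temperatures (degrees C, strictly increasing).
#' @param F_obs fluorescence readings.
#' @param background_subtracted has a no-protein blank been subtracted?
#' @return list of class `melt_curve`.
#' @export
melt_curve <- function(T_C, F_obs, background_subtracted = FALSE) {
  stopifnot(length(T_C) == length(F_obs), all(diff(T_C) > 0))
  structure(list(T = T_C, F = F_obs,
                 background_subtracted = background_subtracted),
            class = "melt_curve")
}

#' Read a DSF CSV (`temp_C, well1, ..., blank`)
#'
#' When a `blank` column is present it is subtracted pointwise from every
#' well (no-protein background), mirroring standard DSF practice.
#'
#' @param path CSV path.
#' @return Named list of [melt_curve()] objects, one per well column.
#' @export
read_dsf_csv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = ",")
  blank <- if ("blank" %in% names(tab)) tab$blank else 0
  wells <- setdiff(names(tab)[-1], "blank")
  setNames(lapply(wells, function(w)
    melt_curve(tab[[1]], tab[[w]] - blank,
               background_subtracted = "blank" %in% names(tab))), wells)
}

#' Fit the Boltzmann sigmoid to a melt curve
#'
#' Least-squares fit of
#' `F(T) = f_min + (f_max - f_min)/(1 + exp((Tm - T)/slope))`; `Tm` is the
#' inflection (50% unfolded). Because dye-based melts decay after the
#' unfolding transition, the fit window is truncated at the fluorescence
#' maximum by default.
#'
#' @param curve a [melt_curve()].
#' @param truncate_at_max restrict the fit to the rising transition window
#'   (up to the global fluorescence maximum).
#' @return list of class `tm_result` with `Tm`, `slope`, `f_min`, `f_max`,
#'   standard errors `se`, `converged`, `window` (temperature range used).
#' @export
fit_boltzmann <- function(curve, truncate_at_max = TRUE) {
  TT <- curve$T; FF <- curve$F
  if (truncate_at_max) {
    cut <- which.max(FF)
    if (cut < 4) stop("degenerate melt: fluorescence maximum at curve start")
    TT <- TT[1:cut]; FF <- FF[1:cut]
  }
  if (diff(range(FF)) < 1e-9) stop("degenerate melt: flat data")
  half <- (min(FF) + max(FF)) / 2
  tm0 <- TT[which.min(abs(FF - half))]
  dat <- data.frame(T = TT, F = FF)
  best <- NULL
  for (s0 in unique(c(1, 2, 0.5))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        F ~ fmin + (fmax - fmin) / (1 + exp((Tm - T) / slope)), data = dat,
        start = list(fmin = min(FF), fmax = max(FF), Tm = tm0, slope = s0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("melt fit did not converge")
  cf <- coef(best$fit)
  if (cf["fmax"] <= cf["fmin"] || cf["slope"] <= 0)
    stop("degenerate melt: no rising sigmoidal transition")
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(cf)))
  structure(list(Tm = unname(cf["Tm"]), slope = unname(cf["slope"]),
                 f_min = unname(cf["fmin"]), f_max = unname(cf["fmax"]),
                 se = se, converged = TRUE, window = range(TT)),
            class = "tm_result")
}

#' Melting-temperature shift relative to a reference complex
#' @param sample,reference `tm_result` objects (both converged).
#' @return `sample$Tm - reference$Tm` in degrees C.
#' @export
delta_tm <- function(sample, reference) {
  if (!isTRUE(sample$converged) || !isTRUE(reference$converged))
    stop("delta Tm requires two converged fits")
  sample$Tm - reference$Tm
}
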