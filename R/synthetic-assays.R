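# Synthetic assay curves generated from the fitted models themselves, with
# homoscedastic Gaussian noise, for parameter-recovery validation.

#' Specification for a synthetic FP competition experiment
#'
#' Defaults mirror the study conditions for the higher-affinity receptor:
#' 10 nM probe at its 10 nM Kd, competitor doses `2e-11 ... 2e-4` M in
#' tenfold steps (eight doses spanning the transition), four replicate
#' wells, noise 2% of the dynamic range.
#'
#' @param true_Ki true inhibition constant (molar).
#' @param probe_conc_nM,probe_Kd_nM probe concentration and Kd (nM).
#' @param top,bottom asymptotes of the displacement curve (mP).
#' @param conc_M dose grid (molar).
#' @param n_replicates replicate wells per dose.
#' @param noise_sd Gaussian noise SD (mP).
#' @param seed integer RNG seed.
#' @return list of class `competition_spec`.
#' @export
competition_spec <- function(true_Ki = 0.4e-6, probe_conc_nM = 10,
                             probe_Kd_nM = 10, top = 200, bottom = 50,
                             conc_M = 2 * 10^seq(-11, -4), n_replicates = 4,
                             noise_sd = 3, seed = 1) {
  stopifnot(true_Ki > 0, probe_conc_nM > 0, probe_Kd_nM > 0, top > bottom,
            all(conc_M > 0), n_replicates >= 1, noise_sd >= 0)
  structure(list(true_Ki = true_Ki, probe_conc_nM = probe_conc_nM,
                 probe_Kd_nM = probe_Kd_nM, top = top, bottom = bottom,
                 conc_M = conc_M, n_replicates = n_replicates,
                 noise_sd = noise_sd, seed = seed),
            class = "competition_spec")
}

#' Generate a synthetic FP competition dataset
#'
#' The noiseless curve follows the one-site displacement model with its
#' midpoint derived from `true_Ki` through the probe correction
#' ([logki_to_logec50()]); Gaussian noise is added per replicate well.
#' Deterministic given the seed.
#'
#' @param spec a [competition_spec()].
#' @return A [competition_dataset()]; the noiseless curve is attached as
#'   attribute `"truth"`.
#' @export
make_competition_dataset <- function(spec = competition_spec()) {
  stopifnot(inherits(spec, "competition_spec"))
  set.seed(spec$seed)
  X <- log10(spec$conc_M)
  logEC50 <- logki_to_logec50(log10(spec$true_Ki), spec$probe_conc_nM,
                              spec$probe_Kd_nM)
  y0 <- .eq1(X, spec$top, spec$bottom, logEC50)
  Y <- matrix(rep(y0, spec$n_replicates), ncol = spec$n_replicates) +
    matrix(rnorm(length(y0) * spec$n_replicates, sd = spec$noise_sd),
           ncol = spec$n_replicates)
  ds <- competition_dataset(spec$conc_M, Y, spec$probe_conc_nM,
                            spec$probe_Kd_nM,
                            label = sprintf("synthetic Ki=%.3g M", spec$true_Ki))
  attr(ds, "truth") <- list(LogEC50 = logEC50, y0 = y0,
                            logKi = log10(spec$true_Ki))
  ds
}

#' Specification for a synthetic thermal melt
#'
#' Defaults: a 55 degree C midpoint with a 1.5 degree transition width on
#' a 25-95 degree ramp read every 0.5 degrees (a 0.5 degree/min ramp with
#' one read per minute), no baseline drift, noise 2% of the fluorescence
#' range.
#'
#' @param true_Tm melting temperature (degrees C), inside the ramp.
#' @param slope transition width (degrees C, > 0).
#' @param f_min,f_max folded/unfolded fluorescence plateaus.
#' @param baseline_slopes length-2: linear drift added to the pre- and
#'   post-transition plateaus (fluorescence units per degree).
#' @param temp_C temperature grid (degrees C).
#' @param noise_sd Gaussian noise SD (fluorescence units).
#' @param seed integer RNG seed.
#' @return list of class `melt_spec`.
#' @export
melt_spec <- function(true_Tm = 55, slope = 1.5, f_min = 10, f_max = 100,
                      baseline_slopes = c(0, 0), temp_C = seq(25, 95, 0.5),
                      noise_sd = 1.8, seed = 1) {
  stopifnot(slope > 0, f_max > f_min, length(baseline_slopes) == 2,
            true_Tm > min(temp_C), true_Tm < max(temp_C), noise_sd >= 0)
  structure(list(true_Tm = true_Tm, slope = slope, f_min = f_min,
                 f_max = f_max, baseline_slopes = baseline_slopes,
                 temp_C = temp_C, noise_sd = noise_sd, seed = seed),
            class = "melt_spec")
}

#' Generate a synthetic melt curve
#'
#' `F(T) = f_min + (f_max - f_min)/(1 + exp((Tm - T)/slope))` plus linear
#' pre/post baselines blended by the same sigmoid, plus Gaussian noise.
#' Deterministic given the seed.
#'
#' @param spec a [melt_spec()].
#' @return A [melt_curve()]; the noiseless curve is attached as attribute
#'   `"truth"`.
#' @export
make_melt_curve <- function(spec = melt_spec()) {
  stopifnot(inherits(spec, "melt_spec"))
  set.seed(spec$seed)
  TT <- spec$temp_C
  frac <- 1 / (1 + exp((spec$true_Tm - TT) / spec$slope))
  base_pre <- spec$baseline_slopes[1] * (TT - TT[1])
  base_post <- spec$baseline_slopes[2] * (TT - TT[1])
  y0 <- spec$f_min + (spec$f_max - spec$f_min) * frac +
    (1 - frac) * base_pre + frac * base_post
  FF <- y0 + rnorm(length(TT), sd = spec$noise_sd)
  mc <- melt_curve(TT, FF)
  attr(mc, "truth") <- list(Tm = spec$true_Tm, y0 = y0)
  mc
}
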