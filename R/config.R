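# Declarative run-configuration validation for the analysis drivers. The
# drivers under analysis/ pass their parameter lists through here so every
# reported number is produced under a validated, echoed configuration.

#' Validate an analysis run configuration
#'
#' Collects all problems (not fail-fast) and either returns the validated
#' configuration with defaults filled in, or stops with the full error
#' list. Defaults are the study parameters: 4.5 A contact cutoff, 0.75
#' contact fraction, source residue 410, sink residue 534, 1000 suboptimal
#' paths.
#'
#' @param config named list (or path to a YAML file) with any of: `track`
#'   (`"ensemble"`, `"trajectory"`, `"assay"`, `"synth"`), `inputs`
#'   (character paths that must exist), `cutoff` (A), `fraction` (in
#'   `[0,1]`), `source`, `sink` (residue ids), `k` (>= 1), `seed`
#'   (integer), `out_dir`.
#' @return The validated config (invisibly carries class `run_config`), or
#'   an error listing every offending field.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list or a YAML path")
  defaults <- list(track = "synth", inputs = character(0), cutoff = 4.5,
                   fraction = 0.75, source = 410, sink = 534, k = 1000,
                   seed = 1L, out_dir = "results")
  cfg <- modifyList(defaults, config)
  errs <- character(0)
  bad <- function(msg) errs <<- c(errs, msg)
  if (!cfg$track %in% c("ensemble", "trajectory", "assay", "synth"))
    bad(sprintf("track: '%s' is not one of ensemble/trajectory/assay/synth", cfg$track))
  for (p in cfg$inputs)
    if (!file.exists(p)) bad(sprintf("inputs: file does not exist: %s", p))
  if (!is.numeric(cfg$cutoff) || cfg$cutoff <= 0)
    bad("cutoff: must be a positive distance in Angstrom")
  if (!is.numeric(cfg$fraction) || cfg$fraction < 0 || cfg$fraction > 1)
    bad(sprintf("fraction: %s is outside [0, 1]", format(cfg$fraction)))
  if (!is.numeric(cfg$k) || cfg$k < 1)
    bad("k: must be >= 1")
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    bad("seed: must be an integer")
  if (length(errs))
    stop("invalid run configuration:\n  - ", paste(errs, collapse = "\n  - "))
  class(cfg) <- "run_config"
  cfg
}
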