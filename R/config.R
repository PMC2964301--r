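#' Analysis configuration
#'
#' Bundles the analysis constants used across the pipeline: the
#' log-likelihood drop defining profile-likelihood intervals, the Fieller
#' confidence level, the critical shut time for burst segmentation, the
#' recording filter cutoff and imposed resolution, and the voltage
#' conventions for chord-conductance calculations.  Concentrations are
#' always in micromolar and log transforms are base 10.
#'
#' @param random_seed integer seed for the run's random stream.
#' @param holding_potential holding potential in mV (single-channel and
#'   whole-cell recordings; default -100 mV as used for outside-out patches).
#' @param reversal_potential assumed reversal potential in mV (default 0,
#'   with no junction-potential correction).
#' @param likelihood_delta log-likelihood drop defining the profile interval
#'   (default 2.01 units, equivalent to about +/- 2 SD for a Gaussian
#'   parameter).
#' @param fieller_confidence confidence level for Fieller ratio intervals,
#'   a fraction in (0, 1) (default 0.95).
#' @param tcrit critical shut time in ms separating bursts (default 5).
#' @param filter_cutoff low-pass filter cutoff in kHz (default 1).
#' @param resolution imposed event resolution in microseconds (default 100).
#'
#' @return An object of class `analysis_config` (a named list).
#' @examples
#' cfg <- analysis_config(random_seed = 1)
#' cfg$likelihood_delta
#' @export
analysis_config <- function(random_seed = 1L,
                            holding_potential = -100,
                            reversal_potential = 0,
                            likelihood_delta = 2.01,
                            fieller_confidence = 0.95,
                            tcrit = 5,
                            filter_cutoff = 1,
                            resolution = 100) {
  stopifnot(likelihood_delta > 0,
            fieller_confidence > 0, fieller_confidence < 1,
            tcrit > 0, resolution > 0, filter_cutoff > 0)
  structure(list(
    random_seed        = as.integer(random_seed),
    concentration_unit = "uM",
    holding_potential  = holding_potential,
    reversal_potential = reversal_potential,
    likelihood_delta   = likelihood_delta,
    fieller_confidence = fieller_confidence,
    tcrit              = tcrit,
    filter_cutoff      = filter_cutoff,
    resolution         = resolution
  ), class = "analysis_config")
}

#' Read / write an analysis configuration
#'
#' The configuration file is a flat `key: value` YAML document mirroring
#' the fields of [analysis_config()].
#'
#' @param path file path.
#' @return `read_config()` returns an `analysis_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(analysis_config)))
  do.call(analysis_config, vals[keep])
}

#' @rdname read_config
#' @param config an `analysis_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  out <- config[names(config) != "concentration_unit"]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration (concentrations in uM, logs base 10)\n")
  for (nm in setdiff(names(x), "concentration_unit")) {
    cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
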