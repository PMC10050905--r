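#' Analysis configuration
#'
#' Bundles every tunable parameter of the pipeline with its standard
#' value.  All downstream functions take their parameters from this
#' object, so a single configuration documents an analysis completely.
#'
#' @param max_width_h,max_width_c Search half-widths around the library
#'   shifts, ppm (defaults 0.15 and 3.0).
#' @param min_corr Minimum 1H-localisation correlation below which a
#'   latent component is discarded (default 0.8).
#' @param retention_fraction Peak-retention fraction for
#'   [filter_peaks()] (default 0.5).
#' @param trust_thresholds `(high, low)` percent thresholds for
#'   [classify_trust()] (defaults 80 and 70).
#' @param linewidth_c Simulated 13C Lorentzian FWHM, Hz (default 1.5).
#' @param epsilon Guard of the [adjusted_score()] denominator, ppm^2
#'   (default 1e-4).
#' @param fit_margin Margin in ppm added on each side of the assigned
#'   multiplet's stick extent when quantifying and scoring the fit
#'   (default 0.2).  The quality score thus measures how well the model
#'   explains the multiplet region, not how empty the search window is.
#' @param gamma_ratio 1H/13C gyromagnetic-ratio quotient used in
#'   [delta_ppm()].
#' @param j_scaling `"auto"` to detect the apparent-J scaling from the
#'   data, or one of 1, 2, 4, 8.
#' @param seed Seed for the ICA initial rotation.
#' @param variance_threshold,max_components Explained-variance threshold
#'   and cap for [choose_n_components()].
#' @param max_centre_candidates Cross-correlation candidates evaluated
#'   per subset during [align_multiplet()].
#' @param include_long_range Treat long-range couplings as splitting
#'   partners (default `FALSE`).
#' @param library_path Resonance library file.
#' @param metabolites Character vector of metabolites to analyse.
#' @param report Report format(s): `"json"`, `"md"` or `"both"`.
#' @param extra Named list echoed verbatim into report metadata (free
#'   user parameters; never interpreted).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(max_width_h = 0.15, max_width_c = 3.0,
                            min_corr = 0.8, retention_fraction = 0.5,
                            trust_thresholds = c(80, 70),
                            linewidth_c = 1.5, epsilon = 1e-4,
                            fit_margin = 0.2,
                            gamma_ratio = gamma_ratio_hc(),
                            j_scaling = "auto", seed = 0L,
                            variance_threshold = 0.995,
                            max_components = 10L,
                            max_centre_candidates = 8L,
                            include_long_range = FALSE,
                            library_path = default_library_path(),
                            metabolites = character(),
                            report = "json",
                            extra = list()) {
  stopifnot(max_width_h > 0, max_width_c > 0,
            min_corr > 0, min_corr < 1,
            retention_fraction > 0, retention_fraction < 1,
            length(trust_thresholds) == 2L,
            trust_thresholds[1] > trust_thresholds[2],
            linewidth_c > 0, epsilon > 0, fit_margin > 0, gamma_ratio > 0)
  if (!identical(j_scaling, "auto")) {
    j_scaling <- as.integer(j_scaling)
    if (is.na(j_scaling) || !(j_scaling %in% c(1L, 2L, 4L, 8L))) {
      stop("j_scaling must be \"auto\" or one of 1, 2, 4, 8", call. = FALSE)
    }
  }
  structure(list(max_width_h = max_width_h, max_width_c = max_width_c,
                 min_corr = min_corr,
                 retention_fraction = retention_fraction,
                 trust_thresholds = as.numeric(trust_thresholds),
                 linewidth_c = linewidth_c, epsilon = epsilon,
                 fit_margin = fit_margin,
                 gamma_ratio = gamma_ratio, j_scaling = j_scaling,
                 j_scaling_value = if (identical(j_scaling, "auto")) 1L
                                   else j_scaling,
                 seed = as.integer(seed),
                 variance_threshold = variance_threshold,
                 max_components = as.integer(max_components),
                 max_centre_candidates = as.integer(max_centre_candidates),
                 include_long_range = include_long_range,
                 library_path = library_path,
                 metabolites = metabolites, report = report,
                 extra = extra),
            class = "analysis_config")
}

# Shallow-update a config (used to try alternative J scalings).
config_with <- function(config, ...) {
  upd <- list(...)
  for (nm in names(upd)) config[[nm]] <- upd[[nm]]
  config
}

#' Read an analysis configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [analysis_config()]; unknown keys are
#' collected into `extra` and echoed in reports.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(analysis_config))
  args <- vals[intersect(names(vals), known)]
  args$extra <- c(vals[setdiff(names(vals), known)],
                  if (!is.null(vals$extra)) vals$extra)
  do.call(analysis_config, args)
}
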