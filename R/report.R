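# End-to-end run and report generation (JSON primary, markdown for
# humans).

REPORT_SCHEMA_VERSION <- 1L

#' Run the full analysis for a configuration
#'
#' Reads the spectrum, loads the resonance library, resolves the
#' apparent-J scaling (detecting it from the data when the configuration
#' says `"auto"`), and analyses every configured metabolite.  Unknown
#' metabolites are reported with a warning; the remaining ones are still
#' processed.
#'
#' @param config An [analysis_config()] with a non-empty `metabolites`
#'   field.
#' @param spectrum Path of a spectrum file, or a [spectrum_grid()]
#'   directly.
#' @param format_hint Passed to [read_spectrum()] when `spectrum` is a
#'   path.
#' @return An object of class `analysis_run`: per-resonance results,
#'   the scaling used, skipped metabolites and the configuration echo.
#' @export
run_analysis <- function(config, spectrum, format_hint = "auto") {
  stopifnot(inherits(config, "analysis_config"))
  grid <- if (inherits(spectrum, "spectrum_grid")) spectrum
          else read_spectrum(spectrum, format_hint)
  library <- load_library(config$library_path)
  known <- unique(vapply(library$entries, function(e) e$metabolite, ""))
  wanted <- config$metabolites
  skipped <- wanted[!tolower(wanted) %in% tolower(known)]
  for (m in skipped) warning("unknown metabolite '", m, "' skipped")
  wanted <- wanted[tolower(wanted) %in% tolower(known)]

  j_used <- if (identical(config$j_scaling, "auto")) {
    if (length(wanted)) {
      detect_j_scaling(grid, library, wanted, config = config)
    } else grid$j_scaling
  } else config$j_scaling
  config <- config_with(config, j_scaling_value = as.integer(j_used))

  results <- list()
  for (m in wanted) {
    results <- c(results, unclass(analyze_metabolite(grid, library, m,
                                                     config)))
  }
  structure(list(results = structure(results, class = "multiplet_results"),
                 j_scaling = as.integer(j_used), skipped = skipped,
                 config = config,
                 library_path = library$path,
                 spectrum_provenance = grid$provenance),
            class = "analysis_run")
}

#' @export
print.analysis_run <- function(x, ...) {
  cat(sprintf("<analysis_run> j_scaling %d, %d resonances\n", x$j_scaling,
              length(x$results)))
  print(x$results)
  invisible(x)
}

result_record <- function(r) {
  found <- isTRUE(r$found)
  list(metabolite = r$metabolite,
       moiety = r$moiety,
       found = found,
       trust = r$fit$trust,
       rho = r$fit$rho,
       x_h = if (found) r$assignment$x_h else NULL,
       x_c = if (found) r$assignment$x_c else NULL,
       delta_ppm = if (found) r$assignment$delta_ppm else NULL,
       correlation = if (found) NULL else NULL,
       source_component = if (found) r$assignment$source_component
                          else NULL,
       components = if (found && !is.null(r$fit$fractions)) {
         lapply(seq_along(r$fit$fractions), function(i) {
           list(label = names(r$fit$fractions)[i],
                percent = 100 * as.numeric(r$fit$fractions[i]))
         })
       } else list())
}

#' Write an analysis report
#'
#' The JSON report is the machine-readable record of a run: per
#' resonance the assigned shifts, the distance from the library shifts,
#' the percentage contribution of every multiplet component, the
#' coefficient of determination and the trust flag, plus the chosen
#' scaling, configuration echo and library provenance.  The markdown
#' report renders the same table for humans with the trust colour-coding
#' semantics spelled out.
#'
#' @param run An [run_analysis()] result.
#' @param path Output file path (for `"both"`, the markdown file gets
#'   the same path with extension `.md`).
#' @param format `"json"`, `"md"` or `"both"`.
#' @return Paths written, invisibly.
#' @export
write_report <- function(run, path, format = c("json", "md", "both")) {
  stopifnot(inherits(run, "analysis_run"))
  format <- match.arg(format)
  cfg <- run$config
  obj <- list(
    schema = "hsqcmult-report",
    schema_version = REPORT_SCHEMA_VERSION,
    j_scaling = run$j_scaling,
    library = run$library_path,
    spectrum = run$spectrum_provenance,
    skipped_metabolites = run$skipped,
    parameters = c(list(max_width_h = cfg$max_width_h,
                        max_width_c = cfg$max_width_c,
                        min_corr = cfg$min_corr,
                        retention_fraction = cfg$retention_fraction,
                        trust_thresholds = cfg$trust_thresholds,
                        linewidth_c = cfg$linewidth_c,
                        epsilon = cfg$epsilon,
                        j_scaling = cfg$j_scaling,
                        seed = cfg$seed),
                   cfg$extra),
    resonances = lapply(run$results, result_record))
  paths <- character()
  if (format %in% c("json", "both")) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    paths <- c(paths, path)
  }
  if (format %in% c("md", "both")) {
    md_path <- if (format == "md") path
               else sub("\\.[A-Za-z0-9]+$", ".md", path)
    writeLines(render_markdown_report(obj), md_path)
    paths <- c(paths, md_path)
  }
  invisible(paths)
}

render_markdown_report <- function(obj) {
  lines <- c("# HSQC multiplet analysis report", "",
             sprintf("Spectrum: %s  ", obj$spectrum),
             sprintf("Library: %s  ", obj$library),
             sprintf("Apparent-J scaling: %d", obj$j_scaling), "",
             "Trust colour coding: **green** = trustworthy (rho >= 80%),",
             "**orange** = borderline (70% < rho < 80%),",
             "**red** = not trustworthy (rho <= 70%) or not found.", "",
             "| metabolite | moiety | 1H (ppm) | 13C (ppm) | dppm | rho (%) | trust | components |",
             "|---|---|---|---|---|---|---|---|")
  for (r in obj$resonances) {
    comps <- if (length(r$components)) {
      paste(vapply(r$components,
                   function(cc) sprintf("%s %.1f%%", cc$label, cc$percent),
                   ""), collapse = ", ")
    } else "-"
    lines <- c(lines, if (isTRUE(r$found)) {
      sprintf("| %s | %s | %.4f | %.3f | %.4f | %.2f | %s | %s |",
              r$metabolite, r$moiety, r$x_h, r$x_c, r$delta_ppm, r$rho,
              r$trust, comps)
    } else {
      sprintf("| %s | %s | - | - | - | 0.00 | not_found | - |",
              r$metabolite, r$moiety)
    })
  }
  lines
}

#' Read back a JSON analysis report
#'
#' @param path Report file written by [write_report()].
#' @return The report as a list (schema-checked).
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "hsqcmult-report")) {
    stop("not an hsqcmult report: ", path, call. = FALSE)
  }
  obj
}
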