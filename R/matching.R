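# Multiplet identification and quantification: peak filtering, the
# shift-distance-adjusted matching score, combinatorial subset alignment,
# hill-climb 1H refinement, constrained regression and the
# coefficient-of-determination quality score.

#' Suppress minor peaks of a trace
#'
#' Local maxima below `retention_fraction` of the global maximum are
#' considered noise or foreign resonances: every point of such a peak
#' (between its surrounding minima) is set to zero, while retained peaks
#' are left untouched.  With the default fraction of 0.5 only signals
#' reaching half the strongest peak survive.
#'
#' @param trace Finite numeric trace.
#' @param retention_fraction Fraction of the global maximum below which a
#'   peak is suppressed; strictly between 0 and 1.
#' @return The filtered trace.
#' @export
filter_peaks <- function(trace, retention_fraction = 0.5) {
  stopifnot(all(is.finite(trace)),
            retention_fraction > 0, retention_fraction < 1)
  if (all(trace == 0)) return(trace)
  gmax <- max(trace)
  peaks <- local_maxima(trace)
  bad <- peaks[trace[peaks] < retention_fraction * gmax]
  if (length(bad) == 0L) return(trace)
  out <- trace
  n <- length(trace)
  for (p in bad) {
    l <- p
    while (l > 1L && trace[l - 1L] < trace[l]) l <- l - 1L
    r <- p
    while (r < n && trace[r + 1L] < trace[r]) r <- r + 1L
    out[l:r] <- 0
  }
  out
}

#' Coefficient of determination of a multiplet fit (percent)
#'
#' `100 * (SStot - SSres) / SStot`, where `SStot` is the total sum of
#' squares of the observed trace about its mean and `SSres` the residual
#' sum of squares against the fitted trace.  Values below 0 (fits worse
#' than the mean) clamp to 0; a constant observed trace is defined as 0
#' with a warning.
#'
#' @param t Observed trace.
#' @param t_hat Fitted trace of the same length.
#' @return Numeric scalar in `[0, 100]`.
#' @export
coefficient_of_determination <- function(t, t_hat) {
  stopifnot(length(t) == length(t_hat))
  tbar <- mean(t)
  sstot <- sum((t - tbar)^2)
  if (sstot == 0) {
    warning("constant observed trace; coefficient of determination set to 0")
    return(0)
  }
  ssres <- sum((t - t_hat)^2)
  min(100, max(0, 100 * (sstot - ssres) / sstot))
}

#' Weighted shift distance from the library position
#'
#' Euclidean distance in ppm between an assigned position and the library
#' position, with the 13C deviation divided by `Gamma_adjusted = 20 *
#' gamma_ratio` so that deviations in both dimensions are commensurate
#' (20 is the ratio of the standard 13C and 1H search half-widths,
#' 3.0 / 0.15; `gamma_ratio` the 1H/13C gyromagnetic-ratio quotient).
#'
#' @param x_h,x_c Assigned shifts, ppm.
#' @param x_hlib,x_clib Library shifts, ppm.
#' @param gamma_ratio Dimensionless 13C-axis compression factor divided
#'   by 20; defaults to [gamma_ratio_hc()].
#' @return Distance in ppm (1H-equivalent units), >= 0.
#' @export
delta_ppm <- function(x_h, x_c, x_hlib, x_clib,
                      gamma_ratio = gamma_ratio_hc()) {
  gamma_adj <- 20 * gamma_ratio
  sqrt((x_h - x_hlib)^2 + ((x_c - x_clib) / gamma_adj)^2)
}

#' Distance-adjusted matching score
#'
#' Ranks candidate (subset, position) pairs during matching: the fit
#' quality is divided by the squared distance from the library position,
#' so that among equally good fits the library-proximal one wins.  The
#' guard `epsilon` bounds the score as the distance approaches zero.
#' Used for ranking only, never reported as a quality value.
#'
#' @param rho Fit quality in percent (>= 0).
#' @param delta Distance from the library position ([delta_ppm()]), ppm.
#' @param epsilon Guard in ppm^2 (default 1e-4).
#' @return `rho / (epsilon + delta^2)`.
#' @export
adjusted_score <- function(rho, delta, epsilon = 1e-4) {
  stopifnot(rho >= 0, delta >= 0, epsilon > 0)
  rho / (epsilon + delta^2)
}

#' Classify the trust level of a fit
#'
#' @param rho Coefficient of determination, percent, in `[0, 100]`.
#' @param thresholds Numeric `(high, low)`; `rho >= high` is trustworthy,
#'   `rho <= low` not trustworthy, values strictly between are
#'   borderline.  Defaults `(80, 70)`.
#' @return One of `"trustworthy"`, `"borderline"`, `"not_trustworthy"`.
#' @export
classify_trust <- function(rho, thresholds = c(80, 70)) {
  stopifnot(rho >= 0, rho <= 100, thresholds[1] > thresholds[2])
  if (rho >= thresholds[1]) "trustworthy"
  else if (rho > thresholds[2]) "borderline"
  else "not_trustworthy"
}

#' Quantify multiplet component fractions by non-negative least squares
#'
#' Solves `min || column - X B ||^2` with `B >= 0`, where the columns of
#' `X` are unit-area simulated component traces, then normalises `B` to
#' relative contributions summing to 1.  The coefficient of determination
#' of the fitted trace gives the quality score, and the trust flag
#' follows from the configured thresholds.  When nothing fits (`sum(B) =
#' 0`) the resonance is reported as not found with a score of 0.
#'
#' @param column Experimental 1D 13C trace.
#' @param design List of simulated components (with traces) or a numeric
#'   matrix whose columns are the component traces.
#' @param thresholds Trust thresholds passed to [classify_trust()].
#' @return An object of class `multiplet_fit` with fields `fractions`
#'   (named, sum 1, or `NULL` when not found), `amplitudes` (raw
#'   nonnegative coefficients), `rho` (percent), `trust`, `fitted_trace`
#'   and `residual_trace`.
#' @export
fit_fractions <- function(column, design, thresholds = c(80, 70)) {
  if (is.list(design) && !is.matrix(design)) {
    labels <- vapply(design, function(d) d$label, "")
    design <- vapply(design, function(d) d$trace, numeric(length(column)))
  } else {
    design <- as.matrix(design)
    labels <- colnames(design)
    if (is.null(labels)) labels <- paste0("component", seq_len(ncol(design)))
  }
  stopifnot(nrow(design) == length(column), ncol(design) >= 1L)
  b <- nnls_solve(design, column)
  fitted <- as.numeric(design %*% b)
  if (sum(b) <= 0) {
    return(structure(list(fractions = NULL, amplitudes = stats::setNames(b, labels),
                          rho = 0, trust = "not_found",
                          fitted_trace = fitted,
                          residual_trace = as.numeric(column) - fitted),
                     class = "multiplet_fit"))
  }
  fractions <- stats::setNames(b / sum(b), labels)
  rho <- coefficient_of_determination(column, fitted)
  structure(list(fractions = fractions,
                 amplitudes = stats::setNames(b, labels),
                 rho = rho, trust = classify_trust(rho, thresholds),
                 fitted_trace = fitted,
                 residual_trace = as.numeric(column) - fitted),
            class = "multiplet_fit")
}

#' @export
print.multiplet_fit <- function(x, ...) {
  cat(sprintf("<multiplet_fit> rho %.2f%%  trust: %s\n", x$rho, x$trust))
  if (!is.null(x$fractions)) {
    for (i in seq_along(x$fractions)) {
      cat(sprintf("  %-12s %6.2f%%\n", names(x$fractions)[i],
                  100 * x$fractions[i]))
    }
  }
  invisible(x)
}

# NNLS fit + coefficient of determination of `target` on design matrix.
nnls_rho <- function(target, design) {
  b <- nnls_solve(design, target)
  fitted <- as.numeric(design %*% b)
  if (sum(b) <= 0) return(list(rho = 0, b = b, fitted = fitted))
  list(rho = suppressWarnings(coefficient_of_determination(target, fitted)),
       b = b, fitted = fitted)
}

simulate_design <- function(components, subset, center_c, axis_c,
                            lineshape, freq_c, j_scaling) {
  vapply(subset, function(k) {
    simulate_component(components[[k]], center_c, axis_c, lineshape,
                       freq_c, j_scaling)$trace
  }, numeric(length(axis_c)))
}

#' Identify the multiplet captured by a latent component
#'
#' Peak-filters the (nonnegative part of the) latent component, then
#' searches over every candidate subset of the resonance's multiplet
#' components and over candidate 13C centre positions on the region's
#' grid.  Candidate centres per subset are found by cross-correlating the
#' equal-intensity subset simulation with the filtered trace (the library
#' centre is always also a candidate); at each candidate the component is
#' regressed on the subset's individual traces under a nonnegativity
#' constraint, the coefficient of determination is computed and weighted
#' by the squared library-shift distance ([adjusted_score()]).  The
#' arg-max assignment wins, with ties broken toward smaller distance and
#' then smaller subsets; the winning centre is finally refined
#' continuously within one grid step.
#'
#' @param component A localised `latent_component`.
#' @param entry The sought [resonance_entry()].
#' @param region The search region the component came from.
#' @param config An [analysis_config()].
#' @return An object of class `multiplet_assignment`, or `NULL` when no
#'   subset achieves a positive coefficient of determination.
#' @export
align_multiplet <- function(component, entry, region,
                            config = analysis_config()) {
  stopifnot(inherits(component, "latent_component"),
            inherits(entry, "resonance_entry"),
            inherits(region, "spectrum_region"))
  if (is.na(component$assigned_h_ppm)) {
    stop("component must be localised before matching", call. = FALSE)
  }
  ax_c <- region$subgrid$axis_c
  nT <- length(ax_c)
  freq_c <- region$subgrid$freq_c
  lineshape <- lineshape_params(config$linewidth_c)
  j_scaling <- config$j_scaling_value
  target <- pmax(component$trace, 0)
  filtered <- filter_peaks(target, config$retention_fraction)
  if (max(filtered) <= 0) return(NULL)

  comps <- enumerate_components(entry, config$include_long_range)
  m <- (nT + 1L) %/% 2L
  sim_ref <- lapply(comps, simulate_component, center_c = ax_c[m],
                    axis_c = ax_c, lineshape = lineshape, freq_c = freq_c,
                    j_scaling = j_scaling)
  subsets <- enumerate_subsets(comps)
  lib_ci <- nearest_index(ax_c, entry$delta_c_lib)

  best <- NULL
  for (si in seq_along(subsets)) {
    sub <- subsets[[si]]
    eq <- equal_intensity_multiplet(sim_ref, sub)
    r <- cross_corr_shifts(filtered, eq)
    shifts <- (1L - m):(nT - m)
    dots <- r[shifts + nT]
    lm <- local_maxima(dots)
    lm <- lm[dots[lm] > 0]
    lm <- lm[order(-dots[lm])]
    # dots[i] is the correlation with the subset simulation centred at
    # axis index i (shift s = i - m applied to the reference simulation)
    cand <- unique(c(lm[seq_len(min(length(lm),
                                    config$max_centre_candidates))],
                     lib_ci))
    cand <- cand[cand >= 1L & cand <= nT]
    for (ci in cand) {
      design <- simulate_design(comps, sub, ax_c[ci], ax_c, lineshape,
                                freq_c, j_scaling)
      fit <- nnls_rho(target, design)
      if (fit$rho <= 0) next
      dpp <- delta_ppm(component$assigned_h_ppm, ax_c[ci],
                       entry$delta_h_lib, entry$delta_c_lib,
                       config$gamma_ratio)
      sc <- adjusted_score(fit$rho, dpp, config$epsilon)
      if (is.null(best) ||
          sc > best$score * (1 + 1e-9) ||
          (abs(sc - best$score) <= best$score * 1e-9 &&
           (dpp < best$dpp - 1e-12 ||
            (abs(dpp - best$dpp) <= 1e-12 && length(sub) < length(best$sub))))) {
        best <- list(score = sc, rho = fit$rho, dpp = dpp, sub = sub,
                     ci = ci, subset_index = si)
      }
    }
  }
  if (is.null(best)) return(NULL)

  # Continuous refinement of the 13C centre within one grid step: data
  # resolution limits the coarse search, but the Lorentzian model is
  # continuous in the centre position.
  step <- abs(axis_step(ax_c))
  obj <- function(cc) {
    nnls_rho(target, simulate_design(comps, best$sub, cc, ax_c,
                                     lineshape, freq_c, j_scaling))$rho
  }
  lo <- max(min(ax_c), ax_c[best$ci] - step)
  hi <- min(max(ax_c), ax_c[best$ci] + step)
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = step * 1e-4)
  x_c <- if (opt$objective > best$rho) opt$maximum else ax_c[best$ci]
  rho <- max(opt$objective, best$rho)
  dpp <- delta_ppm(component$assigned_h_ppm, x_c, entry$delta_h_lib,
                   entry$delta_c_lib, config$gamma_ratio)
  structure(list(entry = entry,
                 x_h = component$assigned_h_ppm, x_c = x_c,
                 delta_ppm = dpp,
                 best_subset = best$sub,
                 subset_labels = vapply(comps[best$sub],
                                        function(cc) cc$label, ""),
                 rho_ident = rho,
                 rho_adjusted = adjusted_score(rho, dpp, config$epsilon),
                 source_component = component$index),
            class = "multiplet_assignment")
}

#' @export
print.multiplet_assignment <- function(x, ...) {
  cat(sprintf(
    "<multiplet_assignment> %s %s at 1H %.4f / 13C %.3f ppm\n  subset {%s}  rho %.2f%%  dppm %.4f  (component #%d)\n",
    x$entry$metabolite, x$entry$moiety, x$x_h, x$x_c,
    paste(x$subset_labels, collapse = ", "), x$rho_ident, x$delta_ppm,
    x$source_component))
  invisible(x)
}

#' Refine the 1H position by hill climbing
#'
#' Starting from the assigned 1H column, moves one column at a time in
#' the direction that increases the coefficient of determination of the
#' nonnegative fit of that column against the design traces, and stops
#' when neither neighbour improves.  Deterministic; never returns a
#' column with a lower score than its start.
#'
#' @param region The search region.
#' @param assignment A `multiplet_assignment` (supplies the start
#'   position).
#' @param design Numeric matrix of component traces (columns =
#'   components) over the region's 13C axis, or over the subset of axis
#'   rows given by `rows`.
#' @param rows Optional integer indices restricting the fit to part of
#'   the 13C axis (the multiplet extent); `NULL` uses all rows.
#' @return List with `x_h` (refined 1H ppm), `column` (its index) and
#'   `rho` (the score at the refined column).
#' @export
refine_proton_shift <- function(region, assignment, design, rows = NULL) {
  stopifnot(inherits(region, "spectrum_region"),
            inherits(assignment, "multiplet_assignment"))
  x <- region$subgrid$intensities
  if (!is.null(rows)) x <- x[rows, , drop = FALSE]
  ax_h <- region$subgrid$axis_h
  design <- as.matrix(design)
  stopifnot(nrow(design) == nrow(x))
  rho_at <- local({
    cache <- rep(NA_real_, ncol(x))
    function(j) {
      if (is.na(cache[j])) cache[j] <<- nnls_rho(x[, j], design)$rho
      cache[j]
    }
  })
  j <- nearest_index(ax_h, assignment$x_h)
  repeat {
    cur <- rho_at(j)
    nb <- c(if (j > 1L) j - 1L, if (j < ncol(x)) j + 1L)
    vals <- vapply(nb, rho_at, 0)
    if (length(nb) == 0L || max(vals) <= cur) break
    j <- nb[which.max(vals)]
  }
  list(x_h = ax_h[j], column = j, rho = rho_at(j))
}
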