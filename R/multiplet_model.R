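# First-order 13C multiplet model: isotopomer component enumeration,
# stick patterns with apparent-J scaling, Lorentzian trace simulation and
# the subset combinatorics used during matching.

#' Lineshape parameters for 13C trace simulation
#'
#' @param linewidth_c Full width at half maximum of the 13C Lorentzian in
#'   Hz (> 0).  The default of 1.5 Hz is typical of well-shimmed aqueous
#'   metabolite extracts after processing.
#' @return An object of class `lineshape_params`.
#' @export
lineshape_params <- function(linewidth_c = 1.5) {
  if (!(is.numeric(linewidth_c) && linewidth_c > 0)) {
    stop("linewidth_c must be > 0", call. = FALSE)
  }
  structure(list(linewidth_c = as.numeric(linewidth_c)),
            class = "lineshape_params")
}

#' Enumerate the isotopomer multiplet components of a resonance
#'
#' Each subset of the carbon's one-bond coupling partners that is
#' 13C-labelled gives one multiplet component: the empty set is the
#' singlet, one labelled partner a doublet, two a doublet of doublets,
#' and so on; `n` one-bond couplings yield `2^n` components.  Long-range
#' couplings are excluded by default because their splittings are not
#' resolved at typical 13C digital resolution.
#'
#' @param entry A [resonance_entry()].
#' @param include_long_range Also treat long-range couplings as splitting
#'   partners (default `FALSE`).
#' @return List of component descriptors (class `multiplet_component`),
#'   ordered by subset size then lexically by partner labels.  Each has
#'   `isotopomer` (character vector of labelled partners), `j` (their
#'   coupling constants, Hz) and a display `label` such as `"s"`,
#'   `"d(C3)"` or `"dd(C1,C3)"`.
#' @export
enumerate_components <- function(entry, include_long_range = FALSE) {
  stopifnot(inherits(entry, "resonance_entry"))
  cpl <- entry$couplings
  if (!include_long_range && nrow(cpl)) cpl <- cpl[cpl$one_bond, , drop = FALSE]
  partners <- cpl$partner
  jvals <- cpl$j
  n <- length(partners)
  subsets <- list(integer(0))
  if (n > 0L) {
    for (q in seq_len(n)) {
      cmb <- utils::combn(seq_len(n), q, simplify = FALSE)
      # lexical order by partner labels within each size
      key <- vapply(cmb, function(ix) paste(sort(partners[ix]),
                                            collapse = ","), "")
      subsets <- c(subsets, cmb[order(key)])
    }
  }
  mult_name <- c("s", "d", "dd", "ddd", "dddd")
  lapply(subsets, function(ix) {
    lab <- if (length(ix) == 0L) "s" else {
      nm <- if (length(ix) < length(mult_name)) mult_name[length(ix) + 1L]
            else paste0("m", length(ix))
      paste0(nm, "(", paste(partners[ix], collapse = ","), ")")
    }
    structure(list(isotopomer = partners[ix], j = jvals[ix], label = lab),
              class = "multiplet_component")
  })
}

#' Stick pattern of one multiplet component
#'
#' First-order (weak-coupling) line positions: every sign combination of
#' `+/- j_scaling * J_k / 2` over the component's couplings.  The pattern
#' is symmetric about the multiplet centre and doubling the apparent-J
#' scaling doubles every offset; a singlet (no couplings) is a single
#' stick at 0 Hz for any scaling.
#'
#' @param component A component from [enumerate_components()], or a bare
#'   numeric vector of coupling constants in Hz.
#' @param j_scaling Apparent-J scaling factor (integer >= 1).
#' @return Sorted numeric vector of `2^q` frequency offsets from the
#'   multiplet centre, in Hz.
#' @export
stick_pattern <- function(component, j_scaling = 1L) {
  stopifnot(j_scaling >= 1)
  j <- if (inherits(component, "multiplet_component")) component$j
       else as.numeric(component)
  if (length(j) == 0L) return(0)
  signs <- as.matrix(do.call(expand.grid, rep(list(c(-1, 1)), length(j))))
  sort(as.numeric(signs %*% (j_scaling * j / 2)))
}

lorentzian <- function(x, fwhm) {
  hw <- fwhm / 2
  (hw / pi) / (x^2 + hw^2)
}

#' Simulate the 1D 13C trace of a multiplet component
#'
#' Places one Lorentzian of equal weight at each stick position (offsets
#' converted from Hz to ppm by the 13C carrier frequency) around
#' `center_c` and normalises the discretised trace to unit area, so that
#' regression coefficients against these traces are proportional to
#' signal integrals rather than peak heights.
#'
#' @param component A component descriptor from [enumerate_components()].
#' @param center_c Multiplet centre, ppm.
#' @param axis_c 13C ppm axis (uniform) on which to evaluate the trace.
#' @param lineshape A [lineshape_params()].
#' @param freq_c 13C carrier frequency, MHz.
#' @param j_scaling Apparent-J scaling factor.
#' @return The component with fields `sticks` (Hz offsets) and `trace`
#'   (nonnegative, unit-area over `axis_c`) added.
#' @export
simulate_component <- function(component, center_c, axis_c,
                               lineshape = lineshape_params(),
                               freq_c, j_scaling = 1L) {
  stopifnot(inherits(lineshape, "lineshape_params"), freq_c > 0)
  sticks <- stick_pattern(component, j_scaling)
  pos <- center_c + sticks / freq_c
  fwhm_ppm <- lineshape$linewidth_c / freq_c
  lo <- min(axis_c); hi <- max(axis_c)
  if (all(pos < lo - fwhm_ppm | pos > hi + fwhm_ppm)) {
    warning("all multiplet sticks fall outside the 13C axis; trace truncated")
  }
  trace <- rep(0, length(axis_c))
  for (p in pos) trace <- trace + lorentzian(axis_c - p, fwhm_ppm)
  step <- abs(axis_step(axis_c))
  area <- sum(trace) * step
  if (area > 0) trace <- trace / area
  component$sticks <- sticks
  component$trace <- trace
  component$center_c <- center_c
  component
}

#' Enumerate candidate component subsets for matching
#'
#' All non-empty subsets of the multiplet components with sizes in
#' `q_range`, in deterministic order (by size, then by member order).
#' Choosing `q` of `p` components gives `choose(p, q)` subsets; the
#' default `q_range` covers all sizes, i.e. `2^p - 1` subsets.
#'
#' @param components List from [enumerate_components()].
#' @param q_range Integer vector of subset sizes to include.
#' @return List of integer index vectors into `components`.
#' @export
enumerate_subsets <- function(components, q_range = seq_along(components)) {
  p <- length(components)
  stopifnot(p >= 1L)
  q_range <- intersect(as.integer(q_range), seq_len(p))
  out <- list()
  for (q in sort(q_range)) {
    out <- c(out, utils::combn(seq_len(p), q, simplify = FALSE))
  }
  out
}

#' Equal-intensity multiplet trace of a component subset
#'
#' The matching stage assumes equal intensities for the multiplet
#' components of a candidate subset: the subset trace is the unweighted
#' mean of the member traces, renormalised to unit area.
#'
#' @param components List of simulated components (with `trace`), as from
#'   [simulate_component()].
#' @param subset Integer indices of the subset members (default: all).
#' @return Numeric unit-area trace over the members' common axis.
#' @export
equal_intensity_multiplet <- function(components, subset = seq_along(components)) {
  stopifnot(length(subset) >= 1L)
  subset <- sort(subset)
  traces <- lapply(components[subset], function(cc) {
    if (is.null(cc$trace)) stop("components must be simulated first",
                                call. = FALSE)
    cc$trace
  })
  tr <- Reduce(`+`, traces) / length(traces)
  s <- sum(tr)
  # renormalise against truncation: target the members' mean discrete sum
  target <- mean(vapply(traces, sum, 0))
  if (s > 0 && abs(s - target) > 1e-12 * target) tr <- tr / s * target
  tr
}
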