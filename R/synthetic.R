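# Synthetic 2D-HSQC spectra with known ground truth: linear superposition
# of first-order 13C multiplets (Lorentzian 13C lineshape, Gaussian 1H
# profile), isotopomer mixing fractions, shift perturbations emulating
# pH/matrix effects, additive Gaussian noise and apparent-J scaling.

draw_perturbation <- function(range) {
  if (length(range) == 1L) return(as.numeric(range))
  stats::runif(1L, min(range), max(range))
}

default_axes_for <- function(entries, step_h, step_c) {
  dh <- vapply(entries, function(e) e$delta_h_lib, 0)
  dc <- vapply(entries, function(e) e$delta_c_lib, 0)
  list(h = seq(max(dh) + 0.3, min(dh) - 0.3, by = -step_h),
       c = seq(max(dc) + 4.0, min(dc) - 4.0, by = -step_c))
}

#' Generate a synthetic 2D-HSQC spectrum with ground truth
#'
#' Each resonance entry contributes one 2D peak at its perturbed (1H,
#' 13C) position: the outer product of a Gaussian 1H profile and the
#' fraction-weighted sum of its simulated multiplet component traces.
#' I.i.d. Gaussian noise is added at the requested signal-to-noise ratio
#' (maximum signal over noise standard deviation).  Everything random
#' (perturbations, fractions when not given, noise) is reproducible from
#' `seed`.
#'
#' @param entries A [resonance_entry()] or list of them.
#' @param fractions List of fraction vectors (one per entry, each over
#'   the entry's [enumerate_components()] order, summing to 1), or
#'   `NULL` to draw uniformly from the simplex.
#' @param perturb_h,perturb_c Shift perturbations in ppm: a single number
#'   applies as-is, a length-2 range is sampled uniformly per entry.
#' @param snr Max-signal-to-noise-sigma ratio; `Inf` for noiseless.
#' @param lineshape 13C [lineshape_params()].
#' @param axes List with ppm axis vectors `h` and `c`; `NULL` builds
#'   descending axes covering all entries with steps `step_h`/`step_c`.
#' @param step_h,step_c Axis steps in ppm used when `axes` is `NULL`;
#'   the defaults reproduce a 15.6 ppm / 1024-point 1H and a 189.8 ppm /
#'   8192-point 13C digitisation, typical of ultra-high-resolution HSQC
#'   acquisitions of metabolite extracts.
#' @param freq_h,freq_c Carrier frequencies, MHz.
#' @param j_scaling Apparent-J scaling applied to the simulated
#'   splittings (recorded in the grid metadata).
#' @param h_fwhm Full width at half maximum of the Gaussian 1H profile,
#'   ppm.
#' @param amplitudes Per-entry overall peak amplitudes (default 1).
#' @param n_spurious Number of weak spurious peaks (amplitude 2-4 noise
#'   sigma) emulating reconstruction artefacts; 0 by default.
#' @param seed Integer seed.
#' @return List with `grid` (a [spectrum_grid()]) and `truth` (class
#'   `ground_truth`): per-entry table of true shifts and perturbations,
#'   the fraction vectors, the noise sigma, SNR, scaling and seed.
#' @export
generate_spectrum <- function(entries, fractions = NULL,
                              perturb_h = c(-0.05, 0.05),
                              perturb_c = c(-0.5, 0.5),
                              snr = 20,
                              lineshape = lineshape_params(3),
                              axes = NULL, step_h = 15.6 / 1024, step_c = 189.8 / 8192,
                              freq_h = 600.13, freq_c = 150.903,
                              j_scaling = 1L, h_fwhm = 0.02,
                              amplitudes = NULL, n_spurious = 0L,
                              seed = 1L) {
  if (inherits(entries, "resonance_entry")) entries <- list(entries)
  stopifnot(length(entries) >= 1L, snr > 0)
  set.seed(seed)
  if (is.null(axes)) axes <- default_axes_for(entries, step_h, step_c)
  axis_h <- axes$h
  axis_c <- axes$c
  if (is.null(amplitudes)) amplitudes <- rep(1, length(entries))
  signal <- matrix(0, nrow = length(axis_c), ncol = length(axis_h))
  rows <- vector("list", length(entries))
  used_fractions <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    comps <- enumerate_components(e)
    f <- if (is.null(fractions) || is.null(fractions[[i]])) {
      w <- stats::rexp(length(comps))
      w / sum(w)
    } else {
      stopifnot(length(fractions[[i]]) == length(comps),
                all(fractions[[i]] >= 0))
      fractions[[i]] / sum(fractions[[i]])
    }
    ph <- draw_perturbation(perturb_h)
    pc <- draw_perturbation(perturb_c)
    true_h <- e$delta_h_lib + ph
    true_c <- e$delta_c_lib + pc
    if (true_h > max(axis_h) || true_h < min(axis_h) ||
        true_c > max(axis_c) || true_c < min(axis_c)) {
      stop("perturbed shift of ", e$metabolite, " ", e$moiety,
           " falls outside the requested axes", call. = FALSE)
    }
    mix <- rep(0, length(axis_c))
    for (k in seq_along(comps)) {
      if (f[k] == 0) next
      sim <- simulate_component(comps[[k]], true_c, axis_c, lineshape,
                                freq_c, j_scaling)
      mix <- mix + f[k] * sim$trace
    }
    hsd <- h_fwhm / (2 * sqrt(2 * log(2)))
    hprof <- exp(-0.5 * ((axis_h - true_h) / hsd)^2)
    nzc <- which(mix > max(mix) * 1e-9)
    nzh <- which(hprof > 1e-9)
    signal[nzc, nzh] <- signal[nzc, nzh] +
      amplitudes[i] * outer(mix[nzc], hprof[nzh])
    rows[[i]] <- data.frame(metabolite = e$metabolite, moiety = e$moiety,
                            true_h = true_h, true_c = true_c,
                            perturb_h = ph, perturb_c = pc,
                            amplitude = amplitudes[i])
    used_fractions[[i]] <- stats::setNames(
      f, vapply(comps, function(cc) cc$label, ""))
  }
  sigma <- if (is.finite(snr)) max(abs(signal)) / snr else 0
  intens <- signal
  if (sigma > 0) {
    intens <- intens + matrix(stats::rnorm(length(signal), sd = sigma),
                              nrow = nrow(signal))
    if (n_spurious > 0L) {
      for (k in seq_len(n_spurious)) {
        ri <- sample.int(length(axis_c), 1L)
        ci <- sample.int(length(axis_h), 1L)
        amp <- stats::runif(1L, 2, 4) * sigma
        rr <- max(1L, ri - 2L):min(length(axis_c), ri + 2L)
        cc <- max(1L, ci - 2L):min(length(axis_h), ci + 2L)
        blob <- outer(stats::dnorm(rr - ri), stats::dnorm(cc - ci))
        intens[rr, cc] <- intens[rr, cc] + amp * blob / max(blob)
      }
    }
  }
  grid <- spectrum_grid(intens, axis_h, axis_c, freq_h, freq_c,
                        j_scaling = j_scaling,
                        provenance = sprintf("synthetic seed=%d", seed))
  truth <- structure(list(table = do.call(rbind, rows),
                          fractions = used_fractions, sigma = sigma,
                          snr = snr, j_scaling = as.integer(j_scaling),
                          h_fwhm = h_fwhm, seed = as.integer(seed)),
                     class = "ground_truth")
  list(grid = grid, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d entries, snr %s, j_scaling %d, seed %d\n",
              nrow(x$table), format(x$snr), x$j_scaling, x$seed))
  print(x$table)
  invisible(x)
}

#' Generate a deterministic benchmark suite of synthetic spectra
#'
#' Emits a parameterised collection of fixtures spanning the apparent-J
#' scaling factors and signal-to-noise levels, with a machine-readable
#' truth table.  Intended for end-to-end evaluation of the pipeline
#' without any external data.
#'
#' @param config List of suite settings: `metabolites` (character, the
#'   resonances to include; default lactate and alanine), `scalings`
#'   (default `c(1, 2, 4, 8)`), `snrs` (default `c(Inf, 20, 10)`),
#'   `library` (a [load_library()] result; default the shipped library).
#' @param seed Integer master seed; every scenario derives its own
#'   sub-seed from it.
#' @return List with `spectra` (list of `generate_spectrum()` results)
#'   and `truth_table` (data frame keyed by scenario id).
#' @export
generate_benchmark_suite <- function(config = list(), seed = 1L) {
  metabolites <- config$metabolites %||% c("lactate", "alanine")
  scalings <- config$scalings %||% c(1L, 2L, 4L, 8L)
  snrs <- config$snrs %||% c(Inf, 20, 10)
  library <- config$library %||% load_library()
  if (length(metabolites) == 0L) {
    warning("empty metabolite list; empty benchmark suite")
    return(list(spectra = list(),
                truth_table = data.frame(scenario = character())))
  }
  entries <- unlist(lapply(metabolites, resonances_of, library = library),
                    recursive = FALSE)
  spectra <- list()
  tt <- list()
  idx <- 0L
  for (s in scalings) {
    for (snr in snrs) {
      idx <- idx + 1L
      id <- sprintf("js%d_snr%s", s, if (is.finite(snr)) format(snr)
                                      else "Inf")
      sp <- generate_spectrum(entries, snr = snr, j_scaling = s,
                              n_spurious = if (is.finite(snr) && snr <= 10)
                                             5L else 0L,
                              seed = seed + 97L * idx)
      spectra[[id]] <- sp
      tab <- sp$truth$table
      tab$scenario <- id
      tab$j_scaling <- s
      tab$snr <- snr
      tab$fractions <- vapply(
        sp$truth$fractions,
        function(f) paste(sprintf("%s=%.6f", names(f), f), collapse = ";"),
        "")
      tt[[id]] <- tab
    }
  }
  list(spectra = spectra, truth_table = do.call(rbind, tt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
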