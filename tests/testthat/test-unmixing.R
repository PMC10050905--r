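make_single_region <- function(snr, seed, entry = NULL, fractions = NULL) {
  lib <- load_library()
  e <- if (is.null(entry)) resonances_of(lib, "lactate")[[1]] else entry
  sp <- generate_spectrum(e, fractions = fractions, snr = snr, seed = seed)
  list(region = extract_region(sp$grid, e$delta_h_lib, e$delta_c_lib,
                               0.15, 3.0),
       entry = e, truth = sp$truth)
}

test_that("component count tracks the matrix rank of the region", {
  lib <- load_library()
  e1 <- resonances_of(lib, "lactate")[[2]]
  e2 <- resonances_of(lib, "alanine")[[2]]
  sp1 <- generate_spectrum(e1, snr = Inf, perturb_h = 0, perturb_c = 0,
                           seed = 1)
  reg1 <- extract_region(sp1$grid, e1$delta_h_lib, e1$delta_c_lib, 0.15, 3)
  expect_equal(choose_n_components(reg1), 1L)

  sp2 <- generate_spectrum(list(e1, e2), snr = Inf, perturb_h = 0,
                           perturb_c = 0, seed = 1)
  reg2 <- extract_region(sp2$grid, 1.385, 19, 0.15, 3)
  expect_equal(choose_n_components(reg2), 2L)
  expect_equal(qr(reg2$subgrid$intensities)$rank, 2L)

  # threshold 1 on a noisy region hits the configured cap
  sp3 <- generate_spectrum(e1, snr = 10, seed = 2)
  reg3 <- extract_region(sp3$grid, e1$delta_h_lib, e1$delta_c_lib, 0.15, 3)
  expect_equal(choose_n_components(reg3, 1.0, max_components = 5L), 5L)
})

test_that("decomposition is deterministic and scale-invariant", {
  f <- make_single_region(snr = 20, seed = 3)
  c1 <- suppressMessages(decompose_region(f$region, 3L, seed = 7L))
  c2 <- suppressMessages(decompose_region(f$region, 3L, seed = 7L))
  expect_identical(lapply(c1, `[[`, "trace"), lapply(c2, `[[`, "trace"))

  scaled <- f$region
  scaled$subgrid$intensities <- scaled$subgrid$intensities * 37.5
  c3 <- suppressMessages(decompose_region(scaled, 3L, seed = 7L))
  for (k in seq_along(c1)) {
    expect_gt(abs(stats::cor(c3[[k]]$trace, c1[[k]]$trace)), 0.999)
  }
})

test_that("a clean single resonance is recovered almost exactly", {
  f <- make_single_region(snr = 200, seed = 5)
  tr_true <- truth_trace(f$entry, f$truth$fractions[[1]],
                         f$truth$table$true_c[1], f$region$subgrid$axis_c)
  comps <- suppressMessages(decompose_region(f$region, "auto", seed = 0L))
  best <- max(vapply(comps, function(cc) abs(stats::cor(cc$trace, tr_true)),
                     0))
  expect_gte(best, 0.99)
})

test_that("overlapping resonances at SNR 50 are separated usefully", {
  # Noise on the 259-point trace bounds the attainable cosine (see the
  # methods vignette); both sources must be matched uniquely and well.
  eA <- toy_entry(37, metabolite = "ovA", moiety = "C1", h = 1.33,
                  c = 21.5)
  eB <- toy_entry(c(35, 52), metabolite = "ovB", moiety = "C1", h = 1.38,
                  c = 19.5)
  hits <- 0L
  for (s in 1:10) {
    sp <- generate_spectrum(list(eA, eB), perturb_h = 0, perturb_c = 0,
                            snr = 50, seed = s,
                            axes = list(h = seq(1.7, 1.0, by = -15.6 / 1024),
                                        c = seq(25, 16, by = -189.8 / 8192)))
    reg <- extract_region(sp$grid, 1.355, 20.5, 0.15, 3.0)
    tA <- truth_trace(eA, sp$truth$fractions[[1]], 21.5,
                      reg$subgrid$axis_c)
    tB <- truth_trace(eB, sp$truth$fractions[[2]], 19.5,
                      reg$subgrid$axis_c)
    comps <- suppressMessages(decompose_region(reg, "auto", seed = s))
    corA <- vapply(comps, function(cc) abs(stats::cor(cc$trace, tA)), 0)
    corB <- vapply(comps, function(cc) abs(stats::cor(cc$trace, tB)), 0)
    if (max(corA) >= 0.8 && max(corB) >= 0.8 &&
        which.max(corA) != which.max(corB)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})

test_that("localisation assigns the maximising column and gates on minCorr", {
  f <- make_single_region(snr = 20, seed = 11)
  reg <- f$region
  x <- reg$subgrid$intensities
  comp <- structure(list(trace = x[, 7], assigned_h_ppm = NA_real_,
                         correlation = NA_real_, rejected = FALSE,
                         index = 1L), class = "latent_component")
  out <- localize_component(comp, reg, min_corr = 0.8)
  expect_false(out$rejected)
  expect_equal(out$correlation, 1)
  expect_equal(out$assigned_h_ppm, reg$subgrid$axis_h[7])

  set.seed(99)
  noise <- structure(list(trace = rnorm(nrow(x)), assigned_h_ppm = NA_real_,
                          correlation = NA_real_, rejected = FALSE,
                          index = 2L), class = "latent_component")
  out2 <- localize_component(noise, reg, min_corr = 0.8)
  expect_true(out2$rejected)
  expect_true(is.na(out2$assigned_h_ppm))
  expect_lt(out2$correlation, 0.8)
})

test_that("localisation ties break to the larger-intensity column", {
  ax_h <- seq(4.2, by = -0.01, length.out = 6)
  ax_c <- seq(70, by = -0.1, length.out = 50)
  shape <- exp(-0.5 * ((seq_len(50) - 25) / 3)^2)
  m <- matrix(0.0, 50, 6)
  m[, 2] <- shape
  m[, 5] <- 2 * shape    # same shape, larger total intensity
  g <- spectrum_grid(m, ax_h, ax_c, 600.13, 150.903)
  reg <- extract_region(g, 4.17, 67.5, 0.2, 10)
  comp <- structure(list(trace = shape, assigned_h_ppm = NA_real_,
                         correlation = NA_real_, rejected = FALSE,
                         index = 1L), class = "latent_component")
  out <- localize_component(comp, reg, min_corr = 0.8)
  expect_equal(out$assigned_h_ppm, ax_h[5])
  # a zero-variance column correlates 0 by definition, not NA
  comp0 <- structure(list(trace = rep(1, 50), assigned_h_ppm = NA_real_,
                          correlation = NA_real_, rejected = FALSE,
                          index = 2L), class = "latent_component")
  out0 <- localize_component(comp0, reg, min_corr = 0.8)
  expect_true(out0$rejected)
  expect_equal(out0$correlation, 0)
})
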