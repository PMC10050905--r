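test_that("minor peaks are suppressed, dominant peaks untouched", {
  tr <- c(0, 0.2, 1.0, 0.2, 0, 0.1, 0.4, 0.1, 0)
  out <- filter_peaks(tr, 0.5)
  expect_equal(out[1:5], tr[1:5])
  expect_true(all(out[6:9] == 0))
  # equal-height peaks survive
  tr2 <- c(0, 1, 0, 1, 0)
  expect_identical(filter_peaks(tr2, 0.5), tr2)
  # single peak and all-zero traces pass through
  tr3 <- c(0, 0.3, 1, 0.3, 0)
  expect_identical(filter_peaks(tr3, 0.5), tr3)
  expect_identical(filter_peaks(rep(0, 5), 0.5), rep(0, 5))
})

test_that("coefficient of determination matches its defining identities", {
  t <- c(1, 2, 3, 4)
  expect_equal(coefficient_of_determination(t, t), 100)
  expect_equal(coefficient_of_determination(t, rep(mean(t), 4)), 0)
  expect_equal(coefficient_of_determination(t, c(1, 2, 3, 5)), 80)
  # negative values clamp to zero; constant traces warn and return 0
  expect_equal(coefficient_of_determination(t, c(10, -10, 10, -10)), 0)
  expect_warning(r0 <- coefficient_of_determination(rep(2, 4), t),
                 "constant")
  expect_equal(r0, 0)
})

test_that("rho is invariant under a common affine rescaling", {
  set.seed(1)
  t <- rnorm(50)
  t_hat <- t + rnorm(50, sd = 0.3)
  base <- coefficient_of_determination(t, t_hat)
  for (ab in list(c(2.5, 0), c(1, 7), c(-3, 2))) {
    expect_equal(
      coefficient_of_determination(ab[1] * t + ab[2],
                                   ab[1] * t_hat + ab[2]),
      base, tolerance = 1e-10)
  }
})

test_that("library-shift distance compresses the 13C axis by 20 gamma", {
  expect_equal(delta_ppm(4.1, 69.3, 4.1, 69.3), 0)
  expect_equal(delta_ppm(4.17, 69.3, 4.1, 69.3), 0.07)
  gamma_adj <- 20 * gamma_ratio_hc()
  expect_equal(gamma_adj, 79.525, tolerance = 1e-3)
  expect_equal(delta_ppm(4.1, 70.3, 4.1, 69.3), 1 / gamma_adj)
})

test_that("the adjusted score penalises distance monotonically", {
  expect_equal(adjusted_score(90, 0, 1e-4), 90 / 1e-4)
  expect_gt(adjusted_score(90, 0.01), adjusted_score(90, 0.02))
  expect_equal(adjusted_score(0, 0.5), 0)
})

test_that("trust classification follows the 80/70 boundaries", {
  expect_equal(classify_trust(85), "trustworthy")
  expect_equal(classify_trust(80), "trustworthy")
  expect_equal(classify_trust(75), "borderline")
  expect_equal(classify_trust(70), "not_trustworthy")
  expect_equal(classify_trust(65), "not_trustworthy")
})

make_design <- function(entry = toy_entry(c(54.9, 37.1)),
                        center = 69.33,
                        ax = seq(72.3, 66.3, by = -0.01)) {
  comps <- enumerate_components(entry)
  sims <- lapply(comps, simulate_component, center_c = center,
                 axis_c = ax, lineshape = lineshape_params(1.5),
                 freq_c = 150.903, j_scaling = 1L)
  list(comps = comps, sims = sims, ax = ax,
       X = vapply(sims, `[[`, numeric(length(ax)), "trace"))
}

test_that("exact mixtures are recovered exactly by constrained regression", {
  d <- make_design()
  f <- c(0.5, 0.3, 0.2)
  col <- d$X[, 1:3] %*% f
  fit <- fit_fractions(as.numeric(col), d$sims[1:3])
  expect_equal(unname(fit$fractions), f, tolerance = 1e-6)
  expect_equal(fit$rho, 100, tolerance = 1e-6)
  expect_equal(fit$trust, "trustworthy")
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-9)

  # a column orthogonal to the design fits nothing
  ortho <- rep(0, length(d$ax))
  ortho[seq(5, 50, by = 9)] <- c(1, -1)
  fit0 <- fit_fractions(ortho - mean(ortho), d$X[, 2, drop = FALSE])
  expect_equal(fit0$trust, "not_found")
  expect_equal(fit0$rho, 0)
  expect_null(fit0$fractions)

  # negative true weights are clamped at the constraint
  col2 <- d$X[, 1] - 0.1 * d$X[, 2]
  fit2 <- fit_fractions(col2, d$sims[1:2])
  expect_equal(unname(fit2$amplitudes[2]), 0)
})

test_that("fractions are a point on the simplex for random mixtures", {
  d <- make_design()
  set.seed(8)
  for (rep in 1:20) {
    f <- stats::rexp(4)
    col <- d$X %*% (f / sum(f)) + stats::rnorm(length(d$ax), sd = 0.02)
    fit <- fit_fractions(as.numeric(col), d$sims)
    if (!identical(fit$trust, "not_found")) {
      expect_true(all(fit$fractions >= 0))
      expect_equal(sum(fit$fractions), 1, tolerance = 1e-9)
    }
  }
})

test_that("subset alignment recovers the generating subset and centre", {
  d <- make_design(center = 69.0)   # true centre 0.33 ppm off library
  sub_true <- c(2L, 3L)             # the two doublets
  trace <- equal_intensity_multiplet(d$sims, sub_true)
  comp <- structure(list(trace = trace / max(trace), assigned_h_ppm = 4.1,
                         correlation = 0.95, rejected = FALSE, index = 1L),
                    class = "latent_component")
  reg <- local({
    m <- outer(trace, c(0.4, 1, 0.4))
    g <- spectrum_grid(m, c(4.11, 4.10, 4.09), d$ax, 600.13, 150.903)
    extract_region(g, 4.10, 69.33, 0.15, 10)
  })
  asg <- align_multiplet(comp, toy_entry(c(54.9, 37.1)), reg,
                         analysis_config(j_scaling = 1))
  expect_identical(sort(asg$best_subset), sub_true)
  expect_lt(abs(asg$x_c - 69.0), 0.011)
  expect_gt(asg$rho_ident, 99)
})

test_that("equal fits resolve toward the library-proximal position", {
  e <- toy_entry(numeric(0), h = 4.10, c = 69.33)   # singlet resonance
  ax <- seq(72.3, 66.3, by = -0.01)
  near <- simulate_component(enumerate_components(e)[[1]], 69.63, ax,
                             lineshape_params(1.5), 150.903, 1)$trace
  far <- simulate_component(enumerate_components(e)[[1]], 68.53, ax,
                            lineshape_params(1.5), 150.903, 1)$trace
  trace <- near + far                # two identical singlets
  comp <- structure(list(trace = trace / max(trace), assigned_h_ppm = 4.1,
                         correlation = 0.95, rejected = FALSE, index = 1L),
                    class = "latent_component")
  reg <- local({
    m <- outer(trace, c(0.4, 1, 0.4))
    g <- spectrum_grid(m, c(4.11, 4.10, 4.09), ax, 600.13, 150.903)
    extract_region(g, 4.10, 69.33, 0.15, 10)
  })
  asg <- align_multiplet(comp, e, reg, analysis_config(j_scaling = 1))
  expect_lt(abs(asg$x_c - 69.63), 0.02)   # 0.30 ppm away beats 0.80 ppm
})

test_that("hill climbing matches exhaustive search on unimodal profiles", {
  d <- make_design()
  A <- d$X[, 2]
  B <- rep(0, length(d$ax)); B[30:35] <- 5   # foreign, unfittable shape
  B <- B - mean(B)
  nh <- 15L
  s <- exp(-0.5 * ((seq_len(nh) - 9) / 2.5)^2)
  m <- vapply(seq_len(nh), function(j) s[j] * A + (1 - s[j]) * B,
              numeric(length(d$ax)))
  g <- spectrum_grid(m, seq(4.2, by = -0.01, length.out = nh), d$ax,
                     600.13, 150.903)
  reg <- extract_region(g, 4.13, 69.33, 0.5, 5)
  asg <- structure(list(entry = toy_entry(c(54.9, 37.1)),
                        x_h = reg$subgrid$axis_h[2], x_c = 69.33,
                        delta_ppm = 0, best_subset = 2L,
                        subset_labels = "d(C3)", rho_ident = 50,
                        rho_adjusted = 1, source_component = 1L),
                   class = "multiplet_assignment")
  design <- d$X[, 2, drop = FALSE]
  ref <- refine_proton_shift(reg, asg, design)
  brute <- vapply(seq_len(nh), function(j) {
    b <- pracma::lsqnonneg(design, reg$subgrid$intensities[, j])$x
    coefficient_of_determination(reg$subgrid$intensities[, j],
                                 as.numeric(design %*% b))
  }, 0)
  expect_equal(ref$column, which.max(brute))
  expect_equal(ref$rho, max(brute))

  # starting at the optimum stays put; a flat region never moves
  asg$x_h <- reg$subgrid$axis_h[which.max(brute)]
  expect_equal(refine_proton_shift(reg, asg, design)$column,
               which.max(brute))
  flat <- reg
  flat$subgrid$intensities <- matrix(rep(A, nh), ncol = nh)
  asg$x_h <- flat$subgrid$axis_h[5]
  expect_equal(refine_proton_shift(flat, asg, design)$column, 5L)
})
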