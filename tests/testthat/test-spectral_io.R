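test_that("portable grid round trip preserves intensities bit-exactly", {
  g <- tiny_grid()
  g$intensities[3, 4] <- pi * 1e4
  g$intensities[1, 1] <- 1 / 3
  p <- withr::local_tempfile(fileext = ".json")
  write_spectrum(g, p)
  g2 <- read_spectrum(p, "grid")
  expect_identical(g2$intensities, g$intensities)
  expect_lt(max(abs(g2$axis_h - g$axis_h)), 1e-9)
  expect_lt(max(abs(g2$axis_c - g$axis_c)), 1e-9)
  expect_identical(g2$j_scaling, g$j_scaling)
  expect_identical(g2$freq_h, g$freq_h)
  expect_identical(g2$provenance, g$provenance)
  # auto-detection picks the grid reader
  g3 <- read_spectrum(p)
  expect_identical(g3$intensities, g$intensities)
})

test_that("NMRPipe reader agrees with an independent header builder", {
  mat <- matrix(as.numeric(1:48), nrow = 6, ncol = 8, byrow = TRUE)
  p <- withr::local_tempfile(fileext = ".ft2")
  sw2 <- 4800; orig2 <- 2280; obs2 <- 600.13
  sw1 <- 3000; orig1 <- 9054; obs1 <- 150.903
  write_nmrpipe_fixture(p, mat, sw2, orig2, obs2, sw1, orig1, obs1)
  g <- read_spectrum(p, "nmrpipe")
  expect_equal(dim(g$intensities), c(6L, 8L))
  # float32 headers: parameters round to ~7 significant digits
  expect_lt(max(abs(g$axis_h - nmrpipe_axis_oracle(sw2, orig2, obs2, 8))),
            1e-4)
  expect_lt(max(abs(g$axis_c - nmrpipe_axis_oracle(sw1, orig1, obs1, 6))),
            1e-4)
  expect_equal(g$intensities, mat, ignore_attr = TRUE)
  expect_equal(g$freq_h, obs2, tolerance = 1e-6)
  expect_equal(g$freq_c, obs1, tolerance = 1e-6)
  # auto-detection via the float-order magic
  expect_equal(read_spectrum(p)$intensities, mat, ignore_attr = TRUE)
})

test_that("non-2D NMRPipe data is rejected", {
  p <- withr::local_tempfile(fileext = ".ft1")
  hdr <- numeric(512)
  hdr[2 + 1] <- 2.345
  hdr[9 + 1] <- 1       # one dimension
  con <- file(p, "wb")
  writeBin(hdr, con, size = 4L, endian = "little")
  writeBin(as.numeric(1:16), con, size = 4L, endian = "little")
  close(con)
  expect_error(read_spectrum(p, "nmrpipe"), "not 2D")
})

test_that("Sparky ucsf reader reassembles tiled data and calibrates axes", {
  mat <- matrix(as.numeric(seq_len(30)), nrow = 5, ncol = 6, byrow = TRUE)
  p <- withr::local_tempfile(fileext = ".ucsf")
  write_ucsf_fixture(p, mat, tile1 = 3L, tile2 = 4L,
                     freq1 = 150.903, sw1 = 3000, center1 = 65,
                     freq2 = 600.13, sw2 = 4800, center2 = 4.7)
  g <- read_spectrum(p, "ucsf")
  expect_equal(dim(g$intensities), c(5L, 6L))
  expect_equal(g$intensities, mat, ignore_attr = TRUE)
  expect_lt(max(abs(g$axis_c - ucsf_axis_oracle(5, 150.903, 3000, 65))),
            1e-3)
  expect_lt(max(abs(g$axis_h - ucsf_axis_oracle(6, 600.13, 4800, 4.7))),
            1e-3)
  expect_equal(read_spectrum(p)$intensities, mat, ignore_attr = TRUE)
})

test_that("search regions use closed ppm windows with edge clipping", {
  ax_h <- seq(4.50, 3.50, by = -0.01)
  ax_c <- seq(80, 60, by = -0.1)
  g <- spectrum_grid(matrix(rnorm(length(ax_c) * length(ax_h)),
                            length(ax_c)), ax_h, ax_c, 600.13, 150.903)
  reg <- extract_region(g, 4.10, 69.3, 0.15, 3.0)
  expect_equal(range(reg$subgrid$axis_h), c(3.95, 4.25))
  expect_equal(range(reg$subgrid$axis_c), c(66.3, 72.3))
  # half widths beyond the grid clip to the full grid
  reg2 <- extract_region(g, 4.10, 69.3, 10, 100)
  expect_identical(reg2$subgrid$intensities, g$intensities)
  # a window with no overlap at all is an error
  expect_error(extract_region(g, 9.0, 69.3, 0.15, 3.0),
               "outside spectral width")
})

test_that("region extraction composes and column lookup is index-faithful", {
  g <- tiny_grid(nh = 20L, nc = 30L)
  r1 <- extract_region(g, 4.0, 65, 0.2, 5)
  r2 <- extract_region(r1$subgrid, 4.0, 65, 0.1, 2)
  direct <- extract_region(g, 4.0, 65, 0.1, 2)
  expect_identical(r2$subgrid$intensities, direct$subgrid$intensities)
  expect_identical(r2$subgrid$axis_c, direct$subgrid$axis_c)

  reg <- extract_region(g, 4.0, 65, 0.2, 5)
  j <- 3L
  col <- column_at(reg, reg$subgrid$axis_h[j])
  expect_identical(as.numeric(col), reg$subgrid$intensities[, j])
  expect_identical(attr(col, "column"), j)
  # midway between two columns: lower index (higher ppm) wins
  mid <- mean(reg$subgrid$axis_h[1:2])
  expect_identical(attr(column_at(reg, mid), "column"), 1L)
  expect_error(column_at(reg, 9.99), "outside region")
})

test_that("grid constructor enforces axis and metadata invariants", {
  expect_error(spectrum_grid(matrix(0, 2, 2), c(2, 1), c(3, 2, 1),
                             600, 150), "axis lengths")
  expect_error(spectrum_grid(matrix(0, 2, 2), c(2, 1), c(1, 2),
                             150, 600), "freq_h > freq_c")
  expect_error(spectrum_grid(matrix(0, 3, 2), c(2, 1), c(1, 3, 2),
                             600, 150), "monotonic")
  # ascending input axes are normalised to descending storage
  m <- matrix(1:6, nrow = 3)
  g <- spectrum_grid(m, c(1, 2), c(10, 20, 30), 600, 150)
  expect_equal(g$axis_h, c(2, 1))
  expect_equal(g$axis_c, c(30, 20, 10))
  expect_equal(g$intensities[1, 1], m[3, 2])
})
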