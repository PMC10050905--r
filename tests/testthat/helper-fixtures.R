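# Shared fixture builders.  Everything is generated in code; no binary
# files ship with the package.

# A small, deterministic spectrum grid with a linear-ramp intensity
# pattern, handy for I/O and indexing tests.
tiny_grid <- function(nh = 8L, nc = 10L) {
  ax_h <- seq(4.25, by = -0.05, length.out = nh)
  ax_c <- seq(72.0, by = -0.5, length.out = nc)
  m <- outer(seq_len(nc), seq_len(nh), function(i, j) i * 100 + j + 0.5)
  spectrum_grid(m, ax_h, ax_c, freq_h = 600.13, freq_c = 150.903,
                j_scaling = 1L, provenance = "tiny")
}

# Library entry with arbitrary couplings, for model-level tests.
toy_entry <- function(js = c(54.9, 37.1), metabolite = "toy",
                      moiety = "C2", h = 4.10, c = 69.33) {
  n <- length(js)
  cpl <- if (n) data.frame(partner = paste0("C", seq_len(n) + 2L),
                           j = js, one_bond = TRUE)
         else data.frame(partner = character(), j = numeric(),
                         one_bond = logical())
  resonance_entry(metabolite, moiety, h, c, cpl)
}

# Fraction-weighted true multiplet trace of an entry on a 13C axis.
truth_trace <- function(entry, fractions, center_c, axis_c,
                        linewidth = 3, freq_c = 150.903, j_scaling = 1L) {
  comps <- enumerate_components(entry)
  tr <- rep(0, length(axis_c))
  for (k in seq_along(comps)) {
    if (fractions[k] == 0) next
    sim <- simulate_component(comps[[k]], center_c, axis_c,
                              lineshape_params(linewidth), freq_c,
                              j_scaling)
    tr <- tr + fractions[k] * sim$trace
  }
  tr
}

# ---- independent NMRPipe fixture builder -------------------------------
# Writes a 2D real ft2 file directly: a 512-float32 header with the
# documented parameter positions, then row-major float32 data.  Kept
# independent of the package reader/writer.
write_nmrpipe_fixture <- function(path, mat, sw2, orig2, obs2, sw1, orig1,
                                  obs1) {
  hdr <- numeric(512)
  hdr[2 + 1]   <- 2.345      # float-order magic
  hdr[9 + 1]   <- 2          # dimension count
  hdr[99 + 1]  <- ncol(mat)  # FDSIZE: points per row (direct dim)
  hdr[219 + 1] <- nrow(mat)  # FDSPECNUM: number of rows
  hdr[56 + 1]  <- 1          # FDF2QUADFLAG: real
  hdr[55 + 1]  <- 1          # FDF1QUADFLAG: real
  hdr[220 + 1] <- 1          # FDF2FTFLAG: frequency domain
  hdr[222 + 1] <- 1          # FDF1FTFLAG
  hdr[100 + 1] <- sw2; hdr[101 + 1] <- orig2; hdr[119 + 1] <- obs2
  hdr[229 + 1] <- sw1; hdr[249 + 1] <- orig1; hdr[218 + 1] <- obs1
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con, size = 4L, endian = "little")
  writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}

# Closed-form ppm axis the NMRPipe calibration implies: the origin is the
# frequency of the last point, spacing sw/n.
nmrpipe_axis_oracle <- function(sw, orig, obs, n) {
  (orig + sw * (n - 1 - (0:(n - 1))) / n) / obs
}

# ---- independent Sparky ucsf fixture builder ---------------------------
# Big-endian, 180-byte file header, two 128-byte axis headers (slow axis
# first), tiled float32 data with edge padding.
write_ucsf_fixture <- function(path, mat, tile1, tile2,
                               freq1, sw1, center1, freq2, sw2, center2) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- raw(180)
  hdr[1:8] <- charToRaw("UCSF NMR")
  hdr[11] <- as.raw(2)  # naxis
  hdr[12] <- as.raw(1)  # real components
  writeBin(hdr, con)
  axis_header <- function(nuc, n, tile, freq, sw, center) {
    h <- raw(128)
    nm <- charToRaw(nuc)
    h[seq_along(nm)] <- nm
    writeBin(h, con)
    seek(con, seek(con) - 128 + 8)
    writeBin(as.integer(n), con, size = 4L, endian = "big")
    seek(con, seek(con) + 4)  # skip "integer points" field
    writeBin(as.integer(tile), con, size = 4L, endian = "big")
    writeBin(c(freq, sw, center), con, size = 4L, endian = "big")
    seek(con, seek(con) + 128 - 32)
  }
  axis_header("13C", nrow(mat), tile1, freq1, sw1, center1)
  axis_header("1H", ncol(mat), tile2, freq2, sw2, center2)
  nt1 <- ceiling(nrow(mat) / tile1)
  nt2 <- ceiling(ncol(mat) / tile2)
  padded <- matrix(0, nt1 * tile1, nt2 * tile2)
  padded[seq_len(nrow(mat)), seq_len(ncol(mat))] <- mat
  for (t1 in seq_len(nt1)) {
    for (t2 in seq_len(nt2)) {
      rows <- (t1 - 1L) * tile1 + seq_len(tile1)
      cols <- (t2 - 1L) * tile2 + seq_len(tile2)
      writeBin(as.numeric(t(padded[rows, cols])), con, size = 4L,
               endian = "big")
    }
  }
  invisible(path)
}

ucsf_axis_oracle <- function(n, freq, sw, center) {
  (center * freq + sw / 2 - (0:(n - 1)) * sw / n) / freq
}

# ---- brute-force two-spin quantum oracle -------------------------------
# Diagonalises the full two-spin Hamiltonian H = da*Iza + db*Izb + J Ia.Ib
# (Hz) and returns the single-quantum lines of the observed spin a
# (selectively excited and detected, as in a heteronuclear coherence-
# transfer experiment): frequencies in Hz and intensities normalised to
# sum 1.
two_spin_oracle <- function(delta_a, delta_b, J) {
  sx <- matrix(c(0, 1, 1, 0) / 2, 2)
  sy <- matrix(c(0, 1i, -1i, 0) / 2, 2)
  sz <- diag(c(1, -1)) / 2
  id <- diag(2)
  H <- delta_a * kronecker(sz, id) + delta_b * kronecker(id, sz) +
    J * (kronecker(sx, id) %*% kronecker(id, sx) +
         kronecker(sy, id) %*% kronecker(id, sy) +
         kronecker(sz, id) %*% kronecker(id, sz))
  e <- eigen(H, symmetric = TRUE)
  V <- e$vectors
  E <- e$values
  Ipa <- kronecker(sx + 1i * sy, id)
  A <- Conj(t(V)) %*% Ipa %*% V
  lines <- NULL
  for (i in 1:4) {
    for (f in 1:4) {
      amp <- Mod(A[f, i])^2
      if (amp > 1e-12) {
        lines <- rbind(lines, c(freq = abs(E[i] - E[f]), int = amp))
      }
    }
  }
  lines[, "int"] <- lines[, "int"] / sum(lines[, "int"])
  lines[order(lines[, "freq"]), , drop = FALSE]
}
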