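# Spectrum file input/output: portable text grid (read/write), NMRPipe ft2
# (read) and Sparky ucsf (read).

GRID_FORMAT_NAME <- "hsqcmult-grid"
GRID_FORMAT_VERSION <- 1L

#' Write a spectrum to the portable grid format
#'
#' The portable grid is a self-describing, versioned JSON container that
#' carries the intensity matrix, both ppm axes and the spectrometer
#' metadata.  Numeric arrays are serialised with 17 significant digits so
#' that IEEE double values round-trip bit-exactly; fixtures therefore need
#' no binary NMR files.
#'
#' @param grid A [spectrum_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(grid, path) {
  stopifnot(inherits(grid, "spectrum_grid"))
  num <- function(x) sprintf("%.17g", x)
  obj <- list(
    format = GRID_FORMAT_NAME,
    version = GRID_FORMAT_VERSION,
    freq_h = num(grid$freq_h),
    freq_c = num(grid$freq_c),
    j_scaling = grid$j_scaling,
    provenance = grid$provenance,
    axis_h = num(grid$axis_h),
    axis_c = num(grid$axis_c),
    intensities = apply(grid$intensities, 1L, num, simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

read_grid_file <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, GRID_FORMAT_NAME)) {
    stop("not a portable grid file: ", path, call. = FALSE)
  }
  if (obj$version > GRID_FORMAT_VERSION) {
    stop("grid format version ", obj$version, " is newer than supported",
         call. = FALSE)
  }
  ints <- obj$intensities
  mat <- if (is.matrix(ints)) {
    matrix(as.numeric(ints), nrow = nrow(ints))
  } else {
    do.call(rbind, lapply(ints, as.numeric))
  }
  spectrum_grid(mat, as.numeric(obj$axis_h), as.numeric(obj$axis_c),
                as.numeric(obj$freq_h), as.numeric(obj$freq_c),
                j_scaling = if (is.null(obj$j_scaling)) 1L else obj$j_scaling,
                provenance = if (is.null(obj$provenance)) "" else obj$provenance)
}

# --- NMRPipe ---------------------------------------------------------------
# 2048-byte header of 512 float32 values; indices below are 0-based
# positions in that float array.
NMRPIPE_IDX <- list(
  FDFLTORDER = 2L, FDDIMCOUNT = 9L, FDSIZE = 99L, FDSPECNUM = 219L,
  FDTRANSPOSED = 221L,
  FDF2SW = 100L, FDF2ORIG = 101L, FDF2OBS = 119L, FDF2FTFLAG = 220L,
  FDF2QUADFLAG = 56L,
  FDF1SW = 229L, FDF1ORIG = 249L, FDF1OBS = 218L, FDF1FTFLAG = 222L,
  FDF1QUADFLAG = 55L)

# Frequency-domain ppm axis from NMRPipe calibration: the origin is the
# frequency (Hz) of the last point, point spacing is SW/N, the first point
# carries the highest frequency.
nmrpipe_axis <- function(sw, orig, obs, n) {
  (orig + sw * (n - 1 - (seq_len(n) - 1)) / n) / obs
}

read_nmrpipe <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "numeric", n = 512L, size = 4L, endian = "little")
  swapped <- FALSE
  ord <- hdr[NMRPIPE_IDX$FDFLTORDER + 1L]
  if (!isTRUE(abs(ord - 2.345) < 1e-4)) {
    seek(con, 0L)
    hdr <- readBin(con, "numeric", n = 512L, size = 4L, endian = "big")
    ord <- hdr[NMRPIPE_IDX$FDFLTORDER + 1L]
    if (!isTRUE(abs(ord - 2.345) < 1e-4)) {
      stop("not an NMRPipe file (bad float-order magic): ", path,
           call. = FALSE)
    }
    swapped <- TRUE
  }
  g <- function(k) hdr[NMRPIPE_IDX[[k]] + 1L]
  if (g("FDDIMCOUNT") != 2) stop("spectrum not 2D", call. = FALSE)
  if (g("FDTRANSPOSED") != 0) {
    stop("transposed NMRPipe data not supported", call. = FALSE)
  }
  if (g("FDF2QUADFLAG") != 1 || g("FDF1QUADFLAG") != 1) {
    stop("spectrum must be real-valued in both dimensions", call. = FALSE)
  }
  if (g("FDF2FTFLAG") != 1 || g("FDF1FTFLAG") != 1) {
    stop("missing axis calibration: data not frequency domain",
         call. = FALSE)
  }
  nx <- as.integer(g("FDSIZE"))      # points per row, direct dimension
  ny <- as.integer(g("FDSPECNUM"))   # number of rows, indirect dimension
  if (nx < 1L || ny < 1L) stop("corrupt NMRPipe header", call. = FALSE)
  dat <- readBin(con, "numeric", n = nx * ny, size = 4L,
                 endian = if (swapped) "big" else "little")
  if (length(dat) < nx * ny) stop("truncated NMRPipe data", call. = FALSE)
  mat <- matrix(dat, nrow = ny, ncol = nx, byrow = TRUE)
  ax_f2 <- nmrpipe_axis(g("FDF2SW"), g("FDF2ORIG"), g("FDF2OBS"), nx)
  ax_f1 <- nmrpipe_axis(g("FDF1SW"), g("FDF1ORIG"), g("FDF1OBS"), ny)
  obs_f2 <- g("FDF2OBS"); obs_f1 <- g("FDF1OBS")
  if (obs_f2 > obs_f1) {
    # direct dimension is 1H: rows already index 13C
    spectrum_grid(mat, ax_f2, ax_f1, obs_f2, obs_f1,
                  provenance = paste0("nmrpipe:", basename(path)))
  } else {
    spectrum_grid(t(mat), ax_f1, ax_f2, obs_f1, obs_f2,
                  provenance = paste0("nmrpipe:", basename(path)))
  }
}

# --- Sparky ucsf -----------------------------------------------------------
# 180-byte file header ("UCSF NMR" magic), one 128-byte header per axis
# (slowest axis first), float32 big-endian data stored in tiles.
read_ucsf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 10L)
  if (!identical(rawToChar(magic[1:8]), "UCSF NMR")) {
    stop("not a Sparky ucsf file: ", path, call. = FALSE)
  }
  naxis <- as.integer(readBin(con, "raw", n = 1L))
  ncomp <- as.integer(readBin(con, "raw", n = 1L))
  if (naxis != 2L) stop("spectrum not 2D", call. = FALSE)
  if (ncomp != 1L) stop("only real ucsf data supported", call. = FALSE)
  seek(con, 180L)
  read_axis <- function() {
    start <- seek(con)
    nuc_raw <- readBin(con, "raw", n = 6L)
    nuc <- rawToChar(nuc_raw[nuc_raw != as.raw(0)])
    nuc <- sub(" .*$", "", nuc)
    seek(con, start + 8L)
    npt <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    seek(con, start + 16L)
    tile <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
    freq <- readBin(con, "numeric", n = 1L, size = 4L, endian = "big")
    sw <- readBin(con, "numeric", n = 1L, size = 4L, endian = "big")
    center <- readBin(con, "numeric", n = 1L, size = 4L, endian = "big")
    seek(con, start + 128L)
    list(nuc = nuc, n = npt, tile = tile, freq = freq, sw = sw,
         center = center)
  }
  ax1 <- read_axis()  # slowest (rows)
  ax2 <- read_axis()  # fastest (columns)
  if (any(c(ax1$n, ax2$n, ax1$tile, ax2$tile) < 1L) ||
      ax1$freq <= 0 || ax2$freq <= 0) {
    stop("missing axis calibration in ucsf header", call. = FALSE)
  }
  nt1 <- ceiling(ax1$n / ax1$tile)
  nt2 <- ceiling(ax2$n / ax2$tile)
  mat <- matrix(0, nrow = nt1 * ax1$tile, ncol = nt2 * ax2$tile)
  for (t1 in seq_len(nt1)) {
    for (t2 in seq_len(nt2)) {
      vals <- readBin(con, "numeric", n = ax1$tile * ax2$tile, size = 4L,
                      endian = "big")
      if (length(vals) < ax1$tile * ax2$tile) {
        stop("truncated ucsf data", call. = FALSE)
      }
      rows <- (t1 - 1L) * ax1$tile + seq_len(ax1$tile)
      cols <- (t2 - 1L) * ax2$tile + seq_len(ax2$tile)
      mat[rows, cols] <- matrix(vals, nrow = ax1$tile, byrow = TRUE)
    }
  }
  mat <- mat[seq_len(ax1$n), seq_len(ax2$n), drop = FALSE]
  # ppm of point i (0-based): (center*freq + sw/2 - i*sw/n) / freq
  ucsf_axis <- function(a) {
    i <- seq_len(a$n) - 1
    (a$center * a$freq + a$sw / 2 - i * a$sw / a$n) / a$freq
  }
  ppm1 <- ucsf_axis(ax1)
  ppm2 <- ucsf_axis(ax2)
  if (ax2$freq > ax1$freq) {
    # columns are 1H (usual layout: w1 = 13C rows, w2 = 1H columns)
    spectrum_grid(mat, ppm2, ppm1, ax2$freq, ax1$freq,
                  provenance = paste0("ucsf:", basename(path)))
  } else {
    spectrum_grid(t(mat), ppm1, ppm2, ax1$freq, ax2$freq,
                  provenance = paste0("ucsf:", basename(path)))
  }
}

detect_format <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 12L)
  if (length(head) >= 8L && identical(rawToChar(head[1:8]), "UCSF NMR")) {
    return("ucsf")
  }
  if (length(head) == 12L) {
    for (endian in c("little", "big")) {
      ord <- readBin(head[9:12], "numeric", size = 4L, endian = endian)
      if (isTRUE(abs(ord - 2.345) < 1e-4)) return("nmrpipe")
    }
  }
  txt <- tryCatch(rawToChar(head), error = function(e) "")
  if (grepl("^\\s*\\{", txt)) return("grid")
  stop("cannot detect spectrum format of ", path, call. = FALSE)
}

#' Read a processed 2D-HSQC spectrum
#'
#' Reads a frequency-domain 2D spectrum into a [spectrum_grid()].  The
#' supported on-disk formats are NMRPipe ft2, Sparky ucsf and the
#' package's portable JSON grid; `format_hint = "auto"` sniffs the file
#' magic.  The apparent-J scaling factor is taken from file metadata when
#' the format carries it (portable grid), otherwise it defaults to 1.
#'
#' @param path Spectrum file path.
#' @param format_hint One of `"auto"`, `"nmrpipe"`, `"ucsf"`, `"grid"`.
#' @return A [spectrum_grid()].
#' @export
read_spectrum <- function(path,
                          format_hint = c("auto", "nmrpipe", "ucsf", "grid")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- if (format_hint == "auto") detect_format(path) else format_hint
  switch(fmt,
         grid = read_grid_file(path),
         nmrpipe = read_nmrpipe(path),
         ucsf = read_ucsf(path))
}
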