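# Internal helpers shared across modules.

# Gyromagnetic ratios (10^7 rad s^-1 T^-1), CODATA values for 1H and 13C.
GAMMA_H <- 26.7522128
GAMMA_C <- 6.728284

#' Ratio of the 1H and 13C gyromagnetic ratios
#'
#' Used to rescale the 13C axis when measuring the distance of an assigned
#' resonance from its library position, so that deviations in both
#' dimensions are commensurate.
#'
#' @return `gamma_H / gamma_C`, approximately 3.976.
#' @export
gamma_ratio_hc <- function() GAMMA_H / GAMMA_C

# Uniform axis step (signed); errors if the axis is not (close to) uniform.
axis_step <- function(axis) {
  if (length(axis) < 2L) stop("axis needs at least two points", call. = FALSE)
  d <- diff(axis)
  if (max(abs(d - d[1])) > 1e-6 * abs(d[1])) {
    stop("axis is not uniformly spaced", call. = FALSE)
  }
  d[1]
}

# Index of the axis value nearest `value`; ties go to the lower index.
nearest_index <- function(axis, value) {
  which.min(abs(axis - value))
}

# Indices of strict local maxima of `x` (plateau-left points count once).
# Endpoints qualify when they exceed their single neighbour.
local_maxima <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(if (x[1] > 0) 1L else integer(0))
  left  <- c(TRUE, x[-1] > x[-n])           # rising into i
  right <- c(x[-n] >= x[-1], TRUE)          # not rising out of i
  which(left & right)
}

# Pearson correlation defined as 0 when either argument has zero variance.
safe_cor <- function(a, b) {
  sa <- stats::sd(a)
  sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(0)
  stats::cor(a, b)
}

# Nonnegative least squares: Lawson-Hanson via pracma, with a projected
# gradient fallback for degenerate design/response pairs on which the
# active-set iteration fails to terminate.
nnls_solve <- function(C, d) {
  out <- tryCatch(pracma::lsqnonneg(C, as.numeric(d))$x,
                  error = function(e) NULL)
  if (!is.null(out)) return(out)
  CtC <- crossprod(C)
  Ctd <- as.numeric(crossprod(C, as.numeric(d)))
  L <- max(sum(diag(CtC)), .Machine$double.xmin)
  x <- rep(0, ncol(C))
  for (it in seq_len(1000L)) {
    g <- as.numeric(CtC %*% x) - Ctd
    x_new <- pmax(0, x - g / L)
    if (max(abs(x_new - x)) <= 1e-12 * max(1, max(abs(x_new)))) {
      x <- x_new
      break
    }
    x <- x_new
  }
  x
}

# Sliding unnormalised cross-correlation of `x` with `y` (same length T).
# Returns a numeric vector r such that r[s + T] = sum_i x[i] * y[i - s]
# for integer shifts s in -(T-1) .. (T-1); out-of-range y values are 0.
cross_corr_shifts <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  stats::convolve(x, y, conj = TRUE, type = "open")
}
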