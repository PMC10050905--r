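# Blind unmixing of a search region into independent 13C source traces
# and localisation of each source along the proton dimension.

#' Choose the number of latent components for a region
#'
#' Picks the smallest K such that the top-K principal components of the
#' column-observation matrix (each 1H column is one observation over the
#' 13C axis) explain at least `variance_threshold` of the total variance,
#' capped at `max_components`.
#'
#' @param region A [extract_region()] result.
#' @param variance_threshold Fraction of variance to explain (default
#'   0.995).
#' @param max_components Upper cap on K (default 10).
#' @return Integer K >= 1.
#' @export
choose_n_components <- function(region, variance_threshold = 0.995,
                                max_components = 10L) {
  stopifnot(inherits(region, "spectrum_region"),
            variance_threshold > 0, variance_threshold <= 1)
  x <- region$subgrid$intensities
  x <- sweep(x, 2L, colMeans(x))
  d2 <- svd(x, nu = 0L, nv = 0L)$d^2
  tot <- sum(d2)
  if (tot <= 0) {
    warning("degenerate all-zero region; using one component")
    return(1L)
  }
  k <- which(cumsum(d2) / tot >= variance_threshold - 1e-12)[1]
  if (is.na(k)) k <- length(d2)
  min(as.integer(k), as.integer(max_components), ncol(x))
}

new_latent_component <- function(trace, index) {
  # Orientation: the largest-magnitude extremum points up (absorption
  # signals are positive); scale to unit maximum.
  m <- max(abs(trace))
  if (m > 0) {
    if (abs(min(trace)) > max(trace)) trace <- -trace
    trace <- trace / max(trace)
  }
  structure(list(trace = trace, assigned_h_ppm = NA_real_,
                 correlation = NA_real_, rejected = FALSE,
                 index = as.integer(index)),
            class = "latent_component")
}

#' @export
print.latent_component <- function(x, ...) {
  cat(sprintf("<latent_component #%d> %s corr %.3f%s\n", x$index,
              if (is.na(x$assigned_h_ppm)) "unlocalised"
              else sprintf("1H %.4f ppm", x$assigned_h_ppm),
              if (is.na(x$correlation)) NA_real_ else x$correlation,
              if (x$rejected) " (rejected)" else ""))
  invisible(x)
}

#' Decompose a search region into independent 13C source traces
#'
#' Treats every 1H column of the region as one observation of a mixture
#' of a small number of statistically independent 13C sub-spectra and
#' separates them with fixed-point ICA (FastICA, log-cosh contrast).
#' Observations are centred and whitened internally; the random rotation
#' initialising the fixed-point iteration is drawn from `seed`, so the
#' decomposition is deterministic given `(region, n_components, seed)`.
#'
#' @param region A [extract_region()] result with at least two 1H columns.
#' @param n_components Number of sources, or `"auto"` to use
#'   [choose_n_components()].
#' @param seed Integer seed for the initial rotation.
#' @param maxit,tol Fixed-point iteration limit and convergence tolerance.
#' @return List of `latent_component` objects (unlocalised), each with a
#'   trace oriented so its largest extremum is positive and scaled to
#'   unit maximum.
#' @export
decompose_region <- function(region, n_components = "auto", seed = 0L,
                             maxit = 500L, tol = 1e-5) {
  stopifnot(inherits(region, "spectrum_region"))
  x <- region$subgrid$intensities
  if (ncol(x) < 2L) stop("region must have at least two 1H columns",
                         call. = FALSE)
  if (!all(is.finite(x))) stop("region intensities must be finite",
                               call. = FALSE)
  nc <- if (identical(n_components, "auto")) choose_n_components(region)
        else as.integer(n_components)
  if (nc > ncol(x)) {
    warning("fewer 1H columns than requested components; reducing to ",
            ncol(x))
    nc <- ncol(x)
  }
  # a (near-)constant region has no mixture structure to separate
  if (max(x) - min(x) <= 0) {
    warning("region carries no signal variation; returning a null component")
    return(list(new_latent_component(rep(0, nrow(x)), 1L)))
  }
  # numerical rank bound: whitening cannot expand a rank-deficient region
  d <- svd(sweep(x, 2L, colMeans(x)), nu = 0L, nv = 0L)$d
  rank <- sum(d > max(d) * 1e-9)
  if (rank < 1L) rank <- 1L
  if (nc > rank) nc <- rank
  rot <- withr_seed(seed, {
    m <- matrix(stats::rnorm(nc * nc), nc, nc)
    qr.Q(qr(m))
  })
  fit <- ica::icafast(x, nc = nc, center = TRUE, maxit = maxit, tol = tol,
                      Rmat = rot, alg = "par", fun = "logcosh")
  if (!isTRUE(fit$converged)) {
    message("FastICA did not converge within ", maxit,
            " iterations; using current estimate")
  }
  lapply(seq_len(nc), function(k) new_latent_component(fit$S[, k], k))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Assign a 1H chemical shift to a latent component
#'
#' Computes the zero-lag Pearson correlation between the component trace
#' and every 1H column of the region (both share the region's 13C axis)
#' and assigns the 1H ppm of the maximising column.  Components whose
#' best correlation falls below `min_corr` are flagged rejected and take
#' no further part in matching.  A zero-variance column or component
#' correlates 0 by definition.  Ties break to the column with larger
#' total intensity, then to the lower column index.
#'
#' @param component A `latent_component` from [decompose_region()].
#' @param region The region it was computed from.
#' @param min_corr Minimum acceptable correlation (default 0.8).
#' @return The component with `assigned_h_ppm`, `correlation` and
#'   `rejected` filled in.
#' @export
localize_component <- function(component, region, min_corr = 0.8) {
  stopifnot(inherits(component, "latent_component"),
            inherits(region, "spectrum_region"))
  x <- region$subgrid$intensities
  if (length(component$trace) != nrow(x)) {
    stop("component trace length must equal the region's 13C axis length",
         call. = FALSE)
  }
  cors <- apply(x, 2L, function(col) safe_cor(component$trace, col))
  best <- max(cors)
  cand <- which(cors >= best - 1e-12)
  if (length(cand) > 1L) {
    tot <- colSums(x[, cand, drop = FALSE])
    cand <- cand[order(-tot, cand)]
  }
  j <- cand[1]
  component$correlation <- cors[j]
  if (cors[j] < min_corr) {
    component$rejected <- TRUE
    component$assigned_h_ppm <- NA_real_
  } else {
    component$rejected <- FALSE
    component$assigned_h_ppm <- region$subgrid$axis_h[j]
  }
  component
}
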