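#' Construct a calibrated 2D-HSQC spectrum grid
#'
#' A `spectrum_grid` holds a processed (frequency-domain, real-valued)
#' 2D-1H,13C-HSQC spectrum: an intensity matrix whose rows are indexed by
#' the 13C chemical-shift axis and whose columns are indexed by the 1H
#' chemical-shift axis.  Axes are stored in ppm, descending left to right
#' (1H) and top to bottom (13C), the usual NMR display convention.  All
#' package operations address the grid by ppm value, never by raw index.
#'
#' @param intensities Numeric matrix, rows = 13C points, columns = 1H
#'   points, arbitrary intensity units.
#' @param axis_h Numeric vector of per-column 1H chemical shifts (ppm),
#'   strictly monotonic and uniformly spaced.
#' @param axis_c Numeric vector of per-row 13C chemical shifts (ppm),
#'   strictly monotonic and uniformly spaced.
#' @param freq_h,freq_c Spectrometer carrier frequencies for 1H and 13C in
#'   MHz; `freq_h > freq_c > 0`.
#' @param j_scaling Apparent-J scaling factor applied during acquisition
#'   (integer >= 1; 1 means no splitting enhancement).
#' @param provenance Free-text origin metadata.
#'
#' @details Axes supplied in ascending order are flipped (together with
#'   the corresponding matrix dimension) so that stored axes are always
#'   descending.
#'
#' @return An object of class `spectrum_grid`.
#' @seealso [read_spectrum()], [extract_region()]
#' @export
spectrum_grid <- function(intensities, axis_h, axis_c, freq_h, freq_c,
                          j_scaling = 1L, provenance = "") {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("intensities must be a numeric matrix", call. = FALSE)
  }
  if (length(axis_c) != nrow(intensities) ||
      length(axis_h) != ncol(intensities)) {
    stop("axis lengths must equal matrix dimensions", call. = FALSE)
  }
  for (ax in list(axis_h, axis_c)) {
    if (length(ax) == 0L) stop("empty axis", call. = FALSE)
    d <- diff(ax)
    if (length(ax) >= 2L && !(all(d > 0) || all(d < 0))) {
      stop("axes must be strictly monotonic", call. = FALSE)
    }
  }
  if (length(axis_h) >= 2L && diff(axis_h)[1] > 0) {
    axis_h <- rev(axis_h)
    intensities <- intensities[, rev(seq_len(ncol(intensities))), drop = FALSE]
  }
  if (length(axis_c) >= 2L && diff(axis_c)[1] > 0) {
    axis_c <- rev(axis_c)
    intensities <- intensities[rev(seq_len(nrow(intensities))), , drop = FALSE]
  }
  if (!(is.numeric(freq_h) && is.numeric(freq_c) &&
        freq_h > freq_c && freq_c > 0)) {
    stop("carrier frequencies must satisfy freq_h > freq_c > 0", call. = FALSE)
  }
  j_scaling <- as.integer(j_scaling)
  if (is.na(j_scaling) || j_scaling < 1L) {
    stop("j_scaling must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(intensities = intensities,
         axis_h = as.numeric(axis_h), axis_c = as.numeric(axis_c),
         freq_h = as.numeric(freq_h), freq_c = as.numeric(freq_c),
         j_scaling = j_scaling, provenance = as.character(provenance)[1]),
    class = "spectrum_grid")
}

#' @export
print.spectrum_grid <- function(x, ...) {
  cat(sprintf(
    "<spectrum_grid> %d (13C) x %d (1H) points\n  1H  %.4f .. %.4f ppm @ %.2f MHz\n  13C %.3f .. %.3f ppm @ %.2f MHz\n  j_scaling %d%s\n",
    nrow(x$intensities), ncol(x$intensities),
    max(x$axis_h), min(x$axis_h), x$freq_h,
    max(x$axis_c), min(x$axis_c), x$freq_c,
    x$j_scaling,
    if (nzchar(x$provenance)) paste0("  [", x$provenance, "]") else ""))
  invisible(x)
}

#' Extract a library-centred search region from a spectrum
#'
#' Restricts the spectrum to the closed windows
#' `[center - half_width, center + half_width]` in both dimensions, the
#' search space used before unmixing.  Windows that partially overlap the
#' spectrum are clipped at the spectrum edge; a window entirely outside
#' the spectral width in either dimension is an error.
#'
#' @param grid A [spectrum_grid()].
#' @param center_h,center_c Window centres (typically library shifts), ppm.
#' @param half_width_h,half_width_c Half widths, ppm (defaults 0.15 and
#'   3.0, the standard search half-widths).
#' @return An object of class `spectrum_region`: a list with the restricted
#'   `subgrid` ([spectrum_grid()]) plus the centring metadata.
#' @export
extract_region <- function(grid, center_h, center_c,
                           half_width_h = 0.15, half_width_c = 3.0) {
  stopifnot(inherits(grid, "spectrum_grid"),
            half_width_h > 0, half_width_c > 0)
  keep_h <- which(grid$axis_h >= center_h - half_width_h &
                  grid$axis_h <= center_h + half_width_h)
  keep_c <- which(grid$axis_c >= center_c - half_width_c &
                  grid$axis_c <= center_c + half_width_c)
  if (length(keep_h) == 0L || length(keep_c) == 0L) {
    stop("resonance outside spectral width", call. = FALSE)
  }
  sub <- spectrum_grid(grid$intensities[keep_c, keep_h, drop = FALSE],
                       grid$axis_h[keep_h], grid$axis_c[keep_c],
                       grid$freq_h, grid$freq_c, grid$j_scaling,
                       grid$provenance)
  structure(list(subgrid = sub,
                 center_h = center_h, center_c = center_c,
                 half_width_h = half_width_h, half_width_c = half_width_c),
            class = "spectrum_region")
}

#' @export
print.spectrum_region <- function(x, ...) {
  cat(sprintf("<spectrum_region> centred at %.3f ppm (1H), %.2f ppm (13C)\n",
              x$center_h, x$center_c))
  print(x$subgrid)
  invisible(x)
}

#' Extract the 13C column nearest a 1H chemical shift
#'
#' Returns the 1D 13C sub-spectrum (one matrix column) of a region whose
#' 1H axis value is nearest to `h_ppm`.  When `h_ppm` falls exactly midway
#' between two columns the lower column index (higher ppm on the stored
#' descending axis) wins.
#'
#' @param region A [extract_region()] result.
#' @param h_ppm Requested 1H position, ppm; must lie within the region's
#'   1H axis range.
#' @return Numeric intensity vector over the region's 13C axis, with
#'   attributes `h_ppm` (the axis value actually used) and `column` (its
#'   index).
#' @export
column_at <- function(region, h_ppm) {
  stopifnot(inherits(region, "spectrum_region"))
  ax <- region$subgrid$axis_h
  if (h_ppm > max(ax) || h_ppm < min(ax)) {
    stop("h_ppm outside region", call. = FALSE)
  }
  j <- nearest_index(ax, h_ppm)
  out <- region$subgrid$intensities[, j]
  attr(out, "h_ppm") <- ax[j]
  attr(out, "column") <- j
  out
}
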