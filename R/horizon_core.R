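# Numeric tolerance for deciding that a deviation sits exactly on a band
# boundary k * thickness (floating-point guard for the ceil convention).
BOUNDARY_TOL <- 1e-9

#' Specify the horizon transform
#'
#' The horizon transform folds a time series into `n_bands` equal-width
#' bands above and below an **origin** (the "horizon"). The origin is the
#' base of the first positive band, where the y-axis value is 0; by default
#' it is the median of the taxon's observed values. The **band thickness**
#' is the y-scale height of one band; by default it is the maximum absolute
#' deviation from the origin divided by `n_bands`, so the most extreme point
#' exactly fills the outermost band. Fixing the origin and/or thickness puts
#' all facets on a common absolute scale, which emphasizes abundant taxa;
#' the per-series default instead emphasizes proportional change, letting
#' taxa whose medians differ by orders of magnitude share one figure.
#'
#' @param origin Fixed origin in percent relative abundance, or `NULL`
#'   (default) for the per-series median of observed values.
#' @param band_thickness Fixed band thickness in percent per band, or `NULL`
#'   (default) for automatic scaling to the extreme deviation.
#' @param n_bands Number of bands on each side of the origin; default 4.
#'   More bands distinguish values more finely and emphasize the extremes;
#'   fewer bands de-emphasize them.
#' @param fixed_scale If `TRUE`, automatic thickness is computed from the
#'   deviations pooled over all series in the panel set (one shared y
#'   scale) instead of per series.
#' @return An object of class `horizon_spec`.
#' @export
horizon_spec <- function(origin = NULL, band_thickness = NULL, n_bands = 4L,
                         fixed_scale = FALSE) {
  if (!is.null(origin) && (!is.numeric(origin) || length(origin) != 1L))
    stop("origin must be a single number (percent)", call. = FALSE)
  if (!is.null(band_thickness) &&
      (!is.numeric(band_thickness) || length(band_thickness) != 1L ||
       band_thickness <= 0))
    stop("band_thickness must be a single positive number", call. = FALSE)
  n_bands <- as.integer(n_bands)
  if (is.na(n_bands) || n_bands < 1L)
    stop("n_bands must be a positive integer", call. = FALSE)
  structure(
    list(origin_mode = if (is.null(origin)) "median" else "fixed",
         fixed_origin = origin,
         thickness_mode = if (is.null(band_thickness)) "auto" else "fixed",
         fixed_thickness = band_thickness,
         n_bands = n_bands,
         scale_scope = if (isTRUE(fixed_scale)) "global" else "per_series"),
    class = "horizon_spec"
  )
}

#' Origin of one series
#'
#' The median of the observed values (even counts average the two middle
#' order statistics), or the fixed origin from the spec. Computed on
#' observed points only, before any interpolation, so interpolation density
#' cannot shift it.
#'
#' @param values Observed percent values of one series.
#' @param spec A [horizon_spec()].
#' @return Origin in percent.
#' @export
compute_origin <- function(values, spec) {
  stopifnot(inherits(spec, "horizon_spec"))
  if (length(values) == 0L)
    stop("origin requires at least one observed value", call. = FALSE)
  if (spec$origin_mode == "fixed") spec$fixed_origin
  else stats::median(values)
}

#' Band thickness of one series
#'
#' Automatic thickness divides the extreme absolute deviation from the
#' origin by the band count, so bands slice the deviation range into
#' `n_bands` equal widths and the extreme point saturates the outermost
#' band. Under a global scale the maximum is taken over pooled deviations
#' from the whole panel set (`pooled_deviations`). A constant series (zero
#' extreme deviation) gets a sentinel thickness of 1 so downstream fills are
#' all zero instead of dividing by zero; such series are flagged degenerate
#' by [build_horizon()].
#'
#' @param values Observed percent values of one series.
#' @param origin Origin in percent.
#' @param spec A [horizon_spec()].
#' @param pooled_deviations Optional numeric vector of signed deviations
#'   pooled over all panel series, used when `spec$scale_scope == "global"`.
#' @return Thickness in percent per band.
#' @export
compute_band_thickness <- function(values, origin, spec,
                                   pooled_deviations = NULL) {
  stopifnot(inherits(spec, "horizon_spec"))
  if (spec$thickness_mode == "fixed") return(spec$fixed_thickness)
  if (length(values) == 0L)
    stop("thickness requires at least one observed value", call. = FALSE)
  devs <- if (spec$scale_scope == "global" && !is.null(pooled_deviations))
    pooled_deviations else values - origin
  extreme <- max(abs(devs))
  if (extreme == 0) 1 else extreme / spec$n_bands
}

#' Signed band index of a deviation
#'
#' 0 for a zero deviation; otherwise
#' `sign(d) * min(ceiling(|d| / thickness), n_bands)`. A deviation landing
#' exactly on a band boundary `k * thickness` belongs to band `k` (the lower
#' band), so the maximal auto-scaled point lands in band `n_bands` rather
#' than overflowing. Deviations beyond `n_bands * thickness` clamp to the
#' outermost band.
#'
#' @param deviation Signed percent deviation(s) from the origin.
#' @param thickness Positive band thickness, percent.
#' @param n_bands Number of bands per side.
#' @return Signed integer(s) in `[-n_bands, n_bands]`.
#' @export
band_index <- function(deviation, thickness, n_bands) {
  if (thickness <= 0) stop("thickness must be positive", call. = FALSE)
  q <- abs(deviation) / thickness
  qr <- round(q)
  k <- ifelse(abs(q - qr) <= BOUNDARY_TOL, qr, ceiling(q))
  as.integer(sign(deviation) * pmin(k, n_bands))
}

#' Per-band fill heights of a deviation
#'
#' Band `k` (counted outward from the origin) is filled by the overflow of
#' `|deviation|` into its slice:
#' `fill_k = clamp(|d| - (k - 1) * thickness, 0, thickness)`. Fills are
#' monotone non-increasing in `k`, their sum is
#' `min(|d|, n_bands * thickness)`, and deviations beyond the outermost band
#' saturate every band at full thickness. The sign records whether the point
#' lies above (+1), below (-1), or on (0) the origin; negative fills are
#' drawn mirrored upward in the red family.
#'
#' @inheritParams band_index
#' @param deviation A single signed percent deviation.
#' @return A list with `fills` (numeric `n_bands` vector in
#'   `[0, thickness]`) and `sign` (-1, 0, or +1).
#' @export
band_fills <- function(deviation, thickness, n_bands) {
  if (thickness <= 0) stop("thickness must be positive", call. = FALSE)
  k <- seq_len(n_bands)
  fills <- pmin(pmax(abs(deviation) - (k - 1) * thickness, 0), thickness)
  list(fills = fills, sign = sign(deviation))
}

#' Apply the horizon transform to one series
#'
#' Computes the origin and band thickness per the spec (on the series'
#' observed points only), then the signed deviation, band index, and band
#' fill vector at every point, observed and interpolated alike.
#'
#' @param series A [taxon_series()] (typically after
#'   [interpolate_regular()]).
#' @param spec A [horizon_spec()].
#' @param panel_context Optional list of [taxon_series()] spanning the whole
#'   panel set; required for pooled automatic thickness when
#'   `spec$fixed_scale` is set. Pass the pre-interpolation series here for
#'   the same reason `calibration` exists.
#' @param calibration Optional [taxon_series()] whose observed values define
#'   the origin and automatic thickness; defaults to `series` itself. Pass
#'   the pre-interpolation series so that regularization (which drops
#'   off-grid interior observations and adds interpolated points) cannot
#'   shift the median or the extreme deviation.
#' @return An object of class `horizon_bands` with fields `series`,
#'   `origin`, `thickness`, `n_bands`, `deviations`, `band_index`, `fills`
#'   (points x bands matrix), `sign`, and `degenerate` (constant series
#'   flag).
#' @export
build_horizon <- function(series, spec, panel_context = NULL,
                          calibration = NULL) {
  stopifnot(inherits(series, "taxon_series"), inherits(spec, "horizon_spec"))
  if (is.null(calibration)) calibration <- series
  obs_values <- calibration$values[calibration$observed]
  if (length(obs_values) == 0L)
    stop("series has no observed points", call. = FALSE)
  origin <- compute_origin(obs_values, spec)

  pooled <- NULL
  if (spec$scale_scope == "global" && spec$thickness_mode == "auto") {
    ctx <- if (is.null(panel_context)) list(series) else panel_context
    pooled <- unlist(lapply(ctx, function(s) {
      ov <- s$values[s$observed]
      ov - compute_origin(ov, spec)
    }))
  }
  thickness <- compute_band_thickness(obs_values, origin, spec,
                                      pooled_deviations = pooled)
  degenerate <- spec$thickness_mode == "auto" &&
    max(abs((if (is.null(pooled)) obs_values - origin else pooled))) == 0
  if (degenerate)
    warning("constant series '", series$taxon_id,
            "': all horizon fills are zero", call. = FALSE)

  dev <- series$values - origin
  idx <- band_index(dev, thickness, spec$n_bands)
  fills <- t(vapply(dev, function(d)
    band_fills(d, thickness, spec$n_bands)$fills,
    numeric(spec$n_bands)))
  structure(
    list(series = series, origin = origin, thickness = thickness,
         n_bands = spec$n_bands, deviations = dev, band_index = idx,
         fills = fills, sign = sign(dev), degenerate = degenerate),
    class = "horizon_bands"
  )
}

#' @export
print.horizon_bands <- function(x, ...) {
  cat(sprintf(
    "<horizon_bands> %s / %s: origin %.4g, thickness %.4g, %d bands, %d points%s\n",
    x$series$taxon_id, x$series$subject_id, x$origin, x$thickness,
    x$n_bands, length(x$deviations),
    if (x$degenerate) " (degenerate: constant series)" else ""))
  invisible(x)
}
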