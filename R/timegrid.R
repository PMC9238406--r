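#' Convert collection dates to day offsets
#'
#' Day offsets are integer differences from the subject's first (earliest)
#' selected sample, so the first offset is always 0. Sub-day sampling is out
#' of scope: times are calendar days.
#'
#' @param dates A `Date` vector, sorted ascending, unique within a subject.
#' @return Integer day offsets.
#' @export
dates_to_days <- function(dates) {
  stopifnot(inherits(dates, "Date"))
  if (length(dates) == 0L) stop("no dates given", call. = FALSE)
  if (is.unsorted(dates, strictly = TRUE) && length(dates) > 1L)
    stop("dates must be strictly increasing within a subject", call. = FALSE)
  as.integer(dates - dates[1L])
}

#' Assign segment ids by breaking a series at large gaps
#'
#' A new segment starts after any consecutive gap strictly greater than
#' `max_gap` days; a gap of exactly `max_gap` is not a break. Segment ids
#' are 1, 2, ... in time order.
#'
#' @param times Strictly increasing numeric day offsets.
#' @param max_gap Maximum tolerated gap, days.
#' @return Integer segment id per time point.
#' @export
split_segments <- function(times, max_gap) {
  if (length(times) == 0L) return(integer(0L))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (!is.numeric(max_gap) || max_gap <= 0)
    stop("max_gap must be positive", call. = FALSE)
  breaks <- c(FALSE, diff(times) > max_gap)
  as.integer(cumsum(breaks) + 1L)
}

#' Specify the interpolation grid
#'
#' `regular_interval` is the spacing (days) at which missing data may be
#' interpolated; `max_gap` is the largest span between consecutive samples
#' that interpolation is allowed to cross -- longer gaps become axis breaks
#' instead of interpolated points. Leaving both `NULL` disables
#' regularization (the mode for studies whose samples are already aligned).
#'
#' @param regular_interval Positive number of days, or `NULL`.
#' @param max_gap Positive number of days, `>= regular_interval`, or `NULL`
#'   (defaults to `regular_interval` when only that is given... see Details).
#' @details If `regular_interval` is given without `max_gap`, every gap is
#'   interpolated across (`max_gap = Inf`). If `max_gap` is given without
#'   `regular_interval`, series are split into segments but not resampled.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(regular_interval = NULL, max_gap = NULL) {
  if (!is.null(regular_interval)) {
    if (!is.numeric(regular_interval) || regular_interval <= 0)
      stop("regular_interval must be a positive number of days",
           call. = FALSE)
    if (is.null(max_gap)) max_gap <- Inf
  }
  if (!is.null(max_gap)) {
    if (!is.numeric(max_gap) || max_gap <= 0)
      stop("max_gap must be a positive number of days", call. = FALSE)
    if (!is.null(regular_interval) && max_gap < regular_interval)
      stop("max_gap must be >= regular_interval", call. = FALSE)
  }
  structure(
    list(regular_interval = regular_interval, max_gap = max_gap,
         enabled = !is.null(regular_interval)),
    class = "grid_spec"
  )
}

#' Construct a single-taxon, single-subject time series
#'
#' @param taxon_id,subject_id Identifiers.
#' @param times Strictly increasing integer day offsets, first equal to 0
#'   for a fully observed series.
#' @param values Percent relative abundances, one per time point.
#' @param observed Logical per point; `FALSE` marks interpolated points.
#' @param segment_id Integer per point, non-decreasing; defaults to a single
#'   segment.
#' @return An object of class `taxon_series`.
#' @export
taxon_series <- function(taxon_id, subject_id, times, values,
                         observed = rep(TRUE, length(times)),
                         segment_id = rep(1L, length(times))) {
  n <- length(times)
  if (n == 0L) stop("a series needs at least one point", call. = FALSE)
  if (length(values) != n || length(observed) != n ||
      length(segment_id) != n)
    stop("times, values, observed, segment_id lengths differ", call. = FALSE)
  if (n > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(values < 0) || any(!is.finite(values)))
    stop("values must be non-negative and finite", call. = FALSE)
  if (any(diff(segment_id) < 0))
    stop("segment ids must be non-decreasing in time", call. = FALSE)
  structure(
    list(taxon_id = as.character(taxon_id),
         subject_id = as.character(subject_id),
         times = as.numeric(times), values = as.numeric(values),
         observed = as.logical(observed),
         segment_id = as.integer(segment_id)),
    class = "taxon_series"
  )
}

#' @export
print.taxon_series <- function(x, ...) {
  cat(sprintf(
    "<taxon_series> %s / %s: %d points (%d observed), %d segment(s), days %g..%g\n",
    x$taxon_id, x$subject_id, length(x$times), sum(x$observed),
    max(x$segment_id), min(x$times), max(x$times)))
  invisible(x)
}

#' Build the observed series of one taxon in one subject
#'
#' Extracts the taxon's percent abundances at the subject's date-ordered
#' samples, converts dates to day offsets, and assigns gap segments per the
#' grid spec (one segment when regularization is disabled or `max_gap` is
#' unset).
#'
#' @param table An [abundance_table()] in percent units.
#' @param subject_metadata Date-ordered metadata rows of one subject (as
#'   returned by [select_samples()] for a single subject).
#' @param taxon_id Taxon to extract.
#' @param grid A [grid_spec()].
#' @return A [taxon_series()] of observed points.
#' @export
build_series <- function(table, subject_metadata, taxon_id,
                         grid = grid_spec()) {
  stopifnot(inherits(table, "abundance_table"), inherits(grid, "grid_spec"))
  if (table$units != "percent")
    stop("build_series requires a percent-normalized table", call. = FALSE)
  subj <- unique(subject_metadata$subject)
  if (length(subj) != 1L)
    stop("subject_metadata must contain exactly one subject", call. = FALSE)
  if (!taxon_id %in% table$taxon_ids)
    stop("unknown taxon id: ", taxon_id, call. = FALSE)
  missing_samples <- setdiff(subject_metadata$sample, table$sample_ids)
  if (length(missing_samples) > 0L)
    stop("sample(s) not in table: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  times <- dates_to_days(subject_metadata$collection_date)
  values <- table$values[taxon_id, subject_metadata$sample]
  seg <- if (!is.null(grid$max_gap) && is.finite(grid$max_gap))
    split_segments(times, grid$max_gap) else rep(1L, length(times))
  taxon_series(taxon_id, subj, times, unname(values), segment_id = seg)
}

#' Resample a series onto a regular grid by linear interpolation
#'
#' Within each gap segment, output points are placed at
#' `segment_start + k * regular_interval` for `k = 0, 1, ...`; the segment's
#' final observed point is appended when it falls off-grid, so no data range
#' is truncated. Values at non-observed grid points are linear interpolations
#' of the bracketing observed points; observed points coinciding with grid
#' points keep their exact values and stay flagged observed. Off-grid
#' interior observations are dropped (the output *is* the regularized
#' series). No point is ever created between segments or beyond the series
#' ends.
#'
#' With the grid disabled the series passes through unchanged. The operation
#' is idempotent: re-running it on its own output with the same grid is the
#' identity.
#'
#' @param series A [taxon_series()] whose segments were assigned with the
#'   same `max_gap` (see [build_series()]).
#' @param grid A [grid_spec()].
#' @return A [taxon_series()].
#' @export
interpolate_regular <- function(series, grid) {
  stopifnot(inherits(series, "taxon_series"), inherits(grid, "grid_spec"))
  if (!grid$enabled) return(series)
  interval <- grid$regular_interval
  if (length(series$times) < 2L) return(series)

  out_t <- numeric(0L); out_v <- numeric(0L)
  out_obs <- logical(0L); out_seg <- integer(0L)
  for (seg in unique(series$segment_id)) {
    in_seg <- series$segment_id == seg
    t <- series$times[in_seg]
    v <- series$values[in_seg]
    obs <- series$observed[in_seg]
    if (length(t) == 1L) {
      g <- t; gv <- v; gobs <- obs
    } else {
      g <- seq(t[1L], t[length(t)], by = interval)
      if (g[length(g)] < t[length(t)]) g <- c(g, t[length(t)])
      gv <- stats::approx(t, v, xout = g, method = "linear")$y
      on_knot <- g %in% t
      gv[on_knot] <- v[match(g[on_knot], t)]  # exact pass-through
      # a grid point keeps the flag of the input point it coincides with
      # (so re-regularizing never promotes interpolated points to observed)
      gobs <- rep(FALSE, length(g))
      gobs[on_knot] <- obs[match(g[on_knot], t)]
    }
    out_t <- c(out_t, g); out_v <- c(out_v, gv)
    out_obs <- c(out_obs, gobs); out_seg <- c(out_seg, rep(seg, length(g)))
  }
  taxon_series(series$taxon_id, series$subject_id, out_t, out_v,
               observed = out_obs, segment_id = out_seg)
}
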