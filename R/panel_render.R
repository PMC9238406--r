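horizon_palette <- function(n_bands) {
  list(
    positive = grDevices::colorRampPalette(c("#C6DBEF", "#08306B"))(n_bands),
    negative = grDevices::colorRampPalette(c("#FCBBA1", "#67000D"))(n_bands)
  )
}

#' Assemble horizon bands into an ordered, faceted panel set
#'
#' Panels share a common time axis spanning the union of the series ranges.
#' Axis breaks are derived per panel from the series' gap segments (the span
#' between the last point of one segment and the first point of the next).
#' All panels must share a band count so the figure can carry one legend.
#'
#' @param bands List of [build_horizon()] results, in facet order.
#' @param labels Character vector of display labels, one per panel, unique.
#' @return An object of class `panel_set`.
#' @export
assemble_panels <- function(bands, labels) {
  if (length(bands) == 0L) stop("no panels to assemble", call. = FALSE)
  if (length(labels) != length(bands))
    stop("need exactly one label per panel", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate facet label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  ok <- vapply(bands, inherits, logical(1L), "horizon_bands")
  if (!all(ok)) stop("bands must be horizon_bands objects", call. = FALSE)
  n_bands <- unique(vapply(bands, function(b) b$n_bands, integer(1L)))
  if (length(n_bands) != 1L)
    stop("panels have mixed band counts (", paste(n_bands, collapse = ", "),
         "); all panels must share n_bands", call. = FALSE)

  axis_breaks <- lapply(bands, function(b) {
    s <- b$series
    segs <- unique(s$segment_id)
    if (length(segs) < 2L) return(matrix(numeric(0L), ncol = 2L))
    ends <- vapply(segs, function(g) max(s$times[s$segment_id == g]),
                   numeric(1L))
    starts <- vapply(segs, function(g) min(s$times[s$segment_id == g]),
                     numeric(1L))
    cbind(gap_start = ends[-length(ends)], gap_end = starts[-1L])
  })
  all_times <- unlist(lapply(bands, function(b) b$series$times))
  structure(
    list(panels = bands, facet_labels = as.character(labels),
         axis_breaks = axis_breaks,
         time_range = range(all_times),
         n_bands = n_bands,
         colors = horizon_palette(n_bands)),
    class = "panel_set"
  )
}

#' @export
print.panel_set <- function(x, ...) {
  cat(sprintf("<panel_set> %d panel(s), %d bands, days %g..%g\n",
              length(x$panels), x$n_bands, x$time_range[1L],
              x$time_range[2L]))
  cat("  facets:", paste(x$facet_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Band geometry of a panel set as a tidy table
#'
#' The machine-readable surface of the figure, decoupled from pixels: one
#' row per (panel, time point, band), with the signed band fill height in
#' data units (percent). This is what `--geometry-out` writes from the CLI.
#'
#' @param panel_set A [assemble_panels()] result.
#' @return A tibble with columns `panel`, `time`, `segment`, `observed`,
#'   `band`, `sign`, `fill`.
#' @export
horizon_geometry <- function(panel_set) {
  stopifnot(inherits(panel_set, "panel_set"))
  rows <- lapply(seq_along(panel_set$panels), function(i) {
    b <- panel_set$panels[[i]]
    s <- b$series
    n <- length(s$times)
    tibble::tibble(
      panel = panel_set$facet_labels[i],
      time = rep(s$times, each = b$n_bands),
      segment = rep(s$segment_id, each = b$n_bands),
      observed = rep(s$observed, each = b$n_bands),
      band = rep(seq_len(b$n_bands), times = n),
      sign = rep(b$sign, each = b$n_bands),
      fill = as.numeric(t(b$fills))
    )
  })
  dplyr::bind_rows(rows)
}

#' Write the band geometry to TSV
#'
#' @param panel_set A [assemble_panels()] result.
#' @param path Output TSV path.
#' @export
write_geometry <- function(panel_set, path) {
  geo <- horizon_geometry(panel_set)
  # fixed-format numbers so repeated runs are byte-identical
  geo$time <- sprintf("%.6g", geo$time)
  geo$fill <- sprintf("%.10g", geo$fill)
  readr::write_tsv(geo, path, progress = FALSE)
  invisible(path)
}

# Refine one segment's (time, deviation) polyline: insert the zero crossing
# wherever the deviation changes sign so band polygons close exactly at the
# origin.
refine_segment <- function(times, dev) {
  if (length(times) < 2L) return(list(t = times, d = dev))
  t_out <- times[1L]; d_out <- dev[1L]
  for (i in seq_len(length(times) - 1L)) {
    d1 <- dev[i]; d2 <- dev[i + 1L]
    if (d1 * d2 < 0) {
      tc <- times[i] + (times[i + 1L] - times[i]) * d1 / (d1 - d2)
      t_out <- c(t_out, tc); d_out <- c(d_out, 0)
    }
    t_out <- c(t_out, times[i + 1L]); d_out <- c(d_out, d2)
  }
  list(t = t_out, d = d_out)
}

# Long data frame of ribbon heights for plotting: one row per refined point
# per band per sign family, heights zero where the other sign is active.
plot_frame <- function(panel_set) {
  out <- list()
  for (i in seq_along(panel_set$panels)) {
    b <- panel_set$panels[[i]]
    s <- b$series
    for (seg in unique(s$segment_id)) {
      in_seg <- s$segment_id == seg
      ref <- refine_segment(s$times[in_seg], b$deviations[in_seg])
      for (k in seq_len(b$n_bands)) {
        hk <- pmin(pmax(abs(ref$d) - (k - 1) * b$thickness, 0), b$thickness)
        for (sgn in c(1, -1)) {
          h <- ifelse(sign(ref$d) == sgn, hk, 0)
          if (all(h == 0)) next
          out[[length(out) + 1L]] <- tibble::tibble(
            panel = panel_set$facet_labels[i], segment = seg,
            band = k, sign = sgn, time = ref$t, height = h,
            thickness = b$thickness)
        }
      }
    }
  }
  if (length(out) == 0L) return(tibble::tibble(
    panel = character(), segment = integer(), band = integer(),
    sign = numeric(), time = numeric(), height = numeric(),
    thickness = numeric()))
  dplyr::bind_rows(out)
}

#' Build a ggplot of a panel set
#'
#' One facet per panel, fixed facet height of one band thickness in data
#' units; band `k` is drawn as a ribbon of height `fill_k` from the facet
#' floor, deeper bands on top, blues above the origin and reds (mirrored
#' upward) below it. Gap segments leave blank spans.
#'
#' @param panel_set A [assemble_panels()] result.
#' @return A ggplot object.
#' @export
horizon_ggplot <- function(panel_set) {
  stopifnot(inherits(panel_set, "panel_set"))
  df <- plot_frame(panel_set)
  nb <- panel_set$n_bands
  df$panel <- factor(df$panel, levels = panel_set$facet_labels)
  # normalize heights so every facet spans [0, 1] regardless of thickness
  df$h01 <- ifelse(df$thickness > 0, df$height / df$thickness, 0)
  df$level <- factor(df$sign * df$band,
                     levels = c(seq(-nb, -1L), seq_len(nb)))
  pal <- c(rev(panel_set$colors$negative), panel_set$colors$positive)
  names(pal) <- c(seq(-nb, -1L), seq_len(nb))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, ymin = 0,
                                   ymax = .data$h01,
                                   group = interaction(.data$segment,
                                                       .data$band,
                                                       .data$sign),
                                   fill = .data$level)) +
    ggplot2::geom_ribbon() +
    ggplot2::scale_fill_manual(values = pal, name = "band", drop = FALSE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), switch = "y") +
    ggplot2::scale_y_continuous(breaks = NULL, expand = c(0, 0)) +
    ggplot2::coord_cartesian(xlim = panel_set$time_range) +
    ggplot2::labs(x = "day", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text.y.left = ggplot2::element_text(angle = 0),
                   panel.spacing = ggplot2::unit(2, "pt"))
}

fmt_px <- function(x) sprintf("%.3f", x)

svg_polygon <- function(xs, ys, fill) {
  pts <- paste(paste0(fmt_px(xs), ",", fmt_px(ys)), collapse = " ")
  sprintf('<polygon points="%s" fill="%s" stroke="none"/>', pts, fill)
}

# Deterministic SVG writer: fixed layout, fixed number formatting, one
# <g class="facet"> per panel. Byte-identical output for identical input.
render_svg <- function(panel_set, path, width = 900, height = NULL) {
  nb <- panel_set$n_bands
  npan <- length(panel_set$panels)
  facet_h <- 60; facet_gap <- 8
  m_left <- 140; m_right <- 20; m_top <- 20; m_bottom <- 70
  if (is.null(height))
    height <- m_top + npan * facet_h + (npan - 1L) * facet_gap + m_bottom
  plot_w <- width - m_left - m_right
  if (plot_w <= 0 || height <= m_top + m_bottom)
    stop("figure has zero drawing area", call. = FALSE)
  tr <- panel_set$time_range
  span <- if (diff(tr) > 0) diff(tr) else 1
  x_of <- function(t) m_left + (t - tr[1L]) / span * plot_w

  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    round(width), round(height), round(width), round(height)),
    '<rect width="100%" height="100%" fill="white"/>')

  for (i in seq_len(npan)) {
    b <- panel_set$panels[[i]]
    s <- b$series
    top <- m_top + (i - 1L) * (facet_h + facet_gap)
    floor_y <- top + facet_h
    g <- c(sprintf('<g class="facet" id="facet-%d">', i),
           sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="#F2F2F2"/>',
                   fmt_px(m_left), fmt_px(top), fmt_px(plot_w),
                   fmt_px(facet_h)))
    for (seg in unique(s$segment_id)) {
      in_seg <- s$segment_id == seg
      ref <- refine_segment(s$times[in_seg], b$deviations[in_seg])
      if (length(ref$t) < 2L) next
      for (k in seq_len(nb)) {
        hk <- pmin(pmax(abs(ref$d) - (k - 1L) * b$thickness, 0),
                   b$thickness)
        for (sgn in c(1, -1)) {
          h <- ifelse(sign(ref$d) == sgn, hk, 0)
          if (all(h == 0)) next
          h01 <- if (b$thickness > 0) h / b$thickness else h * 0
          xs <- c(x_of(ref$t[1L]), x_of(ref$t), x_of(ref$t[length(ref$t)]))
          ys <- c(floor_y, floor_y - h01 * facet_h, floor_y)
          col <- if (sgn > 0) panel_set$colors$positive[k]
                 else panel_set$colors$negative[k]
          g <- c(g, svg_polygon(xs, ys, col))
        }
      }
    }
    # axis-break markers: dashed line at the middle of each gap
    brk <- panel_set$axis_breaks[[i]]
    if (nrow(brk) > 0L) for (j in seq_len(nrow(brk))) {
      xm <- x_of((brk[j, 1L] + brk[j, 2L]) / 2)
      g <- c(g, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#888888" stroke-dasharray="4,3"/>',
        fmt_px(xm), fmt_px(top), fmt_px(xm), fmt_px(floor_y)))
    }
    g <- c(g, sprintf(
      '<text x="%s" y="%s" font-family="sans-serif" font-size="12" text-anchor="end">%s</text>',
      fmt_px(m_left - 8), fmt_px(top + facet_h / 2 + 4),
      xml_escape(panel_set$facet_labels[i])),
      '</g>')
    lines <- c(lines, g)
  }

  # time axis
  axis_y <- m_top + npan * facet_h + (npan - 1L) * facet_gap + 5
  ticks <- pretty(tr, n = 6)
  ticks <- ticks[ticks >= tr[1L] & ticks <= tr[2L]]
  ax <- c('<g class="axis">',
          sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
                  fmt_px(m_left), fmt_px(axis_y), fmt_px(m_left + plot_w),
                  fmt_px(axis_y)))
  for (tk in ticks) ax <- c(ax, sprintf(
    '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/><text x="%s" y="%s" font-family="sans-serif" font-size="10" text-anchor="middle">%s</text>',
    fmt_px(x_of(tk)), fmt_px(axis_y), fmt_px(x_of(tk)), fmt_px(axis_y + 4),
    fmt_px(x_of(tk)), fmt_px(axis_y + 16), format(tk)))
  ax <- c(ax, sprintf(
    '<text x="%s" y="%s" font-family="sans-serif" font-size="11" text-anchor="middle">day</text>',
    fmt_px(m_left + plot_w / 2), fmt_px(axis_y + 32)), '</g>')
  lines <- c(lines, ax)

  # legend: one swatch per band level, reds then blues
  leg_y <- axis_y + 40
  sw <- 14
  levels_neg <- rev(seq_len(nb)); levels_pos <- seq_len(nb)
  leg <- c('<g class="legend">')
  x0 <- m_left
  for (k in levels_neg) {
    leg <- c(leg, sprintf(
      '<rect x="%s" y="%s" width="%d" height="%d" fill="%s"/><text x="%s" y="%s" font-family="sans-serif" font-size="9" text-anchor="middle">-%d</text>',
      fmt_px(x0), fmt_px(leg_y), sw, sw, panel_set$colors$negative[k],
      fmt_px(x0 + sw / 2), fmt_px(leg_y + sw + 10), k))
    x0 <- x0 + sw + 4
  }
  x0 <- x0 + 10
  for (k in levels_pos) {
    leg <- c(leg, sprintf(
      '<rect x="%s" y="%s" width="%d" height="%d" fill="%s"/><text x="%s" y="%s" font-family="sans-serif" font-size="9" text-anchor="middle">+%d</text>',
      fmt_px(x0), fmt_px(leg_y), sw, sw, panel_set$colors$positive[k],
      fmt_px(x0 + sw / 2), fmt_px(leg_y + sw + 10), k))
    x0 <- x0 + sw + 4
  }
  leg <- c(leg, '</g>')
  lines <- c(lines, leg, '</svg>')
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a panel set to an image file
#'
#' SVG output goes through the package's own deterministic vector writer
#' (byte-identical across runs, one `<g class="facet">` group per panel, an
#' axis-break marker per gap, and a legend of `n_bands` blue and `n_bands`
#' red levels). PNG and PDF output render the [horizon_ggplot()] figure
#' through the standard graphics devices.
#'
#' @param panel_set A [assemble_panels()] result.
#' @param path Output file; the format is inferred from its extension unless
#'   `format` is given.
#' @param format One of `"svg"`, `"png"`, `"pdf"`, or `NULL` to infer.
#' @param width,height Figure size. For SVG, pixels (`height = NULL` sizes
#'   to the panel count); for PNG/PDF, inches.
#' @return The output path, invisibly.
#' @export
render_panels <- function(panel_set, path, format = NULL,
                          width = NULL, height = NULL) {
  stopifnot(inherits(panel_set, "panel_set"))
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  if (!format %in% c("svg", "png", "pdf"))
    stop("unknown output format '", format,
         "' (supported: svg, png, pdf)", call. = FALSE)
  if (!is.null(width) && width <= 0 ||
      !is.null(height) && height <= 0)
    stop("figure dimensions must be positive", call. = FALSE)
  if (format == "svg") {
    render_svg(panel_set, path, width = if (is.null(width)) 900 else width,
               height = height)
  } else {
    p <- horizon_ggplot(panel_set)
    w <- if (is.null(width)) 9 else width
    h <- if (is.null(height)) max(2, 0.9 * length(panel_set$panels) + 1.2)
         else height
    if (format == "png") {
      grDevices::png(path, width = w, height = h, units = "in", res = 150,
                     type = "cairo")
    } else {
      grDevices::pdf(path, width = w, height = h)
    }
    on.exit(grDevices::dev.off())
    print(p)
  }
  invisible(path)
}
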