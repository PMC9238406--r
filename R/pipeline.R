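#' Build a horizon panel set from a validated dataset
#'
#' The end-to-end pipeline behind the command-line tool: normalize counts to
#' percent if needed, select and order samples, resolve the taxa (explicitly
#' or by thresholds), build one series per facet, optionally regularize each
#' series onto a fixed-interval grid with gap breaks, apply the horizon
#' transform, and assemble the faceted panel set.
#'
#' In single-taxon mode facets are subjects; otherwise facets are taxa,
#' labeled by taxon id or, with `labels_by_taxonomy`, by the finest
#' non-missing taxonomic rank.
#'
#' @param table An [abundance_table()] (counts or percent).
#' @param metadata Tibble from [read_metadata()].
#' @param taxonomy Optional tibble from [read_taxonomy()].
#' @param selection A [selection_spec()].
#' @param grid A [grid_spec()]; default disabled.
#' @param horizon A [horizon_spec()]; default median origin, auto thickness,
#'   4 bands, per-series scale.
#' @param labels_by_taxonomy Label facets by taxonomy (multi-taxon mode
#'   only)?
#' @return A `panel_set` ready for [render_panels()] /
#'   [horizon_geometry()].
#' @export
horizon_panels <- function(table, metadata, taxonomy = NULL, selection,
                           grid = grid_spec(), horizon = horizon_spec(),
                           labels_by_taxonomy = FALSE) {
  stopifnot(inherits(selection, "selection_spec"),
            inherits(grid, "grid_spec"),
            inherits(horizon, "horizon_spec"))
  dataset <- validate_dataset(table, metadata, taxonomy)
  pct <- normalize_abundance(dataset$table)
  selected <- select_samples(dataset$metadata, selection)

  if (selection$mode == "single_taxon_multi_subject") {
    taxon <- resolve_taxa(pct, selected$sample, selection)
    subjects <- unique(selected$subject)
    series <- lapply(subjects, function(sj)
      build_series(pct, selected[selected$subject == sj, ], taxon, grid))
    labels <- subjects
  } else {
    taxa <- resolve_taxa(pct, selected$sample, selection)
    series <- lapply(taxa, function(tx)
      build_series(pct, selected, tx, grid))
    labels <- facet_labels(taxa, dataset$taxonomy,
                           by_taxonomy = labels_by_taxonomy)
  }
  interp <- lapply(series, interpolate_regular, grid = grid)
  # origin/thickness calibrate on the observed (pre-interpolation) series
  bands <- Map(function(si, raw)
    build_horizon(si, spec = horizon, panel_context = series,
                  calibration = raw),
    interp, series)
  assemble_panels(bands, labels)
}
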