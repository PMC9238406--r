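#' Specify which samples and taxa to plot
#'
#' A horizon figure is drawn in one of two modes:
#' * **one taxon across several subjects** (`single_taxon` set): each facet
#'   is a subject, useful for comparing the same microbe between hosts;
#' * **several taxa within one subject** (default): each facet is a taxon,
#'   chosen either explicitly (`taxa`) or by prevalence/abundance thresholds.
#'
#' Exactly one of `single_taxon`, `taxa`, or threshold-only selection is in
#' effect. Threshold comparisons are inclusive: a taxon with mean relative
#' abundance exactly at `thresh_abundance` is retained.
#'
#' @param subjects Character vector of subject ids. Must have length one
#'   unless `single_taxon` is set.
#' @param single_taxon Optional single taxon id for one-taxon mode.
#' @param taxa Optional explicit character vector of taxon ids, plotted in
#'   the given order.
#' @param thresh_prevalence Minimum prevalence, percent of the selected
#'   subject's samples in which the taxon is detected (abundance > 0),
#'   in `[0, 100]`. Default 0 (no filter).
#' @param thresh_abundance Minimum mean relative abundance across the
#'   selected samples, percent, `>= 0`. Default 0 (no filter).
#' @return An object of class `selection_spec`.
#' @export
selection_spec <- function(subjects, single_taxon = NULL, taxa = NULL,
                           thresh_prevalence = 0, thresh_abundance = 0) {
  subjects <- as.character(subjects)
  if (length(subjects) == 0L)
    stop("at least one subject is required", call. = FALSE)
  if (!is.null(single_taxon) && !is.null(taxa))
    stop("give either single_taxon or taxa, not both", call. = FALSE)
  if (!is.null(single_taxon) && length(single_taxon) != 1L)
    stop("single_taxon must be a single taxon id", call. = FALSE)
  mode <- if (!is.null(single_taxon)) "single_taxon_multi_subject"
          else "multi_taxon_single_subject"
  if (mode == "multi_taxon_single_subject" && length(subjects) != 1L)
    stop("multi-taxon mode requires exactly one subject; ",
         "set single_taxon to compare subjects", call. = FALSE)
  if (!is.numeric(thresh_prevalence) || thresh_prevalence < 0 ||
      thresh_prevalence > 100)
    stop("thresh_prevalence must be in [0, 100]", call. = FALSE)
  if (!is.numeric(thresh_abundance) || thresh_abundance < 0)
    stop("thresh_abundance must be >= 0", call. = FALSE)
  structure(
    list(mode = mode, subjects = subjects,
         single_taxon = single_taxon,
         taxa = if (is.null(taxa)) NULL else as.character(taxa),
         thresh_prevalence = thresh_prevalence,
         thresh_abundance = thresh_abundance),
    class = "selection_spec"
  )
}

#' Select and order the samples of the requested subjects
#'
#' Restricts the metadata to the requested subjects and sorts by subject,
#' then collection date ascending. A subject needs at least two samples to
#' yield a time series.
#'
#' @param metadata Tibble from [read_metadata()].
#' @param spec A [selection_spec()].
#' @return The metadata rows of the requested subjects, ordered by
#'   (subject, date).
#' @export
select_samples <- function(metadata, spec) {
  stopifnot(inherits(spec, "selection_spec"))
  unknown <- setdiff(spec$subjects, metadata$subject)
  if (length(unknown) > 0L)
    stop("unknown subject id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- metadata |>
    dplyr::filter(.data$subject %in% spec$subjects) |>
    dplyr::arrange(.data$subject, .data$collection_date)
  counts <- table(out$subject)
  thin <- names(counts)[counts < 2L]
  if (length(thin) > 0L)
    stop("subject(s) with fewer than 2 samples (no time series to draw): ",
         paste(thin, collapse = ", "), call. = FALSE)
  out
}

#' Taxon prevalence across a set of samples
#'
#' Prevalence is the percentage of samples in which the taxon is detected,
#' i.e. has strictly positive abundance.
#'
#' @param values Numeric vector: one taxon's abundances over the selected
#'   samples.
#' @return Percent in `[0, 100]`.
#' @export
taxon_prevalence <- function(values) {
  if (length(values) == 0L)
    stop("prevalence requires at least one sample", call. = FALSE)
  100 * sum(values > 0) / length(values)
}

#' Taxon mean relative abundance across a set of samples
#'
#' @param values Numeric vector of percent abundances over the selected
#'   samples.
#' @return Arithmetic mean, percent.
#' @export
taxon_mean_abundance <- function(values) {
  if (length(values) == 0L)
    stop("mean abundance requires at least one sample", call. = FALSE)
  mean(values)
}

#' Resolve the taxa to plot
#'
#' Applies the selection spec to a percent-normalized table restricted to the
#' selected samples. Explicit selections (`single_taxon`, `taxa`) bypass the
#' thresholds entirely; otherwise taxa passing both thresholds (inclusive)
#' are returned in descending order of mean relative abundance, which makes
#' panel order deterministic.
#'
#' Thresholds are evaluated on the selected subject's observed samples only,
#' never on interpolated points (interpolation happens downstream of
#' selection).
#'
#' @param table An [abundance_table()] in percent units.
#' @param sample_ids Character vector of selected sample ids.
#' @param spec A [selection_spec()].
#' @return Ordered character vector of taxon ids.
#' @export
resolve_taxa <- function(table, sample_ids, spec) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(spec, "selection_spec"))
  if (table$units != "percent")
    stop("resolve_taxa requires a percent-normalized table; ",
         "call normalize_abundance() first", call. = FALSE)
  missing_samples <- setdiff(sample_ids, table$sample_ids)
  if (length(missing_samples) > 0L)
    stop("sample id(s) not in table: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  sub <- table$values[, sample_ids, drop = FALSE]

  if (!is.null(spec$single_taxon)) {
    if (!spec$single_taxon %in% table$taxon_ids)
      stop("unknown taxon id: ", spec$single_taxon, call. = FALSE)
    return(spec$single_taxon)
  }
  if (!is.null(spec$taxa)) {
    unknown <- setdiff(spec$taxa, table$taxon_ids)
    if (length(unknown) > 0L)
      stop("unknown taxon id(s) in explicit list: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    return(spec$taxa)
  }
  prev <- apply(sub, 1L, taxon_prevalence)
  mab <- apply(sub, 1L, taxon_mean_abundance)
  keep <- prev >= spec$thresh_prevalence & mab >= spec$thresh_abundance
  if (!any(keep)) {
    summary_tbl <- tibble::tibble(taxon_id = table$taxon_ids,
                                  prevalence = prev, mean_abundance = mab)
    cond <- simpleError(paste0(
      "no taxa pass thresh_prevalence = ", spec$thresh_prevalence,
      " and thresh_abundance = ", spec$thresh_abundance))
    cond$taxon_summary <- summary_tbl
    stop(cond)
  }
  table$taxon_ids[keep][order(-mab[keep])]
}

#' Facet labels for the selected taxa
#'
#' With `by_taxonomy = TRUE`, each taxon is labeled by the value of its
#' finest non-missing taxonomic rank (e.g. a taxon resolved to genus
#' *Bacteroides* but not species is labeled "Bacteroides"); a taxon with a
#' wholly missing lineage falls back to its taxon id. Otherwise labels are
#' the taxon ids. Duplicate labels are disambiguated with a numeric suffix
#' ("Prevotella", "Prevotella (2)", ...).
#'
#' @param taxa Ordered character vector of taxon ids.
#' @param taxonomy Optional tibble from [read_taxonomy()]; required when
#'   `by_taxonomy` is `TRUE`.
#' @param by_taxonomy Logical; label by finest taxonomic rank?
#' @return Character vector of unique display labels, one per taxon.
#' @export
facet_labels <- function(taxa, taxonomy = NULL, by_taxonomy = FALSE) {
  labels <- as.character(taxa)
  if (by_taxonomy) {
    if (is.null(taxonomy))
      stop("by_taxonomy = TRUE requires a taxonomy table", call. = FALSE)
    missing_taxa <- setdiff(taxa, taxonomy$taxon_id)
    if (length(missing_taxa) > 0L)
      stop("taxon id(s) missing from taxonomy table: ",
           paste(missing_taxa, collapse = ", "), call. = FALSE)
    idx <- match(taxa, taxonomy$taxon_id)
    ranks <- as.matrix(taxonomy[idx, TAXONOMY_RANKS, drop = FALSE])
    labels <- vapply(seq_along(taxa), function(i) {
      filled <- which(!is.na(ranks[i, ]))
      if (length(filled) == 0L) as.character(taxa[i])
      else ranks[i, max(filled)]
    }, character(1L))
  }
  # numeric-suffix disambiguation, first occurrence unsuffixed
  out <- labels
  for (lab in unique(labels)) {
    hits <- which(labels == lab)
    if (length(hits) > 1L)
      out[hits[-1L]] <- paste0(lab, " (", seq_along(hits[-1L]) + 1L, ")")
  }
  out
}
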