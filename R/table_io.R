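#' @importFrom rlang .data
NULL

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

#' Construct an abundance table
#'
#' An abundance table is a taxa-by-samples matrix of non-negative finite
#' values in one of two units: `"counts"` (raw reads) or `"percent"`
#' (per-sample relative abundance on the 0--100 scale, every column summing
#' to 100). All downstream parameters of the package (origins, band
#' thicknesses, abundance thresholds) are denominated in percent, so count
#' tables must pass through [normalize_abundance()] before filtering or
#' plotting.
#'
#' @param values Numeric matrix, taxa in rows, samples in columns.
#' @param taxon_ids Character vector of unique taxon identifiers (rows).
#' @param sample_ids Character vector of unique sample identifiers (columns).
#' @param units `"counts"` or `"percent"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, taxon_ids, sample_ids,
                            units = c("counts", "percent")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("abundance table is empty", call. = FALSE)
  if (length(taxon_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("taxon/sample id lengths do not match the matrix dimensions",
         call. = FALSE)
  if (anyDuplicated(taxon_ids))
    stop("duplicate taxon ids: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("abundance values must be finite and numeric", call. = FALSE)
  if (any(values < 0))
    stop("abundance values must be non-negative", call. = FALSE)
  if (units == "percent") {
    sums <- colSums(values)
    bad <- abs(sums - 100) > 1e-6 * 100
    if (any(bad))
      stop("percent table has columns not summing to 100: ",
           paste(sample_ids[bad], collapse = ", "), call. = FALSE)
  }
  dimnames(values) <- list(as.character(taxon_ids), as.character(sample_ids))
  structure(
    list(values = values,
         taxon_ids = as.character(taxon_ids),
         sample_ids = as.character(sample_ids),
         units = units),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d taxa x %d samples, units = %s\n",
              length(x$taxon_ids), length(x$sample_ids), x$units))
  invisible(x)
}

# Sniff the delimiter of a delimited text file from its first line:
# tab wins if present, otherwise comma.
sniff_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("file is empty: ", path, call. = FALSE)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

read_delim_quiet <- function(path, delim) {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE,
                    name_repair = "minimal")
}

#' Read an OTU/ASV abundance table from delimited text
#'
#' Expects the common OTU-table layout: a header row of sample ids, the first
#' column holding taxon identifiers (its header is arbitrary), and one row
#' per taxon. The delimiter is sniffed from the first line (tab or comma)
#' unless given.
#'
#' Unit resolution under `units = "auto"`: if every sample column sums to
#' 100 (within 0.5) the table is classified `percent`; if every column sums
#' to 1 (within 0.005) it is treated as proportions, rescaled by 100, and
#' classified `percent`; if columns are split between these regimes the table
#' is ambiguous and an error is raised rather than guessing; otherwise the
#' table is classified `counts`.
#'
#' @param path Path to a TSV/CSV file.
#' @param units `"auto"` (default), `"counts"`, or `"percent"`. A non-auto
#'   value overrides detection.
#' @param delim Field delimiter; `NULL` to sniff.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, units = c("auto", "counts", "percent"),
                                 delim = NULL) {
  units <- match.arg(units)
  if (is.null(delim)) delim <- sniff_delim(path)
  df <- read_delim_quiet(path, delim)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("abundance table is empty or has no sample columns: ", path,
         call. = FALSE)
  taxon_ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat))
    stop("non-numeric abundance value in ", path, call. = FALSE)
  sample_ids <- colnames(df)[-1L]

  resolved <- units
  if (units == "auto") {
    sums <- colSums(mat)
    is_percent <- abs(sums - 100) <= 0.5
    is_prop <- abs(sums - 1) <= 0.005
    if (all(is_percent)) {
      resolved <- "percent"
    } else if (all(is_prop)) {
      mat <- mat * 100
      resolved <- "percent"
    } else if (any(is_percent) || any(is_prop)) {
      stop("cannot auto-detect units: some columns sum to ~100 or ~1 and ",
           "others do not; pass units = 'counts' or 'percent' explicitly",
           call. = FALSE)
    } else {
      resolved <- "counts"
    }
  }
  if (resolved == "percent") {
    # tolerate rounding in files declared/detected as percent by renormalizing
    sums <- colSums(mat)
    if (any(sums <= 0))
      stop("percent table has a non-positive column sum", call. = FALSE)
    if (any(abs(sums - 100) > 1e-6 * 100))
      mat <- sweep(mat, 2L, sums, "/") * 100
  }
  abundance_table(mat, taxon_ids, sample_ids, units = resolved)
}

#' Write an abundance table to delimited text
#'
#' Inverse of [read_abundance_table()]: first column `taxon_id`, one column
#' per sample. Round-trips ids and values exactly (values are written with
#' full precision).
#'
#' @param table An [abundance_table()].
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @export
write_abundance_table <- function(table, path, delim = "\t") {
  stopifnot(inherits(table, "abundance_table"))
  df <- tibble::as_tibble(table$values, .name_repair = "minimal")
  df <- tibble::add_column(df, taxon_id = table$taxon_ids, .before = 1L)
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Convert a count table to per-sample relative abundance (percent)
#'
#' Each cell is divided by its sample-column total and multiplied by 100.
#' A sample with zero total reads has undefined composition and is an error.
#' Applying the function to a table already in percent is the identity.
#'
#' @param table An [abundance_table()].
#' @return An [abundance_table()] with `units = "percent"`.
#' @export
normalize_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$units == "percent") return(table)
  sums <- colSums(table$values)
  zero <- sums <= 0
  if (any(zero))
    stop("sample(s) with zero total reads cannot be normalized: ",
         paste(table$sample_ids[zero], collapse = ", "), call. = FALSE)
  vals <- sweep(table$values, 2L, sums, "/") * 100
  abundance_table(vals, table$taxon_ids, table$sample_ids, units = "percent")
}

#' Read a sample metadata table
#'
#' The metadata table is the longitudinal key: one row per sample, mapping
#' sample id to subject id and collection date. Column names are
#' configurable; the defaults are `sample`, `subject`, and `collection_date`.
#' Dates must be ISO 8601 (`YYYY-MM-DD`).
#'
#' @param path Path to a TSV/CSV file.
#' @param sample_col,subject_col,date_col Column names to use.
#' @param delim Field delimiter; `NULL` to sniff.
#' @return A tibble with columns `sample`, `subject`, `collection_date`
#'   (class `Date`).
#' @export
read_metadata <- function(path, sample_col = "sample",
                          subject_col = "subject",
                          date_col = "collection_date",
                          delim = NULL) {
  if (is.null(delim)) delim <- sniff_delim(path)
  df <- read_delim_quiet(path, delim)
  need <- c(sample_col, subject_col, date_col)
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0L)
    stop("metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- tibble::tibble(
    sample = as.character(df[[sample_col]]),
    subject = as.character(df[[subject_col]]),
    collection_date = as.character(df[[date_col]])
  )
  if (anyDuplicated(out$sample))
    stop("duplicate sample id(s) in metadata: ",
         paste(unique(out$sample[duplicated(out$sample)]), collapse = ", "),
         call. = FALSE)
  if (any(is.na(out$sample) | is.na(out$subject) | is.na(out$collection_date)))
    stop("metadata has missing sample, subject, or date fields",
         call. = FALSE)
  dates <- as.Date(out$collection_date, format = "%Y-%m-%d")
  bad <- is.na(dates)
  if (any(bad))
    stop("unparseable ISO 8601 date(s) in metadata row(s): ",
         paste(which(bad), collapse = ", "),
         " (values: ", paste(out$collection_date[bad], collapse = ", "), ")",
         call. = FALSE)
  out$collection_date <- dates
  out
}

split_lineage <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  length(parts) <- length(TAXONOMY_RANKS)   # pad with NA
  parts[!nzchar(parts) | is.na(parts)] <- NA_character_
  parts
}

check_prefix_complete <- function(ranks, taxon_id) {
  filled <- !is.na(ranks)
  if (any(filled) && any(!filled[seq_len(max(which(filled)))]))
    stop("taxonomy for '", taxon_id, "' has a finer rank filled below a ",
         "missing coarser rank (lineages must be prefix-complete)",
         call. = FALSE)
  invisible(TRUE)
}

#' Read a taxonomy table
#'
#' Two dialects are accepted and auto-detected, never mixed:
#' * per-rank columns named after the seven standard ranks (`domain` or
#'   `kingdom`, `phylum`, `class`, `order`, `family`, `genus`, `species`),
#'   plus a taxon id column;
#' * a single lineage column (named `lineage` or `taxonomy`) holding a
#'   semicolon-delimited string, e.g. `"Bacteria;Bacteroidetes;;;;;"`.
#'
#' Empty strings become missing ranks. Lineages must be prefix-complete: a
#' missing rank may not be followed by a filled finer rank.
#'
#' @param path Path to a TSV/CSV file.
#' @param delim Field delimiter; `NULL` to sniff.
#' @return A tibble with columns `taxon_id` and the seven ranks.
#' @export
read_taxonomy <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- sniff_delim(path)
  df <- read_delim_quiet(path, delim)
  cols <- tolower(colnames(df))
  colnames(df) <- cols

  id_col <- intersect(c("taxon_id", "taxon", "otu", "otu_id"), cols)[1L]
  if (is.na(id_col))
    stop("taxonomy table has no taxon id column ",
         "(expected one of taxon_id, taxon, otu, otu_id)", call. = FALSE)

  rank_cols <- cols[cols %in% c(TAXONOMY_RANKS, "kingdom")]
  lineage_col <- intersect(c("lineage", "taxonomy"), cols)[1L]
  has_ranks <- length(rank_cols) > 0L
  has_lineage <- !is.na(lineage_col)
  if (has_ranks && has_lineage)
    stop("taxonomy table mixes per-rank columns and a lineage column; ",
         "use one dialect", call. = FALSE)
  if (!has_ranks && !has_lineage)
    stop("taxonomy table has neither per-rank columns nor a lineage column",
         call. = FALSE)

  taxon_id <- as.character(df[[id_col]])
  if (anyDuplicated(taxon_id))
    stop("duplicate taxon id(s) in taxonomy table", call. = FALSE)

  mat <- matrix(NA_character_, nrow = nrow(df),
                ncol = length(TAXONOMY_RANKS),
                dimnames = list(NULL, TAXONOMY_RANKS))
  if (has_lineage) {
    for (i in seq_len(nrow(df)))
      mat[i, ] <- split_lineage(as.character(df[[lineage_col]][i]))
  } else {
    for (rk in TAXONOMY_RANKS) {
      src <- if (rk == "domain" && !("domain" %in% cols) &&
                 "kingdom" %in% cols) "kingdom" else rk
      if (src %in% cols) {
        v <- trimws(as.character(df[[src]]))
        v[!nzchar(v) | is.na(v)] <- NA_character_
        mat[, rk] <- v
      }
    }
  }
  for (i in seq_len(nrow(mat)))
    check_prefix_complete(mat[i, ], taxon_id[i])

  out <- tibble::as_tibble(mat)
  tibble::add_column(out, taxon_id = taxon_id, .before = 1L)
}

#' Validate that the three input tables agree
#'
#' Checks the cross-table contracts before any analysis: every sample in the
#' abundance table must have a metadata row (extra metadata rows are allowed,
#' with a warning, since studies often have more metadata than sequenced
#' samples); no subject may have two samples on the same date (the time point
#' would be ambiguous); and if a taxonomy table is supplied it must cover
#' every taxon in the abundance table.
#'
#' @param table An [abundance_table()].
#' @param metadata A tibble from [read_metadata()].
#' @param taxonomy Optional tibble from [read_taxonomy()].
#' @return A list with elements `table`, `metadata`, `taxonomy` (class
#'   `microhorizon_dataset`), unchanged on success.
#' @export
validate_dataset <- function(table, metadata, taxonomy = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  missing_samples <- setdiff(table$sample_ids, metadata$sample)
  if (length(missing_samples) > 0L)
    stop("abundance-table sample(s) missing from metadata: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  extra <- setdiff(metadata$sample, table$sample_ids)
  if (length(extra) > 0L)
    warning("metadata has sample(s) not in the abundance table (ignored): ",
            paste(extra, collapse = ", "), call. = FALSE)
  used <- metadata[metadata$sample %in% table$sample_ids, ]
  key <- paste(used$subject, used$collection_date, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- used[key %in% key[duplicated(key)], ]
    stop("ambiguous time point(s): two samples share (subject, date): ",
         paste(unique(paste0(dups$subject, "@", dups$collection_date)),
               collapse = ", "), call. = FALSE)
  }
  if (!is.null(taxonomy)) {
    missing_taxa <- setdiff(table$taxon_ids, taxonomy$taxon_id)
    if (length(missing_taxa) > 0L)
      stop("taxon id(s) missing from taxonomy table: ",
           paste(missing_taxa, collapse = ", "), call. = FALSE)
  }
  structure(list(table = table, metadata = metadata, taxonomy = taxonomy),
            class = "microhorizon_dataset")
}
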