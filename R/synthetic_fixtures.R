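LINEAGE_POOL <- list(
  c("Bacteria", "Bacteroidetes", "Bacteroidia", "Bacteroidales",
    "Bacteroidaceae", "Bacteroides", NA),
  c("Bacteria", "Bacteroidetes", "Bacteroidia", "Bacteroidales",
    "Prevotellaceae", "Prevotella", NA),
  c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales",
    "Lachnospiraceae", "Blautia", NA),
  c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales",
    "Ruminococcaceae", "Faecalibacterium", "Faecalibacterium prausnitzii"),
  c("Bacteria", "Firmicutes", "Bacilli", "Lactobacillales",
    "Lactobacillaceae", "Lactobacillus", NA),
  c("Bacteria", "Actinobacteria", "Actinomycetia", "Bifidobacteriales",
    "Bifidobacteriaceae", "Bifidobacterium", NA),
  c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
    "Enterobacterales", "Enterobacteriaceae", "Escherichia", NA),
  c("Bacteria", "Verrucomicrobia", "Verrucomicrobiae",
    "Verrucomicrobiales", "Akkermansiaceae", "Akkermansia",
    "Akkermansia muciniphila"),
  c("Bacteria", "Firmicutes", NA, NA, NA, NA, NA),
  c("Bacteria", NA, NA, NA, NA, NA, NA)
)

#' Sampling schedules for the synthetic generator
#'
#' `schedule_regular()` emulates intervention studies where every subject is
#' sampled at set time points; `schedule_irregular()` emulates observational
#' designs (e.g. opportunistic wildlife sampling) with variable spacing and
#' occasional long collection gaps.
#'
#' @param interval_days Fixed spacing between samples, days.
#' @param min_gap,max_gap Range of ordinary gaps, days (uniform integer).
#' @param p_long_gap Probability that a gap is a long collection gap.
#' @param long_gap_days Length of a long gap, days.
#' @return A schedule object for [fixture_spec()].
#' @export
schedule_regular <- function(interval_days = 7) {
  stopifnot(interval_days > 0)
  structure(list(kind = "regular", interval_days = interval_days),
            class = "sampling_schedule")
}

#' @rdname schedule_regular
#' @export
schedule_irregular <- function(min_gap = 5, max_gap = 40, p_long_gap = 0.1,
                               long_gap_days = 120) {
  stopifnot(min_gap > 0, max_gap >= min_gap,
            p_long_gap >= 0, p_long_gap <= 1, long_gap_days > 0)
  structure(list(kind = "irregular", min_gap = min_gap, max_gap = max_gap,
                 p_long_gap = p_long_gap, long_gap_days = long_gap_days),
            class = "sampling_schedule")
}

#' Specify a synthetic longitudinal microbiome dataset
#'
#' The generator draws, per taxon and subject, a latent log-abundance that
#' follows an AR(1) walk (`x_t = rho * x_(t-1) + eps`, Gaussian noise)
#' around a baseline weight, optionally plus a sinusoid of a given period --
#' the minimal dynamics that produce the sustained shifts, comovement, and
#' periodicity horizon plots are designed to reveal. Latent abundances are
#' softmax-normalized across taxa at each sample and multiplied by a library
#' size to give read counts. A seed is mandatory: every dataset is fully
#' reproducible.
#'
#' @param n_subjects Number of subjects.
#' @param n_taxa Number of taxa (>= 2).
#' @param samples_per_subject Samples per subject (>= 2).
#' @param schedule A [schedule_regular()] or [schedule_irregular()].
#' @param baseline_weights Per-taxon log-scale baselines (recycled);
#'   defaults to a decreasing sequence giving realistically uneven
#'   abundances.
#' @param rho AR(1) autocorrelation in `[0, 1)` (recycled per taxon).
#' @param noise_scale AR(1) innovation standard deviation (recycled).
#' @param period_days Optional per-taxon sinusoid period (NA for none;
#'   recycled).
#' @param amplitude Sinusoid amplitude on the log scale (recycled).
#' @param library_size Reads per sample; default 10000.
#' @param seed Integer seed; required.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_subjects = 2, n_taxa = 8,
                         samples_per_subject = 20,
                         schedule = schedule_regular(7),
                         baseline_weights = NULL,
                         rho = 0.8, noise_scale = 0.4,
                         period_days = NA, amplitude = 0,
                         library_size = 10000, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (n_taxa < 2L) stop("n_taxa must be >= 2", call. = FALSE)
  if (samples_per_subject < 2L)
    stop("samples_per_subject must be >= 2", call. = FALSE)
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  stopifnot(inherits(schedule, "sampling_schedule"))
  if (any(rho < 0 | rho >= 1)) stop("rho must be in [0, 1)", call. = FALSE)
  if (any(noise_scale < 0)) stop("noise_scale must be >= 0", call. = FALSE)
  if (library_size <= 0) stop("library_size must be positive", call. = FALSE)
  if (is.null(baseline_weights))
    baseline_weights <- seq(2, -2, length.out = n_taxa)
  structure(
    list(n_subjects = as.integer(n_subjects), n_taxa = as.integer(n_taxa),
         samples_per_subject = as.integer(samples_per_subject),
         schedule = schedule,
         baseline_weights = rep_len(baseline_weights, n_taxa),
         rho = rep_len(rho, n_taxa),
         noise_scale = rep_len(noise_scale, n_taxa),
         period_days = rep_len(period_days, n_taxa),
         amplitude = rep_len(amplitude, n_taxa),
         library_size = library_size, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

draw_schedule_days <- function(schedule, n) {
  if (schedule$kind == "regular") {
    seq(0, by = schedule$interval_days, length.out = n)
  } else {
    gaps <- sample(seq(schedule$min_gap, schedule$max_gap), n - 1L,
                   replace = TRUE)
    long <- stats::runif(n - 1L) < schedule$p_long_gap
    gaps[long] <- schedule$long_gap_days
    cumsum(c(0, gaps))
  }
}

latent_trajectory <- function(days, baseline, rho, noise_scale,
                              period, amplitude) {
  n <- length(days)
  x <- numeric(n)
  # stationary start so early samples are not systematically calmer
  sd0 <- if (rho > 0 && noise_scale > 0)
    noise_scale / sqrt(1 - rho^2) else noise_scale
  x[1L] <- stats::rnorm(1L, 0, max(sd0, 1e-12))
  if (n > 1L) for (i in 2:n)
    x[i] <- rho * x[i - 1L] + stats::rnorm(1L, 0, noise_scale)
  sinus <- if (!is.na(period) && amplitude > 0)
    amplitude * sin(2 * pi * days / period) else 0
  baseline + x + sinus
}

#' Generate a synthetic dataset (counts, metadata, taxonomy)
#'
#' @param spec A [fixture_spec()].
#' @return A list with `table` (an [abundance_table()] of counts),
#'   `metadata` (tibble), and `taxonomy` (tibble).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    taxa <- sprintf("OTU_%03d", seq_len(spec$n_taxa))
    subjects <- sprintf("Subject_%02d", seq_len(spec$n_subjects))
    sample_ids <- character(0L)
    meta_rows <- list()
    counts <- matrix(0, nrow = spec$n_taxa, ncol = 0L)
    origin_date <- as.Date("2020-01-01")
    for (sj in seq_along(subjects)) {
      days <- draw_schedule_days(spec$schedule, spec$samples_per_subject)
      latent <- vapply(seq_len(spec$n_taxa), function(tx)
        latent_trajectory(days, spec$baseline_weights[tx], spec$rho[tx],
                          spec$noise_scale[tx], spec$period_days[tx],
                          spec$amplitude[tx]),
        numeric(spec$samples_per_subject))
      latent <- t(latent)  # taxa x samples
      props <- apply(latent, 2L, function(col) {
        e <- exp(col - max(col)); e / sum(e)
      })
      cts <- round(props * spec$library_size)
      # guard against an all-zero sample column after rounding
      zero_cols <- colSums(cts) == 0
      if (any(zero_cols)) cts[1L, zero_cols] <- 1
      ids <- sprintf("S%02d_%03d", sj, seq_along(days))
      counts <- cbind(counts, cts)
      sample_ids <- c(sample_ids, ids)
      meta_rows[[sj]] <- tibble::tibble(
        sample = ids, subject = subjects[sj],
        collection_date = origin_date + days)
    }
    lineages <- LINEAGE_POOL[((seq_len(spec$n_taxa) - 1L) %%
                                length(LINEAGE_POOL)) + 1L]
    tax <- tibble::as_tibble(do.call(rbind, lineages),
                             .name_repair = ~TAXONOMY_RANKS)
    tax <- tibble::add_column(tax, taxon_id = taxa, .before = 1L)
    list(
      table = abundance_table(counts, taxa, sample_ids, units = "counts"),
      metadata = dplyr::bind_rows(meta_rows),
      taxonomy = tax
    )
  })
}

#' Write a generated dataset to three TSV files
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_abundance_table(dataset$table, file.path(dir, "otu_table.tsv"))
  meta <- dataset$metadata
  meta$collection_date <- format(meta$collection_date, "%Y-%m-%d")
  readr::write_tsv(meta, file.path(dir, "metadata.tsv"), progress = FALSE)
  readr::write_tsv(dataset$taxonomy, file.path(dir, "taxonomy.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' A tiny hand-computable worked example
#'
#' One subject, three taxa, five weekly samples, percent units. Taxon
#' `OTU_001` runs 10, 20, 30, 40, 50 percent: its median origin is 30, the
#' automatic 4-band thickness is 5 (extreme deviation 20 / 4 bands), and the
#' last point saturates band +4 with fills 5, 5, 5, 5. `OTU_002` is constant
#' at 20 percent (its median), so all its fills are zero. `OTU_003` takes up
#' the compositional remainder. Every number in the horizon output can be
#' verified by hand with the clamp formula.
#'
#' @return A list with `table` (percent [abundance_table()]), `metadata`,
#'   and `taxonomy`.
#' @export
generate_worked_example <- function() {
  vals <- rbind(
    OTU_001 = c(10, 20, 30, 40, 50),
    OTU_002 = c(20, 20, 20, 20, 20),
    OTU_003 = c(70, 60, 50, 40, 30)
  )
  samples <- sprintf("WE_%d", 1:5)
  table <- abundance_table(vals, rownames(vals), samples, units = "percent")
  metadata <- tibble::tibble(
    sample = samples, subject = "Subject_WE",
    collection_date = as.Date("2020-01-01") + seq(0, 28, by = 7))
  taxonomy <- tibble::tibble(
    taxon_id = rownames(vals),
    domain = "Bacteria",
    phylum = c("Bacteroidetes", "Firmicutes", "Firmicutes"),
    class = c("Bacteroidia", "Clostridia", "Clostridia"),
    order = c("Bacteroidales", "Clostridiales", "Clostridiales"),
    family = c("Bacteroidaceae", "Lachnospiraceae", "Ruminococcaceae"),
    genus = c("Bacteroides", "Blautia", "Faecalibacterium"),
    species = NA_character_)
  list(table = table, metadata = metadata, taxonomy = taxonomy)
}
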