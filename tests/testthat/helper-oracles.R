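# Independent oracles, deliberately written differently from the package
# implementation so they can cross-check it.

# Fill of band k as the length of the overlap between [0, |d|] and the
# band's slice [(k-1) t, k t] -- an interval-intersection computation, not
# the clamp formula.
oracle_fills <- function(deviation, thickness, n_bands) {
  a <- abs(deviation)
  vapply(seq_len(n_bands), function(k) {
    lo <- (k - 1) * thickness
    hi <- k * thickness
    max(0, min(a, hi) - lo)
  }, numeric(1L))
}

# Band index by scanning band edges upward: the first k whose upper edge
# reaches |d| (with a boundary tolerance), clamped at n_bands.
oracle_band_index <- function(deviation, thickness, n_bands) {
  if (deviation == 0) return(0L)
  a <- abs(deviation)
  for (k in seq_len(n_bands))
    if (a <= k * thickness + 1e-9) return(as.integer(sign(deviation) * k))
  as.integer(sign(deviation) * n_bands)
}

# Two-point line evaluator for checking linear interpolation.
oracle_line <- function(t0, v0, t1, v1, t) {
  v0 + (v1 - v0) * (t - t0) / (t1 - t0)
}

# Random strictly increasing integer day offsets starting at 0.
random_times <- function(n, max_step = 30) {
  cumsum(c(0L, sample(seq_len(max_step), n - 1L, replace = TRUE)))
}

# Random percent abundance table (taxa x samples, columns sum to 100).
random_percent_table <- function(n_taxa, n_samples) {
  m <- matrix(stats::rexp(n_taxa * n_samples), nrow = n_taxa)
  m[sample(length(m), size = floor(length(m) / 4))] <- 0  # some zeros
  keep <- colSums(m) > 0
  m[1L, !keep] <- 1
  m <- sweep(m, 2L, colSums(m), "/") * 100
  abundance_table(m, paste0("T", seq_len(n_taxa)),
                  paste0("S", seq_len(n_samples)), units = "percent")
}

# Write a small delimited file and return its path.
write_fixture <- function(lines, ext = "tsv") {
  path <- withr::local_tempfile(fileext = paste0(".", ext),
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Run the package CLI in a subprocess, inheriting the test library paths.
run_cli <- function(args) {
  script <- system.file("cli", "microhorizon.R", package = "microhorizon")
  stopifnot(nzchar(script))
  out <- suppressWarnings(system2(
    "Rscript", c(script, args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}

# A small two-segment series fixture used in several tests.
make_series <- function(times, values, max_gap = NULL) {
  seg <- if (is.null(max_gap)) rep(1L, length(times))
         else split_segments(times, max_gap)
  taxon_series("T1", "SubjA", times, values, segment_id = seg)
}
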