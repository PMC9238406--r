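test_that("auto unit detection classifies percent, proportion, and count tables", {
  pct <- write_fixture(c("taxon_id\ts1\ts2", "A\t40\t30", "B\t60\t70"))
  tab <- read_abundance_table(pct, units = "auto")
  expect_equal(tab$units, "percent")
  expect_equal(unname(tab$values[, "s1"]), c(40, 60))

  prop <- write_fixture(c("taxon_id\ts1\ts2", "A\t0.4\t0.3", "B\t0.6\t0.7"))
  tab2 <- read_abundance_table(prop, units = "auto")
  expect_equal(tab2$units, "percent")
  expect_equal(unname(tab2$values[, "s2"]), c(30, 70))

  cnt <- write_fixture(c("taxon_id\ts1\ts2", "A\t12\t7", "B\t30\t55"))
  expect_equal(read_abundance_table(cnt, units = "auto")$units, "counts")

  # columns split between ~100 and counts regimes: refuse to guess
  ambig <- write_fixture(c("taxon_id\ts1\ts2", "A\t40\t7", "B\t60\t55"))
  expect_error(read_abundance_table(ambig, units = "auto"), "auto-detect")
  expect_equal(read_abundance_table(ambig, units = "counts")$units, "counts")
})

test_that("comma-delimited tables are sniffed and parsed", {
  csv <- write_fixture(c("otu,s1,s2", "A,1,2", "B,3,4"), ext = "csv")
  tab <- read_abundance_table(csv)
  expect_equal(tab$sample_ids, c("s1", "s2"))
  expect_equal(tab$units, "counts")
})

test_that("invalid abundance tables are rejected with clear errors", {
  neg <- write_fixture(c("taxon_id\ts1", "A\t-1", "B\t5"))
  expect_error(read_abundance_table(neg), "non-negative")
  dup <- write_fixture(c("taxon_id\ts1\ts2", "A\t1\t2", "A\t3\t4"))
  expect_error(read_abundance_table(dup), "duplicate taxon")
  expect_error(
    abundance_table(matrix(1, 1, 2), "A", c("s1", "s1"), "counts"),
    "duplicate sample")
  empty <- write_fixture("taxon_id\ts1")
  expect_error(read_abundance_table(empty), "empty")
  txt <- write_fixture(c("taxon_id\ts1", "A\tabc"))
  expect_error(read_abundance_table(txt), "non-numeric|finite")
})

test_that("count normalization divides by column totals onto the percent scale", {
  tab <- abundance_table(matrix(c(2, 3, 5), ncol = 1), c("a", "b", "c"),
                         "s1", units = "counts")
  norm <- normalize_abundance(tab)
  expect_equal(unname(norm$values[, 1]), c(20, 30, 50))
  expect_equal(norm$units, "percent")

  one <- abundance_table(matrix(7), "a", "s1", units = "counts")
  expect_equal(unname(normalize_abundance(one)$values[1, 1]), 100)

  zero <- abundance_table(matrix(c(1, 0, 2, 0), nrow = 2), c("a", "b"),
                          c("s1", "s2"), units = "counts")
  zero$values[, 2] <- 0
  expect_error(normalize_abundance(zero), "s2")
})

test_that("normalization is idempotent and always lands on 100-percent columns", {
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(sample(0:50, 24, replace = TRUE), nrow = 4)
    m[1L, colSums(m) == 0] <- 1
    tab <- abundance_table(m, paste0("t", 1:4), paste0("s", 1:6), "counts")
    norm <- normalize_abundance(tab)
    expect_true(all(abs(colSums(norm$values) - 100) <= 1e-9 * 100))
    expect_equal(normalize_abundance(norm)$values, norm$values,
                 tolerance = 1e-12)
  }
})

test_that("abundance tables round-trip through TSV", {
  set.seed(5)
  tab <- random_percent_table(6, 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tab, path)
  back <- read_abundance_table(path, units = "percent")
  expect_identical(back$taxon_ids, tab$taxon_ids)
  expect_identical(back$sample_ids, tab$sample_ids)
  expect_equal(back$values, tab$values, tolerance = 1e-12)
})

test_that("metadata parsing enforces unique samples and ISO dates", {
  ok <- write_fixture(c("sample\tsubject\tcollection_date",
                        "s1\tA\t2020-01-01", "s2\tA\t2020-01-26"))
  meta <- read_metadata(ok)
  expect_equal(nrow(meta), 2L)
  expect_s3_class(meta$collection_date, "Date")
  expect_equal(as.integer(diff(meta$collection_date)), 25L)

  dup <- write_fixture(c("sample\tsubject\tcollection_date",
                         "s1\tA\t2020-01-01", "s1\tA\t2020-01-02"))
  expect_error(read_metadata(dup), "duplicate sample")

  bad <- write_fixture(c("sample\tsubject\tcollection_date",
                         "s1\tA\tJan 1 2020"))
  expect_error(read_metadata(bad), "unparseable")

  renamed <- write_fixture(c("id\thost\twhen", "s1\tA\t2020-01-01",
                             "s2\tB\t2020-01-05"))
  meta2 <- read_metadata(renamed, sample_col = "id", subject_col = "host",
                         date_col = "when")
  expect_equal(meta2$subject, c("A", "B"))
})

test_that("taxonomy accepts lineage strings and per-rank columns but not both", {
  lin <- write_fixture(c("taxon_id\tlineage",
                         "A\tBacteria;Bacteroidetes;;;;;",
                         "B\tBacteria;Firmicutes;Clostridia;Clostridiales;Lachnospiraceae;Blautia;Blautia obeum"))
  tax <- read_taxonomy(lin)
  expect_equal(tax$phylum, c("Bacteroidetes", "Firmicutes"))
  expect_true(is.na(tax$class[1]))
  expect_equal(tax$species[2], "Blautia obeum")

  ranks <- write_fixture(c("taxon_id\tdomain\tphylum\tclass\torder\tfamily\tgenus\tspecies",
                           "A\tBacteria\tFirmicutes\t\t\t\t\t"))
  tax2 <- read_taxonomy(ranks)
  expect_equal(tax2$phylum, "Firmicutes")
  expect_true(is.na(tax2$genus))

  holes <- write_fixture(c("taxon_id\tdomain\tphylum\tclass\torder\tfamily\tgenus\tspecies",
                           "A\tBacteria\tFirmicutes\t\t\t\tBlautia\t"))
  expect_error(read_taxonomy(holes), "prefix-complete")

  mixed <- write_fixture(c("taxon_id\tgenus\tlineage",
                           "A\tBlautia\tBacteria;;;;;;"))
  expect_error(read_taxonomy(mixed), "mixes")

  noid <- write_fixture(c("name\tlineage", "A\tBacteria;;;;;;"))
  expect_error(read_taxonomy(noid), "taxon id")
})

test_that("dataset validation checks sample and taxon cross-references", {
  tab <- random_percent_table(3, 2)
  meta <- tibble::tibble(sample = c("S1", "S2", "S3"),
                         subject = "A",
                         collection_date = as.Date("2020-01-01") + 0:2)
  expect_warning(validate_dataset(tab, meta), "S3")
  expect_error(validate_dataset(tab, meta[1, ]), "S2")

  clash <- meta[1:2, ]
  clash$collection_date <- as.Date("2020-01-01")
  expect_error(validate_dataset(tab, clash), "ambiguous")

  tax <- tibble::tibble(taxon_id = c("T1", "T2"))
  expect_error(suppressWarnings(validate_dataset(tab, meta, tax)), "T3")
})
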