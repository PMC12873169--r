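# data model, validation and TSV/JSON round trips

test_that("abundance tables validate, renormalize and re-base on ingest", {
  v <- matrix(c(0.5, 0.3, 0.2, 0.1, 0.6, 0.3), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  tab <- make_table(v, days = c(100, 160))
  expect_s3_class(tab, "abundance_table")
  expect_equal(tab$values, v)
  # collection days re-based to first sample = 0
  expect_equal(tab$samples$collection_day, c(0L, 60L))

  # column summing to 0.5 is renormalized (entries doubled) with a warning
  v2 <- v; v2[, 2] <- v2[, 2] / 2
  expect_warning(tab2 <- make_table(v2), "renormalized")
  expect_equal(tab2$values[, 2], v[, 2])

  # negative abundance is a hard error
  v3 <- v; v3[1, 1] <- -0.1
  expect_error(make_table(v3), "negative abundance")

  # all-zero column cannot be repaired
  v4 <- v; v4[, 2] <- 0
  expect_error(make_table(v4), "zero total abundance")

  # age group must be constant within an individual
  meta <- data.frame(sample_id = c("S1", "S2"), individual_id = "X01",
                     age_group = c("I", "A"), collection_day = c(0, 10),
                     subject_age_years = 3)
  expect_error(abundance_table(v, meta), "age_group differs")
})

test_that("missing metadata rows are reported by sample name", {
  v <- random_composition(3, 2)
  colnames(v) <- c("S1", "S9")
  rownames(v) <- c("a", "b", "c")
  meta <- data.frame(sample_id = "S1", individual_id = "X01",
                     age_group = "A", collection_day = 0,
                     subject_age_years = 40)
  expect_error(abundance_table(v, meta), "S9")
})

test_that("abundance TSV round trip is exact", {
  tab <- generate_cohort(cohort_config(seed = 3, n_individuals_per_group = 2,
                                       n_timepoints = 3, n_taxa = 12))
  d <- withr::local_tempdir()
  p <- file.path(d, "ab.tsv"); mp <- file.path(d, "meta.tsv")
  write_abundance_table(tab, p, mp)
  tab2 <- read_abundance_table(p, mp)
  expect_equal(tab2$taxa, tab$taxa)
  expect_equal(tab2$samples$sample_id, tab$samples$sample_id)
  expect_equal(tab2$samples$collection_day, tab$samples$collection_day)
  expect_equal(tab2$values, tab$values, tolerance = 1e-9)
  # serialized numbers are stable: writing the re-read table is bit-identical
  p2 <- file.path(d, "ab2.tsv"); mp2 <- file.path(d, "meta2.tsv")
  write_abundance_table(tab2, p2, mp2)
  expect_identical(readLines(p), readLines(p2))
  expect_identical(readLines(mp), readLines(mp2))
})

test_that("presence is strictly above the detection threshold", {
  expect_false(is_present(1e-4, detection = 1e-4))
  expect_true(is_present(1e-4 + 1e-12, detection = 1e-4))
  expect_error(is_present(0.5, detection = 1), "detection")
  expect_error(is_present(0.5, detection = -1e-3), "detection")
})

test_that("write_result_tables emits conventional names, a manifest, and round-trips", {
  tab <- generate_cohort(cohort_config(seed = 2, n_individuals_per_group = 2,
                                       n_timepoints = 3, n_taxa = 15))
  core <- extract_core(compute_prevalence(tab, "I"), 1.0)
  fits <- as.data.frame(fit_taylor_cohort(tab))
  d <- withr::local_tempdir()
  paths <- write_result_tables(list(core = core, taylor_fits = fits), d,
                               config = list(x = 1), seed = 7)
  expect_true(file.exists(file.path(d, "core_I_p100.tsv")))
  expect_true(file.exists(file.path(d, "taylor_fits.tsv")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$seed, 7)
  expect_equal(man$config$x, 1)

  # re-reading a written table and re-writing reproduces it bit-exactly
  ft <- read_result_table(file.path(d, "taylor_fits.tsv"))
  d2 <- withr::local_tempdir()
  write_result_tables(list(taylor_fits = ft), d2)
  expect_identical(readLines(file.path(d, "taylor_fits.tsv")),
                   readLines(file.path(d2, "taylor_fits.tsv")))

  # empty result list: manifest only
  d3 <- withr::local_tempdir()
  paths3 <- write_result_tables(list(), d3, seed = 1)
  expect_identical(basename(list.files(d3)), "manifest.json")
})

test_that("genome content TSV round trip preserves the object", {
  gc <- generate_genome_content(genome_content_config(n_taxa = 8,
                                                      n_functions = 20,
                                                      n_pathways = 5,
                                                      n_superpathways = 2,
                                                      seed = 4))
  d <- withr::local_tempdir()
  ps <- file.path(d, c("content.tsv", "rrn.tsv", "map.tsv"))
  write_genome_content(gc, ps[1], ps[2], ps[3])
  gc2 <- read_genome_content(ps[1], ps[2], ps[3])
  expect_equal(gc2$copy_numbers, gc$copy_numbers)
  expect_equal(gc2$rrn, gc$rrn)
  expect_equal(gc2$pathway_map, gc$pathway_map)
})

test_that("pathway map invariants are enforced", {
  m <- diag(2); dimnames(m) <- list(c("g1", "g2"), c("f1", "f2"))
  rrn <- c(g1 = 1, g2 = 2)
  # function mapping to two pathways
  bad1 <- data.frame(function_id = c("f1", "f1", "f2"),
                     pathway_id = c("p1", "p2", "p1"),
                     superpathway_id = "s1")
  expect_error(genome_content(m, rrn, bad1), "more than one pathway")
  # pathway mapping to two superpathways
  bad2 <- data.frame(function_id = c("f1", "f2"),
                     pathway_id = c("p1", "p1"),
                     superpathway_id = c("s1", "s2"))
  expect_error(genome_content(m, rrn, bad2), "more than one superpathway")
  # unmapped function
  bad3 <- data.frame(function_id = "f1", pathway_id = "p1",
                     superpathway_id = "s1")
  expect_error(genome_content(m, rrn, bad3), "absent from pathway map")
})
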