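test_that("peak_table validates shape, names and finiteness", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  storage.mode(m) <- "double"
  pt <- peak_table(m)
  expect_s3_class(pt, "peak_table")
  expect_false(attr(pt, "blank_subtracted"))

  expect_error(peak_table(matrix(1.0, 2, 2)), class = "bvoc_schema_error")
  bad <- m; bad[1, 1] <- NA
  expect_error(peak_table(bad), class = "bvoc_integrity_error")
  dup <- m; rownames(dup) <- c("a", "a")
  expect_error(peak_table(dup), class = "bvoc_integrity_error")
  neg <- m; neg[1, 1] <- -1
  expect_error(peak_table(neg, blank_subtracted = TRUE),
               class = "bvoc_integrity_error")
  expect_silent(peak_table(neg, blank_subtracted = FALSE))
})

test_that("table validators enforce schema and value constraints", {
  d <- make_tiny_dataset()

  expect_error(validate_samples(d$samples[, -1]), class = "bvoc_schema_error")
  expect_error(validate_leaves(d$leaves[, c("branch_id", "leaf_area_total")]),
               class = "bvoc_schema_error")

  bad <- d$leaves; bad$leaf_area_total[1] <- -5
  expect_error(validate_leaves(bad), class = "bvoc_integrity_error")
  bad <- d$leaves; bad$leaf_area_eaten[1] <- bad$leaf_area_total[1] + 1
  expect_error(validate_leaves(bad), class = "bvoc_integrity_error")

  bad <- d$samples; bad$sample_type[1] <- "branchh"
  expect_error(validate_samples(bad), class = "bvoc_integrity_error")
  bad <- d$samples; bad$cartridge_flow[1] <- bad$inflow_rate[1] + 1
  expect_error(validate_samples(bad), class = "bvoc_integrity_error")

  bad <- d$compounds; bad$compound_class[1] <- "XYZ"
  expect_error(validate_compounds(bad), class = "bvoc_integrity_error")
  bad <- d$compounds; bad$match_factor[1] <- 1200
  expect_error(validate_compounds(bad), class = "bvoc_integrity_error")
  bad <- d$compounds
  bad$id_basis[1] <- "library_tentative"; bad$proxy_standard[1] <- ""
  expect_error(validate_compounds(bad), class = "bvoc_integrity_error")
})

test_that("percent_eaten uses the reconstructed original leaf area", {
  expect_equal(percent_eaten(90, 10), 10)
  expect_equal(percent_eaten(200, 0), 0)
  d <- validate_leaves(data.frame(branch_id = "b1", leaf_area_total = 198,
                                  leaf_area_eaten = 2))
  expect_equal(d$percent_eaten, 1)
})

test_that("bvoc_dataset enforces referential integrity", {
  d <- make_tiny_dataset()
  expect_s3_class(d, "bvoc_dataset")

  # peak row without sample metadata
  expect_error(bvoc_dataset(d$peaks, d$samples[-1, ], d$leaves, d$compounds),
               class = "bvoc_integrity_error")
  # peak column without compound descriptor
  expect_error(bvoc_dataset(d$peaks, d$samples, d$leaves, d$compounds[-1, ]),
               class = "bvoc_integrity_error")
  # branch sample without leaf record
  expect_error(bvoc_dataset(d$peaks, d$samples, d$leaves[-1, ], d$compounds),
               class = "bvoc_integrity_error")
})

test_that("write/read round-trip preserves the dataset", {
  d <- make_tiny_dataset()
  dir <- tempfile("roundtrip")
  paths <- write_bvoc_tables(d, dir, meta = list(seed = 1, note = "round trip"))
  expect_true(all(file.exists(paths)))

  # metadata comment lines must be skipped on read
  first_line <- readLines(paths[["peaks"]], n = 1L)
  expect_match(first_line, "^# seed: 1$")

  d2 <- read_bvoc_tables(paths)
  expect_equal(unclass(d2$peaks), unclass(d$peaks))
  expect_equal(d2$samples, d$samples)
  expect_equal(d2$leaves, d$leaves)
  expect_equal(d2$compounds, d$compounds)
  expect_false(attr(d2$peaks, "blank_subtracted"))
})

test_that("read_bvoc_tables reports missing files and paths", {
  expect_error(read_bvoc_tables(list(peaks = "x.csv")),
               class = "bvoc_config_error")
  expect_error(read_bvoc_tables(list(peaks = "nope.csv", samples = "nope.csv",
                                     leaves = "nope.csv",
                                     compounds = "nope.csv")),
               class = "bvoc_schema_error")
})

test_that("read_config handles YAML and JSON and rejects other formats", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c("outdir: out", "alpha: 0.05", "stages:", "  - preprocess"), y)
  cfg <- read_config(y)
  expect_equal(cfg$outdir, "out")
  expect_equal(cfg$alpha, 0.05)
  expect_equal(cfg$stages, "preprocess")

  j <- tempfile(fileext = ".json")
  writeLines('{"outdir": "out", "alpha": 0.05}', j)
  expect_equal(read_config(j)$alpha, 0.05)

  t <- tempfile(fileext = ".txt")
  writeLines("x", t)
  expect_error(read_config(t), class = "bvoc_config_error")
  expect_error(read_config("missing.yaml"), class = "bvoc_config_error")
})

test_that("pipeline runs end to end on file inputs with exact emission rates", {
  d <- make_tiny_dataset()
  dir <- tempfile("inputs")
  paths <- write_bvoc_tables(d, dir)
  out <- tempfile("out")
  res <- run_pipeline(list(inputs = as.list(paths), outdir = out,
                           stages = c("preprocess", "emission")),
                      seed = 7)
  expect_true(file.exists(file.path(out, "E1", "emission_rates.csv")))
  em <- res$experiments$E1$emissions
  # hand computation: ER = 6 * (mass - blank_mean) / leaf_area
  expect_equal(em["s1", "cA"], 6 * (10 - 1) / 200)
  expect_equal(em["s3", "cB"], 6 * (26 - 2) / 220)
  ct <- res$experiments$E1$class_totals
  expect_equal(ct$total, ct$MT + ct$GLV)
})

test_that("pipeline reruns with the same seed are byte-identical", {
  cfg <- function(out) list(simulate = list(replicates = 2, n_blanks = 2),
                            outdir = out, rf_ntree = 100)
  o1 <- tempfile("run1"); o2 <- tempfile("run2")
  suppressWarnings(suppressMessages(run_pipeline(cfg(o1), seed = 42)))
  suppressWarnings(suppressMessages(run_pipeline(cfg(o2), seed = 42)))
  for (f in c("Abisko1/emission_rates.csv", "Abisko1/class_totals.csv",
              "Abisko1/tukey_letters.csv", "Abisko1/damage_regressions.csv")) {
    expect_identical(readLines(file.path(o1, f)), readLines(file.path(o2, f)),
                     label = f)
  }
  o3 <- tempfile("run3")
  suppressWarnings(suppressMessages(run_pipeline(cfg(o3), seed = 43)))
  expect_false(identical(
    readLines(file.path(o1, "Abisko1", "emission_rates.csv")),
    readLines(file.path(o3, "Abisko1", "emission_rates.csv"))))
})

test_that("pipeline rejects bad configurations", {
  expect_error(run_pipeline(list(simulate = TRUE)),
               class = "bvoc_config_error")            # no outdir
  expect_error(run_pipeline(list(outdir = tempfile())),
               class = "bvoc_config_error")            # no inputs
  expect_error(run_pipeline(list(simulate = TRUE, outdir = tempfile(),
                                 stages = "normalise")),
               class = "bvoc_config_error")            # unknown stage
})
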