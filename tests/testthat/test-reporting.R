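test_that("report-only ingestion of the pilot table ranks diabetes first", {
  out <- withr::local_tempdir()
  code <- gap_run(pilot_scores_path(), out, mode = "report-only")
  expect_identical(as.integer(code), 0L)
  res <- attr(code, "results")
  scores <- res$scores
  expect_identical(nrow(scores), 13L)
  expect_identical(scores$condition[scores$rank == 1], "Diabetes mellitus")
  expect_equal(max(scores$overall_gap), 0.61)
  expect_identical(scores$condition[scores$rank == 13],
                   "Lower respiratory infections")
  expect_equal(min(scores$overall_gap), 0.27)
  # ties at 0.30 broken by condition name, ascending
  tied <- scores$condition[scores$overall_gap == 0.30]
  expect_identical(tied, sort(tied))
  csv <- readr::read_csv(file.path(out, "gap_scores.csv"),
                         show_col_types = FALSE)
  expect_identical(nrow(csv), 13L)
})

test_that("missing input files give the I/O exit code and name the path", {
  out <- withr::local_tempdir()
  expect_message(code <- gap_run("no/such/file.csv", out),
                 "no/such/file.csv")
  expect_identical(as.integer(code), 4L)
  expect_message(code2 <- gap_run("nope.csv", out, mode = "report-only"))
  expect_identical(as.integer(code2), 4L)
})

test_that("invalid metrics yield the validation exit code", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- toy_table()
  tab$observations$value[1] <- -3
  # bypass writer validation by writing raw CSV
  df <- tibble::tibble(
    condition_id = tab$observations$condition_id,
    condition_name = "x", domain = "burden",
    metric_id = tab$observations$metric_id,
    year = tab$observations$year, stratum = "",
    value = tab$observations$value, units = ""
  )
  readr::write_csv(df, path)
  out <- withr::local_tempdir()
  expect_message(code <- gap_run(path, out), "nonnegativity|failed")
  expect_identical(as.integer(code), 2L)
})

test_that("a full simulated run succeeds deterministically", {
  sim_dir <- withr::local_tempdir()
  spec_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_conditions: 8", "seed: 31", "planted_gap: cond_05"),
             spec_path)
  expect_identical(as.integer(gap_simulate(sim_dir, spec_path)), 0L)
  metrics <- file.path(sim_dir, "metrics.csv")
  expect_true(file.exists(metrics))

  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  c1 <- gap_run(metrics, out1)
  c2 <- gap_run(metrics, out2)
  expect_identical(as.integer(c1), 0L)
  expect_identical(readLines(file.path(out1, "gap_results.json")),
                   readLines(file.path(out2, "gap_results.json")))
  res <- attr(c1, "results")
  expect_identical(res$scores$condition_id[res$scores$rank == 1], "cond_05")
  expect_true(file.exists(file.path(out1, "run_manifest.json")))
})

test_that("the narrative report names dominant domains and opportunities", {
  res <- rank_conditions(read_score_csv(pilot_scores_path()))
  lines <- gap_report(res)
  expect_identical(length(lines), 13L)
  diabetes <- lines[grepl("Diabetes", lines)]
  expect_match(diabetes, "dominant domain: health care cost")
  ckd <- lines[grepl("Chronic kidney", lines)]
  expect_match(ckd, "low biomedical product innovation")
  expect_match(ckd, "innovation opportunity")

  # a condition whose three contributions tie exactly has no dominant domain
  flat <- tibble::tibble(condition = c("e1", "e2", "e3", "e4"),
                         burden = c(0.4, 0.1, 0.2, 0.3),
                         cost = c(0.4, 0.1, 0.2, 0.3),
                         innovation = c(0.6, 0.9, 0.8, 0.7))
  fl <- gap_report(rank_conditions(flat))
  expect_true(all(grepl("no dominant domain", fl)))
})

test_that("the report reads results JSON back and rejects malformed files", {
  res <- rank_conditions(read_score_csv(pilot_scores_path()))
  out <- withr::local_tempdir()
  paths <- write_results(res, out)
  lines <- gap_report(paths[["results_json"]])
  expect_identical(length(lines), 13L)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(gap_report(bad))
  expect_error(gap_report(tempfile()), "not found")
})
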