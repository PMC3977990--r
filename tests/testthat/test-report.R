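test_that("full analysis of the packaged table populates the right sections", {
  report <- run_full_analysis(kcnj11_table1())

  expect_s3_class(report$models$allele, "gamet_pool")
  expect_equal(report$models$allele$k, 47)
  for (m in c("heterozygous", "homozygous", "dominant", "recessive")) {
    expect_match(report$models[[m]], "^unavailable:")
  }

  eth <- tidy(report$subgroups$ethnicity)
  expect_equal(sort(eth$level),
               sort(c("Caucasian", "East Asian", "Indian", "Other")))
  expect_equal(eth$k[eth$level == "East Asian"], 14)
  expect_equal(eth$k[eth$level == "Indian"], 5)
  expect_equal(eth$k[eth$level == "Other"], 7)

  expect_match(report$subgroups$bmi, "^unavailable:")
  expect_s3_class(report$subgroups$sample_size, "gamet_subgroups")

  expect_equal(nrow(report$sensitivity), 47)
  expect_s3_class(report$egger, "tbl_df")
  expect_equal(nrow(report$funnel$points), 47)
  expect_equal(nrow(report$frequencies), 5)   # overall + 4 strata
  # no per-study transmission counts are published for the two trio studies
  expect_match(report$tdt, "^unavailable:")
  expect_match(report$combined, "^unavailable:")

  # power inputs are the recomputed stratum summaries (2-dp OR and control
  # frequency); with MAF-reconstructed tables these differ from the
  # published stratum ORs, so only structure and sanity are asserted here
  pw <- report$power
  expect_setequal(pw$stratum, c("Caucasian", "East Asian", "Indian", "Other"))
  expect_true(all(pw$n_per_group > 0))
  expect_true(all(pw$n_presented %% 100 == 0))
  expect_equal(pw$p0[pw$stratum == "Caucasian"], 0.40)
  expect_equal(pw$p0[pw$stratum == "East Asian"], 0.36)
})

test_that("synthetic tables with genotypes populate all five genetic models", {
  sim <- simulate_studies(k_studies = 12, k_trios = 2, seed = 44)
  sim$ethnicity <- rep(c("Caucasian", "East Asian"), 7)
  report <- run_full_analysis(sim)
  for (m in names(report$models)) {
    expect_s3_class(report$models[[m]], "gamet_pool")
  }
  expect_s3_class(report$tdt, "gamet_pool")
  expect_s3_class(report$combined, "gamet_combined")
  expect_equal(report$tdt$k, 2)
})

test_that("tsv bundle has forest rows for every study plus the pool", {
  report <- run_full_analysis(kcnj11_table1())
  dir <- withr::local_tempdir()
  files <- write_report(report, dir, format = "tsv_bundle")
  expect_true(file.path(dir, "forest_allele.tsv") %in% files)
  forest <- readr::read_tsv(file.path(dir, "forest_allele.tsv"),
                            show_col_types = FALSE)
  expect_equal(nrow(forest), 48)    # 47 studies + 1 pooled row
  expect_equal(sum(forest$study_id == "POOLED (DL)"), 1)
  # presentation columns are rounded to 2 dp alongside full precision
  expect_true(all(c("or", "or_2dp") %in% names(forest)))
  expect_equal(forest$or_2dp, round(forest$or, 2))
})

test_that("json report round-trips the pooled numbers", {
  report <- run_full_analysis(kcnj11_table1())
  f <- withr::local_tempfile(fileext = ".json")
  write_report(report, f, format = "json")
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$schema, "gamet-report/1")
  expect_equal(back$summary$total_cases, 56349)
  expect_equal(back$models$allele$or, exp(report$models$allele$pooled_log_or))
  expect_equal(back$models$allele$tau2, report$models$allele$tau2)
  expect_equal(back$power$n_presented, report$power$n_presented)
})

test_that("identical inputs give byte-identical reports", {
  studies <- kcnj11_table1()
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report(run_full_analysis(studies), f1, format = "json")
  write_report(run_full_analysis(studies), f2, format = "json")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the Chinese-row remapping changes only the ethnicity stratum", {
  remapped <- run_full_analysis(kcnj11_table1(), map_chinese_to = "east_asian")
  eth <- tidy(remapped$subgroups$ethnicity)
  expect_equal(eth$k[eth$level == "East Asian"], 15)
  default <- run_full_analysis(kcnj11_table1())
  expect_equal(remapped$models$allele$pooled_log_or,
               default$models$allele$pooled_log_or)
})
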