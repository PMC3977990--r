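test_that("an identical configuration yields a byte-identical table", {
  a <- simulate_studies(k_studies = 25, k_trios = 2, seed = 99)
  b <- simulate_studies(k_studies = 25, k_trios = 2, seed = 99)
  expect_identical(a, b)
  fa <- withr::local_tempfile(fileext = ".tsv")
  fb <- withr::local_tempfile(fileext = ".tsv")
  write_study_table(a, fa)
  write_study_table(b, fb)
  expect_identical(readLines(fa), readLines(fb))

  c_ <- simulate_studies(k_studies = 25, k_trios = 2, seed = 100)
  expect_false(identical(a$maf_cases, c_$maf_cases))
})

test_that("generated tables satisfy the schema and round-trip", {
  sim <- simulate_studies(k_studies = 15, k_trios = 3, seed = 5)
  expect_silent(validate_study_table(sim))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_study_table(sim, f)
  back <- read_study_table(f)
  attr(back, "provenance") <- NULL
  expect_equal(back, sim, ignore_attr = c("spec", "problems"))
})

test_that("genotype triples sum to the arm sizes and imply the reported MAF", {
  sim <- simulate_studies(k_studies = 40, k_trios = 0, seed = 6)
  expect_true(all(sim$ee_cases + sim$ek_cases + sim$kk_cases == sim$n_cases))
  expect_true(all(sim$ee_controls + sim$ek_controls + sim$kk_controls ==
                    sim$n_controls))
  expect_equal(sim$maf_cases,
               (sim$ek_cases + 2 * sim$kk_cases) / (2 * sim$n_cases))

  no_geno <- simulate_studies(k_studies = 5, k_trios = 0,
                              genotype_mode = FALSE, seed = 6)
  expect_true(all(is.na(no_geno$ee_cases)))
  expect_false(anyNA(no_geno$maf_cases))
})

test_that("a null generating model pools to the null", {
  for (seed in c(1, 2)) {
    sim <- simulate_studies(k_studies = 500, k_trios = 0, mu = 0, tau2 = 0,
                            seed = seed)
    pooled <- exp(pool_dl(effect_sizes(sim, "allele"))$pooled_log_or)
    expect_gt(pooled, 0.97)
    expect_lt(pooled, 1.03)
  }
})

test_that("the DL estimate recovers the generating mean log OR", {
  sim <- simulate_studies(k_studies = 200, k_trios = 0,
                          mu = log(1.12), tau2 = 0.01, seed = 7)
  est <- pool_dl(effect_sizes(sim, "allele"))
  expect_equal(est$pooled_log_or, log(1.12), tolerance = 0.03 / log(1.12))
})

test_that("per-study sub-streams survive a change of collection size", {
  big <- simulate_studies(k_studies = 30, k_trios = 0, seed = 13)
  small <- simulate_studies(k_studies = 10, k_trios = 0, seed = 13)
  expect_equal(small$maf_cases, big$maf_cases[1:10])
  expect_equal(small$n_cases, big$n_cases[1:10])
})

test_that("family studies emit consistent transmission counts", {
  sim <- simulate_studies(k_studies = 5, k_trios = 10,
                          trios_min = 100, trios_max = 400, seed = 8)
  fam <- sim[sim$design == "family", ]
  expect_equal(nrow(fam), 10)
  expect_true(all(fam$n_trios >= 100 & fam$n_trios <= 400))
  expect_true(all(fam$transmitted + fam$untransmitted <= 2 * fam$n_trios))
  expect_true(all(fam$transmitted + fam$untransmitted > 0))
})

test_that("selection bias suppresses small null studies", {
  unbiased <- simulate_studies(k_studies = 200, k_trios = 0, mu = 0,
                               tau2 = 0, seed = 14)
  biased <- simulate_studies(k_studies = 200, k_trios = 0, mu = 0,
                             tau2 = 0, selection_bias = 0.8, seed = 14)
  # suppressing non-significant small studies inflates the pooled effect
  p_unb <- pool_dl(effect_sizes(unbiased, "allele"))$pooled_log_or
  p_bia <- pool_dl(effect_sizes(biased, "allele"))$pooled_log_or
  expect_gt(abs(p_bia), abs(p_unb) - 0.005)
  expect_equal(nrow(biased), 200)
})

test_that("covariate-driven heterogeneity follows the requested split", {
  full <- simulate_with_covariate(k_studies = 300, tau2 = 0.04,
                                  cov_fraction_of_tau2 = 1, seed = 15)
  est <- effect_sizes(full, "allele") |>
    dplyr::left_join(dplyr::select(full, study_id, x_cov), by = "study_id")
  fit <- meta_regress(est, ~ x_cov)
  expect_gt(fit$prop_explained, 0.8)
  expect_equal(tidy(fit)$estimate[2], sqrt(0.04), tolerance = 0.25)

  none <- simulate_with_covariate(k_studies = 100, tau2 = 0.04,
                                  cov_fraction_of_tau2 = 0, seed = 16)
  est0 <- effect_sizes(none, "allele") |>
    dplyr::left_join(dplyr::select(none, study_id, x_cov), by = "study_id")
  fit0 <- meta_regress(est0, ~ x_cov)
  expect_lt(fit0$prop_explained, 0.2)
})
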