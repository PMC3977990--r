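test_that("fixed-effect pooling matches hand-computed weighted means", {
  single <- suppressWarnings(pool_fixed(make_est(0.3, 0.02)))
  expect_equal(single$pooled_log_or, 0.3)
  expect_equal(single$Q, 0)
  expect_equal(single$df, 0)

  two <- pool_fixed(make_est(c(0.1, 0.3), c(0.01, 0.01)))
  expect_equal(two$pooled_log_or, 0.2)
  expect_equal(two$se, sqrt(1 / 200))
  expect_equal(two$Q, 2.0)

  flat <- pool_fixed(make_est(rep(0.15, 5), runif(5, 0.01, 0.05)))
  expect_equal(flat$Q, 0)
  expect_equal(flat$i2, 0)
})

test_that("DerSimonian-Laird tau2 and weights follow the moments formula", {
  dl <- pool_dl(make_est(c(0.1, 0.3), c(0.01, 0.01)))
  expect_equal(dl$tau2, 0.01)        # (Q - 1) / (200 - 100)
  expect_equal(dl$pooled_log_or, 0.2)
  expect_equal(dl$se, 0.1)
  expect_equal(dl$i2, 0.5)

  # truncation: homogeneous estimates give tau2 = 0 and the fixed result
  est <- make_est(c(0.11, 0.12, 0.10), c(0.05, 0.04, 0.06))
  dl0 <- pool_dl(est)
  fx <- pool_fixed(est)
  expect_equal(dl0$tau2, 0)
  expect_identical(dl0$pooled_log_or, fx$pooled_log_or)
  expect_identical(dl0$se, fx$se)
})

test_that("pooled estimate stays in the convex hull of study estimates", {
  set.seed(21)
  for (i in 1:50) {
    k <- sample(2:12, 1)
    est <- make_est(rnorm(k, 0.1, 0.4), runif(k, 0.001, 0.3))
    for (p in list(pool_fixed(est), pool_dl(est))) {
      expect_gte(p$pooled_log_or, min(est$log_or) - 1e-12)
      expect_lte(p$pooled_log_or, max(est$log_or) + 1e-12)
    }
  }
})

test_that("inflating one study's variance moves the pool away from it", {
  base <- c(0.5, 0.0, -0.1)
  pools <- vapply(c(1, 2, 5, 10, 50), function(m) {
    pool_fixed(make_est(base, c(0.02 * m, 0.02, 0.02)))$pooled_log_or
  }, numeric(1))
  expect_true(all(diff(pools) < 0))   # drifts away from the 0.5 study
})

test_that("Q, tau2 and pooled estimate match metafor on small rational cases", {
  skip_if_not_installed("metafor")
  cases <- list(
    list(y = c(1/10, 3/10), v = c(1/100, 1/100)),
    list(y = c(1/2, -1/3, 1/7), v = c(1/9, 1/16, 1/25)),
    list(y = c(2/5, 1/5, -1/10, 3/10), v = c(1/50, 3/100, 1/40, 1/20)),
    list(y = c(0, 0, 0), v = c(1/10, 1/10, 1/10)))
  for (cs in cases) {
    ours <- pool_dl(make_est(cs$y, cs$v))
    ref <- metafor::rma(yi = cs$y, vi = cs$v, method = "DL")
    expect_equal(ours$Q, as.numeric(ref$QE), tolerance = 1e-12)
    expect_equal(ours$tau2, as.numeric(ref$tau2), tolerance = 1e-12)
    expect_equal(ours$pooled_log_or, as.numeric(ref$beta), tolerance = 1e-12)
    expect_equal(ours$se, as.numeric(ref$se), tolerance = 1e-12)
  }
})

test_that("subgroup pooling reports per-level pools and between-stratum Q", {
  est <- make_est(c(0.1, 0.3, 0.1, 0.3), c(0.01, 0.01, 0.01, 0.01))
  est$group <- c("A", "A", "B", "B")
  sub <- pool_subgroups(est, group)
  expect_equal(sub$q_between, 0)
  expect_equal(sub$p_between, 1)
  expect_equal(nrow(tidy(sub)), 2)

  eth <- effect_sizes(kcnj11_table1(), "allele") |>
    dplyr::mutate(group = ethnicity_group(ethnicity))
  expect_warning(sub_eth <- pool_subgroups(eth, group), "missing stratum")
  lv <- tidy(sub_eth)
  expect_equal(lv$k[lv$level == "East Asian"], 14)
  expect_equal(lv$k[lv$level == "Caucasian"], 20)
  expect_equal(lv$k[lv$level == "Indian"], 5)
  expect_equal(lv$k[lv$level == "Other"], 7)

  # remapping the Chinese-labelled study is an explicit user choice
  eth2 <- effect_sizes(kcnj11_table1(), "allele") |>
    dplyr::mutate(group = ethnicity_group(ethnicity, "east_asian"))
  expect_equal(tidy(pool_subgroups(eth2, group)) |>
                 dplyr::filter(level == "East Asian") |> dplyr::pull(k), 15)
})

test_that("leave-one-out produces one k-1 pool per study in input order", {
  est <- make_est(c(0.2, 0.2, 0.2), c(0.01, 0.02, 0.03))
  loo <- leave_one_out(est)
  expect_equal(nrow(loo), 3)
  expect_equal(loo$excluded, est$study_id)
  expect_true(all(loo$k == 2))
  expect_true(all(abs(loo$pooled_log_or - 0.2) < 1e-12))

  expect_error(leave_one_out(est[1:2, ]), "three")
})
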