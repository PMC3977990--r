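test_that("allele counts are reconstructed by arm-conserving rounding", {
  # Hani 1998: 191 cases / 114 controls, risk-allele freq 0.49 / 0.37
  tab <- allele_table_from_maf(191, 114, 0.49, 0.37)
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 187, b = 195, c = 84, d = 144))
  expect_false(tab$correction_applied)

  sym <- allele_table_from_maf(100, 100, 0.5, 0.5) |> log_odds_ratio()
  expect_equal(sym$log_or, 0)

  corrected <- allele_table_from_maf(10, 10, 0.0, 0.1)
  expect_true(corrected$correction_applied)
  expect_equal(unlist(corrected[c("a", "b", "c", "d")]),
               c(a = 0.5, b = 20.5, c = 2.5, d = 18.5))

  expect_error(allele_table_from_maf(0, 10, 0.5, 0.5), "positive")
})

test_that("genotype models collapse the genotype triples correctly", {
  args <- list(30, 50, 20, 40, 45, 15)
  cells <- function(m) {
    unlist(do.call(genotype_table, c(args, model = m))[c("a", "b", "c", "d")])
  }
  expect_equal(cells("dominant"), c(a = 70, b = 30, c = 60, d = 40))
  expect_equal(cells("recessive"), c(a = 20, b = 80, c = 15, d = 85))
  expect_equal(cells("heterozygous"), c(a = 50, b = 30, c = 45, d = 40))
  expect_equal(cells("homozygous"), c(a = 20, b = 30, c = 15, d = 40))
})

test_that("log odds ratio and Woolf variance match direct arithmetic", {
  tab <- tibble::tibble(a = 187, b = 195, c = 84, d = 144)
  est <- log_odds_ratio(tab)
  expect_equal(est$log_or, log(187 * 144 / (195 * 84)))
  expect_equal(est$log_or, 0.497, tolerance = 1e-3)
  expect_equal(est$variance, 1 / 187 + 1 / 195 + 1 / 84 + 1 / 144)

  flat <- log_odds_ratio(tibble::tibble(a = 100, b = 100, c = 100, d = 100))
  expect_equal(flat$log_or, 0)
  expect_equal(flat$variance, 0.04)

  # transposing case and control rows negates the log OR
  swapped <- log_odds_ratio(tibble::tibble(a = 84, b = 144, c = 187, d = 195))
  expect_equal(swapped$log_or, -est$log_or)
  expect_equal(swapped$variance, est$variance)
})

test_that("odds ratio is invariant under doubling all cells", {
  set.seed(11)
  for (i in 1:20) {
    cells <- sample(1:500, 4)
    one <- log_odds_ratio(tibble::tibble(a = cells[1], b = cells[2],
                                         c = cells[3], d = cells[4]))
    two <- log_odds_ratio(tibble::tibble(a = 2 * cells[1], b = 2 * cells[2],
                                         c = 2 * cells[3], d = 2 * cells[4]))
    expect_equal(two$log_or, one$log_or)
  }
})

test_that("genotype-derived and frequency-derived allele tables agree", {
  set.seed(12)
  for (i in 1:20) {
    geno_ca <- sample(10:200, 3)
    geno_co <- sample(10:200, 3)
    n_ca <- sum(geno_ca); n_co <- sum(geno_co)
    maf_ca <- (geno_ca[2] + 2 * geno_ca[3]) / (2 * n_ca)
    maf_co <- (geno_co[2] + 2 * geno_co[3]) / (2 * n_co)
    from_geno <- log_odds_ratio(tibble::tibble(
      a = geno_ca[2] + 2 * geno_ca[3], b = 2 * n_ca - geno_ca[2] - 2 * geno_ca[3],
      c = geno_co[2] + 2 * geno_co[3], d = 2 * n_co - geno_co[2] - 2 * geno_co[3]))
    from_maf <- log_odds_ratio(
      allele_table_from_maf(n_ca, n_co, maf_ca, maf_co))
    expect_equal(from_maf$log_or, from_geno$log_or, tolerance = 0.02)
  }
})

test_that("effect_sizes covers the case-control rows and named failures", {
  est <- effect_sizes(kcnj11_table1(), "allele")
  expect_equal(nrow(est), 47)
  expect_false("Altshuler_2000" %in% est$study_id)
  expect_true(all(est$variance > 0))
  expect_error(effect_sizes(kcnj11_table1(), "dominant"),
               "dominant model unavailable.*Sakura_1996")

  toy <- toy_table()
  expect_equal(nrow(effect_sizes(toy, "recessive")), 2)
})

test_that("HWE chi-square matches hand-computed and oracle values", {
  exact <- hwe_test(25, 50, 25)
  expect_equal(exact$chi2, 0)
  expect_equal(exact$p, 1)

  dev <- hwe_test(30, 40, 30)
  expect_equal(dev$chi2, 4.0)
  expect_equal(dev$p, 0.0455, tolerance = 1e-3)

  mono <- hwe_test(0, 0, 50)
  expect_equal(mono$chi2, 0)
  expect_equal(mono$p, 1)
})

test_that("HWE statistic equals expected-count computation on all small triples", {
  triples <- expand.grid(ee = 0:30, ek = 0:30, kk = 0:30)
  triples <- triples[rowSums(triples) >= 1 & rowSums(triples) <= 30, ]
  got <- hwe_test(triples$ee, triples$ek, triples$kk)
  n <- rowSums(triples)
  q <- (triples$ek + 2 * triples$kk) / (2 * n)
  expected <- cbind(n * (1 - q)^2, n * 2 * q * (1 - q), n * q^2)
  chi2 <- rowSums((as.matrix(triples) - expected)^2 / expected)
  chi2[q == 0 | q == 1] <- 0
  expect_equal(got$chi2, unname(chi2))
})
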