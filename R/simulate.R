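#' Simulate a collection of association studies with known truth
#'
#' Generates a study table with the same schema as [kcnj11_table1()] from a
#' fully specified generative model, so that every pipeline stage can be
#' exercised against known parameter values. Per case-control study `i`:
#' a true log odds ratio `theta_i ~ Normal(mu, tau2)`; a control risk-allele
#' frequency `p0_i ~ Beta(raf_alpha, raf_beta)`; per-arm sizes log-uniform
#' on `[n_min, n_max]`; control genotypes multinomial under Hardy-Weinberg
#' proportions at `p0_i`; case genotypes multinomial with the per-allele
#' (multiplicative) odds model — genotype weights `1 : OR : OR^2` times the
#' control proportions, renormalised. Reported allele frequencies are
#' computed from the sampled genotype counts. Family studies emit
#' transmission counts: heterozygous-parent transmissions
#' `H ~ Binomial(2 * n_trios, 2 p0 (1 - p0))` and
#' `T ~ Binomial(H, plogis(theta_i))`, `U = H - T`.
#'
#' The default parameters emulate the 48-study KCNJ11 E23K collection: 46
#' case-control plus 2 trio studies, a true per-allele OR of 1.12,
#' between-study variance 0.04, control frequencies centred on 0.38
#' (Beta(8, 13)), arm sizes spanning one hundred to ten thousand.
#'
#' Each study draws from its own sub-stream (a per-study seed derived once
#' from `seed`), so a study's data are reproducible under reordering, and
#' an identical configuration yields a byte-identical table.
#'
#' @param k_studies Number of case-control studies.
#' @param mu True pooled log odds ratio.
#' @param tau2 Between-study variance of the true log OR (>= 0).
#' @param raf_alpha,raf_beta Beta parameters of the control risk-allele
#'   frequency distribution.
#' @param n_min,n_max Per-arm size range, sampled log-uniformly
#'   (`n_min >= 20`).
#' @param genotype_mode Emit per-arm genotype counts (and a control-arm
#'   Hardy-Weinberg p-value) in the table; allele frequencies are reported
#'   either way.
#' @param k_trios Number of family (trio) studies.
#' @param trios_min,trios_max Trio-count range (uniform integer).
#' @param selection_bias Probability that a small study (below the
#'   geometric midpoint of the size range) with a non-significant result is
#'   suppressed, emulating publication bias. 0 (default) keeps every study.
#' @param seed Integer seed; mandatory.
#' @return A validated study tibble of `k_studies + k_trios` rows.
#' @export
#' @examples
#' sim <- simulate_studies(k_studies = 20, seed = 1)
#' sim |> effect_sizes("allele") |> pool_dl()
simulate_studies <- function(k_studies = 46, mu = log(1.12), tau2 = 0.04,
                             raf_alpha = 8, raf_beta = 13,
                             n_min = 100, n_max = 10000,
                             genotype_mode = TRUE,
                             k_trios = 2, trios_min = 150, trios_max = 350,
                             selection_bias = 0, seed) {
  simulate_impl(k_studies = k_studies, mu = mu, tau2 = tau2,
                raf_alpha = raf_alpha, raf_beta = raf_beta,
                n_min = n_min, n_max = n_max, genotype_mode = genotype_mode,
                k_trios = k_trios, trios_min = trios_min,
                trios_max = trios_max, selection_bias = selection_bias,
                seed = seed, beta_cov = 0)
}

#' Simulate studies with a heterogeneity-driving covariate
#'
#' Like [simulate_studies()], but a standard-normal study-level covariate
#' `x_cov` drives part of the between-study variance:
#' `theta_i = mu + beta_cov * x_i + Normal(0, (1 - f) * tau2)` with
#' `beta_cov^2 = f * tau2`, `f = cov_fraction_of_tau2`. Feeding the result
#' to [meta_regress()] with `~ x_cov` should recover about `f` as the
#' proportion of heterogeneity explained.
#'
#' @inheritParams simulate_studies
#' @param cov_fraction_of_tau2 Fraction `f` of `tau2` attributable to the
#'   covariate, in `[0, 1]`.
#' @return A validated study tibble with an extra numeric column `x_cov`.
#' @export
#' @examples
#' sim <- simulate_with_covariate(k_studies = 50, tau2 = 0.05,
#'                                cov_fraction_of_tau2 = 0.5, seed = 2)
simulate_with_covariate <- function(k_studies = 46, mu = log(1.12),
                                    tau2 = 0.04, cov_fraction_of_tau2 = 0.5,
                                    raf_alpha = 8, raf_beta = 13,
                                    n_min = 100, n_max = 10000,
                                    genotype_mode = TRUE,
                                    selection_bias = 0, seed) {
  if (cov_fraction_of_tau2 < 0 || cov_fraction_of_tau2 > 1) {
    abort("cov_fraction_of_tau2 must lie in [0, 1]")
  }
  simulate_impl(k_studies = k_studies, mu = mu, tau2 = tau2,
                raf_alpha = raf_alpha, raf_beta = raf_beta,
                n_min = n_min, n_max = n_max, genotype_mode = genotype_mode,
                k_trios = 0, trios_min = 0, trios_max = 0,
                selection_bias = selection_bias, seed = seed,
                beta_cov = sqrt(cov_fraction_of_tau2 * tau2),
                keep_covariate = TRUE)
}

# ---- internal -------------------------------------------------------------

simulate_impl <- function(k_studies, mu, tau2, raf_alpha, raf_beta,
                          n_min, n_max, genotype_mode,
                          k_trios, trios_min, trios_max,
                          selection_bias, seed, beta_cov,
                          keep_covariate = FALSE) {
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory")
  if (k_studies < 1) abort("k_studies must be at least 1")
  if (tau2 < 0) abort("tau2 must be nonnegative")
  if (n_min < 20 || n_max < n_min) abort("need 20 <= n_min <= n_max")
  if (selection_bias < 0 || selection_bias >= 1) {
    abort("selection_bias must lie in [0, 1)")
  }
  if (k_trios > 0 && (trios_min < 1 || trios_max < trios_min)) {
    abort("need 1 <= trios_min <= trios_max")
  }
  sd_resid <- sqrt(max(0, tau2 - beta_cov^2))

  # per-study sub-stream seeds, drawn once from the configuration seed
  max_candidates <- if (selection_bias > 0) {
    ceiling(k_studies * 4 / (1 - selection_bias))
  } else {
    k_studies
  }
  set.seed(seed)
  cc_seeds <- sample.int(.Machine$integer.max - 1L, max_candidates + k_trios)
  trio_seeds <- utils::tail(cc_seeds, k_trios)
  cc_seeds <- utils::head(cc_seeds, max_candidates)

  n_mid <- sqrt(n_min * n_max)
  draws <- matrix(NA_real_, nrow = max_candidates, ncol = 10)
  kept <- 0L
  used <- 0L
  while (kept < k_studies && used < max_candidates) {
    used <- used + 1L
    row <- sim_one_cc(cc_seeds[used], mu, sd_resid, beta_cov,
                      raf_alpha, raf_beta, n_min, n_max,
                      selection_bias, n_mid)
    if (!is.null(row)) {
      kept <- kept + 1L
      draws[kept, ] <- row
    }
  }
  if (kept < k_studies) {
    abort("selection_bias too severe: could not retain enough studies")
  }
  draws <- draws[seq_len(k_studies), , drop = FALSE]
  colnames(draws) <- c("x_cov", "n_cases", "n_controls",
                       "ee_cases", "ek_cases", "kk_cases",
                       "ee_controls", "ek_controls", "kk_controls", "theta")

  d <- as_tibble(draws)
  cc <- tibble(
    study_id = sprintf("sim_cc_%03d", seq_len(k_studies)),
    year = 2020L,
    ethnicity = "Synthetic",
    design = "population",
    n_cases = as.integer(d$n_cases),
    n_controls = as.integer(d$n_controls),
    maf_cases = (d$ek_cases + 2 * d$kk_cases) / (2 * d$n_cases),
    maf_controls = (d$ek_controls + 2 * d$kk_controls) / (2 * d$n_controls),
    ee_cases = as.integer(d$ee_cases), ek_cases = as.integer(d$ek_cases),
    kk_cases = as.integer(d$kk_cases),
    ee_controls = as.integer(d$ee_controls),
    ek_controls = as.integer(d$ek_controls),
    kk_controls = as.integer(d$kk_controls),
    n_trios = NA_integer_, transmitted = NA_integer_,
    untransmitted = NA_integer_,
    hwe_p = NA_character_)
  if (genotype_mode) {
    cc$hwe_p <- as.character(signif(
      hwe_test(cc$ee_controls, cc$ek_controls, cc$kk_controls)$p, 3))
  } else {
    cc[c("ee_cases", "ek_cases", "kk_cases",
         "ee_controls", "ek_controls", "kk_controls")] <- NA_integer_
  }
  if (keep_covariate) cc$x_cov <- d$x_cov

  if (k_trios > 0) {
    fam <- purrr::map_dfr(seq_len(k_trios), function(i) {
      v <- sim_one_trio(trio_seeds[i], mu, sd_resid,
                        raf_alpha, raf_beta, trios_min, trios_max)
      tibble(study_id = sprintf("sim_fam_%03d", i), year = 2020L,
             ethnicity = "Synthetic", design = "family",
             n_cases = NA_integer_, n_controls = NA_integer_,
             maf_cases = NA_real_, maf_controls = NA_real_,
             ee_cases = NA_integer_, ek_cases = NA_integer_,
             kk_cases = NA_integer_, ee_controls = NA_integer_,
             ek_controls = NA_integer_, kk_controls = NA_integer_,
             n_trios = v[["n_trios"]], transmitted = v[["transmitted"]],
             untransmitted = v[["untransmitted"]],
             hwe_p = NA_character_)
    })
    if (keep_covariate) fam$x_cov <- NA_real_
    cc <- bind_rows(cc, fam)
  }
  validate_study_table(cc)
  cc
}

# one case-control study drawn inside its own sub-stream; returns NULL when
# suppressed by the selection mechanism
sim_one_cc <- function(s, mu, sd_resid, beta_cov, raf_alpha, raf_beta,
                       n_min, n_max, selection_bias, n_mid) {
  set.seed(s)
  x <- rnorm(1)
  theta <- mu + beta_cov * x + rnorm(1, 0, sd_resid)
  p0 <- rbeta(1, raf_alpha, raf_beta)
  n_ca <- round(exp(runif(1, log(n_min), log(n_max))))
  n_co <- round(exp(runif(1, log(n_min), log(n_max))))
  or <- exp(theta)
  g0 <- c((1 - p0)^2, 2 * p0 * (1 - p0), p0^2)
  g1 <- g0 * c(1, or, or^2)
  g1 <- g1 / sum(g1)
  geno_co <- as.numeric(rmultinom(1, n_co, g0))
  geno_ca <- as.numeric(rmultinom(1, n_ca, g1))
  if (selection_bias > 0 && n_ca < n_mid) {
    a <- geno_ca[2] + 2 * geno_ca[3]; b <- 2 * n_ca - a
    cc_ <- geno_co[2] + 2 * geno_co[3]; dd <- 2 * n_co - cc_
    cells <- c(a, b, cc_, dd)
    if (any(cells == 0)) cells <- cells + 0.5
    z <- log(cells[1] * cells[4] / (cells[2] * cells[3])) /
      sqrt(sum(1 / cells))
    if (abs(z) < Z95 && runif(1) < selection_bias) return(NULL)
  }
  c(x, n_ca, n_co, geno_ca, geno_co, theta)
}

sim_one_trio <- function(s, mu, sd_resid, raf_alpha, raf_beta,
                         trios_min, trios_max) {
  set.seed(s)
  theta <- mu + rnorm(1, 0, sd_resid)
  p0 <- rbeta(1, raf_alpha, raf_beta)
  n_trios <- if (trios_max > trios_min) {
    trios_min + sample.int(trios_max - trios_min + 1L, 1) - 1L
  } else {
    as.integer(trios_min)
  }
  h <- max(1L, rbinom(1, 2L * n_trios, 2 * p0 * (1 - p0)))
  t_ <- rbinom(1, h, exp(theta) / (1 + exp(theta)))
  c(n_trios = as.integer(n_trios), transmitted = as.integer(t_),
    untransmitted = as.integer(h - t_))
}
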