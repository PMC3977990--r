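#' Population attributable risk of a risk allele
#'
#' The fraction of disease in the population attributable to carrying the
#' risk allele, from the classical approximation
#' `PAR = (OR - 1) / OR * RAF` with `RAF` the risk-allele frequency.
#' Negative values are possible (and meaningful) for protective alleles.
#'
#' @param or Per-allele odds ratio (> 0), vectorised.
#' @param raf Risk-allele frequency in `[0, 1]`, vectorised.
#' @return Attributable fraction(s), dimensionless.
#' @export
#' @examples
#' attributable_risk(or = 1.12, raf = 0.40)
attributable_risk <- function(or, raf) {
  if (any(is.na(or) | or <= 0)) abort("odds ratio must be positive")
  if (any(is.na(raf) | raf < 0 | raf > 1)) abort("raf must lie in [0, 1]")
  (or - 1) / or * raf
}

#' Sample size for a target power under the allele contrast
#'
#' Closed-form two-proportion normal approximation on allele counts for a
#' case-control study with equal arms: given the control risk-allele
#' frequency `p0` and a per-allele odds ratio, the case frequency is
#' `p1 = p0 * OR / (1 - p0 + p0 * OR)` and the required number of alleles
#' per group is
#' `m = (z_{1-alpha/2} + z_{power})^2 * (p0(1-p0) + p1(1-p1)) / (p1 - p0)^2`;
#' each individual contributes two independent alleles, so `n = ceiling(m/2)`
#' case-control pairs are needed. The presentation value rounds `n` to the
#' nearest hundred.
#'
#' @param p0 Control risk-allele frequency, in `(0, 1)`.
#' @param or Per-allele odds ratio (> 0 and != 1).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @return A tibble: `p0`, `or`, `alpha`, `power`, `p1`,
#'   `alleles_per_group`, `n_per_group` (individuals), `n_presented`
#'   (nearest hundred).
#' @export
#' @examples
#' sample_size_for_power(p0 = 0.40, or = 1.12)
sample_size_for_power <- function(p0, or, alpha = 0.05, power = 0.80) {
  if (any(is.na(p0) | p0 <= 0 | p0 >= 1)) abort("p0 must lie in (0, 1)")
  if (any(is.na(or) | or <= 0)) abort("odds ratio must be positive")
  if (any(or == 1)) abort("or = 1 implies an infinite sample size")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("alpha and power must lie in (0, 1)")
  }
  p1 <- p0 * or / (1 - p0 + p0 * or)
  zz <- (qnorm(1 - alpha / 2) + qnorm(power))^2
  m <- zz * (p0 * (1 - p0) + p1 * (1 - p1)) / (p1 - p0)^2
  n <- ceiling(m / 2)
  tibble(p0 = p0, or = or, alpha = alpha, power = power, p1 = p1,
         alleles_per_group = m, n_per_group = n,
         n_presented = round(n / 100) * 100)
}

#' Control-arm risk-allele frequency summary
#'
#' Summarises the control-arm risk-allele frequency over a study collection
#' (optionally one ethnic stratum): the control-sample-size-weighted mean,
#' the across-study range, and a descriptive 95% CI from the weighted
#' between-study standard error of the frequency.
#'
#' @param studies A validated study tibble.
#' @param ethnicity Optional label: keep only studies whose `ethnicity`
#'   equals it (verbatim match against the table's labels).
#' @return A one-row tibble: `ethnicity`, `k`, `mean` (weighted), `min`,
#'   `max`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' control_freq_summary(kcnj11_table1(), ethnicity = "Caucasian")
control_freq_summary <- function(studies, ethnicity = NULL) {
  validate_study_table(studies)
  sel <- studies[!is.na(studies$maf_controls) & !is.na(studies$n_controls), ]
  if (!is.null(ethnicity)) sel <- sel[sel$ethnicity == ethnicity, ]
  if (nrow(sel) == 0) abort("no matching study with a control allele frequency")
  w <- sel$n_controls / sum(sel$n_controls)
  m <- sum(w * sel$maf_controls)
  # descriptive between-study standard error of the weighted mean
  k <- nrow(sel)
  se <- if (k > 1) {
    sqrt(k / (k - 1) * sum(w^2 * (sel$maf_controls - m)^2))
  } else 0
  tibble(ethnicity = if (is.null(ethnicity)) "all" else ethnicity,
         k = nrow(sel), mean = m,
         min = min(sel$maf_controls), max = max(sel$maf_controls),
         ci_low = max(0, m - Z95 * se), ci_high = min(1, m + Z95 * se))
}
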