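#' Reconstruct an allele-contrast 2x2 table from arm sizes and frequencies
#'
#' Builds the risk-allele vs other-allele contingency table for a
#' case-control study from the published per-arm risk-allele frequencies,
#' treating the two alleles carried by each individual as independent
#' observations (the usual allele-contrast convention). Counts are the
#' nearest integer of `2 * N * maf` (half-values round away from zero); the
#' complementary cell absorbs the remainder so each arm contributes exactly
#' `2 * N` alleles.
#'
#' @param n_cases,n_controls Number of individuals per arm (must be > 0).
#' @param maf_cases,maf_controls Risk-allele frequency per arm, in `[0, 1]`.
#' @return A tibble with columns `a` (risk alleles in cases), `b` (other
#'   alleles in cases), `c`, `d` (same in controls) and
#'   `correction_applied`. When any cell is zero, 0.5 is added to all four
#'   cells (Haldane-Anscombe) and the flag is set.
#' @export
#' @examples
#' allele_table_from_maf(191, 114, 0.49, 0.37)
allele_table_from_maf <- function(n_cases, n_controls, maf_cases, maf_controls) {
  if (any(is.na(n_cases) | is.na(n_controls) | n_cases <= 0 | n_controls <= 0)) {
    abort("arm sizes must be positive")
  }
  if (any(is.na(maf_cases) | is.na(maf_controls) |
            maf_cases < 0 | maf_cases > 1 | maf_controls < 0 | maf_controls > 1)) {
    abort("allele frequencies must lie in [0, 1]")
  }
  a <- round_half_up(2 * n_cases * maf_cases)
  c_ <- round_half_up(2 * n_controls * maf_controls)
  finish_table(a, 2 * n_cases - a, c_, 2 * n_controls - c_)
}

#' Build a genotype-model 2x2 table from genotype counts
#'
#' Collapses per-arm genotype counts (EE, EK, KK; E the reference allele, K
#' the risk allele) into the exposure contrast of a genetic model:
#' heterozygous (EK vs EE), homozygous (KK vs EE), dominant (EK+KK vs EE) or
#' recessive (KK vs EE+EK).
#'
#' @param ee_cases,ek_cases,kk_cases Genotype counts in cases.
#' @param ee_controls,ek_controls,kk_controls Genotype counts in controls.
#' @param model One of `"heterozygous"`, `"homozygous"`, `"dominant"`,
#'   `"recessive"`.
#' @inherit allele_table_from_maf return
#' @export
#' @examples
#' genotype_table(30, 50, 20, 40, 45, 15, model = "dominant")
genotype_table <- function(ee_cases, ek_cases, kk_cases,
                           ee_controls, ek_controls, kk_controls,
                           model = c("heterozygous", "homozygous",
                                     "dominant", "recessive")) {
  model <- match.arg(model)
  counts <- list(ee_cases, ek_cases, kk_cases,
                 ee_controls, ek_controls, kk_controls)
  if (any(vapply(counts, function(x) any(is.na(x) | x < 0), logical(1)))) {
    abort("genotype counts must be present and nonnegative")
  }
  cells <- switch(model,
    heterozygous = list(a = ek_cases, b = ee_cases,
                        c = ek_controls, d = ee_controls),
    homozygous   = list(a = kk_cases, b = ee_cases,
                        c = kk_controls, d = ee_controls),
    dominant     = list(a = ek_cases + kk_cases, b = ee_cases,
                        c = ek_controls + kk_controls, d = ee_controls),
    recessive    = list(a = kk_cases, b = ee_cases + ek_cases,
                        c = kk_controls, d = ee_controls + ek_controls))
  finish_table(cells$a, cells$b, cells$c, cells$d)
}

#' Log odds ratio with Woolf variance
#'
#' Adds the log odds ratio and its Woolf (inverse-cell-count) variance to a
#' table of 2x2 counts: `log_or = log(a * d / (b * c))`,
#' `variance = 1/a + 1/b + 1/c + 1/d`. Cells are strictly positive by
#' construction (the continuity correction in the table builders guarantees
#' it), so both quantities are finite.
#'
#' @param tables A data frame with columns `a`, `b`, `c`, `d` (e.g. from
#'   [allele_table_from_maf()] or [genotype_table()]).
#' @return The input tibble with `log_or` and `variance` columns appended.
#' @export
#' @examples
#' allele_table_from_maf(191, 114, 0.49, 0.37) |> log_odds_ratio()
log_odds_ratio <- function(tables) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  if (any(tables$a <= 0 | tables$b <= 0 | tables$c <= 0 | tables$d <= 0)) {
    abort("all cells must be positive; apply the continuity correction first")
  }
  tables %>%
    mutate(log_or = log(.data$a * .data$d / (.data$b * .data$c)),
           variance = 1 / .data$a + 1 / .data$b + 1 / .data$c + 1 / .data$d)
}

#' Per-study effect estimates under a genetic model
#'
#' The workhorse bridge from a study table to pooling: selects the
#' case-control rows (designs `"population"` and `"both"`), builds the 2x2
#' table of the requested genetic model for each study, and returns log odds
#' ratios with Woolf variances. The allele model reconstructs allele counts
#' from the reported frequencies; the genotype-based models (heterozygous,
#' homozygous, dominant, recessive) need the genotype-count columns and fail
#' by naming the studies that lack them.
#'
#' @param studies A validated study tibble.
#' @param model Genetic model; one of `"allele"`, `"heterozygous"`,
#'   `"homozygous"`, `"dominant"`, `"recessive"`.
#' @return A tibble with one row per case-control study: `study_id`,
#'   `ethnicity`, `design`, `n_cases`, `n_controls`, `model`, the cells
#'   `a`, `b`, `c`, `d`, `correction_applied`, `log_or` and `variance`.
#' @export
#' @examples
#' kcnj11_table1() |> effect_sizes("allele") |> head()
effect_sizes <- function(studies,
                         model = c("allele", "heterozygous", "homozygous",
                                   "dominant", "recessive")) {
  model <- match.arg(model)
  validate_study_table(studies)
  cc <- studies %>% filter(.data$design %in% c("population", "both"))
  if (nrow(cc) == 0) abort("no case-control studies in the table")

  if (model == "allele") {
    no_maf <- cc$study_id[is.na(cc$maf_cases) | is.na(cc$maf_controls)]
    if (length(no_maf) > 0) {
      abort(paste0("allele model unavailable (no allele frequencies) for: ",
                   paste(no_maf, collapse = ", ")))
    }
    tab <- allele_table_from_maf(cc$n_cases, cc$n_controls,
                                 cc$maf_cases, cc$maf_controls)
  } else {
    geno <- c("ee_cases", "ek_cases", "kk_cases",
              "ee_controls", "ek_controls", "kk_controls")
    have <- all(geno %in% names(cc))
    absent <- if (!have) cc$study_id else {
      cc$study_id[!stats::complete.cases(cc[geno])]
    }
    if (length(absent) > 0) {
      abort(paste0(model, " model unavailable (no genotype counts) for: ",
                   paste(absent, collapse = ", ")))
    }
    tab <- genotype_table(cc$ee_cases, cc$ek_cases, cc$kk_cases,
                          cc$ee_controls, cc$ek_controls, cc$kk_controls,
                          model = model)
  }
  dplyr::bind_cols(
    cc %>% select("study_id", "ethnicity", "design", "n_cases", "n_controls"),
    tibble(model = model),
    tab
  ) %>% log_odds_ratio()
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of a genotype triple against
#' the Hardy-Weinberg proportions implied by its own allele frequency.
#' A monomorphic sample (allele frequency 0 or 1) is in equilibrium by
#' definition and returns `chi2 = 0`, `p = 1`.
#'
#' @param ee,ek,kk Genotype counts (vectorised).
#' @return A tibble with columns `chi2` and `p`.
#' @export
#' @examples
#' hwe_test(30, 40, 30)
hwe_test <- function(ee, ek, kk) {
  if (any(is.na(ee) | is.na(ek) | is.na(kk) | ee < 0 | ek < 0 | kk < 0)) {
    abort("genotype counts must be present and nonnegative")
  }
  n <- ee + ek + kk
  if (any(n == 0)) abort("empty genotype sample")
  q <- (ek + 2 * kk) / (2 * n)
  e_ee <- n * (1 - q)^2
  e_ek <- n * 2 * q * (1 - q)
  e_kk <- n * q^2
  chi2 <- ifelse(q == 0 | q == 1, 0,
                 (ee - e_ee)^2 / e_ee + (ek - e_ek)^2 / e_ek +
                   (kk - e_kk)^2 / e_kk)
  tibble(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# ---- internal -------------------------------------------------------------

# round half away from zero (arguments here are always nonnegative)
round_half_up <- function(x) floor(x + 0.5)

finish_table <- function(a, b, c_, d) {
  if (any(a + b <= 0) || any(c_ + d <= 0)) {
    abort("each arm must contribute a positive total")
  }
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  tibble(a = a + 0.5 * zero, b = b + 0.5 * zero,
         c = c_ + 0.5 * zero, d = d + 0.5 * zero,
         correction_applied = zero)
}
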