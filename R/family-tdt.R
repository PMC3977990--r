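#' Transmission-disequilibrium effect sizes for trio studies
#'
#' For each family-design study with transmission counts, computes the TDT
#' odds ratio as the ratio of risk alleles transmitted (`T`) to not
#' transmitted (`U`) from heterozygous parents to affected offspring:
#' `log_or = log(T/U)`, `variance = 1/T + 1/U`. If either count is zero
#' (but not both), 0.5 is added to both.
#'
#' @param studies A data frame with columns `transmitted` and
#'   `untransmitted` (and ideally `study_id`); rows missing either count
#'   are skipped.
#' @return An estimates tibble with `study_id`, `model = "tdt"`,
#'   `design = "family"`, `transmitted`, `untransmitted`, `log_or`,
#'   `variance` — poolable by [pool_dl()] or [pool_tdt()].
#' @export
#' @examples
#' tdt_effects(tibble::tibble(study_id = c("s1", "s2"),
#'                            transmitted = c(60, 45),
#'                            untransmitted = c(40, 55)))
tdt_effects <- function(studies) {
  if (!all(c("transmitted", "untransmitted") %in% names(studies))) {
    abort("need 'transmitted' and 'untransmitted' columns")
  }
  keep <- !is.na(studies$transmitted) & !is.na(studies$untransmitted)
  if (!any(keep)) abort("no study has transmission counts")
  st <- studies[keep, , drop = FALSE]
  t_ <- st$transmitted
  u_ <- st$untransmitted
  if (any(t_ < 0 | u_ < 0)) abort("transmission counts must be nonnegative")
  if (any(t_ + u_ == 0)) abort("transmitted and untransmitted both zero")
  corr <- t_ == 0 | u_ == 0
  t_ <- t_ + 0.5 * corr
  u_ <- u_ + 0.5 * corr
  tibble(
    study_id = if ("study_id" %in% names(st)) st$study_id
               else as.character(seq_len(nrow(st))),
    model = "tdt", design = "family",
    transmitted = st$transmitted, untransmitted = st$untransmitted,
    log_or = log(t_ / u_), variance = 1 / t_ + 1 / u_)
}

#' Pool TDT studies
#'
#' DerSimonian-Laird pooling of the per-study TDT estimates from
#' [tdt_effects()]; a single study falls back to its own estimate.
#'
#' @inheritParams tdt_effects
#' @inherit pool_fixed return
#' @export
pool_tdt <- function(studies) {
  est <- tdt_effects(studies)
  if (nrow(est) == 1) {
    return(suppressWarnings(pool_dl(est)))
  }
  pool_dl(est)
}

#' Combine case-control and family-based designs
#'
#' Two-stage stratified-design combination: case-control and TDT estimates
#' are each pooled by DerSimonian-Laird, and the two design-level estimates
#' are combined by inverse variance. A one-degree-of-freedom Q tests
#' cross-design consistency:
#' `q_design = sum(W_g * (theta_g - theta_comb)^2)` over the two designs,
#' with `W_g` the inverse squared design-level standard error. Robust to
#' population stratification on the family side, this asks whether the two
#' study designs estimate the same allelic effect.
#'
#' @param cc_estimates Case-control estimates (e.g. [effect_sizes()]).
#' @param tdt_estimates TDT estimates (e.g. [tdt_effects()]). Either list
#'   may be empty (`NULL`), in which case the other design's pool is
#'   returned with a warning and the consistency Q is undefined.
#' @return A `gamet_combined` object: `$combined` (one-row tibble with the
#'   combined log OR, SE, OR-scale CI, Z, p), `$by_design` (per-design
#'   [glance.gamet_pool()] rows), `$q_design`, `$p_design`.
#' @export
combine_designs <- function(cc_estimates, tdt_estimates) {
  has_cc <- !is.null(cc_estimates) && nrow(cc_estimates) > 0
  has_tdt <- !is.null(tdt_estimates) && nrow(tdt_estimates) > 0
  if (!has_cc && !has_tdt) abort("no estimates in either design")

  pools <- list()
  if (has_cc) pools$case_control <- pool_dl_quiet(cc_estimates)
  if (has_tdt) pools$family_tdt <- pool_dl_quiet(tdt_estimates)

  if (length(pools) == 1) {
    warn("only one design present: returning its pool; design Q undefined")
    only <- pools[[1]]
    return(new_gamet_combined(
      mu = only$pooled_log_or, se = only$se, pools = pools,
      q_design = NA_real_))
  }
  theta <- vapply(pools, function(p) p$pooled_log_or, numeric(1))
  W <- vapply(pools, function(p) 1 / p$se^2, numeric(1))
  mu <- sum(W * theta) / sum(W)
  se <- 1 / sqrt(sum(W))
  q_design <- sum(W * (theta - mu)^2)
  new_gamet_combined(mu = mu, se = se, pools = pools, q_design = q_design)
}

new_gamet_combined <- function(mu, se, pools, q_design) {
  z <- mu / se
  structure(
    list(
      combined = tibble(
        log_or = mu, se = se, or = exp(mu),
        ci_low = exp(mu - Z95 * se), ci_high = exp(mu + Z95 * se),
        z = z, p_z = 2 * pnorm(-abs(z))),
      by_design = purrr::map_dfr(
        names(pools), function(nm) {
          dplyr::bind_cols(tibble(design = nm), glance(pools[[nm]]))
        }),
      q_design = q_design,
      p_design = if (is.na(q_design)) NA_real_
                 else pchisq(q_design, 1, lower.tail = FALSE)),
    class = "gamet_combined")
}

pool_dl_quiet <- function(est) {
  if (nrow(est) < 2) suppressWarnings(pool_dl(est)) else pool_dl(est)
}

#' @export
print.gamet_combined <- function(x, ...) {
  cat("Combined case-control + family-based estimate\n")
  print(x$combined)
  if (!is.na(x$q_design)) {
    cat(sprintf("Design-consistency Q = %.3f on 1 df (p = %.3g)\n",
                x$q_design, x$p_design))
  }
  invisible(x)
}
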