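#' Fixed-effect (inverse-variance) pooling
#'
#' Pools per-study log odds ratios with weights `1/variance`. Cochran's Q is
#' computed against the fixed-effect mean; `i2 = max(0, (Q - df)/Q)`
#' summarises the fraction of variability beyond chance.
#'
#' @param estimates A data frame of per-study estimates with columns
#'   `log_or` and `variance` (and, ideally, `study_id`), e.g. from
#'   [effect_sizes()].
#' @return A `gamet_pool` object; see [glance.gamet_pool()] for the one-row
#'   summary (pooled log OR, SE, OR-scale 95% CI, Z and its p-value, Q, df,
#'   `p_q`, `tau2`, `i2`, `k`, `method`).
#' @seealso [pool_dl()], [pool_subgroups()], [leave_one_out()]
#' @export
#' @examples
#' kcnj11_table1() |> effect_sizes("allele") |> pool_fixed()
pool_fixed <- function(estimates) {
  est <- check_estimates(estimates)
  new_gamet_pool(pool_core(est$log_or, est$variance, method = "fixed"), est)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Pools per-study log odds ratios under the random-effects model with the
#' DerSimonian-Laird moments estimator of the between-study variance:
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w = 1/variance`, then random-effects weights
#' `1/(variance + tau2)`. When `Q <= k - 1` the estimator truncates at zero
#' and the result coincides with [pool_fixed()]. A single study falls back
#' to fixed-effect pooling with a warning.
#'
#' @inheritParams pool_fixed
#' @inherit pool_fixed return
#' @export
#' @examples
#' kcnj11_table1() |> effect_sizes("allele") |> pool_dl()
pool_dl <- function(estimates) {
  est <- check_estimates(estimates)
  if (nrow(est) < 2) {
    warn("only one study: falling back to fixed-effect pooling")
    return(new_gamet_pool(pool_core(est$log_or, est$variance, "fixed"), est))
  }
  new_gamet_pool(pool_core(est$log_or, est$variance, method = "dl"), est)
}

#' Subgroup (stratified) meta-analysis with between-subgroup heterogeneity
#'
#' Pools each stratum separately by [pool_dl()] and tests heterogeneity
#' between the stratum estimates:
#' `q_between = sum(W_g * (theta_g - theta_bar)^2)` where `W_g` is the
#' inverse squared standard error of stratum `g`'s (random-effects) pooled
#' estimate and `theta_bar` their `W_g`-weighted mean, referred to a
#' chi-square with `levels - 1` degrees of freedom.
#'
#' @inheritParams pool_fixed
#' @param group Column in `estimates` holding the stratum label
#'   (tidy-evaluated), e.g. one built with [ethnicity_group()] or
#'   [size_group()]. Rows with a missing label are dropped with a warning.
#' @return A `gamet_subgroups` object: per-level `gamet_pool`s in `$pools`,
#'   their one-row summaries stacked in `tidy()`, and `q_between`,
#'   `df_between`, `p_between` in `glance()`.
#' @export
#' @examples
#' kcnj11_table1() |>
#'   effect_sizes("allele") |>
#'   dplyr::mutate(group = ethnicity_group(ethnicity)) |>
#'   pool_subgroups(group)
pool_subgroups <- function(estimates, group) {
  est <- check_estimates(estimates)
  labels <- dplyr::pull(est, {{ group }})
  if (anyNA(labels)) {
    warn(paste0(sum(is.na(labels)),
                " estimate(s) with missing stratum label dropped"))
    est <- est[!is.na(labels), , drop = FALSE]
    labels <- labels[!is.na(labels)]
  }
  levels_ <- unique(labels)
  if (length(levels_) < 2) abort("need at least two strata")
  pools <- lapply(levels_, function(lv) pool_dl(est[labels == lv, ]))
  names(pools) <- levels_

  theta <- vapply(pools, function(p) p$pooled_log_or, numeric(1))
  W <- vapply(pools, function(p) 1 / p$se^2, numeric(1))
  theta_bar <- sum(W * theta) / sum(W)
  q_between <- sum(W * (theta - theta_bar)^2)
  df_between <- length(levels_) - 1
  structure(
    list(variable = as_label(enquo(group)), pools = pools,
         q_between = q_between, df_between = df_between,
         p_between = pchisq(q_between, df_between, lower.tail = FALSE)),
    class = "gamet_subgroups")
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the collection by [pool_dl()] after excluding each study in
#' turn, preserving input order. A pooled effect that keeps its sign and
#' significance across all rows indicates that no single study drives the
#' overall result.
#'
#' @inheritParams pool_fixed
#' @return A tibble with one row per excluded study: `excluded` plus the
#'   [glance.gamet_pool()] columns of the remaining k-1 studies.
#' @export
#' @examples
#' kcnj11_table1() |> effect_sizes("allele") |> leave_one_out() |> head()
leave_one_out <- function(estimates) {
  est <- check_estimates(estimates)
  if (nrow(est) < 3) abort("leave-one-out needs at least three studies")
  ids <- if ("study_id" %in% names(est)) est$study_id else as.character(seq_len(nrow(est)))
  purrr::map_dfr(seq_len(nrow(est)), function(i) {
    dplyr::bind_cols(tibble(excluded = ids[i]),
                     glance(pool_dl(est[-i, , drop = FALSE])))
  })
}

#' Ethnic-group labels for stratified analysis
#'
#' Maps the study table's verbatim ethnicity labels onto the four analysis
#' strata (Caucasian, East Asian, Indian, Other). The single row labelled
#' `"Chinese"` is by default assigned to no stratum (`NA`) — the published
#' stratified analysis counts 14 East Asian studies, which excludes it —
#' and can be folded into East Asian explicitly.
#'
#' @param ethnicity Character vector of verbatim labels.
#' @param map_chinese_to `"none"` (default, yields `NA`) or `"east_asian"`.
#' @return Character vector of stratum labels.
#' @export
#' @examples
#' ethnicity_group(c("Caucasian", "Chinese"), map_chinese_to = "east_asian")
ethnicity_group <- function(ethnicity, map_chinese_to = c("none", "east_asian")) {
  map_chinese_to <- match.arg(map_chinese_to)
  out <- ifelse(ethnicity %in% c("Caucasian", "East Asian", "Indian", "Other"),
                ethnicity, NA_character_)
  if (map_chinese_to == "east_asian") {
    out[ethnicity == "Chinese"] <- "East Asian"
  }
  out
}

#' Sample-size stratum labels
#'
#' Labels studies `"Large"` or `"Small"` by the number of cases, the
#' published stratification rule (cases >= 1000 by default).
#'
#' @param n_cases Number of cases per study.
#' @param threshold Case-count boundary for a `"Large"` study.
#' @return Character vector of `"Large"`/`"Small"`.
#' @export
size_group <- function(n_cases, threshold = 1000) {
  ifelse(n_cases >= threshold, "Large", "Small")
}

# ---- core computations ----------------------------------------------------

check_estimates <- function(estimates) {
  if (!is.data.frame(estimates) || nrow(estimates) == 0) {
    abort("need a non-empty data frame of estimates")
  }
  if (!all(c("log_or", "variance") %in% names(estimates))) {
    abort("estimates need 'log_or' and 'variance' columns")
  }
  if (any(!is.finite(estimates$log_or)) ||
        any(!is.finite(estimates$variance) | estimates$variance <= 0)) {
    abort("log_or must be finite and variance positive and finite")
  }
  as_tibble(estimates)
}

# inverse-variance pooling on (y, v); tau2 by the DL moments estimator
pool_core <- function(y, v, method = c("fixed", "dl")) {
  method <- match.arg(method)
  k <- length(y)
  w <- 1 / v
  mu_f <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_f)^2)
  df <- k - 1
  tau2 <- 0
  if (method == "dl" && k >= 2) {
    tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  }
  ws <- 1 / (v + tau2)
  mu <- sum(ws * y) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  z <- mu / se
  list(k = k, method = method,
       pooled_log_or = mu, se = se,
       ci_low = exp(mu - Z95 * se), ci_high = exp(mu + Z95 * se),
       z = z, p_z = 2 * pnorm(-abs(z)),
       Q = Q, df = df,
       p_q = if (df > 0) pchisq(Q, df, lower.tail = FALSE) else NA_real_,
       tau2 = tau2,
       i2 = if (Q > 0) max(0, (Q - df) / Q) else 0)
}

new_gamet_pool <- function(core, estimates) {
  core$estimates <- estimates
  structure(core, class = "gamet_pool")
}

#' @export
print.gamet_pool <- function(x, ...) {
  cat(sprintf("%s-effect pool of %d studies\n",
              if (x$method == "dl") "Random (DerSimonian-Laird)" else "Fixed",
              x$k))
  cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f), Z = %.2f, p = %.3g\n",
              exp(x$pooled_log_or), x$ci_low, x$ci_high, x$z, x$p_z))
  cat(sprintf("  Q = %.2f on %d df (p = %.3g), tau2 = %.4f, I2 = %.1f%%\n",
              x$Q, x$df, x$p_q, x$tau2, 100 * x$i2))
  invisible(x)
}

#' @export
print.gamet_subgroups <- function(x, ...) {
  cat(sprintf("Subgroup meta-analysis by '%s' (%d levels)\n",
              x$variable, length(x$pools)))
  print(tidy(x))
  cat(sprintf("Between-subgroup Q = %.2f on %d df (p = %.3g)\n",
              x$q_between, x$df_between, x$p_between))
  invisible(x)
}
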