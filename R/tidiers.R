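#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' One-row summary of a pooled result
#'
#' @param x A `gamet_pool` from [pool_fixed()] or [pool_dl()].
#' @param ... Unused.
#' @return A one-row tibble: `k`, `method`, `pooled_log_or`, `se`, `or`,
#'   `ci_low`, `ci_high` (OR scale), `z`, `p_z`, `Q`, `df`, `p_q`, `tau2`,
#'   `i2`.
#' @method glance gamet_pool
#' @export
glance.gamet_pool <- function(x, ...) {
  tibble(k = x$k, method = x$method,
         pooled_log_or = x$pooled_log_or, se = x$se,
         or = exp(x$pooled_log_or), ci_low = x$ci_low, ci_high = x$ci_high,
         z = x$z, p_z = x$p_z, Q = x$Q, df = x$df, p_q = x$p_q,
         tau2 = x$tau2, i2 = x$i2)
}

#' Per-study rows of a pooled result (forest-plot coordinates)
#'
#' One row per study with its OR, Woolf 95% CI and percentage weight under
#' the pool's weighting scheme — the numeric content of a forest plot.
#'
#' @inheritParams glance.gamet_pool
#' @return A tibble with `study_id` (when available), `log_or`, `variance`,
#'   `or`, `ci_low`, `ci_high`, `weight_pct`.
#' @method tidy gamet_pool
#' @export
tidy.gamet_pool <- function(x, ...) {
  est <- x$estimates
  w <- 1 / (est$variance + x$tau2)
  out <- tibble(
    log_or = est$log_or, variance = est$variance,
    or = exp(est$log_or),
    ci_low = exp(est$log_or - Z95 * sqrt(est$variance)),
    ci_high = exp(est$log_or + Z95 * sqrt(est$variance)),
    weight_pct = 100 * w / sum(w))
  if ("study_id" %in% names(est)) {
    out <- dplyr::bind_cols(tibble(study_id = est$study_id), out)
  }
  out
}

#' @method tidy gamet_subgroups
#' @export
tidy.gamet_subgroups <- function(x, ...) {
  purrr::map_dfr(names(x$pools), function(lv) {
    dplyr::bind_cols(tibble(level = lv), glance(x$pools[[lv]]))
  })
}

#' @method glance gamet_subgroups
#' @export
glance.gamet_subgroups <- function(x, ...) {
  tibble(variable = x$variable, levels = length(x$pools),
         q_between = x$q_between, df_between = x$df_between,
         p_between = x$p_between)
}
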