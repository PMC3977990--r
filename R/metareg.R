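#' Random-effects meta-regression (method of moments)
#'
#' Regresses per-study log odds ratios on study-level moderators under the
#' random-effects model. The residual between-study variance is estimated
#' by the moments (DerSimonian-Laird analogue) estimator on the
#' fixed-effect weighted residuals,
#' `tau2_res = max(0, (Q_E - (k - p)) / (sum(w) - tr((X'WX)^{-1} X'W^2 X)))`,
#' iterated once: the final coefficients and standard errors come from
#' weighted least squares with weights `1/(variance + tau2_res)`. The
#' proportion of heterogeneity explained compares `tau2_res` with the
#' intercept-only (null) model's `tau2`.
#'
#' @inheritParams pool_fixed
#' @param moderators A one-sided formula naming moderator columns of
#'   `estimates`, e.g. `~ bmi` or `~ ethnicity + log(n_cases)`. Categorical
#'   moderators are dummy-coded against their first level in input order.
#'   Rows with a missing moderator are dropped (with a message reporting
#'   how many).
#' @return A `gamet_metareg` object. `tidy()` gives the coefficient table
#'   (`term`, `estimate`, `std_error`, `statistic`, `p_value`; Wald normal
#'   tests); `glance()` gives `k`, `k_dropped`, `tau2_residual`,
#'   `tau2_null`, `prop_explained` (clamped to `[0, 1]`, `NA` when the null
#'   model shows no heterogeneity) and the residual heterogeneity test
#'   `q_e`, `df_e`, `p_q_e`.
#' @export
#' @examples
#' sim <- simulate_with_covariate(k_studies = 60, tau2 = 0.05,
#'                                cov_fraction_of_tau2 = 0.5, seed = 7)
#' sim |> effect_sizes("allele") |>
#'   dplyr::left_join(dplyr::select(sim, study_id, x_cov), by = "study_id") |>
#'   meta_regress(~ x_cov) |>
#'   glance()
meta_regress <- function(estimates, moderators) {
  est <- check_estimates(estimates)
  if (!inherits(moderators, "formula")) {
    abort("'moderators' must be a one-sided formula, e.g. ~ bmi")
  }
  vars <- all.vars(moderators)
  missing_vars <- setdiff(vars, names(est))
  if (length(missing_vars) > 0) {
    abort(paste0("moderator column(s) not in estimates: ",
                 paste(missing_vars, collapse = ", ")))
  }
  complete <- stats::complete.cases(est[vars])
  k_dropped <- sum(!complete)
  if (k_dropped > 0) {
    inform(paste0(k_dropped, " study(ies) dropped for missing moderators"))
    est <- est[complete, , drop = FALSE]
  }
  dat <- est
  # dummy-code character moderators against their first level in input order
  for (v in vars) {
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]], levels = unique(dat[[v]]))
  }
  X <- stats::model.matrix(moderators, data = dat)
  k <- nrow(X); p <- ncol(X)
  if (qr(X)$rank < p) {
    keep <- qr(X)$pivot[seq_len(qr(X)$rank)]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(colnames(X)[-keep], collapse = ", ")))
  }
  if (k < p + 2) abort("need at least p + 2 studies for meta-regression")

  y <- est$log_or
  v <- est$variance
  fit0 <- wls_fit(X, y, 1 / v)
  q_e <- fit0$rss_w
  tr_corr <- sum(diag(fit0$xtwx_inv %*% crossprod(X * (1 / v)^2, X)))
  tau2_res <- max(0, (q_e - (k - p)) / (sum(1 / v) - tr_corr))

  fit <- wls_fit(X, y, 1 / (v + tau2_res))
  se <- unname(sqrt(diag(fit$xtwx_inv)))
  zstat <- as.numeric(fit$beta) / se

  null_tau2 <- pool_core(y, v, method = "dl")$tau2
  prop <- if (null_tau2 > 0) max(0, min(1, 1 - tau2_res / null_tau2)) else NA_real_

  structure(
    list(
      coefficients = tibble(
        term = colnames(X), estimate = as.numeric(fit$beta),
        std_error = se, statistic = zstat,
        p_value = 2 * pnorm(-abs(zstat))),
      tau2_residual = tau2_res, tau2_null = null_tau2,
      prop_explained = prop,
      q_e = q_e, df_e = k - p,
      p_q_e = pchisq(q_e, k - p, lower.tail = FALSE),
      k = k, k_dropped = k_dropped, moderators = moderators),
    class = "gamet_metareg")
}

#' @method tidy gamet_metareg
#' @export
tidy.gamet_metareg <- function(x, ...) x$coefficients

#' @method glance gamet_metareg
#' @export
glance.gamet_metareg <- function(x, ...) {
  tibble(k = x$k, k_dropped = x$k_dropped,
         tau2_residual = x$tau2_residual, tau2_null = x$tau2_null,
         prop_explained = x$prop_explained,
         q_e = x$q_e, df_e = x$df_e, p_q_e = x$p_q_e)
}

#' @export
print.gamet_metareg <- function(x, ...) {
  cat(sprintf("Meta-regression on %s (k = %d)\n",
              deparse(x$moderators), x$k))
  print(x$coefficients)
  cat(sprintf("tau2 residual = %.4f, null = %.4f; heterogeneity explained = %s\n",
              x$tau2_residual, x$tau2_null,
              if (is.na(x$prop_explained)) "NA"
              else sprintf("%.1f%%", 100 * x$prop_explained)))
  invisible(x)
}

#' Egger regression test for small-study effects
#'
#' Classical Egger test: ordinary least squares of the standardised effect
#' `z_i = log_or_i / sqrt(variance_i)` on the precision
#' `x_i = 1 / sqrt(variance_i)`; a nonzero intercept signals funnel-plot
#' asymmetry (small-study / publication bias). The intercept is tested
#' against zero with a t distribution on `k - 2` degrees of freedom.
#'
#' @inheritParams pool_fixed
#' @return A one-row tibble: `k`, `intercept`, `intercept_se`, `t`, `p`
#'   (two-sided, `k - 2` df), `slope`.
#' @export
#' @examples
#' kcnj11_table1() |> effect_sizes("allele") |> egger_test()
egger_test <- function(estimates) {
  est <- check_estimates(estimates)
  k <- nrow(est)
  if (k < 3) abort("Egger's test needs at least three studies")
  prec <- 1 / sqrt(est$variance)
  snd <- est$log_or * prec
  if (length(unique(prec)) == 1) {
    warn("all precisions equal: intercept and slope are not separable")
    m <- mean(snd)
    s <- stats::sd(snd) / sqrt(k)
    return(tibble(k = k, intercept = m, intercept_se = s,
                  t = m / s, p = 2 * pt(-abs(m / s), df = k - 2),
                  slope = NA_real_))
  }
  fit <- lm(snd ~ prec)
  cf <- summary(fit)$coefficients
  tibble(k = k,
         intercept = cf[1, 1], intercept_se = cf[1, 2],
         t = cf[1, 3], p = 2 * pt(-abs(cf[1, 3]), df = k - 2),
         slope = cf[2, 1])
}

#' Funnel-plot coordinates
#'
#' Per-study points (log OR against its standard error) plus the pseudo-95%
#' confidence funnel around the fixed-effect pooled estimate: boundary
#' lines `pooled +/- 1.96 * se` over the standard-error range from the apex
#' (se = 0) to the least precise study. No graphics are produced; see
#' [ggplot2::autoplot()] for the plot.
#'
#' @inheritParams pool_fixed
#' @return A `gamet_funnel` object: `$points` (one row per study:
#'   `study_id` when available, `log_or`, `se`), `$center` (fixed-effect
#'   pooled log OR), `$boundary` (tibble of `se`, `lower`, `upper`).
#' @export
funnel_coordinates <- function(estimates) {
  est <- check_estimates(estimates)
  pooled <- pool_core(est$log_or, est$variance, method = "fixed")$pooled_log_or
  se <- sqrt(est$variance)
  points <- tibble(log_or = est$log_or, se = se)
  if ("study_id" %in% names(est)) {
    points <- dplyr::bind_cols(tibble(study_id = est$study_id), points)
  }
  se_grid <- seq(0, max(se), length.out = 50)
  structure(
    list(points = points, center = pooled,
         boundary = tibble(se = se_grid,
                           lower = pooled - Z95 * se_grid,
                           upper = pooled + Z95 * se_grid)),
    class = "gamet_funnel")
}

#' @export
print.gamet_funnel <- function(x, ...) {
  cat(sprintf("Funnel coordinates for %d studies (center log OR %.4f)\n",
              nrow(x$points), x$center))
  print(x$points)
  invisible(x)
}

# weighted least squares; returns beta, (X'WX)^-1 and weighted RSS
wls_fit <- function(X, y, w) {
  xtwx <- crossprod(X * w, X)
  xtwx_inv <- solve(xtwx)
  beta <- xtwx_inv %*% crossprod(X * w, y)
  resid <- y - as.numeric(X %*% beta)
  list(beta = beta, xtwx_inv = xtwx_inv, rss_w = sum(w * resid^2))
}
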