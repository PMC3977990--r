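#' Forest plot of a pooled result
#'
#' @param object A `gamet_pool`.
#' @param ... Unused.
#' @return A ggplot: per-study ORs with 95% CIs on a log axis, point size
#'   proportional to pooling weight, a diamond-coloured row for the pooled
#'   estimate and a reference line at OR = 1.
#' @method autoplot gamet_pool
#' @export
autoplot.gamet_pool <- function(object, ...) {
  rows <- tidy(object)
  if (!"study_id" %in% names(rows)) {
    rows$study_id <- as.character(seq_len(nrow(rows)))
  }
  pooled <- glance(object)
  dat <- bind_rows(
    rows %>% mutate(kind = "study"),
    tibble(study_id = "Pooled", or = pooled$or, ci_low = pooled$ci_low,
           ci_high = pooled$ci_high, weight_pct = 100, kind = "pooled"))
  dat$study_id <- factor(dat$study_id, levels = rev(dat$study_id))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$or, y = .data$study_id,
                                    colour = .data$kind)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight_pct)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(study = "black",
                                            pooled = "firebrick"),
                                 guide = "none") +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Funnel plot from precomputed coordinates
#'
#' @param object A `gamet_funnel` from [funnel_coordinates()].
#' @param ... Unused.
#' @return A ggplot: log OR against standard error (inverted axis) with the
#'   pseudo-95% confidence funnel around the fixed-effect estimate.
#' @method autoplot gamet_funnel
#' @export
autoplot.gamet_funnel <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$log_or, y = .data$se)) +
    ggplot2::geom_line(data = object$boundary,
                       ggplot2::aes(x = .data$lower, y = .data$se),
                       linetype = "dotted") +
    ggplot2::geom_line(data = object$boundary,
                       ggplot2::aes(x = .data$upper, y = .data$se),
                       linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$center, colour = "grey50") +
    ggplot2::geom_point(shape = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "log odds ratio", y = "Standard error") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
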