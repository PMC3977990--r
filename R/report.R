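#' Run the full meta-analysis pipeline on a study table
#'
#' Executes every stage the package implements, in the order of the
#' published analysis: allele-contrast pooling (always), the four
#' genotype-based genetic models where genotype counts exist, stratified
#' analyses by ethnicity and sample size (and by mean case BMI where the
#' column exists), leave-one-out sensitivity, the Egger small-study test,
#' funnel coordinates, control-allele-frequency summaries, population
#' attributable risk, power/sample-size requirements per ethnic stratum,
#' and TDT pooling plus cross-design combination where transmission counts
#' exist. Sections whose inputs are absent from the table are marked
#' `"unavailable"` with a reason rather than failing the run. The result is
#' deterministic given the inputs.
#'
#' @param studies A validated study tibble.
#' @param map_chinese_to Passed to [ethnicity_group()]: where the
#'   `"Chinese"`-labelled study belongs in the ethnicity stratification.
#' @param size_threshold Case-count boundary for [size_group()].
#' @return A `gamet_report` object: a named list of sections, each either a
#'   result object/tibble or the string `"unavailable: <reason>"`.
#' @export
#' @examples
#' report <- run_full_analysis(kcnj11_table1())
#' report$models$allele
run_full_analysis <- function(studies,
                              map_chinese_to = c("none", "east_asian"),
                              size_threshold = 1000) {
  map_chinese_to <- match.arg(map_chinese_to)
  validate_study_table(studies)

  section <- function(expr) {
    tryCatch(expr, error = function(e) {
      paste0("unavailable: ", conditionMessage(e))
    })
  }

  models <- lapply(
    setNames(nm = c("allele", "heterozygous", "homozygous",
                    "dominant", "recessive")),
    function(m) section(pool_dl(effect_sizes(studies, m))))

  allele_est <- section(effect_sizes(studies, "allele"))
  have_allele <- is.data.frame(allele_est)

  subgroups <- list(
    ethnicity = section({
      est <- effect_sizes(studies, "allele") %>%
        mutate(group = ethnicity_group(.data$ethnicity,
                                       map_chinese_to = map_chinese_to))
      suppressWarnings(pool_subgroups(est, .data$group))
    }),
    sample_size = section({
      est <- effect_sizes(studies, "allele") %>%
        mutate(group = size_group(.data$n_cases, threshold = size_threshold))
      pool_subgroups(est, .data$group)
    }),
    bmi = section({
      if (!"bmi_cases" %in% names(studies) || all(is.na(studies$bmi_cases))) {
        abort("no per-study mean case BMI in the table")
      }
      bmi <- studies %>% select("study_id", "bmi_cases")
      est <- effect_sizes(studies, "allele") %>%
        left_join(bmi, by = "study_id") %>%
        mutate(group = as.character(cut(.data$bmi_cases,
                                        breaks = c(-Inf, 25, 30, Inf),
                                        labels = c("<25", "25-30", ">30"))))
      suppressWarnings(pool_subgroups(est, .data$group))
    }))

  sensitivity <- section(leave_one_out(effect_sizes(studies, "allele")))
  egger <- section(egger_test(effect_sizes(studies, "allele")))
  funnel <- section(funnel_coordinates(effect_sizes(studies, "allele")))

  strata <- intersect(c("Caucasian", "East Asian", "Indian", "Other"),
                      unique(studies$ethnicity))
  frequencies <- section(bind_rows(
    control_freq_summary(studies),
    purrr::map_dfr(strata, function(e) control_freq_summary(studies, e))))

  eth_pools <- if (is.character(subgroups$ethnicity)) NULL else subgroups$ethnicity

  par_table <- section({
    rows <- tibble(stratum = "overall",
                   or = exp(models$allele$pooled_log_or),
                   raf = control_freq_summary(studies)$mean)
    if (!is.null(eth_pools)) {
      rows <- bind_rows(rows, purrr::map_dfr(names(eth_pools$pools), function(e) {
        tibble(stratum = e,
               or = exp(eth_pools$pools[[e]]$pooled_log_or),
               raf = control_freq_summary(studies, e)$mean)
      }))
    }
    rows %>% mutate(par = attributable_risk(.data$or, .data$raf))
  })

  power_table <- section({
    if (is.null(eth_pools)) abort("no ethnicity strata")
    purrr::map_dfr(names(eth_pools$pools), function(e) {
      # the published summary inputs: stratum OR and control frequency to 2 dp
      or2 <- round(exp(eth_pools$pools[[e]]$pooled_log_or), 2)
      p02 <- round(control_freq_summary(studies, e)$mean, 2)
      if (or2 == 1) {
        return(tibble(stratum = e, p0 = p02, or = or2, p1 = NA_real_,
                      alleles_per_group = NA_real_, n_per_group = NA_real_,
                      n_presented = NA_real_))
      }
      bind_cols(tibble(stratum = e),
                sample_size_for_power(p0 = p02, or = or2))
    })
  })

  tdt <- section({
    if (!all(c("transmitted", "untransmitted") %in% names(studies)) ||
          !any(!is.na(studies$transmitted) & !is.na(studies$untransmitted))) {
      abort("no per-study transmission counts in the table")
    }
    pool_tdt(studies)
  })
  combined <- section({
    if (!inherits(tdt, "gamet_pool")) abort("TDT section unavailable")
    if (!have_allele) abort("allele section unavailable")
    combine_designs(allele_est, tdt_effects(studies))
  })

  structure(
    list(summary = summarize_studies(studies),
         models = models,
         allele_estimates = allele_est,
         subgroups = subgroups,
         sensitivity = sensitivity,
         egger = egger,
         funnel = funnel,
         frequencies = frequencies,
         par = par_table,
         power = power_table,
         tdt = tdt,
         combined = combined,
         provenance = list(
           input = attr(studies, "provenance") %||% "in-memory table",
           map_chinese_to = map_chinese_to,
           size_threshold = size_threshold,
           package_version = as.character(packageVersion("gamet")))),
    class = "gamet_report")
}

#' @export
print.gamet_report <- function(x, ...) {
  cat("Full genetic-association meta-analysis report\n")
  s <- x$summary
  cat(sprintf("  %d studies: %s cases, %s controls, %s trios\n",
              s$n_studies, format(s$total_cases, big.mark = ","),
              format(s$total_controls, big.mark = ","), s$total_trios))
  for (m in names(x$models)) {
    res <- x$models[[m]]
    if (inherits(res, "gamet_pool")) {
      cat(sprintf("  %-12s OR %.2f (%.2f-%.2f), k = %d\n", m,
                  exp(res$pooled_log_or), res$ci_low, res$ci_high, res$k))
    } else {
      cat(sprintf("  %-12s %s\n", m, res))
    }
  }
  invisible(x)
}

#' Write a report to disk
#'
#' `format = "json"` writes one schema-versioned JSON document;
#' `format = "tsv_bundle"` writes one TSV per section into a directory.
#' Presentation columns (`or_2dp` and friends, rounded to 2 decimals) are
#' added here and only here — computation paths carry full precision.
#'
#' @param report A `gamet_report` from [run_full_analysis()].
#' @param path Output file (json) or directory (tsv_bundle).
#' @param format `"tsv_bundle"` or `"json"`.
#' @return The paths written, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv_bundle", "json")) {
  format <- match.arg(format)
  if (!inherits(report, "gamet_report")) abort("not a gamet_report")
  if (format == "json") {
    jsonlite::write_json(report_as_list(report), path,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  written <- character(0)
  emit <- function(name, df) {
    f <- file.path(path, paste0(name, ".tsv"))
    readr::write_tsv(df, f, na = "NA", progress = FALSE)
    written <<- c(written, f)
  }
  present <- function(df) {
    for (col in intersect(c("or", "ci_low", "ci_high", "mean"), names(df))) {
      df[[paste0(col, "_2dp")]] <- round(df[[col]], 2)
    }
    df
  }

  emit("summary", report$summary %>% select(-"ethnicity_counts"))
  emit("ethnicity_counts", report$summary$ethnicity_counts[[1]])
  pooled <- purrr::map_dfr(names(report$models), function(m) {
    res <- report$models[[m]]
    if (inherits(res, "gamet_pool")) {
      bind_cols(tibble(model = m), glance(res))
    } else {
      tibble(model = m, note = res)
    }
  })
  emit("pooled_models", present(pooled))
  if (inherits(report$models$allele, "gamet_pool")) {
    forest <- bind_rows(
      tidy(report$models$allele),
      glance(report$models$allele) %>%
        mutate(study_id = "POOLED (DL)", weight_pct = 100) %>%
        rename(log_or = "pooled_log_or") %>%
        select("study_id", "log_or", "or", "ci_low", "ci_high", "weight_pct"))
    emit("forest_allele", present(forest))
  }
  sub <- purrr::map_dfr(names(report$subgroups), function(v) {
    res <- report$subgroups[[v]]
    if (inherits(res, "gamet_subgroups")) {
      bind_cols(tibble(variable = v), tidy(res),
                glance(res) %>% select("q_between", "df_between", "p_between"))
    } else {
      tibble(variable = v, note = res)
    }
  })
  emit("subgroups", present(sub))
  if (is.data.frame(report$sensitivity)) {
    emit("sensitivity", present(report$sensitivity))
  }
  if (is.data.frame(report$egger)) emit("egger", report$egger)
  if (inherits(report$funnel, "gamet_funnel")) {
    emit("funnel_points", report$funnel$points)
    emit("funnel_boundary", report$funnel$boundary)
  }
  if (is.data.frame(report$frequencies)) {
    emit("frequencies", present(report$frequencies))
  }
  if (is.data.frame(report$par)) emit("par", report$par)
  if (is.data.frame(report$power)) emit("power", report$power)
  if (inherits(report$tdt, "gamet_pool")) {
    emit("tdt", present(glance(report$tdt)))
  }
  if (inherits(report$combined, "gamet_combined")) {
    emit("combined_designs",
         bind_cols(report$combined$combined,
                   tibble(q_design = report$combined$q_design,
                          p_design = report$combined$p_design)))
  }
  emit("provenance", as_tibble(report$provenance))
  invisible(written)
}

# serializable representation of a report (schema-versioned)
report_as_list <- function(report) {
  pool_list <- function(p) as.list(glance(p))
  sec <- function(x) {
    if (inherits(x, "gamet_pool")) {
      pool_list(x)
    } else if (inherits(x, "gamet_subgroups")) {
      list(levels = tidy(x), between = as.list(glance(x)))
    } else if (inherits(x, "gamet_funnel")) {
      list(points = x$points, center = x$center, boundary = x$boundary)
    } else if (inherits(x, "gamet_combined")) {
      list(combined = as.list(x$combined), by_design = x$by_design,
           q_design = x$q_design, p_design = x$p_design)
    } else if (is.data.frame(x)) {
      x
    } else {
      x
    }
  }
  list(
    schema = "gamet-report/1",
    summary = c(as.list(report$summary %>% select(-"ethnicity_counts")),
                list(ethnicity_counts = report$summary$ethnicity_counts[[1]])),
    models = lapply(report$models, sec),
    subgroups = lapply(report$subgroups, sec),
    sensitivity = sec(report$sensitivity),
    egger = sec(report$egger),
    funnel = sec(report$funnel),
    frequencies = sec(report$frequencies),
    par = sec(report$par),
    power = sec(report$power),
    tdt = sec(report$tdt),
    combined = sec(report$combined),
    provenance = report$provenance)
}
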