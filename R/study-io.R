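#' Read a per-study summary table
#'
#' Reads the tabular summary of genetic association studies that every other
#' function in gamet consumes: one row per study, with arm sizes, risk-allele
#' frequencies, optional genotype counts, optional trio (TDT) counts and
#' optional per-arm covariates. Every row is validated against the schema
#' invariants; offending rows are reported by index.
#'
#' @param path Path to a delimited text file with one header row. Missing
#'   values may be encoded as empty cells or `"NA"`.
#' @param dialect `"tsv"` (default) or `"csv"`.
#'
#' @details
#' Mandatory columns: `study_id`, `year`, `ethnicity`, `design` (one of
#' `"population"`, `"family"`, `"both"`), `n_cases`, `n_controls`,
#' `maf_cases`, `maf_controls` (risk-allele frequency per arm, in `[0, 1]`;
#' arm sizes and frequencies may be missing for family-only rows).
#' Optional columns: genotype counts `ee_cases`, `ek_cases`, `kk_cases` and
#' the `_controls` triple (must sum to the arm size and agree with the arm's
#' allele frequency to within 0.005 when both are present), `n_trios`,
#' `transmitted`, `untransmitted` (risk-allele transmissions from
#' heterozygous parents; required together), `bmi_cases`, `bmi_controls`,
#' `age_cases`, `age_controls`, `pct_male_cases`, `pct_male_controls`, and
#' `hwe_p` (the control-arm Hardy-Weinberg p-value as reported, kept
#' verbatim as text so entries like `">0.05"` survive).
#'
#' @return A tibble with one validated row per study, ordered as in the
#'   file, with a `"provenance"` attribute recording the source path.
#' @seealso [kcnj11_table1()] for the packaged 48-study table,
#'   [write_study_table()], [summarize_studies()]
#' @export
#' @examples
#' studies <- kcnj11_table1()
#' dplyr::count(studies, design)
read_study_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("study table not found: ", path))
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                na = c("", "NA"), progress = FALSE)
  missing_cols <- setdiff(mandatory_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  studies <- coerce_study_columns(raw)
  validate_study_table(studies)
  attr(studies, "provenance") <- path
  studies
}

#' Write a per-study summary table
#'
#' Inverse of [read_study_table()]: writes the table so that re-reading it
#' reproduces an identical tibble (missing values as `"NA"`, full numeric
#' precision).
#'
#' @param studies A validated study tibble.
#' @param path Output file path.
#' @inheritParams read_study_table
#' @return `path`, invisibly.
#' @export
write_study_table <- function(studies, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  validate_study_table(studies)
  writer <- if (dialect == "tsv") readr::write_tsv else readr::write_csv
  writer(studies, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' The packaged 48-study KCNJ11 E23K / type 2 diabetes table
#'
#' Returns the summary table of the 48 published association studies of the
#' KCNJ11 E23K polymorphism (rs5219) and type 2 diabetes: 46 population
#' case-control studies, one family-trio study (Altshuler 2000, 333 trios)
#' and one study contributing both arms (Gloyn 2003, 150 trios). The MAF
#' columns carry the reported frequency of the risk (23K) allele per arm —
#' nominally the minor allele, retained verbatim even where it exceeds 0.5.
#' Genotype counts, per-study transmission counts and covariates were not
#' published at the study level and are absent.
#'
#' @return A 48-row study tibble (see [read_study_table()] for the schema).
#' @export
#' @examples
#' summarize_studies(kcnj11_table1())
kcnj11_table1 <- function() {
  read_study_table(gamet_example("kcnj11_t2d_table1.tsv"))
}

#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata/`; `NULL` lists them.
#' @return A file path, or a character vector of available file names.
#' @export
gamet_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "gamet"))
  } else {
    path <- system.file("extdata", file, package = "gamet", mustWork = FALSE)
    if (!nzchar(path)) abort(paste0("no packaged file named '", file, "'"))
    path
  }
}

#' Table-level totals for a study collection
#'
#' @param studies A validated study tibble.
#' @return A one-row tibble: `n_studies`, `total_cases`, `total_controls`
#'   (summed over population and dual-design rows), `total_trios` (summed
#'   over family and dual-design rows), and `ethnicity_counts`, a
#'   list-column holding the per-ethnicity study counts.
#' @export
#' @examples
#' summarize_studies(kcnj11_table1())
summarize_studies <- function(studies) {
  validate_study_table(studies)
  cc <- studies$design %in% c("population", "both")
  fam <- studies$design %in% c("family", "both")
  tibble(
    n_studies = nrow(studies),
    total_cases = sum(studies$n_cases[cc], na.rm = TRUE),
    total_controls = sum(studies$n_controls[cc], na.rm = TRUE),
    total_trios = if (any(fam)) sum(studies$n_trios[fam], na.rm = TRUE) else 0L,
    ethnicity_counts = list(dplyr::count(studies, .data$ethnicity))
  )
}

# ---- internal -------------------------------------------------------------

mandatory_columns <- function() {
  c("study_id", "year", "ethnicity", "design",
    "n_cases", "n_controls", "maf_cases", "maf_controls")
}

count_columns <- function() {
  c("n_cases", "n_controls", "ee_cases", "ek_cases", "kk_cases",
    "ee_controls", "ek_controls", "kk_controls",
    "n_trios", "transmitted", "untransmitted")
}

numeric_columns <- function() {
  c(count_columns(), "maf_cases", "maf_controls",
    "bmi_cases", "bmi_controls", "age_cases", "age_controls",
    "pct_male_cases", "pct_male_controls")
}

coerce_study_columns <- function(raw) {
  out <- raw
  for (col in intersect(c("year", numeric_columns()), names(raw))) {
    txt <- raw[[col]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & is.na(val))
    if (length(bad) > 0) {
      abort(paste0("non-numeric value in column '", col, "' at row(s) ",
                   paste(bad, collapse = ", ")))
    }
    if (col %in% c("year", count_columns())) {
      frac <- which(!is.na(val) & val != trunc(val))
      if (length(frac) > 0) {
        abort(paste0("non-integer count in column '", col, "' at row(s) ",
                     paste(frac, collapse = ", ")))
      }
      val <- as.integer(val)
    }
    out[[col]] <- val
  }
  out
}

#' Validate a study tibble against the schema invariants
#'
#' Checks the invariants documented in [read_study_table()] and aborts with
#' row-indexed messages on the first group of violations found.
#'
#' @param studies A study tibble.
#' @return `studies`, invisibly.
#' @export
validate_study_table <- function(studies) {
  if (!is.data.frame(studies) || nrow(studies) == 0) {
    abort("a study table needs at least one record")
  }
  missing_cols <- setdiff(mandatory_columns(), names(studies))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- studies$study_id[duplicated(studies$study_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate study_id: ", paste(unique(dup), collapse = ", ")))
  }
  bad_design <- which(!studies$design %in% c("population", "family", "both"))
  if (length(bad_design) > 0) {
    abort(paste0("design must be population/family/both at row(s) ",
                 paste(bad_design, collapse = ", ")))
  }

  problems <- character(0)
  flag <- function(rows, msg) {
    if (length(rows) > 0) {
      problems <<- c(problems,
                     paste0("row ", paste(rows, collapse = ", "), ": ", msg))
    }
  }
  cc <- studies$design %in% c("population", "both")
  fam <- studies$design %in% c("family", "both")

  neg <- function(x) which(!is.na(x) & x < 0)
  flag(neg(studies$n_cases), "negative n_cases")
  flag(neg(studies$n_controls), "negative n_controls")
  flag(which(cc & (is.na(studies$n_cases) | studies$n_cases <= 0)),
       "case-control design requires n_cases > 0")
  flag(which(cc & (is.na(studies$n_controls) | studies$n_controls <= 0)),
       "case-control design requires n_controls > 0")
  for (col in c("maf_cases", "maf_controls")) {
    x <- studies[[col]]
    flag(which(!is.na(x) & (x < 0 | x > 1)), paste0(col, " outside [0, 1]"))
  }

  for (arm in c("cases", "controls")) {
    geno <- paste0(c("ee_", "ek_", "kk_"), arm)
    if (!all(geno %in% names(studies))) next
    g <- studies[geno]
    present <- !is.na(g[[1]]) | !is.na(g[[2]]) | !is.na(g[[3]])
    complete <- !is.na(g[[1]]) & !is.na(g[[2]]) & !is.na(g[[3]])
    flag(which(present & !complete),
         paste0("incomplete genotype triple for ", arm))
    n_arm <- studies[[paste0("n_", arm)]]
    total <- g[[1]] + g[[2]] + g[[3]]
    flag(which(complete & !is.na(n_arm) & total != n_arm),
         paste0("genotype counts do not sum to n_", arm))
    maf <- studies[[paste0("maf_", arm)]]
    implied <- (g[[2]] + 2 * g[[3]]) / (2 * total)
    flag(which(complete & !is.na(maf) & total > 0 &
                 abs(implied - maf) > 0.005),
         paste0("genotype counts inconsistent with maf_", arm))
  }

  flag(which(fam & (is.na(studies$n_trios) | studies$n_trios <= 0)),
       "family design requires n_trios > 0")
  if (all(c("transmitted", "untransmitted") %in% names(studies))) {
    t_ <- studies$transmitted; u_ <- studies$untransmitted
    flag(which(is.na(t_) != is.na(u_)),
         "transmitted/untransmitted must be present together")
    flag(which(!is.na(t_) & !is.na(u_) & (t_ < 0 | u_ < 0 | t_ + u_ == 0)),
         "transmitted + untransmitted must be positive")
  }

  if (length(problems) > 0) {
    abort(paste0("invalid study table:\n",
                 paste("-", problems, collapse = "\n")))
  }
  invisible(studies)
}
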