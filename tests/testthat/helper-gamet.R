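# bare estimates tibble from log ORs and variances
make_est <- function(y, v, id = sprintf("s%02d", seq_along(y))) {
  tibble::tibble(study_id = id, log_or = y, variance = v)
}

# a small fully-populated study table (genotype counts, trios) for tests
# that need every optional column
toy_table <- function() {
  tibble::tibble(
    study_id = c("a", "b", "fam"),
    year = c(2001L, 2002L, 2003L),
    ethnicity = c("Caucasian", "East Asian", "Caucasian"),
    design = c("population", "population", "family"),
    n_cases = c(100L, 110L, NA),
    n_controls = c(100L, 105L, NA),
    maf_cases = c((50 + 2 * 20) / 200, (55 + 2 * 25) / 220, NA),
    maf_controls = c((45 + 2 * 15) / 200, (50 + 2 * 20) / 210, NA),
    ee_cases = c(30L, 30L, NA), ek_cases = c(50L, 55L, NA),
    kk_cases = c(20L, 25L, NA),
    ee_controls = c(40L, 35L, NA), ek_controls = c(45L, 50L, NA),
    kk_controls = c(15L, 20L, NA),
    n_trios = c(NA, NA, 200L),
    transmitted = c(NA, NA, 120L), untransmitted = c(NA, NA, 100L),
    hwe_p = c("0.5", "0.5", NA))
}
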