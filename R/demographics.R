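# Reference cohort demographics: the 18-participant clinical cohort
# (6 PD controls, 6 PD intervention, 6 healthy) whose printed demographic
# table ships with the package so its group summaries and between-group
# tests are exactly recomputable.

#' Reference cohort demographic table
#'
#' One row per participant: `subject_id` (C = PD control, E = PD
#' intervention/TPEI, H = healthy), `group`, `bmi` (kg/m^2), `age`
#' (years), `sex`.
#'
#' @return An 18-row tibble.
#' @export
reference_demographics <- function() {
  tibble(
    subject_id = c(sprintf("C%02d", 1:6), sprintf("E%02d", 1:6), sprintf("H%02d", 1:6)),
    group = rep(c("pd_control", "pd_tpei", "healthy"), each = 6),
    bmi = c(24.8, 25.5, 26, 26, 23.4, 27.5,
            23.2, 33.5, 18.3, 26.8, 18.7, 24.9,
            20.52, 23.44, 23.34, 30.12, 21.77, 23.51),
    age = c(59, 70, 76, 69, 79, 56,
            47, 60, 40, 47, 36, 75,
            22, 23, 23, 24, 24, 26),
    sex = c("F", "M", "M", "M", "F", "M",
            "M", "M", "M", "M", "F", "M",
            "M", "F", "F", "M", "F", "M")
  )
}

#' Demographic group summaries and between-group tests
#'
#' Recomputes, from [reference_demographics()] (or any table of the same
#' shape), the per-group mean and SD of each numeric demographic variable,
#' Welch two-sided p-values for PD-control vs PD-TPEI and pooled-PD vs
#' healthy, and Cohen's d (PD-control minus PD-TPEI).
#'
#' @param demographics Tibble with `group` plus numeric columns.
#' @param variables Numeric columns to summarise.
#' @return Tibble: one row per variable with per-group `mean_*`/`sd_*`,
#'   `p_control_vs_tpei`, `p_pd_vs_healthy`, `d_control_vs_tpei`.
#' @export
demographic_summary <- function(demographics = reference_demographics(),
                                variables = c("bmi", "age")) {
  ctrl <- demographics$group == "pd_control"
  tpei <- demographics$group == "pd_tpei"
  heal <- demographics$group == "healthy"
  bind_rows(lapply(variables, function(v) {
    x <- demographics[[v]]
    tibble(
      variable = v,
      mean_pd_control = mean(x[ctrl]), sd_pd_control = sd(x[ctrl]),
      mean_pd_tpei = mean(x[tpei]), sd_pd_tpei = sd(x[tpei]),
      mean_healthy = mean(x[heal]), sd_healthy = sd(x[heal]),
      p_control_vs_tpei = welch_t_test(x[ctrl], x[tpei])$p_value,
      p_pd_vs_healthy = welch_t_test(x[ctrl | tpei], x[heal])$p_value,
      d_control_vs_tpei = cohens_d(x[ctrl], x[tpei])$d
    )
  }))
}
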