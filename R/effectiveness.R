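crc_stages <- c("I", "II", "III", "IV")

#' Stage-level input table for one screening arm
#'
#' One row per cancer stage I-IV holding the stage-specific mean survival
#' time (years), the number of patients diagnosed at that stage, the mean
#' utility score of those patients, and optionally the per-patient
#' treatment cost of that stage. Survival means are exogenous inputs
#' (published restricted means); no survival modelling happens here.
#'
#' @param arm `"iFOBT"` or `"genetic_testing"`.
#' @param stage Stage labels; all of I-IV must appear exactly once.
#' @param survival_mean Non-negative mean survival per stage (years).
#' @param n Non-negative patient count per stage.
#' @param utility_mean Mean utility per stage (in [-1, 1]; NA allowed for
#'   stages with no patients).
#' @param treatment_cost Optional per-patient treatment cost per stage.
#' @return A data.frame of class `stage_table`, ordered I-IV.
#' @export
stage_table <- function(arm = screening_arms, stage, survival_mean, n,
                        utility_mean = NA_real_, treatment_cost = NA_real_) {
  arm <- match.arg(arm)
  df <- data.frame(stage = as.character(stage),
                   survival_mean = as.numeric(survival_mean),
                   n = as.numeric(n),
                   utility_mean = rep_len(as.numeric(utility_mean), length(stage)),
                   treatment_cost = rep_len(as.numeric(treatment_cost), length(stage)),
                   stringsAsFactors = FALSE)
  if (!setequal(df$stage, crc_stages) || nrow(df) != 4L)
    stop("stages I, II, III, IV must each appear exactly once", call. = FALSE)
  df <- df[match(crc_stages, df$stage), ]
  rownames(df) <- NULL
  if (anyNA(df$survival_mean) || any(df$survival_mean < 0))
    stop("`survival_mean` must be non-negative", call. = FALSE)
  if (anyNA(df$n) || any(df$n < 0))
    stop("`n` must be non-negative", call. = FALSE)
  if (any(!is.na(df$utility_mean) & abs(df$utility_mean) > 1))
    stop("`utility_mean` must lie in [-1, 1]", call. = FALSE)
  attr(df, "arm") <- arm
  class(df) <- c("stage_table", "data.frame")
  df
}

effectiveness_result <- function(arm, per_stage, with_qaly) {
  n_total <- sum(per_stage$n)
  res <- list(arm = arm, per_stage = per_stage, n = n_total,
              total_ly = sum(per_stage$ly),
              per_patient_ly = sum(per_stage$ly) / n_total,
              total_qaly = NA_real_, per_patient_qaly = NA_real_)
  if (with_qaly) {
    res$total_qaly <- sum(per_stage$qaly)
    res$per_patient_qaly <- res$total_qaly / n_total
  }
  structure(res, class = "effectiveness_result")
}

#' Stage-wise life-years for one arm
#'
#' Life-years per stage are the stage mean survival multiplied by the
#' stage patient count: `ly_k = s_k * n_k`. The total is their sum and the
#' per-patient value divides by the cohort size. All arithmetic is at full
#' floating precision; rounding is left to rendering.
#'
#' @param table A [stage_table()].
#' @return An `effectiveness_result` with elements `per_stage` (stage,
#'   n, ly), `total_ly`, `per_patient_ly`, `n`.
#' @export
stage_lys <- function(table) {
  stopifnot(inherits(table, "stage_table"))
  if (sum(table$n) == 0)
    stop("cohort is empty: all stage counts are zero", call. = FALSE)
  per_stage <- data.frame(stage = table$stage, n = table$n,
                          ly = table$survival_mean * table$n)
  effectiveness_result(attr(table, "arm"), per_stage, with_qaly = FALSE)
}

#' Stage-wise quality-adjusted life-years for one arm
#'
#' QALYs per stage weight the stage life-years by the stage mean utility:
#' `qaly_k = s_k * n_k * u_k`, summed at full precision before any
#' rounding (summing per-stage values already rounded to 2 dp gives a
#' different, wrong total).
#'
#' @param table A [stage_table()] with utilities for every stage that has
#'   patients.
#' @return An `effectiveness_result` with LY and QALY totals and
#'   per-patient values.
#' @export
stage_qalys <- function(table) {
  stopifnot(inherits(table, "stage_table"))
  if (sum(table$n) == 0)
    stop("cohort is empty: all stage counts are zero", call. = FALSE)
  if (any(table$n > 0 & is.na(table$utility_mean)))
    stop("utility_mean missing for a stage with patients", call. = FALSE)
  u <- ifelse(table$n > 0, table$utility_mean, 0)
  per_stage <- data.frame(stage = table$stage, n = table$n,
                          ly = table$survival_mean * table$n,
                          qaly = table$survival_mean * table$n * u)
  effectiveness_result(attr(table, "arm"), per_stage, with_qaly = TRUE)
}

#' @export
print.effectiveness_result <- function(x, ...) {
  cat("Effectiveness —", x$arm, sprintf("(n = %g)\n", x$n))
  print(x$per_stage, row.names = FALSE)
  cat(sprintf("Total LY: %.2f  (per patient %.2f)\n", x$total_ly, x$per_patient_ly))
  if (!is.na(x$total_qaly))
    cat(sprintf("Total QALY: %.2f  (per patient %.2f)\n",
                x$total_qaly, x$per_patient_qaly))
  invisible(x)
}

#' Per-patient LY and QALY gains of a new strategy over a comparator
#'
#' @param result_new,result_comparator `effectiveness_result` objects on
#'   the same per-patient basis (new minus comparator).
#' @return List with `ly_gain` and `qaly_gain` (years per patient;
#'   `qaly_gain` is NA when either result lacks QALYs).
#' @export
gains <- function(result_new, result_comparator) {
  stopifnot(inherits(result_new, "effectiveness_result"),
            inherits(result_comparator, "effectiveness_result"))
  list(ly_gain = result_new$per_patient_ly - result_comparator$per_patient_ly,
       qaly_gain = result_new$per_patient_qaly - result_comparator$per_patient_qaly)
}
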