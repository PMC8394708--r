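#' Cost per unit of effect
#'
#' Average cost-effectiveness of a single arm: provider cost divided by
#' the effect measure (life-years or QALYs).
#'
#' @param provider_cost Cost (currency units).
#' @param effect Effect in years; must be strictly positive.
#' @return `provider_cost / effect` at full precision.
#' @export
cost_per_effect <- function(provider_cost, effect) {
  if (!is.numeric(effect) || any(effect <= 0))
    stop("`effect` must be strictly positive", call. = FALSE)
  provider_cost / effect
}

#' Ratio of two arms' cost-per-effect values
#'
#' @param cpe_new Cost per effect of the new strategy.
#' @param cpe_comparator Cost per effect of the comparator; must be
#'   strictly positive.
#' @return Dimensionless ratio.
#' @export
cost_ratio <- function(cpe_new, cpe_comparator) {
  if (!is.numeric(cpe_comparator) || any(cpe_comparator <= 0))
    stop("comparator cost per effect must be strictly positive", call. = FALSE)
  cpe_new / cpe_comparator
}

#' Total management cost of one arm's cohort
#'
#' The cost of managing the screened cohort is the stage-wise treatment
#' cost times the number of patients at that stage, summed over stages,
#' plus the cohort-level screening cost.
#'
#' @param arm `"iFOBT"` or `"genetic_testing"`.
#' @param treatment_cost_per_stage Named numeric vector of per-patient
#'   treatment costs keyed by stage (I-IV).
#' @param stage_counts Named numeric vector of patient counts keyed by
#'   stage.
#' @param screening_cost Screening cost for the whole cohort.
#' @return A `management_cost` object with the derived `total`.
#' @export
management_cost <- function(arm = screening_arms, treatment_cost_per_stage,
                            stage_counts, screening_cost) {
  arm <- match.arg(arm)
  stages <- names(stage_counts)
  if (is.null(stages) || !all(stages %in% crc_stages))
    stop("`stage_counts` must be named by stage I-IV", call. = FALSE)
  if (any(stage_counts < 0) || screening_cost < 0)
    stop("counts and costs must be non-negative", call. = FALSE)
  need <- stages[stage_counts > 0]
  have <- names(treatment_cost_per_stage)[!is.na(treatment_cost_per_stage)]
  if (!all(need %in% have))
    stop("treatment cost missing for a stage with patients: ",
         paste(setdiff(need, have), collapse = ", "), call. = FALSE)
  tc <- treatment_cost_per_stage[stages]
  tc[stage_counts == 0 & is.na(tc)] <- 0
  structure(
    list(arm = arm,
         treatment_cost_per_stage = treatment_cost_per_stage,
         stage_counts = stage_counts,
         screening_cost = screening_cost,
         total = sum(tc * stage_counts) + screening_cost),
    class = "management_cost"
  )
}

#' Total of a management-cost object
#'
#' @param mc A [management_cost()].
#' @return The total cost (treatment plus screening).
#' @export
total_management_cost <- function(mc) {
  stopifnot(inherits(mc, "management_cost"))
  mc$total
}

#' Classify a point on the cost-effectiveness plane
#'
#' The plane plots incremental effect (x) against incremental cost (y)
#' for the new strategy versus its comparator. The full sign table, with
#' zeros treated as boundaries:
#'
#' | delta_cost | delta_effect | quadrant   | dominance  |
#' |-----------:|-------------:|------------|------------|
#' | > 0        | > 0          | NE         | trade_off  |
#' | < 0        | > 0          | SE         | dominant   |
#' | < 0        | < 0          | SW         | trade_off  |
#' | > 0        | < 0          | NW         | dominated  |
#' | any 0      | any          | boundary   | trade_off  |
#'
#' Dominance is strict: a strategy dominates only when it costs less and
#' yields more effect (SE quadrant), and is dominated only in the NW
#' quadrant; axis points are reported as boundary trade-offs.
#'
#' @param delta_cost Incremental cost (new minus comparator).
#' @param delta_effect Incremental effect (new minus comparator).
#' @return List with `quadrant` (`"NE"`, `"SE"`, `"SW"`, `"NW"`,
#'   `"boundary"`) and `dominance` (`"dominant"`, `"dominated"`,
#'   `"trade_off"`).
#' @export
classify_plane <- function(delta_cost, delta_effect) {
  if (delta_cost == 0 || delta_effect == 0) {
    quadrant <- "boundary"
  } else if (delta_effect > 0) {
    quadrant <- if (delta_cost > 0) "NE" else "SE"
  } else {
    quadrant <- if (delta_cost > 0) "NW" else "SW"
  }
  dominance <- switch(quadrant, SE = "dominant", NW = "dominated", "trade_off")
  list(quadrant = quadrant, dominance = dominance)
}

#' Incremental cost-effectiveness ratio with plane classification
#'
#' Computes `delta_cost = cost_new - cost_comp`, `delta_effect =
#' effect_new - effect_comp`, their ratio (the ICER), and the
#' cost-effectiveness-plane quadrant and dominance class. When the
#' incremental effect is zero the ICER is undefined (NA) and only the
#' plane classification is returned. A bare negative ICER is ambiguous
#' (cheaper-and-better versus costlier-and-worse), which is why the
#' quadrant always accompanies the ratio.
#'
#' @param cost_new,cost_comp Total costs of the new strategy and the
#'   comparator (same units and cohort basis).
#' @param effect_new,effect_comp Effects (e.g. total QALYs over the same
#'   cohort size).
#' @return A `cea_result` with `delta_cost`, `delta_effect`, `icer`,
#'   `quadrant`, `dominance`.
#' @examples
#' icer(600651.33, 615948.66, 496.74, 343.78)
#' @export
icer <- function(cost_new, cost_comp, effect_new, effect_comp) {
  dc <- cost_new - cost_comp
  de <- effect_new - effect_comp
  cls <- classify_plane(dc, de)
  structure(
    list(delta_cost = dc, delta_effect = de,
         icer = if (de == 0) NA_real_ else dc / de,
         quadrant = cls$quadrant, dominance = cls$dominance),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Incremental cost: %.2f   Incremental effect: %.2f\n",
              x$delta_cost, x$delta_effect))
  if (is.na(x$icer)) {
    cat("ICER: undefined (zero incremental effect)\n")
  } else {
    cat(sprintf("ICER: %.2f per unit effect\n", x$icer))
  }
  cat("CE-plane quadrant:", x$quadrant, "—", x$dominance, "\n")
  invisible(x)
}

#' Classify an ICER against GDP-per-capita willingness-to-pay bands
#'
#' WHO-CHOICE style bands: a dominant strategy is highly cost-effective
#' outright; otherwise an ICER below one GDP per capita per QALY is
#' highly cost-effective, between one and three times GDP per capita is
#' cost-effective, and above three times is not cost-effective. A
#' dominated strategy is not cost-effective regardless of the ratio.
#'
#' @param icer_value ICER in currency units per QALY (ignored when
#'   dominance settles the class).
#' @param dominance `"dominant"`, `"dominated"` or `"trade_off"` (from
#'   [classify_plane()] / [icer()]).
#' @param gdp_per_capita Positive GDP per capita in the same currency.
#' @return One of `"highly_cost_effective"`, `"cost_effective"`,
#'   `"not_cost_effective"`.
#' @export
classify_threshold <- function(icer_value, dominance, gdp_per_capita) {
  if (!is.numeric(gdp_per_capita) || gdp_per_capita <= 0)
    stop("`gdp_per_capita` must be positive", call. = FALSE)
  if (dominance == "dominant") return("highly_cost_effective")
  if (dominance == "dominated") return("not_cost_effective")
  ratio <- icer_value / gdp_per_capita
  if (ratio < 1) "highly_cost_effective"
  else if (ratio <= 3) "cost_effective"
  else "not_cost_effective"
}
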