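discount_methods <- c("multiplicative", "exponential")

#' Apply a discount rate to a value
#'
#' Two discounting rules are offered. `"multiplicative"` is a one-shot
#' cost-reduction: the value is scaled by `(1 - rate)` once, regardless of
#' horizon. This is the rule the bundled study dataset was produced under
#' (every sensitivity-scenario cell equals the base case times `1 - r`).
#' `"exponential"` is conventional compound discounting,
#' `value / (1 + rate)^horizon`. At rate 0 both return the value
#' unchanged.
#'
#' @param value Numeric value(s) to discount (costs, LYs or QALYs).
#' @param rate Discount rate as a fraction in [0, 1).
#' @param method `"multiplicative"` (default) or `"exponential"`.
#' @param horizon Horizon in years for the exponential rule (default 1,
#'   the annual costing period); ignored by the multiplicative rule.
#' @return Discounted value(s).
#' @examples
#' apply_discount(976.26, 0.03)                        # 946.97 after rounding
#' apply_discount(976.26, 0.03, "exponential", horizon = 10)
#' @export
apply_discount <- function(value, rate, method = discount_methods, horizon = 1) {
  method <- match.arg(method)
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1)
    stop("`rate` must be a fraction in [0, 1)", call. = FALSE)
  switch(method,
         multiplicative = value * (1 - rate),
         exponential = value / (1 + rate)^horizon)
}

#' Run discount-rate sensitivity scenarios
#'
#' Applies each discount rate to both arms' provider costs, life-years
#' and QALYs (discounting costs and consequences alike), and reports the
#' between-arm cost difference per scenario. The base case (rate 0) is
#' always included first.
#'
#' @param base Named list with numeric vectors `cost`, `ly`, `qaly`, each
#'   named by arm (both arms required), and optionally `cost_difference`,
#'   a scalar base-case between-arm cost difference to discount directly
#'   (e.g. a published unrounded difference); when absent the difference
#'   of the discounted arm costs is used — under the multiplicative rule
#'   the two agree by linearity.
#' @param rates Numeric vector of discount rates in [0, 1); may be empty,
#'   in which case only the base case is returned.
#' @param method Discounting rule, see [apply_discount()].
#' @param new_arm,comparator_arm Arm names used for the difference
#'   (new minus comparator).
#' @return A `sensitivity_result`: list with `per_arm` (data.frame:
#'   scenario, rate, arm, cost, ly, qaly) and `differences` (data.frame:
#'   scenario, rate, cost_difference).
#' @export
run_scenarios <- function(base, rates, method = discount_methods,
                          new_arm = "genetic_testing",
                          comparator_arm = "iFOBT") {
  method <- match.arg(method)
  for (el in c("cost", "ly", "qaly")) {
    if (is.null(base[[el]]) ||
        !all(c(new_arm, comparator_arm) %in% names(base[[el]])))
      stop("`base$", el, "` must be named by both arms", call. = FALSE)
  }
  all_rates <- c(0, rates)
  labels <- c("base_case", if (length(rates)) sprintf("discount_%g%%", rates * 100))
  per_arm <- do.call(rbind, lapply(seq_along(all_rates), function(i) {
    r <- all_rates[i]
    arms <- names(base$cost)
    data.frame(scenario = labels[i], rate = r, arm = arms,
               cost = apply_discount(base$cost[arms], r, method),
               ly = apply_discount(base$ly[arms], r, method),
               qaly = apply_discount(base$qaly[arms], r, method),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  base_diff <- if (!is.null(base$cost_difference)) base$cost_difference
               else base$cost[[new_arm]] - base$cost[[comparator_arm]]
  differences <- data.frame(
    scenario = labels, rate = all_rates,
    cost_difference = vapply(all_rates, function(r)
      apply_discount(base_diff, r, method), numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(per_arm = per_arm, differences = differences,
                 method = method),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Discount-rate sensitivity (", x$method, " rule)\n", sep = "")
  df <- x$per_arm
  df$cost <- formatC(df$cost, format = "f", digits = 2, big.mark = ",")
  df$ly <- formatC(df$ly, format = "f", digits = 2)
  df$qaly <- formatC(df$qaly, format = "f", digits = 2)
  print(df, row.names = FALSE)
  cat("Cost differences:\n")
  dd <- x$differences
  dd$cost_difference <- formatC(dd$cost_difference, format = "f", digits = 2,
                                big.mark = ",")
  print(dd, row.names = FALSE)
  invisible(x)
}
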