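#' Unit cost by top-down costing
#'
#' Top-down costing divides an aggregate expenditure by the number of
#' patients served and multiplies by the average number of visits, giving
#' the average provider cost per patient per visit cycle.
#'
#' @param total_expenditure Aggregate expenditure (currency units, >= 0).
#' @param n_patients Number of patients over which the expenditure is
#'   spread. Must be a positive count.
#' @param mean_visits Average number of visits per patient. Must be
#'   positive. Defaults to 1.
#' @return Unit cost per patient, at full floating precision.
#' @examples
#' top_down_unit_cost(1000, 100, mean_visits = 2.5)
#' @export
top_down_unit_cost <- function(total_expenditure, n_patients, mean_visits = 1) {
  stopifnot(is.numeric(total_expenditure), length(total_expenditure) == 1L,
            total_expenditure >= 0)
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients <= 0)
    stop("`n_patients` must be a positive count", call. = FALSE)
  if (!is.numeric(mean_visits) || length(mean_visits) != 1L || mean_visits <= 0)
    stop("`mean_visits` must be positive", call. = FALSE)
  (total_expenditure / n_patients) * mean_visits
}

#' Unit cost by activity-based costing
#'
#' Activity-based costing assigns to a service the summed costs of every
#' activity it directly consumes.
#'
#' @param activity_costs Numeric vector of per-activity costs (all >= 0).
#'   An empty vector yields 0.
#' @return The summed unit cost.
#' @examples
#' activity_based_unit_cost(c(45.89, 1.15, 19.45, 43.23))
#' @export
activity_based_unit_cost <- function(activity_costs) {
  if (length(activity_costs) == 0L) return(0)
  if (!is.numeric(activity_costs) || anyNA(activity_costs))
    stop("`activity_costs` must be numeric and non-missing", call. = FALSE)
  if (any(activity_costs < 0))
    stop("activity costs must be non-negative", call. = FALSE)
  sum(activity_costs)
}

#' Currency conversion specification
#'
#' @param from_currency Currency code of the source ledger (e.g. "MYR").
#' @param to_currency Currency code of the reporting currency (e.g. "USD").
#' @param rate Exchange rate expressed as units of `from_currency` per one
#'   unit of `to_currency` (e.g. 4.14 MYR per USD). Must be positive.
#' @param price_year Financial year the rate refers to.
#' @return A `currency_spec` object.
#' @examples
#' currency_spec("MYR", "USD", rate = 4.14, price_year = 2019)
#' @export
currency_spec <- function(from_currency, to_currency, rate, price_year = NA_integer_) {
  stopifnot(is.character(from_currency), is.character(to_currency))
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a positive number", call. = FALSE)
  structure(
    list(from_currency = from_currency, to_currency = to_currency,
         rate = rate, price_year = price_year),
    class = "currency_spec"
  )
}

#' Convert an amount between the two currencies of a specification
#'
#' Amounts in the spec's `from_currency` are divided by the rate; amounts
#' already in `to_currency` are multiplied (the inverse direction).
#'
#' @param amount Non-negative amount(s) to convert.
#' @param spec A [currency_spec()].
#' @param from Currency code the amount is currently expressed in. Must be
#'   one of the two codes in `spec`. Defaults to `spec$from_currency`.
#' @return Converted amount(s), full precision.
#' @examples
#' myr_usd <- currency_spec("MYR", "USD", 4.14, 2019)
#' convert_currency(414, myr_usd)            # -> 100 USD
#' convert_currency(100, myr_usd, from = "USD")  # -> 414 MYR
#' @export
convert_currency <- function(amount, spec, from = spec$from_currency) {
  stopifnot(inherits(spec, "currency_spec"))
  if (any(amount < 0)) stop("`amount` must be non-negative", call. = FALSE)
  if (identical(from, spec$from_currency)) {
    amount / spec$rate
  } else if (identical(from, spec$to_currency)) {
    amount * spec$rate
  } else {
    stop("unknown currency `", from, "` for this specification", call. = FALSE)
  }
}

#' Adjust a cost to the analysis price year with a consumer price index
#'
#' Multiplicative CPI adjustment: the caller supplies the index linking the
#' component's price year to the analysis year. An index of 1 (the default)
#' leaves the amount unchanged.
#'
#' @param amount Non-negative amount(s).
#' @param index Positive multiplicative index.
#' @return Adjusted amount(s).
#' @export
cpi_adjust <- function(amount, index = 1) {
  if (any(amount < 0)) stop("`amount` must be non-negative", call. = FALSE)
  if (!is.numeric(index) || any(index <= 0))
    stop("`index` must be positive", call. = FALSE)
  amount * index
}

cost_categories <- c("capital", "recurrent")
costing_methods <- c("top_down", "activity_based")

#' Create a table of cost components
#'
#' A cost component is one itemised line of an arm's annual per-patient
#' provider cost: a label (building, equipment, human resource, ...), a
#' category (capital or recurrent), the costing method that produced it
#' (top-down or activity-based), the amount, and optionally its standard
#' error.
#'
#' @param name Character vector of component labels.
#' @param category One of `"capital"`/`"recurrent"` per component.
#' @param method One of `"top_down"`/`"activity_based"` per component.
#' @param amount Non-negative amounts (currency units per patient per year).
#' @param se Optional non-negative standard errors (NA when unknown).
#' @return A data.frame of class `cost_components`.
#' @export
cost_components <- function(name, category, method, amount, se = NA_real_) {
  n <- length(name)
  category <- rep_len(as.character(category), n)
  method <- rep_len(as.character(method), n)
  se <- rep_len(as.numeric(se), n)
  if (!all(category %in% cost_categories))
    stop("`category` must be one of: ", paste(cost_categories, collapse = ", "),
         call. = FALSE)
  if (!all(method %in% costing_methods))
    stop("`method` must be one of: ", paste(costing_methods, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(amount) || anyNA(amount) || any(amount < 0))
    stop("`amount` must be non-negative and non-missing", call. = FALSE)
  if (any(!is.na(se) & se < 0))
    stop("`se` must be non-negative when present", call. = FALSE)
  if (anyDuplicated(name))
    stop("component names must be unique", call. = FALSE)
  structure(
    data.frame(name = as.character(name), category = category,
               method = method, amount = as.numeric(amount), se = se,
               stringsAsFactors = FALSE),
    class = c("cost_components", "data.frame")
  )
}

screening_arms <- c("iFOBT", "genetic_testing")

#' Build an arm's cost profile from its components
#'
#' The profile retains the itemisation (for report rendering) and carries
#' the derived total: the plain sum of the component amounts, at full
#' floating precision.
#'
#' @param components A [cost_components()] table (non-empty).
#' @param arm Which screening arm the profile describes: `"iFOBT"` or
#'   `"genetic_testing"`.
#' @return A `cost_profile` object with elements `arm`, `components`,
#'   `total`.
#' @examples
#' cc <- cost_components("laboratory", "recurrent", "activity_based", 45.89)
#' build_cost_profile(cc, "iFOBT")
#' @export
build_cost_profile <- function(components, arm = screening_arms) {
  arm <- match.arg(arm)
  if (!inherits(components, "cost_components"))
    components <- do.call(cost_components, as.list(components[c("name", "category", "method", "amount", "se")]))
  if (nrow(components) == 0L)
    stop("`components` must contain at least one cost line", call. = FALSE)
  structure(
    list(arm = arm, components = components, total = sum(components$amount)),
    class = "cost_profile"
  )
}

#' @export
print.cost_profile <- function(x, ...) {
  cat("Annual per-patient provider cost profile —", x$arm, "\n")
  df <- x$components
  df$amount <- formatC(df$amount, format = "f", digits = 2, big.mark = ",")
  print(df, row.names = FALSE)
  cat("Total:", formatC(x$total, format = "f", digits = 2, big.mark = ","), "\n")
  invisible(x)
}

#' Component-wise and total cost difference between two profiles
#'
#' Returns per-component and total mean differences (`a` minus `b`).
#' When both profiles carry standard errors, a normal-approximation
#' confidence interval `diff +/- z * sqrt(se_a^2 + se_b^2)` is attached per
#' component and for the total (total SEs combined in quadrature over
#' components when no total SE is supplied).
#'
#' @param profile_a,profile_b `cost_profile` objects sharing the same
#'   component names.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A data.frame with columns `name`, `diff`, and (when SEs are
#'   available) `ci_lo`, `ci_hi`; the final row, named `"total"`, holds the
#'   total difference.
#' @export
cost_difference <- function(profile_a, profile_b, conf_level = 0.95) {
  stopifnot(inherits(profile_a, "cost_profile"), inherits(profile_b, "cost_profile"))
  ca <- profile_a$components
  cb <- profile_b$components
  if (!setequal(ca$name, cb$name) || nrow(ca) != nrow(cb))
    stop("profiles do not share the same component set", call. = FALSE)
  cb <- cb[match(ca$name, cb$name), ]
  d <- ca$amount - cb$amount
  out <- data.frame(name = c(ca$name, "total"),
                    diff = c(d, profile_a$total - profile_b$total),
                    stringsAsFactors = FALSE)
  if (!anyNA(ca$se) && !anyNA(cb$se)) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(ca$se^2 + cb$se^2)
    se_tot <- sqrt(sum(se^2))
    out$se <- c(se, se_tot)
    out$ci_lo <- out$diff - z * out$se
    out$ci_hi <- out$diff + z * out$se
  }
  out
}
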