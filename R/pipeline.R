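#' Configuration for the full cost-effectiveness pipeline
#'
#' @param fixture Inputs as returned by [load_crc_fixture()] (the
#'   default), or an equally shaped list built from user CSVs.
#' @param new_arm,comparator_arm Arm labels; incremental quantities are
#'   new minus comparator.
#' @param gdp_per_capita GDP per capita (same currency as costs) for the
#'   willingness-to-pay threshold bands. Default 11414 USD (Malaysia,
#'   2019).
#' @param discount_rates Rates for the sensitivity scenarios.
#' @param discount_method Discounting rule, see [apply_discount()].
#' @param out_dir Output directory for the report bundle; `NULL` skips
#'   writing files.
#' @param seed Integer seed echoed into the manifest (the deterministic
#'   pipeline itself draws no random numbers).
#' @return A `cea_config` list.
#' @export
cea_config <- function(fixture = load_crc_fixture(),
                       new_arm = "genetic_testing",
                       comparator_arm = "iFOBT",
                       gdp_per_capita = 11414,
                       discount_rates = c(0.03, 0.05),
                       discount_method = "multiplicative",
                       out_dir = NULL,
                       seed = 1L) {
  stopifnot(gdp_per_capita > 0)
  structure(list(fixture = fixture, new_arm = new_arm,
                 comparator_arm = comparator_arm,
                 gdp_per_capita = gdp_per_capita,
                 discount_rates = discount_rates,
                 discount_method = discount_method,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "cea_config")
}

#' Run the two-arm cost-effectiveness pipeline
#'
#' Executes the full chain — costing, stage-wise effectiveness, average
#' cost-effectiveness, management costs, ICER with plane and threshold
#' classification, and discount-rate sensitivity — and optionally writes
#' a report bundle: CSV analogues of the costing, effectiveness, CEA,
#' QALY, management-cost and sensitivity tables, a CE-plane coordinate
#' CSV, and a JSON manifest holding every headline number at full
#' precision together with its 2-dp display value.
#'
#' The headline cost-per-LY and cost-per-QALY figures follow the
#' reporting convention of dividing the arm cost by the per-patient
#' effect rounded to 2 dp (the scale at which per-patient effects are
#' reported); full-precision variants are included alongside.
#'
#' @param config A [cea_config()].
#' @return A `cea_report` list (invisibly when writing files) with
#'   elements `cost_profiles`, `cost_difference`, `effectiveness`,
#'   `gains`, `cost_effectiveness`, `management`, `icer`,
#'   `threshold_class`, `sensitivity`, `manifest`.
#' @export
run_cea_pipeline <- function(config = cea_config()) {
  stopifnot(inherits(config, "cea_config"))
  fx <- config$fixture
  new <- config$new_arm
  comp <- config$comparator_arm
  stage_fail <- function(stage, e) {
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
         call. = FALSE)
  }

  prof <- tryCatch({
    p <- fx$cost_profiles
    stopifnot(all(c(new, comp) %in% names(p)))
    p
  }, error = function(e) stage_fail("costing", e))
  cost_diff <- tryCatch(
    cost_difference(prof[[new]], prof[[comp]]),
    error = function(e) stage_fail("costing", e))

  eff <- tryCatch(
    lapply(fx$stage_tables, stage_qalys),
    error = function(e) stage_fail("effectiveness", e))
  g <- gains(eff[[new]], eff[[comp]])

  cea <- tryCatch({
    pp_ly <- vapply(eff, function(x) round(x$per_patient_ly, 2), numeric(1))
    pp_qaly <- vapply(eff, function(x) round(x$per_patient_qaly, 2), numeric(1))
    cost <- vapply(prof, function(x) x$total, numeric(1))
    data.frame(
      arm = names(eff),
      provider_cost = cost[names(eff)],
      per_patient_ly = pp_ly,
      per_patient_qaly = pp_qaly,
      cost_per_ly = cost_per_effect(cost[names(eff)], pp_ly),
      cost_per_qaly = cost_per_effect(cost[names(eff)], pp_qaly),
      cost_per_ly_full = cost_per_effect(
        cost[names(eff)], vapply(eff, `[[`, numeric(1), "per_patient_ly")),
      cost_per_qaly_full = cost_per_effect(
        cost[names(eff)], vapply(eff, `[[`, numeric(1), "per_patient_qaly")),
      row.names = NULL, stringsAsFactors = FALSE)
  }, error = function(e) stage_fail("cea_engine", e))
  ratios <- list(
    ly = cost_ratio(cea$cost_per_ly[cea$arm == new],
                    cea$cost_per_ly[cea$arm == comp]),
    qaly = cost_ratio(cea$cost_per_qaly[cea$arm == new],
                      cea$cost_per_qaly[cea$arm == comp]))

  mgmt <- tryCatch(
    vapply(fx$management_costs, total_management_cost, numeric(1)),
    error = function(e) stage_fail("cea_engine", e))
  ic <- icer(mgmt[[new]], mgmt[[comp]],
             eff[[new]]$total_qaly, eff[[comp]]$total_qaly)
  thr <- classify_threshold(ic$icer, ic$dominance, config$gdp_per_capita)

  sens <- tryCatch({
    # scenario base values are the reported (2-dp) base-case cells, the
    # same convention the headline cost-per-effect figures follow
    base <- list(
      cost = round(vapply(prof, function(x) x$total, numeric(1)), 2),
      ly = round(vapply(eff, `[[`, numeric(1), "per_patient_ly"), 2),
      qaly = round(vapply(eff, `[[`, numeric(1), "per_patient_qaly"), 2))
    pub <- fx$published_differences
    if (!is.null(pub)) {
      base$cost_difference <- pub$mean_diff[pub$name == "total"]
    }
    run_scenarios(base, config$discount_rates, config$discount_method,
                  new_arm = new, comparator_arm = comp)
  }, error = function(e) stage_fail("sensitivity", e))

  disp <- function(x) round(x, 2)
  manifest <- list(
    config = list(new_arm = new, comparator_arm = comp,
                  gdp_per_capita = config$gdp_per_capita,
                  discount_rates = config$discount_rates,
                  discount_method = config$discount_method,
                  seed = config$seed),
    provider_cost = as.list(vapply(prof, function(x) x$total, numeric(1))),
    per_patient_ly = as.list(vapply(eff, `[[`, numeric(1), "per_patient_ly")),
    per_patient_qaly = as.list(vapply(eff, `[[`, numeric(1), "per_patient_qaly")),
    total_qaly = as.list(vapply(eff, `[[`, numeric(1), "total_qaly")),
    ly_gain = g$ly_gain, qaly_gain = g$qaly_gain,
    cost_ratio_ly = ratios$ly, cost_ratio_qaly = ratios$qaly,
    management_cost = as.list(mgmt),
    delta_cost = ic$delta_cost, delta_effect = ic$delta_effect,
    icer = ic$icer, icer_2dp = disp(ic$icer),
    quadrant = ic$quadrant, dominance = ic$dominance,
    threshold_class = thr,
    display = list(ly_gain = disp(g$ly_gain), qaly_gain = disp(g$qaly_gain),
                   icer = disp(ic$icer),
                   cost_ratio_ly = disp(ratios$ly),
                   cost_ratio_qaly = disp(ratios$qaly)))

  report <- structure(
    list(cost_profiles = prof, cost_difference = cost_diff,
         effectiveness = eff, gains = g, cost_effectiveness = cea,
         cost_ratios = ratios, management = fx$management_costs,
         icer = ic, threshold_class = thr, sensitivity = sens,
         manifest = manifest),
    class = "cea_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    written <- character(0)
    on_fail <- function(e) {
      unlink(written)  # no partial bundle on failure
      stage_fail("report", e)
    }
    tryCatch({
      wr <- function(df, name) {
        path <- file.path(config$out_dir, name)
        utils::write.csv(df, path, row.names = FALSE)
        written <<- c(written, path)
        path
      }
      wr(render_table(report, "costs"), "costs.csv")
      wr(render_table(report, "effectiveness"), "effectiveness.csv")
      wr(render_table(report, "cea"), "cea.csv")
      wr(render_table(report, "management"), "management_costs.csv")
      wr(render_table(report, "sensitivity"), "sensitivity.csv")
      wr(data.frame(delta_effect = ic$delta_effect,
                    delta_cost = ic$delta_cost,
                    quadrant = ic$quadrant), "ce_plane.csv")
      manifest_path <- file.path(config$out_dir, "manifest.json")
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      written <- c(written, manifest_path)
    }, error = on_fail)
    return(invisible(report))
  }
  report
}

fmt_money <- function(x) formatC(x, format = "f", digits = 2, big.mark = ",")
fmt_years <- function(x) formatC(x, format = "f", digits = 2)

#' Render a pipeline result as a publication-style table
#'
#' Produces a data.frame laid out like the corresponding report table
#' (money and years rendered at 2 dp with thousands separators; values
#' rounded half-even).
#'
#' @param report A `cea_report` from [run_cea_pipeline()].
#' @param layout One of `"costs"` (itemised cost profiles and
#'   difference), `"effectiveness"` (stage-wise LY/QALY), `"cea"`
#'   (headline cost-effectiveness summary), `"qalys"` (per-stage QALY
#'   breakdown), `"management"` (management costs with total row),
#'   `"sensitivity"` (scenario columns).
#' @return A data.frame of formatted strings.
#' @export
render_table <- function(report, layout = c("costs", "effectiveness", "cea",
                                            "qalys", "management",
                                            "sensitivity")) {
  stopifnot(inherits(report, "cea_report"))
  layout <- match.arg(layout)
  arms <- names(report$cost_profiles)
  new <- report$manifest$config$new_arm
  comp <- report$manifest$config$comparator_arm
  out <- switch(layout,
    costs = {
      a <- report$cost_profiles[[comp]]$components
      b <- report$cost_profiles[[new]]$components
      d <- report$cost_difference
      df <- data.frame(
        component = c(a$name, "total"),
        stringsAsFactors = FALSE)
      df[[comp]] <- fmt_money(c(a$amount, report$cost_profiles[[comp]]$total))
      df[[new]] <- fmt_money(c(b$amount[match(a$name, b$name)],
                               report$cost_profiles[[new]]$total))
      df$difference <- fmt_money(d$diff[match(df$component, d$name)])
      df
    },
    effectiveness = do.call(rbind, lapply(arms, function(arm) {
      e <- report$effectiveness[[arm]]
      ps <- e$per_stage
      data.frame(arm = arm,
                 stage = c(ps$stage, "total", "per_patient"),
                 n = c(ps$n, e$n, NA),
                 ly = fmt_years(c(ps$ly, e$total_ly, e$per_patient_ly)),
                 qaly = fmt_years(c(ps$qaly, e$total_qaly,
                                    e$per_patient_qaly)),
                 stringsAsFactors = FALSE)
    })),
    qalys = do.call(rbind, lapply(arms, function(arm) {
      st <- report$effectiveness[[arm]]$per_stage
      u <- st$qaly / st$ly
      data.frame(arm = arm, stage = st$stage,
                 ly_per_patient = fmt_years(st$ly / st$n),
                 utility = fmt_years(u), n = st$n,
                 qaly = fmt_years(st$qaly), stringsAsFactors = FALSE)
    })),
    cea = {
      ce <- report$cost_effectiveness
      df <- data.frame(item = c("ly_gained", "qaly_gained", "provider_cost",
                                "cost_per_ly", "cost_per_qaly"),
                       stringsAsFactors = FALSE)
      for (arm in arms) {
        row <- ce[ce$arm == arm, ]
        df[[arm]] <- c(fmt_years(row$per_patient_ly),
                       fmt_years(row$per_patient_qaly),
                       fmt_money(row$provider_cost),
                       fmt_money(row$cost_per_ly),
                       fmt_money(row$cost_per_qaly))
      }
      df
    },
    management = {
      mc <- report$management
      stages <- crc_stages
      df <- data.frame(
        item = c(paste0("stage_", stages), "total_treatment_cost",
                 "screening_cost",
                 "Total cost of managing CRC patients"),
        stringsAsFactors = FALSE)
      for (arm in arms) {
        m <- mc[[arm]]
        per_stage <- m$treatment_cost_per_stage[stages] * m$stage_counts[stages]
        df[[arm]] <- fmt_money(c(per_stage, sum(per_stage),
                                 m$screening_cost, m$total))
      }
      df
    },
    sensitivity = {
      pa <- report$sensitivity$per_arm
      dd <- report$sensitivity$differences
      scen <- unique(pa$scenario)
      rows <- expand.grid(item = c("cost", "ly", "qaly"), arm = arms,
                          stringsAsFactors = FALSE)
      df <- data.frame(item = rows$item, arm = rows$arm,
                       stringsAsFactors = FALSE)
      for (s in scen) {
        sub <- pa[pa$scenario == s, ]
        df[[s]] <- vapply(seq_len(nrow(rows)), function(i) {
          v <- sub[sub$arm == rows$arm[i], rows$item[i]]
          if (rows$item[i] == "cost") fmt_money(v) else fmt_years(v)
        }, character(1))
      }
      diff_row <- data.frame(item = "cost_difference", arm = "both",
                             stringsAsFactors = FALSE)
      for (s in scen)
        diff_row[[s]] <- fmt_money(dd$cost_difference[dd$scenario == s])
      rbind(df, diff_row)
    })
  if (nrow(out) == 0L) stop("nothing to render for layout ", layout,
                            call. = FALSE)
  out
}

#' @export
print.cea_report <- function(x, ...) {
  m <- x$manifest
  cat("Two-arm cost-effectiveness report:", m$config$new_arm, "vs",
      m$config$comparator_arm, "\n")
  cat(sprintf("  Provider cost: %s vs %s\n",
              fmt_money(m$provider_cost[[m$config$new_arm]]),
              fmt_money(m$provider_cost[[m$config$comparator_arm]])))
  cat(sprintf("  Per-patient LY %.2f vs %.2f (gain %.2f); QALY %.2f vs %.2f (gain %.2f)\n",
              m$per_patient_ly[[m$config$new_arm]],
              m$per_patient_ly[[m$config$comparator_arm]], m$ly_gain,
              m$per_patient_qaly[[m$config$new_arm]],
              m$per_patient_qaly[[m$config$comparator_arm]], m$qaly_gain))
  cat(sprintf("  ICER: %.2f per QALY (%s, %s) — %s\n", m$icer, m$quadrant,
              m$dominance, m$threshold_class))
  invisible(x)
}
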