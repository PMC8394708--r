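#' Parameters for synthetic cohort generation
#'
#' Defaults reproduce the structure of the bundled two-arm study dataset:
#' 100 patients per arm; stage distributions of 6/17/54/23 percent
#' (iFOBT) and 10/60/25/5 percent (genetic testing) across stages I-IV;
#' arm-by-stage mean utilities from the bundled stage tables; a utility
#' dispersion of 0.273 (the overall cohort SD); and VAS scores centred at
#' 73.58 with SD 18.47.
#'
#' @param n_per_arm Patients per arm.
#' @param stage_probs Named list (one element per arm) of length-4 stage
#'   probability vectors (stages I-IV), each summing to 1.
#' @param utility_means Named list (per arm) of length-4 vectors of mean
#'   utilities by stage.
#' @param utility_sd Pre-truncation SD of the utility noise (>= 0).
#' @param vas_mean,vas_sd VAS location and spread; draws are clipped to
#'   [0, 100].
#' @param allocation `"multinomial"` draws stage labels at random;
#'   `"deterministic"` allocates exact counts `round(n_per_arm * p)`
#'   (probabilities must then give integer counts).
#' @param seed Optional integer seed fixing the cohort.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(
    n_per_arm = 100,
    stage_probs = list(iFOBT = c(0.06, 0.17, 0.54, 0.23),
                       genetic_testing = c(0.10, 0.60, 0.25, 0.05)),
    utility_means = list(iFOBT = c(0.87, 0.74, 0.72, 0.11),
                         genetic_testing = c(0.85, 0.82, 0.77, 0.75)),
    utility_sd = 0.273,
    vas_mean = 73.58, vas_sd = 18.47,
    allocation = c("multinomial", "deterministic"),
    seed = NULL) {
  allocation <- match.arg(allocation)
  stopifnot(n_per_arm >= 1, utility_sd >= 0, vas_sd >= 0)
  for (arm in names(stage_probs)) {
    p <- stage_probs[[arm]]
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("stage probabilities for ", arm,
           " must be 4 non-negative values summing to 1", call. = FALSE)
  }
  if (!setequal(names(stage_probs), names(utility_means)))
    stop("`stage_probs` and `utility_means` must cover the same arms",
         call. = FALSE)
  structure(list(n_per_arm = n_per_arm, stage_probs = stage_probs,
                 utility_means = utility_means, utility_sd = utility_sd,
                 vas_mean = vas_mean, vas_sd = vas_sd,
                 allocation = allocation, seed = seed),
            class = "cohort_params")
}

# Location parameter mu such that a N(mu, sd) truncated above at `upper`
# has the requested mean. Solved by monotone root-finding; keeps the
# generated stage means unbiased despite the utility <= 1 ceiling.
calibrate_truncnorm_mean <- function(target, sd, upper = 1) {
  if (sd == 0) return(target)
  tn_mean <- function(mu) {
    a <- (upper - mu) / sd
    mu - sd * stats::dnorm(a) / stats::pnorm(a)
  }
  lo <- target
  hi <- target + 10 * sd   # truncated mean at mu = target is below target
  stats::uniroot(function(m) tn_mean(m) - target, c(lo, hi),
                 tol = 1e-10)$root
}

# Draws from N(mu, sd) truncated above at `upper` via inverse-CDF.
rtruncnorm_upper <- function(n, mu, sd, upper = 1) {
  if (sd == 0) return(rep(mu, n))
  p_up <- stats::pnorm(upper, mu, sd)
  stats::qnorm(stats::runif(n) * p_up, mu, sd)
}

# Invert the toy linear value set: pick EQ-5D levels whose toy index
# approximates the drawn utility. Plumbing for exercising the outcomes
# module; no clinical claim.
profile_from_utility <- function(u, step = 0.05) {
  deficit <- max(0, min(1, 1 - u))
  k <- min(20L, max(0L, as.integer(round(deficit / step))))
  base <- k %/% 5L
  extra <- k %% 5L
  lv <- rep(1L + base, 5L)
  if (extra > 0) lv[seq_len(extra)] <- lv[seq_len(extra)] + 1L
  pmin(lv, 5L)
}

#' Generate a synthetic patient-level cohort
#'
#' Per arm, stage labels are drawn from the stage distribution (or
#' allocated exactly in deterministic mode), each patient's utility is
#' drawn from a normal distribution calibrated so its mean after upper
#' truncation at 1 equals the arm-by-stage mean utility, an EQ-5D-5L
#' profile is synthesised to approximate that utility under the toy
#' linear value set, and a VAS score is drawn and clipped to [0, 100].
#' Fixing `params$seed` makes the cohort fully reproducible.
#'
#' @param params A [cohort_params()] object.
#' @return Data.frame with columns `id`, `arm`, `stage`, `mo`, `sc`,
#'   `ua`, `pd`, `ad`, `vas`, `utility` (the layout
#'   [summarize_outcomes()] consumes).
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  rows <- lapply(names(params$stage_probs), function(arm) {
    p <- params$stage_probs[[arm]]
    n <- params$n_per_arm
    if (params$allocation == "deterministic") {
      counts <- round(n * p)
      if (sum(counts) != n)
        stop("deterministic allocation needs probabilities giving integer ",
             "stage counts", call. = FALSE)
      stages <- rep(crc_stages, counts)
    } else {
      stages <- sample(crc_stages, n, replace = TRUE, prob = p)
    }
    mu <- params$utility_means[[arm]][match(stages, crc_stages)]
    u <- if (params$utility_sd == 0) mu else {
      mu_cal <- vapply(params$utility_means[[arm]], calibrate_truncnorm_mean,
                       numeric(1), sd = params$utility_sd)
      rtruncnorm_upper(length(stages),
                       mu_cal[match(stages, crc_stages)],
                       params$utility_sd)
    }
    u <- pmax(u, -1)
    lv <- t(vapply(u, profile_from_utility, integer(5)))
    vas <- pmin(100, pmax(0, stats::rnorm(length(stages), params$vas_mean,
                                          params$vas_sd)))
    data.frame(arm = arm, stage = stages,
               mo = lv[, 1], sc = lv[, 2], ua = lv[, 3], pd = lv[, 4],
               ad = lv[, 5], vas = vas, utility = u,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(id = sprintf("P%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic per-patient cost ledger
#'
#' Draws per-patient cost-component amounts around an arm's component
#' means (normal noise, clipped at zero) so the costing module can be
#' exercised on ledger-like input. Defaults use the bundled study
#' dataset's component means and standard errors scaled to patient-level
#' dispersion.
#'
#' @param n_patients Number of patients to draw.
#' @param components A [cost_components()] table supplying means (and,
#'   via `se`, dispersion; the per-patient SD is `se * sqrt(n_ref)`).
#' @param n_ref Reference sample size behind the standard errors
#'   (default 100).
#' @param seed Optional integer seed.
#' @return Data.frame: `patient`, one column per component, `total`.
#' @export
generate_cost_ledger <- function(n_patients, components, n_ref = 100,
                                 seed = NULL) {
  stopifnot(inherits(components, "cost_components"), n_patients >= 1)
  if (!is.null(seed)) set.seed(seed)
  sds <- ifelse(is.na(components$se), 0, components$se) * sqrt(n_ref)
  draws <- vapply(seq_len(nrow(components)), function(i)
    pmax(0, stats::rnorm(n_patients, components$amount[i], sds[i])),
    numeric(n_patients))
  draws <- matrix(draws, nrow = n_patients,
                  dimnames = list(NULL, components$name))
  out <- data.frame(patient = sprintf("P%04d", seq_len(n_patients)), draws,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$total <- rowSums(draws)
  out
}

#' Aggregate a patient-level cohort into a stage table
#'
#' Bridges patient-level data to the stage-level effectiveness inputs:
#' stage counts come from the cohort, stage mean utilities are the means
#' of the patients' utilities, and the stage survival means are passed
#' through from published sources (they are not estimable from a
#' cross-sectional cohort).
#'
#' @param cohort Cohort data.frame (one arm only) with columns `stage`
#'   and `utility`.
#' @param survival_means Named numeric vector of mean survival (years)
#'   keyed by stage; must cover every stage present in the cohort.
#' @param treatment_cost Optional named per-stage treatment costs.
#' @return A [stage_table()] for the cohort's arm.
#' @export
cohort_to_stage_table <- function(cohort, survival_means,
                                  treatment_cost = NULL) {
  stopifnot(is.data.frame(cohort), all(c("arm", "stage", "utility") %in% names(cohort)))
  arm <- unique(cohort$arm)
  if (length(arm) != 1L)
    stop("`cohort` must contain a single arm; split by arm first", call. = FALSE)
  present <- unique(cohort$stage)
  if (!all(present %in% names(survival_means)))
    stop("survival mean missing for stage(s): ",
         paste(setdiff(present, names(survival_means)), collapse = ", "),
         call. = FALSE)
  n_k <- vapply(crc_stages, function(s) sum(cohort$stage == s), numeric(1))
  u_k <- vapply(crc_stages, function(s) {
    if (n_k[[s]] == 0) NA_real_ else mean(cohort$utility[cohort$stage == s])
  }, numeric(1))
  s_k <- survival_means[crc_stages]
  s_k[is.na(s_k)] <- 0  # absent stage with no patients
  tc <- if (is.null(treatment_cost)) NA_real_ else treatment_cost[crc_stages]
  stage_table(arm, crc_stages, s_k, n_k, u_k, tc)
}

#' Load the bundled two-arm CRC screening study dataset
#'
#' Returns the packaged aggregate inputs of the iFOBT versus
#' genetic-testing evaluation: per-arm cost profiles (with the published
#' between-arm difference intervals stored as-published), per-arm stage
#' tables (survival, counts, utilities, treatment costs), cohort
#' screening costs, management costs, the published outcome summaries
#' (EQ-5D problem proportions, utility and VAS — kept as published
#' summaries, not reconstructed patient data), and the published
#' sensitivity-scenario table. File integrity is verified against an MD5
#' manifest.
#'
#' @param dir Directory holding the dataset files; defaults to the copy
#'   installed with the package. Overridable mainly for testing the
#'   integrity check.
#' @return A `crc_fixture` list with elements `cost_components`,
#'   `cost_profiles`, `published_differences`, `stage_tables`,
#'   `screening_costs`, `management_costs`, `outcome_summary`,
#'   `scenario_expectations`, `currency`.
#' @export
load_crc_fixture <- function(dir = system.file("extdata",
                                               package = "ceascreen",
                                               mustWork = TRUE)) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  for (f in names(manifest$files)) {
    sum_now <- unname(tools::md5sum(file.path(dir, f)))
    if (is.na(sum_now) || !identical(sum_now, manifest$files[[f]]))
      stop("bundled dataset file failed its checksum: ", f, call. = FALSE)
  }
  comp <- utils::read.csv(file.path(dir, "cost_components.csv"),
                          stringsAsFactors = FALSE)
  profiles <- lapply(split(comp, comp$arm), function(df)
    build_cost_profile(cost_components(df$name, df$category, df$method,
                                       df$amount, df$se),
                       arm = unique(df$arm)))
  st <- utils::read.csv(file.path(dir, "stage_tables.csv"),
                        stringsAsFactors = FALSE)
  stage_tables <- lapply(split(st, st$arm), function(df)
    stage_table(unique(df$arm), df$stage, df$survival_mean, df$n,
                df$utility_mean, df$treatment_cost))
  sc <- utils::read.csv(file.path(dir, "screening_costs.csv"),
                        stringsAsFactors = FALSE)
  screening <- stats::setNames(sc$screening_cost_per_cohort, sc$arm)
  mgmt <- lapply(stage_tables, function(tab) {
    arm <- attr(tab, "arm")
    management_cost(arm,
                    stats::setNames(tab$treatment_cost, tab$stage),
                    stats::setNames(tab$n, tab$stage),
                    screening[[arm]])
  })
  structure(
    list(cost_components = comp,
         cost_profiles = profiles,
         published_differences = utils::read.csv(
           file.path(dir, "published_cost_differences.csv"),
           stringsAsFactors = FALSE),
         stage_tables = stage_tables,
         screening_costs = screening,
         management_costs = mgmt,
         outcome_summary = utils::read.csv(
           file.path(dir, "outcome_summary.csv"), stringsAsFactors = FALSE),
         scenario_expectations = utils::read.csv(
           file.path(dir, "scenario_expectations.csv"),
           stringsAsFactors = FALSE),
         currency = currency_spec("MYR", "USD", 4.14, 2019)),
    class = "crc_fixture"
  )
}
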