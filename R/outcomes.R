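#' EQ-5D-5L dimension labels
#'
#' The five dimensions of the EQ-5D descriptive system, in canonical order:
#' mobility, self-care, usual activities, pain/discomfort,
#' anxiety/depression.
#'
#' @format Character vector of length 5.
#' @export
eq5d_dimensions <- c("mobility", "self_care", "usual_activities",
                     "pain_discomfort", "anxiety_depression")

#' Create an EQ-5D-5L health profile
#'
#' Each dimension is scored on an integer level from 1 (no problems) to 5
#' (extreme problems).
#'
#' @param mobility,self_care,usual_activities,pain_discomfort,anxiety_depression
#'   Integer levels in 1..5.
#' @return A named integer vector of class `eq5d_profile`.
#' @examples
#' eq5d_profile(1, 1, 1, 2, 1)
#' @export
eq5d_profile <- function(mobility, self_care, usual_activities,
                         pain_discomfort, anxiety_depression) {
  lv <- c(mobility = mobility, self_care = self_care,
          usual_activities = usual_activities,
          pain_discomfort = pain_discomfort,
          anxiety_depression = anxiety_depression)
  if (anyNA(lv) || !all(lv %in% 1:5))
    stop("every EQ-5D-5L level must be an integer in 1..5", call. = FALSE)
  structure(as.integer(lv), names = eq5d_dimensions, class = "eq5d_profile")
}

#' Create an additive EQ-5D value set
#'
#' A value set maps an EQ-5D-5L profile to a utility index. This
#' constructor covers the common additive form: the index equals 1 minus
#' the sum of per-dimension, per-level decrements. Level 1 must carry a
#' zero decrement in every dimension so that full health (11111) anchors
#' at a utility of exactly 1.
#'
#' @param name Label for the value set.
#' @param decrements 5x5 numeric matrix of non-negative decrements; rows
#'   are dimensions in [eq5d_dimensions] order, columns are levels 1..5,
#'   column 1 all zero.
#' @return A `value_set` object.
#' @seealso [linear_value_set()], [load_value_set()]
#' @export
value_set <- function(name, decrements) {
  decrements <- as.matrix(decrements)
  if (!identical(dim(decrements), c(5L, 5L)))
    stop("`decrements` must be a 5x5 matrix (dimension x level)", call. = FALSE)
  if (any(decrements < 0))
    stop("decrements must be non-negative", call. = FALSE)
  if (any(decrements[, 1] != 0))
    stop("level-1 decrements must be zero (full health anchors at 1)", call. = FALSE)
  dimnames(decrements) <- list(eq5d_dimensions, paste0("level", 1:5))
  structure(list(name = name, decrements = decrements), class = "value_set")
}

#' Toy linear EQ-5D-5L value set
#'
#' A documented linear tariff for testing and profile synthesis: utility
#' equals `1 - sum(step * (level - 1))` over the five dimensions, so the
#' worst state 55555 scores `1 - 20 * step` (0 at the default step). This
#' is not a country valuation and carries no clinical meaning; real
#' analyses should load a published tariff with [load_value_set()].
#'
#' @param step Per-level decrement shared by every dimension (default 0.05).
#' @return A `value_set` object.
#' @export
linear_value_set <- function(step = 0.05) {
  dec <- outer(rep(step, 5), 0:4)
  value_set(sprintf("linear (step %.3g)", step), dec)
}

#' Load an additive value set from a coefficient file
#'
#' Reads a CSV with columns `dimension`, `level`, `decrement` (one row per
#' dimension-level pair; level-1 rows may be omitted and default to 0) and
#' builds the additive value set, e.g. for an externally supplied country
#' tariff.
#'
#' @param path Path to the coefficient CSV.
#' @param name Label; defaults to the file name.
#' @return A `value_set` object.
#' @export
load_value_set <- function(path, name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dimension", "level", "decrement")
  if (!all(need %in% names(df)))
    stop("value-set file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(df$dimension %in% eq5d_dimensions))
    stop("unknown dimension label in value-set file", call. = FALSE)
  dec <- matrix(0, 5, 5, dimnames = list(eq5d_dimensions, NULL))
  dec[cbind(match(df$dimension, eq5d_dimensions), df$level)] <- df$decrement
  value_set(name, dec)
}

#' Utility index of an EQ-5D-5L profile under a value set
#'
#' @param profile An [eq5d_profile()].
#' @param vs A [value_set()].
#' @return The utility index (a real number, 1 for full health, possibly
#'   negative for severe states under tariffs that allow it).
#' @examples
#' utility_index(eq5d_profile(1, 1, 1, 2, 1), linear_value_set())
#' @export
utility_index <- function(profile, vs) {
  if (!inherits(profile, "eq5d_profile"))
    profile <- do.call(eq5d_profile, as.list(profile))
  stopifnot(inherits(vs, "value_set"))
  1 - sum(vs$decrements[cbind(1:5, as.integer(profile))])
}

#' Does a profile report a problem in a dimension?
#'
#' A problem is any response above level 1, the conventional EQ-5D
#' dichotomisation used when reporting one proportion per dimension.
#'
#' @param profile An [eq5d_profile()].
#' @param dimension One of [eq5d_dimensions].
#' @return Logical.
#' @export
has_problem <- function(profile, dimension) {
  if (!inherits(profile, "eq5d_profile"))
    profile <- do.call(eq5d_profile, as.list(profile))
  if (!dimension %in% eq5d_dimensions)
    stop("unknown EQ-5D dimension: ", dimension, call. = FALSE)
  profile[[dimension]] > 1L
}

#' Summarise EQ-5D outcomes over a patient cohort
#'
#' Computes, per group (screening arm or the pooled cohort), the
#' proportion of patients reporting a problem (level >= 2) in each EQ-5D
#' dimension and the mean, SD and median of the utility index and VAS.
#'
#' @param cohort Data.frame with one row per patient and columns `arm`,
#'   the five dimension levels named `mo`, `sc`, `ua`, `pd`, `ad`, `vas`,
#'   and `utility`. [generate_cohort()] produces this layout.
#' @param group_by `"arm"` for per-arm rows plus a pooled row, or `"all"`
#'   for the pooled cohort only.
#' @return A data.frame with one row per group: `group`, `n`, the five
#'   problem proportions (`prop_` prefix), and utility/VAS summaries.
#' @export
summarize_outcomes <- function(cohort, group_by = c("arm", "all")) {
  group_by <- match.arg(group_by)
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("`cohort` must be a non-empty data.frame", call. = FALSE)
  lvl_cols <- c("mo", "sc", "ua", "pd", "ad")
  need <- c("arm", lvl_cols, "vas", "utility")
  if (!all(need %in% names(cohort)))
    stop("`cohort` must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  one <- function(df, label) {
    props <- vapply(lvl_cols, function(cl) mean(df[[cl]] > 1L), numeric(1))
    names(props) <- paste0("prop_", eq5d_dimensions)
    cbind(data.frame(group = label, n = nrow(df), stringsAsFactors = FALSE),
          as.data.frame(as.list(props)),
          data.frame(utility_mean = mean(df$utility),
                     utility_sd = stats::sd(df$utility),
                     utility_median = stats::median(df$utility),
                     vas_mean = mean(df$vas),
                     vas_sd = stats::sd(df$vas),
                     vas_median = stats::median(df$vas)))
  }
  if (group_by == "all") return(one(cohort, "all"))
  groups <- split(cohort, cohort$arm)
  out <- do.call(rbind, Map(one, groups, names(groups)))
  out <- rbind(one(cohort, "all"), out)
  rownames(out) <- NULL
  out
}
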