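# The MDSS rule engine.
#
# Fourteen food groups are scored over three windows:
#   meal basis   (fruit, vegetables, cereals, olive oil; <= 3 points/day each)
#   daily basis  (nuts 0/2; dairy 0/1/2; fermented beverages 0/1)
#   weekly basis (seven groups, 1 point each)
# Weekly adherence = (sum of meal + daily points over the week) / n_days
#                    + weekly points, on a 0-24 scale.

MEAL_GROUPS   <- c("fruit", "vegetables", "cereals", "olive_oil")
DAILY_GROUPS  <- c("nuts", "dairy", "fermented_beverages")
WEEKLY_GROUPS <- c("potatoes", "legumes", "eggs", "fish",
                   "white_meat", "red_meat", "sweets")

#' Scoring-rule configuration
#'
#' Collects the tunable switches of the rule engine. Defaults follow the
#' normative serving-threshold reading of the rule table; the alternatives
#' preserve the looser prose readings.
#'
#' @param meal_presence_rule `"threshold"` (default): a main meal earns a
#'   meal-basis group's point only when the group's summed servings in that
#'   meal reach the per-meal minimum (fruit 1, vegetables 2, cereals 1, olive
#'   oil 1). `"presence"`: any positive amount earns the point.
#' @param eggs_rule `"min2"` (default): eggs score with >= 2 servings/week.
#'   `"range"`: eggs score only within 2-4 servings/week.
#' @param extrapolate_weekly For partial weeks, scale observed weekly-group
#'   servings by `7/n_days` before applying the weekly rules. Default
#'   `FALSE` (raw observed servings; conservative).
#' @param conf_threshold Confidence above which a recognizer prediction is
#'   treated as a detected item (used by the pipeline bridge and the
#'   serving-size error metric).
#' @return A list of class `md_rules`.
#' @export
md_rules <- function(meal_presence_rule = c("threshold", "presence"),
                     eggs_rule = c("min2", "range"),
                     extrapolate_weekly = FALSE,
                     conf_threshold = 0.5) {
  structure(list(
    meal_presence_rule = match.arg(meal_presence_rule),
    eggs_rule = match.arg(eggs_rule),
    extrapolate_weekly = isTRUE(extrapolate_weekly),
    conf_threshold = conf_threshold
  ), class = "md_rules")
}

# per-meal serving minima under the threshold rule
MEAL_MINIMA <- c(fruit = 1, vegetables = 2, cereals = 1, olive_oil = 1)

# summed servings per scoring group for a set of entries
group_servings <- function(entries, groups) {
  out <- stats::setNames(numeric(length(groups)), groups)
  for (e in entries) {
    g <- map_category_to_group(e$category)
    if (!is.na(g) && g %in% groups) out[g] <- out[g] + e$servings
  }
  out
}

day_entries <- function(day) {
  unlist(lapply(day$meals, `[[`, "entries"), recursive = FALSE)
}

#' Meal-basis points for one day
#'
#' Each of the three main meals (breakfast, lunch, dinner) can contribute one
#' point per meal-basis group; snacks never contribute. More servings or more
#' categories of a group within one meal earn no extra points, so each group
#' tops out at 3 points per day.
#'
#' @param day A `day_log`.
#' @param rules An [md_rules()] configuration.
#' @return Named integer vector over fruit, vegetables, cereals, olive_oil.
#' @export
score_meal_basis <- function(day, rules = md_rules()) {
  stopifnot(inherits(day, "day_log"))
  pts <- stats::setNames(integer(length(MEAL_GROUPS)), MEAL_GROUPS)
  for (m in day$meals) {
    if (!m$meal_type %in% MAIN_MEALS) next
    s <- group_servings(m$entries, MEAL_GROUPS)
    hit <- if (rules$meal_presence_rule == "threshold")
      s >= MEAL_MINIMA[MEAL_GROUPS] else s > 0
    pts <- pts + as.integer(hit)
  }
  pts
}

#' Daily-basis points for one day
#'
#' Servings are tallied over the whole day regardless of meal: nuts give 2
#' points at >= 1 serving; dairy gives 1 point for one serving and 2 for two
#' or more; fermented beverages (wine, beer) give 1 point for 1-2 glasses and
#' nothing otherwise — abstinence and >= 3 glasses both score 0.
#'
#' @inheritParams score_meal_basis
#' @return Named integer vector over nuts, dairy, fermented_beverages.
#' @export
score_daily_basis <- function(day, rules = md_rules()) {
  stopifnot(inherits(day, "day_log"))
  s <- group_servings(day_entries(day), DAILY_GROUPS)
  c(nuts = if (s[["nuts"]] >= 1) 2L else 0L,
    dairy = if (s[["dairy"]] >= 2) 2L else if (s[["dairy"]] >= 1) 1L else 0L,
    fermented_beverages =
      if (s[["fermented_beverages"]] >= 1 && s[["fermented_beverages"]] <= 2)
        1L else 0L)
}

weekly_points_from_servings <- function(s, rules = md_rules()) {
  eggs_ok <- if (rules$eggs_rule == "range")
    s[["eggs"]] >= 2 && s[["eggs"]] <= 4 else s[["eggs"]] >= 2
  c(potatoes   = as.integer(s[["potatoes"]] <= 3),
    legumes    = as.integer(s[["legumes"]] >= 2),
    eggs       = as.integer(eggs_ok),
    fish       = as.integer(s[["fish"]] >= 2),
    white_meat = as.integer(s[["white_meat"]] >= 2),
    red_meat   = as.integer(s[["red_meat"]] <= 1),
    sweets     = as.integer(s[["sweets"]] <= 2))
}

#' Weekly-basis points
#'
#' Servings are summed over the whole week. Legumes, eggs, fish and white
#' meat score with two or more servings; red meat (<= 1), sweets (<= 2) and
#' potatoes (<= 3) are caps, satisfied by abstinence.
#'
#' @param week A `week_log`.
#' @param rules An [md_rules()] configuration.
#' @return Named integer vector over the seven weekly groups.
#' @export
score_weekly_basis <- function(week, rules = md_rules()) {
  stopifnot(inherits(week, "week_log"))
  s <- group_servings(unlist(lapply(week$days, day_entries),
                             recursive = FALSE), WEEKLY_GROUPS)
  if (rules$extrapolate_weekly && length(week$days) < 7)
    s <- s * 7 / length(week$days)
  weekly_points_from_servings(s, rules)
}

score_breakdown <- function(week, rules, n_days) {
  meal_daily <- lapply(week$days, function(d)
    c(score_meal_basis(d, rules), score_daily_basis(d, rules)))
  per_group <- Reduce(`+`, meal_daily)
  weekly <- score_weekly_basis(week, rules)
  meal_sum <- sum(per_group[MEAL_GROUPS])
  daily_sum <- sum(per_group[DAILY_GROUPS])
  weekly_sum <- sum(weekly)
  total <- (meal_sum + daily_sum) / n_days + weekly_sum
  structure(list(
    per_group_points = c(per_group, weekly),
    meal_sum = meal_sum, daily_sum = daily_sum, weekly_sum = weekly_sum,
    n_days = n_days, total = total, level = classify_adherence(total),
    provisional = n_days < 7
  ), class = "md_score")
}

#' Score a complete week
#'
#' Computes the weekly Mediterranean-diet adherence total: the meal- and
#' daily-basis points summed over the seven days, divided by 7, plus the
#' weekly-basis points — a real value in \[0, 24\] — and the traffic-light
#' adherence band.
#'
#' @param week A complete 7-day `week_log`.
#' @param rules An [md_rules()] configuration.
#' @return An `md_score` with per-group points, the window sums, `total`,
#'   `level` and `provisional = FALSE`.
#' @export
#' @examples
#' w <- generate_week(preset_profile("high"), seed = 1)
#' score_week(w)
score_week <- function(week, rules = md_rules()) {
  stopifnot(inherits(week, "week_log"))
  if (length(week$days) < 7)
    stop("incomplete week (", length(week$days),
         " days): use preliminary_trend() for partial weeks")
  score_breakdown(week, rules, 7L)
}

#' Provisional adherence trend for a partial week
#'
#' Applies the weekly formula with the observed number of days `n` in the
#' divisor; weekly-basis groups are judged on raw servings observed so far
#' (see `extrapolate_weekly` in [md_rules()]). With 7 days this is exactly
#' [score_week()].
#'
#' @param week A `week_log` with 1-7 days.
#' @param rules An [md_rules()] configuration.
#' @return An `md_score`; `provisional = TRUE` when fewer than 7 days.
#' @export
preliminary_trend <- function(week, rules = md_rules()) {
  stopifnot(inherits(week, "week_log"))
  n <- length(week$days)
  if (n == 0) stop("empty week: no days to score")
  if (n == 7) return(score_week(week, rules))
  score_breakdown(week, rules, n)
}

#' Traffic-light adherence band
#'
#' Maps a weekly total to LOW (red, scores 0-8), MEDIUM (orange, 9-15) or
#' HIGH (green, 16-24). Real-valued totals use the interval completion
#' LOW = \[0, 9), MEDIUM = \[9, 16), HIGH = \[16, 24\].
#'
#' @param total Score(s) in \[0, 24\].
#' @return Character vector of bands.
#' @export
#' @examples
#' classify_adherence(c(8.4, 9, 16))
classify_adherence <- function(total) {
  if (!is.numeric(total) || anyNA(total) || any(total < 0) || any(total > 24))
    stop("adherence total must lie in [0, 24]")
  ifelse(total >= 16, "HIGH", ifelse(total >= 9, "MEDIUM", "LOW"))
}

#' @export
print.md_score <- function(x, ...) {
  cat(sprintf("Weekly MD adherence: %.1f / 24  [%s]%s\n",
              x$total, x$level,
              if (x$provisional)
                sprintf("  (provisional, %d day(s))", x$n_days) else ""))
  cat(sprintf("  meal-basis sum %g, daily-basis sum %g, weekly points %g\n",
              x$meal_sum, x$daily_sum, x$weekly_sum))
  grp <- x$per_group_points
  cat("  per-group points:",
      paste(sprintf("%s=%g", names(grp), grp), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a score breakdown to JSON
#'
#' @param x An `md_score`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
score_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "md_score"))
  obj <- list(per_group_points = as.list(x$per_group_points),
              meal_sum = x$meal_sum, daily_sum = x$daily_sum,
              weekly_sum = x$weekly_sum, n_days = x$n_days,
              total = x$total, level = x$level, provisional = x$provisional)
  if (is.null(path))
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  else
    invisible(jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA))
}
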