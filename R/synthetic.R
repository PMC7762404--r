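# Seeded synthetic weekly diaries.
#
# The generator emulates one user's week: 7 consecutive days, three main
# meals plus 0-2 snacks, consumption drawn per scoring group from a
# configurable profile. It exists so the rule engine, the recognition
# pipeline and every property in the test suite run with no external data.

# run code under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Consumption profile for the diary generator
#'
#' Describes one user's eating pattern: for each meal-basis group the
#' probability that a main meal contains it at its serving threshold, and
#' mean serving counts per day (daily-basis groups) and per week (weekly
#' groups). Counts are drawn as truncated Poisson variates by default;
#' `"fixed"` makes every draw equal the rounded mean, giving deterministic
#' extreme diets (saturating or abstinent).
#'
#' @param meal_probs Named numeric in \[0,1\] over fruit, vegetables,
#'   cereals, olive_oil.
#' @param daily_means Named non-negative means over nuts, dairy,
#'   fermented_beverages (servings/day; draws truncated at 6).
#' @param weekly_means Named non-negative means over the seven weekly groups
#'   (servings/week; draws truncated at 12).
#' @param count_dist `"poisson"` or `"fixed"`.
#' @return A `consumption_profile`.
#' @export
consumption_profile <- function(meal_probs, daily_means, weekly_means,
                                count_dist = c("poisson", "fixed")) {
  count_dist <- match.arg(count_dist)
  meal_probs <- meal_probs[MEAL_GROUPS]
  daily_means <- daily_means[DAILY_GROUPS]
  weekly_means <- weekly_means[WEEKLY_GROUPS]
  if (anyNA(meal_probs) || any(meal_probs < 0) || any(meal_probs > 1))
    stop("meal_probs must cover all four meal-basis groups with values in [0,1]")
  if (anyNA(daily_means) || any(daily_means < 0))
    stop("daily_means must cover nuts, dairy, fermented_beverages with values >= 0")
  if (anyNA(weekly_means) || any(weekly_means < 0))
    stop("weekly_means must cover all seven weekly groups with values >= 0")
  structure(list(meal_probs = meal_probs, daily_means = daily_means,
                 weekly_means = weekly_means, count_dist = count_dist),
            class = "consumption_profile")
}

#' Preset adherence profiles
#'
#' Profiles calibrated by Monte-Carlo so that mean weekly totals over many
#' seeds land in the LOW, MEDIUM or HIGH traffic-light band.
#'
#' @param name `"low"`, `"medium"` or `"high"`.
#' @return A `consumption_profile`.
#' @export
preset_profile <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("low", "medium", "high"))
    stop("unknown profile name: ", paste(name, collapse = ", "),
         " (expected low, medium or high)")
  switch(name,
    high = consumption_profile(
      meal_probs = c(fruit = 0.85, vegetables = 0.85, cereals = 0.85,
                     olive_oil = 0.85),
      daily_means = c(nuts = 1.2, dairy = 2.2, fermented_beverages = 1.2),
      weekly_means = c(potatoes = 2, legumes = 2.5, eggs = 2.5, fish = 2.5,
                       white_meat = 2.5, red_meat = 0.5, sweets = 1)),
    medium = consumption_profile(
      meal_probs = c(fruit = 0.55, vegetables = 0.55, cereals = 0.55,
                     olive_oil = 0.55),
      daily_means = c(nuts = 0.5, dairy = 1.2, fermented_beverages = 0.8),
      weekly_means = c(potatoes = 3, legumes = 1.5, eggs = 1.5, fish = 1.5,
                       white_meat = 1.5, red_meat = 1.2, sweets = 2)),
    low = consumption_profile(
      meal_probs = c(fruit = 0.15, vegetables = 0.15, cereals = 0.15,
                     olive_oil = 0.15),
      daily_means = c(nuts = 0.05, dairy = 0.3, fermented_beverages = 0.2),
      weekly_means = c(potatoes = 5, legumes = 0.3, eggs = 0.3, fish = 0.3,
                       white_meat = 0.3, red_meat = 2.5, sweets = 4)))
}

#' Read a consumption profile from YAML
#'
#' The file holds `meal_probs`, `daily_means`, `weekly_means` maps and an
#' optional `count_dist`.
#'
#' @param path YAML file path.
#' @return A `consumption_profile`.
#' @export
profile_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  consumption_profile(
    meal_probs = unlist(x$meal_probs),
    daily_means = unlist(x$daily_means),
    weekly_means = unlist(x$weekly_means),
    count_dist = if (is.null(x$count_dist)) "poisson" else x$count_dist)
}

draw_count <- function(mean, dist, cap) {
  n <- if (dist == "fixed") round(mean) else stats::rpois(1, mean)
  min(n, cap)
}

# representative categories per scoring group (cereals and dairy rotate over
# their member categories; fermented beverages over wine and beer)
GROUP_CATEGORIES <- list(
  fruit = "fruits", vegetables = "vegetables",
  cereals = c("bread white", "bread non-white", "pasta white", "rice white",
              "cereals unprocessed"),
  olive_oil = "olive oil",
  nuts = "nuts", dairy = c("milk", "yogurt", "cheese"),
  fermented_beverages = c("beverage—wine", "beverage—beer"),
  potatoes = c("potatoes non-fried", "French fries"),
  legumes = "legumes/pulses", eggs = "eggs", fish = "fish/seafood",
  white_meat = "meat white", red_meat = "meat red", sweets = "sweets")

pick_category <- function(group) {
  cats <- GROUP_CATEGORIES[[group]]
  if (length(cats) == 1) cats else sample(cats, 1)
}

#' Generate a synthetic weekly diary
#'
#' Draws 7 consecutive days, each with breakfast, lunch and dinner and up to
#' two snacks. Meal-basis groups enter main meals at their serving threshold
#' with the profile's inclusion probabilities; daily-group servings go to
#' snacks when the day has one (main meals otherwise); weekly-group servings
#' are spread uniformly over the week's lunches and dinners. Identical
#' profile and seed reproduce the identical week.
#'
#' @param profile A [consumption_profile()].
#' @param seed Integer seed.
#' @param week_start First date of the week (default an arbitrary Monday).
#' @return A validated `week_log`.
#' @export
#' @examples
#' w <- generate_week(preset_profile("medium"), seed = 7)
#' score_week(w)
generate_week <- function(profile, seed, week_start = as.Date("2024-01-01")) {
  stopifnot(inherits(profile, "consumption_profile"))
  week_start <- as.Date(week_start)
  with_local_seed(seed, {
    # weekly-group servings: weekly count split uniformly over 7 days
    weekly_day <- lapply(WEEKLY_GROUPS, function(g) {
      n <- draw_count(profile$weekly_means[[g]], profile$count_dist, 12)
      tabulate(sample.int(7, n, replace = TRUE), nbins = 7)
    })
    names(weekly_day) <- WEEKLY_GROUPS

    days <- lapply(seq_len(7), function(i) {
      meals <- list(breakfast = list(), lunch = list(), dinner = list())
      for (mt in MAIN_MEALS) {
        for (g in MEAL_GROUPS) {
          if (stats::runif(1) < profile$meal_probs[[g]]) {
            cat_id <- pick_category(g)
            src <- if (cat_id == "olive oil") "manual" else "recognized"
            meals[[mt]] <- c(meals[[mt]], list(
              food_entry(cat_id, unname(MEAL_MINIMA[g]), src)))
          }
        }
      }
      n_snacks <- sample(0:2, 1)
      snacks <- rep(list(list()), n_snacks)
      # daily-group servings land in a snack when one exists
      for (g in DAILY_GROUPS) {
        n <- draw_count(profile$daily_means[[g]], profile$count_dist, 6)
        if (n == 0) next
        entry <- food_entry(pick_category(g), n, "recognized")
        if (n_snacks > 0) {
          k <- sample.int(n_snacks, 1)
          snacks[[k]] <- c(snacks[[k]], list(entry))
        } else {
          mt <- sample(MAIN_MEALS, 1)
          meals[[mt]] <- c(meals[[mt]], list(entry))
        }
      }
      for (g in WEEKLY_GROUPS) {
        n <- weekly_day[[g]][i]
        if (n == 0) next
        mt <- sample(c("lunch", "dinner"), 1)
        meals[[mt]] <- c(meals[[mt]], list(
          food_entry(pick_category(g), n, "recognized")))
      }
      recs <- lapply(MAIN_MEALS, function(mt) meal_record(mt, meals[[mt]]))
      for (sn in snacks)
        if (length(sn) > 0) recs <- c(recs, list(meal_record("snack", sn)))
      day_log(week_start + (i - 1), recs)
    })
    week_log(days)
  })
}
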