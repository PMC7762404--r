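mk_day <- function(...) day_log("2024-01-01", list(...))

test_that("meal-basis points follow the per-meal serving thresholds", {
  fruity <- function(mt, n = 1)
    meal_record(mt, list(food_entry("fruits", n, "recognized")))
  d <- mk_day(fruity("breakfast"), fruity("lunch"), fruity("dinner"))
  expect_equal(score_meal_basis(d)[["fruit"]], 3)

  # many servings in one meal still earn one point
  d <- mk_day(fruity("breakfast", 4))
  expect_equal(score_meal_basis(d)[["fruit"]], 1)

  # snacks never contribute to meal-basis groups
  d <- mk_day(meal_record("snack", list(food_entry("fruits", 2, "recognized"))))
  expect_equal(sum(score_meal_basis(d)), 0)

  # vegetables need two servings per meal under the threshold rule
  veg <- mk_day(meal_record("lunch", list(food_entry("vegetables", 1, "recognized"))))
  expect_equal(score_meal_basis(veg)[["vegetables"]], 0)
  expect_equal(score_meal_basis(veg, md_rules(meal_presence_rule = "presence"))[["vegetables"]], 1)

  # two half servings of different cereals sum within the meal
  d <- mk_day(meal_record("dinner", list(
    food_entry("bread white", 0.5, "recognized"),
    food_entry("rice white", 0.5, "recognized"))))
  expect_equal(score_meal_basis(d)[["cereals"]], 1)
})

test_that("daily-basis points follow the nuts/dairy/fermented tallies", {
  day_with <- function(cat, n) mk_day(
    meal_record("snack", list(food_entry(cat, n, "recognized"))))
  expect_equal(score_daily_basis(day_with("nuts", 1))[["nuts"]], 2)
  expect_equal(score_daily_basis(day_with("nuts", 0.5))[["nuts"]], 0)
  expect_equal(score_daily_basis(day_with("milk", 1))[["dairy"]], 1)
  expect_equal(score_daily_basis(day_with("cheese", 2))[["dairy"]], 2)
  expect_equal(score_daily_basis(day_with("beverage—wine", 1))[["fermented_beverages"]], 1)
  expect_equal(score_daily_basis(day_with("beverage—wine", 2))[["fermented_beverages"]], 1)
  expect_equal(score_daily_basis(day_with("beverage—wine", 3))[["fermented_beverages"]], 0)
  # abstinence earns nothing for a range-style rule
  expect_equal(score_daily_basis(mk_day())[["fermented_beverages"]], 0)
  # wine and beer tally together across meals
  d <- mk_day(meal_record("lunch", list(food_entry("beverage—wine", 1, "recognized"))),
              meal_record("dinner", list(food_entry("beverage—beer", 2, "recognized"))))
  expect_equal(score_daily_basis(d)[["fermented_beverages"]], 0)
})

week_with <- function(cat, n) {
  days <- lapply(0:6, function(i) day_log(as.Date("2024-01-01") + i,
    if (i == 0 && n > 0)
      list(meal_record("lunch", list(food_entry(cat, n, "recognized"))))
    else list()))
  week_log(days)
}

test_that("weekly-basis points: minima for beneficial groups, caps for the rest", {
  expect_equal(score_weekly_basis(week_with("fish/seafood", 2))[["fish"]], 1)
  expect_equal(score_weekly_basis(week_with("fish/seafood", 1))[["fish"]], 0)
  expect_equal(score_weekly_basis(week_with("meat red", 1))[["red_meat"]], 1)
  expect_equal(score_weekly_basis(week_with("meat red", 2))[["red_meat"]], 0)
  expect_equal(score_weekly_basis(week_with("sweets", 3))[["sweets"]], 0)
  expect_equal(score_weekly_basis(week_with("sweets", 1.5))[["sweets"]], 1)
  expect_equal(score_weekly_basis(week_with("French fries", 4))[["potatoes"]], 0)
  # abstinence satisfies every cap
  empty <- score_weekly_basis(week_with("fish/seafood", 0))
  expect_equal(unname(empty[c("red_meat", "sweets", "potatoes")]), c(1, 1, 1))

  expect_equal(score_weekly_basis(week_with("eggs", 5))[["eggs"]], 1)
  expect_equal(score_weekly_basis(week_with("eggs", 5),
                                  md_rules(eggs_rule = "range"))[["eggs"]], 0)
  expect_equal(score_weekly_basis(week_with("eggs", 3),
                                  md_rules(eggs_rule = "range"))[["eggs"]], 1)
})

test_that("weekly totals hit the documented extremes", {
  s_empty <- score_week(empty_week())
  expect_equal(s_empty$total, 3)
  expect_identical(s_empty$level, "LOW")

  s_max <- score_week(saturating_week())
  expect_equal(s_max$total, 24)
  expect_identical(s_max$level, "HIGH")
  expect_false(s_max$provisional)

  s_min <- score_week(adversarial_week())
  expect_equal(s_min$total, 0)
  expect_identical(s_min$level, "LOW")
})

test_that("partial weeks yield a provisional trend with the n-day divisor", {
  full <- saturating_week()
  # a perfect day with no weekly-group consumption: (12 + 5)/1 + 3
  main <- function(mt) meal_record(mt, list(
    food_entry("fruits", 1, "recognized"),
    food_entry("vegetables", 2, "recognized"),
    food_entry("rice white", 1, "recognized"),
    food_entry("olive oil", 1, "manual")))
  one_day <- week_log(list(day_log("2024-01-01", list(
    main("breakfast"), main("lunch"), main("dinner"),
    meal_record("snack", list(
      food_entry("nuts", 1, "recognized"),
      food_entry("yogurt", 2, "recognized"),
      food_entry("beverage—beer", 1, "recognized")))))))
  expect_error(score_week(one_day), "preliminary_trend")
  tr <- preliminary_trend(one_day)
  expect_equal(tr$total, 20)
  expect_true(tr$provisional)

  # with all 7 days the trend is the definitive score
  tr7 <- preliminary_trend(full)
  expect_false(tr7$provisional)
  expect_equal(tr7$total, score_week(full)$total)

  # extrapolation scales observed weekly servings to a full week
  two_days <- week_log(adversarial_week()$days[1:2])
  raw <- preliminary_trend(two_days)
  ext <- preliminary_trend(two_days, md_rules(extrapolate_weekly = TRUE))
  expect_true(ext$total <= raw$total)
})

test_that("traffic-light banding is a monotone step function on [0, 24]", {
  expect_identical(unname(classify_adherence(0:8)), rep("LOW", 9))
  expect_identical(unname(classify_adherence(9:15)), rep("MEDIUM", 7))
  expect_identical(unname(classify_adherence(16:24)), rep("HIGH", 9))
  expect_identical(classify_adherence(8.4), "LOW")
  expect_identical(classify_adherence(8.999), "LOW")
  expect_identical(classify_adherence(15.999), "MEDIUM")
  grid <- seq(0, 24, by = 0.125)
  lev <- match(classify_adherence(grid), c("LOW", "MEDIUM", "HIGH"))
  expect_true(all(diff(lev) >= 0))
  expect_error(classify_adherence(-0.1), "\\[0, 24\\]")
  expect_error(classify_adherence(24.1), "\\[0, 24\\]")
})

test_that("rule engine agrees with the independent brute-force evaluator", {
  for (seed in 1:100) {
    w <- generate_week(random_profile(seed), seed + 1000)
    expect_equal(score_week(w)$total, bf_score_week(w), label = paste("seed", seed))
  }
  # and on the deterministic extremes
  for (w in list(saturating_week(), adversarial_week(), empty_week()))
    expect_equal(score_week(w)$total, bf_score_week(w))
})

add_entry <- function(week, day_i, cat, n = 1) {
  src <- if (cat == "olive oil") "manual" else "recognized"
  m_i <- sample.int(length(week$days[[day_i]]$meals), 1)
  week$days[[day_i]]$meals[[m_i]]$entries <-
    c(week$days[[day_i]]$meals[[m_i]]$entries, list(food_entry(cat, n, src)))
  week
}

test_that("adding beneficial servings never lowers the total; capped ones never raise it", {
  positive <- c("fruits", "vegetables", "bread white", "olive oil", "nuts",
                "milk", "legumes/pulses", "eggs", "fish/seafood", "meat white")
  capped <- c("meat red", "sweets", "French fries")
  set.seed(99)
  for (rep in 1:40) {
    w <- generate_week(random_profile(rep), rep)
    base <- score_week(w)$total
    cat_p <- sample(positive, 1)
    w_p <- add_entry(w, sample.int(7, 1), cat_p)
    expect_gte(score_week(w_p)$total, base)
    cat_c <- sample(capped, 1)
    w_c <- add_entry(w, sample.int(7, 1), cat_c)
    expect_lte(score_week(w_c)$total, base)
    # a third daily glass of wine can only hurt
    day_i <- sample.int(7, 1)
    w_w <- add_entry(w, day_i, "beverage—wine", 3)
    expect_lte(score_week(w_w)$total, base + 0)
  }
})
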