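# Independent brute-force oracles, coded from the rule table and the metric
# definitions directly, sharing no logic with the package internals.

# literal category -> scoring-group map
bf_map <- c(
  "vegetables" = "vegetables", "fruits" = "fruit", "nuts" = "nuts",
  "legumes/pulses" = "legumes",
  "bread white" = "cereals", "bread non-white" = "cereals",
  "pasta white" = "cereals", "pasta non-white" = "cereals",
  "rice white" = "cereals", "rice non-white" = "cereals",
  "cereals unprocessed" = "cereals", "cereals processed" = "cereals",
  "potatoes non-fried" = "potatoes", "French fries" = "potatoes",
  "meat white" = "white_meat", "meat red" = "red_meat",
  "fish/seafood" = "fish", "eggs" = "eggs",
  "sweets" = "sweets", "milk" = "dairy", "yogurt" = "dairy",
  "cheese" = "dairy",
  "beverage—wine" = "fermented_beverages",
  "beverage—beer" = "fermented_beverages",
  "beverage—soft-drink" = "sweets",
  "olive oil" = "olive_oil")

bf_servings <- function(entries, group) {
  tot <- 0
  for (e in entries) {
    g <- bf_map[e$category]
    if (!is.na(g) && g == group) tot <- tot + e$servings
  }
  tot
}

# literal re-reading of the rule table: per-meal minima, daily tallies,
# weekly tallies, Eq-style weekly total
bf_score_week <- function(week) {
  n_days <- length(week$days)
  meal_daily <- 0
  for (day in week$days) {
    for (mt in c("breakfast", "lunch", "dinner")) {
      for (m in day$meals) {
        if (m$meal_type != mt) next
        if (bf_servings(m$entries, "fruit") >= 1)      meal_daily <- meal_daily + 1
        if (bf_servings(m$entries, "vegetables") >= 2) meal_daily <- meal_daily + 1
        if (bf_servings(m$entries, "cereals") >= 1)    meal_daily <- meal_daily + 1
        if (bf_servings(m$entries, "olive_oil") >= 1)  meal_daily <- meal_daily + 1
      }
    }
    all_entries <- list()
    for (m in day$meals) all_entries <- c(all_entries, m$entries)
    if (bf_servings(all_entries, "nuts") >= 1) meal_daily <- meal_daily + 2
    d <- bf_servings(all_entries, "dairy")
    if (d >= 2) meal_daily <- meal_daily + 2
    else if (d >= 1) meal_daily <- meal_daily + 1
    f <- bf_servings(all_entries, "fermented_beverages")
    if (f >= 1 && f <= 2) meal_daily <- meal_daily + 1
  }
  week_entries <- list()
  for (day in week$days) for (m in day$meals)
    week_entries <- c(week_entries, m$entries)
  weekly <- 0
  if (bf_servings(week_entries, "legumes") >= 2)    weekly <- weekly + 1
  if (bf_servings(week_entries, "eggs") >= 2)       weekly <- weekly + 1
  if (bf_servings(week_entries, "fish") >= 2)       weekly <- weekly + 1
  if (bf_servings(week_entries, "white_meat") >= 2) weekly <- weekly + 1
  if (bf_servings(week_entries, "red_meat") <= 1)   weekly <- weekly + 1
  if (bf_servings(week_entries, "sweets") <= 2)     weekly <- weekly + 1
  if (bf_servings(week_entries, "potatoes") <= 3)   weekly <- weekly + 1
  meal_daily / n_days + weekly
}

# exhaustive precision/recall-table average precision: walk every cutoff,
# then take the max precision among cutoffs reaching each recall level
bf_average_precision <- function(conf, pos) {
  n_pos <- sum(pos)
  stopifnot(n_pos > 0)
  ord <- order(-conf, seq_along(conf))
  pos <- pos[ord]
  ks <- seq_along(pos)
  prec <- vapply(ks, function(k) sum(pos[1:k]) / k, numeric(1))
  rec <- vapply(ks, function(k) sum(pos[1:k]) / n_pos, numeric(1))
  levels <- seq_len(n_pos) / n_pos
  mean(vapply(levels, function(r) max(prec[rec >= r - 1e-12]), numeric(1)))
}

bf_mean_ap <- function(preds, truths, categories) {
  tid <- vapply(truths, `[[`, character(1), "image_id")
  pid <- vapply(preds, `[[`, character(1), "image_id")
  preds <- preds[match(tid, pid)]
  aps <- c()
  for (ct in categories) {
    pos <- vapply(truths, function(t) ct %in% t$labels, logical(1))
    if (!any(pos)) next
    conf <- vapply(preds, function(p)
      if (ct %in% names(p$confidence)) p$confidence[[ct]] else 0, numeric(1))
    aps <- c(aps, bf_average_precision(conf, pos))
  }
  mean(aps)
}

# pairwise co-occurrence counter by explicit double loop
bf_cooccurrence <- function(truths, categories) {
  C <- length(categories)
  adj <- matrix(0, C, C, dimnames = list(categories, categories))
  for (i in seq_len(C)) {
    ni <- 0
    for (t in truths) if (categories[i] %in% t$labels) ni <- ni + 1
    if (ni == 0) next
    for (j in seq_len(C)) {
      nij <- 0
      for (t in truths)
        if (categories[i] %in% t$labels && categories[j] %in% t$labels)
          nij <- nij + 1
      adj[i, j] <- nij / ni
    }
  }
  adj
}

# randomized consumption profile covering the rule space
random_profile <- function(seed) {
  set.seed(seed)
  consumption_profile(
    meal_probs = stats::setNames(runif(4), c("fruit", "vegetables",
                                             "cereals", "olive_oil")),
    daily_means = stats::setNames(runif(3, 0, 3),
                                  c("nuts", "dairy", "fermented_beverages")),
    weekly_means = stats::setNames(runif(7, 0, 5),
                                   c("potatoes", "legumes", "eggs", "fish",
                                     "white_meat", "red_meat", "sweets")))
}

# deterministic extreme diets used across suites
saturating_week <- function() {
  day <- function(date) {
    main <- function(mt) meal_record(mt, list(
      food_entry("fruits", 1, "recognized"),
      food_entry("vegetables", 2, "recognized"),
      food_entry("bread white", 1, "recognized"),
      food_entry("olive oil", 1, "manual")))
    day_log(date, list(
      main("breakfast"), main("lunch"), main("dinner"),
      meal_record("snack", list(
        food_entry("nuts", 1, "recognized"),
        food_entry("milk", 2, "recognized"),
        food_entry("beverage—wine", 1, "recognized")))))
  }
  days <- lapply(0:6, function(i) day(as.Date("2024-01-01") + i))
  # weekly groups: two servings each of legumes/eggs/fish/white meat spread
  # over the week; one red meat, two sweets, three potatoes (caps respected)
  add <- function(d, cat, n) {
    d$meals[[2]]$entries <- c(d$meals[[2]]$entries,
                              list(food_entry(cat, n, "recognized")))
    d
  }
  days[[1]] <- add(days[[1]], "legumes/pulses", 2)
  days[[2]] <- add(days[[2]], "eggs", 2)
  days[[3]] <- add(days[[3]], "fish/seafood", 2)
  days[[4]] <- add(days[[4]], "meat white", 2)
  days[[5]] <- add(days[[5]], "meat red", 1)
  days[[6]] <- add(days[[6]], "sweets", 2)
  days[[7]] <- add(days[[7]], "potatoes non-fried", 3)
  week_log(days)
}

adversarial_week <- function() {
  days <- lapply(0:6, function(i) {
    day_log(as.Date("2024-03-04") + i, list(
      meal_record("breakfast", list(
        food_entry("beverage—alcoholic", 3, "manual"))),
      meal_record("lunch", list(
        food_entry("meat red", 1, "recognized"),
        food_entry("sweets", 1, "recognized"))),
      meal_record("dinner", list(
        food_entry("French fries", 1, "recognized")))))
  })
  week_log(days)
}

empty_week <- function() {
  week_log(lapply(0:6, function(i)
    day_log(as.Date("2024-02-05") + i, list(
      meal_record("breakfast"), meal_record("lunch"),
      meal_record("dinner")))))
}
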