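# Diary data model: food entries -> meal records -> day logs -> week logs,
# plus JSON (canonical, nested) and CSV (flat, one row per entry) round-trip.

MEAL_TYPES <- c("breakfast", "lunch", "dinner", "snack")
MAIN_MEALS <- c("breakfast", "lunch", "dinner")

#' Create a diary food entry
#'
#' @param category Category id from the vocabulary (manual-only categories
#'   such as olive oil are allowed; they must carry `source = "manual"`).
#' @param servings Non-negative real number of standard servings.
#' @param source `"recognized"` (from the image recognizer) or `"manual"`
#'   (user-entered; required for non-visually-detectable items).
#' @return A `food_entry` object.
#' @export
food_entry <- function(category, servings, source = "manual") {
  tab <- md_taxonomy()
  idx <- match(category, tab$category)
  if (is.na(idx)) stop("unknown food category: ", category)
  if (!is.numeric(servings) || length(servings) != 1 ||
      is.na(servings) || servings < 0)
    stop("servings must be a single non-negative number")
  source <- match.arg(source, c("manual", "recognized"))
  if (tab$manual_only[idx] && source != "manual")
    stop(sprintf("'%s' is not visually detectable and must be manual", category))
  structure(list(category = category, servings = as.numeric(servings),
                 source = source),
            class = "food_entry")
}

#' Create a meal record
#'
#' @param meal_type One of breakfast, lunch, dinner, snack.
#' @param entries List of [food_entry()] objects. The same category may occur
#'   more than once; servings are summed when scoring.
#' @return A `meal_record` object.
#' @export
meal_record <- function(meal_type, entries = list()) {
  if (!is.character(meal_type) || length(meal_type) != 1 ||
      !meal_type %in% MEAL_TYPES)
    stop("unknown meal_type: ", paste(meal_type, collapse = ", "),
         " (must be one of ", paste(MEAL_TYPES, collapse = ", "), ")")
  if (!all(vapply(entries, inherits, logical(1), "food_entry")))
    stop("entries must be a list of food_entry objects")
  structure(list(meal_type = meal_type, entries = unname(entries)),
            class = "meal_record")
}

#' Create a day log
#'
#' A day holds at most one record each of breakfast, lunch and dinner, and
#' any number of snacks.
#'
#' @param date Calendar date (`Date` or ISO-8601 string).
#' @param meals List of [meal_record()] objects.
#' @return A `day_log` object.
#' @export
day_log <- function(date, meals = list()) {
  date <- as.Date(date)
  if (is.na(date)) stop("invalid date")
  if (!all(vapply(meals, inherits, logical(1), "meal_record")))
    stop("meals must be a list of meal_record objects")
  types <- vapply(meals, `[[`, character(1), "meal_type")
  dup <- types[types %in% MAIN_MEALS][duplicated(types[types %in% MAIN_MEALS])]
  if (length(dup) > 0)
    stop("duplicate main-meal record on ", format(date), ": ",
         paste(unique(dup), collapse = ", "))
  structure(list(date = date, meals = unname(meals)), class = "day_log")
}

#' Create a week log
#'
#' Between 1 and 7 day logs with strictly consecutive dates; 7 days make a
#' complete week, fewer give only a provisional adherence trend.
#'
#' @param days List of [day_log()] objects, ordered by date.
#' @return A `week_log` object.
#' @export
week_log <- function(days) {
  if (!is.list(days) || length(days) < 1 || length(days) > 7)
    stop("a week log needs between 1 and 7 days")
  if (!all(vapply(days, inherits, logical(1), "day_log")))
    stop("days must be a list of day_log objects")
  dates <- as.Date(vapply(days, function(d) format(d$date), character(1)))
  if (length(dates) > 1 && !all(diff(as.integer(dates)) == 1))
    stop("day dates must be strictly consecutive")
  structure(list(week_start = dates[1], days = unname(days)),
            class = "week_log")
}

#' @export
print.week_log <- function(x, ...) {
  n_entries <- sum(vapply(x$days, function(d)
    sum(vapply(d$meals, function(m) length(m$entries), integer(1))),
    integer(1)))
  cat(sprintf("<week_log> %d day(s) starting %s, %d entries\n",
              length(x$days), format(x$week_start), n_entries))
  invisible(x)
}

#' Flatten a week log to a data frame
#'
#' One row per food entry with columns `date`, `meal_type`, `category`,
#' `servings`, `source` (the flat CSV dialect). Meals with no entries are
#' dropped.
#'
#' @param x A `week_log`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.week_log <- function(x, ...) {
  rows <- list()
  for (d in x$days) for (m in d$meals) for (e in m$entries) {
    rows[[length(rows) + 1L]] <- data.frame(
      date = format(d$date), meal_type = m$meal_type,
      category = e$category, servings = e$servings, source = e$source,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(date = character(), meal_type = character(),
                      category = character(), servings = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

week_to_list <- function(week) {
  list(
    week_start = format(week$week_start),
    days = lapply(week$days, function(d) list(
      date = format(d$date),
      meals = lapply(d$meals, function(m) list(
        meal_type = m$meal_type,
        entries = lapply(m$entries, function(e)
          list(category = e$category, servings = e$servings,
               source = e$source))))))
  )
}

week_from_list <- function(x) {
  if (is.null(x$days)) stop("diary is missing 'days'")
  days <- lapply(x$days, function(d) {
    if (is.null(d$date)) stop("day record is missing 'date'")
    meals <- lapply(d$meals, function(m) {
      entries <- lapply(m$entries, function(e) {
        if (is.null(e$category) || is.null(e$servings))
          stop("entry is missing 'category' or 'servings'")
        food_entry(e$category, e$servings,
                   if (is.null(e$source)) "manual" else e$source)
      })
      meal_record(m$meal_type, entries)
    })
    day_log(d$date, meals)
  })
  week_log(days)
}

#' Read a weekly food diary
#'
#' Reads the canonical nested JSON dialect or the flat CSV dialect (one row
#' per entry: `date`, `meal_type`, `category`, `servings`, `source`) and
#' validates structure: known categories and meal types, no duplicate main
#' meals, consecutive dates.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"json"` or `"csv"`.
#' @return A validated `week_log`.
#' @export
read_diary <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    x <- jsonlite::read_json(path, simplifyVector = FALSE)
    week_from_list(x)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    needed <- c("date", "meal_type", "category", "servings")
    missing <- setdiff(needed, names(tab))
    if (length(missing) > 0)
      stop("diary CSV lacks columns: ", paste(missing, collapse = ", "))
    if (is.null(tab$source)) tab$source <- "manual"
    days <- lapply(split(tab, tab$date), function(dd) {
      meals <- lapply(split(dd, factor(dd$meal_type, levels = unique(dd$meal_type))),
                      function(mm) {
        entries <- lapply(seq_len(nrow(mm)), function(i)
          food_entry(mm$category[i], mm$servings[i], mm$source[i]))
        meal_record(mm$meal_type[1], entries)
      })
      day_log(dd$date[1], unname(meals))
    })
    days <- days[order(as.Date(names(days)))]
    week_log(unname(days))
  }
}

#' Write a weekly food diary
#'
#' Inverse of [read_diary()]: `read_diary(write_diary(w, f))` reproduces the
#' week log field for field (empty meals are not representable in the flat
#' CSV dialect and are dropped there).
#'
#' @param week A `week_log`.
#' @param path Output file path.
#' @param format `"auto"`, `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_diary <- function(week, path, format = c("auto", "json", "csv")) {
  stopifnot(inherits(week, "week_log"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    jsonlite::write_json(week_to_list(week), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(as.data.frame(week), path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}
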