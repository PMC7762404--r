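# Food/beverage vocabulary, scoring groups, serving sizes.
#
# The vocabulary is shipped as a plain CSV (inst/extdata/taxonomy.csv) so the
# serving-size reference (British Nutrition Foundation values, with Swiss Food
# Association values where the BNF is silent) can be swapped without touching
# code. It holds the 31 image-recognizable categories plus "olive oil", a
# manual-entry item: olive oil cannot be detected visually but is required for
# the meal-basis olive-oil group, so it exists only with manual_only = TRUE.

# cache for the parsed taxonomy table
.medscore_env <- new.env(parent = emptyenv())

#' Load the food-category taxonomy
#'
#' Reads the packaged taxonomy table: one row per food/beverage category with
#' its Mediterranean-diet scoring group (empty when the category is recorded
#' but never scored), its standard serving size, and flags for beverages,
#' wholegrain variants, and manual-only entries.
#'
#' @param path Path to a taxonomy CSV. Defaults to the table shipped with the
#'   package. The file must have columns `category`, `group`,
#'   `serving_amount`, `serving_unit`, `wholegrain_flag`, `is_beverage`,
#'   `manual_only`.
#' @return A data frame with one row per category.
#' @export
#' @examples
#' tax <- md_taxonomy()
#' nrow(tax)
md_taxonomy <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.medscore_env$taxonomy)) return(.medscore_env$taxonomy)
    path <- system.file("extdata", "taxonomy.csv", package = "medscore")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("category", "group", "serving_amount", "serving_unit",
              "wholegrain_flag", "is_beverage", "manual_only")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0)
    stop("taxonomy file lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(tab$category))
    stop("taxonomy has duplicated category ids")
  tab$group[is.na(tab$group) | tab$group == ""] <- NA_character_
  if (!all(tab$serving_amount > 0, na.rm = TRUE))
    stop("serving sizes must be positive")
  if (cache) .medscore_env$taxonomy <- tab
  tab
}

#' Category vocabulary
#'
#' @param include_manual Also return manual-only entries (olive oil), which
#'   are not part of the 31-category image vocabulary.
#' @return Character vector of category ids.
#' @export
md_categories <- function(include_manual = FALSE) {
  tab <- md_taxonomy()
  if (!include_manual) tab <- tab[!tab$manual_only, ]
  tab$category
}

#' Mediterranean-diet scoring groups
#'
#' The 14 food groups of the serving score, each evaluated over a meal, daily
#' or weekly window, with its maximum point contribution and threshold rule.
#' Group maxima sum to 24, the score's upper bound.
#'
#' @return A data frame with columns `group`, `basis`, `max_points`.
#' @export
md_groups <- function() {
  data.frame(
    group = c("fruit", "vegetables", "cereals", "olive_oil",
              "nuts", "dairy", "fermented_beverages",
              "potatoes", "legumes", "eggs", "fish",
              "white_meat", "red_meat", "sweets"),
    basis = c(rep("meal", 4), rep("daily", 3), rep("weekly", 7)),
    max_points = c(3, 3, 3, 3, 2, 2, 1, rep(1, 7)),
    stringsAsFactors = FALSE
  )
}

#' Map a food category to its scoring group
#'
#' Deterministic, total over the vocabulary. Categories that are recorded but
#' play no role in the classical score (water, coffee, tea, milky coffee,
#' spirits, breaded food) return `NA`. Wine and beer map to fermented
#' beverages; sweetened soft drinks count as sweets; both potato categories
#' (including fries) count toward the weekly potato tally.
#'
#' @param category Character vector of category ids.
#' @return Character vector of group names, `NA` where the category is
#'   unscored.
#' @export
#' @examples
#' map_category_to_group("beverage—wine")   # fermented_beverages
#' map_category_to_group("beverage—water")  # NA
map_category_to_group <- function(category) {
  tab <- md_taxonomy()
  idx <- match(category, tab$category)
  if (anyNA(idx))
    stop("unknown food category: ",
         paste(unique(category[is.na(idx)]), collapse = ", "))
  tab$group[idx]
}

#' Convert a consumed amount to servings
#'
#' Divides the amount by the category's standard serving size (e.g. fruit
#' 80 g, milk 200 mL). The unit must match the serving definition.
#'
#' @param category Category id.
#' @param amount Non-negative amount consumed.
#' @param unit `"g"` or `"mL"`; must equal the category's serving unit.
#' @return Real number of servings.
#' @export
#' @examples
#' servings_from_amount("fruits", 160, "g")  # 2
servings_from_amount <- function(category, amount, unit) {
  stopifnot(length(category) == 1, length(amount) == 1)
  tab <- md_taxonomy()
  idx <- match(category, tab$category)
  if (is.na(idx)) stop("unknown food category: ", category)
  if (!is.numeric(amount) || is.na(amount) || amount < 0)
    stop("amount must be a non-negative number")
  if (!identical(unit, tab$serving_unit[idx]))
    stop(sprintf("unit mismatch for '%s': expected %s, got %s",
                 category, tab$serving_unit[idx], unit))
  amount / tab$serving_amount[idx]
}
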