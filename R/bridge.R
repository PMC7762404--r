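# Bridge between per-image recognition output and the scoring engine, plus
# the label co-occurrence graph estimated from training annotations.

#' Build a label co-occurrence graph
#'
#' Nodes are the food categories; edge weights estimate how often two
#' categories appear in the same image. The default (asymmetric) form is the
#' conditional frequency `a[i, j] = n(i and j) / n(i)`; `mode = "joint"`
#' gives the symmetric joint frequency `n(i and j) / n_images`. Categories
#' never observed get an all-zero row; observed categories have diagonal 1
#' (conditional) or their marginal frequency (joint).
#'
#' @param truths List of [ground_truth()]s (e.g. aggregated training
#'   annotations).
#' @param categories Node order; defaults to the full image vocabulary.
#' @param mode `"conditional"` or `"joint"`.
#' @return A `cooccurrence_graph`: list with `nodes` and the `adjacency`
#'   matrix.
#' @export
build_cooccurrence <- function(truths, categories = NULL,
                               mode = c("conditional", "joint")) {
  mode <- match.arg(mode)
  if (length(truths) == 0) stop("no ground-truth records")
  if (!all(vapply(truths, inherits, logical(1), "ground_truth")))
    stop("truths must be ground_truth objects")
  if (is.null(categories)) categories <- md_categories(include_manual = TRUE)
  lm <- label_matrix(truths, categories)
  joint <- crossprod(lm)                      # n(i and j)
  if (mode == "conditional") {
    n_i <- diag(joint)
    adj <- joint / ifelse(n_i > 0, n_i, 1)    # rows of unseen i stay zero
    adj[n_i == 0, ] <- 0
  } else {
    adj <- joint / nrow(lm)
  }
  structure(list(nodes = categories, adjacency = adj, mode = mode),
            class = "cooccurrence_graph")
}

#' Write a co-occurrence graph as a CSV matrix
#'
#' @param graph A `cooccurrence_graph`.
#' @param path Output path; header row and first column hold category ids.
#' @return `path`, invisibly.
#' @export
write_cooccurrence <- function(graph, path) {
  stopifnot(inherits(graph, "cooccurrence_graph"))
  utils::write.csv(as.data.frame(graph$adjacency), path, row.names = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Perfect recognizer stand-in
#'
#' Produces the prediction a flawless recognizer would emit for a
#' ground-truth record: confidence 1 on every true label, 0 elsewhere, and
#' predicted servings equal to the ground truth. Used to exercise the
#' diary-assembly pipeline without a trained network.
#'
#' @param truth A [ground_truth()].
#' @param categories Confidence universe; defaults to the full vocabulary.
#' @return A `prediction_set` carrying the truth's meal tag and date.
#' @export
oracle_recognizer <- function(truth, categories = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(categories)) categories <- md_categories(include_manual = TRUE)
  conf <- stats::setNames(numeric(length(categories)), categories)
  conf[intersect(truth$labels, categories)] <- 1
  prediction_set(truth$image_id, conf, truth$servings,
                 meal_tag = truth$meal_tag, date = truth$date)
}

#' Render a week log as per-meal ground truths
#'
#' Each meal becomes one ground-truth "image": its categories as labels,
#' same-category servings summed, tagged with the meal type and date. The
#' inverse direction is [assemble_diary()].
#'
#' @param week A `week_log`.
#' @return List of `ground_truth` records (one per meal, empty meals
#'   included).
#' @export
week_to_truths <- function(week) {
  stopifnot(inherits(week, "week_log"))
  out <- list()
  for (d in week$days) {
    snack_i <- 0L
    for (m in d$meals) {
      tag <- m$meal_type
      img <- if (tag == "snack") {
        snack_i <- snack_i + 1L
        sprintf("%s_snack%d", format(d$date), snack_i)
      } else sprintf("%s_%s", format(d$date), tag)
      serv <- numeric(0)
      for (e in m$entries) {
        serv[e$category] <- (if (e$category %in% names(serv))
          serv[[e$category]] else 0) + e$servings
      }
      out[[length(out) + 1L]] <-
        ground_truth(img, names(serv), serv, meal_tag = tag, date = d$date)
    }
  }
  out
}

#' Assemble recognizer predictions into a weekly diary
#'
#' Groups dated, meal-tagged predictions into day logs: categories predicted
#' at confidence at or above the threshold become recognized food entries
#' with their predicted servings; multiple predictions with the same main
#' meal tag on one date are merged (same-category servings summed), while
#' each snack-tagged prediction stays its own snack. Manual entries (olive
#' oil and other undetectable items) can be merged in afterwards.
#'
#' @param preds List of [prediction_set()]s, each carrying `date` and
#'   `meal_tag`.
#' @param conf_threshold Detection threshold on confidence (default 0.5).
#' @return A validated `week_log` (at most 7 consecutive dates).
#' @export
assemble_diary <- function(preds, conf_threshold = 0.5) {
  if (length(preds) == 0) stop("no predictions to assemble")
  if (!all(vapply(preds, inherits, logical(1), "prediction_set")))
    stop("preds must be prediction_set objects")
  dates <- as.Date(vapply(preds, function(p) format(p$date), character(1)))
  tags <- vapply(preds, `[[`, character(1), "meal_tag")
  if (anyNA(dates)) stop("every prediction needs a date")
  if (anyNA(tags) || !all(tags %in% MEAL_TYPES))
    stop("every prediction needs a meal_tag of breakfast/lunch/dinner/snack")
  if (length(unique(dates)) > 7)
    stop("predictions span more than 7 distinct dates")

  pred_entries <- function(p) {
    detected <- names(p$confidence)[p$confidence >= conf_threshold]
    serv <- numeric(0)
    for (ct in detected) {
      s <- if (ct %in% names(p$pred_servings)) p$pred_servings[[ct]] else 0
      serv[ct] <- (if (ct %in% names(serv)) serv[[ct]] else 0) + s
    }
    lapply(names(serv), function(ct) {
      manual <- md_taxonomy()$manual_only[match(ct, md_taxonomy()$category)]
      food_entry(ct, serv[[ct]], if (isTRUE(manual)) "manual" else "recognized")
    })
  }

  days <- lapply(sort(unique(dates)), function(dt) {
    on_day <- preds[dates == dt]
    day_tags <- vapply(on_day, `[[`, character(1), "meal_tag")
    meals <- list()
    for (mt in MAIN_MEALS) {
      sel <- on_day[day_tags == mt]
      if (length(sel) == 0) next
      entries <- unlist(lapply(sel, pred_entries), recursive = FALSE)
      # merge duplicates across images sharing the meal tag
      serv <- numeric(0); src <- character(0)
      for (e in entries) {
        serv[e$category] <- (if (e$category %in% names(serv))
          serv[[e$category]] else 0) + e$servings
        src[e$category] <- e$source
      }
      meals <- c(meals, list(meal_record(mt, lapply(names(serv), function(ct)
        food_entry(ct, serv[[ct]], src[[ct]])))))
    }
    for (p in on_day[day_tags == "snack"])
      meals <- c(meals, list(meal_record("snack", pred_entries(p))))
    day_log(dt, meals)
  })
  week_log(days)
}
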