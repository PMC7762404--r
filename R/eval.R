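# Recognition evaluation: multi-annotator ground-truth aggregation,
# interpolated mean average precision for multi-label recognition, and the
# mean absolute percentage error of serving-size estimates.

#' Create an annotation record
#'
#' One annotator's labels and serving estimates for one image.
#'
#' @param image_id Image identifier.
#' @param annotator_id Annotator identifier.
#' @param labels Character vector of category ids marked present.
#' @param servings Named numeric vector of serving estimates; names must be a
#'   subset of `labels`.
#' @return An `annotation_record`.
#' @export
annotation_record <- function(image_id, annotator_id, labels,
                              servings = numeric()) {
  labels <- unique(as.character(labels))
  if (length(servings) > 0 && !all(names(servings) %in% labels))
    stop("servings keys must be a subset of labels")
  if (any(servings <= 0)) stop("annotated servings must be positive")
  structure(list(image_id = image_id, annotator_id = annotator_id,
                 labels = labels, servings = servings),
            class = "annotation_record")
}

#' Create a ground-truth record
#'
#' @param image_id Image identifier.
#' @param labels Character vector of present categories.
#' @param servings Named numeric vector (positive) over `labels`.
#' @param meal_tag Optional breakfast/lunch/dinner/snack tag.
#' @param date Optional calendar date.
#' @return A `ground_truth`.
#' @export
ground_truth <- function(image_id, labels, servings = numeric(),
                         meal_tag = NA_character_, date = NA) {
  labels <- unique(as.character(labels))
  if (length(servings) > 0 && !all(names(servings) %in% labels))
    stop("servings keys must be a subset of labels")
  if (!is.na(meal_tag) && !meal_tag %in% MEAL_TYPES)
    stop("unknown meal_tag: ", meal_tag)
  structure(list(image_id = image_id, labels = labels, servings = servings,
                 meal_tag = meal_tag,
                 date = if (all(is.na(date))) as.Date(NA) else as.Date(date)),
            class = "ground_truth")
}

#' Create a recognizer prediction set
#'
#' @param image_id Image identifier.
#' @param confidence Named numeric vector of per-category confidences in
#'   \[0, 1\].
#' @param pred_servings Named numeric vector of predicted serving sizes
#'   (non-negative).
#' @param meal_tag,date Optional meal tag and date (needed by
#'   [assemble_diary()]).
#' @return A `prediction_set`.
#' @export
prediction_set <- function(image_id, confidence, pred_servings = numeric(),
                           meal_tag = NA_character_, date = NA) {
  if (length(confidence) > 0 &&
      (is.null(names(confidence)) || any(confidence < 0) || any(confidence > 1)))
    stop("confidence must be a named vector with values in [0, 1]")
  if (any(pred_servings < 0)) stop("predicted servings must be non-negative")
  structure(list(image_id = image_id, confidence = confidence,
                 pred_servings = pred_servings, meal_tag = meal_tag,
                 date = if (all(is.na(date))) as.Date(NA) else as.Date(date)),
            class = "prediction_set")
}

#' Aggregate several annotators into one ground truth
#'
#' A label is kept when a strict majority of the annotators marked it (3 of
#' 5 in the usual five-annotator setting); its serving size is the mean over
#' the annotators who marked it. Order of annotators is irrelevant.
#'
#' @param records List of [annotation_record()]s for a single image.
#' @return A `ground_truth`.
#' @export
#' @examples
#' recs <- lapply(1:5, function(a)
#'   annotation_record("img1", a, "fruits", c(fruits = a / 5)))
#' aggregate_annotations(recs)
aggregate_annotations <- function(records) {
  if (length(records) == 0) stop("no annotation records to aggregate")
  if (!all(vapply(records, inherits, logical(1), "annotation_record")))
    stop("records must be annotation_record objects")
  ids <- unique(vapply(records, `[[`, character(1), "image_id"))
  if (length(ids) != 1)
    stop("records span multiple images: ", paste(ids, collapse = ", "))
  n <- length(records)
  votes <- table(unlist(lapply(records, `[[`, "labels")))
  kept <- names(votes)[votes > n / 2]
  kept <- kept[order(match(kept, md_categories(include_manual = TRUE)))]
  servings <- vapply(kept, function(lab) {
    vals <- unlist(lapply(records, function(r)
      if (lab %in% names(r$servings)) r$servings[[lab]] else NULL))
    if (length(vals) == 0) NA_real_ else mean(vals)
  }, numeric(1))
  servings <- servings[!is.na(servings)]
  ground_truth(ids, kept, servings)
}

#' Read annotation records from CSV
#'
#' Flat dialect: one row per (image, annotator, category) with columns
#' `image_id`, `annotator_id`, `category`, `servings`.
#'
#' @param path CSV file path.
#' @return List of `annotation_record`s, one per (image, annotator).
#' @export
read_annotations <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- c("image_id", "annotator_id", "category", "servings")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0)
    stop("annotation CSV lacks columns: ", paste(missing, collapse = ", "))
  key <- interaction(tab$image_id, tab$annotator_id, drop = TRUE)
  unname(lapply(split(tab, key), function(g)
    annotation_record(g$image_id[1], g$annotator_id[1], g$category,
                      stats::setNames(g$servings, g$category))))
}

# all-points interpolated average precision for one category.
# conf: per-image confidence; pos: logical, image truly positive.
# ties are broken by the order of the images as supplied (callers pass
# images in a fixed id order, making the metric deterministic).
average_precision <- function(conf, pos) {
  n_pos <- sum(pos)
  if (n_pos == 0) return(NA_real_)
  ord <- order(-conf, seq_along(conf))
  pos <- pos[ord]
  prec_at_hit <- cumsum(pos)[pos] / which(pos)
  # interpolate: max precision at this or any deeper recall level
  interp <- rev(cummax(rev(prec_at_hit)))
  mean(interp)
}

confidence_matrix <- function(preds, categories) {
  m <- matrix(0, nrow = length(preds), ncol = length(categories),
              dimnames = list(vapply(preds, `[[`, character(1), "image_id"),
                              categories))
  for (i in seq_along(preds)) {
    conf <- preds[[i]]$confidence
    known <- intersect(names(conf), categories)
    m[i, known] <- conf[known]
  }
  m
}

label_matrix <- function(truths, categories) {
  m <- matrix(FALSE, nrow = length(truths), ncol = length(categories),
              dimnames = list(vapply(truths, `[[`, character(1), "image_id"),
                              categories))
  for (i in seq_along(truths))
    m[i, intersect(truths[[i]]$labels, categories)] <- TRUE
  m
}

match_by_image <- function(preds, truths) {
  pid <- vapply(preds, `[[`, character(1), "image_id")
  tid <- vapply(truths, `[[`, character(1), "image_id")
  if (anyDuplicated(pid) || anyDuplicated(tid))
    stop("duplicated image_ids")
  if (!setequal(pid, tid))
    stop("prediction and ground-truth image_id sets differ")
  preds[match(tid, pid)]
}

#' Mean average precision over categories
#'
#' For each category, images are ranked by predicted confidence and the
#' all-points interpolated average precision (the maximum precision at each
#' achieved recall level) is computed; the mean is taken over categories with
#' at least one positive image. Categories never present in the ground truth
#' are excluded from the mean (set `include_absent = TRUE` to count them with
#' AP 0).
#'
#' @param preds List of [prediction_set()]s.
#' @param truths List of [ground_truth()]s over the same image ids.
#' @param categories Category universe; defaults to the union of ground-truth
#'   labels.
#' @param include_absent Count never-present categories as AP 0.
#' @return mAP in \[0, 1\].
#' @export
mean_average_precision <- function(preds, truths, categories = NULL,
                                   include_absent = FALSE) {
  if (length(truths) == 0) stop("no ground-truth records")
  preds <- match_by_image(preds, truths)
  if (is.null(categories)) {
    universe <- md_categories(include_manual = TRUE)
    categories <- unique(unlist(lapply(truths, `[[`, "labels")))
    categories <- categories[order(match(categories, universe))]
  }
  if (length(categories) == 0) stop("no category has a positive instance")
  cm <- confidence_matrix(preds, categories)
  lm <- label_matrix(truths, categories)
  aps <- vapply(categories, function(ct) average_precision(cm[, ct], lm[, ct]),
                numeric(1))
  if (include_absent) aps[is.na(aps)] <- 0 else aps <- aps[!is.na(aps)]
  if (length(aps) == 0) stop("no category has a positive instance")
  mean(aps)
}

#' Mean absolute percentage error of serving sizes
#'
#' Evaluated over correctly predicted items only: (image, category) pairs
#' predicted at confidence at or above the threshold that are present in the
#' ground truth. False positives and missed labels are excluded; items whose
#' ground-truth serving is zero are dropped with a warning.
#'
#' @param preds List of [prediction_set()]s.
#' @param truths List of [ground_truth()]s over the same image ids.
#' @param conf_threshold Detection threshold on confidence (default 0.5).
#' @return Mean relative error (0.10 means 10%).
#' @export
mape_servings <- function(preds, truths, conf_threshold = 0.5) {
  preds <- match_by_image(preds, truths)
  errs <- numeric(0)
  dropped <- 0L
  for (i in seq_along(truths)) {
    tr <- truths[[i]]; pr <- preds[[i]]
    detected <- names(pr$confidence)[pr$confidence >= conf_threshold]
    correct <- intersect(detected, tr$labels)
    for (ct in correct) {
      sgt <- if (ct %in% names(tr$servings)) tr$servings[[ct]] else NA_real_
      if (is.na(sgt)) next
      if (sgt == 0) { dropped <- dropped + 1L; next }
      spred <- if (ct %in% names(pr$pred_servings))
        pr$pred_servings[[ct]] else 0
      errs <- c(errs, abs(sgt - spred) / sgt)
    }
  }
  if (dropped > 0)
    warning(dropped, " item(s) with zero ground-truth serving excluded")
  if (length(errs) == 0)
    stop("no correctly predicted items at this threshold; MAPE is undefined")
  mean(errs)
}
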