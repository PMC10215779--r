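# Per-genus presence/absence random forests and the largest-Gini-gap
# predictor selection rule. Pseudo-absences follow the co-report assumption:
# a row with any positive genus supplies absence labels for all genera not
# reported there (an observer photographing one jellyfish would report
# others present).

#' Build per-genus presence/absence labels from the curated frame
#'
#' For each genus and row, the label is 1 if the genus has a positive count
#' in that row, else 0. Rows exist only where some genus was reported, so
#' the zeros are co-report pseudo-absences.
#'
#' @param frame An imputed `curated_frame`.
#' @param genera Genus count columns (default: frame attribute).
#' @param predictors Predictor columns (default: canonical ids present).
#' @return A `labeled_table`: list with `features` (data frame), `labels`
#'   (0/1 matrix, one column per genus), `genera`, `predictors`.
#' @export
build_labels <- function(frame, genera = NULL, predictors = NULL) {
  if (nrow(frame) == 0) stop("frame is empty")
  genera <- genera %||% attr(frame, "genera")
  predictors <- predictors %||% intersect(predictor_ids(), names(frame))
  features <- as.data.frame(frame[, predictors, drop = FALSE])
  if (anyNA(features)) stop("features contain missing values; impute first")
  labels <- vapply(genera, function(g) as.integer(frame[[g]] > 0),
                   integer(nrow(frame)))
  structure(list(features = features, labels = labels,
                 genera = genera, predictors = predictors),
            class = "labeled_table")
}

#' Shared 80/20 train/test split
#'
#' One uniform random partition of the rows, reused for every genus so test
#' folds are comparable across models.
#'
#' @param table A `labeled_table` (>= 5 rows).
#' @param seed Integer seed.
#' @param train_fraction Fraction of rows in the training fold.
#' @return List with `train` and `test` (each a `labeled_table`),
#'   `train_idx`, and `seed`.
#' @export
split_80_20 <- function(table, seed = 1, train_fraction = 0.8) {
  n <- nrow(table$features)
  if (n < 5) stop("need at least 5 rows to split")
  n_train <- floor(n * train_fraction)
  if (n_train == 0 || n_train == n) stop("split would leave an empty fold")
  train_idx <- withr::with_seed(seed, sort(sample.int(n, n_train)))
  subset_lt <- function(ix) {
    structure(list(features = table$features[ix, , drop = FALSE],
                   labels = table$labels[ix, , drop = FALSE],
                   genera = table$genera, predictors = table$predictors),
              class = "labeled_table")
  }
  list(train = subset_lt(train_idx),
       test = subset_lt(setdiff(seq_len(n), train_idx)),
       train_idx = train_idx, seed = seed)
}

#' Train a presence/absence random forest for one genus
#'
#' Classification forest with Gini-impurity splitting; variable importance
#' is mean decrease in Gini impurity (the total impurity reduction
#' attributable to splits on the feature, averaged over trees).
#'
#' @param features Training feature data frame.
#' @param labels 0/1 training labels (both classes must be present).
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @return List with `model` (randomForest), `importance` (named vector of
#'   mean decrease Gini), `n_trees`, `seed`.
#' @export
train_rf <- function(features, labels, n_trees = 500, seed = 1) {
  if (length(unique(labels)) < 2) stop("degenerate labels: both classes required")
  y <- factor(labels, levels = c(0, 1))
  model <- withr::with_seed(seed, {
    randomForest::randomForest(x = features, y = y, ntree = n_trees)
  })
  imp <- model$importance[, "MeanDecreaseGini"]
  list(model = model, importance = stats::setNames(as.numeric(imp), rownames(model$importance)),
       n_trees = n_trees, seed = seed)
}

#' Evaluate a forest on the held-out fold
#'
#' @param rf Result of [train_rf()].
#' @param features Test features.
#' @param labels 0/1 test labels.
#' @return List with `accuracy` (percent), `specificity` (percent;
#'   `NA` when the test fold has no actual negatives), and the `confusion`
#'   counts (TN, FP, FN, TP).
#' @export
evaluate_rf <- function(rf, features, labels) {
  if (nrow(features) == 0) stop("test fold is empty")
  # vote fractions + a fixed threshold: class prediction with randomized
  # tie-breaking would make evaluation depend on global RNG state
  votes <- predict(rf$model, features, type = "prob")[, "1"]
  pred <- factor(as.integer(votes > 0.5), levels = c(0, 1))
  obs <- factor(labels, levels = c(0, 1))
  tn <- sum(pred == "0" & obs == "0"); fp <- sum(pred == "1" & obs == "0")
  fn <- sum(pred == "0" & obs == "1"); tp <- sum(pred == "1" & obs == "1")
  total <- tn + fp + fn + tp
  specificity <- if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
  list(accuracy = 100 * (tn + tp) / total, specificity = specificity,
       confusion = c(TN = tn, FP = fp, FN = fn, TP = tp))
}

#' Select the most informative predictors by the largest Gini gap
#'
#' Predictors are sorted by decreasing importance and cut at the largest
#' difference between consecutive values, keeping everything above the gap.
#' If that cut keeps exactly one predictor, the rule is extended to the
#' second-largest gap. Ties in gap size break toward the earlier
#' (larger-importance) position; ties in importance break by canonical
#' predictor order. Degenerate fallback (two predictors, or all gaps tied,
#' so no usable second gap): keep the single top predictor.
#'
#' @param importance Named numeric vector of importances (>= 2 finite
#'   entries).
#' @param canonical_order Predictor order used to break importance ties
#'   (default [predictor_ids()], falling back to `names(importance)` order
#'   for names outside the canonical vocabulary).
#' @return Ordered character vector of selected predictor names (a prefix
#'   of the importance ordering).
#' @export
select_predictors <- function(importance, canonical_order = predictor_ids()) {
  importance <- importance[is.finite(importance)]
  if (length(importance) < 2) stop("need at least 2 predictors with finite importance")
  canon <- match(names(importance), canonical_order)
  canon[is.na(canon)] <- length(canonical_order) + seq_len(sum(is.na(canon)))
  ord <- order(-importance, canon)
  v <- as.numeric(importance[ord])
  gaps <- v[-length(v)] - v[-1]
  cut <- which.max(gaps)                      # ties -> earliest position
  if (cut == 1) {
    if (length(gaps) == 1 || max(gaps) == min(gaps)) {
      cut <- 1                                # documented fallback: top 1
    } else {
      cut <- order(-gaps, seq_along(gaps))[2] # extend to second-largest gap
    }
  }
  names(importance)[ord][seq_len(cut)]
}

#' Train, evaluate, and select predictors for every genus
#'
#' Shared split across genera; genera whose training fold lacks one of the
#' two classes are reported with `NA` metrics and an empty selection.
#'
#' @param table A `labeled_table`.
#' @param split_seed,rf_seed Seeds for the partition and the forests.
#' @param n_trees Trees per forest.
#' @param train_fraction Training fraction.
#' @return An `rf_results` list: `summary` tibble (genus, accuracy,
#'   specificity, n_selected), `importance` tibble (genus, predictor,
#'   importance), `selected` (named list), `models` (named list), `split`.
#' @export
rfm_all <- function(table, split_seed = 1, rf_seed = 2, n_trees = 500,
                    train_fraction = 0.8) {
  sp <- split_80_20(table, seed = split_seed, train_fraction = train_fraction)
  rows <- list(); imps <- list(); selected <- list(); models <- list()
  for (g in table$genera) {
    ytr <- sp$train$labels[, g]
    if (length(unique(ytr)) < 2) {
      rows[[g]] <- tibble::tibble(genus = g, accuracy = NA_real_,
                                  specificity = NA_real_, n_selected = 0L)
      selected[[g]] <- character(0)
      next
    }
    rf <- train_rf(sp$train$features, ytr, n_trees = n_trees, seed = rf_seed)
    ev <- evaluate_rf(rf, sp$test$features, sp$test$labels[, g])
    sel <- select_predictors(rf$importance)
    rows[[g]] <- tibble::tibble(genus = g, accuracy = ev$accuracy,
                                specificity = ev$specificity,
                                n_selected = length(sel))
    imps[[g]] <- tibble::tibble(genus = g, predictor = names(rf$importance),
                                importance = as.numeric(rf$importance))
    selected[[g]] <- sel
    models[[g]] <- rf
  }
  structure(list(summary = dplyr::bind_rows(rows),
                 importance = dplyr::bind_rows(imps),
                 selected = selected, models = models, split = sp),
            class = "rf_results")
}
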