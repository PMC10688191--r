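#' Fit a switch classifier on DoS feature vectors
#'
#' Trains one of three tree-based models to classify angles as switch
#' (bimodal DoS with no intermediate state, label 1) or nonswitch (label 0)
#' from their 14 engineered DoS features.
#'
#' @param features data.frame (or matrix) whose columns are exactly
#'   [dos_feature_names()], one row per angle.
#' @param labels Integer/numeric vector of 0/1 switch labels.
#' @param kind One of `"random_forest"`, `"gradient_boosted"`,
#'   `"decision_tree"`.
#' @param seed Integer seed; fits are deterministic for a fixed seed.
#' @param n_trees Trees for the forest / boosting rounds; ignored by the
#'   single decision tree.
#' @param max_depth Tree depth for the boosted learners (the forest grows
#'   unpruned trees; the single tree uses rpart's defaults).
#' @param ... Extra arguments passed to the backend fitting function.
#' @return Object of class `switch_model` with the fitted backend, the
#'   feature-name manifest and training metadata.
#' @seealso [predict.switch_model()], [cross_validate()]
#' @export
switch_fit <- function(features, labels,
                       kind = c("random_forest", "gradient_boosted",
                                "decision_tree"),
                       seed = 1L, n_trees = 100L, max_depth = 3L, ...) {
  kind <- match.arg(kind)
  features <- check_feature_frame(features)
  labels <- as.integer(labels)
  if (length(labels) != nrow(features))
    stop("labels and feature rows differ in length")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes (switch and nonswitch)")
  if (min(table(labels)) < 2L) stop("need at least 2 examples per class")
  set.seed(seed)
  fit <- switch(kind,
    random_forest = randomForest::randomForest(
      x = features, y = factor(labels, levels = c(0L, 1L)),
      ntree = n_trees, ...),
    gradient_boosted = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    nthread = 1L, seed = seed, ...),
      data = xgboost::xgb.DMatrix(as.matrix(features), label = labels),
      nrounds = n_trees),
    decision_tree = rpart::rpart(
      label ~ ., data = cbind(features, label = factor(labels)),
      method = "class", ...)
  )
  structure(list(kind = kind, fit = fit, manifest = dos_feature_names(),
                 meta = list(seed = seed, n_trees = n_trees,
                             max_depth = max_depth,
                             n_train = nrow(features),
                             class_counts = as.list(table(labels)))),
            class = "switch_model")
}

check_feature_frame <- function(features) {
  features <- as.data.frame(features)
  want <- dos_feature_names()
  missing <- setdiff(want, names(features))
  if (length(missing))
    stop("feature columns missing from input: ",
         paste(missing, collapse = ", "))
  features[want]
}

#' @export
print.switch_model <- function(x, ...) {
  cat("<switch_model> ", x$kind, ", trained on ", x$meta$n_train,
      " angles (", x$meta$class_counts[["0"]], " nonswitch / ",
      x$meta$class_counts[["1"]], " switch), seed ", x$meta$seed, "\n",
      sep = "")
  if (!is.null(x$meta$cv)) print(x$meta$cv)
  invisible(x)
}

#' @export
summary.switch_model <- function(object, ...) {
  print(object)
  imp <- switch(object$kind,
    random_forest = {
      i <- randomForest::importance(object$fit)
      sort(i[, 1L], decreasing = TRUE)
    },
    gradient_boosted = {
      i <- xgboost::xgb.importance(model = object$fit)
      stats::setNames(i$Gain, i$Feature)
    },
    decision_tree = sort(object$fit$variable.importance, decreasing = TRUE))
  cat("feature importance (top 5):\n")
  print(round(utils::head(imp, 5L), 4L))
  invisible(object)
}

#' Predict switch labels for new DoS feature vectors
#'
#' @param object A [switch_fit()] model.
#' @param newdata data.frame of 14-feature rows ([dos_feature_names()]).
#' @param ... Unused.
#' @return Integer vector of 0/1 labels, one per row.
#' @export
predict.switch_model <- function(object, newdata, ...) {
  newdata <- check_feature_frame(newdata)
  if (!identical(names(newdata), object$manifest))
    stop("feature columns do not match the model's manifest")
  switch(object$kind,
    random_forest =
      as.integer(as.character(predict(object$fit, newdata))),
    gradient_boosted =
      as.integer(predict(object$fit, as.matrix(newdata)) >= 0.5),
    decision_tree =
      as.integer(as.character(
        predict(object$fit, newdata, type = "class"))))
}

#' Stratified k-fold cross-validated accuracy of a switch classifier
#'
#' Rows are shuffled with a fixed seed and assigned to stratified folds
#' (each fold preserves the class balance); one model per fold is trained on
#' the remainder and scored on the held-out fold.
#'
#' @inheritParams switch_fit
#' @param n_folds Number of folds (default 5).
#' @return Object of class `cv_report`: per-fold accuracies, their mean and
#'   standard deviation.
#' @export
cross_validate <- function(features, labels,
                           kind = c("random_forest", "gradient_boosted",
                                    "decision_tree"),
                           n_folds = 5L, seed = 1L, ...) {
  kind <- match.arg(kind)
  features <- check_feature_frame(features)
  labels <- as.integer(labels)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  if (min(table(labels)) < n_folds)
    stop("every class needs at least n_folds = ", n_folds, " members")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  acc <- vapply(seq_len(n_folds), function(k) {
    hold <- fold == k
    m <- switch_fit(features[!hold, , drop = FALSE], labels[!hold],
                    kind = kind, seed = seed + k, ...)
    mean(predict(m, features[hold, , drop = FALSE]) == labels[hold])
  }, numeric(1))
  structure(list(kind = kind, n_folds = n_folds, seed = seed,
                 fold_accuracy = acc, mean_accuracy = mean(acc),
                 std_accuracy = stats::sd(acc)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV accuracy [%s]: %.2f (%.2f)\n", x$n_folds, x$kind,
              100 * x$mean_accuracy, 100 * x$std_accuracy))
  invisible(x)
}

#' Roll per-angle switch calls up to a residue-level flag
#'
#' A residue is a switch residue iff at least one of its angles is called a
#' switch.
#'
#' @param triplets data.frame with columns `atom_a`, `vertex`, `atom_b`
#'   (e.g. from [enumerate_triplets()]), one row per classified angle of one
#'   residue.
#' @param labels 0/1 switch call per row of `triplets`.
#' @return List: `is_switch` (logical), `switch_triplets` (subset of rows
#'   called switch), `n_switch`, `n_total`.
#' @export
residue_rollup <- function(triplets, labels) {
  labels <- as.integer(labels)
  if (nrow(triplets) != length(labels))
    stop("one label per triplet required")
  sel <- labels == 1L
  list(is_switch = any(sel),
       switch_triplets = triplets[sel, , drop = FALSE],
       n_switch = sum(sel), n_total = length(labels))
}

#' Save / load a fitted model
#'
#' Serialization round-trips exactly: a reloaded model yields identical
#' predictions.
#'
#' @param model A `switch_model` or `stability_model`.
#' @param path File path.
#' @return `save_model` invisibly returns `path`; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
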