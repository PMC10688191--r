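#' Assign per-frame angular states by two-cluster k-means
#'
#' One-dimensional k-means with k = 2, initialized at the 10th and 90th
#' percentiles of the series and iterated to convergence (Lloyd, up to 300
#' iterations) — deterministic, no random restarts.  States are relabeled so
#' state 0 is the lower-angle cluster.
#'
#' @param series An [angle_series()] or numeric vector of radians.
#' @return Object of class `state_trace`: `states` (0/1 per frame),
#'   `centers` (sorted cluster centers, radians), `segments` (inherited
#'   trajectory boundaries).
#' @export
assign_states <- function(series) {
  if (inherits(series, "angle_series")) {
    vals <- series$values; segments <- series$segments
  } else {
    vals <- as.numeric(series)
    segments <- cbind(start = 0L, end = length(vals))
  }
  if (length(unique(vals)) < 2L)
    stop("no two states resolvable: the angle series is constant")
  init <- stats::quantile(vals, c(0.1, 0.9), names = FALSE)
  if (init[1L] == init[2L]) init <- range(vals)
  km <- suppressWarnings(
    stats::kmeans(vals, centers = matrix(init, ncol = 1L),
                  iter.max = 300L, algorithm = "Lloyd"))
  ord <- order(km$centers[, 1L])
  states <- as.integer(ord[km$cluster] == 2L)  # 0 = lower-angle state
  structure(list(states = states,
                 centers = sort(as.numeric(km$centers[, 1L])),
                 segments = segments),
            class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  r <- instability_ratio(x)
  cat(sprintf(
    "<state_trace> %d frames, centers (%.3f, %.3f) rad, %d transition(s), instability ratio %.2f%%\n",
    length(x$states), x$centers[1L], x$centers[2L], r$transitions,
    r$ratio_percent))
  invisible(x)
}

#' Count inter-state transitions in a state trace
#'
#' A transition is a change of state between consecutive frames of the same
#' trajectory; segment seams (where independent trajectories were pooled)
#' never contribute.
#'
#' @param trace A [assign_states()] trace, or a 0/1 integer vector.
#' @param segments Optional 0-based half-open segment matrix when `trace` is
#'   a plain vector.
#' @return Integer transition count.
#' @export
count_transitions <- function(trace, segments = NULL) {
  if (inherits(trace, "state_trace")) {
    states <- trace$states; segments <- trace$segments
  } else {
    states <- as.integer(trace)
    if (is.null(segments)) segments <- cbind(0L, length(states))
  }
  total <- 0L
  for (i in seq_len(nrow(segments))) {
    s <- states[(segments[i, 1L] + 1L):segments[i, 2L]]
    if (length(s) > 1L) total <- total + sum(diff(s) != 0L)
  }
  total
}

#' Instability ratio of a state trace
#'
#' 100 x (inter-state transitions) / (total frames).  Stable switches (one
#' jump in a long run) sit well below 1%; unstable switches that oscillate
#' constantly sit above 6%.
#'
#' @inheritParams count_transitions
#' @return List of class `instability_record`: `transitions`, `n_frames`,
#'   `ratio_percent`.
#' @export
instability_ratio <- function(trace, segments = NULL) {
  tr <- count_transitions(trace, segments)
  n <- if (inherits(trace, "state_trace")) length(trace$states)
       else length(trace)
  structure(list(transitions = tr, n_frames = n,
                 ratio_percent = 100 * tr / n),
            class = "instability_record")
}

#' @export
print.instability_record <- function(x, ...) {
  cat(sprintf("instability ratio: %d transitions / %d frames = %.3f%%\n",
              x$transitions, x$n_frames, x$ratio_percent))
  invisible(x)
}

#' Fit the 1-D logistic stable/unstable switch classifier
#'
#' Logistic regression of the SS/US label on the scalar instability ratio.
#' The decision boundary is the ratio at which the predicted probability of
#' US is 0.5.  A positive slope (higher ratio, more likely unstable) is a
#' model invariant; a fit with non-positive slope indicates flipped labels
#' and is rejected.
#'
#' @param ratio_percent Numeric instability ratios (percent).
#' @param labels Class per observation: `"SS"`/`"US"`, or 0 (SS) / 1 (US).
#' @param n_folds Folds for the cross-validated accuracy report (set to 0 to
#'   skip CV).
#' @param seed Seed for fold shuffling.
#' @return Object of class `stability_model`: `intercept`, `slope`,
#'   `boundary` (ratio where p = 0.5), `cv` report.
#' @export
stability_fit <- function(ratio_percent, labels, n_folds = 5L, seed = 1L) {
  y <- normalize_stability_labels(labels)
  x <- as.numeric(ratio_percent)
  if (length(x) != length(y)) stop("ratios and labels differ in length")
  if (length(unique(y)) < 2L)
    stop("training data must contain both SS and US examples")
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial()))
  co <- stats::coef(fit)
  if (!is.finite(co[2L]) || co[2L] <= 0)
    stop("fitted slope is not positive: SS/US labels appear flipped ",
         "(higher instability ratio must mean unstable)")
  cv <- NULL
  if (n_folds >= 2L) {
    if (min(table(y)) < n_folds)
      stop("every class needs at least n_folds = ", n_folds, " members")
    set.seed(seed)
    fold <- integer(length(y))
    for (cl in 0:1) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    acc <- vapply(seq_len(n_folds), function(k) {
      hold <- fold == k
      f <- suppressWarnings(
        stats::glm(y[!hold] ~ x[!hold], family = stats::binomial()))
      p <- stats::plogis(stats::coef(f)[1L] + stats::coef(f)[2L] * x[hold])
      mean((p >= 0.5) == (y[hold] == 1L))
    }, numeric(1))
    cv <- structure(list(kind = "logistic", n_folds = n_folds, seed = seed,
                         fold_accuracy = acc, mean_accuracy = mean(acc),
                         std_accuracy = stats::sd(acc)),
                    class = "cv_report")
  }
  structure(list(intercept = unname(co[1L]), slope = unname(co[2L]),
                 boundary = unname(-co[1L] / co[2L]), cv = cv,
                 meta = list(n_train = length(y), seed = seed)),
            class = "stability_model")
}

normalize_stability_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- toupper(as.character(labels))
    if (!all(labels %in% c("SS", "US")))
      stop("stability labels must be 'SS' or 'US'")
    as.integer(labels == "US")
  } else {
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L)))
      stop("numeric stability labels must be 0 (SS) or 1 (US)")
    labels
  }
}

#' @export
print.stability_model <- function(x, ...) {
  cat(sprintf(
    "<stability_model> logit(p_US) = %.3f + %.3f * ratio%%; boundary %.3f%%\n",
    x$intercept, x$slope, x$boundary))
  if (!is.null(x$cv)) print(x$cv)
  invisible(x)
}

#' Classify instability ratios as stable or unstable switch
#'
#' US iff predicted probability of instability is at least 0.5 (a ratio
#' exactly on the boundary is graded US).
#'
#' @param object A [stability_fit()] model.
#' @param newdata Numeric instability ratios (percent), or an
#'   `instability_record`.
#' @param ... Unused.
#' @return Character vector of `"SS"` / `"US"`.
#' @export
predict.stability_model <- function(object, newdata, ...) {
  if (inherits(newdata, "instability_record"))
    newdata <- newdata$ratio_percent
  # with slope > 0, p >= 0.5 is exactly ratio >= boundary
  ifelse(as.numeric(newdata) >= object$boundary, "US", "SS")
}
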