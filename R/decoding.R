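#' Cross-validated multiclass classification of reach endpoint
#'
#' Stratified k-fold cross-validation of a support-vector classifier
#' (RBF kernel, one-vs-one multiclass voting, cost 1). The kernel
#' bandwidth uses the variance-scaled heuristic
#' `gamma = 1 / (p * var(X))` with `var(X)` the pooled variance of all
#' feature entries. Every trial receives exactly one out-of-fold
#' prediction.
#'
#' @param features numeric matrix, trials x features (e.g.
#'   `rate_matrix()` of a centered table, or [ablate_to_plane()]).
#' @param labels class labels, one per trial (condition ids); every
#'   class needs at least `folds` trials.
#' @param folds number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return object of class `decode_result`: `predictions` (data.frame:
#'   `index`, `true`, `predicted`, `fold`), `confusion` (true x
#'   predicted counts), `fold_accuracy`, `accuracy` (mean over folds),
#'   `sem` (SEM over folds), `n_classes`.
#' @export
crossval_classify <- function(features, labels, folds = 10, seed = 1) {
  features <- as.matrix(features)
  labels <- factor(labels)
  stopifnot(nrow(features) == length(labels), folds >= 2)
  fold <- stratified_folds(labels, folds, seed)
  gv <- stats::var(as.vector(features))
  gamma <- if (gv > 0) 1 / (ncol(features) * gv) else 1 / ncol(features)
  pred <- factor(rep(levels(labels)[1], length(labels)),
                 levels = levels(labels))
  for (f in seq_len(folds)) {
    te <- fold == f
    fit <- e1071::svm(x = features[!te, , drop = FALSE], y = labels[!te],
                      kernel = "radial", gamma = gamma, cost = 1,
                      scale = FALSE)
    pred[te] <- stats::predict(fit, features[te, , drop = FALSE])
  }
  acc <- vapply(seq_len(folds),
                function(f) mean(pred[fold == f] == labels[fold == f]),
                numeric(1))
  structure(list(
    predictions = data.frame(index = seq_along(labels), true = labels,
                             predicted = pred, fold = fold),
    confusion = table(true = labels, predicted = pred),
    fold_accuracy = acc, accuracy = mean(acc),
    sem = stats::sd(acc) / sqrt(folds), n_classes = nlevels(labels)),
    class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf(
    "<decode_result: %d classes, %d trials, accuracy %.1f%% +/- %.1f%% (SEM over %d folds)>\n",
    x$n_classes, nrow(x$predictions), 100 * x$accuracy, 100 * x$sem,
    length(x$fold_accuracy)))
  invisible(x)
}

#' Geometry of classification errors
#'
#' Turns a classifier's condition-level confusions into task-space error
#' metrics:
#' * `"angle"` — minimal absolute circular difference between the true
#'   and predicted target angles, radians in `[0, pi]`; requires all true
#'   targets on one ring.
#' * `"arc"` — angle error times the true target's ring radius (cm),
#'   making direction errors directly comparable with distance errors.
#'   The restricted mean keeps only errors within the half-circumference
#'   of the layout's smallest ring (`pi * r_min`), the range of errors
#'   every ring can express.
#' * `"distance"` — absolute difference between true and predicted
#'   target distance (cm); requires a line layout (one direction at a
#'   time).
#'
#' @param result a [crossval_classify()] result whose labels are
#'   condition ids of `layout`.
#' @param layout the [make_target_layout()] the conditions come from.
#' @param metric `"angle"`, `"arc"` or `"distance"`.
#' @return object of class `error_distribution`: `metric`, `errors`
#'   (per trial), `mean`, and for `"arc"` also `restricted_mean` and
#'   `restricted_max`.
#' @export
decode_errors <- function(result, layout, metric = c("angle", "arc", "distance")) {
  metric <- match.arg(metric)
  stopifnot(inherits(result, "decode_result"),
            inherits(layout, "target_layout"))
  tg <- layout$targets
  lookup <- function(f) {
    id <- as.integer(as.character(f))
    i <- match(id, tg$condition_id)
    if (anyNA(i)) stop("labels contain condition ids absent from the layout")
    tg[i, , drop = FALSE]
  }
  true <- lookup(result$predictions$true)
  pred <- lookup(result$predictions$predicted)
  d_true <- target_distance(true$x, true$y)
  d_pred <- target_distance(pred$x, pred$y)
  if (metric %in% c("angle", "arc")) {
    if (diff(range(d_true)) > 1e-9)
      stop("metric '", metric,
           "' requires all true targets on a single ring")
    dth <- atan2(pred$y, pred$x) - atan2(true$y, true$x)
    ang <- abs(atan2(sin(dth), cos(dth)))   # minimal circular difference
    if (metric == "angle") {
      errors <- ang
      out <- list(metric = metric, errors = errors, mean = mean(errors))
    } else {
      errors <- ang * d_true
      rmax <- pi * min(layout$ring_radii)
      out <- list(metric = metric, errors = errors, mean = mean(errors),
                  restricted_mean = mean(errors[errors <= rmax]),
                  restricted_max = rmax)
    }
  } else {
    if (!layout$name %in% c("horizontal", "vertical"))
      stop("metric 'distance' requires a line layout")
    errors <- abs(d_true - d_pred)
    out <- list(metric = metric, errors = errors, mean = mean(errors))
  }
  structure(out, class = "error_distribution")
}

#' @export
print.error_distribution <- function(x, ...) {
  unit <- if (x$metric == "angle") "rad" else "cm"
  cat(sprintf("<error_distribution (%s): n = %d, mean %.3f %s", x$metric,
              length(x$errors), x$mean, unit))
  if (!is.null(x$restricted_mean))
    cat(sprintf(", restricted mean %.3f cm (<= %.2f cm)",
                x$restricted_mean, x$restricted_max))
  cat(">\n")
  invisible(x)
}

#' Restrict features to the spatial plane
#'
#' Projects each trial onto the fitted x/y axes only, discarding the
#' speed axis and every residual dimension — the ablation used to test
#' how much speed information contributes to distance decoding.
#'
#' @param table a [trial_table()].
#' @param model a [delay_subspace()] fit.
#' @return trials x 2 matrix (`x_neural`, `y_neural`).
#' @export
ablate_to_plane <- function(table, model) {
  st <- project_states(table, model)
  cbind(x_neural = st$x_neural, y_neural = st$y_neural)
}

#' Two-sample variance-ratio F test
#'
#' F statistic with the larger sample variance in the numerator and a
#' two-sided p-value — used to compare classification-error
#' distributions across rings.
#'
#' @param a,b numeric samples, each `n >= 2`.
#' @return list with `statistic`, `df`, `p_value`,
#'   `variances` (named, in input order).
#' @export
variance_ratio_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a); vb <- stats::var(b)
  if (min(va, vb) == 0) stop("zero variance in the denominator sample")
  if (va >= vb) {
    f <- va / vb; df <- c(length(a) - 1, length(b) - 1)
  } else {
    f <- vb / va; df <- c(length(b) - 1, length(a) - 1)
  }
  p <- min(1, 2 * stats::pf(f, df[1], df[2], lower.tail = FALSE))
  list(statistic = f, df = df, p_value = p, variances = c(a = va, b = vb))
}

#' Direction-classification accuracy per ring
#'
#' Runs [crossval_classify()] independently on each ring of a
#' three-ring table and reports per-ring accuracy and error geometry.
#'
#' @param table a rings3 [trial_table()].
#' @param layout the matching [make_target_layout()] (`"rings3"`).
#' @param features optional trials x p feature matrix (defaults to the
#'   raw channel rates).
#' @param folds,seed passed to [crossval_classify()].
#' @return list of class `per_ring_accuracy`: `summary` (data.frame:
#'   radius, accuracy, sem, mean_angle_error, mean_arc_error) and
#'   `results`/`angle_errors`/`arc_errors` per ring.
#' @export
per_distance_direction_accuracy <- function(table, layout, features = NULL,
                                            folds = 10, seed = 1) {
  stopifnot(inherits(layout, "target_layout"))
  if (layout$name != "rings3") stop("requires the rings3 layout")
  validate_trial_table(table)
  X <- features %||% rate_matrix(table)
  d <- round_distance(target_distance(table$target_x, table$target_y))
  radii <- sort(unique(round_distance(layout$ring_radii)))
  results <- list(); angle_err <- list(); arc_err <- list()
  for (r in radii) {
    i <- d == r
    res <- crossval_classify(X[i, , drop = FALSE], table$condition_id[i],
                             folds = folds, seed = seed)
    key <- sprintf("r%g", r)
    results[[key]] <- res
    angle_err[[key]] <- decode_errors(res, layout, "angle")
    arc_err[[key]] <- decode_errors(res, layout, "arc")
  }
  summary <- data.frame(
    radius = radii,
    accuracy = vapply(results, `[[`, numeric(1), "accuracy"),
    sem = vapply(results, `[[`, numeric(1), "sem"),
    mean_angle_error = vapply(angle_err, `[[`, numeric(1), "mean"),
    mean_arc_error = vapply(arc_err, `[[`, numeric(1), "mean"))
  rownames(summary) <- NULL
  structure(list(summary = summary, results = results,
                 angle_errors = angle_err, arc_errors = arc_err),
            class = "per_ring_accuracy")
}

#' @export
print.per_ring_accuracy <- function(x, ...) {
  cat("Direction classification per ring:\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Distance classification on a line layout
#'
#' Classifies target distance (12 classes) separately for each side of
#' the line — so direction never informs the classifier — and aggregates
#' the out-of-fold predictions and |true - predicted| distance errors
#' across sides.
#'
#' @param table a horizontal or vertical [trial_table()].
#' @param layout the matching line [make_target_layout()].
#' @inheritParams per_distance_direction_accuracy
#' @return list of class `distance_classification`: `accuracy` (trialwise,
#'   aggregated), `mean_error` (cm), `errors` with their `fold`
#'   assignment, `fold_mean_error`, per-side [crossval_classify()]
#'   results.
#' @export
distance_classification <- function(table, layout, features = NULL,
                                    folds = 10, seed = 1) {
  stopifnot(inherits(layout, "target_layout"))
  if (!layout$name %in% c("horizontal", "vertical"))
    stop("requires a line layout (horizontal or vertical)")
  validate_trial_table(table)
  X <- features %||% rate_matrix(table)
  coordinate <- if (layout$name == "horizontal") table$target_x else table$target_y
  errors <- numeric(0); fold <- integer(0); correct <- logical(0)
  per_side <- list()
  for (s in c(-1, 1)) {
    i <- sign(coordinate) == s
    res <- crossval_classify(X[i, , drop = FALSE], table$condition_id[i],
                             folds = folds, seed = seed)
    err <- decode_errors(res, layout, "distance")
    errors <- c(errors, err$errors)
    fold <- c(fold, res$predictions$fold)
    correct <- c(correct,
                 res$predictions$true == res$predictions$predicted)
    per_side[[if (s < 0) "neg" else "pos"]] <- res
  }
  fold_mean_error <- tapply(errors, fold, mean)
  structure(list(accuracy = mean(correct), mean_error = mean(errors),
                 errors = errors, fold = fold,
                 fold_mean_error = as.numeric(fold_mean_error),
                 per_side = per_side),
            class = "distance_classification")
}

#' @export
print.distance_classification <- function(x, ...) {
  cat(sprintf(
    "<distance_classification: accuracy %.1f%%, mean |distance error| %.2f cm, n = %d>\n",
    100 * x$accuracy, x$mean_error, length(x$errors)))
  invisible(x)
}
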