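#' Condition-averaged firing rates
#'
#' Averages the rate vector over all trials of each condition (a unique
#' target within a task), pooling sessions. Conditions are keyed by
#' `(task, condition_id)` so tables combining tasks keep every target.
#'
#' @param table a [trial_table()].
#' @return list with `matrix` (channels x conditions, spikes/s) and
#'   `index` (data.frame: `task`, `condition_id`, `target_x`, `target_y`,
#'   `n_trials`, one row per column).
#' @export
condition_average <- function(table) {
  validate_trial_table(table)
  key <- interaction(table$task, table$condition_id, drop = TRUE, lex.order = TRUE)
  R <- rate_matrix(table)
  g <- split(seq_len(nrow(R)), key)
  M <- vapply(g, function(i) colMeans(R[i, , drop = FALSE]), numeric(ncol(R)))
  first <- vapply(g, `[`, integer(1), 1)
  index <- data.frame(task = table$task[first],
                      condition_id = table$condition_id[first],
                      target_x = table$target_x[first],
                      target_y = table$target_y[first],
                      n_trials = lengths(g),
                      stringsAsFactors = FALSE)
  list(matrix = M, index = index)
}

#' Principal components of the condition-averaged activity
#'
#' Mean-centers the condition-mean matrix across conditions and computes
#' its principal axes; the number of retained components `d` is the
#' smallest count whose cumulative explained-variance fraction reaches
#' `var_threshold`.
#'
#' @param cond_matrix channels x conditions matrix (e.g.
#'   `condition_average(table)$matrix`).
#' @param var_threshold fraction of variance to retain, in (0, 1].
#' @return list with `rotation` (channels x d, orthonormal columns; the
#'   transform A is its transpose), `ev_fraction` (all components,
#'   non-increasing), `d`, and `center` (per-channel mean over
#'   conditions).
#' @export
fit_pca <- function(cond_matrix, var_threshold = 0.95) {
  stopifnot(is.matrix(cond_matrix), ncol(cond_matrix) >= 2,
            var_threshold > 0, var_threshold <= 1)
  center <- rowMeans(cond_matrix)
  Xc <- cond_matrix - center
  s <- svd(t(Xc))       # conditions as observations
  tot <- sum(s$d^2)
  if (tot == 0) stop("degenerate input: condition means have zero variance")
  ev <- s$d^2 / tot
  d <- which(cumsum(ev) >= var_threshold - 1e-12)[1]
  list(rotation = s$v[, seq_len(d), drop = FALSE], ev_fraction = ev,
       d = d, center = center)
}

#' Fit the initial-condition subspace of delay activity
#'
#' The central model fit. Starting from the delay-activity trial table,
#' it (1) condition-averages and runs PCA ([fit_pca()]), retaining the
#' top `d` components; (2) finds the "spatial plane" by least-squares
#' regression of single-trial PC scores onto the target's x and then y
#' coordinate; and (3) finds the speed axis by regressing the
#' full-dimensional (channel-space) rates onto each trial's maximum reach
#' speed. Fits are sequential (x, then y, then speed by default) and the
#' data are projected into the null-space of each fitted axis before the
#' next fit, so the three channel-space axis vectors are exactly pairwise
#' orthogonal. Trials are centered with the condition-average centering
#' vector, so a trial at the grand mean projects to the origin.
#'
#' The resulting coordinates are in the regressands' units: `x_neural`,
#' `y_neural` in cm, `speed_neural` in cm/s (relative to the mean
#' maximum speed).
#'
#' @param table a [trial_table()], typically session-baseline-corrected.
#' @param var_threshold PCA variance threshold (default 0.95).
#' @param channel_mask optional logical vector (length = channel count),
#'   e.g. `screen_channels(table)$kept`; masked-out channels are ignored
#'   by the fit and their axis loadings set to zero.
#' @param order orthogonalization order, a permutation of
#'   `c("x", "y", "speed")` (exposed for sensitivity analysis).
#' @return an object of class `delay_subspace`: list with `axes`
#'   (channels x 3 matrix, columns `x`, `y`, `speed`, pairwise
#'   orthogonal), `center`, `rotation`, `ev_fraction`, `d`,
#'   `cond_matrix`, `cond_index`, `speed_center`, `var_threshold`,
#'   `order`, `n_channels`, `channel_mask`.
#' @seealso [project_states()] / [predict.delay_subspace()],
#'   [explained_variance_in_plane()], [within_distance_speed_test()]
#' @examples
#' tt <- simulate_trials(make_target_layout("rings3", "J"),
#'                       n_per_condition = 10, seed = 1)
#' fit <- delay_subspace(tt)
#' fit
#' head(predict(fit))
#' @export
delay_subspace <- function(table, var_threshold = 0.95, channel_mask = NULL,
                           order = c("x", "y", "speed")) {
  validate_trial_table(table)
  if (!setequal(order, c("x", "y", "speed")) || length(order) != 3)
    stop("'order' must be a permutation of c('x', 'y', 'speed')")
  nch <- n_channels(table)
  mask <- channel_mask %||% rep(TRUE, nch)
  if (length(mask) != nch) stop("channel_mask length must equal channel count")
  if (sum(mask) < 3) stop("need at least 3 unmasked channels")

  ca <- condition_average(table)
  pca <- fit_pca(ca$matrix[mask, , drop = FALSE], var_threshold)
  R <- rate_matrix(table)[, mask, drop = FALSE]
  Xc <- sweep(R, 2, pca$center)                 # trials x channels, centered
  Z <- Xc %*% pca$rotation                      # trial PC scores
  sp <- table$max_speed
  if (anyNA(sp)) stop("max_speed required for every trial")
  speed_center <- mean(sp)

  regressand <- list(x = table$target_x, y = table$target_y,
                     speed = sp - speed_center)
  for (nm in c("x", "y")) {
    if (stats::var(regressand[[nm]]) == 0)
      stop("degenerate regression: all targets share the same ", nm,
           " coordinate")
  }
  if (stats::var(sp) == 0) stop("degenerate regression: max_speed is constant")

  axes <- matrix(0, sum(mask), 3,
                 dimnames = list(NULL, c("x", "y", "speed")))
  Zp <- Z; Xp <- Xc
  for (nm in order) {
    if (nm == "speed") {
      v <- drop(pinv_lstsq(Xp, regressand$speed))
    } else {
      b <- drop(pinv_lstsq(Zp, regressand[[nm]]))
      v <- drop(pca$rotation %*% b)
    }
    axes[, nm] <- v
    if (sum(v^2) == 0) next   # regressand unpredictable from what remains
    u <- unit_vec(v)
    # project remaining data into the null-space of the fitted axis
    Xp <- Xp - (Xp %*% u) %*% t(u)
    bu <- drop(crossprod(pca$rotation, u))
    if (sum(bu^2) > 0) {
      bu_n <- bu / sqrt(sum(bu^2))
      # remove the axis' footprint from the PC scores likewise
      Zp <- Zp - (Zp %*% bu_n) %*% t(bu_n)
    }
  }

  full_axes <- matrix(0, nch, 3, dimnames = list(NULL, c("x", "y", "speed")))
  full_axes[mask, ] <- axes
  full_center <- rep(0, nch); full_center[mask] <- pca$center

  structure(list(axes = full_axes, center = full_center,
                 rotation = pca$rotation, ev_fraction = pca$ev_fraction,
                 d = pca$d, cond_matrix = ca$matrix, cond_index = ca$index,
                 speed_center = speed_center, var_threshold = var_threshold,
                 order = order, n_channels = nch, channel_mask = mask,
                 call = match.call()),
            class = "delay_subspace")
}

#' Project trials into the fitted subspace
#'
#' Each trial's centered rate vector is projected onto the three fitted
#' axis vectors, giving its neural state `(x_neural, y_neural,
#' speed_neural)`.
#'
#' @param table a [trial_table()] with the model's channel count.
#' @param model a [delay_subspace()] fit.
#' @return a data.frame of class `neural_states`: `trial_id`,
#'   `x_neural`, `y_neural`, `speed_neural`, `condition_id`, `task`,
#'   `target_x`, `target_y` (plus `max_speed`, `max_speed_x/y` carried
#'   through for kinematic analyses).
#' @export
project_states <- function(table, model) {
  stopifnot(inherits(model, "delay_subspace"))
  validate_trial_table(table)
  if (n_channels(table) != model$n_channels)
    stop("channel count mismatch: table has ", n_channels(table),
         ", model expects ", model$n_channels)
  S <- sweep(rate_matrix(table), 2, model$center) %*% model$axes
  out <- data.frame(trial_id = table$trial_id,
                    x_neural = S[, "x"], y_neural = S[, "y"],
                    speed_neural = S[, "speed"],
                    condition_id = table$condition_id, task = table$task,
                    target_x = table$target_x, target_y = table$target_y,
                    max_speed = table$max_speed,
                    max_speed_x = table$max_speed_x,
                    max_speed_y = table$max_speed_y,
                    stringsAsFactors = FALSE)
  class(out) <- c("neural_states", "data.frame")
  out
}

#' @rdname project_states
#' @param object a `delay_subspace` fit.
#' @param newdata a [trial_table()] to project; when omitted, the stored
#'   condition averages are projected instead.
#' @param ... unused.
#' @export
predict.delay_subspace <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    # project the stored condition averages
    S <- t(object$cond_matrix - object$center) %*% object$axes
    out <- cbind(object$cond_index,
                 data.frame(x_neural = S[, "x"], y_neural = S[, "y"],
                            speed_neural = S[, "speed"]))
    rownames(out) <- NULL
    return(out)
  }
  project_states(newdata, object)
}

#' @export
coef.delay_subspace <- function(object, ...) object$axes

#' @export
print.delay_subspace <- function(x, ...) {
  cat("Delay-activity initial-condition subspace\n")
  cat(sprintf("  %d channels (%d unmasked), %d conditions\n",
              x$n_channels, sum(x$channel_mask), ncol(x$cond_matrix)))
  cat(sprintf("  %d PCs retain %.1f%% of condition-averaged variance (threshold %g)\n",
              x$d, 100 * sum(x$ev_fraction[seq_len(x$d)]), x$var_threshold))
  cat(sprintf("  axes orthogonalized in order %s\n",
              paste(x$order, collapse = " -> ")))
  invisible(x)
}

#' @export
summary.delay_subspace <- function(object, ...) {
  evp <- vapply(unique(object$cond_index$task), function(tk)
    explained_variance_in_plane(object, task = tk), numeric(1))
  structure(list(model = object, plane_variance = evp), class = "summary.delay_subspace")
}

#' @export
print.summary.delay_subspace <- function(x, ...) {
  print(x$model)
  cat("  cumulative PC variance:",
      paste0(sprintf("%.0f%%", 100 * cumsum(x$model$ev_fraction[seq_len(min(6, length(x$model$ev_fraction)))])),
             collapse = " "), "\n")
  cat("  spatial-plane explained variance of condition means, per task:\n")
  for (tk in names(x$plane_variance))
    cat(sprintf("    %-10s %.1f%%\n", tk, 100 * x$plane_variance[[tk]]))
  invisible(x)
}

#' @export
plot.delay_subspace <- function(x, ...) {
  st <- predict(x)
  graphics::plot(st$x_neural, st$y_neural, asp = 1,
                 xlab = expression(x[neural] ~ "(cm)"),
                 ylab = expression(y[neural] ~ "(cm)"),
                 main = "Condition-average neural states, spatial plane",
                 pch = 19, col = grDevices::hcl.colors(nrow(st), "Zissou 1"),
                 ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  invisible(x)
}

#' Variance of condition means captured by the spatial plane
#'
#' Fraction of the (centered) condition-averaged variance that lies in
#' the plane spanned by the x and y axis vectors, computed per task.
#'
#' @param model a [delay_subspace()] fit.
#' @param task task name; `NULL` pools all conditions in the model.
#' @param cond optional replacement condition-average list
#'   (as from [condition_average()]).
#' @return a fraction in `[0, 1]`.
#' @export
explained_variance_in_plane <- function(model, task = NULL, cond = NULL) {
  stopifnot(inherits(model, "delay_subspace"))
  M <- if (is.null(cond)) model$cond_matrix else cond$matrix
  index <- if (is.null(cond)) model$cond_index else cond$index
  if (!is.null(task)) {
    sel <- index$task == task
    if (!any(sel)) stop("no conditions for task '", task, "' in the model")
    M <- M[, sel, drop = FALSE]
  }
  Xc <- M - rowMeans(M)
  tot <- sum(Xc^2)
  if (tot == 0) return(0)
  B <- cbind(unit_vec(model$axes[, "x"]), unit_vec(model$axes[, "y"]))
  sum((t(Xc) %*% B)^2) / tot
}
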