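#' Does the speed axis carry speed information within each distance?
#'
#' For every unique target distance, regresses the trials' speed-axis
#' coordinate on their actual maximum reach speed and reports the slope
#' and its p-value; distances whose slope is significant demonstrate
#' speed encoding that cannot be explained by the speed-distance
#' correlation. By default the speed-axis coordinates are cross-fitted
#' (the axis used to project one half of the trials is fitted on the
#' other half), so the per-distance tests are calibrated: an in-sample
#' speed axis regressed on many channels partially fits noise, which
#' would inflate the slopes even when no speed encoding exists.
#'
#' @param table a [trial_table()].
#' @param model a [delay_subspace()] fit on `table`.
#' @param alpha per-distance significance level (default 0.05).
#' @param cross_fit logical; use out-of-fold speed projections (default
#'   `TRUE`). With `FALSE`, uses `project_states()$speed_neural` as is.
#' @return data.frame of class `speed_distance_test` with one row per
#'   usable distance (`distance`, `slope`, `p_value`, `n`,
#'   `significant`), attributes `alpha`, `n_significant`, `excluded`
#'   (distances dropped for constant speed).
#' @export
within_distance_speed_test <- function(table, model, alpha = 0.05,
                                       cross_fit = TRUE) {
  stopifnot(inherits(model, "delay_subspace"))
  validate_trial_table(table)
  d <- round_distance(target_distance(table$target_x, table$target_y))
  sn <- if (cross_fit) crossfit_speed_neural(table, model) else
    project_states(table, model)$speed_neural
  sp <- table$max_speed
  dists <- sort(unique(d))
  rows <- lapply(dists, function(dd) {
    i <- d == dd
    if (length(unique(sp[i])) < 2) return(NULL)
    fit <- summary(stats::lm(sn[i] ~ sp[i]))$coefficients
    data.frame(distance = dd, slope = fit[2, 1], p_value = fit[2, 4],
               n = sum(i))
  })
  excluded <- dists[vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no distance has >= 2 distinct max_speed values")
  out$significant <- out$p_value < alpha
  structure(out, alpha = alpha, n_significant = sum(out$significant),
            excluded = excluded,
            class = c("speed_distance_test", "data.frame"))
}

#' @export
print.speed_distance_test <- function(x, ...) {
  cat(sprintf(
    "Speed-axis encoding within distance: significant at %d / %d distances (p < %g)\n",
    attr(x, "n_significant"), nrow(x), attr(x, "alpha")))
  print.data.frame(x, digits = 3)
  invisible(x)
}

# Out-of-fold speed-axis projections: the plane axes come from the model,
# but the speed axis used for each half of the trials is re-fitted (in
# the plane's null-space) on the other half.
#' @keywords internal
#' @noRd
crossfit_speed_neural <- function(table, model) {
  mask <- model$channel_mask
  Xc <- sweep(rate_matrix(table)[, mask, drop = FALSE], 2,
              model$center[mask])
  for (nm in c("x", "y")) {
    u <- unit_vec(model$axes[mask, nm])
    Xc <- Xc - (Xc %*% u) %*% t(u)
  }
  sp <- table$max_speed
  h <- alternating_halves(nrow(Xc))
  sn <- numeric(nrow(Xc))
  for (fold in list(c(train = "a", test = "b"), c(train = "b", test = "a"))) {
    tr <- h[[fold[["train"]]]]; te <- h[[fold[["test"]]]]
    v <- pinv_lstsq(Xc[tr, , drop = FALSE], sp[tr] - mean(sp[tr]))
    sn[te] <- drop(Xc[te, , drop = FALSE] %*% v)
  }
  sn
}

#' Distance information beyond speed
#'
#' Regresses each channel's rate on the trial's maximum speed, fits a
#' distance-readout axis to the residuals, and correlates the residual
#' projection with target distance. A positive, significant correlation
#' means the population carries distance information that speed cannot
#' account for. The residual distance axis is cross-fitted (fitted on
#' one half of the trials, evaluated on the other) so that the reported
#' correlation is an out-of-sample quantity and is null-calibrated.
#'
#' @param table a [trial_table()].
#' @param model optional [delay_subspace()] fit; only its channel mask is
#'   used.
#' @return list with `estimate` (Pearson r), `p_value`, `n`.
#' @export
residual_distance_correlation <- function(table, model = NULL) {
  validate_trial_table(table)
  mask <- if (is.null(model)) rep(TRUE, n_channels(table)) else
    model$channel_mask
  R <- rate_matrix(table)[, mask, drop = FALSE]
  d <- target_distance(table$target_x, table$target_y)
  X <- cbind(1, table$max_speed)
  E_all <- R - qr.fitted(qr(X), R)
  tot <- sum(sweep(R, 2, colMeans(R))^2)
  if (sum(E_all^2) <= 1e-10 * max(tot, 1))
    stop("degenerate: residual variance is zero after regressing out speed")
  # Residualization and the distance axis are both estimated on the
  # training fold only: residualizing on the pooled table would make the
  # pooled readout exactly orthogonal to speed, which transmits a
  # spurious anti-correlation with distance into the held-out fold.
  h <- alternating_halves(nrow(R))
  proj <- numeric(nrow(R))
  for (fold in list(c(train = "a", test = "b"), c(train = "b", test = "a"))) {
    tr <- h[[fold[["train"]]]]; te <- h[[fold[["test"]]]]
    qr_tr <- qr(X[tr, , drop = FALSE])
    B <- qr.coef(qr_tr, R[tr, , drop = FALSE])
    E_tr <- R[tr, , drop = FALSE] - X[tr, , drop = FALSE] %*% B
    E_te <- R[te, , drop = FALSE] - X[te, , drop = FALSE] %*% B
    mu <- colMeans(E_tr)
    v <- pinv_lstsq(sweep(E_tr, 2, mu), d[tr] - mean(d[tr]))
    proj[te] <- drop(sweep(E_te, 2, mu) %*% v)
  }
  ct <- stats::cor.test(proj, d)
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(d))
}

#' Time-course of convergence to the delay state
#'
#' Projects a rate time-series into the model's spatial plane and, per
#' timestep, measures the mean Euclidean distance between each trial's
#' instantaneous in-plane state and that trial's converged delay state
#' (its mean in-plane state over the delay window before the go cue).
#' The first time the mean distance falls below `threshold` times its
#' initial (first-sample) value is found by linear interpolation between
#' samples.
#'
#' @param series a [simulate_timecourse()] result.
#' @param model a [delay_subspace()] fit with the series' channel count.
#' @param threshold fraction in (0, 1) of the initial distance.
#' @param converged_window ms relative to go cue defining the converged
#'   state (default the 200 ms before it).
#' @return list with `time_ms`, `mean_distance` (cm), `crossing_ms`,
#'   `initial`, `threshold`.
#' @export
state_convergence_profile <- function(series, model, threshold = 0.1,
                                      converged_window = c(-200, 0)) {
  stopifnot(inherits(series, "rate_timeseries"),
            inherits(model, "delay_subspace"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be strictly inside (0, 1)")
  A <- model$axes[, c("x", "y")]
  ntr <- dim(series$rates)[1]; nt <- dim(series$rates)[3]
  SX <- matrix(0, ntr, nt); SY <- matrix(0, ntr, nt)
  for (j in seq_len(nt)) {
    Rj <- matrix(series$rates[, , j], nrow = ntr)
    S <- sweep(Rj, 2, model$center) %*% A
    SX[, j] <- S[, 1]; SY[, j] <- S[, 2]
  }
  rel <- series$time_ms - series$go_cue_ms
  win <- rel > converged_window[1] & rel <= converged_window[2]
  if (!any(win)) stop("converged window contains no samples")
  cx <- rowMeans(SX[, win, drop = FALSE])
  cy <- rowMeans(SY[, win, drop = FALSE])
  dist_t <- colMeans(sqrt((SX - cx)^2 + (SY - cy)^2))
  initial <- dist_t[1]
  if (initial == 0)   # already converged at the first sample
    return(list(time_ms = series$time_ms, mean_distance = dist_t,
                crossing_ms = series$time_ms[1], initial = 0,
                threshold = threshold))
  target <- threshold * initial
  below <- which(dist_t < target)
  crossing <- NA_real_
  if (length(below) > 0) {
    i <- below[1]
    crossing <- if (i == 1) series$time_ms[1] else {
      t0 <- series$time_ms[i - 1]; t1 <- series$time_ms[i]
      t0 + (t1 - t0) * (dist_t[i - 1] - target) / (dist_t[i - 1] - dist_t[i])
    }
  }
  list(time_ms = series$time_ms, mean_distance = dist_t,
       crossing_ms = crossing, initial = initial, threshold = threshold)
}
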