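#' Decompose in-plane deviations into on- and off-axis components
#'
#' A trial's deviation is its displacement from the condition-mean state
#' in the spatial plane. The on-axis component is the projection onto the
#' radial unit vector from the origin to the condition mean (variation in
#' distance); the off-axis component is the projection onto its
#' 90-degree-rotated counterpart `(-u_y, u_x)` (variation in direction).
#' The off-axis sign convention is irrelevant to every reported
#' statistic. By construction `on^2 + off^2` equals the squared in-plane
#' deviation.
#'
#' @param states a [project_states()] result (or any data.frame with
#'   `x_neural`, `y_neural`, `condition_id`, `task`).
#' @param radial optional data.frame overriding the radial reference:
#'   mean-state direction by default; pass target coordinates to use the
#'   instructed-target direction instead.
#' @return data.frame of class `deviation_record`: `trial_id` (if
#'   present), `condition_id`, `task`, `on_axis`, `off_axis` (cm).
#'   Conditions whose mean state sits at the origin (radial direction
#'   undefined) are excluded and listed in attribute `excluded`.
#' @export
decompose_deviations <- function(states, radial = NULL) {
  need <- c("x_neural", "y_neural", "condition_id", "task")
  stopifnot(all(need %in% names(states)))
  key <- interaction(states$task, states$condition_id, drop = TRUE)
  mx <- stats::ave(states$x_neural, key)
  my <- stats::ave(states$y_neural, key)
  rx <- if (is.null(radial)) mx else radial[[1]]
  ry <- if (is.null(radial)) my else radial[[2]]
  nrm <- sqrt(rx^2 + ry^2)
  ok <- nrm > 0
  ux <- rx[ok] / nrm[ok]; uy <- ry[ok] / nrm[ok]
  dx <- states$x_neural[ok] - mx[ok]; dy <- states$y_neural[ok] - my[ok]
  out <- data.frame(condition_id = states$condition_id[ok],
                    task = states$task[ok],
                    on_axis = dx * ux + dy * uy,
                    off_axis = -dx * uy + dy * ux,
                    stringsAsFactors = FALSE)
  if (!is.null(states$trial_id)) out <- cbind(trial_id = states$trial_id[ok], out)
  structure(out,
            excluded = unique(key[!ok]),
            class = c("deviation_record", "data.frame"))
}

#' Trial-by-trial neural-kinematic deviation correlation
#'
#' Tests whether trial-to-trial wander of the preparatory neural state is
#' shared with the upcoming movement. Kinematic deviations are computed
#' exactly like the neural ones — displacement of the hand position at
#' maximum speed from its condition mean, decomposed on/off the radial
#' direction of the mean max-speed position — and correlated with the
#' neural on- and off-axis deviations across trials.
#'
#' @param states a [project_states()] result carrying `max_speed_x/y`.
#' @return list with components `on` and `off`, each holding `estimate`
#'   (Pearson r), `p_value`, `n`.
#' @export
correlate_neural_kinematic <- function(states) {
  if (is.null(states$max_speed_x) || is.null(states$max_speed_y))
    stop("states must carry max_speed_x / max_speed_y")
  if (length(unique(paste(states$task, states$condition_id))) < 3)
    stop("insufficient data: need trials from at least 3 conditions")
  ndev <- decompose_deviations(states)
  kin <- data.frame(x_neural = states$max_speed_x,
                    y_neural = states$max_speed_y,
                    condition_id = states$condition_id, task = states$task,
                    trial_id = states$trial_id %||% seq_len(nrow(states)))
  kdev <- decompose_deviations(kin)
  m <- merge(ndev, kdev, by = c("trial_id", "condition_id", "task"),
             suffixes = c("_neural", "_kin"))
  one <- function(a, b) {
    ct <- stats::cor.test(a, b)
    list(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(a))
  }
  list(on = one(m$on_axis_neural, m$on_axis_kin),
       off = one(m$off_axis_neural, m$off_axis_kin))
}

#' Equal-frequency ellipses of per-condition state distributions
#'
#' For each condition, the in-plane states are summarised by an ellipse
#' whose major/minor axes are the condition's first/second principal
#' components. Axis lengths are the per-component standard deviations
#' multiplied by one global scale factor, chosen by bisection so that the
#' across-condition average fraction of states falling inside their
#' ellipse equals `coverage`.
#'
#' @param states a [project_states()] result; every condition needs at
#'   least 3 trials.
#' @param coverage target average inside-fraction (default 0.95).
#' @return list of class `ellipse_summary`: `ellipses` (data.frame:
#'   center, axis directions, scaled semi-axis lengths, orientation angle
#'   to the radial direction in radians, degenerate flag), `scale`, the
#'   achieved `coverage`.
#' @export
equal_frequency_ellipses <- function(states, coverage = 0.95) {
  stopifnot(coverage > 0, coverage <= 1)
  key <- interaction(states$task, states$condition_id, drop = TRUE)
  groups <- split(seq_len(nrow(states)), key)
  if (any(lengths(groups) < 3)) stop("every condition needs >= 3 trials")
  per <- lapply(groups, function(i) {
    x <- states$x_neural[i]; y <- states$y_neural[i]
    mu <- c(mean(x), mean(y))
    ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE)
    sd1 <- sqrt(max(ev$values[1], 0)); sd2 <- sqrt(max(ev$values[2], 0))
    # squared Mahalanobis-like coordinates in units of component sd
    a1 <- ((x - mu[1]) * ev$vectors[1, 1] + (y - mu[2]) * ev$vectors[2, 1])
    a2 <- ((x - mu[1]) * ev$vectors[1, 2] + (y - mu[2]) * ev$vectors[2, 2])
    list(mu = mu, vec = ev$vectors, sd = c(sd1, sd2),
         m2 = if (sd2 > 0) (a1 / sd1)^2 + (a2 / sd2)^2 else (a1 / sd1)^2,
         degenerate = sd2 == 0)
  })
  inside_frac <- function(s) {
    mean(vapply(per, function(p) mean(p$m2 <= s^2), numeric(1)))
  }
  lo <- 1e-3; hi <- 1
  while (inside_frac(hi) < coverage && hi < 1e4) hi <- hi * 2
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (inside_frac(mid) >= coverage) hi <- mid else lo <- mid
  }
  s <- hi
  tab <- do.call(rbind, lapply(names(per), function(nm) {
    p <- per[[nm]]
    ang <- atan2(p$vec[2, 1], p$vec[1, 1]) - atan2(p$mu[2], p$mu[1])
    ang <- atan2(sin(ang), cos(ang))      # wrap to (-pi, pi]
    # orientation of an axis is defined modulo pi
    if (ang > pi / 2) ang <- ang - pi
    if (ang < -pi / 2) ang <- ang + pi
    data.frame(condition = nm, center_x = p$mu[1], center_y = p$mu[2],
               major_x = p$vec[1, 1], major_y = p$vec[2, 1],
               minor_x = p$vec[1, 2], minor_y = p$vec[2, 2],
               major_len = s * p$sd[1], minor_len = s * p$sd[2],
               orientation = ang, degenerate = p$degenerate,
               stringsAsFactors = FALSE)
  }))
  structure(list(ellipses = tab, scale = s, coverage = inside_frac(s)),
            class = "ellipse_summary")
}

#' @export
print.ellipse_summary <- function(x, ...) {
  cat(sprintf(
    "<ellipse_summary: %d conditions, scale %.3f, mean inside-fraction %.3f, mean axis ratio %.2f>\n",
    nrow(x$ellipses), x$scale, x$coverage,
    mean(x$ellipses$major_len / pmax(x$ellipses$minor_len, 1e-12))))
  invisible(x)
}

#' Relative deviation as a function of reach distance
#'
#' Per unique target distance, the mean absolute on- and off-axis
#' deviation expressed as a fraction of that distance, with standard
#' errors; monotonicity is assessed by the Spearman rank correlation of
#' the per-distance means against distance.
#'
#' @param devs a [decompose_deviations()] result.
#' @param states the matching [project_states()] result (provides target
#'   coordinates per trial).
#' @return list of class `relative_deviation_profile`: `profile`
#'   (data.frame: distance, rel_on, rel_on_sem, rel_off, rel_off_sem, n)
#'   and `trend` (list of Spearman rho and p per component).
#' @export
relative_deviation_profile <- function(devs, states) {
  m <- merge(as.data.frame(devs),
             data.frame(trial_id = states$trial_id %||% seq_len(nrow(states)),
                        condition_id = states$condition_id,
                        task = states$task,
                        distance = round_distance(
                          target_distance(states$target_x, states$target_y))),
             by = c("trial_id", "condition_id", "task"))
  if (length(unique(m$distance)) < 2)
    stop("need >= 2 distinct target distances")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  agg <- do.call(rbind, lapply(split(m, m$distance), function(g) {
    data.frame(distance = g$distance[1],
               rel_on = mean(abs(g$on_axis)) / g$distance[1],
               rel_on_sem = sem(abs(g$on_axis) / g$distance[1]),
               rel_off = mean(abs(g$off_axis)) / g$distance[1],
               rel_off_sem = sem(abs(g$off_axis) / g$distance[1]),
               n = nrow(g))
  }))
  rownames(agg) <- NULL
  trend <- lapply(c(on = "rel_on", off = "rel_off"), function(col) {
    ct <- suppressWarnings(
      stats::cor.test(agg$distance, agg[[col]], method = "spearman"))
    list(rho = unname(ct$estimate), p_value = ct$p.value)
  })
  structure(list(profile = agg, trend = trend),
            class = "relative_deviation_profile")
}

#' @export
print.relative_deviation_profile <- function(x, ...) {
  cat("Relative deviation (fraction of reach distance) by distance:\n")
  print(x$profile, digits = 3)
  cat(sprintf("Spearman trend: on rho = %.2f (p = %.3g), off rho = %.2f (p = %.3g)\n",
              x$trend$on$rho, x$trend$on$p_value,
              x$trend$off$rho, x$trend$off$p_value))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Two-sided t-test assuming unequal variances, with Welch-Satterthwaite
#' degrees of freedom — the package's standard comparison between two
#' distributions.
#'
#' @param a,b numeric samples (each `n >= 2`, finite variance).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
welch_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0 && mean(a) == mean(b))
    stop("undefined: both samples have zero variance and equal means")
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  if (se2 == 0)   # both variances zero, means differ
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0,
                df = NA_real_))
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df), df = df)
}
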