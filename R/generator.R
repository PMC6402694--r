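#' Parameters of the synthetic trial generator
#'
#' The generator emulates the statistical structure that the analysis
#' assumes in delay-period population activity, so every downstream stage
#' can be exercised without recorded data:
#'
#' * linear population encoding: channel rates are
#'   `baseline + W %*% c(e_x, e_y, s) + noise`, clipped at 0, where
#'   `(e_x, e_y)` is the trial's planned endpoint and `s` its maximum
#'   reach speed;
#' * speed-distance correlation: `s = a + b * d + eps`, with
#'   within-distance speed variability `sd = sigma_speed`;
#' * radially anisotropic endpoint variability: the planned endpoint
#'   deviates from the target by `delta_on` along the radial (distance)
#'   axis and `delta_off` along the orthogonal (direction) axis, with
#'   `sd = c_on * sqrt(d)` and `c_off * sqrt(d)` and `c_on > c_off`, so
#'   on-axis spread exceeds off-axis spread while relative deviations
#'   shrink with distance;
#' * neural-kinematic coupling: the hand position at maximum speed shares
#'   a fraction `kappa` of the planned-endpoint deviation.
#'
#' The encoding matrix `W` is drawn once from a seeded standard normal
#' scaled by `gain_pos` / `gain_speed` and stored in the object, so
#' recovery tests can compare fitted axes against ground truth. Noise is
#' Gaussian on rates (the analysis operates on binned multiunit rates,
#' not spike counts). Numeric defaults are chosen for testability of the
#' structure above, not for biological fidelity.
#'
#' @param n_channels number of recorded channels (default 96).
#' @param baseline mean firing rate, spikes/s; large enough that clipping
#'   at zero affects under 1\% of entries at the default gains.
#' @param sigma_ch per-channel rate noise sd, spikes/s.
#' @param gain_pos,gain_speed,gain_distance sd of the encoding weights,
#'   spikes/s per cm (position, distance) and per cm/s (speed).
#'   `gain_distance = 0` by default: distance information reaches the
#'   rates only through the endpoint and speed encodings.
#' @param speed_intercept,speed_slope `a` (cm/s) and `b` ((cm/s)/cm) of
#'   the speed-distance relation.
#' @param sigma_speed within-distance speed sd, cm/s.
#' @param c_on,c_off endpoint deviation scales, cm per sqrt(cm)
#'   (or cm when `deviation_scaling = "constant"`).
#' @param deviation_scaling `"sqrt_d"` (default; deviation sd grows as
#'   `sqrt(d)`, so relative deviation shrinks as `1/sqrt(d)`) or
#'   `"constant"` (absolute cm noise independent of distance, the
#'   construction under which arc-length decoding errors are
#'   distance-independent).
#' @param kappa fraction of the endpoint deviation shared with the
#'   max-speed hand position (dimensionless).
#' @param kin_sd independent kinematic measurement noise sd, cm.
#' @param rho fixed scale mapping planned endpoint to max-speed position
#'   (~ mid-reach); only the shared-deviation structure matters
#'   downstream.
#' @param t0,tau latency (ms) and exponential time constant (ms) of the
#'   post-target-onset ramp used by [simulate_timecourse()].
#' @param w_seed seed for the one-off draw of `W`.
#' @param W optional explicit encoding matrix (`n_channels` x 4 columns
#'   for x, y, speed, distance), overriding the seeded draw.
#' @return an object of class `generator_params` (a list).
#' @examples
#' p <- generator_params(c_on = 0.2, c_off = 0.1)
#' dim(p$W)
#' @export
generator_params <- function(n_channels = 96L,
                             baseline = 20,
                             sigma_ch = 0.5,
                             gain_pos = 0.4,
                             gain_speed = 0.1,
                             gain_distance = 0,
                             speed_intercept = 15,
                             speed_slope = 2.5,
                             sigma_speed = 2,
                             c_on = 0.2,
                             c_off = 0.1,
                             deviation_scaling = c("sqrt_d", "constant"),
                             kappa = 0.5,
                             kin_sd = 0.1,
                             rho = 0.5,
                             t0 = 50,
                             tau = 80,
                             w_seed = 20151009L,
                             W = NULL) {
  deviation_scaling <- match.arg(deviation_scaling)
  for (nm in c("sigma_ch", "sigma_speed", "c_on", "c_off", "kin_sd"))
    if (get(nm) < 0) stop("variance parameter '", nm, "' must be non-negative")
  if (tau <= 0) stop("tau must be positive")
  if (n_channels < 1) stop("n_channels must be >= 1")
  if (is.null(W)) {
    # draw W under w_seed without disturbing the caller's RNG stream
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(w_seed)
    W <- cbind(stats::rnorm(n_channels, sd = gain_pos),
               stats::rnorm(n_channels, sd = gain_pos),
               stats::rnorm(n_channels, sd = gain_speed),
               stats::rnorm(n_channels, sd = 1) * gain_distance)
  } else {
    W <- as.matrix(W)
    if (nrow(W) != n_channels || !ncol(W) %in% 3:4)
      stop("W must be n_channels x 3 or x 4")
    if (ncol(W) == 3) W <- cbind(W, 0)
  }
  colnames(W) <- c("x", "y", "speed", "distance")
  structure(list(n_channels = as.integer(n_channels), baseline = baseline,
                 sigma_ch = sigma_ch, gain_pos = gain_pos,
                 gain_speed = gain_speed, gain_distance = gain_distance,
                 speed_intercept = speed_intercept, speed_slope = speed_slope,
                 sigma_speed = sigma_speed, c_on = c_on, c_off = c_off,
                 deviation_scaling = deviation_scaling, kappa = kappa,
                 kin_sd = kin_sd, rho = rho, t0 = t0, tau = tau,
                 w_seed = w_seed, W = W),
            class = "generator_params")
}

# Per-trial latent draws shared by simulate_trials and simulate_timecourse.
# Consumes the current RNG stream.
#' @keywords internal
#' @noRd
draw_latents <- function(layout, params, n_per_condition) {
  tg <- layout$targets
  n <- nrow(tg) * n_per_condition
  cond <- rep(tg$condition_id, each = n_per_condition)
  px <- rep(tg$x, each = n_per_condition)
  py <- rep(tg$y, each = n_per_condition)
  d <- target_distance(px, py)
  ux <- px / d; uy <- py / d
  sd_axis <- function(c_axis)
    if (params$deviation_scaling == "sqrt_d") c_axis * sqrt(d) else
      rep(c_axis, length(d))
  d_on <- stats::rnorm(n, sd = sd_axis(params$c_on))
  d_off <- stats::rnorm(n, sd = sd_axis(params$c_off))
  # off-axis unit vector: left-handed normal (-u_y, u_x)
  ex <- px + d_on * ux - d_off * uy
  ey <- py + d_on * uy + d_off * ux
  s <- params$speed_intercept + params$speed_slope * d +
    stats::rnorm(n, sd = params$sigma_speed)
  list(n = n, cond = cond, px = px, py = py, d = d, ux = ux, uy = uy,
       d_on = d_on, d_off = d_off, ex = ex, ey = ey, s = s)
}

#' @keywords internal
#' @noRd
encode_rates <- function(params, ex, ey, s, d, noise = TRUE) {
  n <- length(ex)
  R <- cbind(ex, ey, s, d) %*% t(params$W) + params$baseline
  if (noise && params$sigma_ch > 0)
    R <- R + matrix(stats::rnorm(n * params$n_channels, sd = params$sigma_ch),
                    n, params$n_channels)
  R[R < 0] <- 0
  R
}

#' Simulate a table of delay-period trials
#'
#' Draws `n_per_condition` trials for every target of `layout` under the
#' generative model described in [generator_params()]. The same seed
#' yields a bit-identical table.
#'
#' @param layout a [make_target_layout()] object.
#' @param params a [generator_params()] object.
#' @param n_per_condition trials per target (>= 1).
#' @param seed integer RNG seed.
#' @param session_id session label stored in every row.
#' @return a [trial_table()] with `nrow(layout$targets) * n_per_condition`
#'   rows. Columns `max_speed_x/y` hold the simulated hand position at
#'   maximum speed (shares a fraction `kappa` of the planned-endpoint
#'   deviation).
#' @examples
#' tt <- simulate_trials(make_target_layout("ring", "J"),
#'                       n_per_condition = 2, seed = 1)
#' nrow(tt)  # 48
#' @export
simulate_trials <- function(layout, params = generator_params(),
                            n_per_condition, seed,
                            session_id = "sim-01") {
  stopifnot(inherits(layout, "target_layout"))
  if (n_per_condition < 1) stop("n_per_condition must be >= 1")
  force(params)
  set.seed(seed)
  L <- draw_latents(layout, params, n_per_condition)
  R <- encode_rates(params, L$ex, L$ey, L$s, L$d)
  # max-speed hand position: scaled target plus coupled deviation + noise
  kx <- params$rho * (L$px + params$kappa * (L$ex - L$px)) +
    stats::rnorm(L$n, sd = params$kin_sd)
  ky <- params$rho * (L$py + params$kappa * (L$ey - L$py)) +
    stats::rnorm(L$n, sd = params$kin_sd)
  delay_rng <- if (layout$subject == "J") c(300, 700) else c(400, 900)
  df <- data.frame(trial_id = seq_len(L$n),
                   session_id = session_id,
                   task = layout$name,
                   condition_id = L$cond,
                   target_x = L$px, target_y = L$py,
                   delay = stats::runif(L$n, delay_rng[1], delay_rng[2]),
                   max_speed = L$s,
                   max_speed_x = kx, max_speed_y = ky,
                   stringsAsFactors = FALSE)
  colnames(R) <- sprintf("rate_%03d", seq_len(params$n_channels) - 1)
  trial_table(cbind(df, as.data.frame(R)))
}

#' Simulate post-target-onset rate time-series
#'
#' After target onset the population state ramps from baseline toward the
#' trial's converged delay state along an exponential: the latent gain is
#' `g(t) = 0` for `t < t0` and `1 - exp(-(t - t0) / tau)` after, applied
#' to the trial's latent `(e_x, e_y, s)` before encoding.
#'
#' @inheritParams simulate_trials
#' @param timesteps number of samples per trial.
#' @param dt sample spacing, ms; the series spans `t = dt, 2*dt, ...,
#'   timesteps*dt` ms after target onset and must cover `t0`.
#' @param go_cue_ms go-cue time relative to target onset; defaults to the
#'   end of the series.
#' @return an object of class `rate_timeseries`: list with `rates`
#'   (array trials x channels x timesteps, spikes/s), `time_ms`,
#'   `go_cue_ms`, and `trials` (per-trial metadata data.frame).
#' @export
simulate_timecourse <- function(layout, params = generator_params(),
                                n_per_condition = 1, timesteps, dt, seed,
                                go_cue_ms = timesteps * dt,
                                session_id = "sim-01") {
  stopifnot(inherits(layout, "target_layout"))
  if (params$tau <= 0) stop("tau must be positive")
  if (timesteps * dt < params$t0)
    stop("series too short: timesteps * dt must cover the latency t0")
  set.seed(seed)
  L <- draw_latents(layout, params, n_per_condition)
  time_ms <- dt * seq_len(timesteps)
  g <- ifelse(time_ms < params$t0, 0,
              1 - exp(-(time_ms - params$t0) / params$tau))
  rates <- array(0, dim = c(L$n, params$n_channels, timesteps))
  for (j in seq_len(timesteps)) {
    rates[, , j] <- encode_rates(params, g[j] * L$ex, g[j] * L$ey,
                                 g[j] * L$s, g[j] * L$d)
  }
  trials <- data.frame(trial_id = seq_len(L$n), session_id = session_id,
                       task = layout$name, condition_id = L$cond,
                       target_x = L$px, target_y = L$py,
                       delay = go_cue_ms, max_speed = L$s,
                       max_speed_x = params$rho * L$px,
                       max_speed_y = params$rho * L$py,
                       stringsAsFactors = FALSE)
  structure(list(rates = rates, time_ms = time_ms, go_cue_ms = go_cue_ms,
                 trials = trials),
            class = "rate_timeseries")
}

#' @export
print.rate_timeseries <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf(
    "<rate_timeseries: %d trials x %d channels x %d timesteps, go cue %g ms>\n",
    d[1], d[2], d[3], x$go_cue_ms))
  invisible(x)
}
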