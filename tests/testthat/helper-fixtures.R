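# Shared fixture builders. Everything is generated in code; no files.

# Encoding matrix with exactly orthogonal columns (Gram-Schmidt of the
# default seeded draw, rescaled to the default gain norms). With
# orthogonal loadings the sequential orthogonalized regression recovers
# the latents exactly on noiseless data.
orthogonal_W <- function(n_channels = 96) {
  W0 <- generator_params(n_channels = n_channels)$W[, 1:3]
  Q <- qr.Q(qr(W0))
  sweep(Q, 2, sqrt(n_channels) * c(0.4, 0.4, 0.1), "*")
}

# Noise-free generator: orthogonal W and a baseline high enough that the
# rate floor at 0 is never hit, so the encoding is exactly linear.
noiseless_params <- function(...) {
  generator_params(baseline = 50, sigma_ch = 0, sigma_speed = 0,
                   c_on = 0, c_off = 0, kin_sd = 0,
                   W = orthogonal_W(), ...)
}

# Horizontal + vertical line tables pooled, as the subspace fit requires
# (a single line leaves one target coordinate constant).
simulate_line_pair <- function(params = generator_params(),
                               n_per_condition, seed, subject = "J") {
  pool_trials(
    simulate_trials(make_target_layout("horizontal", subject), params,
                    n_per_condition, seed = seed),
    simulate_trials(make_target_layout("vertical", subject), params,
                    n_per_condition, seed = seed + 1000003L))
}

# Minimal hand-built trial table: k trials, nch channels, rates supplied
# as a matrix; metadata filled with consistent defaults.
tiny_table <- function(rates, condition_id, target_x, target_y,
                       max_speed = NULL, session_id = "s1",
                       task = "rings3") {
  rates <- as.matrix(rates)
  k <- nrow(rates)
  colnames(rates) <- sprintf("rate_%03d", seq_len(ncol(rates)) - 1)
  trial_table(cbind(
    data.frame(trial_id = seq_len(k), session_id = session_id, task = task,
               condition_id = condition_id, target_x = target_x,
               target_y = target_y, delay = 500,
               max_speed = max_speed %||% (15 + 2.5 * sqrt(target_x^2 + target_y^2)),
               max_speed_x = target_x / 2, max_speed_y = target_y / 2,
               stringsAsFactors = FALSE),
    as.data.frame(rates)))
}

# A hand-rolled rate_timeseries object for window-averaging tests.
tiny_series <- function(rates_array, time_ms, go_cue_ms, targets = NULL) {
  ntr <- dim(rates_array)[1]
  tg <- targets %||% data.frame(x = rep(8, ntr), y = rep(0, ntr))
  structure(list(
    rates = rates_array, time_ms = time_ms, go_cue_ms = go_cue_ms,
    trials = data.frame(trial_id = seq_len(ntr), session_id = "s1",
                        task = "ring", condition_id = seq_len(ntr) - 1L,
                        target_x = tg$x, target_y = tg$y, delay = go_cue_ms,
                        max_speed = 30, max_speed_x = tg$x / 2,
                        max_speed_y = tg$y / 2, stringsAsFactors = FALSE)),
    class = "rate_timeseries")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
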