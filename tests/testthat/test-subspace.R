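test_that("condition averaging is an exact group-by mean", {
  # one trial per condition: averages are the rows themselves
  t1 <- simulate_trials(make_target_layout("ring", "J"),
                        generator_params(n_channels = 5), 1, seed = 1)
  ca1 <- condition_average(t1)
  expect_equal(unname(t(ca1$matrix)), unname(rate_matrix(t1)))
  # two trials: column is (a + b) / 2, and a loop oracle agrees
  t2 <- simulate_trials(make_target_layout("ring", "J"),
                        generator_params(n_channels = 5), 2, seed = 2)
  ca2 <- condition_average(t2)
  R <- rate_matrix(t2)
  for (j in seq_len(ncol(ca2$matrix))) {
    rows <- which(t2$condition_id == ca2$index$condition_id[j])
    expect_equal(unname(ca2$matrix[, j]), unname((R[rows[1], ] + R[rows[2], ]) / 2))
  }
})

test_that("fit_pca matches a brute-force eigendecomposition oracle", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(3:10, 1); c <- sample(3:10, 1)
    M <- matrix(rnorm(n * c), n, c)
    p <- fit_pca(M, var_threshold = 1)
    # oracle: eigen of the covariance across conditions
    ev <- eigen(cov(t(M)), symmetric = TRUE)
    frac <- ev$values / sum(ev$values)
    k <- min(n, c - 1)
    expect_equal(p$ev_fraction[1:k], frac[1:k], tolerance = 1e-10)
    for (j in seq_len(p$d)) {
      if (frac[j] < 1e-12) next
      dot <- abs(sum(p$rotation[, j] * ev$vectors[, j]))
      expect_equal(dot, 1, tolerance = 1e-8)
    }
  }
})

test_that("fit_pca retains the smallest d reaching the threshold", {
  # conditions exactly in a 2-D affine plane: two components explain 100%
  set.seed(4)
  B <- matrix(rnorm(12), 6, 2)
  M <- B %*% matrix(rnorm(2 * 9), 2, 9) + rnorm(6)
  p <- fit_pca(M, 0.95)
  expect_equal(p$d, 2)
  expect_equal(sum(p$ev_fraction[1:2]), 1, tolerance = 1e-12)
  expect_true(all(diff(p$ev_fraction) <= 1e-12))
  expect_error(fit_pca(matrix(1, 4, 5)), "degenerate")
})

test_that("noiseless data is recovered exactly and axes are orthogonal", {
  tt <- simulate_trials(make_target_layout("rings3", "J"),
                        noiseless_params(), 1, seed = 1)
  fit <- delay_subspace(tt)
  st <- predict(fit)     # condition averages
  scale <- max(abs(st$target_x))
  expect_lt(max(abs(st$x_neural - st$target_x)) / scale, 1e-8)
  expect_lt(max(abs(st$y_neural - st$target_y)) / scale, 1e-8)
  g <- crossprod(coef(fit))
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
})

test_that("fitted axes are invariant to trial order", {
  tt <- simulate_trials(make_target_layout("rings3", "J"),
                        generator_params(), 5, seed = 6)
  f1 <- delay_subspace(tt)
  set.seed(1)
  perm <- sample.int(nrow(tt))
  tp <- trial_table(as.data.frame(tt)[perm, ])
  f2 <- delay_subspace(tp)
  expect_equal(f2$axes, f1$axes, tolerance = 1e-8)
})

test_that("projection is linear and sends the grand center to the origin", {
  tt <- simulate_trials(make_target_layout("rings3", "J"),
                        generator_params(), 5, seed = 7)
  fit <- delay_subspace(tt)
  ctr <- tiny_table(matrix(fit$center, 1), 0L, 4, 0)
  st <- project_states(ctr, fit)
  expect_equal(c(st$x_neural, st$y_neural, st$speed_neural), c(0, 0, 0),
               tolerance = 1e-10)
  # linearity in the rate vector
  a <- rnorm(96); b <- rnorm(96)
  pr <- function(r) unlist(project_states(
    tiny_table(matrix(r, 1), 0L, 4, 0), fit)[, c("x_neural", "y_neural",
                                                 "speed_neural")])
  expect_equal(pr(a + b - fit$center), pr(a) + pr(b) - 2 * pr(fit$center) +
                 pr(fit$center), tolerance = 1e-9)
  # channel-count mismatch is a shape error
  expect_error(project_states(tiny_table(matrix(1, 1, 5), 0L, 4, 0), fit),
               "channel count")
})

test_that("degenerate regressands raise per-axis errors", {
  tt <- simulate_trials(make_target_layout("vertical", "J"),
                        generator_params(), 2, seed = 8)
  expect_error(delay_subspace(tt), "x coordinate")
  tr <- as.data.frame(simulate_trials(make_target_layout("ring", "J"),
                                      generator_params(), 2, seed = 8))
  tr$max_speed <- 20
  expect_error(delay_subspace(trial_table(tr)), "max_speed")
})

test_that("plane explained variance hits its exact limiting cases", {
  # speed encoding absent: condition means are rank 2 and the plane
  # captures all of their variance
  p2 <- noiseless_params()
  W <- p2$W; W[, 3] <- 0
  p2 <- generator_params(baseline = 50, sigma_ch = 0, sigma_speed = 1,
                         c_on = 0, c_off = 0, kin_sd = 0, W = W[, 1:3])
  tt <- simulate_trials(make_target_layout("rings3", "J"), p2, 2, seed = 9)
  fit <- delay_subspace(tt)
  expect_equal(explained_variance_in_plane(fit), 1, tolerance = 1e-10)
  # a plane orthogonal to all condition variation captures none of it
  doctored <- fit
  ns <- svd(fit$cond_matrix - rowMeans(fit$cond_matrix))
  doctored$axes[, "x"] <- ns$u[, ncol(ns$u) - 1]
  doctored$axes[, "y"] <- ns$u[, ncol(ns$u)]
  expect_equal(explained_variance_in_plane(doctored), 0, tolerance = 1e-10)
})

test_that("held-out spatial-plane prediction is accurate under default noise", {
  tt <- simulate_trials(make_target_layout("rings3", "J"),
                        generator_params(), 20, seed = 10)
  odd <- seq(1, nrow(tt), 2)
  fit <- delay_subspace(trial_table(as.data.frame(tt)[odd, ]))
  st <- project_states(trial_table(as.data.frame(tt)[-odd, ]), fit)
  r2 <- 1 - sum((st$x_neural - st$target_x)^2 + (st$y_neural - st$target_y)^2) /
    sum(st$target_x^2 + st$target_y^2)
  expect_gt(r2, 0.95)
})

test_that("speed axis slope is unity when speed_neural equals max speed", {
  # doctored model whose speed axis reads channel 0 directly
  set.seed(11)
  n <- 40
  speeds <- runif(n, 10, 40)
  rates <- cbind(speeds, matrix(rnorm(n * 2), n, 2))
  tt <- tiny_table(rates, condition_id = rep(0:3, each = 10),
                   target_x = rep(c(4, 8, 4, 8), each = 10),
                   target_y = 0, max_speed = speeds)
  model <- structure(list(
    axes = matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3,
                  dimnames = list(NULL, c("x", "y", "speed"))),
    center = c(0, 0, 0), n_channels = 3L, channel_mask = rep(TRUE, 3)),
    class = "delay_subspace")
  res <- suppressWarnings(
    within_distance_speed_test(tt, model, cross_fit = FALSE))
  expect_equal(res$slope, rep(1, nrow(res)), tolerance = 1e-10)
  expect_true(all(res$p_value < 1e-6))
})

test_that("residual distance correlation flags degenerate inputs", {
  n <- 30
  speeds <- seq(10, 40, length.out = n)
  rates <- cbind(speeds, 2 * speeds)   # rates are exact functions of speed
  tt <- tiny_table(rates, condition_id = seq_len(n) - 1L,
                   target_x = seq(1, 5, length.out = n), target_y = 0,
                   max_speed = speeds)
  expect_error(residual_distance_correlation(tt), "degenerate")
})

test_that("convergence profile finds the exponential crossing", {
  p0 <- noiseless_params()
  lay <- make_target_layout("rings3", "J")
  fitted_tt <- simulate_trials(lay, p0, 1, seed = 1)
  fit <- delay_subspace(fitted_tt)
  ser <- simulate_timecourse(lay, p0, 1, timesteps = 400, dt = 2, seed = 2)
  prof <- state_convergence_profile(ser, fit, 0.1)
  expect_equal(prof$crossing_ms, 50 + 80 * log(10), tolerance = 0.01)
  # doubling tau doubles the latency-corrected crossing time
  p2 <- noiseless_params(tau = 160)
  ser2 <- simulate_timecourse(lay, p2, 1, timesteps = 700, dt = 2, seed = 2)
  prof2 <- state_convergence_profile(ser2, fit, 0.1)
  expect_equal((prof2$crossing_ms - 50) / (prof$crossing_ms - 50), 2,
               tolerance = 0.02)
  # a series already at the converged state crosses immediately
  conv <- rate_matrix(fitted_tt)
  rr <- array(0, dim = c(nrow(conv), 96, 10))
  for (j in 1:10) rr[, , j] <- conv
  ser3 <- tiny_series(rr, time_ms = 20 * (1:10), go_cue_ms = 200,
                      targets = data.frame(x = fitted_tt$target_x,
                                           y = fitted_tt$target_y))
  prof3 <- state_convergence_profile(ser3, fit, 0.5)
  expect_equal(max(prof3$mean_distance), 0)
  expect_equal(prof3$crossing_ms, 20)
  expect_error(state_convergence_profile(ser, fit, 1.5), "threshold")
})
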