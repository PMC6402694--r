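fake_states <- function(x, y, cond, task = "ring", tx = NULL, ty = NULL) {
  df <- data.frame(trial_id = seq_along(x), x_neural = x, y_neural = y,
                   speed_neural = 0, condition_id = cond, task = task,
                   target_x = tx %||% ave(x, cond),
                   target_y = ty %||% ave(y, cond),
                   max_speed = 20, max_speed_x = 0, max_speed_y = 0,
                   stringsAsFactors = FALSE)
  class(df) <- c("neural_states", "data.frame")
  df
}

test_that("on/off decomposition handles the canonical cases", {
  # two trials per condition, means at (3,0) and (0,2)
  st <- fake_states(x = c(4, 2, 1, -1), y = c(0, 0, 2, 2),
                    cond = c(0, 0, 1, 1))
  d <- decompose_deviations(st)
  expect_equal(d$on_axis, c(1, -1, 0, 0))
  expect_equal(d$off_axis, c(0, 0, -1, 1))
  # trial equal to its condition mean: both components zero
  st2 <- fake_states(x = c(3, 3), y = c(1, 1), cond = c(0, 0))
  d2 <- decompose_deviations(st2)
  expect_equal(unlist(d2[, c("on_axis", "off_axis")]), rep(0, 4),
               ignore_attr = TRUE)
})

test_that("on^2 + off^2 equals the squared in-plane deviation", {
  set.seed(1)
  st <- fake_states(x = rnorm(200, rep(c(4, -3, 0), length.out = 200)),
                    y = rnorm(200, rep(c(0, 3, 5), length.out = 200)),
                    cond = rep(0:2, length.out = 200))
  d <- decompose_deviations(st)
  dx <- st$x_neural - ave(st$x_neural, st$condition_id)
  dy <- st$y_neural - ave(st$y_neural, st$condition_id)
  expect_equal(d$on_axis^2 + d$off_axis^2, dx^2 + dy^2, tolerance = 1e-12)
})

test_that("a condition with its mean at the origin is excluded", {
  st <- fake_states(x = c(1, -1, 5, 5), y = c(1, -1, 0, 2),
                    cond = c(0, 0, 1, 1))
  d <- decompose_deviations(st)
  expect_equal(nrow(d), 2)
  expect_length(attr(d, "excluded"), 1)
})

test_that("neural-kinematic correlation is perfect for copied deviations", {
  set.seed(2)
  n <- 120
  cond <- rep(0:5, each = 20)
  mx <- c(4, 0, -4, 0, 3, -3)[cond + 1]
  my <- c(0, 4, 0, -4, 3, -3)[cond + 1]
  x <- mx + rnorm(n, sd = 0.5); y <- my + rnorm(n, sd = 0.3)
  st <- fake_states(x, y, cond)
  st$max_speed_x <- x / 2   # kinematics are an exact rescaling
  st$max_speed_y <- y / 2
  r <- correlate_neural_kinematic(st)
  expect_equal(r$on$estimate, 1, tolerance = 1e-10)
  expect_equal(r$off$estimate, 1, tolerance = 1e-10)
  expect_lt(r$on$p_value, 1e-20)
})

test_that("generator coupling drives the neural-kinematic correlation", {
  lay <- make_target_layout("ring", "J")
  t_c <- subtract_session_baseline(
    simulate_trials(lay, generator_params(kappa = 0.8), 50, seed = 3))
  m <- delay_subspace(t_c)
  r <- correlate_neural_kinematic(project_states(t_c, m))
  expect_gt(r$on$estimate, 0); expect_lt(r$on$p_value, 0.01)
  expect_gt(r$off$estimate, 0); expect_lt(r$off$p_value, 0.01)
})

test_that("equal-frequency ellipses calibrate coverage and shape", {
  set.seed(4)
  n <- 400
  cond <- rep(0:3, each = n / 4)
  mx <- c(6, -6, 0, 0)[cond + 1]; my <- c(0, 0, 6, -6)[cond + 1]
  st <- fake_states(mx + rnorm(n), my + rnorm(n), cond)
  ell <- equal_frequency_ellipses(st, coverage = 0.95)
  expect_equal(ell$coverage, 0.95, tolerance = 0.011)
  ratio <- ell$ellipses$major_len / ell$ellipses$minor_len
  expect_true(all(ratio < 1.35))          # isotropic: near-circular
  # coverage = 1 puts every state inside
  ell1 <- equal_frequency_ellipses(st, coverage = 1)
  expect_equal(ell1$coverage, 1)
  expect_error(equal_frequency_ellipses(st[c(1:2, 101:200), ]), ">= 3 trials")
})

test_that("anisotropic conditions give radial ellipses with ratio ~ 2", {
  tt <- subtract_session_baseline(
    simulate_trials(make_target_layout("rings3", "J"),
                    generator_params(), 100, seed = 5))
  st <- project_states(tt, delay_subspace(tt))
  ell <- equal_frequency_ellipses(st)
  ratio <- ell$ellipses$major_len / ell$ellipses$minor_len
  expect_equal(mean(ratio), 2, tolerance = 0.25)
  expect_gt(mean(abs(ell$ellipses$orientation) < 15 * pi / 180), 0.6)
})

test_that("relative deviations follow the arithmetic and the sqrt(d) trend", {
  # constant |deviation| 1 at distances 4 and 8: relative 25% and 12.5%
  st <- fake_states(x = c(5, 3, 9, 7), y = 0, cond = c(0, 0, 1, 1),
                    tx = c(4, 4, 8, 8), ty = 0)
  d <- decompose_deviations(st)
  prof <- relative_deviation_profile(d, st)$profile
  expect_equal(prof$rel_on, c(0.25, 0.125))
  expect_equal(prof$rel_off, c(0, 0))
  # sqrt(d) generator: relative deviation decreases with distance
  ttv <- simulate_line_pair(generator_params(), 100, seed = 6)
  stv <- project_states(ttv, delay_subspace(subtract_session_baseline(ttv)))
  rel <- relative_deviation_profile(decompose_deviations(stv), stv)
  expect_lt(rel$trend$on$rho, 0)
  expect_lt(rel$trend$on$p_value, 0.05)
  expect_lt(rel$trend$off$rho, 0)
  expect_lt(rel$trend$off$p_value, 0.05)
})

test_that("welch_ttest matches the textbook formula and a stats oracle", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  w <- welch_ttest(a, b)
  # hand-computed: means 2.5/3.5, vars 5/3 each, se = sqrt(5/6), df = 6
  expect_equal(w$statistic, -1 / sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(w$df, 6, tolerance = 1e-12)
  o <- t.test(a, b)
  expect_equal(w$statistic, unname(o$statistic), tolerance = 1e-12)
  expect_equal(w$p_value, o$p.value, tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  w0 <- welch_ttest(a, a)
  expect_equal(w0$statistic, 0); expect_equal(w0$p_value, 1)
  # separated Gaussians
  set.seed(7)
  expect_lt(welch_ttest(rnorm(500), rnorm(500, 1))$p_value, 1e-10)
  expect_error(welch_ttest(c(1, 1), c(1, 1)), "zero variance")
})
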