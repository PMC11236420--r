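test_that("confidence scaling hits its analytic limits", {
  expect_equal(confidence_noise_scale(10, 1, 1), 10)
  expect_equal(confidence_noise_scale(10, 5, 1), 10)
  expect_equal(confidence_noise_scale(10, 1, 0), 10 * exp(1))
  expect_equal(confidence_noise_scale(10, 1e6, 0), 10, tolerance = 1e-5)
  cs <- confidence_noise_scale(10, 0.5, seq(0, 1, 0.1))
  expect_true(all(diff(cs) < 0))  # strictly decreasing in confidence
  expect_error(confidence_noise_scale(10, 1, 1.5), "confidence")
})

test_that("delta-rule steps do no learning at alpha = 0 and full at 1", {
  s0 <- rl_step(40, 60, rl_params(0, 5, 40, 1))
  expect_equal(s0$perceived, 60)
  expect_equal(s0$expectation_next, 40)
  s1 <- rl_step(40, 60, rl_params(1, 5, 40, 1))
  expect_equal(s1$expectation_next, 60)
})

test_that("eRL with gamma = 0 reproduces RL trajectories exactly", {
  d <- toy_trials(seed = 2)
  rl <- run_model(d, rl_params(0.35, 6, 45, 1.2))
  erl <- run_model(d, erl_params(0.35, 6, 45, 1.2, gamma = 0))
  expect_equal(erl$perceived, rl$perceived)
  expect_equal(erl$expectation_next, rl$expectation_next)
  # and with gamma > 0 perception is a convex mix of input and expectation
  erl2 <- run_model(d, erl_params(0.35, 6, 45, 1.2, gamma = 0.4))
  e_prev <- c(45, erl2$expectation_next[-nrow(erl2)])
  lo <- pmin(d$input, e_prev)
  hi <- pmax(d$input, e_prev)
  expect_true(all(erl2$perceived >= lo - 1e-12 & erl2$perceived <= hi + 1e-12))
})

test_that("eKF with epsilon = 0 reproduces KF trajectories exactly", {
  d <- toy_trials(seed = 3)
  kf <- run_model(d, kf_params(7, 3, 5, 50, 5, 1.5))
  ekf <- run_model(d, ekf_params(0, 7, 3, 5, 50, 5, 1.5))
  expect_equal(ekf$perceived, kf$perceived)
  expect_equal(ekf$expectation_next, kf$expectation_next)
  st <- kf_step(50, 25, 60, ekf_params(0, 7, 3, 5, 50, 5, 1.5))
  expect_equal(st$gamma_t, 0)
})

test_that("Kalman gain is 1/2 when belief and observation noise match", {
  st <- kf_step(50, 49, 60, kf_params(s = 7, v = 3, xi = 5, e0 = 50,
                                      w0 = 7, c_scale = 1))
  expect_equal(st$gain, 0.5)
})

test_that("static KF matches the conjugate-Gaussian batch posterior", {
  # Independent oracle: with v = 0 the filter is exact Bayesian updating of
  # a Gaussian mean with known observation variance; the batch posterior is
  # available in closed form from precision-weighted averaging.
  set.seed(99)
  m0 <- 45
  w0 <- 6
  s <- 4
  x <- rnorm(30, 52, s)
  p <- kf_params(s = s, v = 0, xi = 5, e0 = m0, w0 = w0, c_scale = 1)
  m <- m0
  w2 <- w0^2
  for (t in seq_along(x)) {
    st <- kf_step(m, w2, x[t], p)
    m <- st$mean_next
    w2 <- st$variance_next
  }
  prec <- 1 / w0^2 + length(x) / s^2
  m_oracle <- (m0 / w0^2 + sum(x) / s^2) / prec
  expect_equal(m, m_oracle, tolerance = 1e-10)
  expect_equal(w2, 1 / prec, tolerance = 1e-10)
})

test_that("belief variance converges to the numerically solved fixed point", {
  s <- 7
  v <- 3
  p <- kf_params(s, v, 5, 50, 12, 1)
  w2 <- 144
  for (t in 1:500) w2 <- kf_step(50, w2, 50, p)$variance_next
  fp <- stats::uniroot(function(w) w * s^2 / (w + s^2) + v^2 - w,
                       c(1e-6, 1e4), tol = 1e-12)$root
  expect_equal(w2, fp, tolerance = 1e-8)
  expect_equal(kf_stationary_variance(s, v), fp, tolerance = 1e-8)
})

test_that("eKF weight gamma_t moves the right way with each noise source", {
  base <- ekf_params(5, 7, 3, 5, 50, 5, 1)
  g <- function(p, w2 = 25) kf_step(50, w2, 60, p)$gamma_t
  expect_gt(g(ekf_params(8, 7, 3, 5, 50, 5, 1)), g(base))   # up in epsilon
  expect_lt(g(ekf_params(5, 10, 3, 5, 50, 5, 1)), g(base))  # down in s
  expect_lt(g(base, w2 = 60), g(base, w2 = 25))             # down in w2
  expect_true(g(base) >= 0 && g(base) < 1)
  # gain always in (0,1)
  gains <- sapply(c(1, 10, 100), function(w2) kf_step(0, w2, 0, base)$gain)
  expect_true(all(gains > 0 & gains < 1))
})

test_that("trial log-likelihood matches the Gaussian density formula", {
  # oracle: direct arithmetic evaluation of the Normal log-density
  grid <- expand.grid(resp = c(0, 35.2, 50, 100), mean = c(20, 50.5),
                      conf = c(0, 0.4, 1))
  for (r in seq_len(nrow(grid))) {
    gmu <- grid$mean[r]
    sdv <- 8 * exp((1 - grid$conf[r]) / 1.3)
    oracle <- -0.5 * log(2 * pi * sdv^2) -
      (grid$resp[r] - gmu)^2 / (2 * sdv^2)
    expect_equal(
      trial_loglik(grid$resp[r], gmu, 8, 1.3, grid$conf[r]),
      oracle, tolerance = 1e-12
    )
  }
  # at the mode, doubling the sd lowers the log-density by log 2
  expect_equal(trial_loglik(50, 50, 4, 1, 1) - trial_loglik(50, 50, 8, 1, 1),
               log(2))
})

test_that("run_model evaluates the right mean on each trial type", {
  d <- toy_trials(seed = 4)
  d$response <- 50
  # random model: mean is the constant on every trial
  rnd <- run_model(d, random_params(62, 5, 1))
  expect_true(all(rnd$model_mean == 62))
  # RL with alpha = 0: every prediction mean equals e0
  rl0 <- run_model(d, rl_params(0, 5, 47, 1))
  expect_true(all(rl0$model_mean[rl0$response_type == "prediction"] == 47))
  expect_equal(rl0$model_mean[rl0$response_type == "perception"],
               d$input[rl0$response_type == "perception"])
  # total log-likelihood is the sum of the per-trial values
  expect_equal(attr(rl0, "total_loglik"), sum(rl0$loglik))
  # missing responses are flagged and contribute nothing
  d2 <- d
  d2$response[1:5] <- NA
  out2 <- run_model(d2, rl_params(0.3, 5, 47, 1))
  expect_equal(attr(out2, "n_missing"), 5)
  expect_equal(attr(out2, "total_loglik"), sum(out2$loglik, na.rm = TRUE))
  # belief updates are unaffected by which trials were answered
  expect_equal(out2$expectation_next,
               run_model(d, rl_params(0.3, 5, 47, 1))$expectation_next)
})

test_that("run_model rejects malformed input", {
  d <- toy_trials(seed = 5)
  expect_error(run_model(dplyr::select(d, -input), rl_params(.3, 5, 50, 1)),
               "columns")
  d$response_type[1] <- "guess"
  expect_error(run_model(d, rl_params(.3, 5, 50, 1)), "response_type")
})

test_that("simulated responses follow the confidence-scaled noise law", {
  d <- toy_trials(seed = 6)[rep(1, 10000), ]
  d$trial <- seq_len(nrow(d))
  d$confidence <- 0.3
  p <- random_params(55, 6, 0.8)
  sim <- simulate_responses(d, p, seed = 8)
  expect_equal(sd(sim$response),
               confidence_noise_scale(6, 0.8, 0.3), tolerance = 0.03)
  expect_equal(mean(sim$response), 55, tolerance = 0.02)
  # degenerate noise: responses collapse onto the model means
  d2 <- toy_trials(seed = 7)
  sim2 <- simulate_responses(d2, rl_params(0.4, 1e-9, 45, 1), seed = 9)
  tr <- run_model(d2, rl_params(0.4, 1e-9, 45, 1))
  expect_equal(sim2$response, tr$model_mean, tolerance = 1e-6)
})

test_that("a model fits its own data better than a mismatched model", {
  # smoke test for recovery: average log-likelihood of data simulated from
  # a strongly expectation-weighted eRL is higher under the generating
  # parameters than under the plain RL with the same core parameters
  d <- toy_trials(seed = 10)
  gen <- erl_params(0.4, 4, 50, 1, gamma = 0.7)
  lls <- sapply(1:20, function(s) {
    sim <- simulate_responses(d, gen, seed = s)
    c(gen = attr(run_model(sim, gen), "total_loglik"),
      rl = attr(run_model(sim, rl_params(0.4, 4, 50, 1)), "total_loglik"))
  })
  expect_gt(mean(lls["gen", ] - lls["rl", ]), 0)
})
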