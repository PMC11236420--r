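test_that("model builder produces the five observer models", {
  ks <- c(rl = 4, erl = 5, kf = 6, ekf = 7, random = 3)
  for (id in names(ks)) {
    m <- build_model(id)
    expect_s3_class(m, "painseq_model")
    expect_equal(nrow(m$params), unname(ks[id]))
    expect_true(all(c("xi", "c_scale") %in% m$params$name))
    expect_match(m$bugs, "dgamma\\(1.5, 1.5\\)")  # half-t(3,0,1) mixture
    expect_match(m$bugs, "mu\\[k\\] ~ dnorm\\(0, 1\\)")
  }
  expect_error(build_model("hgf"), "Unknown model")
})

test_that("non-centred construction collapses and bounds as it should", {
  m <- build_model("erl")
  mu <- c(0.3, 1.2, 1.0, 0.2, -0.4)
  sig <- c(0.5, 0.3, 0.1, 0.2, 0.4)
  z0 <- matrix(0, 6, 5)
  th0 <- natural_params(m, mu, sig, z0)
  # zero offsets: every individual sits at the link-transformed location
  for (i in 2:6) expect_equal(th0[i, ], th0[1, ])
  expect_equal(unname(th0[1, "alpha"]), phi_approx(0.3))
  expect_equal(unname(th0[1, "xi"]), exp(1.2))
  expect_equal(unname(th0[1, "e0"]), 50)
  # zero group scale: complete pooling whatever the offsets
  z <- matrix(rnorm(30), 6, 5)
  thp <- natural_params(m, mu, rep(0, 5), z)
  for (i in 2:6) expect_equal(thp[i, ], thp[1, ])
  # (0,1) link respects its bounds over a wide raw range
  th_wide <- natural_params(m, mu, sig, matrix(seq(-8, 8, length = 30), 6, 5))
  expect_true(all(th_wide[, "alpha"] > 0 & th_wide[, "alpha"] < 1))
  expect_true(all(th_wide[, "gamma"] > 0 & th_wide[, "gamma"] < 1))
  expect_true(all(th_wide[, "xi"] > 0))
})

test_that("sampling is reproducible and respects its preconditions", {
  study <- simulate_study("random", 2, seed = 51,
                          condition = make_condition("low", "low",
                                                     n_trials = 20))
  cfg <- fit_config(chains = 2, warmup = 200, samples = 200, seed = 5)
  f1 <- sample_posterior(study$trials, "random", cfg)
  f2 <- sample_posterior(study$trials, "random", cfg)
  expect_identical(lapply(f1$samples, as.matrix),
                   lapply(f2$samples, as.matrix))
  expect_identical(f1$loglik, f2$loglik)
  one <- dplyr::filter(study$trials, participant == 1)
  expect_error(sample_posterior(one, "random", cfg), ">= 2 participants")
  two_cond <- dplyr::mutate(study$trials,
                            condition = rep(c("a", "b"), length.out = dplyr::n()))
  expect_error(sample_posterior(two_cond, "random", cfg), "one condition")
})

test_that("posterior mean matches the conjugate oracle on a toy problem", {
  # Two subjects responding around constant levels with fixed confidence:
  # conditional on the (tightly estimated) response noise, each subject's
  # level has a conjugate Normal posterior essentially at the sample mean,
  # because the group-level prior is far wider than the likelihood.
  set.seed(61)
  truth <- c(44, 58)
  d <- purrr::map_dfr(1:2, function(i) {
    tibble::tibble(
      participant = i, trial = 1:100, input = 50,
      response_type = rep(c("perception", "prediction"), 50),
      response = rnorm(100, truth[i], 8), confidence = 1
    )
  })
  fit <- sample_posterior(d, "random",
                          fit_config(chains = 2, warmup = 500,
                                     samples = 500, seed = 7))
  est <- individual_posterior_means(fit)
  xbar <- tapply(d$response, d$participant, mean)
  expect_equal(est$r0, as.numeric(xbar), tolerance = 0.5)
})

test_that("split R-hat and ESS behave on constructed chains", {
  set.seed(71)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_lt(rhat(iid), 1.01)
  expect_equal(ess_bulk(iid), 4000, tolerance = 0.1)
  expect_equal(ess_tail(iid), 4000, tolerance = 0.15)
  shifted <- iid + rep(c(0, 0, 0, 3), each = 1000)
  expect_gt(rhat(shifted), 1.1)
  # agreement with an independent PSRF implementation on the same chains
  ml <- coda::mcmc.list(lapply(1:4, function(c) coda::mcmc(shifted[, c])))
  gd <- coda::gelman.diag(ml)$psrf[1, 1]
  expect_gt(gd, 1.1)
  ml2 <- coda::mcmc.list(lapply(1:4, function(c) coda::mcmc(iid[, c])))
  expect_lt(coda::gelman.diag(ml2)$psrf[1, 1], 1.01)
  expect_error(rhat(matrix(rnorm(100), 100, 1)), "2 chains")
  # autocorrelated chains have reduced ESS
  ar <- apply(matrix(rnorm(4000), 1000, 4), 2,
              function(x) as.numeric(stats::filter(x, 0.9, "recursive")))
  expect_lt(ess_bulk(ar), 1500)
})

test_that("diagnostics cover group, offset and natural parameters", {
  study <- simulate_study("random", 2, seed = 52,
                          condition = make_condition("low", "low",
                                                     n_trials = 20))
  fit <- sample_posterior(study$trials, "random",
                          fit_config(chains = 2, warmup = 200,
                                     samples = 200, seed = 9))
  d <- diagnostics(fit)
  expect_true(all(c("mu[1]", "sig[1]", "z[1,1]", "theta[1,1]") %in%
                    d$parameter))
  expect_equal(nrow(d), 3 + 3 + 2 * 3 + 2 * 3)
  expect_true(all(c("rhat", "ess_bulk", "ess_tail") %in% names(d)))
  single <- fit
  single$samples <- fit$samples[1]
  expect_error(diagnostics(single), "2 chains")
  # merged draw extraction on both levels
  g <- param_draws(fit, "r0", "group")
  expect_length(g, 2 * 200)
  ind <- param_draws(fit, "r0", "individual", participant = 1)
  expect_length(ind, 2 * 200)
  expect_true(all(is.finite(ind)))
  expect_error(param_draws(fit, "alpha"), "Unknown parameter")
  expect_error(param_draws(fit, "r0", "individual", participant = 99),
               "participant")
})

test_that("eKF group parameters are at least fairly recoverable", {
  # reliability surface of the modelling pipeline: correlation between
  # generating and estimated individual-level parameters for the eKF
  ref <- ekf_reference_fit()
  est <- individual_posterior_means(ref$fit)
  truth <- ref$study$true_params
  for (p in c("s", "xi", "e0")) {
    expect_gt(cor(truth[[p]], est[[p]]), 0.5)
  }
})

test_that("posteriors agree with an independent MCMC engine", {
  # JAGS fit of the identical model (same priors, links, likelihood,
  # generated BUGS program) as an external oracle; individual-level
  # posteriors are data-dominated and must agree closely
  requireNamespace("rjags", quietly = TRUE)
  set.seed(63)
  truth <- c(44, 58)
  d <- purrr::map_dfr(1:2, function(i) {
    tibble::tibble(
      participant = i, trial = 1:100, input = 50,
      response_type = rep(c("perception", "prediction"), 50),
      response = rnorm(100, truth[i], 8), confidence = 1
    )
  })
  fit <- sample_posterior(d, "random",
                          fit_config(chains = 2, warmup = 1000,
                                     samples = 2000, seed = 7))
  m <- build_model("random")
  jd <- list(
    I = 2, T = 100, K = 3,
    N = rbind(d$input[1:100], d$input[101:200]),
    conf = matrix(1, 2, 100),
    isperc = rbind(
      as.integer(d$response_type[1:100] == "perception"),
      as.integer(d$response_type[101:200] == "perception")
    ),
    Nobs = 200, respall = d$response,
    suba = rep(1:2, each = 100), tra = rep(1:100, 2),
    Nfit = 200, respfit = d$response,
    subf = rep(1:2, each = 100), trf = rep(1:100, 2)
  )
  jm <- suppressWarnings(rjags::jags.model(
    textConnection(m$bugs), data = jd, n.chains = 2,
    inits = lapply(1:2, function(c) {
      list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = c)
    }),
    n.adapt = 1000, quiet = TRUE
  ))
  stats::update(jm, 1000, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("theta"), n.iter = 2000,
                            progress.bar = "none")
  jags_draws <- do.call(rbind, lapply(sm, as.matrix))
  own_draws <- do.call(rbind, lapply(fit$samples, as.matrix))
  for (v in c("theta[1,1]", "theta[2,1]", "theta[1,2]", "theta[2,2]")) {
    expect_equal(mean(own_draws[, v]), mean(jags_draws[, v]),
                 tolerance = 0.02)
    expect_equal(sd(own_draws[, v]), sd(jags_draws[, v]), tolerance = 0.15)
  }
})
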