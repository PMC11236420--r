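#' Observer-model parameter constructors
#'
#' Each of the five observer models has its own free parameters, all on the
#' 0-100 response scale unless noted:
#'
#' * `rl_params()`: Rescorla-Wagner delta-rule learner with constant learning
#'   rate `alpha` in \[0,1\], response noise `xi` > 0, initial expectation
#'   `e0`, and confidence scaling factor `c_scale` > 0.
#' * `erl_params()`: adds the perceptual weight `gamma` in \[0,1\] mixing the
#'   prior expectation into reported perception.
#' * `kf_params()`: Kalman-filter learner with subjective stochasticity `s`
#'   (observation noise sd), volatility `v` (random-walk drift sd), `xi`,
#'   `e0`, initial uncertainty `w0` (sd) and `c_scale`.
#' * `ekf_params()`: adds the subjective noise `epsilon` >= 0 that makes the
#'   input an imperfect indicator of the true pain level; the trial-wise
#'   perceptual weight becomes `gamma_t = epsilon^2 / (epsilon^2 + s^2 +
#'   w_t^2)`.
#' * `random_params()`: baseline that responds around a constant `r0` with
#'   confidence-scaled noise.
#'
#' @param alpha Learning rate in \[0,1\].
#' @param xi Response noise sd (> 0), response-scale units.
#' @param e0 Initial expectation, response-scale units.
#' @param c_scale Confidence scaling factor C (> 0).
#' @param gamma Perceptual weight in \[0,1\].
#' @param s,v Subjective stochasticity and volatility sds (> 0).
#' @param w0 Initial belief uncertainty sd (> 0).
#' @param epsilon Subjective noise sd (>= 0).
#' @param r0 Constant response level.
#' @return A classed list of parameters (`painseq_params`).
#' @name model_params
NULL

new_params <- function(model, values) {
  structure(c(list(model = model), values),
            class = c(paste0(model, "_params"), "painseq_params"))
}

#' @rdname model_params
#' @export
rl_params <- function(alpha, xi, e0, c_scale) {
  check_scalar_number(alpha, "alpha", 0, 1)
  check_scalar_number(xi, "xi", 0, closed_lower = FALSE)
  check_scalar_number(e0, "e0")
  check_scalar_number(c_scale, "c_scale", 0, closed_lower = FALSE)
  new_params("rl", list(alpha = alpha, xi = xi, e0 = e0, c_scale = c_scale))
}

#' @rdname model_params
#' @export
erl_params <- function(alpha, xi, e0, c_scale, gamma) {
  p <- rl_params(alpha, xi, e0, c_scale)
  check_scalar_number(gamma, "gamma", 0, 1)
  new_params("erl", c(unclass(p)[-1], list(gamma = gamma)))
}

#' @rdname model_params
#' @export
kf_params <- function(s, v, xi, e0, w0, c_scale) {
  check_scalar_number(s, "s", 0, closed_lower = FALSE)
  check_scalar_number(v, "v", 0)
  check_scalar_number(xi, "xi", 0, closed_lower = FALSE)
  check_scalar_number(e0, "e0")
  check_scalar_number(w0, "w0", 0, closed_lower = FALSE)
  check_scalar_number(c_scale, "c_scale", 0, closed_lower = FALSE)
  new_params("kf", list(s = s, v = v, xi = xi, e0 = e0, w0 = w0,
                        c_scale = c_scale))
}

#' @rdname model_params
#' @export
ekf_params <- function(epsilon, s, v, xi, e0, w0, c_scale) {
  p <- kf_params(s, v, xi, e0, w0, c_scale)
  check_scalar_number(epsilon, "epsilon", 0)
  new_params("ekf", c(list(epsilon = epsilon), unclass(p)[-1]))
}

#' @rdname model_params
#' @export
random_params <- function(r0, xi, c_scale) {
  check_scalar_number(r0, "r0")
  check_scalar_number(xi, "xi", 0, closed_lower = FALSE)
  check_scalar_number(c_scale, "c_scale", 0, closed_lower = FALSE)
  new_params("random", list(r0 = r0, xi = xi, c_scale = c_scale))
}

#' @export
print.painseq_params <- function(x, ...) {
  vals <- unlist(x[-1])
  cat("<", x$model, " parameters> ",
      paste(names(vals), signif(vals, 4), sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

model_ids <- function() c("rl", "erl", "kf", "ekf", "random")

#' Confidence-scaled response noise
#'
#' Maps a trial's confidence rating into the standard deviation of the
#' response distribution: `xi * exp((1 - confidence) / c_scale)`. At full
#' confidence the sd is the raw response noise `xi`; as confidence drops the
#' sd inflates, the more steeply the smaller the confidence scaling factor
#' `c_scale`. As `c_scale` grows the effect of confidence vanishes.
#'
#' @param xi Response noise sd (> 0).
#' @param c_scale Confidence scaling factor (> 0).
#' @param confidence Confidence rating(s) in \[0,1\] (vectorised).
#' @return Standard deviation(s), same length as `confidence`.
#' @examples
#' confidence_noise_scale(10, 1, c(0, 0.5, 1))
#' @export
confidence_noise_scale <- function(xi, c_scale, confidence) {
  check_scalar_number(xi, "xi", 0, closed_lower = FALSE)
  check_scalar_number(c_scale, "c_scale", 0, closed_lower = FALSE)
  if (!is.numeric(confidence) || anyNA(confidence) ||
      any(confidence < 0 | confidence > 1)) {
    abort("`confidence` must be numeric in [0, 1].")
  }
  xi * exp((1 - confidence) / c_scale)
}

#' One trial of the (e)RL delta-rule update
#'
#' Given the current expectation and the trial's input, returns the modelled
#' perception and the updated expectation. For the plain RL model perception
#' equals the input and the prediction error is `input - expectation`; for
#' the expectation-weighted eRL, perception is the convex combination
#' `(1 - gamma) * input + gamma * expectation` and the prediction error is
#' taken from that weighted percept.
#'
#' @param expectation Current expectation `E_t`.
#' @param input Trial input `N_t` (response scale).
#' @param params [rl_params()] or [erl_params()].
#' @return List with `perceived` (`P_t`) and `expectation_next` (`E_{t+1}`).
#' @export
rl_step <- function(expectation, input, params) {
  stopifnot(inherits(params, "painseq_params"),
            params$model %in% c("rl", "erl"),
            is.finite(expectation), is.finite(input))
  gamma <- params$gamma %||% 0
  p <- (1 - gamma) * input + gamma * expectation
  delta <- p - expectation    # reduces to input - expectation when gamma = 0
  list(perceived = p, expectation_next = expectation + params$alpha * delta)
}

#' One trial of the (e)KF Bayesian filter update
#'
#' Propagates the belief about the latent mean pain level through one
#' observation. The Kalman gain is `w2 / (w2 + s^2)` for the KF and
#' `w2 / (epsilon^2 + w2 + s^2)` for the eKF; the posterior predictive belief
#' for the next trial inflates by the volatility drift `v^2`. For the eKF the
#' modelled perception mixes the prior mean into the input with weight
#' `gamma_t = epsilon^2 / (epsilon^2 + s^2 + w2)`; for the KF perception is
#' the input itself.
#'
#' @param mean Current belief mean `m_t`.
#' @param variance Current belief variance `w_t^2` (> 0).
#' @param input Trial input `N_t`.
#' @param params [kf_params()] or [ekf_params()].
#' @return List with `perceived`, `mean_next`, `variance_next`, `gain`
#'   (trial-wise learning rate `alpha_t`) and `gamma_t` (0 for the KF).
#' @export
kf_step <- function(mean, variance, input, params) {
  stopifnot(inherits(params, "painseq_params"),
            params$model %in% c("kf", "ekf"),
            is.finite(mean), is.finite(input))
  if (!is.numeric(variance) || variance <= 0) {
    abort("`variance` (w_t^2) must be > 0.")
  }
  eps2 <- (params$epsilon %||% 0)^2
  s2 <- params$s^2
  gamma_t <- eps2 / (eps2 + s2 + variance)
  gain <- variance / (eps2 + variance + s2)
  p <- gamma_t * mean + (1 - gamma_t) * input
  list(
    perceived = p,
    mean_next = mean + gain * (input - mean),
    variance_next = variance * (1 - gain) + params$v^2,
    gain = gain,
    gamma_t = gamma_t
  )
}

#' Gaussian log-likelihood of one response
#'
#' Log-density of a rated response under the model's trial distribution: a
#' Gaussian centred on the modelled perception (perception trials) or the
#' updated expectation (prediction trials), with confidence-scaled sd.
#' The Gaussian is untruncated even though the rating scale is bounded.
#'
#' @param response Observed rating (vectorised).
#' @param mean Modelled mean (vectorised).
#' @param xi,c_scale,confidence As in [confidence_noise_scale()].
#' @return Log-density value(s).
#' @export
trial_loglik <- function(response, mean, xi, c_scale, confidence) {
  sdv <- confidence_noise_scale(xi, c_scale, confidence)
  dnorm(response, mean = mean, sd = sdv, log = TRUE)
}

#' Run an observer model over a trial table
#'
#' Deterministically orchestrates the per-trial updates of one model over a
#' single participant-condition trial table: the belief is updated from the
#' input on every trial regardless of the question asked, the modelled
#' response mean is the perception `P_t` on perception trials and the
#' post-update expectation `E_{t+1}` on prediction trials, and the Gaussian
#' log-likelihood is evaluated wherever a response is present.
#'
#' @param data Trial tibble with columns `input`, `response_type`,
#'   `confidence` and (optionally) `response` — see [make_trials()].
#' @param params A [model_params] object; its `model` field selects the
#'   update rule.
#' @return The input tibble with added columns `perceived` (`P_t`),
#'   `expectation_next` (`E_{t+1}`), `model_mean` (the mean actually rated
#'   against), `model_sd`, and `loglik` (NA where `response` is missing).
#'   The total log-likelihood over answered trials is in attribute
#'   `total_loglik`; the number of unanswered trials in `n_missing`.
#' @examples
#' trials <- make_trials(
#'   generate_sequence(make_condition("low", "low"), seed = 1),
#'   generate_schedule(80, seed = 2)
#' )
#' trials$confidence <- 0.8
#' out <- run_model(trials, rl_params(0.3, 5, 40, 1))
#' attr(out, "total_loglik")
#' @export
run_model <- function(data, params) {
  stopifnot(inherits(params, "painseq_params"))
  need <- c("input", "response_type", "confidence")
  if (!all(need %in% names(data))) {
    abort(paste("`data` must have columns:", paste(need, collapse = ", ")))
  }
  n <- nrow(data)
  if (!"response" %in% names(data)) data$response <- NA_real_
  if (anyNA(data$input) || anyNA(data$confidence) ||
      anyNA(data$response_type)) {
    abort("`input`, `response_type` and `confidence` must be complete.")
  }
  if (!all(data$response_type %in% c("perception", "prediction"))) {
    abort("`response_type` must be \"perception\" or \"prediction\".")
  }

  perceived <- numeric(n)
  e_next <- numeric(n)
  model <- params$model
  if (model %in% c("rl", "erl")) {
    e <- params$e0
    for (t in seq_len(n)) {
      st <- rl_step(e, data$input[t], params)
      perceived[t] <- st$perceived
      e <- st$expectation_next
      e_next[t] <- e
    }
  } else if (model %in% c("kf", "ekf")) {
    m <- params$e0
    w2 <- params$w0^2
    for (t in seq_len(n)) {
      st <- kf_step(m, w2, data$input[t], params)
      perceived[t] <- st$perceived
      m <- st$mean_next
      w2 <- st$variance_next
      e_next[t] <- m
    }
  } else if (model == "random") {
    perceived[] <- params$r0
    e_next[] <- params$r0
  } else {
    abort(sprintf("Unknown model id: %s", model))
  }

  model_mean <- ifelse(data$response_type == "perception", perceived, e_next)
  model_sd <- confidence_noise_scale(params$xi, params$c_scale,
                                     data$confidence)
  ll <- ifelse(
    is.na(data$response), NA_real_,
    dnorm(data$response, model_mean, model_sd, log = TRUE)
  )
  out <- dplyr::mutate(
    as_tibble(data),
    perceived = perceived,
    expectation_next = e_next,
    model_mean = model_mean,
    model_sd = model_sd,
    loglik = ll
  )
  attr(out, "total_loglik") <- sum(ll, na.rm = TRUE)
  attr(out, "n_missing") <- sum(is.na(data$response))
  out
}

#' Simulate responses from an observer model
#'
#' Draws trial-wise responses from the model's Gaussian response
#' distribution over a trial table (replacing any existing `response`
#' column). Confidence ratings must already be present.
#'
#' @inheritParams run_model
#' @param seed Integer seed recorded in attribute `seed`.
#' @return The trial tibble with simulated `response` values.
#' @export
simulate_responses <- function(data, params, seed) {
  data$response <- NULL
  traj <- run_model(data, params)
  resp <- with_seed(seed, rnorm(nrow(traj), traj$model_mean, traj$model_sd))
  out <- dplyr::mutate(
    as_tibble(data)[setdiff(names(data), "response")],
    response = resp,
    .after = "response_type"
  )
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Steady-state belief variance of the Kalman filter
#'
#' Fixed point of the variance recursion `w2 -> w2 * s^2 / (w2 + s^2) + v^2`,
#' solved in closed form; the filter's trial-wise uncertainty converges here
#' from any positive start.
#'
#' @param s,v Stochasticity and volatility sds.
#' @param epsilon Optional subjective noise sd (eKF); the effective
#'   observation sd becomes `sqrt(s^2 + epsilon^2)`.
#' @return The stationary variance `w2`.
#' @export
kf_stationary_variance <- function(s, v, epsilon = 0) {
  o2 <- s^2 + epsilon^2
  v2 <- v^2
  # w2 = w2*o2/(w2+o2) + v2  =>  w2^2 - v2*w2 - v2*o2 = 0
  (v2 + sqrt(v2^2 + 4 * v2 * o2)) / 2
}
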