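#' Sample participant input-transform coefficients
#'
#' Draws (slope, intercept) pairs from independent Gaussians, emulating the
#' population spread of participants' intensity-to-rating transforms.
#' Negative slopes are rejected and redrawn (a rating scale that decreases
#' with intensity indicates an inverted response). The defaults are
#' synthetic stand-ins for a distribution that, in a real study, would be
#' estimated from the participants' own transforms.
#'
#' @param n Number of pairs.
#' @param slope_mean,slope_sd,intercept_mean,intercept_sd Gaussian
#'   parameters (response units per level; response units).
#' @param seed Integer seed.
#' @return Tibble with `slope` and `intercept`; attribute `degenerate`
#'   flags a zero-variance distribution.
#' @export
sample_transform_coefficients <- function(n,
                                          slope_mean = 5, slope_sd = 1,
                                          intercept_mean = 15,
                                          intercept_sd = 5,
                                          seed) {
  stopifnot(n >= 1, slope_sd >= 0, intercept_sd >= 0)
  if (slope_mean <= 0 && slope_sd == 0) {
    abort("Degenerate distribution with non-positive slope mean.")
  }
  out <- with_seed(seed, {
    slopes <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        sl <- rnorm(1, slope_mean, slope_sd)
        if (sl > 0) break
      }
      slopes[i] <- sl
    }
    tibble(slope = slopes,
           intercept = rnorm(n, intercept_mean, intercept_sd))
  })
  attr(out, "degenerate") <- slope_sd == 0 && intercept_sd == 0
  out
}

#' Simulate confidence ratings from local sequence stability
#'
#' Confidence on trial t is the lag-1 autocorrelation of the trailing
#' moving window of the transformed input sequence, mapped affinely from
#' \[-1, 1\] onto \[0, 1\] (`(r + 1) / 2`) and clipped. A locally smooth,
#' predictable stretch of the sequence therefore yields high confidence; an
#' alternating, noisy stretch yields low confidence. Trials before the
#' first complete window inherit the first complete-window value; a
#' zero-variance window (undefined correlation) maps to 0.5.
#'
#' @param x Numeric transformed input sequence.
#' @param window Window length in trials (>= 3).
#' @return Numeric vector of confidences in \[0, 1\], same length as `x`.
#' @export
simulate_confidence <- function(x, window = 10) {
  check_scalar_number(window, "window", lower = 3)
  n <- length(x)
  if (n < window) abort("Sequence shorter than the confidence window.")
  conf <- rep(NA_real_, n)
  for (t in window:n) {
    w <- x[(t - window + 1):t]
    a <- w[-length(w)]
    b <- w[-1]
    if (sd(a) == 0 || sd(b) == 0) {
      conf[t] <- 0.5
    } else {
      r <- cor(a, b)
      conf[t] <- min(1, max(0, (r + 1) / 2))
    }
  }
  conf[seq_len(window - 1)] <- conf[window]
  conf
}

# Group-level generative settings (location/scale on the unconstrained link
# scale) used by the synthetic studies. Chosen once to give plausible
# rating behaviour on the 0-100 scale; see the methods vignette.
#' Default group-level generative configuration for synthetic studies
#'
#' @param model_id Model id string.
#' @return Tibble with `name`, `location`, `scale` (unconstrained scale).
#' @export
default_group_config <- function(model_id) {
  cfg <- switch(model_id,
    rl = tibble(
      name = c("alpha", "xi", "e0", "c_scale"),
      location = c(0, log(5), 1, log(1.5)),
      scale = c(0.8, 0.25, 0.1, 0.25)
    ),
    erl = tibble(
      name = c("alpha", "xi", "e0", "c_scale", "gamma"),
      location = c(0, log(5), 1, log(1.5), -0.5),
      scale = c(0.8, 0.25, 0.1, 0.25, 0.5)
    ),
    kf = tibble(
      name = c("s", "v", "xi", "e0", "w0", "c_scale"),
      location = c(log(7), log(3), log(5), 1, log(5), log(1.5)),
      scale = c(0.25, 0.25, 0.25, 0.1, 0.25, 0.25)
    ),
    ekf = tibble(
      name = c("epsilon", "s", "v", "xi", "e0", "w0", "c_scale"),
      location = c(log(8), log(7), log(3), log(5), 1, log(5), log(1.5)),
      scale = c(0.3, 0.25, 0.25, 0.25, 0.1, 0.25, 0.25)
    ),
    random = tibble(
      name = c("r0", "xi", "c_scale"),
      location = c(1, log(8), log(1.5)),
      scale = c(0.15, 0.25, 0.25)
    ),
    abort(sprintf("Unknown model id: %s", model_id))
  )
  cfg
}

params_from_row <- function(model_id, values) {
  vals <- as.list(values)
  switch(model_id,
    rl = rl_params(vals$alpha, vals$xi, vals$e0, vals$c_scale),
    erl = erl_params(vals$alpha, vals$xi, vals$e0, vals$c_scale,
                     vals$gamma),
    kf = kf_params(vals$s, vals$v, vals$xi, vals$e0, vals$w0,
                   vals$c_scale),
    ekf = ekf_params(vals$epsilon, vals$s, vals$v, vals$xi, vals$e0,
                     vals$w0, vals$c_scale),
    random = random_params(vals$r0, vals$xi, vals$c_scale)
  )
}

#' Draw individual-level parameters from the group-level distribution
#'
#' Raw values are drawn from `N(location, scale)` per parameter and pushed
#' through the model's links — the same generative structure the
#' hierarchical fit assumes.
#'
#' @param model_id Model id string.
#' @param n_subjects Number of subjects.
#' @param group_config Tibble as from [default_group_config()].
#' @param seed Integer seed.
#' @return Tibble of natural-scale parameters, one row per subject.
#' @export
draw_subject_params <- function(model_id, n_subjects,
                                group_config = default_group_config(model_id),
                                seed) {
  tbl <- param_table(model_id)
  stopifnot(identical(group_config$name, tbl$name))
  raw <- with_seed(seed, {
    vapply(seq_len(nrow(tbl)), function(k) {
      rnorm(n_subjects, group_config$location[k], group_config$scale[k])
    }, numeric(n_subjects))
  })
  raw <- matrix(raw, nrow = n_subjects)
  nat <- vapply(seq_len(nrow(tbl)), function(k) {
    link_fun(tbl$link[k])(raw[, k])
  }, numeric(n_subjects))
  nat <- matrix(nat, nrow = n_subjects)
  colnames(nat) <- tbl$name
  dplyr::bind_cols(tibble(participant = seq_len(n_subjects)),
                   as_tibble(nat))
}

#' Simulate a full synthetic study for one model and condition
#'
#' For each synthetic subject: generate a fresh noxious-input sequence under
#' the condition, a perception/prediction schedule, a participant-specific
#' linear input transform (sampled from the transform-coefficient
#' distribution), confidence ratings from the lag-1 autocorrelation of the
#' transformed inputs, and model-generated responses with
#' confidence-scaled Gaussian noise.
#'
#' @param model_id Model generating the responses.
#' @param n_subjects Number of synthetic subjects.
#' @param seed Integer seed; all per-subject seeds derive from it.
#' @param condition A [make_condition()] spec (defaults to low volatility,
#'   low stochasticity).
#' @param group_config Group-level generative settings
#'   ([default_group_config()]); pass a modified tibble to change the study
#'   population.
#' @param window Confidence-simulation window ([simulate_confidence()]).
#' @param coef_args List of arguments to [sample_transform_coefficients()].
#' @return List with `trials` (all subjects' trial tibble), `true_params`
#'   (generating natural-scale parameters), `transforms`, `condition`,
#'   `seed`.
#' @export
simulate_study <- function(model_id, n_subjects, seed,
                           condition = make_condition("low", "low"),
                           group_config = default_group_config(model_id),
                           window = 10,
                           coef_args = list()) {
  stopifnot(n_subjects >= 1)
  true_params <- draw_subject_params(model_id, n_subjects, group_config,
                                     seed = child_seed(seed, 1))
  coefs <- do.call(sample_transform_coefficients,
                   c(list(n = n_subjects, seed = child_seed(seed, 2)),
                     coef_args))
  trials <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    sq <- generate_sequence(condition, seed = child_seed(seed, 100 + i))
    sch <- generate_schedule(condition$n_trials,
                             seed = child_seed(seed, 300 + i))
    tr <- input_transform(coefs$slope[i], coefs$intercept[i])
    d <- make_trials(sq, sch, transform = tr, participant = i)
    d$confidence <- simulate_confidence(d$input, window = window)
    pars <- params_from_row(model_id, true_params[i, -1])
    simulate_responses(d, pars, seed = child_seed(seed, 500 + i))
  })
  list(trials = trials, true_params = true_params, transforms = coefs,
       condition = condition, seed = as.integer(seed))
}

#' Recovery quality category for a correlation
#'
#' Grades a generating-vs-estimated Pearson correlation: poor (r < 0.5),
#' fair (0.5-0.75), good (0.75-0.9), excellent (r > 0.9).
#'
#' @param r Pearson correlation(s).
#' @return Character vector of categories.
#' @export
recovery_category <- function(r) {
  dplyr::case_when(
    is.na(r) ~ NA_character_,
    r < 0.5 ~ "poor",
    r < 0.75 ~ "fair",
    r <= 0.9 ~ "good",
    TRUE ~ "excellent"
  )
}

#' Parameter-recovery study
#'
#' Simulates a synthetic study from a model ([simulate_study()]), refits the
#' same model hierarchically, and correlates the generating individual-level
#' parameters with their posterior means.
#'
#' @inheritParams simulate_study
#' @param config Sampler configuration ([fit_config()]).
#' @param ... Passed to [simulate_study()].
#' @return A `recovery_report` tibble with `parameter`, `r`, `category`;
#'   attributes `fit`, `true_params`, `estimates`, `n_subjects`, `seed`,
#'   `converged`.
#' @export
parameter_recovery <- function(model_id, n_subjects = 12, seed,
                               config = fit_config(seed = child_seed(seed, 9)),
                               ...) {
  if (n_subjects < 8) {
    abort("Need >= 8 subjects for a meaningful recovery correlation.")
  }
  study <- simulate_study(model_id, n_subjects, seed, ...)
  fit <- sample_posterior(study$trials, build_model(model_id), config)
  est <- individual_posterior_means(fit)
  pars <- param_table(model_id)$name
  out <- purrr::map_dfr(pars, function(p) {
    tibble(
      parameter = p,
      r = cor(study$true_params[[p]], est[[p]]),
      category = recovery_category(cor(study$true_params[[p]], est[[p]]))
    )
  })
  converged <- all(fit$diagnostics$rhat < 1.1, na.rm = TRUE)
  if (!converged) {
    warning("Recovery refit did not fully converge (max R-hat >= 1.1); ",
            "correlations reported anyway.", call. = FALSE)
  }
  structure(
    out,
    fit = fit, true_params = study$true_params, estimates = est,
    n_subjects = n_subjects, seed = as.integer(seed),
    converged = converged,
    class = c("recovery_report", class(out))
  )
}

#' @rdname parameter_recovery
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$parameter, y = .data$r,
                                  fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(0.5, 0.75, 0.9), linetype = 3) +
    ggplot2::scale_fill_manual(values = c(
      poor = "#d73027", fair = "#fdae61", good = "#a6d96a",
      excellent = "#1a9850"
    ), drop = FALSE) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(y = "Generating vs estimated Pearson r", x = NULL) +
    ggplot2::theme_minimal()
}

#' Model-recovery study (confusion matrix)
#'
#' Simulates datasets from each generating model, fits every candidate
#' model to each dataset, and tallies which model wins by LOOIC. Ties split
#' the count equally (flagged via attribute `ties`).
#'
#' @param model_ids Character vector of generating (= candidate) models.
#' @param n_per_model Simulated datasets per generating model.
#' @param n_subjects Subjects per dataset.
#' @param seed Integer seed.
#' @param config Sampler configuration shared by all fits.
#' @param ... Passed to [simulate_study()] (e.g. `condition`).
#' @return A `confusion_matrix`: square counts matrix (rows = generating
#'   model, columns = best-fitting model), with attributes `comparisons`
#'   (list of `model_comparison` tibbles, one per dataset, named
#'   `<generator>_<replicate>`) and `ties`.
#' @export
model_recovery <- function(model_ids = c("rl", "erl", "kf", "ekf", "random"),
                           n_per_model = 1,
                           n_subjects = 8, seed,
                           config = fit_config(seed = child_seed(seed, 9)),
                           ...) {
  stopifnot(length(model_ids) >= 1, n_per_model >= 1)
  M <- length(model_ids)
  cm <- matrix(0, M, M, dimnames = list(
    generating = model_ids, best = model_ids
  ))
  comparisons <- list()
  ties <- 0L
  for (g in seq_len(M)) {
    for (ri in seq_len(n_per_model)) {
      dseed <- child_seed(seed, g * 37 + ri)
      study <- simulate_study(model_ids[g], n_subjects, dseed, ...)
      fits <- purrr::map(model_ids, function(mid) {
        sample_posterior(study$trials, build_model(mid), config)
      })
      names(fits) <- model_ids
      comp <- suppressWarnings(compare_models(fits))
      comparisons[[paste0(model_ids[g], "_", ri)]] <- comp
      best_looic <- min(comp$looic)
      winners <- comp$model[comp$looic == best_looic]
      if (length(winners) > 1) ties <- ties + 1L
      cm[g, winners] <- cm[g, winners] + 1 / length(winners)
    }
  }
  structure(cm, comparisons = comparisons, ties = ties,
            n_per_model = n_per_model,
            class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = generating model, cols = LOOIC winner\n")
  print(unclass(x)[, , drop = FALSE])
  if (attr(x, "ties") > 0) {
    cat(sprintf("(%d tie(s) split equally)\n", attr(x, "ties")))
  }
  invisible(x)
}
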