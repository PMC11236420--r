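#' Fit a hierarchical observer model by MCMC
#'
#' Samples the posterior of a [build_model()] specification for one
#' condition's trial data. Individual parameters use the non-centred
#' parametrisation; the likelihood jointly covers every answered perception
#' and prediction response of every participant. Trials with a missing
#' response are excluded from the likelihood (and from the pointwise
#' log-likelihood matrix) but still drive the belief updates.
#'
#' The sampler combines per-subject joint adaptive-Metropolis updates of
#' the non-centred offsets (proposal covariance learned during warmup, so
#' proposals align with the ridges among weakly separated noise
#' parameters) with an interweaving group step in which, holding the raw
#' individual values fixed, the group location is drawn from its conjugate
#' Normal conditional and the group scale is slice-sampled under its
#' half-Student-t(3,0,1) prior. See the methods vignette for the design
#' rationale and validation.
#'
#' @param data Trial tibble with columns `participant`, `trial`, `input`
#'   (already on the 0-100 response scale), `response_type`, `response`,
#'   `confidence`; a single condition (if a `condition` column is present it
#'   must be constant). At least 2 participants.
#' @param model A `painseq_model` from [build_model()], or a model id
#'   string.
#' @param config A [fit_config()].
#' @param holdout Integer indices of observation units (rows of the fit's
#'   `units` table) to leave out of the likelihood — used for exact
#'   leave-one-out cross-validation. Their pointwise log-likelihood is still
#'   recorded.
#' @return A `pain_fit` object with elements `samples` (a
#'   \pkg{coda}`::mcmc.list` over group locations `mu`, scales `sig`,
#'   offsets `z` and natural-scale individual parameters `theta`), `loglik`
#'   (draws x units matrix, chains merged), `units` (one row per answered
#'   response), `diagnostics` (split R-hat and bulk/tail ESS per
#'   parameter), `accept_rate` (post-warmup subject-block acceptance) and
#'   metadata. Reproducible: the same seed gives identical draws.
#' @export
sample_posterior <- function(data, model, config = fit_config(),
                             holdout = integer(0)) {
  if (is.character(model)) model <- build_model(model)
  stopifnot(inherits(model, "painseq_model"), inherits(config, "fit_config"))
  need <- c("participant", "trial", "input", "response_type", "response",
            "confidence")
  if (!all(need %in% names(data))) {
    abort(paste("`data` must have columns:", paste(need, collapse = ", ")))
  }
  if ("condition" %in% names(data) &&
      length(unique(data$condition)) > 1) {
    abort("Fit one condition at a time: `condition` is not constant.")
  }
  participants <- unique(data$participant)
  I <- length(participants)
  if (I < 2) abort("Hierarchical fitting needs >= 2 participants.")

  data <- dplyr::arrange(data, match(.data$participant, participants),
                         .data$trial)
  by_sub <- split(data, match(data$participant, participants))
  units <- vector("list", I)
  subs <- vector("list", I)
  for (i in seq_len(I)) {
    d <- by_sub[[i]]
    ans <- which(!is.na(d$response))
    subs[[i]] <- list(
      N = d$input,
      isperc = d$response_type == "perception",
      conf = d$confidence,
      resp = d$response,
      ans = ans,
      fit_mask = rep(TRUE, length(ans))
    )
    units[[i]] <- tibble(
      participant = participants[i], sub = i, tr = ans,
      trial = d$trial[ans], response_type = d$response_type[ans],
      response = d$response[ans]
    )
  }
  units <- dplyr::bind_rows(units)
  units$unit <- seq_len(nrow(units))
  if (nrow(units) == 0) abort("No answered trials to fit.")
  if (length(holdout) > 0 &&
      (any(holdout < 1) || any(holdout > nrow(units)))) {
    abort("`holdout` indices must address rows of the units table.")
  }
  unit_offsets <- split(units$unit, units$sub)
  for (h in holdout) {
    i <- units$sub[h]
    subs[[i]]$fit_mask[match(h, unit_offsets[[as.character(i)]])] <- FALSE
  }
  names(unit_offsets) <- NULL

  data_list <- list(I = I, subs = subs, n_units = nrow(units),
                    unit_offsets = unit_offsets)
  res <- with_seed(config$seed,
                   sample_posterior_mcmc(model, data_list, config))

  fit <- structure(
    list(
      model = model,
      config = config,
      samples = res$samples,
      loglik = res$loglik,
      units = units,
      holdout = as.integer(holdout),
      participants = participants,
      n_subjects = I,
      n_obs = nrow(units),
      accept_rate = res$accept_rate
    ),
    class = "pain_fit"
  )
  fit$diagnostics <- diagnostics(fit)
  fit
}

#' @export
print.pain_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    paste0("<pain_fit> %s model: %d subjects, %d responses; ",
           "%d chains x %d draws\n  max split R-hat = %.3f (%s)\n"),
    x$model$model_id, x$n_subjects, x$n_obs,
    x$config$chains, x$config$samples,
    max(d$rhat, na.rm = TRUE),
    if (all(d$rhat < 1.1, na.rm = TRUE)) "converged" else "NOT converged"
  ))
  invisible(x)
}

# draws of one monitored scalar node as an iterations x chains matrix
node_draws <- function(fit, node) {
  vn <- coda::varnames(fit$samples)
  if (!node %in% vn) abort(sprintf("No monitored node `%s`.", node))
  sapply(fit$samples, function(m) as.numeric(m[, node]))
}

#' Extract merged posterior draws of a parameter
#'
#' Group-level draws are the link-transformed group location (the
#' population-typical value of the parameter, on its natural scale);
#' individual-level draws are the natural-scale parameter of one
#' participant. Chains are merged (concatenated) as required for
#' HDI-based condition contrasts.
#'
#' @param fit A `pain_fit`.
#' @param parameter Parameter name (see `fit$model$params$name`).
#' @param level `"group"` or `"individual"`.
#' @param participant Participant id (for `level = "individual"`).
#' @return Numeric vector of merged posterior draws.
#' @export
param_draws <- function(fit, parameter, level = c("group", "individual"),
                        participant = NULL) {
  stopifnot(inherits(fit, "pain_fit"))
  level <- rlang::arg_match(level)
  tbl <- fit$model$params
  k <- tbl$k[tbl$name == parameter]
  if (length(k) != 1) {
    abort(sprintf("Unknown parameter `%s` for model %s.", parameter,
                  fit$model$model_id))
  }
  if (level == "group") {
    raw <- as.numeric(node_draws(fit, sprintf("mu[%d]", k)))
    link_fun(tbl$link[k])(raw)
  } else {
    i <- match(participant, fit$participants)
    if (is.na(i)) abort("Unknown `participant`.")
    as.numeric(node_draws(fit, sprintf("theta[%d,%d]", i, k)))
  }
}

#' Posterior means of individual-level parameters
#'
#' @param fit A `pain_fit`.
#' @return Tibble with `participant` and one column per model parameter
#'   (posterior means on the natural scale).
#' @export
individual_posterior_means <- function(fit) {
  stopifnot(inherits(fit, "pain_fit"))
  tbl <- fit$model$params
  out <- purrr::map_dfc(seq_len(nrow(tbl)), function(k) {
    means <- vapply(seq_len(fit$n_subjects), function(i) {
      mean(node_draws(fit, sprintf("theta[%d,%d]", i, k)))
    }, numeric(1))
    tibble(!!tbl$name[k] := means)
  })
  dplyr::bind_cols(tibble(participant = fit$participants), out)
}

#' @rdname sample_posterior
#' @param x A `pain_fit`.
#' @param ... Unused.
#' @method tidy pain_fit
#' @export
tidy.pain_fit <- function(x, ...) {
  tbl <- x$model$params
  group <- purrr::map_dfr(seq_len(nrow(tbl)), function(k) {
    draws <- link_fun(tbl$link[k])(
      as.numeric(node_draws(x, sprintf("mu[%d]", k)))
    )
    h <- hdi(draws)
    tibble(
      term = tbl$name[k], level = "group",
      participant = NA, estimate = mean(draws),
      std.error = sd(draws), conf.low = h[1], conf.high = h[2]
    )
  })
  indiv <- purrr::map_dfr(seq_len(nrow(tbl)), function(k) {
    purrr::map_dfr(seq_len(x$n_subjects), function(i) {
      draws <- as.numeric(node_draws(x, sprintf("theta[%d,%d]", i, k)))
      h <- hdi(draws)
      tibble(
        term = tbl$name[k], level = "individual",
        participant = x$participants[i], estimate = mean(draws),
        std.error = sd(draws), conf.low = h[1], conf.high = h[2]
      )
    })
  })
  dplyr::bind_rows(group, indiv)
}

#' @rdname sample_posterior
#' @method glance pain_fit
#' @export
glance.pain_fit <- function(x, ...) {
  d <- x$diagnostics
  tibble(
    model = x$model$model_id,
    n_subjects = x$n_subjects,
    n_obs = x$n_obs,
    n_draws = x$config$chains * x$config$samples,
    max_rhat = max(d$rhat, na.rm = TRUE),
    min_ess_bulk = min(d$ess_bulk, na.rm = TRUE),
    min_ess_tail = min(d$ess_tail, na.rm = TRUE),
    converged = all(d$rhat < 1.1, na.rm = TRUE)
  )
}
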