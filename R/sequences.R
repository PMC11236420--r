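#' Define a sequence condition from volatility and stochasticity levels
#'
#' Builds the generative specification of one cell of the 2x2
#' volatility-by-stochasticity design. Volatility is operationalised through
#' the mean chunk length (fewer trials per chunk = more volatile); the
#' stochasticity level sets the trial-wise observation variance around the
#' latent chunk mean.
#'
#' Defaults: mean chunk length 15 (high volatility) or 25 (low), chunk-length
#' jitter 3, observation variance 1.75 (high stochasticity) or 0.25 (low),
#' chunk means uniform on \[3.5, 10.5\] with consecutive means at least 2
#' intensity levels apart, discrete intensities on \[1, 13\], 80 trials.
#'
#' @param volatility,stochasticity `"low"` or `"high"`.
#' @param mean_chunk_length Mean number of trials per chunk (`L`). Defaults to
#'   15 for high volatility, 25 for low.
#' @param length_jitter Half-width `a` of the uniform jitter on chunk length,
#'   so lengths are drawn uniformly from `L - a, ..., L + a`.
#' @param obs_variance Observation variance `sigma^2` of trial intensities
#'   around their chunk mean. Defaults to 1.75 for high stochasticity, 0.25
#'   for low.
#' @param mean_range Numeric length-2: support of the uniform distribution of
#'   chunk means, on the intensity scale.
#' @param min_mean_separation Minimum absolute difference between consecutive
#'   chunk means, in intensity levels.
#' @param intensity_range Integer length-2: valid discrete intensity levels.
#' @param n_trials Number of trials in the sequence.
#' @return An object of class `condition_spec` (a named list).
#' @examples
#' make_condition("high", "low")
#' @export
make_condition <- function(volatility = c("low", "high"),
                           stochasticity = c("low", "high"),
                           mean_chunk_length = NULL,
                           length_jitter = 3,
                           obs_variance = NULL,
                           mean_range = c(3.5, 10.5),
                           min_mean_separation = 2,
                           intensity_range = c(1L, 13L),
                           n_trials = 80L) {
  volatility <- rlang::arg_match(volatility)
  stochasticity <- rlang::arg_match(stochasticity)
  mean_chunk_length <- mean_chunk_length %||%
    switch(volatility, high = 15, low = 25)
  obs_variance <- obs_variance %||%
    switch(stochasticity, high = 1.75, low = 0.25)
  check_scalar_number(mean_chunk_length, "mean_chunk_length", lower = 1)
  check_scalar_number(length_jitter, "length_jitter", lower = 0)
  check_scalar_number(obs_variance, "obs_variance", lower = 0)
  check_scalar_number(min_mean_separation, "min_mean_separation", lower = 0)
  check_scalar_number(n_trials, "n_trials", lower = 1)
  stopifnot(length(mean_range) == 2, mean_range[1] < mean_range[2],
            length(intensity_range) == 2,
            intensity_range[1] < intensity_range[2])
  if (mean_chunk_length - length_jitter < 1) {
    abort("Smallest possible chunk length is below 1 trial.")
  }
  if (min_mean_separation > diff(mean_range)) {
    abort(paste(
      "`min_mean_separation` exceeds the width of `mean_range`:",
      "no admissible pair of consecutive chunk means exists."
    ))
  }
  structure(
    list(
      volatility = volatility,
      stochasticity = stochasticity,
      mean_chunk_length = mean_chunk_length,
      length_jitter = length_jitter,
      obs_variance = obs_variance,
      mean_range = as.numeric(mean_range),
      min_mean_separation = min_mean_separation,
      intensity_range = as.integer(intensity_range),
      n_trials = as.integer(n_trials)
    ),
    class = "condition_spec"
  )
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<condition_spec> volatility = %s (L = %g +/- %g), ",
      "stochasticity = %s (sigma^2 = %g)\n",
      "  chunk means ~ U(%g, %g), separation >= %g; ",
      "intensities in [%d, %d]; %d trials\n"
    ),
    x$volatility, x$mean_chunk_length, x$length_jitter,
    x$stochasticity, x$obs_variance,
    x$mean_range[1], x$mean_range[2], x$min_mean_separation,
    x$intensity_range[1], x$intensity_range[2], x$n_trials
  ))
  invisible(x)
}

#' Label for a condition, e.g. "lowS_highV"
#' @param spec A [make_condition()] object.
#' @return A string.
#' @export
condition_label <- function(spec) {
  stopifnot(inherits(spec, "condition_spec"))
  sprintf("%sS_%sV", spec$stochasticity, spec$volatility)
}

#' The four conditions of the 2x2 design
#'
#' @inheritParams make_condition
#' @return A named list of four `condition_spec` objects, named
#'   `lowS_lowV`, `highS_lowV`, `lowS_highV`, `highS_highV`.
#' @export
all_conditions <- function(n_trials = 80L) {
  grid <- expand.grid(stochasticity = c("low", "high"),
                      volatility = c("low", "high"),
                      stringsAsFactors = FALSE)
  specs <- purrr::pmap(grid, function(stochasticity, volatility) {
    make_condition(volatility, stochasticity, n_trials = n_trials)
  })
  names(specs) <- purrr::map_chr(specs, condition_label)
  specs
}

#' Generate one noxious-input sequence
#'
#' Samples a chunked intensity sequence under a condition specification.
#' Chunk means are drawn uniformly from the mean support, redrawing until a
#' new mean differs from its predecessor by at least the minimum separation.
#' Chunk lengths are drawn uniformly (integers) from `L - a, ..., L + a`;
#' chunks are appended until the sequence is long enough, and the last chunk
#' is truncated to fit. Trial values are drawn from a Gaussian centred on the
#' chunk mean with the condition's observation variance, then rounded to the
#' nearest integer level; a value whose rounding falls outside the valid
#' intensity range is discarded and redrawn (per trial, so the chunk
#' structure is preserved).
#'
#' @param spec A [make_condition()] specification.
#' @param seed Integer seed; all randomness in the sequence flows from it.
#' @return A tibble of class `pain_sequence` with columns `trial`,
#'   `intensity` (discrete level), `pre_disc` (the accepted Gaussian draw
#'   before rounding), `chunk_index`, `chunk_mean`. Attributes `condition`,
#'   `seed`, `chunk_means`, `chunk_lengths` (full drawn lengths, before
#'   truncation of the last chunk) and `chunk_truncated` record the
#'   generative state.
#' @examples
#' s <- generate_sequence(make_condition("high", "high"), seed = 1)
#' range(s$intensity)
#' @export
generate_sequence <- function(spec, seed) {
  stopifnot(inherits(spec, "condition_spec"))
  with_seed(seed, {
    means <- numeric(0)
    lengths <- integer(0)
    while (sum(lengths) < spec$n_trials) {
      repeat {
        m <- runif(1, spec$mean_range[1], spec$mean_range[2])
        if (length(means) == 0 ||
            abs(m - means[length(means)]) >= spec$min_mean_separation) break
      }
      means <- c(means, m)
      lo <- as.integer(round(spec$mean_chunk_length - spec$length_jitter))
      hi <- as.integer(round(spec$mean_chunk_length + spec$length_jitter))
      # draw uniformly on {lo, ..., hi}; sample(lo:hi, 1) misfires when
      # lo == hi (scalar expansion), so index explicitly
      lengths <- c(lengths, lo + sample.int(hi - lo + 1L, 1L) - 1L)
    }
    used_lengths <- lengths
    overshoot <- sum(lengths) - spec$n_trials
    truncated <- overshoot > 0
    used_lengths[length(used_lengths)] <-
      used_lengths[length(used_lengths)] - overshoot

    chunk_index <- rep(seq_along(used_lengths), used_lengths)
    chunk_mean <- means[chunk_index]
    sdv <- sqrt(spec$obs_variance)
    lo_i <- spec$intensity_range[1]
    hi_i <- spec$intensity_range[2]
    pre <- numeric(spec$n_trials)
    for (t in seq_len(spec$n_trials)) {
      repeat {
        x <- rnorm(1, chunk_mean[t], sdv)
        if (round(x) >= lo_i && round(x) <= hi_i) break
      }
      pre[t] <- x
    }
    out <- tibble(
      trial = seq_len(spec$n_trials),
      intensity = as.integer(round(pre)),
      pre_disc = pre,
      chunk_index = as.integer(chunk_index),
      chunk_mean = chunk_mean
    )
    structure(
      out,
      condition = spec,
      seed = as.integer(seed),
      chunk_means = means,
      chunk_lengths = lengths,
      chunk_truncated = truncated,
      class = c("pain_sequence", class(out))
    )
  })
}

#' Generate a perception/prediction trial schedule
#'
#' Produces a randomised order of response types with exactly half perception
#' and half prediction trials (40 + 40 at the default 80 trials).
#'
#' @param n_trials Even number of trials.
#' @param seed Integer seed for the permutation.
#' @return A tibble with columns `trial` and `response_type`
#'   (`"perception"` or `"prediction"`).
#' @export
generate_schedule <- function(n_trials = 80L, seed) {
  check_scalar_number(n_trials, "n_trials", lower = 2)
  if (n_trials %% 2 != 0) {
    abort("`n_trials` must be even: half perception, half prediction.")
  }
  with_seed(seed, {
    types <- sample(rep(c("perception", "prediction"), n_trials / 2))
    tibble(trial = seq_len(as.integer(n_trials)), response_type = types)
  })
}

#' Assemble a trial table from a sequence and a schedule
#'
#' Joins a generated sequence with a response-type schedule into the
#' trial-level table shared by all downstream functions. The `input` column
#' is the raw discrete intensity unless a linear transform is supplied, in
#' which case it is mapped onto the 0-100 response scale.
#'
#' @param sequence A [generate_sequence()] tibble.
#' @param schedule A [generate_schedule()] tibble of the same length.
#' @param transform Optional [input_transform()] mapping intensity levels to
#'   the response scale.
#' @param participant,condition Optional identifier columns.
#' @return A tibble with columns `participant`, `condition`, `trial`,
#'   `input`, `response_type`, `response` (NA until rated or simulated),
#'   `confidence` (NA until rated or simulated).
#' @export
make_trials <- function(sequence, schedule, transform = NULL,
                        participant = 1L, condition = NULL) {
  stopifnot(nrow(sequence) == nrow(schedule))
  input <- sequence$intensity
  if (!is.null(transform)) input <- apply_transform(transform, input)
  cond <- condition %||% tryCatch(
    condition_label(attr(sequence, "condition")),
    error = function(e) NA_character_
  )
  tibble(
    participant = participant,
    condition = cond,
    trial = sequence$trial,
    input = as.numeric(input),
    response_type = schedule$response_type,
    response = NA_real_,
    confidence = NA_real_
  )
}

#' @rdname generate_sequence
#' @param object A `pain_sequence`.
#' @param ... Unused.
#' @method autoplot pain_sequence
#' @export
autoplot.pain_sequence <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$chunk_mean),
                       colour = "grey50", linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity),
                        colour = "#1b7837", size = 1.4) +
    ggplot2::labs(
      x = "Trial", y = "Intensity level",
      title = sprintf(
        "Sequence: %s volatility, %s stochasticity",
        attr(object, "condition")$volatility,
        attr(object, "condition")$stochasticity
      )
    ) +
    ggplot2::theme_minimal()
}
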