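# Pareto-smoothed importance sampling and approximate leave-one-out
# cross-validation (Vehtari, Gelman & Gabry 2017), with the generalised
# Pareto tail fit of Zhang & Stephens (2009).

# Fit GPD (location 0) to exceedances x; returns shape k and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bj <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bj * xstar)
  k_of <- function(th) vapply(th, function(t) -mean(log1p(-t * x)),
                              numeric(1))
  kj <- k_of(theta)
  l_theta <- n * (log(theta / kj) + kj - 1)
  w <- 1 / vapply(jj, function(j) sum(exp(l_theta - l_theta[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k_hat <- -mean(log1p(-theta_hat * x))
  sigma_hat <- k_hat / theta_hat
  # weakly-informative shrinkage of the shape towards 0.5 (as in standard
  # PSIS practice) stabilises small tails
  k_hat <- (n * k_hat + 10 * 0.5) / (n + 10)
  list(k = k_hat, sigma = sigma_hat)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Smooth one vector of log importance ratios; returns list(log_weights, k).
psis_smooth <- function(log_ratios) {
  s <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  tail_len <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  if (tail_len < 5) {
    return(list(log_weights = lw, k = Inf))
  }
  ord <- order(lw)
  tail_ids <- ord[(s - tail_len + 1):s]
  cutoff <- lw[ord[s - tail_len]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  if (all(exceed <= 0) || length(unique(exceed)) < 2) {
    return(list(log_weights = lw, k = NA_real_))
  }
  fit <- gpd_fit(exceed)
  p <- (seq_len(tail_len) - 0.5) / tail_len
  smoothed <- log(qgpd(p, fit$k, fit$sigma) + exp(cutoff))
  lw[tail_ids[order(lw[tail_ids])]] <- smoothed
  lw <- pmin(lw, 0)  # cap at the largest raw weight
  list(log_weights = lw - max(lw), k = fit$k)
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' Approximate leave-one-out cross-validation from the pointwise
#' log-likelihood draws of a fit. The held-out predictive density of each
#' observation unit (one participant-trial response) is estimated by
#' Pareto-smoothed importance sampling; the ELPD is the sum of the pointwise
#' values and LOOIC = -2 ELPD. Units whose Pareto shape diagnostic exceeds
#' 0.7 are reported with a warning (not refit).
#'
#' @param fit A `pain_fit`, or a draws x units pointwise log-likelihood
#'   matrix.
#' @return A `pain_loo` object: list with `elpd`, `se`, `looic`,
#'   `pointwise` (tibble with `elpd_i` and `pareto_k` per unit) and `n`.
#' @export
elpd_loo <- function(fit) {
  ll <- if (inherits(fit, "pain_fit")) {
    fit$loglik
  } else if (is.matrix(fit)) {
    fit
  } else {
    abort("`fit` must be a pain_fit or a pointwise log-likelihood matrix.")
  }
  if (is.null(ll) || nrow(ll) < 2) {
    abort("Pointwise log-likelihood draws are required.")
  }
  n <- ncol(ll)
  res <- purrr::map(seq_len(n), function(i) {
    sm <- psis_smooth(-ll[, i])
    lw <- sm$log_weights
    elpd_i <- log_sum_exp(lw + ll[, i]) - log_sum_exp(lw)
    list(elpd_i = elpd_i, k = sm$k)
  })
  pointwise <- tibble(
    unit = seq_len(n),
    elpd_i = vapply(res, `[[`, numeric(1), "elpd_i"),
    pareto_k = vapply(res, `[[`, numeric(1), "k")
  )
  bad <- sum(pointwise$pareto_k > 0.7, na.rm = TRUE)
  if (bad > 0) {
    warning(sprintf("%d of %d units have Pareto k > 0.7; their LOO
  contribution may be unreliable.", bad, n), call. = FALSE)
  }
  elpd <- sum(pointwise$elpd_i)
  structure(
    list(
      elpd = elpd,
      se = sqrt(n * var(pointwise$elpd_i)),
      looic = -2 * elpd,
      pointwise = pointwise,
      n = n,
      model = if (inherits(fit, "pain_fit")) fit$model$model_id else NA
    ),
    class = "pain_loo"
  )
}

#' @export
print.pain_loo <- function(x, ...) {
  cat(sprintf("<pain_loo> %s: elpd = %.1f (SE %.1f), looic = %.1f, n = %d\n",
              x$model %||% "?", x$elpd, x$se, x$looic, x$n))
  invisible(x)
}

#' Compare fitted models by ELPD
#'
#' Ranks a set of fits of the same data by PSIS-LOO ELPD and reports, for
#' each model, the ELPD difference to the best model, the standard error of
#' that difference (computed from the paired pointwise contributions), and
#' the sigma effect — the ratio |difference| / SE. A sigma effect of at
#' least 2 is conventionally read as a significant difference.
#'
#' @param fits Named list of `pain_fit` objects (or `pain_loo` objects) fit
#'   to identical observation units.
#' @return A `model_comparison` tibble with columns `model`, `elpd`,
#'   `se_elpd`, `looic`, `elpd_diff`, `se_diff`, `sigma`, `n_high_k`,
#'   ordered best first.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  loos <- purrr::map(fits, function(f) {
    if (inherits(f, "pain_loo")) f else elpd_loo(f)
  })
  nms <- names(loos)
  if (is.null(nms)) nms <- rep("", length(loos))
  fallback <- vapply(loos, function(l) as.character(l$model %||% "model"),
                     character(1))
  nms[nms == ""] <- fallback[nms == ""]
  names(loos) <- make.unique(nms)
  ns <- vapply(loos, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1) {
    abort("All fits must cover identical observation units.")
  }
  elpds <- vapply(loos, `[[`, numeric(1), "elpd")
  best <- which.max(elpds)
  out <- purrr::imap_dfr(loos, function(l, nm) {
    d <- l$pointwise$elpd_i - loos[[best]]$pointwise$elpd_i
    tibble(
      model = nm,
      elpd = l$elpd,
      se_elpd = l$se,
      looic = l$looic,
      elpd_diff = sum(d),
      se_diff = sqrt(l$n * var(d)),
      sigma = if (sum(d) == 0) 0 else abs(sum(d)) / sqrt(l$n * var(d)),
      n_high_k = sum(l$pointwise$pareto_k > 0.7, na.rm = TRUE)
    )
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$elpd))
  class(out) <- c("model_comparison", class(out))
  out
}

#' @rdname compare_models
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) as_tibble(x)

#' @rdname compare_models
#' @param object A `model_comparison`.
#' @method autoplot model_comparison
#' @export
autoplot.model_comparison <- function(object, ...) {
  d <- dplyr::mutate(as_tibble(object),
                     model = factor(.data$model, levels = rev(.data$model)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$elpd_diff, y = .data$model)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$elpd_diff - .data$se_diff,
      xmax = .data$elpd_diff + .data$se_diff
    )) +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$sigma > 0, sprintf("%.1f sigma", .data$sigma), "")
    ), vjust = -1, size = 3) +
    ggplot2::labs(x = "ELPD difference to best model (+/- SE)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Highest-density interval
#'
#' Shortest interval containing a given posterior mass, computed from
#' sorted draws.
#'
#' @param draws Numeric vector of posterior draws.
#' @param level Probability mass (default 0.95).
#' @return Numeric length-2 vector `c(lower, upper)`.
#' @export
hdi <- function(draws, level = 0.95) {
  draws <- sort(draws[is.finite(draws)])
  n <- length(draws)
  if (n < 2) abort("Need >= 2 finite draws.")
  m <- max(1L, floor(level * n))
  starts <- seq_len(n - m)
  widths <- draws[starts + m] - draws[starts]
  j <- starts[which.min(widths)]
  c(draws[j], draws[j + m])
}

#' Between-condition parameter contrast by HDI of the paired difference
#'
#' Merges (across chains) posterior draws of the same parameter from two
#' condition fits, takes the elementwise difference `draws_b - draws_a`, and
#' reports its highest-density interval. A difference is flagged significant
#' when the interval excludes zero. If the draw vectors differ in length the
#' longer one is subsampled (seeded) to match.
#'
#' @param draws_a,draws_b Merged posterior draws of one parameter under two
#'   conditions (see [param_draws()]).
#' @param level HDI probability mass.
#' @param seed Seed for subsampling when lengths differ.
#' @return Tibble with `estimate` (mean difference), `lower`, `upper`,
#'   `level`, `significant`.
#' @export
hdi_contrast <- function(draws_a, draws_b, level = 0.95, seed = 1) {
  na <- length(draws_a)
  nb <- length(draws_b)
  if (na != nb) {
    n <- min(na, nb)
    if (na > n) draws_a <- with_seed(seed, sample(draws_a, n))
    if (nb > n) draws_b <- with_seed(seed, sample(draws_b, n))
  }
  d <- draws_b - draws_a
  h <- hdi(d, level)
  tibble(
    estimate = mean(d), lower = h[1], upper = h[2], level = level,
    significant = h[1] > 0 | h[2] < 0
  )
}
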