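# MCMC convergence diagnostics: split R-hat and rank-normalised bulk/tail
# effective sample size, computed from an iterations x chains draw matrix.
# Follows the rank-normalised formulation of Vehtari, Gelman, Simpson,
# Carpenter & Buerkner (2021).

split_chains <- function(x) {
  n <- nrow(x)
  half <- n %/% 2L
  # drop the middle draw when n is odd
  cbind(x[seq_len(half), , drop = FALSE],
        x[(n - half + 1):n, , drop = FALSE])
}

rank_normalise <- function(x) {
  r <- rank(as.numeric(x), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(x))
}

rhat_basic <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  if (n < 2 || m < 2) return(NA_real_)
  chain_means <- colMeans(x)
  chain_vars <- apply(x, 2, var)
  w <- mean(chain_vars)
  b <- n * var(chain_means)
  if (!is.finite(w) || w == 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# biased autocovariance (lags 0..n-1) via FFT
acov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  nfft <- stats::nextn(2 * n)
  f <- stats::fft(c(x, rep(0, nfft - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / nfft
  ac / n
}

ess_basic <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4 || any(!is.finite(x))) return(NA_real_)
  if (sd(x) == 0) return(NA_real_)
  acov <- apply(x, 2, acov_fft)
  chain_means <- colMeans(x)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n +
    (if (m > 1) var(chain_means) else 0)
  if (var_plus == 0) return(NA_real_)

  rho_hat <- rep(0, n)
  rho_hat[1] <- 1
  rho_even <- 1
  rho_odd <- 1 - (mean_var - mean(acov[2, ])) / var_plus
  rho_hat[2] <- rho_odd
  t <- 0
  while (t < n - 5 && !is.nan(rho_even + rho_odd) &&
         (rho_even + rho_odd) > 0) {
    t <- t + 2
    rho_even <- 1 - (mean_var - mean(acov[t + 1, ])) / var_plus
    rho_odd <- 1 - (mean_var - mean(acov[t + 2, ])) / var_plus
    if ((rho_even + rho_odd) >= 0) {
      rho_hat[t + 1] <- rho_even
      rho_hat[t + 2] <- rho_odd
    }
  }
  max_t <- t
  if (rho_even > 0) rho_hat[max_t + 1] <- rho_even
  # Geyer's initial monotone sequence
  t <- 0
  while (t <= max_t - 4) {
    t <- t + 2
    if (rho_hat[t + 1] + rho_hat[t + 2] > rho_hat[t - 1] + rho_hat[t]) {
      rho_hat[t + 1] <- (rho_hat[t - 1] + rho_hat[t]) / 2
      rho_hat[t + 2] <- rho_hat[t + 1]
    }
  }
  s_total <- n * m
  tau_hat <- -1 + 2 * sum(rho_hat[seq_len(max_t)]) + rho_hat[max_t + 1]
  tau_hat <- max(tau_hat, 1 / log10(s_total))
  min(s_total / tau_hat, s_total * log10(s_total))
}

#' Split R-hat of one parameter
#'
#' Rank-normalised split potential-scale-reduction statistic: the maximum of
#' the classic split R-hat applied to rank-normalised draws (bulk) and to
#' rank-normalised absolute deviations from the median (tails). Values near
#' 1 indicate the chains have mixed; the conventional convergence cut-off
#' used throughout the package is 1.1.
#'
#' @param x Draws matrix, iterations x chains (>= 2 chains).
#' @return The R-hat value (NA for constant draws).
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("R-hat needs >= 2 chains.")
  if (sd(x) == 0) return(NA_real_)
  bulk <- rhat_basic(rank_normalise(split_chains(x)))
  folded <- rhat_basic(rank_normalise(split_chains(
    abs(x - stats::median(x))
  )))
  max(bulk, folded)
}

#' Bulk and tail effective sample size
#'
#' Rank-normalised split effective sample size; `ess_tail()` is the smaller
#' of the ESS of the 5% and 95% quantile indicators.
#'
#' @inheritParams rhat
#' @return Effective sample size (NA for constant draws).
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  ess_basic(rank_normalise(split_chains(x)))
}

#' @rdname ess_bulk
#' @export
ess_tail <- function(x) {
  x <- as.matrix(x)
  qs <- quantile(x, c(0.05, 0.95))
  min(
    ess_basic(rank_normalise(split_chains(1 * (x <= qs[1])))),
    ess_basic(rank_normalise(split_chains(1 * (x <= qs[2]))))
  )
}

#' Convergence diagnostics for a fitted model
#'
#' Split R-hat and rank-normalised bulk/tail ESS for every monitored
#' parameter: group locations and scales, every non-centred individual
#' offset, and every natural-scale individual parameter.
#'
#' @param fit A `pain_fit` from [sample_posterior()].
#' @return Tibble with columns `parameter`, `rhat`, `ess_bulk`, `ess_tail`,
#'   plus attribute `converged` (all R-hat < 1.1).
#' @export
diagnostics <- function(fit) {
  stopifnot(inherits(fit, "pain_fit"))
  if (length(fit$samples) < 2) {
    abort("Convergence diagnostics need >= 2 chains.")
  }
  vn <- coda::varnames(fit$samples)
  out <- purrr::map_dfr(vn, function(v) {
    x <- sapply(fit$samples, function(m) as.numeric(m[, v]))
    tibble(parameter = v, rhat = rhat(x),
           ess_bulk = ess_bulk(x), ess_tail = ess_tail(x))
  })
  attr(out, "converged") <- all(out$rhat < 1.1, na.rm = TRUE)
  out
}
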