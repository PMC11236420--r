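#' Logistic approximation to the standard-Normal CDF
#'
#' The link used for (0,1)-bounded parameters, on both the R side and inside
#' the generated BUGS code: `plogis(0.07056 x^3 + 1.5976 x)`.
#'
#' @param x Numeric vector on the unconstrained scale.
#' @return Values in (0, 1).
#' @export
phi_approx <- function(x) stats::plogis(0.07056 * x^3 + 1.5976 * x)

# Scale applied to identity-linked response-scale parameters (E0, R): raw
# N(0,1) group priors are stretched onto the 0-100 rating scale.
RESPONSE_SCALE_FACTOR <- 50

link_fun <- function(link) {
  switch(link,
    unit = phi_approx,
    pos = exp,
    response = function(x) RESPONSE_SCALE_FACTOR * x,
    abort(sprintf("Unknown link: %s", link))
  )
}

param_table <- function(model_id) {
  tbl <- switch(model_id,
    rl = tibble(
      name = c("alpha", "xi", "e0", "c_scale"),
      link = c("unit", "pos", "response", "pos")
    ),
    erl = tibble(
      name = c("alpha", "xi", "e0", "c_scale", "gamma"),
      link = c("unit", "pos", "response", "pos", "unit")
    ),
    kf = tibble(
      name = c("s", "v", "xi", "e0", "w0", "c_scale"),
      link = c("pos", "pos", "pos", "response", "pos", "pos")
    ),
    ekf = tibble(
      name = c("epsilon", "s", "v", "xi", "e0", "w0", "c_scale"),
      link = c("pos", "pos", "pos", "pos", "response", "pos", "pos")
    ),
    random = tibble(
      name = c("r0", "xi", "c_scale"),
      link = c("response", "pos", "pos")
    ),
    abort(sprintf("Unknown model id: %s (expected one of %s)",
                  model_id, paste(model_ids(), collapse = ", ")))
  )
  dplyr::mutate(tbl, k = dplyr::row_number(), .before = 1)
}

bugs_link_line <- function(k, link) {
  rhs <- switch(link,
    unit = sprintf(
      "ilogit(0.07056 * pow(raw[i,%d], 3) + 1.5976 * raw[i,%d])", k, k),
    pos = sprintf("exp(raw[i,%d])", k),
    response = sprintf("%d * raw[i,%d]", RESPONSE_SCALE_FACTOR, k)
  )
  sprintf("    theta[i,%d] <- %s", k, rhs)
}

bugs_recursion <- function(model_id) {
  switch(model_id,
    rl = "
    E[i,1] <- theta[i,3]
    for (t in 1:T) {
      E[i,t+1] <- E[i,t] + theta[i,1] * (N[i,t] - E[i,t])
      mresp[i,t] <- isperc[i,t] * N[i,t] + (1 - isperc[i,t]) * E[i,t+1]
    }",
    erl = "
    E[i,1] <- theta[i,3]
    for (t in 1:T) {
      P[i,t] <- (1 - theta[i,5]) * N[i,t] + theta[i,5] * E[i,t]
      E[i,t+1] <- E[i,t] + theta[i,1] * (P[i,t] - E[i,t])
      mresp[i,t] <- isperc[i,t] * P[i,t] + (1 - isperc[i,t]) * E[i,t+1]
    }",
    kf = "
    m[i,1] <- theta[i,4]
    w2[i,1] <- pow(theta[i,5], 2)
    for (t in 1:T) {
      a[i,t] <- w2[i,t] / (w2[i,t] + pow(theta[i,1], 2))
      m[i,t+1] <- m[i,t] + a[i,t] * (N[i,t] - m[i,t])
      w2[i,t+1] <- w2[i,t] * (1 - a[i,t]) + pow(theta[i,2], 2)
      mresp[i,t] <- isperc[i,t] * N[i,t] + (1 - isperc[i,t]) * m[i,t+1]
    }",
    ekf = "
    m[i,1] <- theta[i,5]
    w2[i,1] <- pow(theta[i,6], 2)
    for (t in 1:T) {
      g[i,t] <- pow(theta[i,1], 2) /
        (pow(theta[i,1], 2) + pow(theta[i,2], 2) + w2[i,t])
      a[i,t] <- w2[i,t] /
        (pow(theta[i,1], 2) + w2[i,t] + pow(theta[i,2], 2))
      P[i,t] <- g[i,t] * m[i,t] + (1 - g[i,t]) * N[i,t]
      m[i,t+1] <- m[i,t] + a[i,t] * (N[i,t] - m[i,t])
      w2[i,t+1] <- w2[i,t] * (1 - a[i,t]) + pow(theta[i,3], 2)
      mresp[i,t] <- isperc[i,t] * P[i,t] + (1 - isperc[i,t]) * m[i,t+1]
    }",
    random = "
    for (t in 1:T) {
      mresp[i,t] <- theta[i,1]
    }"
  )
}

#' Build a hierarchical observer-model specification
#'
#' Defines one of the five observer models with the hierarchical prior
#' structure: standard-Normal priors on group-level locations,
#' half-Student-t(3, 0, 1) group-level scales (the gamma-mixture
#' representation of that prior is used in the generated BUGS program),
#' non-centred standard-Normal individual offsets, a logistic
#' approximation to the Normal CDF ([phi_approx()]) linking (0,1)-bounded
#' parameters, an exponential link for strictly positive scale
#' parameters, and a x50 rescaling of the raw group prior for
#' response-scale location parameters (`e0`, `r0`).
#'
#' The returned object carries the parameter/link table used by
#' [sample_posterior()]'s sampler, plus an equivalent BUGS program that
#' documents the model declaratively and lets an external MCMC engine
#' (JAGS) fit the identical model — used as an independent cross-check in
#' the package's tests.
#'
#' @param model_id One of `"rl"`, `"erl"`, `"kf"`, `"ekf"`, `"random"`.
#' @return A `painseq_model` object: list with `model_id`, `params` (the
#'   parameter/link table) and `bugs` (the model code).
#' @examples
#' cat(build_model("random")$bugs)
#' @export
build_model <- function(model_id) {
  tbl <- param_table(model_id)
  xi_k <- tbl$k[tbl$name == "xi"]
  c_k <- tbl$k[tbl$name == "c_scale"]
  code <- paste0(
    "model {\n",
    "  for (k in 1:K) {\n",
    "    mu[k] ~ dnorm(0, 1)\n",
    "    lam[k] ~ dgamma(1.5, 1.5)\n",
    "    sig_raw[k] ~ dnorm(0, lam[k])\n",
    "    sig[k] <- abs(sig_raw[k])\n",
    "    for (i in 1:I) {\n",
    "      z[i,k] ~ dnorm(0, 1)\n",
    "      raw[i,k] <- mu[k] + sig[k] * z[i,k]\n",
    "    }\n",
    "  }\n",
    "  for (i in 1:I) {\n",
    paste(purrr::map2_chr(tbl$k, tbl$link, bugs_link_line),
          collapse = "\n"), "\n",
    bugs_recursion(model_id), "\n",
    "    for (t in 1:T) {\n",
    sprintf(
      "      tau[i,t] <- pow(theta[i,%d] * exp((1 - conf[i,t]) / theta[i,%d]), -2)\n",
      xi_k, c_k),
    "    }\n",
    "  }\n",
    "  for (n in 1:Nobs) {\n",
    "    loglik[n] <- logdensity.norm(respall[n], mresp[suba[n], tra[n]],\n",
    "                                 tau[suba[n], tra[n]])\n",
    "  }\n",
    "  for (u in 1:Nfit) {\n",
    "    respfit[u] ~ dnorm(mresp[subf[u], trf[u]], tau[subf[u], trf[u]])\n",
    "  }\n",
    "}\n"
  )
  structure(
    list(model_id = model_id, params = tbl, bugs = code),
    class = "painseq_model"
  )
}

#' @export
print.painseq_model <- function(x, ...) {
  cat(sprintf("<painseq_model> %s: %d free parameters (%s)\n",
              x$model_id, nrow(x$params),
              paste(x$params$name, collapse = ", ")))
  invisible(x)
}

#' Map unconstrained individual draws to natural-scale parameters
#'
#' The non-centred construction: individual raw value = group location +
#' group scale x standard-Normal offset, pushed through the parameter's
#' link. With all offsets at zero every individual sits exactly at the
#' group location; with the group scale at zero the hierarchy collapses to
#' complete pooling.
#'
#' @param model A [build_model()] object.
#' @param mu,sigma Numeric vectors of group-level locations and scales (one
#'   per parameter, in the order of `model$params`).
#' @param z Matrix of standard-Normal offsets (subjects x parameters).
#' @return Matrix of natural-scale parameter values (subjects x parameters,
#'   named columns).
#' @export
natural_params <- function(model, mu, sigma, z) {
  stopifnot(inherits(model, "painseq_model"))
  K <- nrow(model$params)
  stopifnot(length(mu) == K, length(sigma) == K, ncol(z) == K)
  out <- vapply(seq_len(K), function(k) {
    link_fun(model$params$link[k])(mu[k] + sigma[k] * z[, k])
  }, numeric(nrow(z)))
  out <- matrix(out, nrow = nrow(z))
  colnames(out) <- model$params$name
  out
}

#' Sampler configuration
#'
#' Desk-scale defaults are 4 chains with 1000 warmup and 1000 retained
#' draws; the full-scale analysis configuration (4 chains x 6000 warmup +
#' 6000 draws) is available via `fit_config(full_scale = TRUE)`. Half of the
#' warmup is spent in the sampler's adaptive phase.
#'
#' @param chains Number of MCMC chains (>= 2 for convergence diagnostics).
#' @param warmup Discarded iterations per chain.
#' @param samples Retained iterations per chain.
#' @param thin Thinning interval.
#' @param seed Integer seed; chain RNGs are derived from it.
#' @param full_scale If `TRUE`, use the full-scale 6000/6000 configuration.
#' @param quiet Suppress sampler progress output.
#' @return A `fit_config` list.
#' @export
fit_config <- function(chains = 4, warmup = 1000, samples = 1000, thin = 1,
                       seed = 1, full_scale = FALSE, quiet = TRUE) {
  if (full_scale) {
    warmup <- 6000
    samples <- 6000
  }
  stopifnot(chains >= 1, warmup >= 2, samples >= 2, thin >= 1)
  structure(
    list(chains = as.integer(chains), warmup = as.integer(warmup),
         samples = as.integer(samples), thin = as.integer(thin),
         seed = as.integer(seed), quiet = isTRUE(quiet)),
    class = "fit_config"
  )
}
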