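# Hierarchical MCMC for the observer models.
#
# The posterior is the non-centred hierarchical model: group locations
# mu_k ~ N(0,1), group scales sigma_k ~ half-Student-t(3,0,1), offsets
# z_ik ~ N(0,1), individual parameter theta_ik = link(mu_k + sigma_k z_ik),
# with the per-trial Gaussian response likelihood of the selected observer
# model. Sampling combines two kernels, each leaving the posterior
# invariant:
#
#  1. per-subject joint adaptive-Metropolis updates of z_i (a 7-dim — or
#     K-dim — multivariate Normal proposal whose covariance is learned
#     during warmup), which moves efficiently along the within-subject
#     ridges of weakly separated noise parameters;
#  2. an interweaving (ancillarity-sufficiency) group step: holding the
#     raw individual values mu + sigma z fixed, the group location has a
#     conjugate Normal conditional (Gibbs draw) and the group scale a
#     one-dimensional conditional sampled by slice sampling; the offsets
#     are then recomputed from the new (mu, sigma).
#
# Componentwise samplers random-walk along the epsilon/s/v ridge of the
# Kalman-filter models; the joint subject proposal is what makes the
# desk-scale configuration (4 chains x 1000/1000) converge.

# fast per-subject trajectory of response means (no tibble overhead);
# mirrors run_model() exactly and is tested against it
trial_means <- function(model_id, th, N, isperc) {
  Tn <- length(N)
  mresp <- numeric(Tn)
  if (model_id == "rl" || model_id == "erl") {
    alpha <- th[["alpha"]]
    gamma <- if (model_id == "erl") th[["gamma"]] else 0
    e <- th[["e0"]]
    for (t in seq_len(Tn)) {
      p <- (1 - gamma) * N[t] + gamma * e
      e <- e + alpha * (p - e)
      mresp[t] <- if (isperc[t]) p else e
    }
  } else if (model_id == "kf" || model_id == "ekf") {
    eps2 <- if (model_id == "ekf") th[["epsilon"]]^2 else 0
    s2 <- th[["s"]]^2
    v2 <- th[["v"]]^2
    m <- th[["e0"]]
    w2 <- th[["w0"]]^2
    for (t in seq_len(Tn)) {
      tot <- eps2 + s2 + w2
      g <- eps2 / tot
      a <- w2 / tot
      p <- g * m + (1 - g) * N[t]
      m <- m + a * (N[t] - m)
      w2 <- w2 * (1 - a) + v2
      mresp[t] <- if (isperc[t]) p else m
    }
  } else if (model_id == "random") {
    mresp[] <- th[["r0"]]
  } else {
    abort(sprintf("Unknown model id: %s", model_id))
  }
  mresp
}

# pointwise log-likelihood of one subject's answered trials
subject_loglik <- function(model_id, th, sub) {
  mresp <- trial_means(model_id, th, sub$N, sub$isperc)
  sdv <- th[["xi"]] * exp((1 - sub$conf[sub$ans]) / th[["c_scale"]])
  dnorm(sub$resp[sub$ans], mresp[sub$ans], sdv, log = TRUE)
}

# natural parameters of one subject from raw values
theta_from_raw <- function(raw, links) {
  th <- numeric(length(raw))
  for (k in seq_along(raw)) th[k] <- link_fun(links[k])(raw[k])
  names(th) <- names(links)
  th
}

# log density of the half-Student-t(3,0,1) group-scale prior (equivalently
# the gamma-mixture representation integrated out)
log_half_t3 <- function(x) {
  if (x <= 0) return(-Inf)
  -2 * log1p(x^2 / 3)
}

# univariate slice sampler with stepping out (Neal 2003)
slice_sample_1d <- function(x0, logf, w = 0.5, lower = 1e-8, upper = Inf,
                            max_steps = 50) {
  f0 <- logf(x0)
  y <- f0 + log(runif(1))
  l <- x0 - runif(1) * w
  r <- l + w
  steps <- 0
  while (l > lower && logf(l) > y && steps < max_steps) {
    l <- l - w
    steps <- steps + 1
  }
  steps <- 0
  while (r < upper && logf(r) > y && steps < max_steps) {
    r <- r + w
    steps <- steps + 1
  }
  l <- max(l, lower)
  r <- min(r, upper)
  repeat {
    x1 <- runif(1, l, r)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
    if (r - l < 1e-12) return(x0)
  }
}

# multivariate normal proposal from a Cholesky factor
rmvn_chol <- function(mean, chol_up) {
  mean + drop(rnorm(length(mean)) %*% chol_up)
}

run_chain <- function(model_id, links, subs, K, I, config, chain_seed,
                      n_units, unit_offsets) {
  set.seed(chain_seed)
  warmup <- config$warmup
  n_keep <- config$samples
  thin <- config$thin
  total_iter <- warmup + n_keep * thin

  # initial state: data-informed location for the response-scale and
  # response-noise parameters, slight overdispersion across chains
  all_resp <- unlist(lapply(subs, function(s) s$resp[s$ans]))
  mu <- rnorm(K, 0, 0.1)
  resp_k <- which(links == "response")
  if (length(resp_k) == 1) {
    mu[resp_k] <- mean(all_resp) / RESPONSE_SCALE_FACTOR + rnorm(1, 0, 0.05)
  }
  xi_k <- which(names(links) == "xi")
  mu[xi_k] <- log(max(sd(all_resp) / 2, 0.5)) + rnorm(1, 0, 0.1)
  sig <- rep(0.3, K)
  raw <- matrix(rnorm(I * K, 0, 0.05), I, K) +
    matrix(mu, I, K, byrow = TRUE)

  cur_ll <- vector("list", I)     # pointwise loglik, answered trials
  cur_fit_ll <- numeric(I)        # loglik over trials in the likelihood
  for (i in seq_len(I)) {
    th <- theta_from_raw(raw[i, ], links)
    ll <- subject_loglik(model_id, th, subs[[i]])
    cur_ll[[i]] <- ll
    cur_fit_ll[i] <- sum(ll[subs[[i]]$fit_mask])
  }

  # per-subject adaptive proposal on the raw (centred) coordinates, whose
  # conditional geometry is stable because the likelihood part is fixed;
  # a second, sigma-scaled diagonal mixture component serves the
  # prior-dominated directions
  prop_scale <- rep(2.38^2 / K, I)
  prop_chol <- replicate(I, diag(0.05, K), simplify = FALSE)
  hist_mean <- raw
  hist_cov <- replicate(I, diag(1e-4, K), simplify = FALSE)
  n_hist <- 0
  accept <- numeric(I)
  mh_sweeps <- 8L   # subject-block sweeps per group update
  # population-translation move: shifts mu and every subject's raw value
  # together, so the whole group can slide along weakly identified valleys
  # (e.g. the epsilon/v decomposition) that subject-wise moves cross only
  # by slow collective diffusion
  g_scale <- 2.38^2 / K
  g_chol <- diag(0.05, K)
  g_hist_mean <- mu
  g_hist_cov <- diag(1e-4, K)
  g_translations <- 4L
  # population-scaling move: contracts or expands every subject's raw
  # value around mu jointly with sigma (per parameter), the analogous
  # collective move for the group scales
  sc_step <- rep(0.15, K)

  keep_mu <- matrix(NA_real_, n_keep, K)
  keep_sig <- matrix(NA_real_, n_keep, K)
  keep_z <- matrix(NA_real_, n_keep, I * K)
  keep_theta <- matrix(NA_real_, n_keep, I * K)
  keep_ll <- matrix(NA_real_, n_keep, n_units)

  for (it in seq_len(total_iter)) {
    # forget the initialisation transient: restart the covariance
    # estimate from the mid-warmup state
    if (it == warmup %/% 2) {
      hist_mean <- raw
      hist_cov <- replicate(I, diag(1e-6, K), simplify = FALSE)
      g_hist_mean <- mu
      g_hist_cov <- diag(1e-6, K)
      n_hist <- 0
    }
    if (it <= warmup) n_hist <- n_hist + 1
    ## 1. per-subject joint raw updates (Metropolis, mixture proposal)
    for (sweep_i in seq_len(mh_sweeps)) for (i in seq_len(I)) {
      raw_old <- raw[i, ]
      if (runif(1) < 0.7) {
        raw_new <- rmvn_chol(raw_old, sqrt(prop_scale[i]) * prop_chol[[i]])
      } else {
        raw_new <- raw_old + rnorm(K, 0, pmax(0.4 * sig, 0.02))
      }
      th_new <- theta_from_raw(raw_new, links)
      ll_new <- subject_loglik(model_id, th_new, subs[[i]])
      fit_ll_new <- sum(ll_new[subs[[i]]$fit_mask])
      log_acc <- fit_ll_new - cur_fit_ll[i] +
        sum(dnorm(raw_new, mu, sig, log = TRUE)) -
        sum(dnorm(raw_old, mu, sig, log = TRUE))
      acc <- is.finite(log_acc) && log(runif(1)) < log_acc
      if (acc) {
        raw[i, ] <- raw_new
        cur_ll[[i]] <- ll_new
        cur_fit_ll[i] <- fit_ll_new
      }
      if (it <= warmup) {
        # Robbins-Monro scale adaptation towards 0.23 acceptance, and a
        # running estimate of the raw-coordinate covariance
        eta <- min(0.5, 5 / n_hist)
        prop_scale[i] <- exp(log(prop_scale[i]) +
                               eta * ((if (acc) 1 else 0) - 0.23) * 0.5)
        dlt <- raw[i, ] - hist_mean[i, ]
        hist_mean[i, ] <- hist_mean[i, ] + dlt / (n_hist + 1)
        hist_cov[[i]] <- hist_cov[[i]] * (1 - 1 / (n_hist + 1)) +
          tcrossprod(dlt) / (n_hist + 1)
        if (it %% 50 == 0 && n_hist >= 100) {
          ch <- tryCatch(
            chol(hist_cov[[i]] + diag(1e-8, K)),
            error = function(e) NULL
          )
          if (!is.null(ch)) prop_chol[[i]] <- ch
        }
      } else if (acc) {
        accept[i] <- accept[i] + 1
      }
    }

    ## 1b. population translation moves
    for (gt in seq_len(g_translations)) {
      delta <- rmvn_chol(numeric(K), sqrt(g_scale) * g_chol)
      mu_new <- mu + delta
      ll_prop <- vector("list", I)
      fit_ll_prop <- numeric(I)
      for (i in seq_len(I)) {
        th_new <- theta_from_raw(raw[i, ] + delta, links)
        ll_prop[[i]] <- subject_loglik(model_id, th_new, subs[[i]])
        fit_ll_prop[i] <- sum(ll_prop[[i]][subs[[i]]$fit_mask])
      }
      log_acc <- sum(fit_ll_prop) - sum(cur_fit_ll) +
        sum(dnorm(mu_new, log = TRUE)) - sum(dnorm(mu, log = TRUE))
      acc <- is.finite(log_acc) && log(runif(1)) < log_acc
      if (acc) {
        mu <- mu_new
        raw <- raw + matrix(delta, I, K, byrow = TRUE)
        cur_ll <- ll_prop
        cur_fit_ll <- fit_ll_prop
      }
      if (it <= warmup) {
        eta <- min(0.5, 5 / n_hist)
        g_scale <- exp(log(g_scale) + eta * ((if (acc) 1 else 0) - 0.23) * 0.5)
      }
    }
    if (it <= warmup) {
      dlt <- mu - g_hist_mean
      g_hist_mean <- g_hist_mean + dlt / (n_hist + 1)
      g_hist_cov <- g_hist_cov * (1 - 1 / (n_hist + 1)) +
        tcrossprod(dlt) / (n_hist + 1)
      if (it %% 50 == 0 && n_hist >= 100) {
        ch <- tryCatch(chol(g_hist_cov + diag(1e-8, K)),
                       error = function(e) NULL)
        if (!is.null(ch)) g_chol <- ch
      }
    }

    ## 1c. population scaling moves (one per parameter)
    for (k in seq_len(K)) {
      cf <- exp(rnorm(1, 0, sc_step[k]))
      sig_new_k <- sig[k] * cf
      raw_k_new <- mu[k] + cf * (raw[, k] - mu[k])
      ll_prop <- vector("list", I)
      fit_ll_prop <- numeric(I)
      for (i in seq_len(I)) {
        raw_i <- raw[i, ]
        raw_i[k] <- raw_k_new[i]
        th_new <- theta_from_raw(raw_i, links)
        ll_prop[[i]] <- subject_loglik(model_id, th_new, subs[[i]])
        fit_ll_prop[i] <- sum(ll_prop[[i]][subs[[i]]$fit_mask])
      }
      # scaling transform of (sigma_k, raw_.k): prior ratio for the raws is
      # cf^-I, Jacobian cf^(I+1); net log cf plus the half-t prior ratio
      log_acc <- sum(fit_ll_prop) - sum(cur_fit_ll) +
        log_half_t3(sig_new_k) - log_half_t3(sig[k]) + log(cf)
      acc <- is.finite(log_acc) && log(runif(1)) < log_acc
      if (acc) {
        sig[k] <- sig_new_k
        raw[, k] <- raw_k_new
        cur_ll <- ll_prop
        cur_fit_ll <- fit_ll_prop
      }
      if (it <= warmup) {
        eta <- min(0.5, 5 / n_hist)
        sc_step[k] <- exp(log(sc_step[k]) +
                            eta * ((if (acc) 1 else 0) - 0.35) * 0.5)
        sc_step[k] <- min(max(sc_step[k], 0.01), 2)
      }
    }

    ## 2. group step conditional on the raw individual values:
    ##    conjugate Normal draw for the location, slice draw for the scale
    for (k in seq_len(K)) {
      rk <- raw[, k]
      prec <- 1 + I / sig[k]^2
      mu[k] <- rnorm(1, (sum(rk) / sig[k]^2) / prec, sqrt(1 / prec))
      mu_k <- mu[k]
      logf <- function(s) {
        log_half_t3(s) - I * log(s) - sum((rk - mu_k)^2) / (2 * s^2)
      }
      sig[k] <- slice_sample_1d(max(sig[k], 1e-6), logf)
    }

    if (it > warmup && (it - warmup) %% thin == 0) {
      s_idx <- (it - warmup) %/% thin
      keep_mu[s_idx, ] <- mu
      keep_sig[s_idx, ] <- sig
      z <- sweep(sweep(raw, 2, mu, `-`), 2, sig, `/`)
      keep_z[s_idx, ] <- as.numeric(z)
      th_all <- numeric(I * K)
      for (k in seq_len(K)) {
        th_all[(k - 1) * I + seq_len(I)] <- link_fun(links[k])(raw[, k])
      }
      keep_theta[s_idx, ] <- th_all
      for (i in seq_len(I)) {
        keep_ll[s_idx, unit_offsets[[i]]] <- cur_ll[[i]]
      }
    }
  }

  list(mu = keep_mu, sig = keep_sig, z = keep_z, theta = keep_theta,
       loglik = keep_ll,
       accept_rate = accept / (n_keep * thin * mh_sweeps))
}

sample_posterior_mcmc <- function(model, data_list, config) {
  model_id <- model$model_id
  K <- nrow(model$params)
  links <- model$params$link
  names(links) <- model$params$name
  I <- data_list$I
  subs <- data_list$subs
  n_units <- data_list$n_units
  unit_offsets <- data_list$unit_offsets

  chains <- lapply(seq_len(config$chains), function(ch) {
    run_chain(model_id, links, subs, K, I, config,
              chain_seed = child_seed(config$seed, ch),
              n_units = n_units, unit_offsets = unit_offsets)
  })

  par_names <- c(
    sprintf("mu[%d]", seq_len(K)),
    sprintf("sig[%d]", seq_len(K)),
    sprintf("z[%d,%d]", rep(seq_len(I), K), rep(seq_len(K), each = I)),
    sprintf("theta[%d,%d]", rep(seq_len(I), K), rep(seq_len(K), each = I))
  )
  samples <- coda::mcmc.list(lapply(chains, function(cc) {
    m <- cbind(cc$mu, cc$sig, cc$z, cc$theta)
    colnames(m) <- par_names
    coda::mcmc(m, start = 1, thin = 1)
  }))
  loglik <- do.call(rbind, lapply(chains, `[[`, "loglik"))
  accept <- rowMeans(sapply(chains, `[[`, "accept_rate"))
  list(samples = samples, loglik = loglik, accept_rate = accept)
}
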