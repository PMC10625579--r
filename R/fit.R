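#' Priors for model fitting on the transformed scale
#'
#' Parameters are fitted on unconstrained scales: learning rates through a
#' logit transform, the inverse temperature through a log transform, the
#' bias untransformed. Each transformed parameter gets an independent normal
#' prior. Defaults are weakly informative: logit-alpha ~ N(0, 2), log-beta ~
#' N(log 5, 1), bias ~ N(0, 1).
#'
#' @param alpha_mean,alpha_sd Normal prior on logit(alpha).
#' @param beta_mean,beta_sd Normal prior on log(beta).
#' @param bias_mean,bias_sd Normal prior on the bias.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(alpha_mean = 0, alpha_sd = 2,
                       beta_mean = log(5), beta_sd = 1,
                       bias_mean = 0, bias_sd = 1) {
  stopifnot(alpha_sd > 0, beta_sd > 0, bias_sd > 0)
  structure(list(alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 beta_mean = beta_mean, beta_sd = beta_sd,
                 bias_mean = bias_mean, bias_sd = bias_sd),
            class = "prior_spec")
}

# Names of the natural-scale parameters of a model spec, in packing order.
param_names <- function(spec) {
  a <- if (spec$split_valence && spec$split_block) {
    c(paste0("alpha_win_", 1:3), paste0("alpha_loss_", 1:3))
  } else if (spec$split_valence) {
    c("alpha_win", "alpha_loss")
  } else if (spec$split_block) {
    paste0("alpha_", 1:3)
  } else {
    "alpha"
  }
  c(a, "beta", if (spec$include_bias) "bias")
}

n_alpha <- function(spec) {
  (if (spec$split_valence) 2L else 1L) * (if (spec$split_block) 3L else 1L)
}

# Expand a prior_spec into per-parameter (mu, sd) vectors aligned with the
# transformed parameter vector of `spec`. Pass-through for already-expanded
# priors (as produced by the empirical-Bayes loop).
expand_prior <- function(priors, spec) {
  k <- n_alpha(spec) + 1L + as.integer(spec$include_bias)
  if (is.list(priors) && !inherits(priors, "prior_spec") &&
      all(c("mu", "sd") %in% names(priors))) {
    stopifnot(length(priors$mu) == k, length(priors$sd) == k)
    return(list(mu = priors$mu, sd = priors$sd))
  }
  na <- n_alpha(spec)
  mu <- c(rep(priors$alpha_mean, na), priors$beta_mean,
          if (spec$include_bias) priors$bias_mean)
  sd <- c(rep(priors$alpha_sd, na), priors$beta_sd,
          if (spec$include_bias) priors$bias_sd)
  names(mu) <- names(sd) <- param_names(spec)
  list(mu = mu, sd = sd)
}

# theta (transformed) -> agent_params
unpack_theta <- function(theta, spec) {
  na <- n_alpha(spec)
  a_nat <- inv_logit(theta[seq_len(na)])
  alpha <- if (spec$split_valence && spec$split_block) {
    matrix(a_nat, 3, 2)                       # win block 1..3, loss block 1..3
  } else if (spec$split_valence) {
    matrix(a_nat, 3, 2, byrow = TRUE)
  } else if (spec$split_block) {
    matrix(a_nat, 3, 2)
  } else {
    matrix(a_nat, 3, 2)
  }
  beta <- exp(theta[na + 1L])
  bias <- if (spec$include_bias) theta[na + 2L] else 0
  agent_params(alpha, beta, bias)
}

# agent_params (natural) -> named natural-scale vector for `spec`
params_to_vector <- function(params, spec) {
  a <- params$alpha
  av <- if (spec$split_valence && spec$split_block) {
    c(a[, "win"], a[, "loss"])
  } else if (spec$split_valence) {
    c(a[1, "win"], a[1, "loss"])
  } else if (spec$split_block) {
    a[, "win"]
  } else {
    a[1, 1]
  }
  out <- c(av, params$beta, if (spec$include_bias) params$bias)
  names(out) <- param_names(spec)
  out
}

# quiet likelihood used inside optimisers/samplers (floors silently)
loglik_quiet <- function(data, params) {
  v <- state_trajectories(data, params)
  p_a <- choice_probability(v[, 1], v[, 2], params$beta, params$bias)
  p_obs <- ifelse(data$chose_A, p_a, 1 - p_a)
  sum(log(pmax(p_obs, 1e-10)))
}

# Pre-extract a dataset's outcome/choice vectors once, returning a fast
# closure loglik(alpha 3x2 matrix, beta, bias) used inside optimisers and
# samplers. Numerically identical to loglik_quiet().
make_loglik_fn <- function(data) {
  segs <- block_segments(data$block)
  per_seg <- lapply(segs, function(s) {
    list(block = s$block,
         win = as.numeric(data$win_on_A[s$idx]),
         loss = as.numeric(data$loss_on_A[s$idx]))
  })
  sign_choice <- ifelse(data$chose_A, 1, -1)
  function(alpha, beta, bias = 0) {
    vw <- vector("list", length(per_seg))
    vl <- vector("list", length(per_seg))
    for (j in seq_along(per_seg)) {
      b <- per_seg[[j]]$block
      vw[[j]] <- pre_choice_values(per_seg[[j]]$win, alpha[b, 1])
      vl[[j]] <- pre_choice_values(per_seg[[j]]$loss, alpha[b, 2])
    }
    x <- beta * 2 * (unlist(vw) - unlist(vl)) + bias
    # log P(observed) = log plogis(sign * x)
    sum(log(pmax(stats::plogis(sign_choice * x), 1e-10)))
  }
}

# theta -> (alpha matrix, beta, bias) without agent_params validation
theta_to_raw <- function(theta, spec) {
  na <- n_alpha(spec)
  a_nat <- inv_logit(theta[seq_len(na)])
  alpha <- if (spec$split_valence && !spec$split_block) {
    matrix(a_nat, 3, 2, byrow = TRUE)
  } else {
    matrix(a_nat, 3, 2)
  }
  list(alpha = alpha, beta = exp(theta[na + 1L]),
       bias = if (spec$include_bias) theta[na + 2L] else 0)
}

make_logpost_fn <- function(data, spec, pr) {
  llfn <- make_loglik_fn(data)
  function(theta) {
    raw <- theta_to_raw(theta, spec)
    llfn(raw$alpha, raw$beta, raw$bias) +
      sum(stats::dnorm(theta, pr$mu, pr$sd, log = TRUE))
  }
}

log_posterior <- function(theta, data, spec, pr) {
  make_logpost_fn(data, spec, pr)(theta)
}

#' Maximum a posteriori fit of an agent model to one subject
#'
#' Maximises log-likelihood plus log-prior on the transformed scale from
#' several random starts (BFGS, Nelder-Mead fallback) and returns the best.
#'
#' @param data One subject's trial table (as from [simulate_agent()]).
#' @param spec A [model_spec()].
#' @param priors A [prior_spec()] (or expanded `list(mu, sd)`).
#' @param n_restarts Number of optimisation starts.
#' @param seed Optional seed for the start jitter.
#' @return An object of class `rl_fit`: list with `params` (an
#'   [agent_params()]), `estimate` (named natural-scale vector), `theta`,
#'   `loglik`, `logpost`, `convergence`, `spec`, `n_trials`, `subject_id`.
#' @export
fit_rl_map <- function(data, spec = winning_model_spec(),
                       priors = prior_spec(), n_restarts = 2L, seed = NULL) {
  stopifnot(nrow(data) >= 1L)
  local_seed_if(seed)
  pr <- expand_prior(priors, spec)
  k <- length(pr$mu)
  lpfn <- make_logpost_fn(data, spec, pr)
  negobj <- function(theta) -lpfn(theta)
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    start <- pr$mu + if (r == 1L) 0 else stats::rnorm(k, 0, 0.7)
    fit <- tryCatch(
      stats::optim(start, negobj, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) {
      fit <- tryCatch(
        stats::optim(start, negobj, method = "Nelder-Mead",
                     control = list(maxit = 2000)),
        error = function(e) NULL)
    }
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("all optimisation restarts failed to converge", call. = FALSE)
  }
  params <- unpack_theta(best$par, spec)
  theta <- best$par
  names(theta) <- param_names(spec)
  structure(list(
    subject_id = data$subject_id[1] %||% NA_character_,
    spec = spec,
    params = params,
    estimate = params_to_vector(params, spec),
    theta = theta,
    loglik = loglik_quiet(data, params),
    logpost = -best$value,
    convergence = best$convergence,
    n_trials = nrow(data)
  ), class = "rl_fit")
}

#' @export
print.rl_fit <- function(x, ...) {
  cat("<rl_fit> model:", x$spec$name, " subject:", x$subject_id, "\n")
  print(round(x$estimate, 4))
  cat("log-lik:", round(x$loglik, 2), " log-post:", round(x$logpost, 2), "\n")
  invisible(x)
}

#' Broom-style tidier for an `rl_fit`
#'
#' @param x An `rl_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate` (natural scale).
#' @exportS3Method generics::tidy
tidy.rl_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate))
}

#' @rdname tidy.rl_fit
#' @return For `glance`, a one-row tibble with fit summaries.
#' @exportS3Method generics::glance
glance.rl_fit <- function(x, ...) {
  tibble::tibble(model = x$spec$name, n_params = length(x$estimate),
                 n_trials = x$n_trials, loglik = x$loglik,
                 logpost = x$logpost, convergence = x$convergence)
}

#' Random-walk Metropolis posterior sampling for one subject
#'
#' Samples the transformed parameters with a diagonal random-walk proposal,
#' adapting the global step size during burn-in towards a 20-45% acceptance
#' rate; draws are returned on the natural scale.
#'
#' @inheritParams fit_rl_map
#' @param n_samples Number of retained draws (must be positive).
#' @param burn_in Number of discarded adaptation iterations.
#' @param init Optional starting value (transformed scale); defaults to the
#'   MAP estimate.
#' @return An object of class `rl_posterior`: list with `draws` (tibble,
#'   natural scale), `acceptance`, `n_samples`, `spec`.
#' @export
sample_rl_posterior <- function(data, spec = winning_model_spec(),
                                priors = prior_spec(), n_samples = 2000L,
                                burn_in = 1000L, seed = NULL, init = NULL) {
  if (n_samples <= 0L) stop("n_samples must be positive", call. = FALSE)
  local_seed_if(seed)
  pr <- expand_prior(priors, spec)
  k <- length(pr$mu)
  theta <- init %||% fit_rl_map(data, spec, priors, n_restarts = 1L)$theta
  lpfn <- make_logpost_fn(data, spec, pr)
  lp <- lpfn(theta)
  scale <- 0.3
  total <- burn_in + n_samples
  draws <- matrix(NA_real_, n_samples, k)
  acc_window <- 0L
  accepted <- 0L
  for (i in seq_len(total)) {
    prop <- theta + stats::rnorm(k, 0, scale)
    lp_prop <- lpfn(prop)
    if (log(stats::runif(1)) < lp_prop - lp) {
      theta <- prop
      lp <- lp_prop
      acc_window <- acc_window + 1L
      if (i > burn_in) accepted <- accepted + 1L
    }
    if (i <= burn_in && i %% 50L == 0L) {
      rate <- acc_window / 50
      if (rate < 0.20) scale <- scale * 0.7
      if (rate > 0.45) scale <- scale * 1.4
      acc_window <- 0L
    }
    if (i > burn_in) draws[i - burn_in, ] <- theta
  }
  acc_rate <- accepted / n_samples
  if (acc_rate < 0.05) {
    warning(sprintf(
      "MCMC diagnostic failure: acceptance rate %.1f%% after adaptation",
      100 * acc_rate))
  }
  nat <- purrr::map(seq_len(n_samples),
                    function(i) params_to_vector(unpack_theta(draws[i, ], spec), spec))
  nat <- do.call(rbind, nat)
  structure(list(
    draws = tibble::as_tibble(as.data.frame(nat)),
    acceptance = acc_rate,
    n_samples = n_samples,
    step_scale = scale,
    spec = spec
  ), class = "rl_posterior")
}

#' Fit every subject of a cohort by MAP
#'
#' @param cohort A cohort trial table (rows = trials, many subjects).
#' @inheritParams fit_rl_map
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   `order`, one column per natural-scale parameter, `loglik`,
#'   `convergence`.
#' @export
fit_cohort <- function(cohort, spec = winning_model_spec(),
                       priors = prior_spec(), n_restarts = 2L, seed = NULL) {
  assert_columns(cohort, c("subject_id", "chose_A", "win_on_A", "loss_on_A", "block"))
  local_seed_if(seed)
  subs <- split(cohort, cohort$subject_id)
  rows <- purrr::imap(subs, function(d, sid) {
    f <- fit_rl_map(d, spec, priors, n_restarts = n_restarts)
    tibble::tibble(
      subject_id = sid,
      group = d$group[1] %||% NA_character_,
      order = d$order[1] %||% NA_character_,
      !!!as.list(f$estimate),
      loglik = f$loglik,
      convergence = f$convergence
    )
  })
  dplyr::bind_rows(rows)
}
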