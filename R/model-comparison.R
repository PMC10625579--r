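# internal: MAP-fit all subjects under an expanded prior, return theta matrix
fit_subjects_theta <- function(datasets, spec, pr, n_restarts = 1L) {
  th <- purrr::map(datasets, function(d) {
    fit_rl_map(d, spec, priors = pr, n_restarts = n_restarts)$theta
  })
  do.call(rbind, th)
}

#' Monte-Carlo marginal log-likelihood of one subject under a group prior
#'
#' Estimates `p(data) = integral L(data | theta) N(theta; mu, sd) dtheta`
#' on the transformed scale by importance sampling with a defensive
#' mixture proposal: half the draws come from the prior itself, half from
#' a Laplace approximation centred on the subject's MAP under that prior.
#' Because the proposal dominates the prior everywhere, the weights are
#' bounded and the estimate converges quickly even when a subject's
#' likelihood peak sits in the prior's tail (where a plain prior-draw
#' average is ruinously noisy).
#'
#' @param data One subject's trial table.
#' @param spec A [model_spec()].
#' @param mu,sd Group-prior moments on the transformed scale (aligned with
#'   the model's parameter vector).
#' @param n_mc Number of Monte-Carlo draws.
#' @param seed Optional seed.
#' @return Scalar marginal log-likelihood estimate (<= 0 for choice data).
#' @export
marginal_loglik <- function(data, spec, mu, sd, n_mc = 500L, seed = NULL) {
  local_seed_if(seed)
  k <- length(mu)
  llfn <- make_loglik_fn(data)
  pr <- list(mu = mu, sd = sd)
  map <- fit_rl_map(data, spec, priors = pr, n_restarts = 1L)
  lpfn <- make_logpost_fn(data, spec, pr)
  hess <- tryCatch(stats::optimHess(map$theta, function(t) -lpfn(t)),
                   error = function(e) NULL)
  lap_sd <- rep(NA_real_, k)
  if (!is.null(hess)) {
    d <- diag(hess)
    lap_sd <- ifelse(is.finite(d) & d > 0, 1 / sqrt(d), NA_real_)
  }
  lap_sd <- ifelse(is.na(lap_sd), sd, pmin(1.5 * lap_sd, sd))
  lw <- vapply(seq_len(n_mc), function(j) {
    from_prior <- stats::runif(1) < 0.5
    theta <- if (from_prior) stats::rnorm(k, mu, sd)
             else stats::rnorm(k, map$theta, lap_sd)
    raw <- theta_to_raw(theta, spec)
    lp <- sum(stats::dnorm(theta, mu, sd, log = TRUE))
    lq <- log(0.5) + log_sum_exp(c(
      sum(stats::dnorm(theta, mu, sd, log = TRUE)),
      sum(stats::dnorm(theta, map$theta, lap_sd, log = TRUE))))
    llfn(raw$alpha, raw$beta, raw$bias) + lp - lq
  }, numeric(1))
  log_sum_exp(lw) - log(n_mc)
}

#' Compare agent models by the integrated BIC
#'
#' Empirical-Bayes scheme: for each candidate model, a factorised normal
#' group prior on the transformed parameters is fitted by iterating between
#' MAP fits of all subjects under the current prior and moment updates of
#' the prior from the subject estimates. Per-subject marginal likelihoods
#' are then estimated by [marginal_loglik()], and
#' `iBIC = -2 * sum_s log p(data_s) + k_prior * log(total choices)` where
#' `k_prior` counts the group-level hyperparameters (a mean and an SD per
#' parameter). The winning model minimises iBIC.
#'
#' @param cohort A cohort trial table (>= 2 subjects).
#' @param specs Named list of [model_spec()]s; defaults to [model_family()].
#' @param priors Initial [prior_spec()].
#' @param n_mc Monte-Carlo draws per subject for the marginal likelihood.
#' @param max_iter Empirical-Bayes iterations.
#' @param n_restarts MAP restarts inside the loop.
#' @param sd_floor Lower bound for fitted prior SDs (degenerate-variance
#'   guard; flooring triggers a warning).
#' @param seed Optional seed.
#' @return A tibble of class `ibic_comparison` with one row per model:
#'   `model`, `n_params`, `k_prior`, `sum_marginal_loglik`, `penalty`,
#'   `ibic`, `winner`; fitted group priors in attribute `"priors"`.
#' @export
integrated_bic <- function(cohort, specs = model_family(),
                           priors = prior_spec(), n_mc = 1000L,
                           max_iter = 3L, n_restarts = 1L,
                           sd_floor = 0.1, seed = NULL) {
  datasets <- split(cohort, cohort$subject_id)
  if (length(datasets) < 2L) stop("need at least 2 subjects", call. = FALSE)
  local_seed_if(seed)
  total_choices <- nrow(cohort)
  fitted_priors <- list()
  rows <- purrr::imap(specs, function(spec, nm) {
    pr <- expand_prior(priors, spec)
    for (it in seq_len(max_iter)) {
      th <- fit_subjects_theta(datasets, spec, pr, n_restarts)
      mu_new <- colMeans(th)
      sd_new <- apply(th, 2, stats::sd)
      if (any(sd_new < sd_floor)) {
        warning(sprintf("model %s: prior SD floored at %.2f", nm, sd_floor))
        sd_new <- pmax(sd_new, sd_floor)
      }
      moved <- max(abs(mu_new - pr$mu), abs(sd_new - pr$sd))
      pr <- list(mu = mu_new, sd = sd_new)
      if (moved < 0.02) break
    }
    fitted_priors[[nm]] <<- pr
    ml <- vapply(datasets, function(d) {
      marginal_loglik(d, spec, pr$mu, pr$sd, n_mc = n_mc)
    }, numeric(1))
    k_prior <- 2L * length(pr$mu)
    penalty <- k_prior * log(total_choices)
    tibble::tibble(model = nm, n_params = length(pr$mu), k_prior = k_prior,
                   sum_marginal_loglik = sum(ml), penalty = penalty,
                   ibic = -2 * sum(ml) + penalty)
  })
  out <- dplyr::bind_rows(rows)
  out$winner <- out$ibic == min(out$ibic)
  out <- dplyr::arrange(out, .data$ibic)
  attr(out, "priors") <- fitted_priors
  class(out) <- c("ibic_comparison", class(out))
  out
}

#' Parameter-recovery harness
#'
#' Simulates agents at known parameters, refits them by MAP, and tabulates
#' per-parameter recovery (correlation between true and recovered values,
#' mean bias, RMSE). Parameters with recovery correlation below
#' `flag_threshold` (or undefined, e.g. with a single replicate) are
#' flagged.
#'
#' @param spec A [model_spec()].
#' @param design Optional tibble of true natural-scale parameter values
#'   (columns = [param_names()] of the spec), one row per replicate. By
#'   default `n_reps` rows with learning rates uniform on `[0.05, 0.8]` and
#'   beta uniform on `[1, 15]`.
#' @param n_reps Number of replicates when `design` is NULL.
#' @param config Schedule configuration for the simulated task.
#' @param priors,n_restarts Passed to [fit_rl_map()].
#' @param flag_threshold Correlation below which a parameter is flagged.
#' @param seed Optional seed.
#' @return A tibble with one row per parameter: `term`, `cor`, `bias`,
#'   `rmse`, `flagged`; the per-replicate true/recovered values in
#'   attribute `"values"`.
#' @export
parameter_recovery <- function(spec = winning_model_spec(), design = NULL,
                               n_reps = 40L, config = schedule_config(),
                               priors = prior_spec(), n_restarts = 1L,
                               flag_threshold = 0.5, seed = NULL) {
  local_seed_if(seed)
  nms <- param_names(spec)
  if (is.null(design)) {
    na <- n_alpha(spec)
    design <- purrr::map(seq_len(n_reps), function(i) {
      v <- c(stats::runif(na, 0.05, 0.8), stats::runif(1, 1, 15),
             if (spec$include_bias) stats::rnorm(1, 0, 0.5))
      stats::setNames(as.list(v), nms)
    })
    design <- dplyr::bind_rows(design)
  }
  assert_columns(design, nms, "design")
  rec <- purrr::map(seq_len(nrow(design)), function(i) {
    truth <- unlist(design[i, nms])
    theta <- c(logit(truth[seq_len(n_alpha(spec))]),
               log(truth[["beta"]]),
               if (spec$include_bias) truth[["bias"]])
    params <- unpack_theta(theta, spec)
    sched <- generate_schedule(config)
    sim <- simulate_agent(sched, params, subject_id = paste0("rep", i))
    fit <- fit_rl_map(sim, spec, priors, n_restarts = n_restarts)
    fit$estimate
  })
  rec <- do.call(rbind, rec)
  values <- tidyr::pivot_longer(
    dplyr::bind_cols(
      rep = seq_len(nrow(design)),
      dplyr::rename_with(design[nms], ~ paste0("true.", .x)),
      dplyr::rename_with(tibble::as_tibble(as.data.frame(rec)), ~ paste0("fit.", .x))
    ),
    cols = -"rep",
    names_to = c(".value", "term"), names_sep = "\\."
  )
  out <- dplyr::summarise(
    dplyr::group_by(values, .data$term),
    cor = if (dplyr::n() >= 3L && stats::sd(.data$true) > 0)
      stats::cor(.data$true, .data$fit) else NA_real_,
    bias = mean(.data$fit - .data$true),
    rmse = sqrt(mean((.data$fit - .data$true)^2)),
    .groups = "drop"
  )
  out$flagged <- is.na(out$cor) | out$cor < flag_threshold
  out <- out[match(nms, out$term), ]
  attr(out, "values") <- values
  out
}

#' Posterior-predictive check of fitted agents
#'
#' Re-simulates every fitted subject on their own schedule `n_sim` times at
#' the fitted parameters, and compares observed switch/stay statistics per
#' valence x volatility cell against the simulated mean and 95% interval.
#'
#' @param fits Cohort fit table from [fit_cohort()] (winning model layout).
#' @param cohort The cohort trial table the fits came from.
#' @param n_sim Simulations per subject.
#' @param seed Optional seed.
#' @return A tibble with one row per subject x cell: `subject_id`, `group`,
#'   `valence`, `volatility`, `observed`, `sim_mean`, `sim_lo`, `sim_hi`,
#'   `covered`, plus one row per subject for the win total
#'   (`valence = "money"`, `volatility = "total"`).
#' @export
posterior_predictive_check <- function(fits, cohort, n_sim = 100L, seed = NULL) {
  if (nrow(fits) == 0L) stop("empty fits table", call. = FALSE)
  local_seed_if(seed)
  spec <- winning_model_spec()
  rows <- purrr::map(seq_len(nrow(fits)), function(i) {
    frow <- fits[i, ]
    d <- cohort[cohort$subject_id == frow$subject_id, ]
    params <- agent_params(
      matrix(c(frow$alpha_win_1, frow$alpha_win_2, frow$alpha_win_3,
               frow$alpha_loss_1, frow$alpha_loss_2, frow$alpha_loss_3), 3, 2),
      beta = frow$beta)
    obs_stay <- compute_stay_cells(d)
    obs <- dplyr::bind_rows(
      dplyr::select(obs_stay, "valence", "volatility", observed = "stay_proportion"),
      tibble::tibble(valence = "money", volatility = "total",
                     observed = d$money_after[nrow(d)])
    )
    sims <- purrr::map(seq_len(n_sim), function(j) {
      s <- simulate_agent(d, params, subject_id = frow$subject_id)
      st <- compute_stay_cells(s)
      dplyr::bind_rows(
        dplyr::select(st, "valence", "volatility", value = "stay_proportion"),
        tibble::tibble(valence = "money", volatility = "total",
                       value = s$money_after[nrow(s)])
      )
    })
    simd <- dplyr::bind_rows(sims)
    summ <- dplyr::summarise(
      dplyr::group_by(simd, .data$valence, .data$volatility),
      sim_mean = mean(.data$value, na.rm = TRUE),
      sim_lo = stats::quantile(.data$value, 0.025, na.rm = TRUE, names = FALSE),
      sim_hi = stats::quantile(.data$value, 0.975, na.rm = TRUE, names = FALSE),
      .groups = "drop")
    out <- dplyr::left_join(obs, summ, by = c("valence", "volatility"))
    dplyr::mutate(out, subject_id = frow$subject_id, group = frow$group,
                  covered = .data$observed >= .data$sim_lo &
                    .data$observed <= .data$sim_hi,
                  .before = 1L)
  })
  dplyr::bind_rows(rows)
}
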