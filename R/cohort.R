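#' Group presets for the synthetic cohort
#'
#' Each participant group is described by its size, the normal distribution
#' of per-valence learning-rate adjustments (volatile minus stable), the
#' distribution of stable learning rates and inverse temperatures, the
#' pupil receipt-response amplitudes per valence x volatility cell, and an
#' optional coupling between a subject's reward adjustment and their
#' volatile-reward pupil amplitude. Default adjustment distributions match
#' the three study groups (RA 0.191/0.169, EA 0.134/0.180, HC 0.107/0.195,
#' n = 25/25/32); the RA preset adds greater dilation to stable rewards,
#' reduced dilation to stable losses, and a positive reward
#' pupil-adjustment coupling.
#'
#' @param name Group label.
#' @param n_subjects Group size.
#' @param adjustment_mean,adjustment_sd Normal distribution of the
#'   per-valence learning-rate adjustment.
#' @param stable_alpha_mean,stable_alpha_sd Normal distribution (truncated
#'   to `[0.02, 0.98]`) of the stable-block learning rate.
#' @param beta_meanlog,beta_sdlog Log-normal inverse-temperature
#'   distribution.
#' @param pupil_receipt Named amplitudes (arbitrary units) of the pupil
#'   response to *received* outcomes: `win_volatile`, `win_stable`,
#'   `loss_volatile`, `loss_stable`.
#' @param pupil_nonreceipt Amplitude of the response to shown-but-not-
#'   received outcomes.
#' @param pupil_amp_sd Between-subject SD of cell amplitudes.
#' @param coupling_slope Added volatile-reward amplitude per unit of the
#'   subject's reward adjustment (0 = no coupling).
#' @return A list of class `group_preset`.
#' @export
group_preset <- function(name, n_subjects, adjustment_mean, adjustment_sd,
                         stable_alpha_mean = 0.2, stable_alpha_sd = 0.06,
                         beta_meanlog = log(6), beta_sdlog = 0.4,
                         pupil_receipt = c(win_volatile = 0.6, win_stable = 0.4,
                                           loss_volatile = 0.6, loss_stable = 0.4),
                         pupil_nonreceipt = 0.2,
                         pupil_amp_sd = 0.15,
                         coupling_slope = 0) {
  stopifnot(n_subjects >= 1L, adjustment_sd >= 0)
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 adjustment_mean = adjustment_mean, adjustment_sd = adjustment_sd,
                 stable_alpha_mean = stable_alpha_mean,
                 stable_alpha_sd = stable_alpha_sd,
                 beta_meanlog = beta_meanlog, beta_sdlog = beta_sdlog,
                 pupil_receipt = pupil_receipt,
                 pupil_nonreceipt = pupil_nonreceipt,
                 pupil_amp_sd = pupil_amp_sd,
                 coupling_slope = coupling_slope),
            class = "group_preset")
}

#' @rdname group_preset
#' @export
default_presets <- function() {
  list(
    # coupling_slope targets a within-RA pupil-adjustment correlation of
    # ~0.5: the subtraction series carries amplitude jitter from both the
    # volatile and stable win cells (sd sqrt(2) * 0.15), so
    # slope = r/sqrt(1-r^2) * sqrt(2)*0.15 / 0.169 ~= 0.72
    RA = group_preset("RA", 25, 0.191, 0.169,
                      pupil_receipt = c(win_volatile = 0.6, win_stable = 0.7,
                                        loss_volatile = 0.6, loss_stable = 0.15),
                      coupling_slope = 0.72),
    EA = group_preset("EA", 25, 0.134, 0.180),
    HC = group_preset("HC", 32, 0.107, 0.195)
  )
}

#' Pupil trace noise/response model
#'
#' @param native_rate_hz Sampling rate of the simulated eye-tracker stream.
#' @param base_diameter Mean pupil diameter (arbitrary units).
#' @param white_sd White measurement-noise SD.
#' @param drift_sd SD of the slow diameter drift (spline through knots).
#' @param drift_knot_s Spacing of drift knots in seconds.
#' @param blink_rate_hz Poisson blink rate per second.
#' @param blink_dur_ms Range of blink durations.
#' @param kernel_shape,kernel_scale_s Gamma impulse-response parameters
#'   (mode at `(shape - 1) * scale` seconds after the event).
#' @param kernel_dur_s Kernel support truncation.
#' @return A list of class `pupil_noise`.
#' @export
pupil_noise <- function(native_rate_hz = 100, base_diameter = 4,
                        white_sd = 0.1, drift_sd = 0.3, drift_knot_s = 30,
                        blink_rate_hz = 0.1, blink_dur_ms = c(100, 300),
                        kernel_shape = 3, kernel_scale_s = 0.5,
                        kernel_dur_s = 5) {
  structure(list(native_rate_hz = native_rate_hz, base_diameter = base_diameter,
                 white_sd = white_sd, drift_sd = drift_sd,
                 drift_knot_s = drift_knot_s, blink_rate_hz = blink_rate_hz,
                 blink_dur_ms = blink_dur_ms, kernel_shape = kernel_shape,
                 kernel_scale_s = kernel_scale_s, kernel_dur_s = kernel_dur_s),
            class = "pupil_noise")
}

#' Cohort configuration
#'
#' @param presets Named list of [group_preset()]s.
#' @param noise A [pupil_noise()] model.
#' @param schedule_config A [schedule_config()] template (the block order is
#'   counterbalanced per subject).
#' @param master_seed Master seed; every stage seed derives from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(presets = default_presets(), noise = pupil_noise(),
                          schedule_config = volatilearn::schedule_config(),
                          master_seed = 1L) {
  structure(list(presets = presets, noise = noise,
                 schedule_config = schedule_config,
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

#' Sample subject-level agent parameters from a group preset
#'
#' Per subject and valence: the stable learning rate is drawn from the
#' preset's truncated-normal base distribution, the adjustment from
#' `Normal(adjustment_mean, adjustment_sd)`, and the volatile rate is
#' stable + adjustment, truncated to `[0.02, 0.98]`. Block-1 rates equal
#' the volatile rates (block 1 is volatile for both valences). Warns when
#' truncation moves the realised mean adjustment by more than 0.05.
#'
#' @param preset A [group_preset()].
#' @param n Number of subjects (defaults to the preset size).
#' @param seed Optional seed.
#' @return A tibble with one row per subject: drawn adjustments, stable and
#'   volatile rates per valence (post-truncation), and `beta`.
#' @export
sample_group_params <- function(preset, n = preset$n_subjects, seed = NULL) {
  local_seed_if(seed)
  trunc01 <- function(x) pmin(0.98, pmax(0.02, x))
  out <- tibble::tibble(
    group = preset$name,
    subject = seq_len(n),
    alpha_stable_win = trunc01(stats::rnorm(n, preset$stable_alpha_mean,
                                            preset$stable_alpha_sd)),
    alpha_stable_loss = trunc01(stats::rnorm(n, preset$stable_alpha_mean,
                                             preset$stable_alpha_sd)),
    adjustment_win = stats::rnorm(n, preset$adjustment_mean, preset$adjustment_sd),
    adjustment_loss = stats::rnorm(n, preset$adjustment_mean, preset$adjustment_sd),
    beta = stats::rlnorm(n, preset$beta_meanlog, preset$beta_sdlog)
  )
  out$alpha_volatile_win <- trunc01(out$alpha_stable_win + out$adjustment_win)
  out$alpha_volatile_loss <- trunc01(out$alpha_stable_loss + out$adjustment_loss)
  realised <- mean(c(out$alpha_volatile_win - out$alpha_stable_win,
                     out$alpha_volatile_loss - out$alpha_stable_loss))
  drawn <- mean(c(out$adjustment_win, out$adjustment_loss))
  if (abs(realised - drawn) > 0.05) {
    warning(sprintf(
      "truncation moved the mean adjustment by %.3f (drawn %.3f, realised %.3f)",
      realised - drawn, drawn, realised))
  }
  out
}

# agent_params for one sampled subject given their block order
params_from_draws <- function(draw, block_order) {
  bc <- block_conditions(block_order)
  a <- matrix(NA_real_, 3, 2)
  for (b in 1:3) {
    a[b, 1] <- if (bc$win_condition[b] == "volatile") draw$alpha_volatile_win
               else draw$alpha_stable_win
    a[b, 2] <- if (bc$loss_condition[b] == "volatile") draw$alpha_volatile_loss
               else draw$alpha_stable_loss
  }
  agent_params(a, beta = draw$beta)
}

#' Simulate a pupil trace for one subject's task run
#'
#' The trace is a base diameter plus a slow drift, a gamma-shaped impulse
#' response added at every outcome onset (amplitude set by the preset's
#' receipt/non-receipt cell amplitudes plus subject-level variability and,
#' when `adjustment` is supplied with a non-zero `coupling_slope`, a
#' volatile-reward amplitude proportional to the subject's reward
#' adjustment), white measurement noise, and Poisson blinks (zeroed and
#' invalid-flagged).
#'
#' @param dataset One subject's trial table (needs `win_received`,
#'   `loss_received`, `win_condition`, `loss_condition`,
#'   `win_shown_first`, `inter_outcome_delay_s`).
#' @param preset A [group_preset()].
#' @param noise A [pupil_noise()] model.
#' @param adjustment Optional list/row with `adjustment_win` used for the
#'   pupil-behaviour coupling.
#' @param seed Optional seed.
#' @return A list of class `pupil_trace` with `samples` (tibble `t_ms`,
#'   `pupil`, `valid`) and `events` (tibble `subject_id`, `trial`, `block`,
#'   `valence`, `received`, `volatility`, `onset_ms`).
#' @export
simulate_pupil_trace <- function(dataset, preset, noise = pupil_noise(),
                                 adjustment = NULL, seed = NULL) {
  local_seed_if(seed)
  nt <- nrow(dataset)
  # timeline: 2 s pre-outcome period, first outcome, jittered delay, second
  # outcome, 5 s tail
  dur <- 2 + dataset$inter_outcome_delay_s + 5
  start <- c(0, cumsum(dur))[seq_len(nt)]
  first_on <- start + 2
  second_on <- first_on + dataset$inter_outcome_delay_s
  ev <- tibble::tibble(
    subject_id = rep(dataset$subject_id %||% "s1", 2),
    trial = rep(seq_len(nt), 2),
    block = rep(dataset$block, 2),
    valence = c(ifelse(dataset$win_shown_first, "win", "loss"),
                ifelse(dataset$win_shown_first, "loss", "win")),
    onset_ms = 1000 * c(first_on, second_on)
  )
  ev <- dplyr::arrange(ev, .data$onset_ms)
  ev$received <- ifelse(ev$valence == "win",
                        dataset$win_received[ev$trial],
                        dataset$loss_received[ev$trial])
  ev$volatility <- ifelse(ev$valence == "win",
                          dataset$win_condition[ev$trial],
                          dataset$loss_condition[ev$trial])
  total_s <- sum(dur)
  dt <- 1 / noise$native_rate_hz
  t_s <- seq(0, total_s, by = dt)
  n <- length(t_s)
  # slow drift: smooth spline through sparse normal knots
  knots <- seq(0, total_s, by = noise$drift_knot_s)
  drift <- if (noise$drift_sd > 0 && length(knots) > 3) {
    stats::spline(knots, stats::rnorm(length(knots), 0, noise$drift_sd),
                  xout = t_s)$y
  } else rep(0, n)
  pupil <- noise$base_diameter + drift +
    if (noise$white_sd > 0) stats::rnorm(n, 0, noise$white_sd) else 0
  # gamma kernel normalised to unit peak
  k_t <- seq(0, noise$kernel_dur_s, by = dt)
  mode <- (noise$kernel_shape - 1) * noise$kernel_scale_s
  kern <- stats::dgamma(k_t, shape = noise$kernel_shape,
                        scale = noise$kernel_scale_s) /
    stats::dgamma(mode, shape = noise$kernel_shape, scale = noise$kernel_scale_s)
  amp_jitter <- stats::rnorm(4, 0, preset$pupil_amp_sd)
  names(amp_jitter) <- names(preset$pupil_receipt)
  coupling <- 0
  if (!is.null(adjustment) && preset$coupling_slope != 0) {
    coupling <- preset$coupling_slope * adjustment$adjustment_win
  }
  for (i in seq_len(nrow(ev))) {
    cell <- paste(ev$valence[i], ev$volatility[i], sep = "_")
    amp <- if (ev$received[i]) {
      preset$pupil_receipt[[cell]] + amp_jitter[[cell]] +
        if (cell == "win_volatile") coupling else 0
    } else preset$pupil_nonreceipt
    i0 <- as.integer(round(ev$onset_ms[i] / 1000 / dt)) + 1L
    idx <- i0:min(n, i0 + length(kern) - 1L)
    pupil[idx] <- pupil[idx] + amp * kern[seq_along(idx)]
  }
  valid <- rep(TRUE, n)
  if (noise$blink_rate_hz > 0) {
    n_blinks <- stats::rpois(1, noise$blink_rate_hz * total_s)
    if (n_blinks > 0) {
      onsets <- sort(stats::runif(n_blinks, 0, total_s))
      durs <- stats::runif(n_blinks, noise$blink_dur_ms[1] / 1000,
                           noise$blink_dur_ms[2] / 1000)
      for (j in seq_len(n_blinks)) {
        i0 <- max(1L, as.integer(ceiling(onsets[j] / dt)) + 1L)
        i1 <- min(n, as.integer(floor((onsets[j] + durs[j]) / dt)) + 1L)
        if (i0 <= i1) {
          pupil[i0:i1] <- 0
          valid[i0:i1] <- FALSE
        }
      }
    }
  }
  structure(list(
    samples = tibble::tibble(t_ms = t_s * 1000, pupil = pupil, valid = valid),
    events = ev
  ), class = "pupil_trace")
}

#' Simulate a complete synthetic study cohort
#'
#' Per subject: a task schedule (block order counterbalanced within group),
#' agent parameters drawn from the group preset, simulated choices, and
#' (optionally) a simulated pupil trace aligned to the outcome events.
#' Fully reproducible from the config's master seed.
#'
#' @param config A [cohort_config()].
#' @param include_pupil Simulate pupil traces?
#' @return A list of class `synthetic_cohort`: `behaviour` (trial table for
#'   all subjects), `params` (true parameter table), `pupil` (named list of
#'   `pupil_trace` objects, or NULL), `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), include_pupil = FALSE) {
  behaviour <- list(); params <- list(); pupil <- list()
  for (gname in names(config$presets)) {
    preset <- config$presets[[gname]]
    draws <- sample_group_params(
      preset, seed = derive_seed(config$master_seed, paste0("params_", gname)))
    for (i in seq_len(nrow(draws))) {
      sid <- sprintf("%s_%02d", gname, i)
      order <- if (i %% 2L == 1L) "win_volatile_second" else "loss_volatile_second"
      cfg <- config$schedule_config
      cfg$block_order <- order
      sched <- generate_schedule(cfg, seed = derive_seed(config$master_seed,
                                                         paste0("sched_", sid)))
      pars <- params_from_draws(draws[i, ], order)
      dat <- simulate_agent(sched, pars,
                            seed = derive_seed(config$master_seed,
                                               paste0("choices_", sid)),
                            subject_id = sid, group = gname)
      behaviour[[sid]] <- dat
      params[[sid]] <- dplyr::mutate(draws[i, ], subject_id = sid,
                                     order = order, .before = 1L)
      if (include_pupil) {
        pupil[[sid]] <- simulate_pupil_trace(
          dat, preset, config$noise, adjustment = draws[i, ],
          seed = derive_seed(config$master_seed, paste0("pupil_", sid)))
      }
    }
  }
  structure(list(behaviour = dplyr::bind_rows(behaviour),
                 params = dplyr::bind_rows(params),
                 pupil = if (include_pupil) pupil else NULL,
                 config = config),
            class = "synthetic_cohort")
}
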