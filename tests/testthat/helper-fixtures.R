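# Shared fixture builders. Everything is generated in code under fixed seeds.

# A small three-group cohort config with scaled-down group sizes.
quick_cohort_config <- function(n_ra = 6L, n_ea = 6L, n_hc = 6L,
                                master_seed = 101L, rate_hz = 60) {
  pre <- default_presets()
  pre$RA$n_subjects <- as.integer(n_ra)
  pre$EA$n_subjects <- as.integer(n_ea)
  pre$HC$n_subjects <- as.integer(n_hc)
  cohort_config(presets = pre, noise = pupil_noise(native_rate_hz = rate_hz),
                master_seed = master_seed)
}

# One simulated subject at given parameters.
make_subject <- function(seed, alpha = matrix(0.3, 3, 2), beta = 6, bias = 0,
                         order = "win_volatile_second", subject_id = "s1",
                         group = "HC") {
  cfg <- schedule_config(block_order = order)
  sched <- generate_schedule(cfg, seed = seed)
  simulate_agent(sched, agent_params(alpha, beta = beta, bias = bias),
                 seed = seed + 1L, subject_id = subject_id, group = group)
}

# Long-format null time-series for the cluster permutation test:
# `n_per_group` subjects per group, `n_time` timepoints, AR(1) temporal
# noise, a subject random intercept shared across valences (enters the
# subject mean, not the valence difference, keeping the flip-null exact).
make_series <- function(n_per_group = 8L, n_time = 100L, ar = 0.7,
                        groups = c("RA", "EA", "HC"),
                        effect = NULL) {
  n <- n_per_group * length(groups)
  times <- seq(0, by = 20, length.out = n_time)
  rows <- list()
  for (i in seq_len(n)) {
    g <- groups[ceiling(i / n_per_group)]
    offs <- rnorm(1, 0, 0.5)
    for (v in c("win", "loss")) {
      e <- as.numeric(stats::arima.sim(list(ar = ar), n_time, sd = 1))
      val <- offs + e
      if (!is.null(effect)) val <- val + effect(g, v, times)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sprintf("s%03d", i), group = g, valence = v,
        time = times, value = val)
    }
  }
  dplyr::bind_rows(rows)
}

# Minimal pupil_epochs object built from explicit per-epoch series.
make_epochs <- function(meta, series, times = seq(-1000, 6000, by = 20)) {
  structure(list(meta = meta, series = series, times = times,
                 n_dropped_partial = 0), class = "pupil_epochs")
}

# A numeric vector with exactly the requested mean and sd.
with_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  as.numeric(scale(x)) * sd + mean
}
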