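test_that("group parameter draws follow the preset distributions", {
  pre <- group_preset("RA", 25, 0.191, 0.169)
  big <- sample_group_params(pre, n = 10000, seed = 301)
  drawn <- c(big$adjustment_win, big$adjustment_loss)
  expect_lt(abs(mean(drawn) - 0.191), 0.01)
  expect_lt(abs(sd(drawn) - 0.169), 0.01)
  expect_true(all(big$alpha_volatile_win >= 0.02 & big$alpha_volatile_win <= 0.98))

  # zero spread pins every subject's realised adjustment to the mean
  exact <- sample_group_params(group_preset("x", 10, 0.15, 0), seed = 302)
  expect_equal(exact$alpha_volatile_win - exact$alpha_stable_win,
               rep(0.15, 10))

  # normal support allows negative adjustments
  hc <- sample_group_params(group_preset("HC", 32, 0.107, 0.195), n = 500,
                            seed = 303)
  expect_gt(sum(hc$adjustment_win < 0), 0)

  # heavy truncation is reported
  expect_warning(
    sample_group_params(group_preset("t", 200, -0.6, 0.05), seed = 304),
    "truncation")
})

test_that("the default cohort has the study's size and structure", {
  co <- simulate_cohort(cohort_config(master_seed = 311))
  subj <- dplyr::distinct(co$behaviour, subject_id, group, order)
  expect_identical(nrow(subj), 82L)
  expect_identical(as.integer(table(subj$group)[c("RA", "EA", "HC")]),
                   c(25L, 25L, 32L))
  expect_identical(unique(as.integer(table(co$behaviour$subject_id))), 240L)
  # block order counterbalanced within each group to within one subject
  bal <- dplyr::count(subj, group, order)
  spread <- tapply(bal$n, bal$group, function(x) abs(diff(x)))
  expect_true(all(spread <= 1))
  expect_true(all(co$behaviour$money_after[co$behaviour$trial == 1] %in%
                    c(1.35, 1.5, 1.65)))
})

test_that("cohort simulation is reproducible end-to-end from the master seed", {
  cfg <- quick_cohort_config(2, 2, 2, master_seed = 321)
  a <- simulate_cohort(cfg, include_pupil = TRUE)
  b <- simulate_cohort(cfg, include_pupil = TRUE)
  expect_identical(a$behaviour, b$behaviour)
  expect_identical(a$params, b$params)
  expect_identical(a$pupil[[1]]$samples, b$pupil[[1]]$samples)
})

test_that("noise-free single-event traces reproduce the response kernel", {
  pre <- group_preset("t", 1, 0, 0, pupil_amp_sd = 0,
                      pupil_receipt = c(win_volatile = 1, win_stable = 1,
                                        loss_volatile = 1, loss_stable = 1),
                      pupil_nonreceipt = 1)
  quiet <- pupil_noise(white_sd = 0, drift_sd = 0, blink_rate_hz = 0,
                       native_rate_hz = 100)
  d <- make_subject(331, subject_id = "s1")[1, ]
  tr <- simulate_pupil_trace(d, pre, quiet, seed = 332)
  # all effect amplitudes equal, no noise: flat baseline outside kernels
  expect_equal(min(tr$samples$pupil), quiet$base_diameter)
  # first kernel peaks at the gamma mode after the first onset
  on1 <- min(tr$events$onset_ms)
  seg <- tr$samples[tr$samples$t_ms >= on1 &
                      tr$samples$t_ms < on1 + 2000, ]
  peak_ms <- seg$t_ms[which.max(seg$pupil)] - on1
  expect_equal(peak_ms, 1000 * (quiet$kernel_shape - 1) * quiet$kernel_scale_s,
               tolerance = 20)

  # zero-amplitude events with zero noise give a perfectly flat trace
  flat_pre <- group_preset("t", 1, 0, 0, pupil_amp_sd = 0,
                           pupil_receipt = c(win_volatile = 0, win_stable = 0,
                                             loss_volatile = 0, loss_stable = 0),
                           pupil_nonreceipt = 0)
  tr0 <- simulate_pupil_trace(d, flat_pre, quiet, seed = 333)
  expect_equal(unique(tr0$samples$pupil), quiet$base_diameter)
})

test_that("blink artefacts appear at roughly the configured rate", {
  pre <- default_presets()$HC
  noisy <- pupil_noise(native_rate_hz = 60, blink_rate_hz = 0.3)
  d <- make_subject(341, subject_id = "s1")
  tr <- simulate_pupil_trace(d, pre, noisy, seed = 342)
  total_s <- max(tr$samples$t_ms) / 1000
  expected_frac <- 0.3 * mean(noisy$blink_dur_ms) / 1000
  observed_frac <- mean(!tr$samples$valid)
  expect_gt(observed_frac, 0.5 * expected_frac)
  expect_lt(observed_frac, 1.5 * expected_frac)
  # and preprocessing flags a matching share of interpolated samples
  clean <- preprocess_trace(tr$samples)
  expect_gte(mean(clean$interpolated), observed_frac)
})

test_that("preset group and valence effects are detectable end-to-end", {
  hits <- logical(12)
  for (r in seq_along(hits)) {
    cfg <- quick_cohort_config(16, 16, 16, master_seed = 4000 + r)
    co <- simulate_cohort(cfg, include_pupil = TRUE)
    pcfg <- pupil_config()
    eps <- purrr::imap(co$pupil, function(tr, sid) {
      epoch_outcomes(preprocess_trace(tr$samples, pcfg), tr$events, pcfg, sid)
    })
    kept <- apply_exclusions(bind_epochs(eps), pcfg)
    ct <- condition_timeseries(kept$epochs)
    gmap <- dplyr::distinct(co$params, subject_id, group)
    subtr <- dplyr::left_join(ct$subtraction, gmap, by = "subject_id")
    cl <- cluster_permutation_test(subtr, n_perm = 100,
                                   seed = derive_seed(4000 + r, "cl"))
    hits[r] <- any(cl$effect == "group:valence" & cl$p_value <= 0.05)
  }
  expect_gte(mean(hits), 0.8)
})
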