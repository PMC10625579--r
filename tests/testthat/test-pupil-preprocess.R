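flat_trace <- function(n_s = 30, rate = 100, level = 4) {
  t_ms <- seq(0, n_s * 1000, by = 1000 / rate)
  tibble::tibble(t_ms = t_ms, pupil = level, valid = TRUE)
}

test_that("a fully valid trace passes through unchanged", {
  tr <- flat_trace()
  tr$pupil <- tr$pupil + sin(tr$t_ms / 500)
  out <- preprocess_trace(tr)
  expect_equal(out$pupil, tr$pupil)
  expect_false(any(out$interpolated))
})

test_that("blinks are padded and linearly interpolated", {
  tr <- flat_trace()
  blink <- tr$t_ms >= 10000 & tr$t_ms <= 10200
  tr$pupil[blink] <- 0
  tr$valid[blink] <- FALSE
  out <- preprocess_trace(tr)
  expect_equal(out$pupil, rep(4, nrow(tr)))
  # interpolation extends one padding width beyond the blink
  expect_true(all(out$interpolated[tr$t_ms >= 9910 & tr$t_ms <= 10290]))
  expect_false(any(out$interpolated[tr$t_ms < 9890 | tr$t_ms > 10310]))

  # on a ramp the filled values lie exactly on the line
  tr2 <- flat_trace()
  tr2$pupil <- 3 + 0.0002 * tr2$t_ms
  keepv <- tr2$pupil
  tr2$pupil[blink] <- 0
  tr2$valid[blink] <- FALSE
  out2 <- preprocess_trace(tr2)
  expect_equal(out2$pupil, keepv, tolerance = 1e-9)
})

test_that("unprocessable traces are rejected", {
  tr <- flat_trace(5)
  tr$valid <- FALSE
  expect_error(preprocess_trace(tr), "unprocessable")
  tr2 <- flat_trace(5)
  tr2$t_ms[2] <- tr2$t_ms[1]
  expect_error(preprocess_trace(tr2), "increasing")
})

test_that("epochs span the configured window, subtract baseline, and capture steps", {
  cfg <- pupil_config()
  tr <- flat_trace(30)
  ev <- tibble::tibble(trial = 1:2, valence = c("win", "loss"),
                       received = TRUE, volatility = "volatile",
                       onset_ms = c(5000, 15000))
  out <- preprocess_trace(tr, cfg)
  ep <- epoch_outcomes(out, ev, cfg, subject_id = "s1")
  expect_identical(dim(ep$series), c(2L, 351L))  # 7 s at 50 Hz + 1
  expect_equal(as.vector(ep$series), rep(0, 2 * 351))

  # unit step shortly after the first onset
  tr2 <- flat_trace(30)
  tr2$pupil <- tr2$pupil + as.numeric(tr2$t_ms > 5001)
  ep2 <- epoch_outcomes(preprocess_trace(tr2, cfg), ev[1, ], cfg, "s1")
  rel <- ep2$times
  expect_equal(ep2$series[1, rel <= 0], rep(0, sum(rel <= 0)))
  expect_equal(ep2$series[1, rel >= 40], rep(1, sum(rel >= 40)))

  # windows that leave the trace are dropped and counted
  ev3 <- dplyr::bind_rows(ev, tibble::tibble(
    trial = 3, valence = "win", received = FALSE, volatility = "stable",
    onset_ms = 29800))
  ep3 <- epoch_outcomes(out, ev3, cfg, "s1")
  expect_identical(nrow(ep3$meta), 2L)
  expect_identical(ep3$n_dropped_partial, 1L)
})

test_that("interpolation-based exclusions follow the trial and participant rules", {
  meta <- tibble::tibble(
    subject_id = rep(c("clean", "dirty"), each = 10),
    trial = rep(1:10, 2),
    valence = "win", received = TRUE, volatility = "volatile",
    interp_fraction = c(c(0.45, 0.55, rep(0.1, 8)),
                        c(rep(0.6, 6), rep(0.1, 4))),
    baseline = 0)
  ep <- make_epochs(meta, matrix(0, 20, 351))
  res <- apply_exclusions(ep)
  expect_identical(res$excluded_subjects, "dirty")
  kept <- res$epochs$meta
  expect_false(any(kept$subject_id == "dirty"))
  expect_false(any(kept$interp_fraction > 0.5))
  expect_true(any(kept$interp_fraction == 0.45))
  # decomposition: kept set equals the intersection of the two rules applied
  # in either order
  manual <- meta$interp_fraction <= 0.5 & meta$subject_id != "dirty"
  expect_identical(nrow(kept), sum(manual))
})

test_that("condition series equal hand-computed receipt contrasts and subtractions", {
  grid <- tidyr::expand_grid(valence = c("win", "loss"),
                             volatility = c("volatile", "stable"),
                             received = c(TRUE, FALSE), rep = 1:2)
  meta <- dplyr::mutate(grid, subject_id = "s1", trial = dplyr::row_number(),
                        interp_fraction = 0, baseline = 0)
  level <- with(meta, 2 * received + (valence == "win") +
                  0.5 * (volatility == "volatile") + 0.1 * rep)
  series <- matrix(level, nrow(meta), 351)
  ct <- condition_timeseries(make_epochs(meta, series))
  # receipt - non-receipt = 2 everywhere (rep terms average out)
  expect_true(all(abs(ct$cells$value - 2) < 1e-12))
  expect_true(all(abs(ct$subtraction$value) < 1e-12))

  # a subject missing a cell is flagged and omitted
  meta2 <- meta[!(meta$valence == "win" & meta$volatility == "stable" &
                    meta$received), ]
  series2 <- series[!(meta$valence == "win" & meta$volatility == "stable" &
                        meta$received), ]
  ct2 <- condition_timeseries(make_epochs(meta2, series2))
  expect_identical(ct2$flagged_subjects, "s1")
  expect_identical(nrow(ct2$subtraction), 0L)
})

test_that("the pipeline is invariant to constant diameter shifts", {
  pre <- default_presets()$HC
  d <- make_subject(161, subject_id = "s1")
  tr <- simulate_pupil_trace(d, pre, pupil_noise(native_rate_hz = 60), seed = 162)
  cfg <- pupil_config()
  run <- function(samples) {
    ep <- epoch_outcomes(preprocess_trace(samples, cfg), tr$events, cfg, "s1")
    condition_timeseries(ep)$subtraction$value
  }
  shifted <- tr$samples
  shifted$pupil <- ifelse(shifted$valid, shifted$pupil + 2.5, shifted$pupil)
  expect_equal(run(tr$samples), run(shifted), tolerance = 1e-9)
})
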