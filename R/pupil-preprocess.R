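#' Pupillometry pipeline configuration
#'
#' @param pad_ms Padding around invalid samples also treated as artefactual.
#' @param epoch_start_ms,epoch_end_ms Epoch window relative to outcome onset.
#' @param working_rate_hz Resampling rate of epochs and condition series.
#' @param trial_interp_threshold Epochs with a larger interpolated fraction
#'   are dropped.
#' @param subject_interp_threshold Subjects whose fraction of
#'   above-threshold trials exceeds this are removed.
#' @param smooth_ms Moving-average smoothing width (0 = off).
#' @param max_invalid_fraction Above this overall invalid fraction a trace
#'   is unprocessable.
#' @return A list of class `pupil_config`.
#' @export
pupil_config <- function(pad_ms = 100, epoch_start_ms = -1000,
                         epoch_end_ms = 6000, working_rate_hz = 50,
                         trial_interp_threshold = 0.5,
                         subject_interp_threshold = 0.5,
                         smooth_ms = 0, max_invalid_fraction = 0.95) {
  structure(list(pad_ms = pad_ms, epoch_start_ms = epoch_start_ms,
                 epoch_end_ms = epoch_end_ms, working_rate_hz = working_rate_hz,
                 trial_interp_threshold = trial_interp_threshold,
                 subject_interp_threshold = subject_interp_threshold,
                 smooth_ms = smooth_ms,
                 max_invalid_fraction = max_invalid_fraction),
            class = "pupil_config")
}

#' Clean a raw pupil trace
#'
#' Invalid, missing, or non-positive samples (blinks) are padded by
#' `pad_ms` on each side and linearly interpolated from the flanking valid
#' samples; edge gaps take the nearest valid value. Optional moving-average
#' smoothing. The per-sample `interpolated` flag is propagated downstream
#' to quantify data quality.
#'
#' @param samples Tibble with columns `t_ms`, `pupil`, `valid` (timestamps
#'   strictly increasing).
#' @param cfg A [pupil_config()].
#' @return The samples tibble with cleaned `pupil` and an added logical
#'   `interpolated` column.
#' @export
preprocess_trace <- function(samples, cfg = pupil_config()) {
  assert_columns(samples, c("t_ms", "pupil", "valid"))
  t <- samples$t_ms
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  bad <- !samples$valid | is.na(samples$pupil) | samples$pupil <= 0
  if (mean(bad) > cfg$max_invalid_fraction) {
    stop(sprintf("trace unprocessable: %.0f%% of samples invalid", 100 * mean(bad)),
         call. = FALSE)
  }
  p <- samples$pupil
  if (any(bad)) {
    dt <- stats::median(diff(t))
    pad_n <- max(0L, as.integer(round(cfg$pad_ms / dt)))
    interp <- bad
    if (pad_n > 0L) {
      win <- rep(1, 2L * pad_n + 1L)
      dil <- stats::filter(as.numeric(bad), win, sides = 2)
      dil[is.na(dil)] <- vapply(which(is.na(dil)), function(i) {
        sum(bad[max(1L, i - pad_n):min(length(bad), i + pad_n)])
      }, numeric(1))
      interp <- as.numeric(dil) > 0
    }
    good <- !interp
    if (!any(good)) stop("trace unprocessable: no valid samples left", call. = FALSE)
    p[interp] <- stats::approx(t[good], p[good], xout = t[interp], rule = 2)$y
  } else {
    interp <- bad
  }
  if (cfg$smooth_ms > 0) {
    dt <- stats::median(diff(t))
    w <- max(1L, as.integer(round(cfg$smooth_ms / dt)))
    if (w > 1L) {
      sm <- stats::filter(p, rep(1 / w, w), sides = 2)
      p <- ifelse(is.na(sm), p, as.numeric(sm))
    }
  }
  out <- samples
  out$pupil <- p
  out$interpolated <- interp
  out
}

#' Epoch a cleaned trace around outcome onsets
#'
#' Extracts a fixed window from `epoch_start_ms` to `epoch_end_ms` around
#' every outcome event at the working rate, subtracts the pre-onset
#' baseline (mean over the pre-onset second), and records the fraction of
#' interpolated samples per epoch. Epochs whose window exceeds the trace
#' bounds are dropped.
#'
#' @param samples Cleaned samples from [preprocess_trace()].
#' @param events Tibble with columns `trial`, `valence`, `received`,
#'   `volatility`, `onset_ms` (and optionally `block`).
#' @param cfg A [pupil_config()].
#' @param subject_id Subject label attached to the epochs.
#' @return An object of class `pupil_epochs`: list with `meta` (one row per
#'   epoch: event columns plus `interp_fraction`, `baseline`), `series`
#'   (epochs x timepoints matrix, baseline-subtracted) and `times`
#'   (timepoints in ms relative to onset).
#' @export
epoch_outcomes <- function(samples, events, cfg = pupil_config(),
                           subject_id = events$subject_id[1] %||% "s1") {
  assert_columns(samples, c("t_ms", "pupil"))
  assert_columns(events, c("trial", "valence", "received", "volatility", "onset_ms"))
  if (!"interpolated" %in% names(samples)) samples$interpolated <- FALSE
  rel <- seq(cfg$epoch_start_ms, cfg$epoch_end_ms, by = 1000 / cfg$working_rate_hz)
  t0 <- min(samples$t_ms); t1 <- max(samples$t_ms)
  inside <- events$onset_ms + cfg$epoch_start_ms >= t0 &
    events$onset_ms + cfg$epoch_end_ms <= t1
  ev <- events[inside, ]
  if (nrow(ev) == 0L) stop("no event window fits inside the trace", call. = FALSE)
  series <- matrix(NA_real_, nrow(ev), length(rel))
  interp_frac <- numeric(nrow(ev))
  baseline <- numeric(nrow(ev))
  ts <- samples$t_ms
  dts <- diff(ts)
  regular <- max(dts) - min(dts) < 1e-6
  dt <- dts[1]
  p_all <- samples$pupil
  ifl_all <- as.numeric(samples$interpolated)
  lerp <- function(y, xout) {
    if (regular) {
      pos <- (xout - ts[1]) / dt + 1
      i <- pmin(length(ts) - 1L, pmax(1L, floor(pos)))
      w <- pos - i
      (1 - w) * y[i] + w * y[i + 1L]
    } else {
      stats::approx(ts, y, xout = xout)$y
    }
  }
  for (i in seq_len(nrow(ev))) {
    xout <- ev$onset_ms[i] + rel
    vals <- lerp(p_all, xout)
    ifl <- lerp(ifl_all, xout) > 0
    interp_frac[i] <- mean(ifl)
    baseline[i] <- mean(vals[rel <= 0])
    series[i, ] <- vals - baseline[i]
  }
  meta <- dplyr::mutate(tibble::as_tibble(ev), subject_id = subject_id,
                        interp_fraction = interp_frac, baseline = baseline,
                        .before = 1L)
  structure(list(meta = meta, series = series, times = rel,
                 n_dropped_partial = sum(!inside)),
            class = "pupil_epochs")
}

#' Combine epoch sets from several subjects
#'
#' @param ... `pupil_epochs` objects (or a single list of them).
#' @return A single `pupil_epochs` object.
#' @export
bind_epochs <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "pupil_epochs")) xs <- xs[[1]]
  stopifnot(all(vapply(xs, inherits, logical(1), "pupil_epochs")))
  times <- xs[[1]]$times
  stopifnot(all(vapply(xs, function(x) identical(x$times, times), logical(1))))
  structure(list(meta = dplyr::bind_rows(purrr::map(xs, "meta")),
                 series = do.call(rbind, purrr::map(xs, "series")),
                 times = times,
                 n_dropped_partial = sum(vapply(xs, `[[`, numeric(1),
                                                "n_dropped_partial"))),
            class = "pupil_epochs")
}

#' Apply interpolation-based trial and participant exclusions
#'
#' An epoch is dropped when more than `trial_interp_threshold` of its
#' samples were interpolated; a participant is removed when more than
#' `subject_interp_threshold` of their task trials exceed that trial
#' threshold (a trial's interpolation is the mean over its outcome epochs).
#' The two rules commute: epoch-level exclusion never changes which
#' subjects are removed.
#'
#' @param epochs A `pupil_epochs` object (possibly many subjects).
#' @param cfg A [pupil_config()].
#' @return A list: `epochs` (filtered `pupil_epochs`), `excluded_subjects`,
#'   `n_dropped_epochs`.
#' @export
apply_exclusions <- function(epochs, cfg = pupil_config()) {
  meta <- epochs$meta
  trial_interp <- dplyr::summarise(
    dplyr::group_by(meta, .data$subject_id, .data$trial),
    bad = mean(.data$interp_fraction) > cfg$trial_interp_threshold,
    .groups = "drop")
  subj_bad <- dplyr::summarise(
    dplyr::group_by(trial_interp, .data$subject_id),
    frac_bad = mean(.data$bad), .groups = "drop")
  excluded <- subj_bad$subject_id[subj_bad$frac_bad > cfg$subject_interp_threshold]
  keep <- !(meta$subject_id %in% excluded) &
    meta$interp_fraction <= cfg$trial_interp_threshold
  out <- structure(list(meta = meta[keep, ],
                        series = epochs$series[keep, , drop = FALSE],
                        times = epochs$times,
                        n_dropped_partial = epochs$n_dropped_partial),
                   class = "pupil_epochs")
  list(epochs = out, excluded_subjects = as.character(excluded),
       n_dropped_epochs = sum(!keep))
}

#' Per-subject condition time-series and volatility subtraction series
#'
#' For every valence x volatility cell, the receipt-minus-non-receipt
#' contrast: the mean epoch where the chosen stimulus carried the outcome
#' minus the mean epoch where it did not. The per-valence subtraction
#' series is the volatile cell minus the stable cell (block-1 epochs are
#' labelled volatile for both valences, so they pool into the volatile
#' cells). Subjects missing any receipt/non-receipt cell are flagged and
#' omitted.
#'
#' @param epochs A `pupil_epochs` object.
#' @return A list: `cells` (long tibble `subject_id`, `valence`,
#'   `volatility`, `time`, `value`), `subtraction` (long tibble
#'   `subject_id`, `valence`, `time`, `value`), `flagged_subjects`.
#' @export
condition_timeseries <- function(epochs) {
  meta <- epochs$meta
  times <- epochs$times
  flagged <- character()
  cells <- list(); subtr <- list()
  for (sid in unique(meta$subject_id)) {
    rows <- which(meta$subject_id == sid)
    m <- meta[rows, ]
    ok <- TRUE
    cell_means <- list()
    for (v in c("win", "loss")) for (vol in c("volatile", "stable")) {
      r_idx <- rows[m$valence == v & m$volatility == vol & m$received]
      n_idx <- rows[m$valence == v & m$volatility == vol & !m$received]
      if (length(r_idx) == 0L || length(n_idx) == 0L) { ok <- FALSE; next }
      contrast <- colMeans(epochs$series[r_idx, , drop = FALSE]) -
        colMeans(epochs$series[n_idx, , drop = FALSE])
      cell_means[[paste(v, vol, sep = ".")]] <- contrast
      cells[[length(cells) + 1L]] <- tibble::tibble(
        subject_id = sid, valence = v, volatility = vol,
        time = times, value = contrast)
    }
    if (!ok) { flagged <- c(flagged, sid); next }
    for (v in c("win", "loss")) {
      subtr[[length(subtr) + 1L]] <- tibble::tibble(
        subject_id = sid, valence = v, time = times,
        value = cell_means[[paste(v, "volatile", sep = ".")]] -
          cell_means[[paste(v, "stable", sep = ".")]])
    }
  }
  cells_df <- dplyr::bind_rows(cells)
  subtr_df <- dplyr::bind_rows(subtr)
  # drop the cell rows of flagged subjects: all four cells or nothing
  if (length(flagged) > 0L && nrow(cells_df) > 0L) {
    cells_df <- cells_df[!cells_df$subject_id %in% flagged, ]
  }
  list(cells = cells_df, subtraction = subtr_df,
       flagged_subjects = unique(flagged))
}
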