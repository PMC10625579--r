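#' Exclude participants who showed no evidence of learning
#'
#' A participant is excluded when their final monetary total is the same as
#' or less than the GBP 1.50 they started with.
#'
#' @param cohort Cohort trial table with `subject_id` and `money_after`.
#' @param start_money Starting total.
#' @return A list with elements `kept` and `excluded` (cohort subsets) and
#'   `summary` (per-subject final money and keep flag).
#' @export
exclude_nonlearners <- function(cohort, start_money = 1.50) {
  assert_columns(cohort, c("subject_id", "money_after"))
  summ <- dplyr::summarise(
    dplyr::group_by(cohort, .data$subject_id),
    final_money = dplyr::last(.data$money_after),
    .groups = "drop")
  summ$kept <- summ$final_money > start_money
  keep_ids <- summ$subject_id[summ$kept]
  list(kept = cohort[cohort$subject_id %in% keep_ids, ],
       excluded = cohort[!cohort$subject_id %in% keep_ids, ],
       summary = summ)
}

#' Switch/stay statistics per valence and volatility
#'
#' For each valence, trials are selected where the chosen stimulus carried
#' that outcome (the outcome was *received*); a *stay* means the same
#' stimulus was chosen on the next trial. The last trial of each block is
#' excluded (stimuli change between blocks, so there is no within-block next
#' choice). The volatile cell for a valence pools block 1 (both outcomes
#' volatile) with the block where only that outcome is volatile; the stable
#' cell is the remaining block. Proportions get an add-half continuity
#' correction, `(k + 0.5) / (n + 1)`, before the logit so it stays finite.
#'
#' @param data Trial table for one or more subjects with columns
#'   `subject_id`, `block`, `win_condition`, `loss_condition`, `chose_A`,
#'   `win_received`, `loss_received`.
#' @return A tibble with one row per subject x valence x volatility:
#'   `n_outcome_trials`, `n_stays`, `stay_proportion` (uncorrected),
#'   `stay_logit` (continuity-corrected). Cells with no qualifying trials
#'   are returned with `n_outcome_trials = 0` and missing statistics.
#' @export
compute_stay_cells <- function(data) {
  assert_columns(data, c("subject_id", "block", "win_condition",
                         "loss_condition", "chose_A", "win_received",
                         "loss_received"))
  per_subject <- function(d) {
    d <- d[order(d$block, d$trial %||% seq_len(nrow(d))), ]
    last_of_block <- !duplicated(d$block, fromLast = TRUE)
    next_choice <- c(d$chose_A[-1], NA)
    stay <- d$chose_A == next_choice
    cells <- tidyr::expand_grid(valence = c("win", "loss"),
                                volatility = c("volatile", "stable"))
    purrr::pmap_dfr(cells, function(valence, volatility) {
      received <- if (valence == "win") d$win_received else d$loss_received
      cond <- if (valence == "win") d$win_condition else d$loss_condition
      sel <- received & cond == volatility & !last_of_block
      n <- sum(sel)
      k <- sum(stay[sel])
      p_corr <- (k + 0.5) / (n + 1)
      tibble::tibble(
        subject_id = d$subject_id[1], group = d$group[1] %||% NA_character_,
        order = d$order[1] %||% NA_character_,
        valence = valence, volatility = volatility,
        n_outcome_trials = n, n_stays = k,
        stay_proportion = if (n > 0) k / n else NA_real_,
        stay_logit = if (n > 0) logit(p_corr) else NA_real_
      )
    })
  }
  dplyr::bind_rows(purrr::map(split(data, data$subject_id), per_subject))
}

#' Mixed-design repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Full factorial decomposition of between-subject and within-subject
#' factors (type-III sums of squares with sum-to-zero contrasts), with a
#' Greenhouse-Geisser sphericity correction for within-subject terms.
#' Two-level within factors are spherical by construction (`epsilon = 1`).
#' Subjects missing any within-factor cell are dropped listwise.
#'
#' @param data Long-format table: one row per subject x within-cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor columns.
#' @param between Character vector of between-subject factor columns (may
#'   be empty).
#' @param subject Name of the subject-identifier column.
#' @return A tibble with one row per effect: `effect`, `df_num`, `df_den`,
#'   `statistic` (F), `p_value`, `gg_epsilon`, `p_gg`.
#' @export
mixed_anova <- function(data, dv, within, between = character(),
                        subject = "subject_id") {
  assert_columns(data, c(dv, within, between, subject))
  df <- dplyr::as_tibble(data[, c(subject, between, within, dv)])
  names(df)[names(df) == subject] <- ".subject"
  names(df)[names(df) == dv] <- ".dv"
  df <- dplyr::mutate(df, dplyr::across(dplyr::all_of(c(between, within)), as.factor))
  df <- df[stats::complete.cases(df), ]
  wide <- tidyr::pivot_wider(df, names_from = dplyr::all_of(within),
                             values_from = ".dv", names_sep = ".")
  idata <- do.call(tidyr::expand_grid,
                   purrr::map(stats::setNames(within, within),
                              function(w) levels(df[[w]])))
  # order the response columns exactly as the idata rows enumerate the cells
  cell_cols <- apply(as.data.frame(idata), 1, paste, collapse = ".")
  assert_columns(wide, cell_cols, "within-cell structure")
  wide <- wide[stats::complete.cases(wide[, cell_cols]), ]  # listwise
  if (length(between) > 0L) {
    counts <- table(wide[, between])
    if (any(counts < 2L)) {
      stop("every between-subject cell needs at least 2 subjects", call. = FALSE)
    }
  }
  idata <- as.data.frame(purrr::map(idata, as.factor))
  y <- as.matrix(wide[, cell_cols])
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  rhs <- if (length(between) > 0L) paste(between, collapse = "*") else "1"
  withr::local_options(contrasts = c("contr.sum", "contr.poly"))
  mlm <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = wide)
  a <- car::Anova(mlm, idata = idata, idesign = idesign, type = 3)
  # 1-df within effects are spherical by definition; car emits NaN/NA
  # adjustment warnings for them, which carry no information
  s <- suppressWarnings(summary(a, multivariate = FALSE))
  uni <- s$univariate.tests
  eff <- rownames(uni)
  fval <- unname(uni[, "F value"])
  pval <- unname(uni[, "Pr(>F)"])
  # an effect with zero sum of squares has no signal: report F = 0, p = 1
  # (covers the 0/0 case where the error stratum is also empty)
  degenerate <- !is.finite(fval) & unname(uni[, "Sum Sq"]) < 1e-12
  fval[degenerate] <- 0
  pval[degenerate] <- 1
  out <- tibble::tibble(
    effect = eff,
    df_num = unname(uni[, "num Df"]),
    df_den = unname(uni[, "den Df"]),
    statistic = fval,
    p_value = pval,
    gg_epsilon = 1,
    p_gg = pval
  )
  adj <- s$pval.adjustments
  if (!is.null(adj) && nrow(adj) > 0L) {
    usable <- which(is.finite(adj[, "GG eps"]))
    m <- match(rownames(adj)[usable], out$effect)
    out$gg_epsilon[m] <- adj[usable, "GG eps"]
    out$p_gg[m] <- adj[usable, "Pr(>F[GG])"]
  }
  out[out$effect != "(Intercept)", ]
}

#' One-sample t-test
#'
#' @param values Numeric sample (n >= 2, non-zero variance).
#' @param mu0 Null value.
#' @return A tibble with `estimate`, `statistic` (t), `df`, `p_value`, `n`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance", call. = FALSE)
  tt <- stats::t.test(values, mu = mu0)
  tibble::tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 n = length(values))
}

#' Welch's two-sample t-test (unequal variances)
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return A tibble with `estimate` (mean difference x - y), `statistic`,
#'   `df` (Welch-Satterthwaite), `p_value`, `n_x`, `n_y`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per sample", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) stop("zero variance in both samples", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = FALSE)
  tibble::tibble(estimate = unname(diff(rev(tt$estimate))),
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, n_x = length(x), n_y = length(y))
}

#' Compare two independent correlations via Fisher's r-to-z transform
#'
#' `z_i = atanh(r_i)`; the test statistic is
#' `(z_1 - z_2) / sqrt(1/(n_1 - 3) + 1/(n_2 - 3))`, referred to a standard
#' normal (two-sided).
#'
#' @param r1,n1 First correlation and its sample size.
#' @param r2,n2 Second correlation and its sample size.
#' @return A tibble with `r1`, `n1`, `r2`, `n2`, `z1`, `z2`, `statistic`
#'   (the z difference statistic) and `p_value`.
#' @export
fisher_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1", call. = FALSE)
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both groups", call. = FALSE)
  z1 <- atanh(r1); z2 <- atanh(r2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z <- (z1 - z2) / se
  tibble::tibble(r1 = r1, n1 = n1, r2 = r2, n2 = n2, z1 = z1, z2 = z2,
                 statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Learning-rate adjustment table from winning-model fits
#'
#' For each valence, the volatile learning rate is the mean of the block-1
#' rate and the rate in the block where only that valence was volatile; the
#' stable rate is the remaining block's rate. The adjustment is volatile
#' minus stable, per valence, with the subject mean across valences.
#'
#' @param fits Cohort fit table from [fit_cohort()] under the winning model
#'   (columns `alpha_win_1..3`, `alpha_loss_1..3`, plus `subject_id`,
#'   `group`, `order`).
#' @return A tibble with one row per subject: per-valence volatile/stable
#'   rates and adjustments (`adjustment_win`, `adjustment_loss`) and
#'   `mean_adjustment`.
#' @export
adjustment_table <- function(fits) {
  assert_columns(fits, c("subject_id", "order",
                         paste0("alpha_win_", 1:3), paste0("alpha_loss_", 1:3)))
  purrr::pmap_dfr(fits, function(...) {
    row <- list(...)
    if (is.na(row$order)) stop("block order required to map conditions", call. = FALSE)
    win2 <- identical(row$order, "win_volatile_second")
    a <- function(v, b) row[[paste0("alpha_", v, "_", b)]]
    win_vol_block <- if (win2) 2L else 3L
    loss_vol_block <- if (win2) 3L else 2L
    av_win <- mean(c(a("win", 1), a("win", win_vol_block)))
    as_win <- a("win", if (win2) 3L else 2L)
    av_loss <- mean(c(a("loss", 1), a("loss", loss_vol_block)))
    as_loss <- a("loss", if (win2) 2L else 3L)
    tibble::tibble(
      subject_id = row$subject_id,
      group = row$group %||% NA_character_,
      order = row$order,
      alpha_volatile_win = av_win, alpha_stable_win = as_win,
      alpha_volatile_loss = av_loss, alpha_stable_loss = as_loss,
      adjustment_win = av_win - as_win,
      adjustment_loss = av_loss - as_loss,
      mean_adjustment = mean(c(av_win - as_win, av_loss - as_loss)),
      beta = row$beta %||% NA_real_
    )
  })
}

#' Stack per-valence adjustments into the long format used for group tests
#'
#' @param adj Output of [adjustment_table()].
#' @return Long tibble: `subject_id`, `group`, `order`, `valence`,
#'   `adjustment` (two rows per subject).
#' @export
adjustment_long <- function(adj) {
  tidyr::pivot_longer(
    dplyr::select(adj, "subject_id", "group", "order",
                  win = "adjustment_win", loss = "adjustment_loss"),
    cols = c("win", "loss"), names_to = "valence", values_to = "adjustment")
}
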