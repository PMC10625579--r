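toy_log <- function(chose, win_rec, block = 1L, order = "win_volatile_second",
                    loss_rec = NULL) {
  n <- length(chose)
  bc <- block_conditions(order)
  tibble::tibble(
    subject_id = "t1", group = "HC", order = order,
    trial = seq_len(n), block = block,
    win_condition = bc$win_condition[match(block, bc$block)],
    loss_condition = bc$loss_condition[match(block, bc$block)],
    chose_A = chose, win_received = win_rec,
    loss_received = if (is.null(loss_rec)) rep(FALSE, n) else loss_rec,
    money_after = 1.5 + cumsum(0.15 * win_rec)
  )
}

test_that("non-learners are excluded at or below the starting total", {
  mk <- function(id, final) tibble::tibble(
    subject_id = id, money_after = c(1.5, final))
  cohort <- dplyr::bind_rows(mk("at", 1.50), mk("above", 1.65), mk("below", 1.35))
  res <- exclude_nonlearners(cohort)
  expect_identical(sort(unique(res$excluded$subject_id)), c("at", "below"))
  expect_identical(unique(res$kept$subject_id), "above")
  expect_error(exclude_nonlearners(tibble::tibble(subject_id = "x")),
               "money_after")
})

test_that("stay proportions match hand counts and the continuity-corrected logit stays finite", {
  # 10 trials, win received on 9 (last excluded -> 8 qualifying), 6 stays
  chose <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  # stays after trials 1-9: T,T,F,T,T,F,T,T,T -> pick win receipts so 6/8 stay
  win_rec <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  d <- toy_log(chose, win_rec)
  st <- compute_stay_cells(d)
  cell <- st[st$valence == "win" & st$volatility == "volatile", ]
  expect_identical(cell$n_outcome_trials, 9L)
  stays_hand <- sum(chose[-10] == chose[-1] & win_rec[-10])
  expect_identical(cell$n_stays, as.integer(stays_hand))
  expect_equal(cell$stay_proportion, stays_hand / 9)
  expect_equal(cell$stay_logit, qlogis((stays_hand + 0.5) / 10))
  expect_true(is.finite(cell$stay_logit))

  # uncorrected 6-of-8 example: proportion 0.75, raw logit ln 3
  d2 <- toy_log(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
                c(rep(TRUE, 8), FALSE))
  c2 <- compute_stay_cells(d2)
  c2 <- c2[c2$valence == "win" & c2$volatility == "volatile", ]
  expect_identical(c2$n_outcome_trials, 8L)
  expect_identical(c2$n_stays, 6L)
  expect_equal(c2$stay_proportion, 0.75)
  expect_equal(qlogis(c2$stay_proportion), log(3))

  # all-stay subject: correction keeps the logit finite
  d3 <- toy_log(rep(TRUE, 12), rep(TRUE, 12))
  c3 <- compute_stay_cells(d3)
  expect_true(all(is.finite(c3$stay_logit[c3$n_outcome_trials > 0])))
  # half stays -> corrected proportion exactly 0.5 -> logit 0
  d4 <- toy_log(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
                c(rep(TRUE, 8), FALSE))
  c4 <- compute_stay_cells(d4)
  c4 <- c4[c4$valence == "win" & c4$volatility == "volatile", ]
  expect_equal(c4$stay_logit, qlogis((c4$n_stays + 0.5) / (c4$n_outcome_trials + 1)))
})

test_that("volatile stay cells pool block 1 with the valence-volatile block", {
  d <- dplyr::bind_rows(
    toy_log(rep(c(TRUE, FALSE), 5), rep(TRUE, 10), block = 1L),
    toy_log(rep(TRUE, 10), rep(TRUE, 10), block = 2L),
    toy_log(rep(TRUE, 10), rep(TRUE, 10), block = 3L))
  st <- compute_stay_cells(d)   # order: win volatile in blocks 1 and 2
  expect_identical(
    st$n_outcome_trials[st$valence == "win" & st$volatility == "volatile"], 18L)
  expect_identical(
    st$n_outcome_trials[st$valence == "win" & st$volatility == "stable"], 9L)
})

test_that("higher volatile learning rates produce larger volatile-vs-stable stay differences", {
  diff_for <- function(adj, seeds) {
    vapply(seeds, function(s) {
      a_stable <- 0.2
      alpha <- matrix(c(a_stable + adj, a_stable + adj, a_stable,
                        a_stable + adj, a_stable, a_stable + adj), 3, 2)
      d <- make_subject(s, alpha = alpha, beta = 8)
      st <- compute_stay_cells(d)
      st$stay_proportion[st$valence == "win" & st$volatility == "volatile"] -
        st$stay_proportion[st$valence == "win" & st$volatility == "stable"]
    }, numeric(1))
  }
  expect_gt(mean(diff_for(0.5, 1:30)), mean(diff_for(0, 1:30)))
})

test_that("the mixed ANOVA agrees with base R's split-plot decomposition", {
  set.seed(61)
  df <- tidyr::expand_grid(
    subject_id = sprintf("s%02d", 1:16),
    volatility = c("volatile", "stable"), valence = c("win", "loss"))
  df$group <- ifelse(df$subject_id <= "s08", "a", "b")
  df$dv <- rnorm(nrow(df)) + ifelse(df$volatility == "volatile", 0.5, 0)
  res <- mixed_anova(df, dv = "dv", within = c("volatility", "valence"),
                     between = "group")
  oracle <- summary(aov(
    dv ~ group * volatility * valence +
      Error(subject_id / (volatility * valence)),
    data = dplyr::mutate(df, dplyr::across(c(group, volatility, valence,
                                             subject_id), factor))))
  get_f <- function(stratum, term) {
    tab <- oracle[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  expect_equal(res$statistic[res$effect == "group"],
               get_f("Error: subject_id", "group"))
  expect_equal(res$statistic[res$effect == "volatility"],
               get_f("Error: subject_id:volatility", "volatility"))
  expect_equal(res$statistic[res$effect == "volatility:valence"],
               get_f("Error: subject_id:volatility:valence", "volatility:valence"))
  expect_equal(res$statistic[res$effect == "group:valence"],
               get_f("Error: subject_id:valence", "group:valence"))
  # two-level within factors are spherical: epsilon 1, uncorrected p kept
  expect_true(all(res$gg_epsilon == 1))
  expect_equal(res$p_gg, res$p_value)
})

test_that("a within effect with no variance yields F = 0", {
  df <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:10),
                           volatility = c("volatile", "stable"))
  set.seed(3)
  base <- rnorm(10)
  df$dv <- base[match(df$subject_id, sort(unique(df$subject_id)))]
  res <- mixed_anova(df, dv = "dv", within = "volatility")
  expect_equal(res$statistic[res$effect == "volatility"], 0)
})

test_that("the Greenhouse-Geisser epsilon matches its covariance-based formula for 3-level factors", {
  set.seed(71)
  df <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:14),
                           cond = c("a", "b", "c"))
  df$dv <- rnorm(nrow(df)) +
    rep(rnorm(14), each = 3) * rep(c(1, 0.2, 0.1), 14)
  res <- mixed_anova(df, dv = "dv", within = "cond")
  wide <- tidyr::pivot_wider(df, names_from = "cond", values_from = "dv")
  S <- stats::cov(as.matrix(wide[, c("a", "b", "c")]))
  k <- 3
  sbar <- mean(S); dbar <- mean(diag(S)); rowm <- rowMeans(S)
  eps <- (k^2 * (dbar - sbar)^2) /
    ((k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * sbar^2))
  expect_equal(res$gg_epsilon[res$effect == "cond"], eps, tolerance = 1e-8)
  expect_lt(res$gg_epsilon[res$effect == "cond"], 1)
})

test_that("under-filled between cells are rejected", {
  df <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:3),
                           valence = c("win", "loss"))
  df$group <- ifelse(df$subject_id == "s01", "a", "b")
  df$dv <- rnorm(6)
  expect_error(mixed_anova(df, dv = "dv", within = "valence", between = "group"),
               "at least 2 subjects")
})

test_that("one-sample and Welch t-tests match their formulas", {
  x <- with_moments(50, 0.191, 0.169)
  res <- one_sample_t(x)
  expect_equal(res$statistic, 0.191 / (0.169 / sqrt(50)), tolerance = 1e-10)
  expect_identical(res$df, 49)
  sym <- c(-2, -1, 1, 2)
  expect_equal(one_sample_t(sym)$statistic, 0)
  expect_error(one_sample_t(rep(1, 5)), "variance")
  expect_error(one_sample_t(1), "at least 2")

  w <- welch_t(c(1, 2, 3), c(2, 4, 6))
  se <- sqrt(1 / 3 + 4 / 3)
  expect_equal(w$statistic, (2 - 4) / se, tolerance = 1e-10)
  expect_equal(w$df, (1 / 3 + 4 / 3)^2 / ((1 / 3)^2 / 2 + (4 / 3)^2 / 2),
               tolerance = 1e-10)
  w2 <- welch_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(w2$statistic, -w$statistic)
  expect_equal(w2$p_value, w$p_value)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
})

test_that("the Fisher r-to-z comparison reproduces its closed form and is antisymmetric", {
  res <- fisher_compare(0.512, 24, -0.176, 30)
  expect_equal(res$statistic,
               (atanh(0.512) - atanh(-0.176)) / sqrt(1 / 21 + 1 / 27),
               tolerance = 1e-12)
  expect_equal(fisher_compare(0.4, 20, 0.4, 25)$statistic, 0)
  expect_equal(fisher_compare(0.4, 20, 0.4, 25)$p_value, 1)
  swapped <- fisher_compare(-0.176, 30, 0.512, 24)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p_value, res$p_value)
  # recomputation from printed rounded inputs lands near, not on, 1.71
  expect_equal(fisher_compare(0.512, 24, 0.067, 25)$statistic, 1.64,
               tolerance = 0.01)
  expect_error(fisher_compare(1, 10, 0.2, 10), "< 1")
  expect_error(fisher_compare(0.5, 3, 0.2, 10), "n > 3")
})

test_that("adjustments derive from the order-dependent block mapping", {
  fits <- tibble::tibble(
    subject_id = c("a", "b"), group = "RA",
    order = c("win_volatile_second", "loss_volatile_second"),
    alpha_win_1 = 0.5, alpha_win_2 = 0.3, alpha_win_3 = 0.1,
    alpha_loss_1 = 0.6, alpha_loss_2 = 0.2, alpha_loss_3 = 0.4,
    beta = 6)
  adj <- adjustment_table(fits)
  # subject a: win volatile in blocks 1 & 2, stable block 3
  expect_equal(adj$alpha_volatile_win[1], mean(c(0.5, 0.3)))
  expect_equal(adj$alpha_stable_win[1], 0.1)
  expect_equal(adj$adjustment_win[1], 0.3)
  expect_equal(adj$alpha_volatile_loss[1], mean(c(0.6, 0.4)))
  expect_equal(adj$alpha_stable_loss[1], 0.2)
  # subject b: win volatile in blocks 1 & 3
  expect_equal(adj$alpha_volatile_win[2], mean(c(0.5, 0.1)))
  expect_equal(adj$alpha_stable_win[2], 0.3)
  expect_equal(adj$mean_adjustment,
               (adj$adjustment_win + adj$adjustment_loss) / 2)
  # equal volatile and stable rates -> zero adjustment
  flat <- dplyr::mutate(fits, alpha_win_2 = alpha_win_1,
                        alpha_win_3 = alpha_win_1,
                        alpha_loss_2 = alpha_loss_1,
                        alpha_loss_3 = alpha_loss_1)
  expect_true(all(adjustment_table(flat)$mean_adjustment == 0))
  long <- adjustment_long(adj)
  expect_identical(nrow(long), 4L)
})
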