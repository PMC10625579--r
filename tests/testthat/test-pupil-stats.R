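test_that("constant series produce no clusters", {
  ser <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:12),
                            valence = c("win", "loss"),
                            time = seq(0, 980, 20))
  ser$group <- rep(c("RA", "EA", "HC"), each = nrow(ser) / 3)
  ser$value <- 1
  cl <- cluster_permutation_test(ser, n_perm = 100, seed = 1)
  expect_identical(nrow(cl), 0L)
})

test_that("an injected group effect is detected where it was injected", {
  hits <- logical(20)
  set.seed(201)
  for (r in 1:20) {
    ser <- make_series(n_per_group = 8, n_time = 150, ar = 0.5,
                       effect = function(g, v, times) {
                         if (g == "RA") 3 * (times >= 1000 & times <= 2960)
                         else 0
                       })
    cl <- cluster_permutation_test(ser, n_perm = 100)
    sig <- cl[cl$effect == "group" & cl$p_value <= 0.05, ]
    hits[r] <- nrow(sig) > 0 &&
      any(sig$start <= 2960 & sig$end >= 1000)
  }
  expect_gte(mean(hits), 0.95)
})

test_that("cluster p-values respect the permutation floor and cluster geometry", {
  set.seed(211)
  ser <- make_series(n_per_group = 8, n_time = 80, ar = 0.5,
                     effect = function(g, v, times) {
                       if (g == "RA" && v == "win") 4 * (times >= 400 & times <= 1000)
                       else 0
                     })
  cl <- cluster_permutation_test(ser, n_perm = 199, seed = 212)
  expect_true(all(cl$p_value >= 1 / 200 & cl$p_value <= 1))
  expect_true(all(cl$end >= cl$start))
  gv <- cl[cl$effect == "group:valence", ]
  expect_gt(nrow(gv), 0)
  expect_lte(min(gv$p_value), 0.05)
  expect_warning(cluster_permutation_test(ser, n_perm = 50, seed = 1), "coarse")
})

test_that("window permutation tests behave at their degenerate limits", {
  base <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:20),
                             time = seq(0, 980, 20))
  base$group <- rep(c("a", "b"), each = nrow(base) / 2)
  allsame <- dplyr::mutate(base, value = 2)
  expect_equal(window_permutation_test(allsame, c(0, 980), n_perm = 100,
                                       seed = 1)$p_value, 1)
  # complete separation: minimal achievable p
  set.seed(2)
  sep <- dplyr::mutate(base, value = ifelse(group == "a", 10, 0) + rnorm(nrow(base), 0, 0.01))
  res <- window_permutation_test(sep, c(0, 980), n_perm = 199, seed = 3)
  expect_equal(res$p_value, 1 / 200)
  expect_error(window_permutation_test(sep, c(5000, 6000)), "empty time window")
})

test_that("window permutation p-values are uniform under the null", {
  set.seed(221)
  ps <- vapply(1:100, function(r) {
    df <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:18),
                             time = c(0, 20))
    df$group <- rep(c("a", "b", "c"), each = 12)
    df$value <- rnorm(nrow(df))
    window_permutation_test(df, c(0, 20), n_perm = 100)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
})

test_that("pupil-behaviour correlations recover coupling and skip tiny groups", {
  set.seed(231)
  adj <- rnorm(40, 0.2, 0.15)
  df <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:43),
    group = c(rep("RA", 20), rep("HC", 20), rep("tiny", 3)),
    adjustment = c(adj, rnorm(3)),
    pupil = c(2 * adj[1:20] + rnorm(20, 0, 0.08),   # strong coupling
              rnorm(20), rnorm(3)))
  res <- pupil_behaviour_correlation(df)
  expect_gt(res$correlations$r[res$correlations$group == "RA"], 0.9)
  expect_true(is.na(res$correlations$r[res$correlations$group == "tiny"]))
  expect_identical(nrow(res$comparisons), 1L)
  expect_gt(abs(res$comparisons$statistic), 2)

  # perfect linear coupling: r is exactly 1 (degenerate for comparisons)
  exact <- tibble::tibble(subject_id = as.character(1:10), group = "g",
                          adjustment = 1:10, pupil = 2 * (1:10) + 3)
  expect_equal(pupil_behaviour_correlation(exact)$correlations$r, 1)

  # shuffled pairing: correlations centre on zero
  set.seed(232)
  rs <- vapply(1:50, function(r) {
    d <- tibble::tibble(subject_id = as.character(1:20), group = "g",
                        adjustment = rnorm(20), pupil = rnorm(20))
    pupil_behaviour_correlation(d)$correlations$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
})
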