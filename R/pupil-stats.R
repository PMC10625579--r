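# Split-plot pointwise F statistics for a 2-level within factor (valence)
# crossed with a between factor (group), vectorised over timepoints.
# M = subject mean across valences (N x T), D = win - loss difference.
split_plot_F <- function(M, D, g) {
  N <- nrow(M)
  counts <- as.vector(table(g))
  k <- length(counts)
  gm_M <- rowsum(M, g) / counts              # k x T group means
  grand_M <- colMeans(M)
  ssb_M <- colSums(counts * (sweep(gm_M, 2, grand_M))^2)
  ssw_M <- colSums(M^2) - colSums(counts * gm_M^2)
  F_group <- (ssb_M / (k - 1)) / (ssw_M / (N - k))

  gm_D <- rowsum(D, g) / counts
  grand_D <- colMeans(D)
  ss_val <- N * grand_D^2
  ss_gv <- colSums(counts * gm_D^2) - ss_val
  ss_err <- colSums(D^2) - colSums(counts * gm_D^2)
  mse <- ss_err / (N - k)
  list(
    group = list(F = F_group, df1 = k - 1, df2 = N - k),
    valence = list(F = ss_val / mse, df1 = 1, df2 = N - k),
    `group:valence` = list(F = (ss_gv / (k - 1)) / mse, df1 = k - 1, df2 = N - k)
  )
}

clusters_from_F <- function(Fv, crit, times) {
  sig <- !is.na(Fv) & Fv > crit   # degenerate (zero-variance) points never enter
  if (!any(sig)) {
    return(tibble::tibble(start = numeric(), end = numeric(), mass = numeric()))
  }
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble::tibble(
    start = times[starts[keep]],
    end = times[ends[keep]],
    mass = vapply(keep, function(j) sum(Fv[starts[j]:ends[j]]), numeric(1))
  )
}

max_cluster_mass <- function(Fv, crit) {
  sig <- !is.na(Fv) & Fv > crit
  if (!any(sig)) return(0)
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  max(vapply(which(r$values), function(j) sum(Fv[starts[j]:ends[j]]), numeric(1)))
}

#' Cluster-based permutation test of group and valence effects on
#' subtraction time-series
#'
#' At every timepoint a split-plot factorial model is evaluated on the
#' per-subject volatile-minus-stable series: group (between subjects),
#' valence (within subjects, the random valence slope reducing to the
#' subject-paired valence difference because there is one averaged series
#' per subject per valence), and their interaction. Contiguous runs of
#' pointwise-significant timepoints (`p < alpha_point`) form clusters whose
#' mass is the summed F; each effect's null distribution is the maximal
#' cluster mass over label permutations (group labels shuffled across
#' subjects, valence labels flipped within subject), and
#' `p = (1 + #null >= observed) / (n_perm + 1)`.
#'
#' @param series Long tibble with columns `subject_id`, `group`, `valence`
#'   (`"win"`/`"loss"`), `time`, `value` - one averaged series per subject
#'   per valence, on a common time grid.
#' @param n_perm Number of permutations (warns below 100).
#' @param alpha_point Pointwise cluster-forming alpha.
#' @param seed Optional seed.
#' @return A tibble of class `cluster_result`: one row per cluster with
#'   `effect`, `start`, `end` (ms), `mass`, `p_value`; pointwise F curves
#'   in attribute `"pointwise"`.
#' @export
cluster_permutation_test <- function(series, n_perm = 1000L,
                                     alpha_point = 0.05, seed = NULL) {
  assert_columns(series, c("subject_id", "group", "valence", "time", "value"))
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse permutation null")
  local_seed_if(seed)
  series <- dplyr::arrange(series, .data$subject_id, .data$valence, .data$time)
  wide <- tidyr::pivot_wider(series, names_from = "time", values_from = "value")
  win <- wide[wide$valence == "win", ]
  loss <- wide[wide$valence == "loss", ]
  loss <- loss[match(win$subject_id, loss$subject_id), ]
  stopifnot(nrow(win) == nrow(loss), !anyNA(loss$subject_id))
  g <- factor(win$group)
  times <- as.numeric(setdiff(names(wide), c("subject_id", "group", "valence")))
  Yw <- as.matrix(win[, as.character(times)])
  Yl <- as.matrix(loss[, as.character(times)])
  M <- (Yw + Yl) / 2
  D <- Yw - Yl
  N <- nrow(M)
  obs <- split_plot_F(M, D, g)
  crit <- purrr::map(obs, ~ stats::qf(1 - alpha_point, .x$df1, .x$df2))
  obs_clusters <- purrr::imap(obs, function(o, nm) {
    cl <- clusters_from_F(o$F, crit[[nm]], times)
    if (nrow(cl) > 0L) cl$effect <- nm
    cl
  })
  null_max <- matrix(0, n_perm, 3,
                     dimnames = list(NULL, names(obs)))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(N)
    signs <- sample(c(-1, 1), N, replace = TRUE)
    perm <- split_plot_F(M[idx, , drop = FALSE],
                         signs * D[idx, , drop = FALSE], g)
    for (nm in names(obs)) {
      null_max[b, nm] <- max_cluster_mass(perm[[nm]]$F, crit[[nm]])
    }
  }
  out <- purrr::imap(obs_clusters, function(cl, nm) {
    if (nrow(cl) == 0L) return(cl)
    cl$p_value <- vapply(cl$mass, function(m) {
      (1 + sum(null_max[, nm] >= m)) / (n_perm + 1)
    }, numeric(1))
    cl
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) > 0L) {
    out <- dplyr::select(out, "effect", "start", "end", "mass", "p_value")
    out <- dplyr::arrange(out, .data$effect, .data$start)
  } else {
    out <- tibble::tibble(effect = character(), start = numeric(),
                          end = numeric(), mass = numeric(),
                          p_value = numeric())
  }
  attr(out, "pointwise") <- list(times = times, observed = obs, crit = crit)
  class(out) <- c("cluster_result", class(out))
  out
}

#' Permutation test of a group effect on a time-window average
#'
#' Averages each subject's series over the window and tests the
#' between-group effect on the scalar with a permutation one-way F test
#' (group labels shuffled across subjects).
#'
#' @param series Long tibble `subject_id`, `group`, `time`, `value` (one
#'   series per subject; filter to a valence/condition beforehand).
#' @param window_ms Length-2 numeric window (ms), inclusive.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return A tibble with `statistic` (observed F), `df1`, `df2`, `p_value`,
#'   `n_subjects`.
#' @export
window_permutation_test <- function(series, window_ms, n_perm = 1000L,
                                    seed = NULL) {
  assert_columns(series, c("subject_id", "group", "time", "value"))
  local_seed_if(seed)
  inwin <- series$time >= window_ms[1] & series$time <= window_ms[2]
  if (!any(inwin)) stop("empty time window", call. = FALSE)
  means <- dplyr::summarise(
    dplyr::group_by(series[inwin, ], .data$subject_id, .data$group),
    value = mean(.data$value), .groups = "drop")
  g <- factor(means$group)
  y <- means$value
  one_way_F <- function(y, g) {
    counts <- as.vector(table(g))
    gm <- rowsum(y, g) / counts
    grand <- mean(y)
    ssb <- sum(counts * (gm - grand)^2)
    ssw <- sum(y^2) - sum(counts * gm^2)
    if (ssw <= 0) return(if (ssb <= 0) 0 else Inf)
    (ssb / (length(counts) - 1)) / (ssw / (length(y) - length(counts)))
  }
  obs <- one_way_F(y, g)
  null <- vapply(seq_len(n_perm), function(b) one_way_F(y, sample(g)), numeric(1))
  tibble::tibble(
    statistic = obs, df1 = nlevels(g) - 1, df2 = length(y) - nlevels(g),
    p_value = (1 + sum(null >= obs)) / (n_perm + 1),
    n_subjects = length(y))
}

#' Correlate pupil volatility effects with learning-rate adjustment
#'
#' Pearson correlation, within each group, between a subject's pupil
#' subtraction-series window mean and their learning-rate adjustment, plus
#' pairwise group comparisons via [fisher_compare()]. Groups with fewer
#' than `min_n` subjects are skipped.
#'
#' @param data Tibble with columns `subject_id`, `group`, `pupil` (window
#'   mean) and `adjustment` (matched subjects).
#' @param min_n Minimum group size for a correlation.
#' @return A list: `correlations` (tibble `group`, `n`, `r`, `p_value`) and
#'   `comparisons` (pairwise [fisher_compare()] rows with `group1`,
#'   `group2`).
#' @export
pupil_behaviour_correlation <- function(data, min_n = 4L) {
  assert_columns(data, c("subject_id", "group", "pupil", "adjustment"))
  data <- data[stats::complete.cases(data[, c("pupil", "adjustment")]), ]
  cors <- dplyr::summarise(
    dplyr::group_by(data, .data$group),
    n = dplyr::n(),
    r = if (dplyr::n() >= min_n) stats::cor(.data$pupil, .data$adjustment)
        else NA_real_,
    p_value = if (dplyr::n() >= min_n)
      stats::cor.test(.data$pupil, .data$adjustment)$p.value else NA_real_,
    .groups = "drop")
  usable <- cors[!is.na(cors$r) & abs(cors$r) < 1 & cors$n > 3, ]
  comparisons <- NULL
  if (nrow(usable) >= 2L) {
    pairs <- utils::combn(seq_len(nrow(usable)), 2)
    comparisons <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      dplyr::mutate(
        fisher_compare(usable$r[i1], usable$n[i1], usable$r[i2], usable$n[i2]),
        group1 = usable$group[i1], group2 = usable$group[i2], .before = 1L)
    })
  }
  list(correlations = cors, comparisons = comparisons)
}
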