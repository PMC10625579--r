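#' Read and write pipeline tables
#'
#' All tables travel as comma-separated UTF-8 text with a header row and
#' full double precision; probabilities and currency are never rounded on
#' disk.
#'
#' @param x A data frame.
#' @param path File path.
#' @return `write_table()` returns `x` invisibly; `read_table()` returns a
#'   tibble.
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Full-run configuration
#'
#' @param cohort A [cohort_config()].
#' @param pupil A [pupil_config()].
#' @param include_pupil Run the pupillometry arm?
#' @param compare_models Run the integrated-BIC model comparison (slower)?
#' @param n_perm Permutations for the cluster and window tests.
#' @param n_restarts MAP restarts per subject.
#' @param out_dir Optional directory for result tables.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), pupil = pupil_config(),
                       include_pupil = TRUE, compare_models = FALSE,
                       n_perm = 500L, n_restarts = 2L, out_dir = NULL) {
  structure(list(cohort = cohort, pupil = pupil,
                 include_pupil = include_pupil,
                 compare_models = compare_models,
                 n_perm = as.integer(n_perm),
                 n_restarts = as.integer(n_restarts), out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates (or accepts) a cohort, applies the non-learner exclusion, fits
#' the winning reinforcement-learning model, computes the switch/stay and
#' learning-rate-adjustment statistics (mixed ANOVAs with GG correction,
#' per-group one-sample t-tests, Welch post-hocs), optionally compares the
#' model family by integrated BIC, runs the pupillometry pipeline with
#' cluster-based permutation tests, window post-hocs and pupil-behaviour
#' correlations, and returns everything as one results bundle. Every stage
#' seed derives from the cohort's master seed and is logged.
#'
#' @param config A [run_config()].
#' @param cohort Optionally, a pre-built `synthetic_cohort` (ingest path);
#'   simulated from `config$cohort` otherwise.
#' @return A list of class `pipeline_result` with elements `exclusions`,
#'   `fits`, `adjustment`, `adjustment_anova`, `adjustment_t`,
#'   `welch_posthoc`, `block1_anova`, `stay_cells`, `stay_anova`,
#'   `model_comparison`, `clusters`, `window_tests`, `correlation`,
#'   `ns`, `seeds`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  master <- config$cohort$master_seed
  seeds <- list()
  log_seed <- function(stg, s) {
    seeds[[length(seeds) + 1L]] <<- tibble::tibble(stage = stg, seed = s)
    s
  }
  cohort <- cohort %||% stage("simulate_cohort",
                              simulate_cohort(config$cohort,
                                              include_pupil = config$include_pupil))
  excl <- stage("exclusions", exclude_nonlearners(cohort$behaviour))
  kept <- excl$kept
  fits <- stage("fit", fit_cohort(
    kept, winning_model_spec(), n_restarts = config$n_restarts,
    seed = log_seed("fit", derive_seed(master, "fit"))))
  adj <- stage("adjustment", adjustment_table(fits))
  adj_long <- adjustment_long(adj)
  adj_anova <- stage("adjustment_anova", mixed_anova(
    adj_long, dv = "adjustment", within = "valence",
    between = c("group", "order")))
  adj_t <- stage("adjustment_t", dplyr::bind_rows(purrr::imap(
    split(adj_long, adj_long$group),
    function(d, g) dplyr::mutate(one_sample_t(d$adjustment), group = g,
                                 .before = 1L))))
  groups <- unique(adj_long$group)
  welch <- NULL
  if (length(groups) >= 2L) {
    pairs <- utils::combn(groups, 2)
    welch <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      dplyr::mutate(
        welch_t(adj_long$adjustment[adj_long$group == g1],
                adj_long$adjustment[adj_long$group == g2]),
        group1 = g1, group2 = g2, .before = 1L)
    })
  }
  block1 <- tidyr::pivot_longer(
    dplyr::select(fits, "subject_id", "group", "order",
                  win = "alpha_win_1", loss = "alpha_loss_1"),
    c("win", "loss"), names_to = "valence", values_to = "alpha")
  block1_anova <- stage("block1_anova", mixed_anova(
    block1, dv = "alpha", within = "valence", between = c("group", "order")))
  stay <- stage("stay", compute_stay_cells(kept))
  stay_anova <- stage("stay_anova", mixed_anova(
    stay[!is.na(stay$stay_logit), ], dv = "stay_logit",
    within = c("volatility", "valence"), between = c("group", "order")))
  comparison <- NULL
  if (config$compare_models) {
    comparison <- stage("compare_models", integrated_bic(
      kept, seed = log_seed("ibic", derive_seed(master, "ibic"))))
  }
  clusters <- NULL; window_tests <- NULL; correlation <- NULL
  if (config$include_pupil && !is.null(cohort$pupil)) {
    kept_ids <- unique(kept$subject_id)
    series <- stage("pupil_preprocess", {
      eps <- purrr::imap(cohort$pupil[names(cohort$pupil) %in% kept_ids],
                         function(tr, sid) {
        clean <- preprocess_trace(tr$samples, config$pupil)
        epoch_outcomes(clean, tr$events, config$pupil, subject_id = sid)
      })
      all_ep <- bind_epochs(eps)
      kept_ep <- apply_exclusions(all_ep, config$pupil)
      condition_timeseries(kept_ep$epochs)
    })
    group_of <- stats::setNames(
      dplyr::distinct(kept, .data$subject_id, .data$group)$group,
      dplyr::distinct(kept, .data$subject_id, .data$group)$subject_id)
    subtr <- dplyr::mutate(series$subtraction,
                           group = unname(group_of[.data$subject_id]))
    clusters <- stage("cluster_test", cluster_permutation_test(
      subtr, n_perm = config$n_perm,
      seed = log_seed("cluster", derive_seed(master, "cluster"))))
    gv <- clusters[clusters$effect == "group:valence" & clusters$p_value < 0.05, ]
    window <- if (nrow(gv) > 0L) c(gv$start[1], gv$end[1])
              else c(0, config$pupil$epoch_end_ms)
    win_series <- dplyr::filter(subtr, .data$valence == "win")
    window_tests <- stage("window_tests", dplyr::mutate(
      window_permutation_test(win_series, window, n_perm = config$n_perm,
                              seed = log_seed("window",
                                              derive_seed(master, "window"))),
      effect = "group on reward subtraction window mean", .before = 1L))
    win_means <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(win_series, .data$time >= window[1],
                                    .data$time <= window[2]),
                      .data$subject_id, .data$group),
      pupil = mean(.data$value), .groups = "drop")
    corr_df <- dplyr::inner_join(
      win_means, dplyr::select(adj, "subject_id", adjustment = "adjustment_win"),
      by = "subject_id")
    correlation <- stage("correlation", pupil_behaviour_correlation(corr_df))
  }
  res <- structure(list(
    exclusions = excl$summary,
    fits = fits,
    adjustment = adj,
    adjustment_anova = adj_anova,
    adjustment_t = adj_t,
    welch_posthoc = welch,
    block1_anova = block1_anova,
    stay_cells = stay,
    stay_anova = stay_anova,
    model_comparison = comparison,
    clusters = clusters,
    window_tests = window_tests,
    correlation = correlation,
    ns = dplyr::count(dplyr::distinct(kept, .data$subject_id, .data$group),
                      .data$group),
    seeds = dplyr::bind_rows(seeds)
  ), class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("fits", "adjustment", "adjustment_anova", "adjustment_t",
                 "stay_cells", "stay_anova", "ns", "seeds")) {
      if (!is.null(res[[nm]])) {
        write_table(res[[nm]], file.path(config$out_dir, paste0(nm, ".csv")))
      }
    }
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  subjects kept:", sum(x$exclusions$kept), "of", nrow(x$exclusions), "\n")
  gl <- x$adjustment_anova[x$adjustment_anova$effect == "group", ]
  if (nrow(gl) == 1L) {
    cat(sprintf("  adjustment group effect: F(%g, %g) = %.2f, p = %.3f\n",
                gl$df_num, gl$df_den, gl$statistic, gl$p_gg))
  }
  if (!is.null(x$clusters) && nrow(x$clusters) > 0L) {
    sig <- x$clusters[x$clusters$p_value < 0.05, ]
    cat("  significant pupil clusters:", nrow(sig), "\n")
  }
  cat("  components:", paste(names(x)[!vapply(x, is.null, logical(1))],
                             collapse = ", "), "\n")
  invisible(x)
}
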