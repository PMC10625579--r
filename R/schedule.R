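#' Configuration of the volatility task schedule
#'
#' The task has three blocks of 80 trials. Win and loss contingencies for
#' stimulus A are manipulated independently: a *volatile* outcome alternates
#' between a high (0.85) and a low (0.15) probability in epochs of 14-30
#' trials, a *stable* outcome stays at 0.5 throughout the block. Block 1 is
#' volatile for both valences; blocks 2 and 3 each have exactly one volatile
#' valence, in an order counterbalanced between participants.
#'
#' @param p_high,p_low High/low probability levels of a volatile outcome.
#'   Must satisfy `p_low = 1 - p_high`.
#' @param p_stable Constant probability of a stable outcome.
#' @param epoch_min,epoch_max Bounds (in trials) on the run length between
#'   probability switches of a volatile outcome.
#' @param n_trials_per_block Trials per block.
#' @param block_order `"win_volatile_second"` (block 2 win-volatile,
#'   block 3 loss-volatile) or `"loss_volatile_second"` (the reverse).
#' @param seed Optional integer seed used by [generate_schedule()].
#' @return A list of class `schedule_config`.
#' @export
schedule_config <- function(p_high = 0.85, p_low = 0.15, p_stable = 0.5,
                            epoch_min = 14L, epoch_max = 30L,
                            n_trials_per_block = 80L,
                            block_order = c("win_volatile_second",
                                            "loss_volatile_second"),
                            seed = NULL) {
  block_order <- match.arg(block_order)
  cfg <- list(p_high = p_high, p_low = p_low, p_stable = p_stable,
              epoch_min = as.integer(epoch_min),
              epoch_max = as.integer(epoch_max),
              n_trials_per_block = as.integer(n_trials_per_block),
              block_order = block_order, seed = seed)
  if (!(0 < p_low && p_low < p_stable && p_stable < p_high && p_high < 1)) {
    stop("require 0 < p_low < p_stable < p_high < 1", call. = FALSE)
  }
  if (abs(p_low - (1 - p_high)) > 1e-12) {
    stop("p_low must equal 1 - p_high", call. = FALSE)
  }
  if (!(1L <= cfg$epoch_min && cfg$epoch_min <= cfg$epoch_max &&
        cfg$epoch_max <= cfg$n_trials_per_block)) {
    stop("require 1 <= epoch_min <= epoch_max <= n_trials_per_block",
         call. = FALSE)
  }
  structure(cfg, class = "schedule_config")
}

#' Block-wise volatility conditions implied by a block order
#'
#' @param block_order `"win_volatile_second"` or `"loss_volatile_second"`.
#' @return A tibble with columns `block`, `win_condition`, `loss_condition`.
#' @export
block_conditions <- function(block_order) {
  win2 <- identical(block_order, "win_volatile_second")
  tibble::tibble(
    block = 1:3,
    win_condition = c("volatile", if (win2) "volatile" else "stable",
                      if (win2) "stable" else "volatile"),
    loss_condition = c("volatile", if (win2) "stable" else "volatile",
                       if (win2) "volatile" else "stable")
  )
}

# Sample a composition of `total` trials into `k` epochs, each within
# [emin, emax]. Sequential draws with feasibility-truncated supports.
sample_composition <- function(total, k, emin, emax) {
  out <- integer(k)
  remaining <- total
  for (i in seq_len(k)) {
    left <- k - i
    lo <- max(emin, remaining - left * emax)
    hi <- min(emax, remaining - left * emin)
    if (lo > hi) stop("infeasible epoch composition", call. = FALSE)
    out[i] <- if (lo == hi) lo else sample(lo:hi, 1L)
    remaining <- remaining - out[i]
  }
  out
}

#' Build the per-trial probability trajectory for one valence in one block
#'
#' Stable outcomes give a constant `p_stable` sequence. Volatile outcomes
#' alternate between `p_high` and `p_low` in epochs whose lengths lie in
#' `[epoch_min, epoch_max]`, constructed so that exactly half of the block's
#' trials sit at each level (block mean exactly 0.5, so the task never
#' systematically favours one shape). The starting level is random.
#'
#' @param condition `"volatile"` or `"stable"`.
#' @param n_trials Number of trials (the block length).
#' @param config A [schedule_config()].
#' @param seed Optional seed.
#' @return Numeric vector of length `n_trials`.
#' @export
build_probability_trajectory <- function(condition, n_trials = 80L,
                                         config = schedule_config(),
                                         seed = NULL) {
  condition <- match.arg(condition, c("volatile", "stable"))
  local_seed_if(seed)
  if (condition == "stable") return(rep(config$p_stable, n_trials))
  half <- n_trials / 2
  if (half != floor(half)) {
    stop("volatile blocks need an even number of trials for exact balance",
         call. = FALSE)
  }
  # Epochs alternate levels, so each level contributes the same number of
  # epochs (k per level, 2k total) and must cover exactly half the trials.
  k_lo <- ceiling(half / config$epoch_max)
  k_hi <- floor(half / config$epoch_min)
  # pairing to `half` further restricts each epoch to
  # [half - (k-1)*epoch_max, ...]; feasibility is just k_lo <= k_hi
  if (k_lo > k_hi) {
    stop(sprintf(paste0("cannot partition %d trials per level into epochs ",
                        "of %d-%d trials; adjust epoch_min/epoch_max"),
                 as.integer(half), config$epoch_min, config$epoch_max),
         call. = FALSE)
  }
  k <- if (k_lo == k_hi) k_lo else sample(k_lo:k_hi, 1L)
  len_a <- sample_composition(half, k, config$epoch_min, config$epoch_max)
  len_b <- sample_composition(half, k, config$epoch_min, config$epoch_max)
  start_high <- stats::runif(1) < 0.5
  lens <- as.vector(rbind(len_a, len_b))
  levels2 <- rep(if (start_high) c(config$p_high, config$p_low)
                 else c(config$p_low, config$p_high), k)
  rep(levels2, lens)
}

#' Realize win/loss outcome locations from scheduled probabilities
#'
#' Independent Bernoulli draws per trial and valence: `win_on_A[t] ~
#' Bernoulli(p_win_A[t])`, likewise for losses. Whatever stimulus does not
#' carry an outcome's "on" draw carries its complement, so exactly one
#' stimulus carries the win and one the loss on every trial.
#'
#' @param p_win_A,p_loss_A Numeric vectors of per-trial probabilities.
#' @param seed Optional seed.
#' @return A tibble with logical columns `win_on_A`, `loss_on_A`.
#' @export
realize_outcomes <- function(p_win_A, p_loss_A, seed = NULL) {
  stopifnot(length(p_win_A) == length(p_loss_A))
  local_seed_if(seed)
  n <- length(p_win_A)
  tibble::tibble(
    win_on_A = stats::runif(n) < p_win_A,
    loss_on_A = stats::runif(n) < p_loss_A
  )
}

#' Generate a complete three-block task schedule
#'
#' @param config A [schedule_config()].
#' @param seed Optional seed (overrides `config$seed`).
#' @return A tibble of class `task_schedule` with one row per trial
#'   (1-based, contiguous across blocks) and columns `trial`, `block`,
#'   `win_condition`, `loss_condition`, `p_win_A`, `p_loss_A`, `win_on_A`,
#'   `loss_on_A`, `win_shown_first`, `inter_outcome_delay_s`. The config is
#'   attached as attribute `"config"`.
#' @export
generate_schedule <- function(config = schedule_config(), seed = NULL) {
  seed <- seed %||% config$seed
  local_seed_if(seed)
  blocks <- block_conditions(config$block_order)
  nb <- config$n_trials_per_block
  per_block <- purrr::pmap(blocks, function(block, win_condition, loss_condition) {
    p_win <- build_probability_trajectory(win_condition, nb, config)
    p_loss <- build_probability_trajectory(loss_condition, nb, config)
    out <- realize_outcomes(p_win, p_loss)
    tibble::tibble(
      block = block,
      win_condition = win_condition,
      loss_condition = loss_condition,
      p_win_A = p_win, p_loss_A = p_loss,
      win_on_A = out$win_on_A, loss_on_A = out$loss_on_A,
      # outcome display order counterbalanced by strict alternation
      win_shown_first = (seq_len(nb) %% 2L) == 1L,
      inter_outcome_delay_s = stats::runif(nb, 2, 6)
    )
  })
  sched <- dplyr::bind_rows(per_block)
  sched <- dplyr::mutate(sched, trial = dplyr::row_number(), .before = 1L)
  attr(sched, "config") <- config
  class(sched) <- c("task_schedule", class(sched))
  sched
}

run_lengths_ok <- function(p, emin, emax) {
  r <- rle(p)$lengths
  all(r >= emin & r <= emax)
}

#' Validate a task schedule against the task's structural invariants
#'
#' Report-only check of every structural rule: trial count and numbering,
#' block conditions (block 1 doubly volatile; blocks 2 and 3 complementary),
#' legal probability levels, epoch run lengths, exact 50% block-mean
#' probability per valence, outcome-delay range.
#'
#' @param schedule A `task_schedule` tibble (or compatible data frame).
#' @param config The schedule's configuration; defaults to the attached one.
#' @return A tibble of violations (`rule`, `detail`); zero rows when valid.
#' @export
validate_schedule <- function(schedule,
                              config = attr(schedule, "config") %||% schedule_config()) {
  assert_columns(schedule, c("trial", "block", "win_condition", "loss_condition",
                             "p_win_A", "p_loss_A", "inter_outcome_delay_s"))
  v <- list()
  note <- function(rule, detail) tibble::tibble(rule = rule, detail = detail)
  n_expected <- 3L * config$n_trials_per_block
  if (nrow(schedule) != n_expected ||
      !identical(as.integer(schedule$trial), seq_len(nrow(schedule)))) {
    v <- c(v, list(note("trial_count", sprintf(
      "expected %d contiguous 1-based trials, got %d", n_expected, nrow(schedule)))))
  }
  bc <- dplyr::distinct(schedule, .data$block, .data$win_condition, .data$loss_condition)
  b1 <- dplyr::filter(bc, .data$block == 1)
  if (nrow(b1) != 1L || b1$win_condition != "volatile" || b1$loss_condition != "volatile") {
    v <- c(v, list(note("block1_volatile", "block 1 must be volatile for both valences")))
  }
  b23 <- dplyr::filter(bc, .data$block %in% 2:3)
  one_each <- all((b23$win_condition == "volatile") != (b23$loss_condition == "volatile"))
  differ <- length(unique(b23$win_condition)) == 2L
  if (nrow(b23) != 2L || !one_each || !differ) {
    v <- c(v, list(note("block23_conditions",
                        "blocks 2 and 3 must each have exactly one volatile valence, and differ")))
  }
  legal <- c(config$p_low, config$p_stable, config$p_high)
  for (val in c("win", "loss")) {
    pcol <- paste0("p_", val, "_A")
    ccol <- paste0(val, "_condition")
    for (b in 1:3) {
      rows <- schedule[schedule$block == b, ]
      p <- rows[[pcol]]
      cond <- rows[[ccol]][1]
      if (any(vapply(p, function(x) min(abs(x - legal)) > 1e-9, logical(1)))) {
        v <- c(v, list(note("illegal_probability_level",
                            sprintf("%s block %d has levels outside {%.2f, %.2f, %.2f}",
                                    val, b, config$p_low, config$p_stable, config$p_high))))
        next
      }
      if (cond == "stable") {
        if (any(abs(p - config$p_stable) > 1e-9)) {
          v <- c(v, list(note("stable_not_constant",
                              sprintf("%s block %d stable valence must stay at %.2f",
                                      val, b, config$p_stable))))
        }
      } else {
        if (any(abs(p - config$p_stable) < 1e-9)) {
          v <- c(v, list(note("illegal_probability_level",
                              sprintf("%s block %d volatile valence contains p_stable", val, b))))
        }
        if (!run_lengths_ok(p, config$epoch_min, config$epoch_max)) {
          v <- c(v, list(note("epoch_length",
                              sprintf("%s block %d has an epoch length outside [%d, %d]",
                                      val, b, config$epoch_min, config$epoch_max))))
        }
      }
      if (abs(mean(p) - 0.5) > 1e-9) {
        v <- c(v, list(note("block_mean",
                            sprintf("%s block %d mean scheduled probability %.4f != 0.5",
                                    val, b, mean(p)))))
      }
    }
  }
  if (any(schedule$inter_outcome_delay_s < 2 | schedule$inter_outcome_delay_s > 6)) {
    v <- c(v, list(note("outcome_delay", "inter-outcome delays must lie in [2, 6] s")))
  }
  if (length(v) == 0L) {
    return(tibble::tibble(rule = character(), detail = character()))
  }
  dplyr::bind_rows(v)
}
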