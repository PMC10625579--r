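#' Specify a member of the reinforcement-learning model family
#'
#' The family crosses three factors: whether learning rates are split by
#' valence (win vs loss), whether they are split by block, and whether a
#' constant choice bias towards one shape is included. All members share a
#' single inverse temperature. The best-supported member for this task has
#' separate learning rates per valence and per block, no bias.
#'
#' @param split_valence Separate win/loss learning rates?
#' @param split_block Separate learning rates per block?
#' @param include_bias Include a constant additive preference for shape A?
#' @param name Optional display name; autogenerated otherwise.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(split_valence = TRUE, split_block = TRUE,
                       include_bias = FALSE, name = NULL) {
  nm <- name %||% paste0(
    "alpha_",
    if (split_block && split_valence) "block_x_valence"
    else if (split_valence) "valence"
    else if (split_block) "block"
    else "single",
    if (include_bias) "_bias" else ""
  )
  structure(list(split_valence = split_valence, split_block = split_block,
                 include_bias = include_bias, beta_policy = "single",
                 name = nm),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
winning_model_spec <- function() model_spec(TRUE, TRUE, FALSE)

#' The default candidate model roster
#'
#' Single learning rate, per-valence, and per-valence-per-block learning
#' rates, each with and without a shape bias (six models).
#'
#' @return A named list of [model_spec()] objects.
#' @export
model_family <- function() {
  specs <- list(
    model_spec(FALSE, FALSE, FALSE),
    model_spec(TRUE, FALSE, FALSE),
    model_spec(TRUE, TRUE, FALSE),
    model_spec(FALSE, FALSE, TRUE),
    model_spec(TRUE, FALSE, TRUE),
    model_spec(TRUE, TRUE, TRUE)
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Agent parameters
#'
#' @param alpha Learning rate(s) in `[0, 1]`: a scalar, a length-2 vector
#'   `c(win, loss)`, or a 3 x 2 matrix (blocks x valences, columns
#'   `win`/`loss`). Always stored as the full 3 x 2 matrix.
#' @param beta Inverse temperature, `>= 0`.
#' @param bias Constant additive preference for shape A (logit units).
#' @return A list of class `agent_params` with elements `alpha` (3 x 2
#'   matrix), `beta`, `bias`.
#' @export
agent_params <- function(alpha, beta, bias = 0) {
  if (is.matrix(alpha)) {
    stopifnot(nrow(alpha) == 3L, ncol(alpha) == 2L)
    a <- alpha
  } else if (length(alpha) == 1L) {
    a <- matrix(alpha, 3, 2)
  } else if (length(alpha) == 2L) {
    a <- matrix(alpha, 3, 2, byrow = TRUE)
  } else {
    stop("alpha must be scalar, length 2, or a 3 x 2 matrix", call. = FALSE)
  }
  dimnames(a) <- list(paste0("block", 1:3), c("win", "loss"))
  if (any(a < 0 | a > 1)) stop("learning rates must lie in [0, 1]", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  structure(list(alpha = a, beta = beta, bias = bias), class = "agent_params")
}

#' Delta-rule value update
#'
#' `v' = v + alpha * (outcome - v)`: the learnt outcome probability moves
#' towards the observed outcome by a fraction `alpha` of the prediction
#' error. With `alpha` and `v` in `[0, 1]` the update stays in `[0, 1]`.
#'
#' @param v Current estimate in `[0, 1]`.
#' @param outcome Observed outcome, 0 or 1.
#' @param alpha Learning rate in `[0, 1]`.
#' @return Updated estimate(s).
#' @export
update_value <- function(v, outcome, alpha) {
  if (any(alpha < 0 | alpha > 1)) {
    stop("learning rate alpha must lie in [0, 1]", call. = FALSE)
  }
  v + alpha * (outcome - v)
}

#' Softmax probability of choosing shape A
#'
#' The decision variable contrasts the net value of A against B. With
#' complementary contingencies (`v_B = 1 - v_A` for each valence) the net
#' difference is `2 * (v_win_A - v_loss_A)`, so
#' `P(A) = logistic(beta * 2 * (v_win_A - v_loss_A) + bias)`.
#'
#' @param v_win_A,v_loss_A Learnt win/loss probabilities for shape A.
#' @param beta Inverse temperature.
#' @param bias Additive preference for A (logit units).
#' @return Probability of choosing A (vectorised).
#' @export
choice_probability <- function(v_win_A, v_loss_A, beta, bias = 0) {
  stats::plogis(beta * 2 * (v_win_A - v_loss_A) + bias)
}

# Pre-choice value trajectory for one block and valence: the value used on
# trial t is the estimate after t-1 delta-rule updates, starting at v0.
pre_choice_values <- function(outcomes, alpha, v0 = 0.5) {
  n <- length(outcomes)
  v <- numeric(n)
  cur <- v0
  for (t in seq_len(n)) {
    v[t] <- cur
    cur <- cur + alpha * (outcomes[t] - cur)
  }
  v
}

# Consecutive runs of equal block labels: values reset at each segment
# (stimuli change between blocks; concatenated sessions also reset).
block_segments <- function(block) {
  r <- rle(as.integer(block))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  purrr::map(seq_along(starts),
             function(j) list(block = r$values[j], idx = starts[j]:ends[j]))
}

# Pre-choice win/loss value trajectories for a whole schedule. Values reset
# to 0.5 at block boundaries (new stimulus pair each block). Depends only on
# the realized outcome locations, never on choices (full feedback).
state_trajectories <- function(schedule, params) {
  n <- nrow(schedule)
  vw <- numeric(n)
  vl <- numeric(n)
  for (seg in block_segments(schedule$block)) {
    vw[seg$idx] <- pre_choice_values(as.numeric(schedule$win_on_A[seg$idx]),
                                     params$alpha[seg$block, "win"])
    vl[seg$idx] <- pre_choice_values(as.numeric(schedule$loss_on_A[seg$idx]),
                                     params$alpha[seg$block, "loss"])
  }
  cbind(v_win_A = vw, v_loss_A = vl)
}

#' Simulate an agent playing the volatility task
#'
#' Full feedback: both stimuli's outcomes are shown on every trial, so both
#' valence estimates are updated every trial regardless of choice. Wins add
#' 15p to and losses subtract 15p from a monetary total initialised at
#' GBP 1.50; an outcome is *received* when the chosen stimulus carried it.
#'
#' @param schedule A `task_schedule` tibble.
#' @param params An [agent_params()] object.
#' @param seed Optional seed.
#' @param subject_id,group Labels attached to the output.
#' @return A tibble (class `subject_data`) with the schedule columns plus
#'   `subject_id`, `group`, `order`, `chose_A`, `win_received`,
#'   `loss_received`, `money_after`; true parameters in attribute
#'   `"true_params"`.
#' @export
simulate_agent <- function(schedule, params, seed = NULL,
                           subject_id = "s1", group = NA_character_) {
  local_seed_if(seed)
  v <- state_trajectories(schedule, params)
  p_a <- choice_probability(v[, 1], v[, 2], params$beta, params$bias)
  chose_A <- stats::runif(nrow(schedule)) < p_a
  win_received <- chose_A == schedule$win_on_A
  loss_received <- chose_A == schedule$loss_on_A
  cfg <- attr(schedule, "config")
  out <- dplyr::mutate(
    tibble::as_tibble(schedule),
    subject_id = subject_id,
    group = group,
    order = (cfg %||% list(block_order = NA_character_))$block_order,
    chose_A = chose_A,
    win_received = win_received,
    loss_received = loss_received,
    money_after = 1.50 + cumsum(0.15 * win_received - 0.15 * loss_received)
  )
  attr(out, "true_params") <- params
  attr(out, "config") <- cfg
  class(out) <- c("subject_data", class(out))
  out
}

#' Log-likelihood of observed choices under an agent parameterisation
#'
#' The latent value trajectory is recomputed from the dataset's realized
#' outcome locations (both stimuli are always shown), so it is identical
#' whatever the subject chose; the likelihood scores the observed choices
#' against the resulting softmax probabilities. Per-trial probabilities are
#' floored at 1e-10 (with a warning if the floor binds).
#'
#' @param data A subject's trial table with columns `block`, `win_on_A`,
#'   `loss_on_A`, `chose_A`.
#' @param params An [agent_params()] object.
#' @return The summed log-likelihood (scalar).
#' @export
log_likelihood <- function(data, params) {
  assert_columns(data, c("block", "win_on_A", "loss_on_A", "chose_A"))
  v <- state_trajectories(data, params)
  p_a <- choice_probability(v[, 1], v[, 2], params$beta, params$bias)
  p_obs <- ifelse(data$chose_A, p_a, 1 - p_a)
  if (any(p_obs < 1e-10)) {
    warning("per-trial choice probabilities floored at 1e-10")
    p_obs <- pmax(p_obs, 1e-10)
  }
  sum(log(p_obs))
}
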