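#' Parameters of the dual-systems agent
#'
#' The agent mixes model-based planning values (planet values propagated
#' through the known deterministic transition map) with model-free cached
#' values learned by temporal-difference updates. The mixture weight is
#' stake-conditioned: `w_high` applies on high-stake trials, `w_low` on
#' low-stake trials, and their difference `w_high - w_low` is the
#' metacontrol score (positive = more model-based control when the stakes
#' are high).
#'
#' @param alpha learning rate in \[0, 1\].
#' @param beta softmax inverse temperature (>= 0), applied to values on the
#'   \[0, 1\] scaled-treasure scale.
#' @param lam eligibility-trace weight in \[0, 1\] carrying the
#'   second-stage prediction error back to the first-stage value.
#' @param w_low,w_high model-based weights in \[0, 1\] for low- and
#'   high-stake trials.
#' @param pi choice-stickiness weight: bonus for choosing the spaceship
#'   flying to the same planet as the previous choice.
#' @param rho response-key stickiness weight: bonus for repeating the
#'   previous physical response side.
#' @return an object of class `agent_params`.
#' @export
agent_params <- function(alpha = 0.3, beta = 4, lam = 0.6,
                         w_low = 0.5, w_high = 0.5, pi = 0, rho = 0) {
  p <- list(alpha = alpha, beta = beta, lam = lam,
            w_low = w_low, w_high = w_high, pi = pi, rho = rho)
  for (nm in c("alpha", "lam", "w_low", "w_high"))
    if (!is.finite(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1)
      mc_error(sprintf("%s must lie in [0, 1]", nm), "invalid_parameter")
  if (!is.finite(beta) || beta < 0)
    mc_error("beta must be a nonnegative real", "invalid_parameter")
  if (!is.finite(p$pi) || !is.finite(p$rho))
    mc_error("stickiness weights must be finite", "invalid_parameter")
  structure(p, class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(paste0("dual-systems agent: alpha=%.3f beta=%.3f lam=%.3f ",
                     "w_low=%.3f w_high=%.3f pi=%.3f rho=%.3f ",
                     "(metacontrol %.3f)\n"),
              x$alpha, x$beta, x$lam, x$w_low, x$w_high, x$pi, x$rho,
              x$w_high - x$w_low))
  invisible(x)
}

#' Initial agent state
#'
#' Model-free values are cached per spaceship (hence per pair: the
#' model-free system cannot generalize across pairs), planet values are
#' shared. Both start at 0.5, the midpoint of the scaled treasure range,
#' so neither option is favoured on the first trial.
#'
#' @param config a [task_config()].
#' @return an object of class `agent_state` with fields `q_mf` (4 values),
#'   `v_planet` (2 values), `prev_planet`, `prev_key`.
#' @export
agent_state_init <- function(config) {
  ships <- names(config$transition_map)
  structure(list(q_mf = stats::setNames(rep(0.5, length(ships)), ships),
                 v_planet = stats::setNames(rep(0.5, 2L), config$planets),
                 prev_planet = NA_character_, prev_key = NA_character_),
            class = "agent_state")
}

#' Model-based values for a spaceship pair
#'
#' The planning system values each spaceship by the current value of the
#' planet it deterministically reaches, so spaceships in different pairs
#' that share a destination share a value exactly.
#'
#' @param state an [agent_state_init()] state.
#' @param config a [task_config()].
#' @param pair pair id (`"pairA"` or `"pairB"` under the default config).
#' @return named numeric vector of length 2 (one value per spaceship).
#' @export
mb_values <- function(state, config, pair) {
  ships <- config$pairs[[pair]]
  if (is.null(ships)) mc_error(sprintf("unknown pair id: %s", pair), "key")
  stats::setNames(state$v_planet[transition(ships, config)], ships)
}

#' Model-free temporal-difference update
#'
#' Two-step TD with an eligibility trace: the first-stage cached value
#' moves toward the destination-planet value (delta1), the planet value
#' moves toward the received scaled reward (delta2), and a fraction `lam`
#' of delta2 is carried back to the first-stage value. Unchosen options
#' are untouched.
#'
#' @param state an `agent_state`.
#' @param pair pair id shown on the trial.
#' @param choice the chosen spaceship id.
#' @param reward_scaled received treasure scaled to \[0, 1\] (treasure/9).
#' @param alpha learning rate in \[0, 1\].
#' @param lam eligibility-trace weight in \[0, 1\].
#' @param config a [task_config()].
#' @return the updated `agent_state`.
#' @export
mf_update <- function(state, pair, choice, reward_scaled, alpha, lam,
                      config = task_config()) {
  if (alpha < 0 || alpha > 1 || lam < 0 || lam > 1)
    mc_error("alpha and lam must lie in [0, 1]", "invalid_parameter")
  if (!is.finite(reward_scaled))
    mc_error("reward_scaled must be finite", "data")
  dest <- transition(choice, config)
  d1 <- state$v_planet[[dest]] - state$q_mf[[choice]]
  state$q_mf[[choice]] <- state$q_mf[[choice]] + alpha * d1
  d2 <- reward_scaled - state$v_planet[[dest]]
  state$v_planet[[dest]] <- state$v_planet[[dest]] + alpha * d2
  state$q_mf[[choice]] <- state$q_mf[[choice]] + alpha * lam * d2
  state
}

#' Stake-conditioned choice probabilities
#'
#' Mixes model-based and model-free values with the stake-appropriate
#' weight and passes the net values through a softmax with optional
#' planet-level choice stickiness (`pi`) and response-key stickiness
#' (`rho`).
#'
#' @inheritParams mf_update
#' @param stake the trial's stake (1 or the multiplier).
#' @param params an [agent_params()].
#' @param keys optional named character vector mapping the pair's two
#'   spaceships to response sides (`"left"`/`"right"`); needed only when
#'   `rho != 0`.
#' @return named probability vector over the pair's two spaceships,
#'   entries strictly inside (0, 1) and summing to 1.
#' @export
choice_probabilities <- function(state, pair, stake, params,
                                 config = task_config(), keys = NULL) {
  ships <- config$pairs[[pair]]
  if (is.null(ships)) mc_error(sprintf("unknown pair id: %s", pair), "key")
  w <- if (stake > 1) params$w_high else params$w_low
  q_mb <- mb_values(state, config, pair)
  q_net <- w * q_mb + (1 - w) * state$q_mf[ships]
  logits <- params$beta * q_net
  if (!is.na(state$prev_planet))
    logits <- logits + params$pi * (transition(ships, config) ==
                                      state$prev_planet)
  if (!is.na(state$prev_key) && !is.null(keys))
    logits <- logits + params$rho * (keys[ships] == state$prev_key)
  logits <- logits - max(logits)
  p <- exp(logits)
  stats::setNames(as.numeric(p / sum(p)), ships)
}

#' Simulate one subject's session
#'
#' Generates a full session: a stake schedule and reward walks from the
#' task config, a uniformly random pair and side assignment per trial,
#' softmax choices from the agent, deterministic transitions, treasure
#' read off the (rounded) walk, points under the stake, and
#' temporal-difference learning from the scaled treasure. The stake
#' multiplier amplifies points only; the learning signal is the stake-free
#' scaled treasure.
#'
#' @param params an [agent_params()].
#' @param config a [task_config()].
#' @param seed integer seed; the whole session is reproducible from it.
#' @param subject_id id written into the trial table.
#' @param miss_prob probability a trial is missed (no response, no
#'   learning); default 0.
#' @return a trial-table `data.frame` in the package CSV schema (see
#'   [read_trials()]).
#' @export
simulate_subject <- function(params, config = task_config(), seed = NULL,
                             subject_id = "s01", miss_prob = 0) {
  stopifnot(inherits(params, "agent_params"), inherits(config, "task_config"))
  local_rng(seed)
  n <- config$n_trials
  walks <- generate_reward_walks(config, seed = NULL)
  stakes <- sample_stakes(config, seed = NULL)
  pair_seq <- sample(names(config$pairs), n, replace = TRUE)
  left_first <- stats::runif(n) < 0.5
  missed <- stats::runif(n) < miss_prob
  state <- agent_state_init(config)
  opt_l <- opt_r <- choice_v <- planet_v <- character(n)
  treasure_v <- points_v <- rep(NA_integer_, n)
  for (t in seq_len(n)) {
    ships <- config$pairs[[pair_seq[t]]]
    opts <- if (left_first[t]) ships else rev(ships)
    opt_l[t] <- opts[1]; opt_r[t] <- opts[2]
    if (missed[t]) {
      choice_v[t] <- NA_character_
      planet_v[t] <- NA_character_
      next
    }
    keys <- stats::setNames(c("left", "right"), opts)
    pr <- choice_probabilities(state, pair_seq[t], stakes[t], params,
                               config, keys)
    choice <- sample(names(pr), 1L, prob = pr)
    dest <- transition(choice, config)
    treasure <- as.integer(round(walks[t, dest]))
    state <- mf_update(state, pair_seq[t], choice,
                       treasure / config$reward_high,
                       params$alpha, params$lam, config)
    state$prev_planet <- dest
    state$prev_key <- keys[[choice]]
    choice_v[t] <- choice; planet_v[t] <- dest
    treasure_v[t] <- treasure
    points_v[t] <- points_awarded(treasure, stakes[t], config)
  }
  data.frame(subject_id = subject_id, trial = seq_len(n), pair = pair_seq,
             stake = as.integer(stakes), option_left = opt_l,
             option_right = opt_r, choice = choice_v, planet = planet_v,
             treasure = treasure_v, points = points_v, missed = missed,
             reward_red = round(walks[, "red"], 4),
             reward_purple = round(walks[, "purple"], 4),
             stringsAsFactors = FALSE)
}
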