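#' Task configuration for the two-step stakes task
#'
#' Builds the environment definition for a space-themed sequential
#' decision task: two pairs of spaceships, each pair containing one ship
#' that deterministically flies to the red planet and one to the purple
#' planet; each planet pays out 0--9 pieces of treasure according to an
#' independently drifting reward series; and a per-trial stake amplifier
#' (1x or 5x) that multiplies treasure into points.
#'
#' @param n_trials number of trials in a session (default 200).
#' @param reward_low,reward_high bounds of the treasure scale (default 0, 9).
#' @param walk_sd Gaussian step SD of the drifting reward walks, in
#'   treasure units per trial (default 2).
#' @param stake_prob probability that a trial is high stake (default 0.5).
#' @param stake_multiplier points per treasure piece on high-stake trials
#'   (default 5).
#' @param transition_map named character vector mapping each of the four
#'   spaceship ids to a planet id. The default follows the canonical task
#'   layout: dark_blue and orange fly to red; green and pink to purple.
#' @param pairs list of two character vectors naming the spaceships shown
#'   together. Each pair must contain exactly one ship per planet.
#' @param seed default RNG seed carried with the config (optional).
#' @return an object of class `task_config`.
#' @export
task_config <- function(n_trials = 200L,
                        reward_low = 0,
                        reward_high = 9,
                        walk_sd = 2,
                        stake_prob = 0.5,
                        stake_multiplier = 5L,
                        transition_map = c(dark_blue = "red", green = "purple",
                                           orange = "red", pink = "purple"),
                        pairs = list(pairA = c("dark_blue", "green"),
                                     pairB = c("orange", "pink")),
                        seed = NULL) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1)
    mc_error("n_trials must be a positive integer", "config")
  if (reward_low >= reward_high)
    mc_error("reward_low must be strictly below reward_high", "config")
  if (walk_sd < 0)
    mc_error("walk_sd must be nonnegative", "invalid_parameter")
  if (stake_prob < 0 || stake_prob > 1)
    mc_error("stake_prob must lie in [0, 1]", "config")
  if (stake_multiplier < 1 || stake_multiplier != round(stake_multiplier))
    mc_error("stake_multiplier must be a positive integer", "config")
  if (length(transition_map) != 4L || is.null(names(transition_map)))
    mc_error("transition_map must name exactly 4 spaceships", "config")
  planets <- sort(unique(unname(transition_map)))
  if (length(planets) != 2L)
    mc_error("transition_map must target exactly 2 planets", "config")
  if (length(pairs) != 2L || is.null(names(pairs)))
    mc_error("pairs must be a named list of 2 spaceship pairs", "config")
  for (p in names(pairs)) {
    ships <- pairs[[p]]
    if (length(ships) != 2L || !all(ships %in% names(transition_map)))
      mc_error(sprintf("pair %s must contain 2 known spaceships", p), "config")
    if (length(unique(transition_map[ships])) != 2L)
      mc_error(sprintf("pair %s must map onto both planets exactly once", p),
               "config")
  }
  structure(list(n_trials = as.integer(n_trials),
                 reward_low = reward_low, reward_high = reward_high,
                 walk_sd = walk_sd, stake_prob = stake_prob,
                 stake_multiplier = as.integer(stake_multiplier),
                 transition_map = transition_map, pairs = pairs,
                 planets = planets, seed = seed),
            class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Two-step stakes task:", x$n_trials, "trials, treasure",
      x$reward_low, "-", x$reward_high,
      sprintf("(walk SD %.2f), stakes 1x/%dx at P(high) = %.2f\n",
              x$walk_sd, x$stake_multiplier, x$stake_prob))
  for (p in names(x$pairs)) {
    s <- x$pairs[[p]]
    cat(sprintf("  %s: %s -> %s, %s -> %s\n", p,
                s[1], x$transition_map[s[1]], s[2], x$transition_map[s[2]]))
  }
  invisible(x)
}

# Reflect a proposed step x + eps into [lo, hi]: one fold at whichever
# bound is crossed (2*lo - y below, 2*hi - y above). Steps so large that
# a single fold does not return to the interval raise an error rather
# than iterating silently.
reflect_step <- function(x, eps, lo, hi) {
  y <- x + eps
  below <- y < lo
  y[below] <- 2 * lo - y[below]
  above <- y > hi
  y[above] <- 2 * hi - y[above]
  if (any(y < lo | y > hi))
    mc_error("walk step too large for single reflection at the bounds",
             "invalid_parameter")
  y
}

#' Generate drifting per-planet reward walks
#'
#' Each planet's payout follows an independent Gaussian random walk with
#' step SD `walk_sd`, reflected at the treasure bounds; initial values are
#' uniform on the bounds.
#'
#' @param config a [task_config()].
#' @param seed integer seed (falls back to `config$seed`).
#' @return numeric matrix `n_trials` x 2 with one column per planet, values
#'   in `[reward_low, reward_high]`.
#' @export
generate_reward_walks <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "task_config"))
  if (config$walk_sd < 0) mc_error("walk_sd must be nonnegative",
                                   "invalid_parameter")
  local_rng(seed)
  lo <- config$reward_low; hi <- config$reward_high
  n <- config$n_trials
  walks <- matrix(NA_real_, n, 2L, dimnames = list(NULL, config$planets))
  x <- stats::runif(2L, lo, hi)
  walks[1L, ] <- x
  if (n > 1L) for (t in 2L:n) {
    eps <- stats::rnorm(2L, 0, config$walk_sd)
    x <- reflect_step(x, eps, lo, hi)
    walks[t, ] <- x
  }
  walks
}

#' Sample the stake schedule
#'
#' i.i.d. Bernoulli(`stake_prob`) draws mapped to
#' `{stake_multiplier, 1}` so that high and low stakes occur at random in
#' the requested ratio.
#'
#' @inheritParams generate_reward_walks
#' @return integer vector of length `n_trials` with entries in
#'   `{1, stake_multiplier}`.
#' @export
sample_stakes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "task_config"))
  local_rng(seed)
  high <- stats::runif(config$n_trials) < config$stake_prob
  ifelse(high, config$stake_multiplier, 1L)
}

#' Deterministic spaceship-to-planet transition
#'
#' @param spaceship a spaceship id present in the config's transition map.
#' @param config a [task_config()].
#' @return the planet id the spaceship always flies to.
#' @export
transition <- function(spaceship, config) {
  stopifnot(inherits(config, "task_config"))
  if (!all(spaceship %in% names(config$transition_map)))
    mc_error(sprintf("unknown spaceship id: %s",
                     paste(setdiff(spaceship, names(config$transition_map)),
                           collapse = ", ")), "key")
  unname(config$transition_map[spaceship])
}

#' Points awarded for a treasure haul under a stake
#'
#' On low-stake trials each treasure piece is worth one point; on
#' high-stake trials treasure is multiplied by the stake amplifier.
#'
#' @param treasure integer treasure count within the task bounds.
#' @param stake 1 or the configured stake multiplier.
#' @param config a [task_config()].
#' @return integer points.
#' @export
points_awarded <- function(treasure, stake, config = task_config()) {
  if (any(treasure < config$reward_low | treasure > config$reward_high) ||
      any(treasure != round(treasure)))
    mc_error("treasure must be an integer within the task bounds",
             "invalid_input")
  if (!all(stake %in% c(1L, config$stake_multiplier)))
    mc_error("stake must be 1 or the stake multiplier", "invalid_input")
  as.integer(treasure * stake)
}

# Which pair a spaceship belongs to.
pair_of <- function(spaceship, config) {
  for (p in names(config$pairs))
    if (spaceship %in% config$pairs[[p]]) return(p)
  mc_error(sprintf("unknown spaceship id: %s", spaceship), "key")
}
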