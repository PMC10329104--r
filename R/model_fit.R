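# --- parameter transforms -------------------------------------------------
# MLE runs in an unconstrained-ish box: logit scale for the unit-interval
# parameters, log scale for beta, identity for the stickiness weights.
# Box bounds keep the optimizer away from the non-identifiable plateaus at
# the parameter-space edges.

.par_names <- c("alpha", "beta", "lam", "w_low", "w_high", "pi", "rho")

transform_params <- function(params) {
  c(stats::qlogis(params$alpha), log(params$beta),
    stats::qlogis(params$lam), stats::qlogis(params$w_low),
    stats::qlogis(params$w_high), params$pi, params$rho)
}

untransform_params <- function(u) {
  agent_params(alpha = stats::plogis(u[1]), beta = exp(u[2]),
               lam = stats::plogis(u[3]), w_low = stats::plogis(u[4]),
               w_high = stats::plogis(u[5]), pi = u[6], rho = u[7])
}

transform_bounds <- function() {
  list(lower = c(-8, log(1e-3), -8, -8, -8, -5, -5),
       upper = c(8, log(20), 8, 8, 8, 5, 5))
}

# --- trial encoding -------------------------------------------------------
# Integer-code a trial table once so the C++ likelihood can run a flat
# loop. Also the central data-validation point for the fitting path.
encode_trials <- function(trials, config) {
  ships <- names(config$transition_map)
  li <- match(trials$option_left, ships)
  ri <- match(trials$option_right, ships)
  if (anyNA(li) || anyNA(ri))
    mc_error("unknown spaceship id in option columns", "data")
  missed <- as.logical(trials$missed)
  chosen <- rep(-1L, nrow(trials))
  ch <- ifelse(trials$choice == trials$option_left, 0L,
               ifelse(trials$choice == trials$option_right, 1L, NA_integer_))
  chosen[!missed] <- ch[!missed]
  if (anyNA(chosen[!missed]))
    mc_error("choice not among the shown spaceships", "data")
  rsc <- trials$treasure / config$reward_high
  if (any(!is.finite(rsc[!missed])))
    mc_error("NaN or missing reward on a non-missed trial", "data")
  planet_idx <- function(s) match(unname(config$transition_map[s]),
                                  config$planets) - 1L
  enc <- cbind(li - 1L, ri - 1L, chosen,
               planet_idx(trials$option_left),
               planet_idx(trials$option_right),
               as.integer(trials$stake > 1))
  storage.mode(enc) <- "integer"
  list(enc = enc, rsc = rsc)
}

#' Negative log-likelihood of a session under the dual-systems model
#'
#' Steps the agent through the observed session, trial by trial, using
#' the observed choices and rewards, and accumulates `-log P(choice)`
#' over non-missed trials. Missed trials contribute nothing and do not
#' update values. Two engines are provided: a compiled path (`"cpp"`,
#' default, used by the fitter) and a plain-R path (`"r"`) built from the
#' exported agent primitives, kept as an independent cross-check.
#'
#' @param params an [agent_params()].
#' @param trials a trial table (see [read_trials()] for the schema).
#' @param config a [task_config()].
#' @param engine `"cpp"` or `"r"`.
#' @return nonnegative scalar, natural-log units.
#' @export
negative_log_likelihood <- function(params, trials, config = task_config(),
                                    engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "agent_params"))
  if (engine == "cpp") {
    ed <- encode_trials(trials, config)
    return(nll_cpp(unlist(params[.par_names]), ed$enc, ed$rsc))
  }
  # reference path: drive the exported state functions
  encode_trials(trials, config)   # shared validation
  state <- agent_state_init(config)
  nll <- 0
  for (i in seq_len(nrow(trials))) {
    row <- trials[i, ]
    if (isTRUE(as.logical(row$missed))) next
    keys <- stats::setNames(c("left", "right"),
                            c(row$option_left, row$option_right))
    pr <- choice_probabilities(state, row$pair, row$stake, params,
                               config, keys)
    nll <- nll - log(pr[[row$choice]])
    state <- mf_update(state, row$pair, row$choice,
                       row$treasure / config$reward_high,
                       params$alpha, params$lam, config)
    state$prev_planet <- transition(row$choice, config)
    state$prev_key <- keys[[row$choice]]
  }
  nll
}

#' Fit the dual-systems model to one subject by maximum likelihood
#'
#' Bounded quasi-Newton optimization of the negative log-likelihood over
#' transformed parameters, restarted from `n_restarts` seeded uniform
#' start points; the best optimum is retained (ties broken by restart
#' index). If the session contains no trial of one stake condition, the
#' corresponding weight is unidentified and the metacontrol score is
#' reported as `NA`.
#'
#' @param trials a trial table for one subject.
#' @param config a [task_config()].
#' @param n_restarts number of random restarts (default 20).
#' @param seed integer seed controlling the start points.
#' @param fit_stickiness if `FALSE`, the stickiness weights `pi` and `rho`
#'   are fixed at 0 instead of estimated.
#' @return an object of class `fit_result`: `params_hat`, `nll`,
#'   `n_restarts`, `converged`, `n_trials_used`, `metacontrol`,
#'   `w_identified`.
#' @export
fit_subject <- function(trials, config = task_config(), n_restarts = 20L,
                        seed = NULL, fit_stickiness = TRUE) {
  ed <- encode_trials(trials, config)
  used <- ed$enc[, 3] >= 0L
  n_used <- sum(used)
  if (n_used == 0L) mc_error("no usable (non-missed) trials", "data")
  w_identified <- c(low = any(ed$enc[used, 6] == 0L),
                    high = any(ed$enc[used, 6] == 1L))
  b <- transform_bounds()
  free <- if (fit_stickiness) 1:7 else 1:5
  obj <- function(u_free) {
    u <- c(u_free, 0, 0)[1:7]
    if (!fit_stickiness) u[6:7] <- 0
    p <- c(stats::plogis(u[1]), exp(u[2]), stats::plogis(u[3]),
           stats::plogis(u[4]), stats::plogis(u[5]), u[6], u[7])
    nll_cpp(p, ed$enc, ed$rsc)
  }
  local_rng(seed)
  starts <- matrix(stats::runif(n_restarts * length(free),
                                min = rep(b$lower[free], each = n_restarts),
                                max = rep(b$upper[free], each = n_restarts)),
                   nrow = n_restarts)
  best <- NULL
  any_converged <- FALSE
  for (k in seq_len(n_restarts)) {
    res <- tryCatch(
      stats::optim(starts[k, ], obj, method = "L-BFGS-B",
                   lower = b$lower[free], upper = b$upper[free],
                   control = list(maxit = 500L, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (res$convergence == 0L) any_converged <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    return(structure(list(params_hat = NULL, nll = NA_real_,
                          n_restarts = n_restarts, converged = FALSE,
                          n_trials_used = n_used, metacontrol = NA_real_,
                          w_identified = w_identified),
                     class = "fit_result"))
  u <- c(best$par, 0, 0)[1:7]
  if (!fit_stickiness) u[6:7] <- 0
  params_hat <- untransform_params(u)
  fit <- structure(list(params_hat = params_hat, nll = best$value,
                        n_restarts = n_restarts, converged = any_converged,
                        n_trials_used = n_used, metacontrol = NA_real_,
                        w_identified = w_identified),
                   class = "fit_result")
  fit$metacontrol <- metacontrol_score(fit)
  fit
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit over %d trials: nll = %.4f (%d restarts, converged: %s)\n",
              x$n_trials_used, x$nll, x$n_restarts, x$converged))
  if (!is.null(x$params_hat)) print(x$params_hat)
  cat("metacontrol:", format(x$metacontrol), "\n")
  invisible(x)
}

#' Metacontrol score of a fitted subject
#'
#' The stake-sensitivity of model-based control: `w_high - w_low`.
#' Positive values mean more model-based decision-making when the stakes
#' are high. `NA` if either weight is unidentified (no trials of that
#' stake condition).
#'
#' @param fit a `fit_result` from [fit_subject()].
#' @return scalar in \[-1, 1\], or `NA`.
#' @export
metacontrol_score <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  if (is.null(fit$params_hat) || !all(fit$w_identified)) return(NA_real_)
  fit$params_hat$w_high - fit$params_hat$w_low
}
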