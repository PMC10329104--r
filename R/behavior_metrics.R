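#' Corrected reward rate of a session
#'
#' Performance against the yoked chance level: the mean over non-missed
#' trials of obtained treasure minus the mean treasure available across
#' the two planets on that trial. Zero is chance; positive values mean
#' the subject tracked the drifting rewards better than a coin flip.
#' Computed on the treasure scale so the stake schedule's luck does not
#' contaminate the metric. An alternative correction against the richer
#' planet's payout (`method = "max"`) is provided; its chance level is
#' negative.
#'
#' @param trials a trial table.
#' @param method `"mean"` (default) or `"max"` available-reward baseline.
#' @return scalar in treasure units per trial; `NA` if every trial was
#'   missed.
#' @export
corrected_reward_rate <- function(trials, method = c("mean", "max")) {
  method <- match.arg(method)
  ok <- !as.logical(trials$missed)
  if (!any(ok)) return(NA_real_)
  avail <- if (method == "mean")
    (trials$reward_red[ok] + trials$reward_purple[ok]) / 2
  else pmax(trials$reward_red[ok], trials$reward_purple[ok])
  mean(trials$treasure[ok] - avail)
}

#' Missed-trial exclusion rule
#'
#' A subject is excluded when strictly more than `max_pct_missed` percent
#' of trials were missed; exactly at the boundary they are kept.
#'
#' @param trials a trial table.
#' @param max_pct_missed exclusion boundary in percent (default 30).
#' @return list with `pct_missed` and `included`.
#' @export
apply_exclusions <- function(trials, max_pct_missed = 30) {
  pct <- 100 * mean(as.logical(trials$missed))
  list(pct_missed = pct, included = pct <= max_pct_missed)
}

#' Stay-probability generalization analysis
#'
#' A model-agnostic marker of model-based control. "Stay" is defined at
#' the planet level: did the subject choose the spaceship flying to the
#' previously visited planet? A logistic regression of stay on the
#' previous scaled reward, with separate slopes for same-pair and
#' different-pair trial transitions. The different-pair slope is the
#' generalization index: only a planning agent transfers a reward
#' experience across pairs, because model-free values are cached per
#' spaceship.
#'
#' Caveat: with serially correlated reward walks (the default
#' environment) the index is upward-biased for any value-persistent
#' agent, planner or not — the previous reward correlates with the
#' current richness of its planet, which the agent's cached values also
#' track. The index therefore separates planners from cachers by
#' magnitude (planners score several times higher in simulation), not by
#' a sharp zero for cachers.
#'
#' @param trials a trial table.
#' @param min_pairs minimum usable consecutive-trial pairs (default 30).
#' @return list with `generalization_index` (different-pair previous-
#'   reward slope), `same_pair_index`, `coefficients` (full glm
#'   coefficients), `n_pairs`, `degenerate`.
#' @export
stay_probability_analysis <- function(trials, min_pairs = 30L) {
  ok <- !as.logical(trials$missed)
  n <- nrow(trials)
  idx <- which(ok[-n] & ok[-1])         # usable consecutive pairs (t, t+1)
  if (length(idx) < min_pairs)
    mc_error(sprintf("need at least %d usable consecutive-trial pairs",
                     min_pairs), "data")
  prev <- trials[idx, ]
  cur <- trials[idx + 1L, ]
  # stayed iff the current choice flies to the previously visited planet
  stay <- as.integer(cur$planet == prev$planet)
  prev_r <- prev$treasure / 9 - 0.5
  same_pair <- as.integer(cur$pair == prev$pair)
  if (length(unique(stay)) < 2L)
    return(list(generalization_index = NA_real_, same_pair_index = NA_real_,
                coefficients = NULL, n_pairs = length(idx),
                degenerate = TRUE))
  x_same <- prev_r * same_pair
  x_diff <- prev_r * (1L - same_pair)
  fit <- stats::glm(stay ~ same_pair + x_same + x_diff,
                    family = stats::binomial())
  co <- stats::coef(fit)
  list(generalization_index = unname(co["x_diff"]),
       same_pair_index = unname(co["x_same"]),
       coefficients = co, n_pairs = length(idx), degenerate = FALSE)
}

#' Summarize one subject's session
#'
#' @param trials a trial table.
#' @param max_pct_missed exclusion boundary in percent.
#' @return one-row `data.frame`: `subject_id`, `corrected_reward_rate`,
#'   `pct_missed`, `included`, `generalization_index`.
#' @export
subject_summary <- function(trials, max_pct_missed = 30) {
  excl <- apply_exclusions(trials, max_pct_missed)
  gi <- tryCatch(stay_probability_analysis(trials)$generalization_index,
                 error = function(e) NA_real_)
  data.frame(subject_id = trials$subject_id[1],
             corrected_reward_rate = corrected_reward_rate(trials),
             pct_missed = excl$pct_missed, included = excl$included,
             generalization_index = gi, stringsAsFactors = FALSE)
}
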