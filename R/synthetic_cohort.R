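#' Specification of a synthetic developmental cohort
#'
#' Encodes the individual-difference structure the downstream inference
#' assumes: a middle-childhood age range, a model-based weight mildly
#' increasing with age, a metacontrol score uncorrelated with age but
#' correlated with an inhibition-cost (Flanker) score and with
#' standardized dorsolateral-prefrontal thickness proxies. Correlation
#' targets apply to latent Gaussian scores; observed variables are
#' monotone transforms of those latents, so realized Pearson correlations
#' are mildly attenuated.
#'
#' @param n_subjects cohort size (default 69).
#' @param age_range years, default `c(6.19, 12.61)`.
#' @param r_age_w target correlation of age with the low-stake
#'   model-based weight (default 0.25).
#' @param r_age_metacontrol default 0.
#' @param r_flanker_metacontrol default 0.42.
#' @param r_thickness_metacontrol_left,r_thickness_metacontrol_right
#'   calibration targets for the thickness proxies (defaults 0.37, 0.42;
#'   back-converted from the reported ROI t statistics, not reproduction
#'   targets).
#' @param metacontrol_sd population SD of the metacontrol score on the
#'   weight scale (default 0.25).
#' @param w_latent_sd SD of the latent logit of the low-stake weight
#'   (default 1.6, giving a near-flat weight distribution on \[0, 1\],
#'   matching the strongly dispersed fitted weights this task family
#'   reports).
#' @param prop_female proportion female (default 35/69).
#' @param comprehension_rate probability a child reports the transition
#'   structure correctly (default 0.96).
#' @param seed default seed carried with the spec.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 69L,
                        age_range = c(6.19, 12.61),
                        r_age_w = 0.25,
                        r_age_metacontrol = 0,
                        r_flanker_metacontrol = 0.42,
                        r_thickness_metacontrol_left = 0.37,
                        r_thickness_metacontrol_right = 0.42,
                        metacontrol_sd = 0.25,
                        w_latent_sd = 1.6,
                        prop_female = 35 / 69,
                        comprehension_rate = 0.96,
                        seed = NULL) {
  rs <- c(r_age_w = r_age_w, r_age_metacontrol = r_age_metacontrol,
          r_flanker_metacontrol = r_flanker_metacontrol,
          r_thickness_metacontrol_left = r_thickness_metacontrol_left,
          r_thickness_metacontrol_right = r_thickness_metacontrol_right)
  if (any(abs(rs) >= 1))
    mc_error("all target correlations must lie in (-1, 1)", "spec")
  if (n_subjects < 4) mc_error("n_subjects must be at least 4", "spec")
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 r_age_w = r_age_w, r_age_metacontrol = r_age_metacontrol,
                 r_flanker_metacontrol = r_flanker_metacontrol,
                 r_thickness_metacontrol_left = r_thickness_metacontrol_left,
                 r_thickness_metacontrol_right = r_thickness_metacontrol_right,
                 metacontrol_sd = metacontrol_sd, w_latent_sd = w_latent_sd,
                 prop_female = prop_female,
                 comprehension_rate = comprehension_rate, seed = seed),
            class = "cohort_spec")
}

# Latent correlation matrix over (age, w_low, metacontrol, flanker,
# thickness_left, thickness_right). Pairs the spec does not constrain
# are 0.
cohort_corr_matrix <- function(spec) {
  vars <- c("age", "w_low", "metacontrol", "flanker", "thick_l", "thick_r")
  R <- diag(6)
  dimnames(R) <- list(vars, vars)
  set_r <- function(R, a, b, r) { R[a, b] <- R[b, a] <- r; R }
  R <- set_r(R, "age", "w_low", spec$r_age_w)
  R <- set_r(R, "age", "metacontrol", spec$r_age_metacontrol)
  R <- set_r(R, "metacontrol", "flanker", spec$r_flanker_metacontrol)
  R <- set_r(R, "metacontrol", "thick_l", spec$r_thickness_metacontrol_left)
  R <- set_r(R, "metacontrol", "thick_r", spec$r_thickness_metacontrol_right)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    # name the most loaded pair for the error message
    off <- abs(R); diag(off) <- 0
    ij <- which(off == max(off), arr.ind = TRUE)[1, ]
    mc_error(sprintf(
      "correlation targets are jointly infeasible (matrix not PSD); largest request is %s-%s = %.3f",
      vars[ij[1]], vars[ij[2]], R[ij[1], ij[2]]), "spec")
  }
  R
}

#' Generate a synthetic cohort
#'
#' Draws correlated latent Gaussian scores through a Gaussian copula
#' (Cholesky factor of the target correlation matrix), then maps them to
#' observables: age uniform on the age range, the low-stake model-based
#' weight through a logistic link, the metacontrol score as a bounded
#' Gaussian shift of `w_low` (so `w_high = w_low + metacontrol` stays in
#' \[0, 1\]), and standardized Flanker / Stroop / working-memory /
#' thickness scores. Remaining agent parameters come from fixed plausible
#' population distributions (configurable calibration choices, not
#' reproduction targets).
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed (falls back to `spec$seed`).
#' @return `data.frame` of class `cohort`, one row per subject.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  R <- cohort_corr_matrix(spec)
  local_rng(seed)
  n <- spec$n_subjects
  # copula draw: Z %*% chol(R) gives rows with correlation R
  Z <- matrix(stats::rnorm(n * 6L), n, 6L) %*% chol(R + diag(1e-12, 6))
  colnames(Z) <- colnames(R)
  age <- stats::qunif(stats::pnorm(Z[, "age"]),
                      spec$age_range[1], spec$age_range[2])
  w_low <- stats::plogis(spec$w_latent_sd * Z[, "w_low"])
  meta_raw <- spec$metacontrol_sd * Z[, "metacontrol"]
  w_high <- pmin(pmax(w_low + meta_raw, 0), 1)
  metacontrol <- w_high - w_low
  out <- data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    age = age,
    sex = ifelse(stats::runif(n) < spec$prop_female, "F", "M"),
    alpha = stats::plogis(stats::rnorm(n, -0.2, 0.6)),
    beta = pmin(exp(stats::rnorm(n, log(4), 0.3)), 20),
    lam = stats::plogis(stats::rnorm(n, 0, 0.7)),
    w_low = w_low,
    w_high = w_high,
    metacontrol = metacontrol,
    pi = stats::rnorm(n, 0.2, 0.2),
    rho = stats::rnorm(n, 0, 0.2),
    flanker = Z[, "flanker"],
    stroop = stats::rnorm(n),
    wm_span = stats::rnorm(n),
    thickness_left = Z[, "thick_l"],
    thickness_right = Z[, "thick_r"],
    comprehension = stats::runif(n) < spec$comprehension_rate,
    stringsAsFactors = FALSE)
  class(out) <- c("cohort", "data.frame")
  out
}

#' Subject's true agent parameters from a cohort row
#'
#' @param cohort a `cohort` data frame.
#' @param i row index.
#' @return an [agent_params()].
#' @export
cohort_params <- function(cohort, i) {
  agent_params(alpha = cohort$alpha[i], beta = cohort$beta[i],
               lam = cohort$lam[i], w_low = cohort$w_low[i],
               w_high = cohort$w_high[i], pi = cohort$pi[i],
               rho = cohort$rho[i])
}

#' Simulate task sessions for a whole cohort
#'
#' One session per subject, generated with that subject's true
#' parameters; per-subject seeds are derived deterministically from the
#' master seed so any subject can be regenerated in isolation.
#'
#' @param cohort a `cohort` data frame.
#' @param config a [task_config()].
#' @param seed master integer seed.
#' @return named list of trial tables, one per subject.
#' @export
simulate_cohort_behavior <- function(cohort, config = task_config(),
                                     seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  tables <- vector("list", nrow(cohort))
  names(tables) <- cohort$subject_id
  for (i in seq_len(nrow(cohort))) {
    tables[[i]] <- simulate_subject(cohort_params(cohort, i), config,
                                    seed = derive_seed(seed, 1L, i),
                                    subject_id = cohort$subject_id[i])
  }
  tables
}
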