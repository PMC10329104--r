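cfg <- task_config()

test_that("a flat policy scores exactly T*ln(2) regardless of the data", {
  p <- agent_params(beta = 0, pi = 0, rho = 0)
  tt <- simulate_subject(agent_params(alpha = 0.4, beta = 5, w_low = 0.8,
                                      w_high = 0.8), cfg, seed = 2)
  expect_equal(negative_log_likelihood(p, tt, cfg), 200 * log(2))
  expect_equal(negative_log_likelihood(p, tt, cfg, engine = "r"),
               200 * log(2))
})

test_that("3-trial likelihood matches an independent hand computation", {
  p <- agent_params(alpha = 0.5, beta = 3, lam = 0.5, w_low = 0.3,
                    w_high = 0.9, pi = 0.4, rho = 0.2)
  tt <- make_trials(list(
    tr("pairA", 1, "dark_blue", "green", "green", 2.0, 6.0),
    tr("pairB", 5, "pink", "orange", "orange", 3.0, 1.0),
    tr("pairA", 1, "green", "dark_blue", "dark_blue", 9.0, 5.0)))
  # trial 1: all values 0.5, no stickiness carry-over -> P = 1/2.
  #   update green (purple, r = 6/9): v_pur = .5 + .5*(2/3 - .5) = 7/12
  #   q_green = .5 + .5*0 + .5*.5*(2/3 - .5) = 13/24
  v_pur <- 7 / 12; q_green <- 13 / 24
  # trial 2 (high stake, w = .9): Qnet_pink = .9*v_pur + .1*.5,
  #   Qnet_orange = .9*.5 + .1*.5; pink flies to the previous planet
  #   (+pi); orange repeats the right key (+rho)
  l_pink <- 3 * (0.9 * v_pur + 0.05) + 0.4
  l_orange <- 3 * 0.5 + 0.2
  p2 <- exp(l_orange) / (exp(l_orange) + exp(l_pink))
  #   update orange (red, r = 3/9): v_red = .5 + .5*(1/3 - .5) = 5/12
  v_red <- 5 / 12
  # trial 3 (low stake, w = .3): dark_blue flies to prev planet (+pi) and
  #   repeats the right key (+rho)
  l_green <- 3 * (0.3 * v_pur + 0.7 * q_green)
  l_db <- 3 * (0.3 * v_red + 0.7 * 0.5) + 0.4 + 0.2
  p3 <- exp(l_db) / (exp(l_db) + exp(l_green))
  expected <- -log(0.5) - log(p2) - log(p3)
  expect_equal(negative_log_likelihood(p, tt, cfg), expected,
               tolerance = 1e-12)
  expect_equal(negative_log_likelihood(p, tt, cfg, engine = "r"), expected,
               tolerance = 1e-12)
})

test_that("compiled and reference engines agree to 1e-10 on small tables", {
  set.seed(41)
  for (rep in 1:12) {
    p <- agent_params(alpha = runif(1), beta = runif(1, 0, 8),
                      lam = runif(1), w_low = runif(1), w_high = runif(1),
                      pi = runif(1, -1, 1), rho = runif(1, -1, 1))
    small_cfg <- task_config(n_trials = 5)
    tt <- simulate_subject(p, small_cfg, seed = 500 + rep)
    expect_equal(negative_log_likelihood(p, tt, small_cfg, engine = "cpp"),
                 negative_log_likelihood(p, tt, small_cfg, engine = "r"),
                 tolerance = 1e-10)
  }
})

test_that("missed trials are exact no-ops for the likelihood", {
  p <- agent_params(alpha = 0.5, beta = 4, lam = 0.3, w_low = 0.2,
                    w_high = 0.7, pi = 0.3, rho = 0.1)
  rows <- list(
    tr("pairA", 1, "dark_blue", "green", "green", 2.0, 6.0),
    tr("pairB", 5, "pink", "orange", NA, 3.0, 1.0),
    tr("pairA", 1, "green", "dark_blue", "dark_blue", 9.0, 5.0),
    tr("pairB", 1, "orange", "pink", NA, 4.0, 4.0),
    tr("pairB", 5, "orange", "pink", "pink", 1.0, 8.0),
    tr("pairA", 5, "dark_blue", "green", NA, 2.0, 2.0),
    tr("pairA", 1, "dark_blue", "green", "dark_blue", 7.0, 1.0),
    tr("pairB", 1, "pink", "orange", "orange", 6.0, 3.0),
    tr("pairA", 5, "green", "dark_blue", "green", 2.0, 9.0),
    tr("pairB", 1, "orange", "pink", NA, 5.0, 5.0))
  with_missed <- make_trials(rows)
  without <- make_trials(rows[!vapply(rows, function(r) is.na(r$choice),
                                      logical(1))])
  expect_equal(negative_log_likelihood(p, with_missed, cfg),
               negative_log_likelihood(p, without, cfg), tolerance = 1e-12)
})

test_that("likelihood rejects corrupt data", {
  tt <- make_trials(list(tr("pairA", 1, "dark_blue", "green", "green",
                            2.0, 6.0)))
  p <- agent_params()
  bad <- tt; bad$treasure <- NA_integer_
  expect_error(negative_log_likelihood(p, bad, cfg),
               class = "metacontrolr_data_error")
  bad <- tt; bad$option_left <- "millennium_falcon"
  expect_error(negative_log_likelihood(p, bad, cfg),
               class = "metacontrolr_data_error")
  bad <- tt; bad$choice <- "orange"   # not in the shown pair
  expect_error(negative_log_likelihood(p, bad, cfg),
               class = "metacontrolr_data_error")
})

test_that("parameter transform round-trips on the open box", {
  set.seed(77)
  for (i in 1:20) {
    p <- agent_params(alpha = runif(1, .01, .99), beta = runif(1, .05, 19),
                      lam = runif(1, .01, .99), w_low = runif(1, .01, .99),
                      w_high = runif(1, .01, .99), pi = runif(1, -4, 4),
                      rho = runif(1, -4, 4))
    back <- metacontrolr:::untransform_params(
      metacontrolr:::transform_params(p))
    expect_equal(unclass(back), unclass(p), tolerance = 1e-12)
  }
})

test_that("the fit is never beaten by the generating parameters", {
  for (s in 1:3) {
    p <- agent_params(alpha = 0.4, beta = 5, lam = 0.5,
                      w_low = c(.2, .5, .8)[s], w_high = c(.8, .5, .2)[s],
                      pi = 0.2, rho = -0.1)
    tt <- simulate_subject(p, cfg, seed = 600 + s)
    f <- fit_subject(tt, cfg, n_restarts = 8, seed = 700 + s)
    expect_lte(f$nll, negative_log_likelihood(p, tt, cfg) + 1e-6)
    expect_true(f$converged)
    expect_identical(f$n_trials_used, 200L)
  }
})

test_that("fitting random choosers lands near the flat-policy bound", {
  # generating beta = 0 gives uniform choices; MLE can only undercut
  # T*ln2 by the finite-sample overfitting gain of the free parameters
  # (about chi-squared(df)/2 nats), never exceed it
  tt <- simulate_subject(agent_params(beta = 0), cfg, seed = 31)
  f <- fit_subject(tt, cfg, n_restarts = 10, seed = 32)
  expect_lte(f$nll, 200 * log(2) + 1e-9)
  expect_gt(f$nll, 200 * log(2) - 12)
})

test_that("metacontrol score is the stake difference of the fitted weights", {
  f <- structure(list(params_hat = agent_params(w_low = 0.5, w_high = 0.8),
                      w_identified = c(low = TRUE, high = TRUE)),
                 class = "fit_result")
  expect_equal(metacontrol_score(f), 0.3)
  f$params_hat <- agent_params(w_low = 0.4, w_high = 0.4)
  expect_equal(metacontrol_score(f), 0)
  f$params_hat <- agent_params(w_low = 0.2, w_high = 0.9)
  expect_gt(metacontrol_score(f), 0)
  f$w_identified <- c(low = TRUE, high = FALSE)
  expect_true(is.na(metacontrol_score(f)))
})

test_that("a session without high stakes flags w_high as unidentified", {
  cfg0 <- task_config(n_trials = 60, stake_prob = 0)
  tt <- simulate_subject(agent_params(alpha = .4, beta = 5, w_low = .7,
                                      w_high = .7), cfg0, seed = 8)
  f <- fit_subject(tt, cfg0, n_restarts = 5, seed = 9)
  expect_false(f$w_identified[["high"]])
  expect_true(is.na(f$metacontrol))
})

test_that("fits of stake-indifferent agents show no metacontrol bias", {
  # agents generated with w_high = w_low exactly
  spec <- cohort_spec(n_subjects = 20, metacontrol_sd = 0)
  coh <- generate_cohort(spec, seed = 21)
  expect_true(all(coh$metacontrol == 0))
  tabs <- simulate_cohort_behavior(coh, cfg, seed = 22)
  meta_hat <- vapply(seq_len(20), function(i)
    fit_subject(tabs[[i]], cfg, n_restarts = 10, seed = 800 + i)$metacontrol,
    numeric(1))
  se <- sd(meta_hat) / sqrt(length(meta_hat))
  expect_lt(abs(mean(meta_hat)), 2 * se + 1e-8)
})

test_that("weight recovery improves with session length", {
  n_sub <- 24
  coh <- generate_cohort(cohort_spec(n_subjects = n_sub), seed = 51)
  rec <- function(n_trials, seed0) {
    cfg_n <- task_config(n_trials = n_trials)
    tabs <- simulate_cohort_behavior(coh, cfg_n, seed = seed0)
    w_hat <- vapply(seq_len(n_sub), function(i)
      fit_subject(tabs[[i]], cfg_n, n_restarts = 10,
                  seed = seed0 + i)$params_hat$w_low, numeric(1))
    cor(coh$w_low, w_hat)
  }
  expect_gt(rec(200, 5000), rec(50, 6000))
})
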