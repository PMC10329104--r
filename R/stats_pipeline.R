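new_stat_result <- function(estimate, ci, statistic, df, p, d,
                            method = "") {
  structure(list(estimate = estimate, ci_low = ci[1], ci_high = ci[2],
                 statistic = statistic, df = df, p = min(max(p, 0), 1),
                 effect_size_d = d, method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  p_str <- if (x$p < 1e-15) "p < 1e-15" else
    if (x$p < 0.001) "p < .001" else sprintf("p = %.3f", x$p)
  cat(sprintf("%s: estimate = %.4f, 95%% CI [%.4f, %.4f], t(%.2f) = %.3f, %s",
              x$method, x$estimate, x$ci_low, x$ci_high, x$df, x$statistic,
              p_str))
  if (!is.na(x$effect_size_d)) cat(sprintf(", d = %.3f", x$effect_size_d))
  cat("\n")
  invisible(x)
}

#' Pearson correlation test with Fisher-z interval
#'
#' Pearson r with a Fisher-z 95% confidence interval and the usual
#' `t = r * sqrt((n - 2) / (1 - r^2))` two-sided test of zero
#' correlation.
#'
#' @param x,y equal-length numeric vectors, n >= 4, nonzero variance.
#' @return a `stat_result` (estimate = r, df = n - 2).
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4)
    mc_error("x and y must have equal length >= 4", "invalid_input")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    mc_error("inputs must be finite", "invalid_input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    mc_error("zero variance input", "degenerate")
  n <- length(x)
  r <- stats::cor(x, y)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  hw <- stats::qnorm(0.975) / sqrt(n - 3)
  ci <- tanh(c(z - hw, z + hw))
  if (abs(r) >= 1) {
    tt <- sign(r) * Inf; p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  new_stat_result(r, ci, tt, n - 2, p, NA_real_, "Pearson correlation")
}

#' One-sample t test
#'
#' @param x numeric vector, n >= 2.
#' @param mu0 null mean (default 0).
#' @return a `stat_result`; `effect_size_d` is Cohen's d
#'   `(mean - mu0) / sd`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  n <- length(x)
  if (n < 2) mc_error("need n >= 2", "invalid_input")
  s <- stats::sd(x)
  if (s == 0) mc_error("zero variance input", "degenerate")
  m <- mean(x)
  se <- s / sqrt(n)
  tt <- (m - mu0) / se
  hw <- stats::qt(0.975, n - 1) * se
  new_stat_result(m - mu0, c(m - mu0 - hw, m - mu0 + hw), tt, n - 1,
                  2 * stats::pt(-abs(tt), n - 1), (m - mu0) / s,
                  "one-sample t")
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch–Satterthwaite degrees of freedom;
#' Cohen's d uses the average-variance standardizer
#' `sqrt((s1^2 + s2^2) / 2)`.
#'
#' @param x1,x2 numeric vectors, n >= 2 each.
#' @return a `stat_result` (estimate = mean difference, fractional df).
#' @export
welch_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) mc_error("need n >= 2 per group", "invalid_input")
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  if (v1 + v2 == 0) mc_error("zero variance in both groups", "degenerate")
  se2 <- v1 / n1 + v2 / n2
  tt <- (mean(x1) - mean(x2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  est <- mean(x1) - mean(x2)
  hw <- stats::qt(0.975, df) * sqrt(se2)
  d <- est / sqrt((v1 + v2) / 2)
  new_stat_result(est, c(est - hw, est + hw), tt, df,
                  2 * stats::pt(-abs(tt), df), d, "Welch two-sample t")
}

#' Bonferroni per-test threshold
#'
#' @param alpha_family family-wise error rate in (0, 1).
#' @param m number of tests (>= 1).
#' @return per-test alpha `alpha_family / m`.
#' @export
bonferroni_threshold <- function(alpha_family, m) {
  if (m < 1 || m != round(m))
    mc_error("m must be a positive integer", "invalid_parameter")
  if (alpha_family <= 0 || alpha_family >= 1)
    mc_error("alpha_family must lie in (0, 1)", "invalid_parameter")
  alpha_family / m
}

# Gauss hypergeometric 2F1(a, b; c; x) by direct series; converges fast
# here because c grows with n while x stays below 1.
hyp2f1 <- function(a, b, cc, x) {
  term <- 1; s <- 1
  for (k in 0:5000) {
    term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * x
    s <- s + term
    if (abs(term) < 1e-16 * abs(s)) break
  }
  s
}

#' Density of the sample correlation coefficient
#'
#' Exact sampling density of Pearson r from a bivariate normal sample of
#' size `n` with population correlation `rho` (Hotelling's form with a
#' Gauss hypergeometric factor).
#'
#' @param r evaluation points in (-1, 1).
#' @param rho population correlation.
#' @param n sample size (>= 4).
#' @return density values.
#' @export
dcorr <- function(r, rho, n) {
  lc <- log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-rho^2) -
    0.5 * log(2 * pi) - lgamma(n - 0.5)
  lf <- lc + ((n - 4) / 2) * log1p(-r^2) - (n - 1.5) * log1p(-rho * r)
  exp(lf) * vapply(r, function(ri)
    hyp2f1(0.5, 0.5, n - 0.5, (1 + rho * ri) / 2), numeric(1))
}

# Power of the t test of rho = 0 at sample size n under true rho.
correlation_power <- function(n, rho, alpha = 0.05,
                              tails = c("two", "one")) {
  tails <- match.arg(tails)
  a <- if (tails == "one") alpha else alpha / 2
  tc <- stats::qt(1 - a, n - 2)
  rc <- tc / sqrt(n - 2 + tc^2)
  up <- stats::integrate(dcorr, rc, 1, rho = abs(rho), n = n,
                         rel.tol = 1e-9)$value
  if (tails == "one") return(up)
  lo <- stats::integrate(dcorr, -1, -rc, rho = abs(rho), n = n,
                         rel.tol = 1e-9)$value
  up + lo
}

#' Sample size for a Pearson correlation test
#'
#' Smallest N at which the test of zero correlation reaches the requested
#' power under a bivariate-normal alternative with true correlation
#' `rho1`. The default `"exact"` method integrates the exact sampling
#' distribution of r above the t-based critical value; `"fisher"` uses
#' the Fisher-z normal approximation (typically 1–2 subjects more
#' conservative); `"mc"` estimates power by Monte Carlo simulation of
#' bivariate-normal samples.
#'
#' @param rho1 true correlation under the alternative, 0 < |rho1| < 1.
#' @param alpha test level in (0, 1) (default 0.05).
#' @param power requested power in (alpha, 1) (default 0.90).
#' @param tails `"one"` or `"two"` (default `"two"`).
#' @param method `"exact"`, `"fisher"`, or `"mc"`.
#' @param mc_reps Monte Carlo replicates per candidate N (method
#'   `"mc"` only; default 1e5).
#' @param seed seed for the Monte Carlo method.
#' @param n_max search cap.
#' @return smallest integer N with power >= `power`.
#' @export
correlation_sample_size <- function(rho1, alpha = 0.05, power = 0.90,
                                    tails = c("two", "one"),
                                    method = c("exact", "fisher", "mc"),
                                    mc_reps = 1e5, seed = 1L,
                                    n_max = 100000L) {
  tails <- match.arg(tails)
  method <- match.arg(method)
  if (abs(rho1) <= 0 || abs(rho1) >= 1)
    mc_error("rho1 must satisfy 0 < |rho1| < 1", "invalid_parameter")
  if (alpha <= 0 || alpha >= 1 || power <= alpha || power >= 1)
    mc_error("need 0 < alpha < power < 1", "invalid_parameter")
  pw <- switch(method,
    exact = function(n) correlation_power(n, rho1, alpha, tails),
    fisher = function(n) {
      a <- if (tails == "one") alpha else alpha / 2
      stats::pnorm(sqrt(n - 3) * atanh(abs(rho1)) - stats::qnorm(1 - a))
    },
    mc = function(n) mc_correlation_power(n, rho1, alpha, tails,
                                          mc_reps, seed))
  # bracket with doubling, then bisect to the smallest attaining N
  lo <- 5L
  if (pw(lo) >= power) return(lo)
  hi <- lo
  repeat {
    hi <- min(hi * 2L, n_max)
    if (pw(hi) >= power) break
    if (hi >= n_max) mc_error("requested power unattainable within n_max",
                              "invalid_parameter")
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= power) hi <- mid else lo <- mid
  }
  hi
}

#' Monte Carlo power of the correlation test
#'
#' Independent simulation oracle for [correlation_sample_size()]:
#' draws `reps` bivariate-normal samples of size `n`, computes Pearson r
#' for each, and reports the fraction exceeding the critical value.
#'
#' @param n sample size.
#' @param rho true correlation.
#' @param alpha test level.
#' @param tails `"one"` or `"two"`.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @return estimated power.
#' @export
mc_correlation_power <- function(n, rho, alpha = 0.05,
                                 tails = c("two", "one"),
                                 reps = 1e5, seed = 1L) {
  tails <- match.arg(tails)
  local_rng(seed)
  a <- if (tails == "one") alpha else alpha / 2
  tc <- stats::qt(1 - a, n - 2)
  rc <- tc / sqrt(n - 2 + tc^2)
  hits <- 0
  chunk <- 20000L
  done <- 0
  while (done < reps) {
    m <- min(chunk, reps - done)
    x <- matrix(stats::rnorm(n * m), n, m)
    y <- rho * x + sqrt(1 - rho^2) * matrix(stats::rnorm(n * m), n, m)
    xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
    r <- colSums(xc * yc) / sqrt(colSums(xc^2) * colSums(yc^2))
    hits <- hits + if (tails == "one") sum(r > rc) else sum(abs(r) > rc)
    done <- done + m
  }
  hits / reps
}

#' Percentile-bootstrap mediation analysis
#'
#' Simple three-variable mediation by ordinary least squares: path a
#' (`x -> m`), paths b and c' from the joint regression `y ~ x + m`, and
#' total path c (`y ~ x`). The indirect effect is `a * b`, with a
#' percentile bootstrap interval over paired case resamples. For OLS on
#' one sample the decomposition `c = c' + a * b` holds to machine
#' precision.
#'
#' @param x,m,y equal-length numeric vectors, n >= 10.
#' @param n_boot bootstrap resamples (default 5000).
#' @param seed integer seed (mandatory for reproducibility).
#' @param conf confidence level (default 0.95).
#' @return an object of class `mediation_result`: `path_a`, `path_b`,
#'   `path_c_total`, `path_c_prime_direct`, `indirect`, `indirect_ci`,
#'   `n_boot`, `seed`.
#' @export
mediation <- function(x, m, y, n_boot = 5000L, seed = 1L, conf = 0.95) {
  n <- length(x)
  if (length(m) != n || length(y) != n || n < 10)
    mc_error("x, m, y must have equal length >= 10", "invalid_input")
  paths <- tryCatch(mediation_paths(x, m, y),
                    error = function(e) mc_error(
                      "collinear or degenerate inputs", "degenerate"))
  local_rng(seed)
  boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    pb <- tryCatch(mediation_paths(x[idx], m[idx], y[idx]),
                   error = function(e) NULL)
    boot[b] <- if (is.null(pb)) NA_real_ else pb$a * pb$b
  }
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(path_a = paths$a, path_b = paths$b,
                 path_c_total = paths$c,
                 path_c_prime_direct = paths$c_prime,
                 indirect = paths$a * paths$b,
                 indirect_ci = qs, n_boot = n_boot, seed = seed),
            class = "mediation_result")
}

# OLS paths in closed form (with intercepts).
mediation_paths <- function(x, m, y) {
  vx <- stats::var(x)
  if (vx == 0) stop("zero variance")
  a <- as.numeric(stats::cov(x, m) / vx)
  c_tot <- as.numeric(stats::cov(x, y) / vx)
  S <- stats::cov(cbind(x, m))
  if (abs(det(S)) < 1e-14 * prod(diag(S) + 1e-300)) stop("collinear")
  bc <- as.numeric(solve(S, c(stats::cov(x, y), stats::cov(m, y))))
  list(a = a, b = bc[2], c = c_tot, c_prime = bc[1])
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(paste0("mediation: a = %.4f, b = %.4f, c = %.4f, ",
                     "c' = %.4f\nindirect a*b = %.4f, ",
                     "95%% bootstrap CI [%.4f, %.4f] (%d resamples)\n"),
              x$path_a, x$path_b, x$path_c_total, x$path_c_prime_direct,
              x$indirect, x$indirect_ci[1], x$indirect_ci[2], x$n_boot))
  invisible(x)
}

#' Correlation battery over a cohort table
#'
#' Runs [pearson_test()] for each requested variable pair and flags
#' which survive the Bonferroni threshold.
#'
#' @param data a data frame.
#' @param pairs two-column character matrix (or data frame) of variable
#'   names to correlate.
#' @param alpha_family family-wise alpha (default 0.05).
#' @param m_tests Bonferroni divisor; defaults to the number of pairs.
#' @return long-format `data.frame`: var1, var2, r, ci_low, ci_high,
#'   statistic, df, p, p_threshold, significant.
#' @export
correlation_battery <- function(data, pairs, alpha_family = 0.05,
                                m_tests = nrow(pairs)) {
  pairs <- as.matrix(pairs)
  thr <- bonferroni_threshold(alpha_family, m_tests)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    v1 <- pairs[i, 1]; v2 <- pairs[i, 2]
    st <- pearson_test(data[[v1]], data[[v2]])
    data.frame(var1 = v1, var2 = v2, r = st$estimate,
               ci_low = st$ci_low, ci_high = st$ci_high,
               statistic = st$statistic, df = st$df, p = st$p,
               p_threshold = thr, significant = st$p < thr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
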