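# Poisson chance predictor, its sensitivity, the two-sided exact binomial
# p-value, and the cohort median-improvement test.

#' Poisson rate of the chance predictor
#'
#' A chance predictor that spends proportion `rho_w` of its time in warning,
#' raising alarms as a Poisson process with warning windows of `tau_w`
#' seconds, has rate `lambda_w = -ln(1 - rho_w) / tau_w` (nonnegative; the
#' sign convention follows lambda >= 0).
#'
#' @param rho_w proportion of time in warning, `0 <= rho_w < 1`.
#' @param tau_w warning (SPH + SOP) horizon in seconds.
#' @return Poisson rate per second.
#' @export
poisson_rate <- function(rho_w, tau_w) {
  if (tau_w <= 0) stop("poisson_rate: tau_w must be positive", call. = FALSE)
  if (rho_w < 0 || rho_w >= 1) {
    stop("poisson_rate: need 0 <= rho_w < 1 (rho_w = 1 diverges)",
         call. = FALSE)
  }
  -log(1 - rho_w) / tau_w
}

#' Chance model for significance testing
#'
#' @param tau_w SPH + SOP horizon, seconds.
#' @param tau_w0 detection interval, seconds (`0 <= tau_w0 <= tau_w`):
#'   a short grace period distinguishing detection from prediction.
#' @param rho_w proportion of time in warning.
#' @return object of class `chance_model` with the derived `lambda_w` and
#'   `s_nc`.
#' @param snc_form `"printed"` (published formula) or `"limit"` (its
#'   small-rate limit).
#' @export
chance_model <- function(tau_w, rho_w, tau_w0 = 0,
                         snc_form = c("printed", "limit")) {
  if (!(tau_w >= tau_w0 && tau_w0 >= 0)) {
    stop("chance_model: need tau_w >= tau_w0 >= 0", call. = FALSE)
  }
  snc_form <- match.arg(snc_form)
  lambda_w <- poisson_rate(rho_w, tau_w)
  m <- structure(list(tau_w = tau_w, tau_w0 = tau_w0, rho_w = rho_w,
                      lambda_w = lambda_w, s_nc = NA_real_,
                      snc_form = snc_form),
                 class = "chance_model")
  m$s_nc <- chance_sensitivity(m)
  m
}

#' Sensitivity of the Poisson chance predictor
#'
#' The published closed form
#' `S_nc = 1 - exp(-lambda_w tau_w + (1 - exp(-lambda_w tau_w0)))`,
#' clamped to \[0, 1\]. With `snc_form = "limit"` the small-rate limit
#' `1 - exp(-lambda_w (tau_w - tau_w0))` is used instead (the two agree at
#' `tau_w0 = 0` and to first order in `lambda_w`).
#'
#' @param model a [chance_model()], or a list with `lambda_w`, `tau_w`,
#'   `tau_w0` and optionally `snc_form`.
#' @return chance sensitivity in \[0, 1\].
#' @export
chance_sensitivity <- function(model) {
  form <- if (is.null(model$snc_form)) "printed" else model$snc_form
  s <- if (form == "limit") {
    1 - exp(-model$lambda_w * (model$tau_w - model$tau_w0))
  } else {
    1 - exp(-model$lambda_w * model$tau_w +
              (1 - exp(-model$lambda_w * model$tau_w0)))
  }
  min(1, max(0, s))
}

#' Binomial distribution function
#'
#' `F_B(k; N, p) = P(X <= k)` for `X ~ Binomial(N, p)`, with `F_B(k < 0) = 0`
#' and `F_B(k >= N) = 1`.
#'
#' @param k integer (may be negative or exceed `N`).
#' @param N number of trials.
#' @param p success probability.
#' @return cumulative probability.
#' @export
binom_cdf <- function(k, N, p) {
  stopifnot(N >= 0, p >= 0, p <= 1)
  stats::pbinom(floor(k), size = N, prob = p)
}

#' Two-sided exact binomial p-value against the chance predictor
#'
#' Probability that a chance predictor with sensitivity `s_nc` shows a
#' deviation `|X/N - s_nc|` at least as large as the observed `|n/N - s_nc|`.
#' Implements the two-branch closed form with reflection points
#' `k_f = floor(2 N s_nc - n)` and `k_c = ceiling(2 N s_nc - n)`:
#' for `n/N >= s_nc`, `p = [1 - F_B(n-1)] + F_B(k_f)`; otherwise
#' `p = [1 - F_B(k_c - 1)] + F_B(n)`. At zero deviation the two tails
#' overlap and the raw value exceeds 1; the result is clamped to \[0, 1\].
#'
#' @param n seizures identified by the algorithm.
#' @param N total seizures.
#' @param s_nc chance sensitivity.
#' @return two-sided p-value in \[0, 1\].
#' @export
two_sided_pvalue <- function(n, N, s_nc) {
  stopifnot(N >= 1, n >= 0, n <= N, s_nc >= 0, s_nc <= 1)
  # upper tails via lower.tail = FALSE: 1 - F_B(k) computed directly keeps
  # relative precision when the tail is tiny
  if (n / N >= s_nc) {
    kf <- floor(2 * N * s_nc - n)
    p <- stats::pbinom(n - 1, N, s_nc, lower.tail = FALSE) +
      binom_cdf(kf, N, s_nc)
  } else {
    kc <- ceiling(2 * N * s_nc - n)
    p <- stats::pbinom(kc - 1, N, s_nc, lower.tail = FALSE) +
      binom_cdf(n, N, s_nc)
  }
  min(1, max(0, p))
}

#' Exact cohort median-improvement test
#'
#' Tests H0: median(S_n - S_nc) = 0 against the two-sided alternative over a
#' cohort of patients, by the exact sign test on the paired differences
#' (zero differences dropped); optionally by the Wilcoxon signed-rank test.
#'
#' @param pairs two-column matrix or data frame: observed sensitivity `S_n`
#'   and chance sensitivity `S_nc` per patient.
#' @param method `"sign"` (default, exact) or `"wilcoxon"`.
#' @return two-sided p-value.
#' @export
median_improvement_test <- function(pairs, method = c("sign", "wilcoxon")) {
  method <- match.arg(method)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 1L) {
    stop("median_improvement_test: need at least one pair", call. = FALSE)
  }
  d <- pairs[, 1L] - pairs[, 2L]
  d <- d[d != 0]
  if (length(d) == 0L) return(1)
  if (method == "wilcoxon") {
    return(stats::wilcox.test(d, mu = 0, exact = TRUE)$p.value)
  }
  stats::binom.test(sum(d > 0), length(d), p = 0.5,
                    alternative = "two.sided")$p.value
}

#' Simulate the Poisson chance predictor
#'
#' Draws Poisson alarms at rate `lambda_w` over a horizon and measures the
#' fraction of planted seizures preceded by an alarm within `tau_w` seconds
#' -- the empirical counterpart of [chance_sensitivity()] at `tau_w0 = 0`.
#'
#' @param lambda_w alarm rate per second.
#' @param tau_w warning horizon, seconds.
#' @param n_seizures number of planted seizures.
#' @param spacing_s spacing between seizures, seconds; must exceed `tau_w`
#'   so trials are independent.
#' @return empirical sensitivity.
#' @export
simulate_chance_predictor <- function(lambda_w, tau_w, n_seizures = 1000,
                                      spacing_s = 2 * tau_w) {
  stopifnot(spacing_s >= tau_w)
  horizon <- n_seizures * spacing_s
  n_alarms <- stats::rpois(1L, lambda_w * horizon)
  alarms <- sort(stats::runif(n_alarms, 0, horizon))
  onsets <- spacing_s * seq_len(n_seizures)
  hit <- vapply(onsets, function(t) {
    any(alarms > t - tau_w & alarms <= t)
  }, logical(1))
  mean(hit)
}
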