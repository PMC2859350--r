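#' Coverage probability at a fixed boundary
#'
#' The coverage probability is the proportion of absolute paired differences
#' inside a pre-specified boundary kappa:
#' \deqn{p_\kappa = \Phi((\kappa - |\mu_D|)/\sigma_D) -
#'       \Phi((-\kappa - |\mu_D|)/\sigma_D).}
#' It is the inverse of the TDI: `cp_estimate(mu, sigma, kappa_p) = p`.
#'
#' @param mu_D mean difference.
#' @param sigma_D standard deviation of the difference (> 0).
#' @param kappa boundary (> 0, measurement units).
#' @return The probability \eqn{p_\kappa} in (0, 1).
#' @export
#' @examples
#' cp_estimate(2.174, sqrt(2 * 52.867), 17.29)  # ~0.90
cp_estimate <- function(mu_D, sigma_D, kappa) {
  stopifnot(is.finite(mu_D), is.finite(sigma_D), sigma_D > 0,
            is.finite(kappa), kappa > 0)
  mu <- abs(mu_D)
  pnorm((kappa - mu) / sigma_D) - pnorm((-kappa - mu) / sigma_D)
}

#' Lower confidence bound for the coverage probability
#'
#' Inverts the one-sided tolerance interval: given a fixed boundary kappa,
#' finds the largest proportion \eqn{p_\kappa} whose tolerance-interval
#' upper bound would equal kappa at confidence \eqn{1-\alpha}. The search is
#' a bisection on the proportion over (0, 1); at each candidate the
#' non-centrality \eqn{\Delta = \sqrt{N} z_{p_1}} is recomputed (with
#' \eqn{p_1} solved from the candidate through the probability-interval
#' link), and the candidate is raised while the observed studentised
#' statistic \eqn{\sqrt{N}(\kappa - |\hat\mu_D|)/\hat\sigma_D} exceeds the
#' non-central t quantile.
#'
#' This bound is dual to [tdi_upper_bound()]: evaluated at kappa equal to
#' the TI upper bound for proportion p, it returns p (to within twice the
#' search tolerance).
#'
#' @param params a [difference_params()] object.
#' @param kappa boundary (> 0).
#' @param policy a [ti_policy()].
#' @param settings a [search_settings()] object.
#' @return An object of class `"cp_result"` with `kappa`, `p_kappa_hat`
#'   (point estimate), `lower_bound`, `confidence`, `iterations`.
#' @export
cp_lower_bound <- function(params, kappa, policy = ti_policy(),
                           settings = search_settings()) {
  stopifnot(inherits(params, "difference_params"),
            is.finite(kappa), kappa > 0,
            params$sigma_D > 0, params$N >= 2, params$nu >= 1)
  tol <- settings$tol
  mu <- abs(params$mu_D)
  sig <- params$sigma_D
  N <- params$N
  nu <- params$nu
  cf <- policy$confidence
  t_obs <- sqrt(N) * (kappa - mu) / sig
  p_hat <- cp_estimate(mu, sig, kappa)
  # d(mid) = t_obs - t'_{cf; nu; Delta(mid)}; decreasing in mid
  dfun <- function(pk) {
    p1 <- as.numeric(solve_p1(mu / sig, pk, settings))
    t_obs - qt_noncentral(cf, nu, sqrt(N) * qnorm(p1), N = N)
  }
  low <- 0
  high <- 1
  mid <- NA_real_
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(settings$max_iter)) {
    mid <- (low + high) / 2
    d <- dfun(mid)
    iterations <- it
    if (abs(d) <= tol) { converged <- TRUE; break }
    if (d > 0) low <- mid + tol else high <- mid - tol
    if (high - low < tol) { converged <- TRUE; mid <- (low + high) / 2; break }
  }
  if (!converged) {
    stop(sprintf(
      "coverage-probability search did not converge in %d iterations (bracket [%.10g, %.10g])",
      settings$max_iter, low, high))
  }
  lb <- min(max(mid, 0), 1)
  structure(list(kappa = kappa, p_kappa_hat = p_hat, lower_bound = lb,
                 confidence = cf, iterations = iterations,
                 kind = params$kind), class = "cp_result")
}

#' @export
print.cp_result <- function(x, ...) {
  cat(sprintf("Coverage probability at boundary kappa = %.6g (%s)\n",
              x$kappa, x$kind))
  cat(sprintf("  estimate %.6g, one-sided %g%% lower bound %.6g\n",
              x$p_kappa_hat, 100 * x$confidence, x$lower_bound))
  invisible(x)
}

#' Hypothesis test on the coverage probability
#'
#' Tests \eqn{H_0: p_\kappa \le p_0} against \eqn{H_1: p_\kappa > p_0} at
#' level \eqn{\alpha}: H0 is rejected iff the lower confidence bound for
#' \eqn{p_\kappa} exceeds \eqn{p_0}. Dual to [tdi_hypothesis_test()]: with
#' \eqn{\kappa_0 = \kappa} and \eqn{p_0 = p} the two tests reach the same
#' decision.
#'
#' @param params a [difference_params()] object.
#' @param kappa boundary (> 0).
#' @param p0 required minimum proportion in (0, 1).
#' @param policy a [ti_policy()].
#' @param settings a [search_settings()] object.
#' @return A list of class `"cp_test"`.
#' @export
cp_hypothesis_test <- function(params, kappa, p0, policy = ti_policy(),
                               settings = search_settings()) {
  stopifnot(is.numeric(p0), length(p0) == 1L, p0 > 0, p0 < 1)
  res <- cp_lower_bound(params, kappa, policy, settings)
  reject <- res$lower_bound > p0
  structure(list(
    kappa = kappa, p0 = p0, alpha = 1 - policy$confidence,
    p_kappa_hat = res$p_kappa_hat, lower_bound = res$lower_bound,
    reject_H0 = reject,
    decision = if (reject) "reject H0" else "retain H0",
    conclusion = if (reject) {
      sprintf("boundary %.4g captures more than %.0f%% of absolute differences",
              kappa, 100 * p0)
    } else {
      sprintf("cannot conclude boundary %.4g captures at least %.0f%% of differences",
              kappa, 100 * p0)
    }
  ), class = "cp_test")
}

#' @export
print.cp_test <- function(x, ...) {
  cat(sprintf("Coverage-probability test: H0: p_kappa <= %.4g at kappa = %.4g\n",
              x$p0, x$kappa))
  cat(sprintf("  estimate %.4g, lower bound %.4g -> %s\n",
              x$p_kappa_hat, x$lower_bound, x$decision))
  cat(" ", x$conclusion, "\n")
  invisible(x)
}
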