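#' Tolerance-interval policy
#'
#' Bundles the confidence level and the residual degrees-of-freedom
#' convention used by the one-sided tolerance-interval bound.
#'
#' @param confidence one-sided confidence level \eqn{1-\alpha} in (0.5, 1).
#' @param df_convention `"interaction"`, `"no_interaction"`, `"fixed_only"`
#'   or `"satterthwaite"`; `NULL` lets [difference_params()] choose from the
#'   fitted model structure.
#' @return An object of class `"ti_policy"`.
#' @export
ti_policy <- function(confidence = 0.95, df_convention = NULL) {
  stopifnot(is.numeric(confidence), length(confidence) == 1L,
            confidence > 0.5, confidence < 1)
  if (!is.null(df_convention)) {
    df_convention <- match.arg(df_convention,
                               c("interaction", "no_interaction",
                                 "fixed_only", "satterthwaite"))
  }
  structure(list(confidence = confidence, df_convention = df_convention),
            class = "ti_policy")
}

#' Residual degrees of freedom for the tolerance interval
#'
#' Conventions for the degrees of freedom nu attached to the pooled error
#' variance of the paired difference, for n subjects and m replicates per
#' subject-by-device cell:
#' \itemize{
#' \item `"interaction"` (conservative, all effects consume df):
#'   \eqn{\nu = 2n(m-1)};
#' \item `"no_interaction"`: \eqn{\nu = 2nm - (n + m - 1)};
#' \item `"fixed_only"` (random effects consume no df):
#'   \eqn{\nu = 2nm - 2};
#' \item `"satterthwaite"`: Welch-style effective df for the combination of
#'   the two device-specific error variances (requires a fit with per-device
#'   error variances).
#' }
#'
#' @param n number of subjects (>= 2).
#' @param m replicates per subject-by-device cell (>= 1).
#' @param convention one of the labels above.
#' @param fit a `"mixed_model_fit"`, required for `"satterthwaite"`.
#' @return nu (scalar).
#' @export
#' @examples
#' residual_df(384, 2, "interaction")     # 768
#' residual_df(384, 2, "no_interaction")  # 1151
#' residual_df(384, 2, "fixed_only")      # 1534
residual_df <- function(n, m,
                        convention = c("no_interaction", "interaction",
                                       "fixed_only", "satterthwaite"),
                        fit = NULL) {
  convention <- match.arg(convention)
  stopifnot(n >= 2, m >= 1)
  switch(convention,
    interaction = {
      if (m < 2) stop("`interaction` convention needs m >= 2")
      2 * n * (m - 1)
    },
    no_interaction = 2 * n * m - (n + m - 1),
    fixed_only = 2 * n * m - 2,
    satterthwaite = {
      if (is.null(fit) || is.null(fit$sigma2_e_dev)) {
        stop("`satterthwaite` needs a fit with device-specific error ",
             "variances")
      }
      v <- unlist(fit$sigma2_e_dev)
      d <- unlist(fit$err_df_dev)
      sum(v)^2 / sum(v^2 / d)
    })
}

# Non-central t quantile with a large-noncentrality fallback.
# R's qt(..., ncp) warns about final precision (~1e-8, harmless) and can
# fail for very large ncp; beyond `delta_max` (or on a non-finite result)
# the classical closed-form one-sided normal tolerance factor approximation
# k = (z_p + sqrt(z_p^2 - a b)) / a, a = 1 - z_cf^2/(2 nu),
# b = z_p^2 - z_cf^2/N is used (ncp = sqrt(N) z_p, quantile = sqrt(N) k).
qt_noncentral <- function(cf, nu, ncp, N = NULL, delta_max = 5000) {
  stopifnot(is.finite(nu), nu >= 1, is.finite(ncp))
  if (abs(ncp) <= delta_max) {
    q <- suppressWarnings(qt(cf, df = nu, ncp = ncp))
    if (is.finite(q)) return(q)
  }
  if (is.null(N)) stop("non-central t quantile failed at ncp = ", ncp,
                       "; supply N for the large-ncp tolerance-factor ",
                       "fallback")
  zp <- ncp / sqrt(N)
  zcf <- qnorm(cf)
  a <- 1 - zcf^2 / (2 * nu)
  b <- zp^2 - zcf^2 / N
  disc <- zp^2 - a * b
  if (a <= 0 || disc < 0) stop("non-central t quantile failed at ncp = ",
                               ncp, "; nu = ", nu)
  sqrt(N) * (zp + sqrt(disc)) / a
}

#' One-sided tolerance-interval upper bound for a TDI estimate
#'
#' The studentised TDI statistic follows a non-central Student-t
#' distribution with non-centrality \eqn{\Delta = \sqrt{N} z_{p_1}}, giving
#' the exact one-sided upper tolerance bound for at least a \eqn{p_1}
#' proportion of the difference population:
#' \deqn{UB = |\hat\mu_D| + \hat\sigma_D\,
#'   t'_{1-\alpha;\,\nu;\,\sqrt{N} z_{p_1}} / \sqrt{N}.}
#' For `kind = "intra"` the mean term is zero and \eqn{p_1 = (1+p)/2}; for
#' `kind = "inter"` \eqn{p_1} follows the estimate's mode (`"strict"` from
#' the inter ratio, `"paper_compat"` from the total ratio).
#'
#' @param params a [difference_params()] object (carries mu_D, sigma_D, N
#'   and nu).
#' @param p target proportion in (0, 1).
#' @param policy a [ti_policy()]; its `df_convention`, when set, overrides
#'   the one recorded in `params` (nu is recomputed from the printed
#'   formulas, so `"satterthwaite"` cannot be requested here without a fit).
#' @param settings a [search_settings()] object.
#' @param mode inter-method mode, see [tdi_inter()].
#' @param total_params for inter paper_compat mode, see [tdi_inter()].
#' @return A `"tdi_result"` with both `kappa_hat` and `upper_bound` filled.
#' @export
#' @examples
#' fitlike <- structure(list(mu_D = 2.174, sigma_D = sqrt(2 * 52.867),
#'                           kind = "total", N = 1536, nu = 1151,
#'                           df_convention = "no_interaction"),
#'                      class = "difference_params")
#' tdi_upper_bound(fitlike, 0.90)
tdi_upper_bound <- function(params, p, policy = ti_policy(),
                            settings = search_settings(),
                            mode = c("strict", "paper_compat"),
                            total_params = NULL) {
  stopifnot(inherits(params, "difference_params"),
            is.finite(params$sigma_D), params$sigma_D > 0,
            params$N >= 2, params$nu >= 1, p > 0, p < 1)
  mode <- match.arg(mode)
  nu <- params$nu
  df_convention <- params$df_convention
  if (!is.null(policy$df_convention) &&
      !identical(policy$df_convention, df_convention)) {
    df_convention <- policy$df_convention
    if (is.null(params$n) || is.null(params$m)) {
      stop("cannot recompute nu: difference parameters lack n and m")
    }
    nu <- residual_df(params$n, params$m, df_convention)
  }
  if (params$kind == "intra") {
    est <- new_tdi_result(p = p, p1 = (1 + p) / 2,
                          kappa_hat = params$sigma_D * qnorm((1 + p) / 2),
                          kind = "intra", mode = "strict")
  } else if (params$kind == "inter") {
    est <- tdi_inter(params$mu_D, params$sigma_D, p, mode = mode,
                     total_params = total_params, settings = settings)
  } else {
    est <- tdi_probability_interval(params$mu_D, params$sigma_D, p,
                                    settings = settings, kind = "total")
  }
  ncp <- sqrt(params$N) * qnorm(est$p1)
  tq <- qt_noncentral(policy$confidence, nu, ncp, N = params$N)
  ub <- abs(params$mu_D) * (params$kind != "intra") +
    params$sigma_D * tq / sqrt(params$N)
  new_tdi_result(p = p, p1 = est$p1, kappa_hat = est$kappa_hat,
                 kind = params$kind, mode = est$mode,
                 iterations = est$iterations,
                 upper_bound = ub, confidence = policy$confidence,
                 df_convention = df_convention, nu = nu, N = params$N)
}

#' Hypothesis test for a pre-specified agreement boundary
#'
#' Tests \eqn{H_0: \kappa_p \ge \kappa_0} (disagreement) against
#' \eqn{H_1: \kappa_p < \kappa_0} (agreement) at level \eqn{\alpha}:
#' H0 is rejected iff the one-sided tolerance-interval upper bound falls
#' below \eqn{\kappa_0}. Rejecting H0 supports interchangeability of the
#' devices at boundary `kappa0`.
#'
#' @param x an [agreement_data()] object, a `"mixed_model_fit"`, or a
#'   [difference_params()] object.
#' @param kappa0 agreement boundary (> 0, measurement units).
#' @param p proportion of differences that must fall inside the boundary.
#' @param policy a [ti_policy()].
#' @param kind,mode,total_params,settings passed through to the bound, see
#'   [tdi_upper_bound()].
#' @return A list of class `"tdi_test"` with the bound, the decision and
#'   its polarity.
#' @export
tdi_hypothesis_test <- function(x, kappa0, p = 0.90, policy = ti_policy(),
                                kind = "total",
                                mode = c("strict", "paper_compat"),
                                total_params = NULL,
                                settings = search_settings()) {
  stopifnot(is.numeric(kappa0), length(kappa0) == 1L, kappa0 > 0)
  mode <- match.arg(mode)
  params <- resolve_difference_params(x, kind, policy)
  res <- tdi_upper_bound(params, p, policy, settings, mode = mode,
                         total_params = total_params)
  reject <- res$upper_bound < kappa0
  structure(list(
    kappa0 = kappa0, p = p, alpha = 1 - policy$confidence,
    kappa_hat = res$kappa_hat, upper_bound = res$upper_bound,
    kind = res$kind, df_convention = res$df_convention,
    reject_H0 = reject,
    decision = if (reject) "reject H0" else "retain H0",
    conclusion = if (reject) {
      sprintf("agreement: at least %.0f%% of absolute differences fall below %.4g",
              100 * p, kappa0)
    } else {
      sprintf("no demonstrated agreement at boundary %.4g (devices not interchangeable)",
              kappa0)
    }
  ), class = "tdi_test")
}

#' @export
print.tdi_test <- function(x, ...) {
  cat(sprintf("TDI agreement test (%s): H0: kappa_%.2g >= %.4g\n",
              x$kind, x$p, x$kappa0))
  cat(sprintf("  estimate %.4g, one-sided %g%% UB %.4g -> %s\n",
              x$kappa_hat, 100 * (1 - x$alpha), x$upper_bound, x$decision))
  cat(" ", x$conclusion, "\n")
  invisible(x)
}

# Accept raw data, a fit, or ready-made difference parameters.
resolve_difference_params <- function(x, kind, policy) {
  if (inherits(x, "difference_params")) return(x)
  if (inherits(x, "agreement_data")) {
    x <- fit_balanced_vc(x, include_interaction = FALSE)
  }
  if (!inherits(x, "mixed_model_fit")) {
    stop("expected agreement_data, mixed_model_fit or difference_params")
  }
  difference_params(x, kind, df_convention = policy$df_convention)
}
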