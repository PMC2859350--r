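# Closed-form maximum likelihood for the balanced no-interaction model.
# With compound-symmetry covariance and balanced data, GLS = OLS for the
# fixed effects, and the likelihood factorises over the between-subject and
# within-subject strata:
#   lambda1 = 2 m sigma2_alpha + sigma2_e  (subject-mean stratum, n terms)
#   sigma2_e                               (within, n(2m - 1) terms)
# giving lambda1_hat = SSB/n, sigma2_e_hat = SSW/(n(2m-1)) before the
# non-negativity constraint on sigma2_alpha.
ml_balanced <- function(data) {
  stopifnot(inherits(data, "agreement_data"), data$balanced)
  if (length(data$covariates)) stop("covariates unsupported in balanced ML")
  n <- data$n
  m <- data$m
  df <- data$data
  dev2 <- data$devices[2L]
  y <- df$value
  dev_means <- tapply(y, df$device, mean)
  beta_diff <- unname(dev_means[dev2] - dev_means[data$devices[1L]])
  fitted <- dev_means[df$device]
  r <- y - fitted
  r_subj <- tapply(r, df$subject, mean)
  ssb <- 2 * m * sum(r_subj^2)
  ssw <- sum((r - r_subj[df$subject])^2)
  lambda1 <- ssb / n
  sigma2_e <- ssw / (n * (2 * m - 1))
  truncated <- character(0L)
  if (lambda1 < sigma2_e) {
    # boundary solution sigma2_alpha = 0: single variance stratum
    sigma2_e <- (ssb + ssw) / (2 * n * m)
    sigma2_alpha <- 0
    truncated <- "sigma2_alpha"
  } else {
    sigma2_alpha <- (lambda1 - sigma2_e) / (2 * m)
  }
  list(beta_diff = beta_diff, intercept = mean(dev_means),
       sigma2_alpha = sigma2_alpha, sigma2_e = sigma2_e,
       n = n, m = m, ssb = ssb, ssw = ssw, truncated = truncated)
}

# Exact log-likelihood of the balanced no-interaction model at
# theta = (intercept, beta_diff, sigma2_alpha, sigma2_e); used for the
# observed-information covariance of the ML plug-in comparator.
ml_balanced_loglik <- function(theta, data) {
  mu0 <- theta[1L]; bd <- theta[2L]; s2a <- theta[3L]; s2e <- theta[4L]
  if (s2e <= 0 || s2a < 0) return(-Inf)
  df <- data$data
  n <- data$n
  m <- data$m
  lambda1 <- 2 * m * s2a + s2e
  mu_fit <- mu0 + ifelse(df$device == data$devices[2L], bd / 2, -bd / 2)
  r <- df$value - mu_fit
  r_subj <- tapply(r, df$subject, mean)
  ssb <- 2 * m * sum(r_subj^2)
  ssw <- sum((r - r_subj[df$subject])^2)
  -0.5 * (n * log(lambda1) + n * (2 * m - 1) * log(s2e) +
            ssb / lambda1 + ssw / s2e + 2 * n * m * log(2 * pi))
}

#' Lin's MSD-based TDI upper bound
#'
#' The comparator estimate \eqn{\hat\kappa_p = z_{(1+p)/2}\sqrt{\hat\mu_D^2
#' + \hat\sigma_D^2}} with moment (working-independence GEE) parameter
#' estimates, and a log-scale normal-theory upper bound
#' \eqn{UB = \exp(\log\hat\kappa + z_{1-\alpha}\, se_{\log})}. The standard
#' error of \eqn{\log\hat\kappa} comes from the delta method with a
#' numerically differentiated gradient and the moment estimators' asymptotic
#' covariance (independent mean-square strata); it is an approximate
#' variance, flagged as such in the result.
#'
#' @param data a balanced [agreement_data()] object.
#' @param p proportion in (0, 1).
#' @param confidence one-sided confidence level.
#' @param include_interaction estimate the subject-by-device interaction.
#' @return An object of class `"comparator_result"`.
#' @export
lin_tdi_ub <- function(data, p, confidence = 0.95,
                       include_interaction = FALSE) {
  stopifnot(inherits(data, "agreement_data"), p > 0, p < 1)
  if (!data$balanced) stop("Lin comparator requires balanced data")
  fit <- fit_balanced_vc(data, include_interaction = include_interaction)
  n <- fit$n
  m <- fit$m
  g2 <- if (is.na(fit$sigma2_gamma)) 0 else fit$sigma2_gamma
  theta <- c(mu_D = fit$beta_diff, sigma2_gamma = g2,
             sigma2_e = fit$sigma2_e)
  if (theta[3L] <= 0) stop("degenerate error variance")
  logkappa <- function(th) {
    sd2 <- 2 * th[2L] + 2 * th[3L]
    log(qnorm((1 + p) / 2) * sqrt(th[1L]^2 + sd2))
  }
  # asymptotic covariance of the moment estimators:
  #  var(mu_D)     = (2 sigma2_gamma + 2 sigma2_e/m)/n  (difference of device means)
  #  mean squares  ~ scaled chi-square: var(MS) = 2 MS^2/df
  if (include_interaction) {
    df_err <- 2 * n * (m - 1)
    df_int <- n - 1
    ms_err <- fit$sigma2_e
    ms_int <- m * g2 + ms_err
    v_e <- 2 * ms_err^2 / df_err
    v_g <- (2 * ms_int^2 / df_int + 2 * ms_err^2 / df_err) / m^2
    cov_ge <- -v_e / m
    Sigma <- rbind(c((2 * g2 + 2 * fit$sigma2_e / m) / n, 0, 0),
                   c(0, v_g, cov_ge),
                   c(0, cov_ge, v_e))
  } else {
    df_err <- 2 * n * m - n - 1
    v_e <- 2 * fit$sigma2_e^2 / df_err
    Sigma <- rbind(c(2 * fit$sigma2_e / (m * n), 0, 0),
                   c(0, 0, 0),
                   c(0, 0, v_e))
  }
  grad <- pracma::grad(logkappa, theta)
  se_log <- sqrt(drop(t(grad) %*% Sigma %*% grad))
  kappa <- exp(logkappa(theta))
  ub <- exp(log(kappa) + qnorm(confidence) * se_log)
  new_comparator_result("lin", kappa, ub, se_log, "GEE-moment", confidence, p)
}

#' Choudhary's maximum-likelihood plug-in TDI upper bound
#'
#' The TDI evaluated by the non-central chi-square definition at the
#' maximum-likelihood parameter estimates, with a log-scale delta-method
#' upper bound: the gradient of \eqn{\log\kappa} over the model parameters
#' is differentiated numerically and the covariance is the inverse observed
#' information of the ML fit (an approximate variance, flagged as such).
#' The point estimate is identical to the probability-interval TDI at the
#' same parameter values.
#'
#' @inheritParams lin_tdi_ub
#' @return An object of class `"comparator_result"`.
#' @export
choudhary_tdi_ub <- function(data, p, confidence = 0.95) {
  stopifnot(inherits(data, "agreement_data"), p > 0, p < 1)
  if (!data$balanced || length(data$covariates)) {
    fit <- fit_reml_general(data, covariate_names = data$covariates,
                            include_interaction = FALSE, method = "ML")
    ml <- list(beta_diff = fit$beta_diff, intercept = fit$intercept,
               sigma2_alpha = fit$sigma2_alpha, sigma2_e = fit$sigma2_e)
  } else {
    ml <- ml_balanced(data)
  }
  if (ml$sigma2_e <= 0) stop("degenerate error variance")
  sigma_D <- sqrt(2 * ml$sigma2_e)
  kappa <- tdi_ncx2_exact(ml$beta_diff, sigma_D, p)
  theta <- c(ml$intercept, ml$beta_diff, ml$sigma2_alpha, ml$sigma2_e)
  # keep the hessian's central differences off the sigma2_alpha >= 0 boundary
  if (theta[3L] <= 0) theta[3L] <- 1e-6 * ml$sigma2_e
  H <- pracma::hessian(function(th) ml_balanced_loglik(th, data), theta)
  Sigma <- tryCatch(solve(-H), error = function(e)
    stop("observed information is singular: ", conditionMessage(e)))
  logkappa <- function(th) log(tdi_ncx2_exact(th[2L], sqrt(2 * th[4L]), p))
  grad <- pracma::grad(logkappa, theta)
  se_log <- sqrt(drop(t(grad) %*% Sigma %*% grad))
  ub <- exp(log(kappa) + qnorm(confidence) * se_log)
  new_comparator_result("choudhary", kappa, ub, se_log, "MLE", confidence, p)
}

new_comparator_result <- function(method, kappa_hat, upper_bound, se_log,
                                  estimation, confidence, p) {
  kappa_hat <- unname(kappa_hat)
  upper_bound <- unname(upper_bound)
  se_log <- unname(se_log)
  stopifnot(upper_bound >= kappa_hat, se_log > 0)
  structure(list(method = method, p = p, kappa_hat = kappa_hat,
                 upper_bound = upper_bound, se_log = se_log,
                 estimation = estimation, confidence = confidence,
                 approx_variance = TRUE), class = "comparator_result")
}

#' @export
print.comparator_result <- function(x, ...) {
  cat(sprintf("%s TDI comparator (%s estimation), p = %.2f\n",
              x$method, x$estimation, x$p))
  cat(sprintf("  estimate %.6g, %g%% UB %.6g (se_log %.4g, delta-method, approximate)\n",
              x$kappa_hat, 100 * x$confidence, x$upper_bound, x$se_log))
  invisible(x)
}
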