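#' Closed-form variance components for balanced two-device data
#'
#' Balanced-ANOVA estimators of the mixed model
#' \deqn{y_{ijl} = \mu + \beta_j + \alpha_i + \gamma_{ij} + e_{ijl}}
#' with subject effects \eqn{\alpha_i \sim N(0, \sigma^2_\alpha)}, optional
#' subject-by-device interaction \eqn{\gamma_{ij} \sim N(0, \sigma^2_\gamma)}
#' and errors \eqn{e_{ijl} \sim N(0, \sigma^2_e)} (optionally device-specific).
#' For balanced data these moment estimators coincide with REML whenever the
#' raw solutions are non-negative; negative solutions are truncated to zero
#' and flagged.
#'
#' Mean-square construction: the error variance comes from within-cell
#' replicate scatter (pooled, or per device when
#' `equal_error_variances = FALSE`); when the interaction is omitted the
#' interaction stratum is pooled into the error (additive-model residual);
#' \eqn{\sigma^2_\gamma} is (interaction MS - error MS)/m; and
#' \eqn{\sigma^2_\alpha} is (subject MS - next stratum MS)/(2m).
#'
#' @param data a balanced, covariate-free [agreement_data()] object.
#' @param include_interaction estimate the subject-by-device interaction
#'   component (requires m >= 2).
#' @param equal_error_variances pool the error variance across devices
#'   (default) or estimate one per device (requires m >= 2).
#' @return An object of class `"mixed_model_fit"`.
#' @export
fit_balanced_vc <- function(data, include_interaction = TRUE,
                            equal_error_variances = TRUE) {
  stopifnot(inherits(data, "agreement_data"))
  if (!data$balanced) {
    stop("`fit_balanced_vc` requires balanced data; use `fit_reml_general`")
  }
  if (length(data$covariates)) {
    stop("`fit_balanced_vc` does not support covariates; use ",
         "`fit_reml_general`")
  }
  n <- data$n
  m <- data$m
  if (n < 2L) stop("at least 2 subjects are required for model fitting")
  if (m < 2L && include_interaction) {
    stop("m = 1: interaction and error are confounded; set ",
         "`include_interaction = FALSE`")
  }
  if (m < 2L && !equal_error_variances) {
    stop("m = 1: device-specific error variances are not estimable")
  }
  df <- data$data
  dev1 <- data$devices[1L]
  dev2 <- data$devices[2L]
  y <- df$value
  # cell means and the classical balanced two-way decomposition
  cell <- tapply(y, list(df$subject, df$device), mean)
  subj_means <- rowMeans(cell)
  dev_means <- colMeans(cell)
  grand <- mean(y)
  cell_of <- cell[cbind(df$subject, df$device)]
  sse_within <- sum((y - cell_of)^2)             # df = 2n(m-1)
  ss_int <- m * sum((cell - outer(subj_means, dev_means, "+") + grand)^2)
  df_int <- n - 1L                                # (n-1)(2-1)
  ms_subj <- 2 * m * sum((subj_means - grand)^2) / (n - 1L)

  truncated <- character(0L)
  if (equal_error_variances) {
    if (include_interaction) {
      df_err <- 2L * n * (m - 1L)
      ms_err <- sse_within / df_err
      ms_int <- ss_int / df_int
      sigma2_gamma <- (ms_int - ms_err) / m
      next_ms <- ms_int
    } else {
      # additive model: interaction stratum pooled into the residual
      df_err <- 2L * n * m - n - 1L
      ms_err <- (sse_within + ss_int) / df_err
      sigma2_gamma <- NA_real_
      next_ms <- ms_err
    }
    sigma2_e <- ms_err
    sigma2_e_dev <- NULL
    err_df_dev <- NULL
  } else {
    # per-device within-cell scatter
    sigma2_e_dev <- vapply(data$devices, function(d) {
      idx <- df$device == d
      sum((y[idx] - cell_of[idx])^2) / (n * (m - 1L))
    }, numeric(1L))
    err_df_dev <- rep(n * (m - 1L), 2L)
    names(err_df_dev) <- data$devices
    ms_err <- mean(sigma2_e_dev)
    if (include_interaction) {
      ms_int <- ss_int / df_int
      sigma2_gamma <- (ms_int - ms_err) / m
      next_ms <- ms_int
    } else {
      sigma2_gamma <- NA_real_
      next_ms <- ms_err
    }
    sigma2_e <- ms_err
    df_err <- 2L * n * (m - 1L)
  }
  if (!is.na(sigma2_gamma) && sigma2_gamma < 0) {
    truncated <- c(truncated, "sigma2_gamma")
    sigma2_gamma <- 0
  }
  sigma2_alpha <- (ms_subj - next_ms) / (2 * m)
  if (sigma2_alpha < 0) {
    truncated <- c(truncated, "sigma2_alpha")
    sigma2_alpha <- 0
  }
  beta_diff <- unname(dev_means[dev2] - dev_means[dev1])
  new_mixed_model_fit(
    beta_diff = beta_diff,
    intercept = grand,
    covariate_effects = numeric(0L),
    sigma2_alpha = sigma2_alpha,
    sigma2_gamma = sigma2_gamma,
    sigma2_e = if (equal_error_variances) sigma2_e else NA_real_,
    sigma2_e_dev = sigma2_e_dev,
    err_df_dev = err_df_dev,
    n = n, m = m,
    devices = data$devices,
    method = "balanced-ANOVA/REML",
    truncated = truncated,
    loglik = NA_real_, aic = NA_real_,
    include_interaction = include_interaction
  )
}

#' General REML (or ML) fit of the two-device mixed model
#'
#' Numerical fit of the mixed model via [lme4::lmer()], supporting
#' covariates, unbalanced data and the subject-by-device interaction. On
#' balanced covariate-free data the variance components agree with
#' [fit_balanced_vc()] to optimiser tolerance.
#'
#' @param data an [agreement_data()] object.
#' @param covariate_names character vector of covariate columns to enter as
#'   fixed effects (must be present on every record).
#' @param include_interaction include the subject-by-device random
#'   interaction.
#' @param method `"REML"` (default) or `"ML"` (used by the
#'   maximum-likelihood plug-in comparator).
#' @return An object of class `"mixed_model_fit"` with `loglik` and `aic`
#'   filled.
#' @export
fit_reml_general <- function(data, covariate_names = NULL,
                             include_interaction = TRUE,
                             method = c("REML", "ML")) {
  stopifnot(inherits(data, "agreement_data"))
  method <- match.arg(method)
  if (data$n < 2L) stop("at least 2 subjects are required")
  df <- data$data
  if (!is.null(covariate_names)) {
    missing_cov <- setdiff(covariate_names, names(df))
    if (length(missing_cov)) {
      stop("covariate(s) not present: ", paste(missing_cov, collapse = ", "))
    }
    for (cv in covariate_names) {
      if (anyNA(df[[cv]])) stop("covariate `", cv, "` has missing values")
      vals <- df[[cv]]
      if (length(unique(vals)) < 2L) {
        stop("covariate `", cv, "` is constant (confounded with the ",
             "intercept)")
      }
    }
  }
  df$device <- factor(df$device, levels = data$devices)
  df$subject <- factor(df$subject)
  fixed <- paste(c("device", covariate_names), collapse = " + ")
  rand <- if (include_interaction) "(1 | subject) + (1 | subject:device)"
          else "(1 | subject)"
  form <- stats::as.formula(paste("value ~", fixed, "+", rand))
  fit <- tryCatch(
    lme4::lmer(form, data = df, REML = (method == "REML"),
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) stop("mixed-model fit failed: ",
                             conditionMessage(e)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- function(grp) {
    hit <- vc$vcov[vc$grp == grp]
    if (length(hit)) hit[1L] else NA_real_
  }
  fe <- lme4::fixef(fit)
  dev_coef_name <- paste0("device", data$devices[2L])
  if (!dev_coef_name %in% names(fe)) {
    stop("device effect not estimable (rank-deficient fixed effects)")
  }
  cov_eff <- fe[setdiff(names(fe), c("(Intercept)", dev_coef_name))]
  sigma2_gamma <- if (include_interaction) comp("subject:device") else NA_real_
  new_mixed_model_fit(
    beta_diff = unname(fe[[dev_coef_name]]),
    intercept = unname(fe[["(Intercept)"]]),
    covariate_effects = cov_eff,
    sigma2_alpha = comp("subject"),
    sigma2_gamma = sigma2_gamma,
    sigma2_e = sigma(fit)^2,
    sigma2_e_dev = NULL, err_df_dev = NULL,
    n = data$n,
    m = if (data$balanced) data$m else NA_integer_,
    devices = data$devices,
    method = paste0("general-", method),
    truncated = character(0L),
    loglik = as.numeric(logLik(fit)),
    aic = AIC(fit),
    include_interaction = include_interaction
  )
}

new_mixed_model_fit <- function(beta_diff, intercept, covariate_effects,
                                sigma2_alpha, sigma2_gamma, sigma2_e,
                                sigma2_e_dev, err_df_dev, n, m, devices,
                                method, truncated, loglik, aic,
                                include_interaction) {
  stopifnot(is.na(sigma2_alpha) || sigma2_alpha >= 0,
            is.na(sigma2_gamma) || sigma2_gamma >= 0,
            is.na(sigma2_e) || sigma2_e >= 0)
  structure(list(
    beta_diff = beta_diff, intercept = intercept,
    covariate_effects = covariate_effects,
    sigma2_alpha = sigma2_alpha, sigma2_gamma = sigma2_gamma,
    sigma2_e = sigma2_e, sigma2_e_dev = sigma2_e_dev,
    err_df_dev = err_df_dev,
    n = n, m = m, devices = devices, method = method,
    truncated = truncated, loglik = loglik, aic = aic,
    include_interaction = include_interaction
  ), class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("Two-device mixed model (%s), n = %d subjects, m = %s\n",
              x$method, x$n, ifelse(is.na(x$m), "unbalanced", x$m)))
  cat(sprintf("  device effect (%s - %s): %.6g\n",
              x$devices[2L], x$devices[1L], x$beta_diff))
  cat(sprintf("  sigma2_alpha = %.6g", x$sigma2_alpha))
  if (!is.na(x$sigma2_gamma)) cat(sprintf(", sigma2_gamma = %.6g",
                                          x$sigma2_gamma))
  if (!is.na(x$sigma2_e)) cat(sprintf(", sigma2_e = %.6g", x$sigma2_e))
  if (!is.null(x$sigma2_e_dev)) {
    cat(sprintf(", sigma2_e[%s] = %.6g, sigma2_e[%s] = %.6g",
                x$devices[1L], x$sigma2_e_dev[[1L]],
                x$devices[2L], x$sigma2_e_dev[[2L]]))
  }
  cat("\n")
  if (length(x$truncated)) {
    cat("  truncated at zero:", paste(x$truncated, collapse = ", "), "\n")
  }
  if (is.finite(x$aic)) cat(sprintf("  logLik = %.4f, AIC = %.4f\n",
                                    x$loglik, x$aic))
  invisible(x)
}

#' Distribution of the paired difference implied by a fitted model
#'
#' Derives the normal distribution of the relevant paired difference, plus
#' the tolerance-interval bookkeeping (N, the count of paired differences,
#' and the residual degrees of freedom nu):
#' \itemize{
#' \item `total`: single readings across devices,
#'   \eqn{\mu_D = \beta_2-\beta_1},
#'   \eqn{\sigma^2_D = 2\sigma^2_\gamma + 2\sigma^2_e}
#'   (or \eqn{2\sigma^2_\gamma + \sigma^2_{e1} + \sigma^2_{e2}}); N = 2nm.
#' \item `intra`: replicates within one device, \eqn{\mu_D = 0},
#'   \eqn{\sigma^2_D = 2\sigma^2_e} (device-specific under unequal error
#'   variances); N = 2nm.
#' \item `inter`: replicate averages across devices,
#'   \eqn{\mu_D = \beta_2-\beta_1},
#'   \eqn{\sigma^2_D = 2\sigma^2_\gamma + 2\sigma^2_e/m}
#'   (or \eqn{2\sigma^2_\gamma + (\sigma^2_{e1}+\sigma^2_{e2})/m}); N = 2n.
#' }
#'
#' @param fit a `"mixed_model_fit"`.
#' @param kind `"total"`, `"intra"` or `"inter"`.
#' @param df_convention degrees-of-freedom convention, see [residual_df()].
#'   Default: `"interaction"` if the fit includes the interaction term,
#'   `"no_interaction"` otherwise; `"satterthwaite"` is selected
#'   automatically when device-specific error variances are present.
#' @param alpha_device for `kind = "intra"` with unequal error variances:
#'   which device's repeatability is wanted.
#' @return An object of class `"difference_params"` with fields `mu_D`,
#'   `sigma_D`, `kind`, `N`, `nu`, `df_convention`.
#' @export
difference_params <- function(fit, kind = c("total", "intra", "inter"),
                              df_convention = NULL, alpha_device = NULL) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  kind <- match.arg(kind)
  n <- fit$n
  m <- fit$m
  if (is.na(m)) {
    stop("unbalanced fit: replicate count undefined; tolerance-interval ",
         "quantities require balanced data in this release")
  }
  unequal <- !is.null(fit$sigma2_e_dev)
  g2 <- if (is.na(fit$sigma2_gamma)) 0 else fit$sigma2_gamma
  if (is.null(df_convention)) {
    df_convention <- if (unequal) "satterthwaite"
      else if (fit$include_interaction) "interaction" else "no_interaction"
  }
  if (kind == "total") {
    mu <- fit$beta_diff
    s2 <- if (unequal) 2 * g2 + sum(fit$sigma2_e_dev)
          else 2 * g2 + 2 * fit$sigma2_e
    N <- 2 * n * m
  } else if (kind == "intra") {
    mu <- 0
    if (unequal) {
      if (is.null(alpha_device)) {
        stop("unequal error variances: `alpha_device` must name the device")
      }
      stopifnot(alpha_device %in% fit$devices)
      s2 <- 2 * fit$sigma2_e_dev[[alpha_device]]
    } else {
      s2 <- 2 * fit$sigma2_e
    }
    N <- 2 * n * m
  } else {
    mu <- fit$beta_diff
    s2 <- if (unequal) 2 * g2 + sum(fit$sigma2_e_dev) / m
          else 2 * g2 + 2 * fit$sigma2_e / m
    N <- 2 * n
  }
  if (!is.finite(s2) || s2 <= 0) {
    stop("sigma_D = 0: the ", kind, " difference distribution is degenerate")
  }
  nu <- residual_df(n, m, df_convention, fit = fit)
  structure(list(mu_D = mu, sigma_D = sqrt(s2), kind = kind,
                 N = N, nu = nu, df_convention = df_convention,
                 n = n, m = m),
            class = "difference_params")
}

#' @export
print.difference_params <- function(x, ...) {
  cat(sprintf("%s-method paired difference: N(mu = %.6g, sd = %.6g)\n",
              x$kind, x$mu_D, x$sigma_D))
  cat(sprintf("  N = %g paired differences, nu = %.4g df (%s)\n",
              x$N, x$nu, x$df_convention))
  invisible(x)
}
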