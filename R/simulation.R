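#' Define a Monte-Carlo scenario
#'
#' A scenario fixes the generating mixed model for two devices with
#' replicated readings: per subject, the 2m-vector of measurements is
#' multivariate normal with mean `intercept` plus the device effect and
#' compound-symmetry covariance
#' \eqn{\sigma^2_\alpha \mathbf{1}\mathbf{1}' + \sigma^2_e I} (no
#' subject-by-device interaction). The defaults are the blood-pressure
#' emulation: intercept 133.369 mmHg and subject variance 380.187, with the
#' device effect and error variance varied over \{0, 2.174, 5\} and
#' \{16, 52.867\} in the full study grid.
#'
#' @param n subjects per data set.
#' @param m replicates per subject-by-device cell.
#' @param beta_diff device effect (second device minus first).
#' @param sigma2_e error variance.
#' @param sigma2_alpha subject variance.
#' @param intercept grand mean.
#' @param n_sims Monte-Carlo replicates.
#' @param seed master seed; all replicate substreams derive from it.
#' @param p_levels proportions evaluated per replicate.
#' @param alpha one-sided type-I error of the upper bounds.
#' @param methods subset of `"TI"` (probability interval + tolerance
#'   bound), `"choudhary"`, `"lin"`.
#' @param tol binary-search tolerance used inside the harness.
#' @return An object of class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(n = 20, m = 2, beta_diff = 0,
                                sigma2_e = 52.867, sigma2_alpha = 380.187,
                                intercept = 133.369, n_sims = 1000,
                                seed = 20100408,
                                p_levels = c(0.80, 0.85, 0.90, 0.95),
                                alpha = 0.05,
                                methods = c("TI", "choudhary", "lin"),
                                tol = 1e-4) {
  methods <- match.arg(methods, c("TI", "choudhary", "lin"),
                       several.ok = TRUE)
  stopifnot(n >= 2, m >= 1, sigma2_e >= 0, sigma2_alpha >= 0, n_sims >= 1,
            all(p_levels > 0 & p_levels < 1), alpha > 0, alpha < 0.5)
  seed <- as.integer(seed)
  structure(list(n = as.integer(n), m = as.integer(m),
                 beta_diff = beta_diff, sigma2_e = sigma2_e,
                 sigma2_alpha = sigma2_alpha, intercept = intercept,
                 n_sims = as.integer(n_sims), seed = seed,
                 p_levels = p_levels, alpha = alpha, methods = methods,
                 tol = tol), class = "simulation_scenario")
}

#' Analytic (true) log TDI of a scenario
#'
#' The generating model has no interaction, so the total difference has
#' \eqn{\sigma_D = \sqrt{2\sigma^2_e}}; the true TDI comes from the
#' non-central chi-square definition, reported on the log scale (the scale
#' on which the estimates are summarised).
#'
#' @param scenario a [simulation_scenario()].
#' @param p proportion in (0, 1).
#' @return log of the true \eqn{\kappa_p}.
#' @export
#' @examples
#' true_log_tdi(simulation_scenario(beta_diff = 0, sigma2_e = 16), 0.80)
true_log_tdi <- function(scenario, p) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  log(tdi_ncx2_exact(scenario$beta_diff, sqrt(2 * scenario$sigma2_e), p))
}

#' Generate one synthetic agreement data set
#'
#' Draws n independent subject vectors of length 2m from the scenario's
#' multivariate normal (compound-symmetry covariance), assembled as
#' long-format [agreement_data()] with devices `"dev1"` and `"dev2"`
#' (difference convention dev2 - dev1).
#'
#' @param scenario a [simulation_scenario()].
#' @param seed integer seed for this draw (deterministic: the same seed
#'   yields the same data set).
#' @return An [agreement_data()] object, balanced by construction.
#' @export
generate_dataset <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(as.integer(seed))
  n <- scenario$n
  m <- scenario$m
  # alpha_i + e_ijl decomposition == MVN with sigma2_alpha J + sigma2_e I
  alpha <- rnorm(n, 0, sqrt(scenario$sigma2_alpha))
  mu1 <- scenario$intercept
  mu2 <- scenario$intercept + scenario$beta_diff
  y1 <- rep(alpha, each = m) + rnorm(n * m, mu1, sqrt(scenario$sigma2_e))
  y2 <- rep(alpha, each = m) + rnorm(n * m, mu2, sqrt(scenario$sigma2_e))
  subj <- sprintf("S%03d", rep(seq_len(n), each = m))
  repl <- rep(seq_len(m), times = n)
  agreement_data(data.frame(
    subject = c(subj, subj),
    device = rep(c("dev1", "dev2"), each = n * m),
    replicate = c(repl, repl),
    value = c(y1, y2),
    stringsAsFactors = FALSE
  ), device_order = c("dev1", "dev2"))
}

# one replicate: fit per method, return log estimates and log UBs
sim_one_rep <- function(scenario, seed, settings, policy) {
  data <- generate_dataset(scenario, seed)
  out <- list()
  need_anova <- any(c("TI", "lin") %in% scenario$methods)
  if (need_anova) {
    fit <- fit_balanced_vc(data, include_interaction = FALSE)
  }
  if ("TI" %in% scenario$methods) {
    params <- difference_params(fit, "total",
                                df_convention = "no_interaction")
    out$TI <- vapply(scenario$p_levels, function(p) {
      r <- tdi_upper_bound(params, p, policy, settings)
      c(log_est = log(r$kappa_hat), log_ub = log(r$upper_bound))
    }, c(log_est = 0, log_ub = 0))
  }
  if ("choudhary" %in% scenario$methods) {
    out$choudhary <- vapply(scenario$p_levels, function(p) {
      r <- choudhary_tdi_ub(data, p, confidence = policy$confidence)
      c(log_est = log(r$kappa_hat), log_ub = log(r$upper_bound))
    }, c(log_est = 0, log_ub = 0))
  }
  if ("lin" %in% scenario$methods) {
    out$lin <- vapply(scenario$p_levels, function(p) {
      r <- lin_tdi_ub(data, p, confidence = policy$confidence)
      c(log_est = log(r$kappa_hat), log_ub = log(r$upper_bound))
    }, c(log_est = 0, log_ub = 0))
  }
  out
}

#' Run one Monte-Carlo scenario
#'
#' For each replicate: generate a data set, fit the model per method
#' (closed-form balanced ANOVA/REML for the tolerance-interval method,
#' closed-form balanced ML for the plug-in comparator, moment/GEE for the
#' MSD comparator), compute the TDI estimate and its one-sided upper bound
#' for every requested proportion, then aggregate on the log scale: mean of
#' log estimates, MSE (x1000) of log estimates against the analytic truth,
#' and empirical confidence EC = percentage of replicates whose true log TDI
#' does not exceed the log upper bound. Monte-Carlo standard errors
#' accompany each aggregate.
#'
#' @param scenario a [simulation_scenario()].
#' @return A data frame of class `"simulation_summary"`, one row per
#'   (proportion, method), with columns `p`, `method`, `true_log_kappa`,
#'   `mean_log_estimate`, `mean_log_se`, `mse_log_x1000`, `ec_percent`,
#'   `ec_se`, `n_sims`, `n_failed`, `seed` and the scenario parameters.
#' @export
run_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  settings <- search_settings(tol = scenario$tol)
  policy <- ti_policy(confidence = 1 - scenario$alpha,
                      df_convention = "no_interaction")
  set.seed(scenario$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, scenario$n_sims)
  n_p <- length(scenario$p_levels)
  acc <- lapply(scenario$methods, function(m)
    list(est = matrix(NA_real_, scenario$n_sims, n_p),
         ub = matrix(NA_real_, scenario$n_sims, n_p)))
  names(acc) <- scenario$methods
  n_failed <- 0L
  for (s in seq_len(scenario$n_sims)) {
    rep_res <- tryCatch(
      sim_one_rep(scenario, rep_seeds[s], settings, policy),
      error = function(e) NULL)
    if (is.null(rep_res)) {
      n_failed <- n_failed + 1L
      next
    }
    for (meth in scenario$methods) {
      acc[[meth]]$est[s, ] <- rep_res[[meth]]["log_est", ]
      acc[[meth]]$ub[s, ] <- rep_res[[meth]]["log_ub", ]
    }
  }
  if (n_failed / scenario$n_sims >= 0.01) {
    stop(n_failed, " of ", scenario$n_sims,
         " replicates failed to fit (>= 1%); scenario aborted")
  }
  rows <- do.call(rbind, lapply(seq_along(scenario$p_levels), function(k) {
    p <- scenario$p_levels[k]
    truth <- true_log_tdi(scenario, p)
    do.call(rbind, lapply(scenario$methods, function(meth) {
      est <- acc[[meth]]$est[, k]
      ub <- acc[[meth]]$ub[, k]
      ok <- is.finite(est)
      est <- est[ok]; ub <- ub[ok]
      nrep <- length(est)
      cover <- mean(truth <= ub)
      data.frame(
        p = p, method = meth, true_log_kappa = truth,
        mean_log_estimate = mean(est),
        mean_log_se = sd(est) / sqrt(nrep),
        mse_log_x1000 = 1000 * mean((est - truth)^2),
        ec_percent = 100 * cover,
        ec_se = 100 * sqrt(cover * (1 - cover) / nrep),
        n_sims = nrep, n_failed = n_failed,
        stringsAsFactors = FALSE)
    }))
  }))
  rows$n <- scenario$n
  rows$m <- scenario$m
  rows$beta_diff <- scenario$beta_diff
  rows$sigma2_e <- scenario$sigma2_e
  rows$seed <- scenario$seed
  class(rows) <- c("simulation_summary", "data.frame")
  rows
}

#' Replicate the full simulation-study table
#'
#' Runs [run_scenario()] over a grid of scenarios — by default the full
#' 3 (device effect) x 2 (error variance) x 2 (sample size) design with
#' four proportions — and binds the per-scenario summaries into one
#' long-format table.
#'
#' @param grid a data frame with columns `beta_diff`, `sigma2_e`, `n` (one
#'   row per scenario); `NULL` for the full design.
#' @param n_sims replicates per scenario.
#' @param seed master seed; scenario s uses `seed + s - 1` so any subset of
#'   the grid is independently reproducible.
#' @param methods,p_levels,alpha,tol,m see [simulation_scenario()].
#' @param verbose print progress lines.
#' @return A `"simulation_summary"` data frame (rows: scenario x p x
#'   method).
#' @export
replicate_table3 <- function(grid = NULL, n_sims = 1000, seed = 20100408,
                             methods = "TI",
                             p_levels = c(0.80, 0.85, 0.90, 0.95),
                             alpha = 0.05, tol = 1e-4, m = 2,
                             verbose = FALSE) {
  if (is.null(grid)) {
    grid <- expand.grid(beta_diff = c(0, 2.174, 5),
                        sigma2_e = c(16, 52.867),
                        n = c(20, 100))
  }
  stopifnot(all(c("beta_diff", "sigma2_e", "n") %in% names(grid)))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sc <- simulation_scenario(
      n = grid$n[i], m = m, beta_diff = grid$beta_diff[i],
      sigma2_e = grid$sigma2_e[i], n_sims = n_sims,
      seed = seed + i - 1L, p_levels = p_levels, alpha = alpha,
      methods = methods, tol = tol)
    if (verbose) {
      message(sprintf("scenario %d/%d: n=%d beta_diff=%g sigma2_e=%g",
                      i, nrow(grid), sc$n, sc$beta_diff, sc$sigma2_e))
    }
    out[[i]] <- run_scenario(sc)
  }
  res <- do.call(rbind, out)
  class(res) <- c("simulation_summary", "data.frame")
  res
}
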