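test_that("constant data give zero variance components and zero device effect", {
  d <- agreement_data(data.frame(
    subject = rep(c("a", "b", "c"), each = 4),
    device = rep(rep(c("A", "B"), each = 2), 3),
    replicate = rep(1:2, 6),
    value = 7.5))
  fit <- fit_balanced_vc(d)
  expect_equal(fit$beta_diff, 0)
  expect_equal(fit$sigma2_alpha, 0)
  expect_equal(fit$sigma2_gamma, 0)
  expect_equal(fit$sigma2_e, 0)
  expect_equal(fit$intercept, 7.5)
})

test_that("balanced estimators reproduce the loop-based sums-of-squares oracle", {
  d <- make_tiny_data()
  for (incl in c(TRUE, FALSE)) {
    fit <- fit_balanced_vc(d, include_interaction = incl)
    orc <- oracle_vc(d, include_interaction = incl)
    expect_equal(fit$beta_diff, unname(orc$beta_diff), tolerance = 1e-12)
    expect_equal(fit$sigma2_e, orc$sigma2_e, tolerance = 1e-12)
    expect_equal(fit$sigma2_alpha, max(orc$sigma2_alpha, 0),
                 tolerance = 1e-12)
    if (incl) {
      expect_equal(fit$sigma2_gamma, max(orc$sigma2_gamma, 0),
                   tolerance = 1e-12)
    }
  }
  # and on a larger simulated instance
  sc <- simulation_scenario(n = 40, m = 3, beta_diff = 2.174,
                            sigma2_e = 52.867)
  d2 <- generate_dataset(sc, seed = 99)
  fit2 <- fit_balanced_vc(d2, include_interaction = TRUE)
  orc2 <- oracle_vc(d2, include_interaction = TRUE)
  expect_equal(fit2$sigma2_e, orc2$sigma2_e, tolerance = 1e-10)
  expect_equal(fit2$beta_diff, unname(orc2$beta_diff), tolerance = 1e-10)
})

test_that("negative interaction solutions are truncated to zero and flagged", {
  # generated without interaction, so the raw solution is negative about
  # half the time; whenever it is, the fit must truncate and flag
  hits <- 0
  for (seed in 1:12) {
    sc <- simulation_scenario(n = 20, m = 2, beta_diff = 0, sigma2_e = 30)
    d <- generate_dataset(sc, seed = seed)
    fit <- fit_balanced_vc(d, include_interaction = TRUE)
    raw <- oracle_vc(d, include_interaction = TRUE)$sigma2_gamma
    expect_gte(fit$sigma2_gamma, 0)
    if (raw < 0) {
      hits <- hits + 1
      expect_equal(fit$sigma2_gamma, 0)
      expect_true("sigma2_gamma" %in% fit$truncated)
    } else {
      expect_equal(fit$sigma2_gamma, raw, tolerance = 1e-12)
    }
  }
  expect_gt(hits, 0)
})

test_that("variance components are recovered without bias across simulations", {
  n_rep <- 500
  est <- matrix(NA_real_, n_rep, 3)
  sc <- simulation_scenario(n = 100, m = 2, beta_diff = 2.174,
                            sigma2_e = 52.867, sigma2_alpha = 380.187)
  set.seed(2024)
  seeds <- sample.int(1e8, n_rep)
  for (k in seq_len(n_rep)) {
    fit <- fit_balanced_vc(generate_dataset(sc, seeds[k]),
                           include_interaction = FALSE)
    est[k, ] <- c(fit$beta_diff, fit$sigma2_alpha, fit$sigma2_e)
  }
  truth <- c(2.174, 380.187, 52.867)
  for (j in 1:3) {
    se <- sd(est[, j]) / sqrt(n_rep)
    expect_lt(abs(mean(est[, j]) - truth[j]), 3 * se)
  }
})

test_that("precondition violations raise errors", {
  df <- data.frame(subject = c("a", "a", "a", "b", "b"),
                   device = c("A", "A", "B", "A", "B"),
                   replicate = c(1, 2, 1, 1, 1), value = rnorm(5, 100))
  expect_error(fit_balanced_vc(agreement_data(df)), "balanced")
  d1 <- agreement_data(data.frame(subject = rep(c("a", "b"), each = 2),
                                  device = rep(c("A", "B"), 2),
                                  replicate = 1, value = rnorm(4)))
  expect_error(fit_balanced_vc(d1, include_interaction = TRUE), "m = 1")
})

test_that("general REML matches the closed form on balanced covariate-free data", {
  sc <- simulation_scenario(n = 60, m = 2, beta_diff = 2.174,
                            sigma2_e = 52.867)
  d <- generate_dataset(sc, seed = 404)
  closed <- fit_balanced_vc(d, include_interaction = FALSE)
  reml <- fit_reml_general(d, include_interaction = FALSE)
  expect_equal(reml$beta_diff, closed$beta_diff, tolerance = 1e-6)
  expect_equal(reml$sigma2_e, closed$sigma2_e, tolerance = 1e-5)
  expect_equal(reml$sigma2_alpha, closed$sigma2_alpha, tolerance = 1e-4)
  expect_true(is.finite(reml$aic))
})

test_that("a pure-noise covariate leaves the TDI ingredients unchanged", {
  sc <- simulation_scenario(n = 60, m = 2, beta_diff = 2.174,
                            sigma2_e = 52.867)
  d <- generate_dataset(sc, seed = 77)
  # subject-level covariate: orthogonal to the within-subject device
  # contrast in a balanced design, as in a real demographic adjustment
  set.seed(78)
  subj_noise <- setNames(rnorm(d$n), unique(d$data$subject))
  d$data$noise <- subj_noise[d$data$subject]
  d$covariates <- "noise"
  plain <- fit_reml_general(d, include_interaction = FALSE)
  withcov <- fit_reml_general(d, covariate_names = "noise",
                              include_interaction = FALSE)
  expect_equal(withcov$beta_diff, plain$beta_diff, tolerance = 1e-3)
  expect_equal(withcov$sigma2_e, plain$sigma2_e, tolerance = 0.05)
  # constant covariate is confounded with the intercept
  d$data$flat <- 1
  expect_error(fit_reml_general(d, covariate_names = "flat"), "constant")
})

test_that("difference parameters follow the mixed-model distributions", {
  # a fit frozen at the blood-pressure point estimates
  fit <- structure(list(
    beta_diff = 2.174, intercept = 133.369, covariate_effects = numeric(0),
    sigma2_alpha = 380.187, sigma2_gamma = NA_real_, sigma2_e = 52.867,
    sigma2_e_dev = NULL, err_df_dev = NULL, n = 384L, m = 2L,
    devices = c("manual", "auto"), method = "balanced-ANOVA/REML",
    truncated = character(0), loglik = NA_real_, aic = NA_real_,
    include_interaction = FALSE), class = "mixed_model_fit")
  tot <- difference_params(fit, "total")
  expect_equal(tot$mu_D, 2.174)
  expect_equal(tot$sigma_D, 10.283, tolerance = 5e-4)
  expect_equal(tot$N, 1536)
  expect_equal(tot$nu, 1151)
  intra <- difference_params(fit, "intra")
  expect_equal(intra$mu_D, 0)
  expect_equal(intra$sigma_D, sqrt(2 * 52.867), tolerance = 1e-12)
  inter <- difference_params(fit, "inter")
  expect_equal(inter$sigma_D, sqrt(52.867), tolerance = 1e-12)
  expect_equal(inter$N, 768)
  # total-difference spread dominates the averaged-difference spread
  expect_gt(tot$sigma_D, inter$sigma_D)
})

test_that("device-specific error variances feed Satterthwaite df", {
  sc <- simulation_scenario(n = 30, m = 2, beta_diff = 1, sigma2_e = 40)
  d <- generate_dataset(sc, seed = 5)
  fit <- fit_balanced_vc(d, include_interaction = FALSE,
                         equal_error_variances = FALSE)
  expect_length(fit$sigma2_e_dev, 2L)
  pars <- difference_params(fit, "total")
  expect_equal(pars$df_convention, "satterthwaite")
  # Welch combination lies between min df and the pooled df
  expect_gte(pars$nu, min(unlist(fit$err_df_dev)))
  expect_lte(pars$nu, sum(unlist(fit$err_df_dev)))
  expect_error(difference_params(fit, "intra"), "alpha_device")
  intra1 <- difference_params(fit, "intra", alpha_device = "dev1")
  expect_equal(intra1$sigma_D, sqrt(2 * fit$sigma2_e_dev[["dev1"]]),
               tolerance = 1e-12)
})
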