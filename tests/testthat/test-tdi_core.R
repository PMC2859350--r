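mu_bp <- 2.174
sd_bp <- sqrt(2 * 52.867)

test_that("binary search reproduces the blood-pressure p1 solutions", {
  p1 <- vapply(c(0.80, 0.85, 0.90, 0.95),
               function(p) as.numeric(solve_p1(mu_bp / sd_bp, p)),
               numeric(1))
  expect_equal(round(p1, 3), c(0.864, 0.896, 0.929, 0.963))
})

test_that("p1 is (1+p)/2 exactly for a zero mean difference", {
  for (p in c(0.5, 0.80, 0.90, 0.95, 0.99)) {
    expect_identical(as.numeric(solve_p1(0, p)), (1 + p) / 2)
  }
})

test_that("binary search agrees with a uniroot oracle and p1 shrinks toward p with bias", {
  # as |mu|/sigma grows the interval is dominated by one tail, so p1 moves
  # down from (1+p)/2 toward p
  ratios <- c(0.05, 0.2, 2.174 / sd_bp, 2.174 / sqrt(52.867), 1, 2.5)
  for (p in c(0.6, 0.80, 0.90, 0.95)) {
    p1 <- vapply(ratios, function(r) as.numeric(solve_p1(r, p)), numeric(1))
    orc <- vapply(ratios, function(r) oracle_p1(r, p), numeric(1))
    expect_equal(p1, orc, tolerance = 1e-8)
    expect_true(all(diff(p1) < 0))
    expect_true(all(p1 > p & p1 < (1 + p) / 2))
  }
})

test_that("binary search respects its logarithmic iteration bound", {
  for (tol in c(1e-4, 1e-8, 1e-10)) {
    s <- search_settings(tol = tol)
    bound <- ceiling(log2(1 / tol)) + 5
    for (r in c(0.01, 0.21, 1.7)) {
      p1 <- solve_p1(r, 0.9, s)
      expect_lte(attr(p1, "iterations"), bound)
    }
  }
})

test_that("probability-interval TDI reproduces the case example and reduces to the central interval", {
  r <- tdi_probability_interval(mu_bp, sd_bp, 0.90)
  expect_equal(r$kappa_hat, 17.29, tolerance = 0.005)
  # mu = 0: central normal interval for any sigma, p
  for (sig in c(0.3, 1, 10.28)) {
    for (p in c(0.8, 0.95)) {
      r0 <- tdi_probability_interval(0, sig, p)
      expect_equal(r0$kappa_hat, sig * qnorm((1 + p) / 2), tolerance = 1e-12)
    }
  }
  # large-bias scenario matches the analytic truth used by the harness
  r5 <- tdi_probability_interval(5, sd_bp, 0.95)
  expect_equal(log(r5$kappa_hat), 3.105, tolerance = 5e-4)
})

test_that("probability-interval and non-central chi-square estimates are identical", {
  # the defining identity, over a grid of standardised means and proportions
  grid <- expand.grid(ratio = seq(0, 3, length.out = 25),
                      p = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.975, 0.99))
  for (k in seq_len(nrow(grid))) {
    mu <- grid$ratio[k] * 7.5
    kap_pi <- tdi_probability_interval(mu, 7.5, grid$p[k])$kappa_hat
    kap_x2 <- tdi_ncx2_exact(mu, 7.5, grid$p[k])
    expect_equal(kap_pi, kap_x2, tolerance = 1e-8)
  }
})

test_that("non-central chi-square TDI matches closed-form central cases", {
  expect_equal(tdi_ncx2_exact(0, sqrt(32), 0.80), sqrt(32) * qnorm(0.90),
               tolerance = 1e-10)
  expect_equal(log(tdi_ncx2_exact(0, sqrt(32), 0.80)), 1.981,
               tolerance = 5e-4)
  expect_equal(tdi_ncx2_exact(0, 1, 0.95), 1.95996, tolerance = 1e-5)
})

test_that("MSD approximation is exact at zero mean and follows its closed form", {
  for (sig in c(1, 5.6569, 10.2827)) {
    expect_equal(tdi_msd_approx(0, sig, 0.9), tdi_ncx2_exact(0, sig, 0.9),
                 tolerance = 1e-12)
  }
  expect_equal(tdi_msd_approx(2.174, sqrt(2 * 52.867), 0.90),
               qnorm(0.95) * sqrt(2.174^2 + 2 * 52.867), tolerance = 1e-12)
  expect_equal(tdi_msd_approx(5, 5.6569, 0.80),
               qnorm(0.90) * sqrt(25 + 5.6569^2), tolerance = 1e-12)
})

test_that("intra-method TDI matches the repeatability column and scales as sqrt(variance)", {
  expect_equal(tdi_intra(52.867, 0.90), 16.9, tolerance = 0.05)
  expect_equal(tdi_intra(52.867, 0.95), 20.2, tolerance = 0.06)
  expect_equal(tdi_intra(4 * 52.867, 0.9), 2 * tdi_intra(52.867, 0.9),
               tolerance = 1e-12)
  expect_error(tdi_intra(0, 0.9), "positive")
})

test_that("inter-method TDI: strict vs paper_compat modes", {
  s_int <- sqrt(52.867)
  tp <- list(mu_D = mu_bp, sigma_D = sd_bp)
  compat <- tdi_inter(mu_bp, s_int, 0.90, mode = "paper_compat",
                      total_params = tp)
  expect_equal(compat$kappa_hat, 12.9, tolerance = 0.05)
  strict <- tdi_inter(mu_bp, s_int, 0.90, mode = "strict")
  expect_equal(strict$kappa_hat, oracle_tdi(mu_bp, s_int, 0.90),
               tolerance = 1e-6)
  expect_lt(strict$kappa_hat, compat$kappa_hat)
  # modes coincide for a zero mean difference
  z0 <- tdi_inter(0, s_int, 0.9, mode = "paper_compat",
                  total_params = list(mu_D = 0, sigma_D = sd_bp))
  expect_equal(z0$kappa_hat, s_int * qnorm(0.95), tolerance = 1e-10)
  expect_error(tdi_inter(1, 1, 0.9, mode = "paper_compat"), "total_params")
})

test_that("TDI is symmetric in the sign of the mean difference", {
  for (mu in c(0.5, 2.174, 8)) {
    expect_equal(tdi_probability_interval(mu, 5, 0.9)$kappa_hat,
                 tdi_probability_interval(-mu, 5, 0.9)$kappa_hat)
    expect_equal(tdi_ncx2_exact(mu, 5, 0.9), tdi_ncx2_exact(-mu, 5, 0.9))
    expect_equal(tdi_msd_approx(mu, 5, 0.9), tdi_msd_approx(-mu, 5, 0.9))
  }
})

test_that("TDI is strictly increasing in p, sigma and |mu|", {
  ps <- seq(0.55, 0.99, by = 0.04)
  k_p <- vapply(ps, function(p)
    tdi_probability_interval(2, 5, p)$kappa_hat, numeric(1))
  expect_true(all(diff(k_p) > 0))
  sigs <- seq(0.5, 12, length.out = 15)
  k_s <- vapply(sigs, function(s)
    tdi_probability_interval(2, s, 0.9)$kappa_hat, numeric(1))
  expect_true(all(diff(k_s) > 0))
  mus <- seq(0, 10, length.out = 15)
  k_m <- vapply(mus, function(mu)
    tdi_probability_interval(mu, 5, 0.9)$kappa_hat, numeric(1))
  expect_true(all(diff(k_m) > 0))
})

test_that("the interval (-kappa, kappa) captures exactly probability p", {
  # defining property, by direct normal-CDF evaluation
  set.seed(11)
  for (k in 1:25) {
    mu <- runif(1, -8, 8)
    sig <- runif(1, 0.5, 15)
    p <- runif(1, 0.55, 0.98)
    kap <- tdi_probability_interval(mu, sig, p)$kappa_hat
    mass <- pnorm((kap - mu) / sig) - pnorm((-kap - mu) / sig)
    expect_equal(mass, p, tolerance = 1e-8)
  }
})

test_that("search settings validate their invariants", {
  expect_error(search_settings(tol = 0.5), "tol")
  expect_error(search_settings(tol = 1e-6, max_iter = 3), "max_iter")
})
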