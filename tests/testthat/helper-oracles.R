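# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: root finding by uniroot, sums of squares by
# explicit loops.

# root of the probability-interval link, independent of the binary search
oracle_p1 <- function(mu_over_sigma, p) {
  r <- abs(mu_over_sigma)
  f <- function(p1) pnorm(qnorm(p1)) - pnorm(-2 * r - qnorm(p1)) - p
  uniroot(f, c(p + 1e-12, 1 - 1e-12), tol = 1e-12)$root
}

oracle_tdi <- function(mu_D, sigma_D, p) {
  abs(mu_D) + sigma_D * qnorm(oracle_p1(mu_D / sigma_D, p))
}

# loop-based balanced two-way mean squares (subjects x devices, m replicates)
oracle_mean_squares <- function(data) {
  df <- data$data
  subjects <- unique(df$subject)
  devices <- data$devices
  n <- length(subjects)
  m <- data$m
  grand <- mean(df$value)
  cell <- matrix(NA_real_, n, 2)
  sse_within <- 0
  for (i in seq_len(n)) {
    for (j in 1:2) {
      vals <- df$value[df$subject == subjects[i] & df$device == devices[j]]
      cell[i, j] <- mean(vals)
      sse_within <- sse_within + sum((vals - mean(vals))^2)
    }
  }
  subj_means <- rowMeans(cell)
  dev_means <- colMeans(cell)
  ss_int <- 0
  for (i in seq_len(n)) {
    for (j in 1:2) {
      ss_int <- ss_int + m * (cell[i, j] - subj_means[i] - dev_means[j] +
                                grand)^2
    }
  }
  list(
    ms_subject = 2 * m * sum((subj_means - grand)^2) / (n - 1),
    ms_interaction = ss_int / (n - 1),
    ms_error = if (m > 1) sse_within / (2 * n * (m - 1)) else NA_real_,
    ms_error_additive = (sse_within + ss_int) / (2 * n * m - n - 1),
    beta_diff = dev_means[2] - dev_means[1]
  )
}

# raw (untruncated) ANOVA variance-component solutions from the oracle MS
oracle_vc <- function(data, include_interaction = TRUE) {
  ms <- oracle_mean_squares(data)
  m <- data$m
  if (include_interaction) {
    s2e <- ms$ms_error
    s2g <- (ms$ms_interaction - ms$ms_error) / m
    s2a <- (ms$ms_subject - ms$ms_interaction) / (2 * m)
  } else {
    s2e <- ms$ms_error_additive
    s2g <- NA_real_
    s2a <- (ms$ms_subject - s2e) / (2 * m)
  }
  list(sigma2_e = s2e, sigma2_gamma = s2g, sigma2_alpha = s2a,
       beta_diff = ms$beta_diff)
}

# small deterministic balanced data set used by several tests
make_tiny_data <- function() {
  agreement_data(data.frame(
    subject = rep(c("s1", "s2", "s3", "s4", "s5"), each = 4),
    device = rep(rep(c("A", "B"), each = 2), times = 5),
    replicate = rep(c(1, 2), times = 10),
    value = c(120, 122, 118, 121,
              135, 133, 130, 132,
              110, 113, 112, 115,
              128, 126, 129, 131,
              142, 140, 139, 138)
  ), device_order = c("A", "B"))
}

case_example_params <- function(df_convention = "no_interaction") {
  structure(list(mu_D = 2.174, sigma_D = sqrt(2 * 52.867), kind = "total",
                 N = 2 * 384 * 2,
                 nu = residual_df(384, 2, df_convention),
                 df_convention = df_convention, n = 384, m = 2),
            class = "difference_params")
}
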