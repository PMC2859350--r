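#' Settings for the modified binary search
#'
#' Controls the bisection used to solve for the upper-tail proportion
#' \eqn{p_1} (and for the coverage-probability lower bound). The tolerance is
#' on the probability scale: the search stops when the probability equation is
#' satisfied to within `tol`.
#'
#' @param tol convergence tolerance on the probability scale; must lie in
#'   (0, 0.01). The default `1e-10` matches a high-precision analysis run;
#'   simulation work typically uses `1e-4`.
#' @param max_iter iteration cap; must be at least
#'   `ceiling(log2(1/tol)) + 5`, the logarithmic bound of bisection plus
#'   head-room for the tolerance-shifted brackets.
#' @return An object of class `"search_settings"`.
#' @export
#' @examples
#' search_settings()
#' search_settings(tol = 1e-4)
search_settings <- function(tol = 1e-10, max_iter = NULL) {
  stopifnot(is.numeric(tol), length(tol) == 1L, tol > 0, tol < 0.01)
  min_iter <- ceiling(log2(1 / tol)) + 5L
  if (is.null(max_iter)) max_iter <- min_iter
  max_iter <- as.integer(max_iter)
  if (max_iter < min_iter) {
    stop("`max_iter` must be at least ceiling(log2(1/tol)) + 5 = ", min_iter)
  }
  structure(list(tol = tol, max_iter = max_iter), class = "search_settings")
}

#' Solve for the upper-tail proportion p1 of a centred probability interval
#'
#' For a difference variable \eqn{D \sim N(\mu_D, \sigma_D)}, the interval
#' \eqn{[-\kappa_p, \kappa_p]} symmetric about zero that captures probability
#' \eqn{p} has upper limit \eqn{\kappa_p = |\mu_D| + \sigma_D z_{p_1}}, where
#' \eqn{p_1} solves
#' \deqn{\Phi(z_{p_1}) - \Phi(-2|\mu_D|/\sigma_D - z_{p_1}) = p.}
#' The equation has a single root in \eqn{[p, 1]} and no closed form; it is
#' found by a modified binary search that repeatedly halves the bracket,
#' shifting each new endpoint by the tolerance.
#'
#' @param mu_over_sigma the ratio \eqn{\mu_D/\sigma_D} (dimensionless); the
#'   absolute value is used, as the interval is symmetric in the sign.
#' @param p target proportion in (0, 1).
#' @param settings a [search_settings()] object.
#' @return `p1`, a value in `[p, 1]`, with attribute `"iterations"`.
#' @seealso [tdi_probability_interval()]
#' @export
#' @examples
#' solve_p1(2.174 / sqrt(2 * 52.867), 0.90)  # 0.929 to 3 dp
#' solve_p1(0, 0.90)                         # exactly 0.95
solve_p1 <- function(mu_over_sigma, p, settings = search_settings()) {
  stopifnot(is.finite(mu_over_sigma), is.numeric(p), length(p) == 1L,
            p > 0, p < 1)
  r <- abs(mu_over_sigma)
  if (r == 0) {
    # symmetric case: Phi(z) - Phi(-z) = p  =>  p1 = (1 + p)/2 exactly
    p1 <- (1 + p) / 2
    attr(p1, "iterations") <- 0L
    return(p1)
  }
  tol <- settings$tol
  lhs <- function(p1) p1 - pnorm(-2 * r - qnorm(p1))
  low <- p
  high <- 1
  for (it in seq_len(settings$max_iter)) {
    mid <- (low + high) / 2
    val <- lhs(mid)
    if (abs(val - p) < tol) {
      attr(mid, "iterations") <- it
      return(mid)
    }
    if (val > p) high <- mid - tol else low <- mid + tol
  }
  stop(sprintf(
    "p1 search did not converge in %d iterations (bracket [%.15g, %.15g])",
    settings$max_iter, low, high))
}

#' TDI point estimate via a probability interval
#'
#' The total deviation index \eqn{\kappa_p} is the boundary such that a
#' proportion \eqn{p} of paired-measurement differences
#' \eqn{D \sim N(\mu_D, \sigma_D)} fall inside \eqn{(-\kappa_p, \kappa_p)}.
#' It is computed as \eqn{\kappa_p = |\mu_D| + \sigma_D z_{p_1}} with
#' \eqn{p_1} from [solve_p1()].
#'
#' @param mu_D mean difference between devices (measurement units).
#' @param sigma_D standard deviation of the difference (> 0).
#' @param p proportion in (0, 1).
#' @param settings a [search_settings()] object.
#' @param kind label stored on the result, one of `"total"`, `"intra"`,
#'   `"inter"`.
#' @return A `"tdi_result"` object with fields `p`, `p1`, `kappa_hat`,
#'   `kind`, `mode`, `iterations` (the upper bound slot is `NA` until
#'   [tdi_upper_bound()] fills it).
#' @export
#' @examples
#' tdi_probability_interval(2.174, sqrt(2 * 52.867), 0.90)  # 17.29
tdi_probability_interval <- function(mu_D, sigma_D, p,
                                     settings = search_settings(),
                                     kind = "total") {
  stopifnot(is.finite(mu_D), is.finite(sigma_D), sigma_D > 0)
  p1 <- solve_p1(mu_D / sigma_D, p, settings)
  kappa <- abs(mu_D) + sigma_D * qnorm(as.numeric(p1))
  new_tdi_result(p = p, p1 = as.numeric(p1), kappa_hat = kappa,
                 kind = kind, mode = "strict",
                 iterations = attr(p1, "iterations"))
}

#' TDI point estimate via the non-central chi-square definition
#'
#' \eqn{|D|^2/\sigma_D^2} follows a non-central chi-square distribution with
#' 1 degree of freedom and non-centrality \eqn{(\mu_D/\sigma_D)^2}, so
#' \eqn{\kappa_p = \sigma_D \sqrt{q_p}} where \eqn{q_p} is its p-quantile.
#' This is identical to the probability-interval estimate; both routes are
#' kept because the binary search additionally yields \eqn{p_1}, which the
#' tolerance-interval inference needs.
#'
#' @inheritParams tdi_probability_interval
#' @return The TDI estimate (scalar, measurement units).
#' @export
#' @examples
#' tdi_ncx2_exact(0, sqrt(32), 0.80)  # exp(1.981)
tdi_ncx2_exact <- function(mu_D, sigma_D, p) {
  stopifnot(is.finite(mu_D), is.finite(sigma_D), sigma_D > 0,
            p > 0, p < 1)
  q <- qchisq(p, df = 1, ncp = (mu_D / sigma_D)^2)
  if (!is.finite(q)) stop("non-central chi-square quantile failed")
  sigma_D * sqrt(q)
}

#' TDI approximation based on the mean squared deviation
#'
#' Lin's approximation \eqn{\kappa_p \approx z_{(1+p)/2}\sqrt{MSD}} with
#' \eqn{MSD = E(D^2) = \mu_D^2 + \sigma_D^2}. Exact when \eqn{\mu_D = 0};
#' otherwise slightly conservative for usual p.
#'
#' @inheritParams tdi_probability_interval
#' @return The approximate TDI (scalar, measurement units).
#' @export
tdi_msd_approx <- function(mu_D, sigma_D, p) {
  stopifnot(is.finite(mu_D), is.finite(sigma_D), sigma_D > 0,
            p > 0, p < 1)
  qnorm((1 + p) / 2) * sqrt(mu_D^2 + sigma_D^2)
}

#' Intra-method (repeatability) TDI
#'
#' Differences between two replicates from the same device are
#' \eqn{N(0, 2\sigma^2_e)}, so the intra-method TDI is
#' \eqn{\sqrt{2\sigma^2_e}\, z_{(1+p)/2}}. With the 95th percentile this is
#' the ISO repeatability coefficient.
#'
#' @param sigma2_e within-device error variance (> 0), for the device of
#'   interest when error variances differ.
#' @param p proportion in (0, 1).
#' @return The intra-method TDI (scalar, measurement units).
#' @export
#' @examples
#' tdi_intra(52.867, 0.90)  # 16.9
tdi_intra <- function(sigma2_e, p) {
  stopifnot(is.numeric(sigma2_e), length(sigma2_e) == 1L, p > 0, p < 1)
  if (!is.finite(sigma2_e) || sigma2_e <= 0) {
    stop("`sigma2_e` must be positive; the difference distribution is ",
         "degenerate otherwise")
  }
  sqrt(2 * sigma2_e) * qnorm((1 + p) / 2)
}

#' Inter-method TDI (agreement of replicate averages)
#'
#' The difference of the per-device replicate averages is
#' \eqn{N(\mu_D, \sigma^2_{inter})} with
#' \eqn{\sigma^2_{inter} = 2\sigma^2_\gamma + 2\sigma^2_e/m}. In `"strict"`
#' mode \eqn{p_1} is solved from the inter ratio
#' \eqn{\mu_D/\sigma_{inter}}, which makes the interval capture exactly
#' probability p of the averaged-difference distribution. In
#' `"paper_compat"` mode \eqn{p_1} is taken from the total-difference ratio
#' \eqn{\mu_D/\sigma_{D,total}} (supplied via `total_params`); this
#' alternative convention is retained because published concordance tables
#' have been produced with it.
#'
#' @param mu_D mean difference between devices.
#' @param sigma_inter standard deviation of the averaged difference (> 0).
#' @param p proportion in (0, 1).
#' @param mode `"strict"` (default) or `"paper_compat"`.
#' @param total_params for `"paper_compat"`: a list or numeric vector with
#'   elements `mu_D` and `sigma_D` of the total difference.
#' @param settings a [search_settings()] object.
#' @return A `"tdi_result"` object (`kind = "inter"`).
#' @export
#' @examples
#' tdi_inter(2.174, sqrt(52.867), 0.90, mode = "paper_compat",
#'           total_params = list(mu_D = 2.174, sigma_D = sqrt(2 * 52.867)))
tdi_inter <- function(mu_D, sigma_inter, p,
                      mode = c("strict", "paper_compat"),
                      total_params = NULL,
                      settings = search_settings()) {
  mode <- match.arg(mode)
  stopifnot(is.finite(mu_D), is.finite(sigma_inter), sigma_inter > 0)
  if (mode == "paper_compat") {
    if (is.null(total_params)) {
      stop("`total_params` (mu_D and sigma_D of the total difference) is ",
           "required in paper_compat mode")
    }
    tp <- as.list(total_params)
    ratio <- tp$mu_D / tp$sigma_D
  } else {
    ratio <- mu_D / sigma_inter
  }
  p1 <- solve_p1(ratio, p, settings)
  kappa <- abs(mu_D) + sigma_inter * qnorm(as.numeric(p1))
  new_tdi_result(p = p, p1 = as.numeric(p1), kappa_hat = kappa,
                 kind = "inter", mode = mode,
                 iterations = attr(p1, "iterations"))
}

# constructor shared by the estimation and inference layers
new_tdi_result <- function(p, p1, kappa_hat, kind, mode,
                           iterations = NA_integer_,
                           upper_bound = NA_real_, confidence = NA_real_,
                           df_convention = NA_character_,
                           nu = NA_real_, N = NA_real_) {
  stopifnot(p1 >= p - 1e-12, p1 <= 1, kappa_hat > 0)
  structure(list(
    p = p, p1 = p1, kappa_hat = kappa_hat,
    upper_bound = upper_bound, confidence = confidence,
    kind = kind, mode = mode, df_convention = df_convention,
    nu = nu, N = N,
    iterations = if (is.null(iterations)) NA_integer_ else iterations
  ), class = "tdi_result")
}

#' @export
print.tdi_result <- function(x, ...) {
  cat(sprintf("Total deviation index (%s%s)\n", x$kind,
              if (identical(x$mode, "paper_compat")) ", paper_compat" else ""))
  cat(sprintf("  proportion p  : %.4g (p1 = %.6g)\n", x$p, x$p1))
  cat(sprintf("  TDI estimate  : %.6g\n", x$kappa_hat))
  if (is.finite(x$upper_bound)) {
    cat(sprintf("  one-sided %g%% TI upper bound: %.6g  (nu = %g, N = %g, %s)\n",
                100 * x$confidence, x$upper_bound, x$nu, x$N,
                x$df_convention))
  }
  invisible(x)
}
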