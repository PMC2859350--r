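#' All-in-one TDI analysis
#'
#' Fits the two-device mixed model (closed-form balanced ANOVA/REML, or
#' general REML when covariates are supplied or the data are unbalanced) and
#' returns total, intra- and inter-method TDI estimates with their one-sided
#' tolerance-interval upper bounds for each requested proportion.
#'
#' @param data an [agreement_data()] object (or a data frame accepted by
#'   it).
#' @param p proportions to evaluate.
#' @param confidence one-sided confidence level of the upper bounds.
#' @param kinds subset of `"total"`, `"intra"`, `"inter"`.
#' @param df_convention degrees-of-freedom convention ([residual_df()]);
#'   `NULL` selects it from the fitted model structure.
#' @param inter_mode `"strict"` or `"paper_compat"`, see [tdi_inter()].
#' @param include_interaction include the subject-by-device interaction in
#'   the model.
#' @param covariate_names covariates to adjust for (forces the general REML
#'   fit; they do not alter the TDI, which depends only on the device effect
#'   and the error variance, but allow model comparison by AIC).
#' @param settings a [search_settings()] object.
#' @return A list of class `"tdi_analysis"`: the fit, a results data frame
#'   (one row per kind x p), and the configuration.
#' @export
#' @examples
#' sc <- simulation_scenario(n = 50, beta_diff = 2.174)
#' d <- generate_dataset(sc, seed = 7)
#' tdi(d, p = c(0.80, 0.90))
tdi <- function(data, p = c(0.80, 0.85, 0.90, 0.95), confidence = 0.95,
                kinds = c("total", "intra", "inter"),
                df_convention = NULL,
                inter_mode = c("strict", "paper_compat"),
                include_interaction = FALSE,
                covariate_names = NULL,
                settings = search_settings()) {
  if (!inherits(data, "agreement_data")) data <- agreement_data(data)
  inter_mode <- match.arg(inter_mode)
  kinds <- match.arg(kinds, several.ok = TRUE)
  policy <- ti_policy(confidence, df_convention)
  fit <- if (length(covariate_names) || !data$balanced) {
    fit_reml_general(data, covariate_names = covariate_names,
                     include_interaction = include_interaction)
  } else {
    fit_balanced_vc(data, include_interaction = include_interaction)
  }
  total_pars <- difference_params(fit, "total",
                                  df_convention = policy$df_convention)
  rows <- list()
  for (kind in kinds) {
    pars <- difference_params(fit, kind,
                              df_convention = policy$df_convention)
    for (pp in p) {
      res <- tdi_upper_bound(
        pars, pp, policy, settings,
        mode = if (kind == "inter") inter_mode else "strict",
        total_params = if (kind == "inter" && inter_mode == "paper_compat")
          list(mu_D = total_pars$mu_D, sigma_D = total_pars$sigma_D))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, p = pp, p1 = res$p1, estimate = res$kappa_hat,
        upper_bound = res$upper_bound, confidence = res$confidence,
        nu = res$nu, N = res$N, df_convention = res$df_convention,
        mode = res$mode, stringsAsFactors = FALSE)
    }
  }
  structure(list(fit = fit, results = do.call(rbind, rows),
                 p = p, confidence = confidence,
                 inter_mode = inter_mode,
                 tol = settings$tol), class = "tdi_analysis")
}

#' @export
print.tdi_analysis <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nTDI estimates and one-sided tolerance-interval upper bounds\n")
  df <- x$results
  df$p1 <- round(df$p1, 6)
  df$estimate <- signif(df$estimate, digits)
  df$upper_bound <- signif(df$upper_bound, digits)
  print(df[, c("kind", "p", "p1", "estimate", "upper_bound", "nu",
               "df_convention", "mode")], row.names = FALSE)
  invisible(x)
}
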