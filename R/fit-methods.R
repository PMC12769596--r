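#' Tidy a fitted MBFD model
#'
#' Coefficient-level summary in the broom convention: one row per fixed
#' effect with estimate, standard error, t-statistic, degrees of freedom and
#' two-sided p-value. For LMM fits the standard errors are model-based and
#' the df are Satterthwaite; for GEE fits choose the robust sandwich
#' (default), Mancl-DeRouen corrected, or model-based variance, with
#' `df = n_clusters - p`.
#'
#' @param x An `mbfd_fit`.
#' @param variance For GEE fits: `"robust"`, `"md"` or `"model"`. Ignored for
#'   LMM fits.
#' @param reference For GEE fits, the reference distribution (see
#'   [gee_test()]): under the default `"canonical"`, sandwich and model-based
#'   tests use the asymptotic normal (`df = Inf`) and Mancl-DeRouen tests use
#'   t with `n_clusters - p` df.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `df`, `p.value`.
#' @method tidy mbfd_fit
#' @export
tidy.mbfd_fit <- function(x, variance = c("robust", "md", "model"),
                          reference = c("canonical", "n-p", "normal"), ...) {
  variance <- match.arg(variance)
  reference <- match.arg(reference)
  if (x$estimator == "gee") {
    v <- switch(variance, robust = x$vcov_robust, md = x$vcov_md, model = x$vcov)
    df <- rep(gee_reference_df(x, variance, reference), x$p)
  } else {
    v <- x$vcov
    df <- unname(x$df)
  }
  se <- sqrt(diag(v))
  stat <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(stat),
    df = df,
    p.value = unname(2 * pt(-abs(stat), df))
  )
}

#' Glance at a fitted MBFD model
#'
#' @param x An `mbfd_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit-level summaries: sample sizes, the
#'   estimator, variance components (LMM) or working correlation and scale
#'   (GEE), and convergence information.
#' @method glance mbfd_fit
#' @export
glance.mbfd_fit <- function(x, ...) {
  out <- tibble::tibble(
    estimator = x$estimator, model = x$model,
    n_participants = x$n_clusters, nobs = x$n_obs, p = x$p,
    converged = x$converged
  )
  if (x$estimator == "lmm") {
    out$tau2 <- x$tau2
    out$sigma2 <- x$sigma2
    out$icc <- x$tau2 / (x$tau2 + x$sigma2)
    out$reml_loglik <- x$reml_loglik
  } else {
    out$alpha_work <- x$alpha_work
    out$phi <- x$phi
    out$iterations <- x$iterations
  }
  out
}

#' @export
print.mbfd_fit <- function(x, ...) {
  cat(sprintf(
    "<mbfd_fit> %s, model %s: %d participants, %d observations\n",
    toupper(x$estimator), x$model, x$n_clusters, x$n_obs
  ))
  if (x$estimator == "lmm") {
    cat(sprintf("  tau^2 = %.4g, sigma^2 = %.4g (ICC = %.3f)\n",
                x$tau2, x$sigma2, x$tau2 / (x$tau2 + x$sigma2)))
    print(as.data.frame(tidy(x)), row.names = FALSE, digits = 4)
  } else {
    cat(sprintf("  working correlation = %.4f, scale = %.4g\n", x$alpha_work, x$phi))
    rob <- tidy(x, variance = "robust")
    md <- tidy(x, variance = "md")
    rob$std.error.md <- md$std.error
    rob$p.value.md <- md$p.value
    print(as.data.frame(rob), row.names = FALSE, digits = 4)
  }
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Estimates, standard errors (all available variance flavours), degrees of
#' freedom, p-values and convergence metadata, as a JSON string.
#'
#' @param fit An `mbfd_fit`.
#' @return A JSON string.
#' @export
fit_to_json <- function(fit) {
  payload <- list(
    estimator = fit$estimator, model = fit$model,
    n_participants = fit$n_clusters, n_obs = fit$n_obs,
    converged = fit$converged,
    coefficients = as.list(fit$coefficients),
    df = as.list(fit$df)
  )
  if (fit$estimator == "lmm") {
    payload$tau2 <- fit$tau2
    payload$sigma2 <- fit$sigma2
    payload$se <- as.list(setNames(sqrt(diag(fit$vcov)), names(fit$coefficients)))
  } else {
    payload$alpha_work <- fit$alpha_work
    payload$phi <- fit$phi
    payload$se_robust <- as.list(setNames(sqrt(diag(fit$vcov_robust)), names(fit$coefficients)))
    payload$se_md <- as.list(setNames(sqrt(diag(fit$vcov_md)), names(fit$coefficients)))
  }
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
}
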