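# Identity-link Gaussian GEE with an exchangeable working correlation.
#
# For R(alpha) = (1 - alpha) I + alpha 11' the inverse is
# 1/(1-alpha) [I - alpha/(1 - alpha + n_i alpha) 11'], so the estimating
# equations again reduce to cluster sums; moment updates of the scale and the
# common within-cluster correlation alternate with weighted least squares for
# the coefficients until the coefficients stabilize.

# One GLS step at a fixed working correlation alpha (the 1/(1-alpha) factor
# cancels in beta, kept for the information matrix).
gee_beta_step <- function(cs, alpha) {
  c_i <- alpha / (1 - alpha + cs$n_i * alpha)
  a <- (cs$xtx - crossprod(cs$s, cs$s * c_i)) / (1 - alpha)
  b <- (cs$xty - colSums(cs$s * (c_i * cs$sy))) / (1 - alpha)
  list(beta = solve(a, b), a = a, c_i = c_i)
}

#' Fit a model by generalized estimating equations
#'
#' Identity-link Gaussian GEE with exchangeable working correlation for the
#' three MBFD analysis models. Starting from ordinary least squares, the
#' algorithm alternates (i) weighted estimating equations for the
#' coefficients at the current working correlation with (ii) moment
#' estimation of the scale `phi` (Pearson residuals, denominator
#' `sum(n_i) - p`) and of the exchangeable correlation `alpha_work` (all
#' within-cluster pairs, denominator `n_pairs - p`), until the max absolute
#' coefficient change is below `1e-8` or 50 iterations. Both the model-based
#' and the Liang-Zeger robust (sandwich) covariance are returned, together
#' with the Mancl-DeRouen bias-corrected sandwich (see [md_variance()]).
#'
#' @param data Trial data (`mbfd_trial` columns).
#' @param model Model id: 1, 2 or 3.
#' @param working_corr Optional fixed working correlation in
#'   `(-1/(max n_i - 1), 1)`. When supplied, no moment updating is done — the
#'   fit is one GLS solve at that correlation (`0` reproduces ordinary least
#'   squares exactly). Intended for testing and for sensitivity analyses.
#' @return An `mbfd_fit` with `vcov` (model-based), `vcov_robust`,
#'   `vcov_md`, the working correlation `alpha_work`, scale `phi`, and
#'   convergence metadata. Degrees of freedom for t-tests are
#'   `n_clusters - p` (see [gee_test()]).
#' @examples
#' d <- mbfd_design()
#' dat <- simulate_trial(d, randomize(d, 30, 1),
#'   effect_parameters(beta_a = 0.8, beta_b = 0.8, beta_c = 1.6),
#'   variance_components(icc = 0.1), seed = 7
#' )
#' tidy(fit_gee(dat, model = 1), variance = "md")
#' @export
fit_gee <- function(data, model, working_corr = NULL) {
  mm <- mbfd_model_matrix(data, model)
  fit_gee_matrix(mm$x, mm$y, mm$id, model, working_corr = working_corr)
}

fit_gee_matrix <- function(x, y, id, model = NA_integer_, working_corr = NULL) {
  cs <- cluster_stats(x, y, id)
  if (qr(cs$xtx)$rank < cs$p) {
    abort(paste0(
      "Design matrix is rank deficient; collinear columns among: ",
      paste(colnames(x), collapse = ", ")
    ))
  }
  if (cs$n_clusters < cs$p + 1L) {
    abort("GEE needs more participants than model parameters.")
  }
  lower <- -1 / (max(cs$n_i) - 1)
  n_pairs <- sum(cs$n_i * (cs$n_i - 1)) / 2

  moment_estimates <- function(beta) {
    r <- cs$y - cs$x %*% beta
    t_i <- rowsum(as.numeric(r), cs$f, reorder = FALSE)[, 1]
    ssr_i <- rowsum(as.numeric(r)^2, cs$f, reorder = FALSE)[, 1]
    phi <- sum(ssr_i) / (cs$n_obs - cs$p)
    pair_sum <- sum(t_i^2 - ssr_i) / 2
    alpha <- pair_sum / ((n_pairs - cs$p) * phi)
    list(phi = phi, alpha = alpha)
  }

  fixed <- !is.null(working_corr)
  alpha <- if (fixed) working_corr else 0
  if (fixed && (alpha <= lower || alpha >= 1)) {
    abort("`working_corr` must lie in (-1/(max cluster size - 1), 1).")
  }
  beta <- gee_beta_step(cs, alpha)$beta
  converged <- fixed
  iter <- 1L
  if (!fixed) {
    for (iter in seq_len(50L)) {
      mom <- moment_estimates(beta)
      alpha <- mom$alpha
      if (alpha <= lower + 1e-8 || alpha >= 1 - 1e-8) {
        warn("Estimated working correlation outside its valid range; clipped.")
        alpha <- min(max(alpha, lower + 1e-6), 1 - 1e-6)
      }
      step <- gee_beta_step(cs, alpha)
      if (max(abs(step$beta - beta)) < 1e-8) {
        beta <- step$beta
        converged <- TRUE
        break
      }
      beta <- step$beta
    }
  }
  mom <- moment_estimates(beta)
  phi <- mom$phi
  step <- gee_beta_step(cs, alpha)

  # Bread A = sum_i X_i' V_i^{-1} X_i with V_i = phi R(alpha); meat from the
  # empirical cluster scores g_i = X_i' V_i^{-1} r_i.
  a_inv_corr <- solve(step$a) # inverse of sum X' R^{-1} X
  r <- as.numeric(cs$y - cs$x %*% beta)
  xr <- rowsum(cs$x * r, cs$f, reorder = FALSE) # per-cluster X_i' r_i
  t_i <- rowsum(r, cs$f, reorder = FALSE)[, 1]
  g <- (xr - cs$s * (step$c_i * t_i)) / (1 - alpha) # per-cluster X_i' R^{-1} r_i
  meat <- crossprod(g)
  vcov_model <- phi * a_inv_corr
  vcov_robust <- a_inv_corr %*% meat %*% a_inv_corr
  vcov_robust <- (vcov_robust + t(vcov_robust)) / 2

  beta <- setNames(as.numeric(beta), colnames(x))
  dimnames(vcov_model) <- dimnames(vcov_robust) <- list(colnames(x), colnames(x))

  fit <- structure(
    list(
      estimator = "gee", model = model,
      coefficients = beta, vcov = vcov_model, vcov_robust = vcov_robust,
      alpha_work = alpha, phi = phi,
      n_clusters = cs$n_clusters, n_obs = cs$n_obs, p = cs$p,
      df = setNames(rep(cs$n_clusters - cs$p, cs$p), colnames(x)),
      converged = converged, iterations = iter,
      cluster_stats = cs, residuals = r
    ),
    class = "mbfd_fit"
  )
  fit$vcov_md <- md_variance(fit)
  fit
}

#' Mancl-DeRouen bias-corrected sandwich covariance
#'
#' Small-sample correction of the robust sandwich: each cluster's residual
#' vector is pre-multiplied by the inverse of `I - H_i`, where
#' `H_i = X_i A^{-1} X_i' V_i^{-1}` is the cluster leverage
#' (`A = sum_i X_i' V_i^{-1} X_i`), before forming the meat. This offsets the
#' downward bias of raw residual cross-products and inflates the standard
#' errors when the number of clusters is small.
#'
#' @param fit A converged GEE `mbfd_fit`.
#' @return The corrected covariance matrix (symmetric, positive
#'   semi-definite). Also stored on GEE fits as `vcov_md`.
#' @export
md_variance <- function(fit) {
  stopifnot(inherits(fit, "mbfd_fit"), fit$estimator == "gee")
  if (!fit$converged) abort("Mancl-DeRouen correction requires a converged fit.")
  cs <- fit$cluster_stats
  alpha <- fit$alpha_work
  phi <- fit$phi
  step <- gee_beta_step(cs, alpha)
  a_inv_corr <- solve(step$a) # (sum X' R^{-1} X)^{-1}
  r <- fit$residuals
  idx <- split(seq_len(cs$n_obs), cs$f)
  meat <- matrix(0, cs$p, cs$p)
  for (ci in seq_along(idx)) {
    rows <- idx[[ci]]
    n_i <- length(rows)
    x_i <- cs$x[rows, , drop = FALSE]
    r_corr <- (diag(n_i) - alpha / (1 - alpha + n_i * alpha) *
      matrix(1, n_i, n_i)) / (1 - alpha) # R(alpha)^{-1}
    h_i <- x_i %*% a_inv_corr %*% t(x_i) %*% r_corr # leverage (phi cancels)
    adj <- tryCatch(solve(diag(n_i) - h_i, r[rows]), error = function(e) {
      abort(sprintf("Mancl-DeRouen correction: (I - H) singular for cluster %s.",
                    levels(cs$f)[ci]))
    })
    g_i <- crossprod(x_i, r_corr %*% adj)
    meat <- meat + tcrossprod(g_i)
  }
  v <- a_inv_corr %*% meat %*% a_inv_corr
  v <- (v + t(v)) / 2
  dimnames(v) <- dimnames(fit$vcov)
  v
}

# Reference distribution for each variance flavour under "canonical":
# the uncorrected sandwich is an asymptotic estimator and is tested against
# the normal (df = Inf), as classic GEE software reports; the small-sample
# Mancl-DeRouen correction is paired with t and df = N - p, as its source
# recommends.
gee_reference_df <- function(fit, variance, reference) {
  switch(reference,
    canonical = if (variance == "md") fit$n_clusters - fit$p else Inf,
    `n-p` = fit$n_clusters - fit$p,
    normal = Inf
  )
}

#' Wald test for a contrast from a GEE fit
#'
#' Two-sided Wald test of `c' beta = 0` using the requested variance (robust
#' sandwich or Mancl-DeRouen corrected). With the default
#' `reference = "canonical"`, the uncorrected sandwich statistic is referred
#' to the asymptotic normal distribution (the convention of standard GEE
#' software output), while the Mancl-DeRouen statistic is referred to a t
#' distribution with `n_clusters - p` degrees of freedom (the convention
#' recommended with that correction). `reference = "n-p"` forces the t
#' reference for either variance; `reference = "normal"` forces the normal.
#'
#' @param fit A converged GEE `mbfd_fit`.
#' @param contrast Numeric vector in coefficient space.
#' @param variance `"robust"` or `"md"`.
#' @param reference `"canonical"`, `"n-p"` or `"normal"`.
#' @return A one-row tibble: `estimate`, `std.error`, `statistic`, `df`
#'   (`Inf` for the normal reference), `p.value`.
#' @export
gee_test <- function(fit, contrast, variance = c("robust", "md"),
                     reference = c("canonical", "n-p", "normal")) {
  stopifnot(inherits(fit, "mbfd_fit"), fit$estimator == "gee")
  variance <- match.arg(variance)
  reference <- match.arg(reference)
  cc <- as.numeric(contrast)
  if (length(cc) != fit$p) abort("`contrast` must have one entry per coefficient.")
  if (fit$n_clusters - fit$p <= 0) {
    abort("Non-positive degrees of freedom (too few participants).")
  }
  df <- gee_reference_df(fit, variance, reference)
  v <- if (variance == "md") fit$vcov_md else fit$vcov_robust
  est <- sum(cc * fit$coefficients)
  se <- sqrt(drop(t(cc) %*% v %*% cc))
  stat <- est / se
  tibble::tibble(
    estimate = est, std.error = se, statistic = stat,
    df = df, p.value = 2 * pt(-abs(stat), df)
  )
}
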