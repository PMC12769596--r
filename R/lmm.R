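# Random-intercept LMM by profiled REML.
#
# For V_i = sigma^2 (I + gamma 11') with gamma = tau^2/sigma^2, the
# Sherman-Morrison identity gives V_i^{-1} proportional to
# I - gamma/(1 + n_i gamma) 11', so for fixed gamma the GLS coefficients and
# the profiled sigma^2 are closed-form in the cluster sums; REML reduces to a
# one-dimensional search over gamma.

# Pieces of the restricted likelihood at a fixed variance ratio gamma:
# "a" is sigma^2 X'V^{-1}X, "b" is sigma^2 X'V^{-1}y, "q" the weighted RSS.
reml_pieces <- function(cs, gamma) {
  c_i <- gamma / (1 + cs$n_i * gamma)
  a <- cs$xtx - crossprod(cs$s, cs$s * c_i)
  b <- cs$xty - colSums(cs$s * (c_i * cs$sy))
  beta <- solve(a, b)
  ywy <- cs$yty - sum(c_i * cs$sy^2)
  q <- ywy - sum(beta * b) # (y - Xb)' W (y - Xb) at the GLS minimiser
  list(a = a, beta = beta, q = q, c_i = c_i)
}

# -2 * restricted log-likelihood, profiled over beta and sigma^2 (constant
# terms dropped).
reml_profiled_dev <- function(cs, gamma) {
  pc <- reml_pieces(cs, gamma)
  dfree <- cs$n_obs - cs$p
  # q can round to <= 0 on noise-free data; floor keeps the criterion finite
  sigma2 <- max(pc$q, 1e-300) / dfree
  dfree * log(sigma2) + sum(log1p(cs$n_i * gamma)) +
    determinant(pc$a, logarithm = TRUE)$modulus[1]
}

# -2 * restricted log-likelihood at theta = (tau2, sigma2), profiled over
# beta only (for the observed REML information used by Satterthwaite).
reml_dev_theta <- function(cs, tau2, sigma2) {
  pc <- reml_pieces(cs, tau2 / sigma2)
  (cs$n_obs - cs$p) * log(sigma2) + sum(log1p(cs$n_i * tau2 / sigma2)) +
    determinant(pc$a, logarithm = TRUE)$modulus[1] + pc$q / sigma2
}

# Observed REML information at theta = (tau2, sigma2): half the numerical
# Hessian (central differences) of the restricted deviance.
reml_information <- function(cs, theta) {
  hs <- pmax(abs(theta), 1e-8) * 1e-4
  dv <- function(th) reml_dev_theta(cs, th[1], th[2])
  hess <- matrix(0, 2, 2)
  f0 <- dv(theta)
  for (a in 1:2) {
    for (b in a:2) {
      if (a == b) {
        tp <- tm <- theta
        tp[a] <- tp[a] + hs[a]
        tm[a] <- tm[a] - hs[a]
        hess[a, a] <- (dv(tp) - 2 * f0 + dv(tm)) / hs[a]^2
      } else {
        tpp <- tpm <- tmp <- tmm <- theta
        tpp[a] <- tpp[a] + hs[a]; tpp[b] <- tpp[b] + hs[b]
        tpm[a] <- tpm[a] + hs[a]; tpm[b] <- tpm[b] - hs[b]
        tmp[a] <- tmp[a] - hs[a]; tmp[b] <- tmp[b] + hs[b]
        tmm[a] <- tmm[a] - hs[a]; tmm[b] <- tmm[b] - hs[b]
        hess[a, b] <- hess[b, a] <-
          (dv(tpp) - dv(tpm) - dv(tmp) + dv(tmm)) / (4 * hs[a] * hs[b])
      }
    }
  }
  hess / 2
}

#' Fit a random-intercept linear mixed model by REML
#'
#' Fits one of the three MBFD analysis models with a participant-level random
#' intercept by restricted maximum likelihood. The compound-symmetry
#' structure is exploited: for a fixed variance ratio the coefficients and
#' residual variance are closed-form, and REML is a one-dimensional
#' optimization over the ratio, with the boundary (zero random-intercept
#' variance) permitted. Wald t-tests use Satterthwaite degrees of freedom
#' (see [satterthwaite_df()]).
#'
#' @param data Trial data (`mbfd_trial` columns).
#' @param model Model id: 1, 2 or 3.
#' @return An object of class `mbfd_fit` with coefficient estimates, their
#'   model-based covariance, per-coefficient Satterthwaite df, the variance
#'   components `tau2` and `sigma2`, the REML log-likelihood (up to an
#'   additive constant), and convergence metadata. Use [tidy()] for the
#'   coefficient table.
#' @examples
#' d <- mbfd_design()
#' dat <- simulate_trial(d, randomize(d, 30, 1),
#'   effect_parameters(beta_a = 0.8, beta_b = 0.8, beta_c = 1.6),
#'   variance_components(icc = 0.1), seed = 7
#' )
#' tidy(fit_lmm(dat, model = 1))
#' @export
fit_lmm <- function(data, model) {
  mm <- mbfd_model_matrix(data, model)
  fit_lmm_matrix(mm$x, mm$y, mm$id, model)
}

# Matrix-level fitter (also the fast path for the simulation engine).
fit_lmm_matrix <- function(x, y, id, model = NA_integer_) {
  cs <- cluster_stats(x, y, id)
  if (qr(cs$xtx)$rank < cs$p) {
    abort(paste0(
      "Design matrix is rank deficient; collinear columns among: ",
      paste(colnames(x), collapse = ", ")
    ))
  }
  if (cs$n_clusters < 2L) abort("At least two participants are required.")

  # Optimize the profiled REML deviance over log(gamma), and compare with the
  # independence boundary gamma = 0.
  obj <- function(u) reml_profiled_dev(cs, exp(u))
  opt <- optimise(obj, c(-16, 8), tol = 1e-12)
  dev0 <- reml_profiled_dev(cs, 0)
  if (dev0 <= opt$objective) {
    gamma <- 0
    dev <- dev0
  } else {
    gamma <- exp(opt$minimum)
    dev <- opt$objective
  }
  pc <- reml_pieces(cs, gamma)
  dfree <- cs$n_obs - cs$p
  sigma2 <- max(pc$q, 1e-300) / dfree
  tau2 <- gamma * sigma2
  vcov <- sigma2 * solve(pc$a)
  beta <- pc$beta
  names(beta) <- colnames(x)
  dimnames(vcov) <- list(colnames(x), colnames(x))

  fit <- structure(
    list(
      estimator = "lmm", model = model,
      coefficients = beta, vcov = vcov,
      tau2 = tau2, sigma2 = sigma2, gamma = gamma,
      reml_loglik = -dev / 2,
      n_clusters = cs$n_clusters, n_obs = cs$n_obs, p = cs$p,
      converged = TRUE, iterations = NA_integer_,
      df_fallback = FALSE,
      cluster_stats = cs
    ),
    class = "mbfd_fit"
  )
  # near-interpolation (noise-free data) leaves no curvature to estimate the
  # variance-component uncertainty from; flag it and use residual df instead
  fit$degenerate <- sigma2 + tau2 < 1e-10 * max(cs$yty / cs$n_obs, 1e-8)
  if (!fit$degenerate && tau2 > 1e-10 * sigma2) {
    fit$reml_info <- tryCatch(reml_information(cs, c(tau2, sigma2)),
      error = function(e) NULL
    )
  }
  dfs <- lapply(seq_len(cs$p), function(k) {
    e <- rep(0, cs$p)
    e[k] <- 1
    satterthwaite_df(fit, e)
  })
  fit$df_fallback <- any(vapply(dfs, function(d) isTRUE(attr(d, "fallback")), logical(1)))
  fit$df <- setNames(vapply(dfs, as.numeric, numeric(1)), colnames(x))
  fit
}

#' Satterthwaite degrees of freedom for a contrast
#'
#' Moment-matching approximate df for the Wald t-statistic of a contrast
#' `c' beta`: `df = 2 (c' V c)^2 / Var(c' V c)`, where `V` is the model-based
#' coefficient covariance as a function of the variance components
#' `theta = (tau^2, sigma^2)`. The variance of `c' V c` is obtained by the
#' delta method: a central finite-difference gradient (relative step 1e-5)
#' combined with the inverse observed REML information (numerical Hessian of
#' the restricted deviance). The result is clamped to `[1, n_obs - p]`. At
#' the boundary `tau^2 = 0`, or if the information matrix is numerically
#' singular, the residual-based fallback `n_clusters - p` / `n_obs - p`
#' convention applies (flagged via a warning and the fit's `df_fallback`).
#'
#' @param fit An LMM `mbfd_fit`.
#' @param contrast Numeric vector in coefficient space.
#' @return Approximate degrees of freedom (scalar).
#' @export
satterthwaite_df <- function(fit, contrast) {
  stopifnot(inherits(fit, "mbfd_fit"), fit$estimator == "lmm")
  cs <- fit$cluster_stats
  cc <- as.numeric(contrast)
  if (length(cc) != fit$p) abort("`contrast` must have one entry per coefficient.")
  upper <- fit$n_obs - fit$p
  theta <- c(fit$tau2, fit$sigma2)
  if (isTRUE(fit$degenerate) || theta[1] <= 1e-10 * theta[2]) {
    return(upper) # independence boundary or interpolation: residual df
  }
  fvar <- function(th) {
    pcs <- reml_pieces(cs, th[1] / th[2])
    th[2] * sum(cc * solve(pcs$a, cc))
  }
  h <- pmax(abs(theta), 1e-8) * 1e-5
  grad <- vapply(1:2, function(k) {
    tp <- tm <- theta
    tp[k] <- tp[k] + h[k]
    tm[k] <- tm[k] - h[k]
    (fvar(tp) - fvar(tm)) / (2 * h[k])
  }, numeric(1))
  info <- fit$reml_info %||% reml_information(cs, theta)
  vtheta <- tryCatch(solve(info), error = function(e) NULL)
  fc <- fvar(theta)
  fallback <- fit$n_clusters - fit$p # matches the GEE df convention
  if (is.null(vtheta) || any(diag(vtheta) < 0)) {
    warn("Singular REML information; using the cluster-based fallback df.")
    return(structure(fallback, fallback = TRUE))
  }
  denom <- drop(t(grad) %*% vtheta %*% grad)
  if (denom <= 0) {
    warn("Non-positive Satterthwaite denominator; using the fallback df.")
    return(structure(fallback, fallback = TRUE))
  }
  min(max(2 * fc^2 / denom, 1), upper)
}
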