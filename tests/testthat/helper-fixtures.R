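# Shared fixtures: all simulated in code at test time.

std_design <- mbfd_design()

make_trial <- function(seed, n = 30, icc = 0.05,
                       effects = effect_parameters(), sigma = 1) {
  al <- randomize(std_design, n, seed = seed)
  simulate_trial(
    std_design, al, effects,
    variance_components(icc = icc, sigma = sigma),
    seed = seed
  )
}

# Brute-force REML oracle: numerically maximize the restricted multivariate
# normal log-likelihood over (log tau2, log sigma2) with a generic optimizer,
# forming each cluster's covariance matrix explicitly. Independent of the
# package's profiled solver.
bruteforce_reml <- function(data, model) {
  mm <- mbfd_model_matrix(data, model)
  x <- mm$x
  y <- mm$y
  ids <- unique(mm$id)
  idx <- split(seq_along(mm$id), factor(mm$id, levels = ids))
  p <- ncol(x)
  m <- length(y)
  negll <- function(par) {
    tau2 <- exp(par[1])
    sigma2 <- exp(par[2])
    a <- matrix(0, p, p)
    b <- numeric(p)
    logdet_v <- 0
    quad <- 0
    pieces <- lapply(idx, function(rows) {
      v <- diag(sigma2, length(rows)) + tau2
      vi <- solve(v)
      list(rows = rows, vi = vi, ld = determinant(v, logarithm = TRUE)$modulus[1])
    })
    for (pc in pieces) {
      xi <- x[pc$rows, , drop = FALSE]
      yi <- y[pc$rows]
      a <- a + t(xi) %*% pc$vi %*% xi
      b <- b + t(xi) %*% pc$vi %*% yi
      logdet_v <- logdet_v + pc$ld
    }
    beta <- solve(a, b)
    for (pc in pieces) {
      ri <- y[pc$rows] - x[pc$rows, , drop = FALSE] %*% beta
      quad <- quad + t(ri) %*% pc$vi %*% ri
    }
    0.5 * (logdet_v + determinant(a, logarithm = TRUE)$modulus[1] + drop(quad))
  }
  opt <- optim(c(log(0.1), log(1)), negll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  tau2 <- exp(opt$par[1])
  sigma2 <- exp(opt$par[2])
  # recover beta at the optimum
  a <- matrix(0, p, p)
  b <- numeric(p)
  for (rows in idx) {
    vi <- solve(diag(sigma2, length(rows)) + tau2)
    xi <- x[rows, , drop = FALSE]
    a <- a + t(xi) %*% vi %*% xi
    b <- b + t(xi) %*% vi %*% y[rows]
  }
  list(
    beta = drop(solve(a, b)), tau2 = tau2, sigma2 = sigma2,
    restricted_loglik = -opt$value
  )
}

# Closed-form GLS oracle at a known compound-symmetric covariance.
gls_oracle <- function(data, model, tau2, sigma2) {
  mm <- mbfd_model_matrix(data, model)
  ids <- unique(mm$id)
  idx <- split(seq_along(mm$id), factor(mm$id, levels = ids))
  p <- ncol(mm$x)
  a <- matrix(0, p, p)
  b <- numeric(p)
  for (rows in idx) {
    vi <- solve(diag(sigma2, length(rows)) + tau2)
    xi <- mm$x[rows, , drop = FALSE]
    a <- a + t(xi) %*% vi %*% xi
    b <- b + t(xi) %*% vi %*% mm$y[rows]
  }
  drop(solve(a, b))
}
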