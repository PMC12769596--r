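test_that("design matrices carry the documented column roles", {
  dat <- make_trial(seed = 1, n = 12)
  m1 <- mbfd_model_matrix(dat, 1)
  expect_equal(colnames(m1$x), c("(Intercept)", "period", "beta_a", "beta_b"))
  ctrl <- which(dat$condition[order(dat$participant_id, dat$period)] == "C")[1]
  expect_equal(unname(m1$x[ctrl, 3:4]), c(0, 0))
  ab <- which(dat$condition[order(dat$participant_id, dat$period)] == "AB")[1]
  expect_equal(unname(m1$x[ab, 3:4]), c(1, 1))

  m2 <- mbfd_model_matrix(dat, 2)
  expect_equal(ncol(m2$x), 5L)
  expect_equal(unname(m2$x[, "beta_i"]), unname(m2$x[, "beta_a"] * m2$x[, "beta_b"]))

  m3 <- mbfd_model_matrix(dat, 3)
  expect_equal(unname(m3$x[ab, 3:5]), c(0, 0, 1))
  expect_true(all(rowSums(m3$x[, 3:5]) <= 1))
  expect_error(mbfd_model_matrix(dat, 4), "1, 2 or 3")
})

test_that("noise-free data are interpolated exactly", {
  d <- mbfd_design()
  al <- randomize(d, 12, seed = 2)
  eff <- effect_parameters(u = 0.3, beta_t = 0.7, beta_a = 0.8, beta_b = 0.5, beta_c = 1.6)
  dat <- simulate_trial(d, al, eff, variance_components(tau = 0, sigma = 1e-12), seed = 2)
  fit <- fit_lmm(dat, 3)
  expect_equal(
    unname(coef <- fit$coefficients),
    c(0.3, 0.7, 0.8, 0.5, 1.6),
    tolerance = 1e-6
  )
  expect_lt(fit$sigma2, 1e-12)
})

test_that("profiled REML matches the brute-force restricted-likelihood oracle", {
  for (seed in 1:20) {
    dat <- make_trial(
      seed = seed, n = 18,
      icc = c(0.05, 0.10, 0.30)[1 + seed %% 3],
      effects = effect_parameters(beta_a = 0.4, beta_b = 0.2, beta_c = 0.9)
    )
    model <- 1 + seed %% 3
    fit <- fit_lmm(dat, model)
    oracle <- bruteforce_reml(dat, model)
    expect_lt(max(abs(fit$coefficients - oracle$beta)), 1e-6)
    expect_equal(fit$tau2, oracle$tau2, tolerance = 1e-4)
    expect_equal(fit$sigma2, oracle$sigma2, tolerance = 1e-4)
    # compare the restricted log-likelihood at each solution (same constant)
    dev_own <- mbfd:::reml_dev_theta(fit$cluster_stats, fit$tau2, fit$sigma2)
    dev_oracle <- mbfd:::reml_dev_theta(fit$cluster_stats, oracle$tau2, oracle$sigma2)
    expect_lt(abs(dev_own - dev_oracle) / 2, 1e-6)
    expect_lte(dev_own, dev_oracle + 1e-8)
  }
})

test_that("REML at the independence boundary reduces to ordinary least squares", {
  # tau = 0 generator: REML usually lands on the boundary; compare with OLS
  d <- mbfd_design()
  al <- randomize(d, 30, seed = 3)
  dat <- simulate_trial(
    d, al, effect_parameters(beta_a = 0.4),
    variance_components(tau = 0, sigma = 1), seed = 33
  )
  fit <- fit_lmm(dat, 1)
  if (fit$tau2 < 1e-8) {
    ols <- lm(y ~ period + x_a + x_b, data = dat)
    expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-6)
    expect_equal(unname(fit$df), rep(150 - 4, 4))
  } else {
    # sampling noise put the REML optimum in the interior; df must stay clamped
    expect_true(all(fit$df <= 150 - 4))
  }
})

test_that("estimates, variance components and Satterthwaite df match lmerTest", {
  skip_if_not_installed("lmerTest")
  forms <- list(
    "1" = y ~ period + x_a + x_b + (1 | participant_id),
    "2" = y ~ period + x_a * x_b + (1 | participant_id),
    "3" = y ~ period + z_a + z_b + z_c + (1 | participant_id)
  )
  for (seed in c(4, 9, 21)) {
    for (model in 1:3) {
      dat <- make_trial(
        seed = seed, icc = 0.10,
        effects = effect_parameters(beta_a = 0.8, beta_b = 0.8, beta_c = 2.0)
      )
      fit <- fit_lmm(dat, model)
      ref <- lmerTest::lmer(forms[[as.character(model)]], data = dat, REML = TRUE)
      sm <- summary(ref)$coefficients
      # lmerTest orders the interaction column last as we do
      expect_equal(unname(fit$coefficients), unname(sm[, "Estimate"]), tolerance = 1e-5)
      expect_equal(
        unname(sqrt(diag(fit$vcov))), unname(sm[, "Std. Error"]),
        tolerance = 1e-5
      )
      expect_equal(unname(fit$df), unname(sm[, "df"]), tolerance = 0.02)
      vc <- as.data.frame(lme4::VarCorr(ref))
      expect_equal(fit$tau2, vc$vcov[1], tolerance = 1e-4)
      expect_equal(fit$sigma2, vc$vcov[2], tolerance = 1e-4)
    }
  }
})

test_that("Satterthwaite df agree with a Richardson-extrapolated oracle", {
  dat <- make_trial(seed = 7, icc = 0.10, effects = effect_parameters(beta_a = 0.8))
  fit <- fit_lmm(dat, 1)
  cs <- fit$cluster_stats
  theta <- c(fit$tau2, fit$sigma2)
  info <- mbfd:::reml_information(cs, theta)
  vtheta <- solve(info)
  fvar <- function(th, cc) {
    pcs <- mbfd:::reml_pieces(cs, th[1] / th[2])
    th[2] * sum(cc * solve(pcs$a, cc))
  }
  for (k in seq_len(fit$p)) {
    cc <- replace(rep(0, fit$p), k, 1)
    # central differences at two step sizes + Richardson extrapolation
    grad_at <- function(h_scale) {
      vapply(1:2, function(j) {
        h <- abs(theta[j]) * h_scale
        tp <- tm <- theta
        tp[j] <- tp[j] + h
        tm[j] <- tm[j] - h
        (fvar(tp, cc) - fvar(tm, cc)) / (2 * h)
      }, numeric(1))
    }
    g1 <- grad_at(1e-4)
    g2 <- grad_at(5e-5)
    grad <- (4 * g2 - g1) / 3
    df_oracle <- 2 * fvar(theta, cc)^2 / drop(t(grad) %*% vtheta %*% grad)
    df_oracle <- min(max(df_oracle, 1), fit$n_obs - fit$p)
    expect_equal(unname(fit$df[k]), df_oracle, tolerance = 0.02)
  }
})

test_that("fits are invariant to participant ordering and flag rank deficiency", {
  dat <- make_trial(seed = 10, effects = effect_parameters(beta_a = 0.6))
  fit <- fit_lmm(dat, 1)
  perm <- dat[order(rev(dat$participant_id), dat$period), ]
  fit_perm <- fit_lmm(perm, 1)
  expect_equal(fit$coefficients, fit_perm$coefficients, tolerance = 1e-10)
  expect_equal(fit$vcov, fit_perm$vcov, tolerance = 1e-10)
  expect_equal(fit$df, fit_perm$df, tolerance = 1e-6)

  dup <- dat
  dup$z_a <- dup$x_a # makes model-3 columns collinear with x-style columns
  mm <- mbfd_model_matrix(dat, 1)
  x_bad <- cbind(mm$x, beta_dup = mm$x[, "beta_a"])
  expect_error(mbfd:::fit_lmm_matrix(x_bad, mm$y, mm$id, 1), "rank deficient")
})
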