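test_that("hypothesis sets split the family-wise level exactly", {
  h1 <- hypothesis_set(1)
  expect_equal(h1$terms, c("beta_a", "beta_b"))
  expect_equal(h1$adjusted_level * length(h1$terms), 0.05)
  h2 <- hypothesis_set(2)
  expect_equal(h2$terms, c("beta_a", "beta_b", "beta_i"))
  expect_equal(h2$adjusted_level, 0.05 / 3)
  expect_equal(hypothesis_set(3)$terms, c("beta_a", "beta_b", "beta_c"))
})

test_that("replicates are deterministic and match the public simulate/fit pipeline", {
  cfg <- scenario_config(
    n = 30, icc = 0.10,
    effects = effect_parameters(beta_a = 0.8, beta_b = 0.8, beta_c = 1.6),
    model = 1, n_sim = 10, seed = 77
  )
  r1 <- run_replicate(cfg, 4)
  r2 <- run_replicate(cfg, 4)
  expect_identical(r1, r2)

  # the engine's fast path must reproduce randomize() + simulate_trial() +
  # fit_lmm()/fit_gee() exactly
  r_seed <- mbfd:::derive_seed(77L, 4L)
  al <- randomize(mbfd_design(), 30, seed = r_seed)
  dat <- simulate_trial(
    mbfd_design(), al, cfg$effects, cfg$variance,
    seed = r_seed
  )
  lt <- tidy(fit_lmm(dat, 1))
  keep <- lt$term %in% c("beta_a", "beta_b")
  expect_equal(r1$estimate[r1$estimator == "lmm"], lt$estimate[keep], tolerance = 1e-12)
  expect_equal(r1$p.value[r1$estimator == "lmm"], lt$p.value[keep], tolerance = 1e-12)
  gt <- tidy(fit_gee(dat, 1), variance = "md")
  expect_equal(r1$std.error[r1$estimator == "gee-md"], gt$std.error[keep], tolerance = 1e-12)
})

test_that("scenario aggregation recovers estimates near the generating values", {
  cfg <- scenario_config(
    n = 30, icc = 0.05,
    effects = effect_parameters(beta_a = 0.8, beta_b = 0.8, beta_c = 1.6),
    model = 3, estimators = "lmm", n_sim = 150, seed = 5
  )
  res <- run_scenario(cfg)
  tab <- tidy(res)
  expect_equal(tab$term, c("beta_a", "beta_b", "beta_c"))
  # unbiased under the correctly specified multi-arm model: within 3 MC SEs
  expect_true(all(abs(tab$bias) < 3.2 * tab$estimate_mcse))
  expect_true(all(tab$reject_rate >= 0 & tab$reject_rate <= 1))
  expect_equal(
    tab$reject_mcse,
    sqrt(tab$reject_rate * (1 - tab$reject_rate) / tab$n_used)
  )
  # disjunctive rate can only exceed any single per-coefficient rate
  expect_gte(res$disjunctive$disjunctive_rate, max(tab$reject_rate) - 1e-12)
  expect_equal(glance(res)$n_sim, 150)
})

test_that("combined-effect contrasts agree across model parameterizations", {
  dat <- make_trial(
    seed = 9,
    effects = effect_parameters(beta_a = 0.8, beta_b = 0.8, beta_c = 2.0)
  )
  f1 <- fit_lmm(dat, 1)
  f2 <- fit_lmm(dat, 2)
  f3 <- fit_lmm(dat, 3)
  c1 <- combined_effect(f1)
  c2 <- combined_effect(f2)
  c3 <- combined_effect(f3)
  expect_equal(c2$estimate, sum(f2$coefficients[c("beta_a", "beta_b", "beta_i")]))
  expect_equal(c3$estimate, unname(f3$coefficients["beta_c"]))
  expect_equal(c1$estimate, sum(f1$coefficients[c("beta_a", "beta_b")]))

  # noise-free additive data: model 2's interaction vanishes and the combined
  # estimates coincide
  d <- mbfd_design()
  al <- randomize(d, 12, seed = 2)
  clean <- simulate_trial(
    d, al, effect_parameters(beta_a = 0.8, beta_b = 0.8, beta_c = 1.6),
    variance_components(tau = 0, sigma = 1e-12), seed = 3
  )
  g1 <- fit_lmm(clean, 1)
  g2 <- fit_lmm(clean, 2)
  expect_equal(unname(g2$coefficients["beta_i"]), 0, tolerance = 1e-6)
  expect_equal(combined_effect(g1)$estimate, combined_effect(g2)$estimate,
    tolerance = 1e-6
  )
})

test_that("misspecifying the additive model under interaction biases the main effects", {
  # interaction generator: model 1 absorbs ~half the interaction into each
  # main effect (the documented +0.2 pattern), model 2 stays unbiased
  cfg1 <- scenario_config(
    n = 30, icc = 0.05,
    effects = effect_parameters(beta_a = 0.8, beta_b = 0.8, beta_c = 2.0),
    model = 1, estimators = "lmm", n_sim = 200, seed = 13
  )
  cfg2 <- scenario_config(
    n = 30, icc = 0.05,
    effects = effect_parameters(beta_a = 0.8, beta_b = 0.8, beta_c = 2.0),
    model = 2, estimators = "lmm", n_sim = 200, seed = 13
  )
  t1 <- tidy(run_scenario(cfg1))
  t2 <- tidy(run_scenario(cfg2))
  expect_gt(t1$mean_estimate[t1$term == "beta_a"], 0.9) # biased upward
  expect_lt(abs(t2$bias[t2$term == "beta_a"]), 3.2 * t2$estimate_mcse[t2$term == "beta_a"])
  expect_lt(abs(t2$mean_estimate[t2$term == "beta_i"] - 0.4), 0.1)
})

test_that("power is monotone in sample size and in effect size under common seeds", {
  eff_add <- effect_parameters(beta_a = 0.8, beta_b = 0.8, beta_c = 1.6)
  rates <- vapply(c(30, 120), function(n) {
    cfg <- scenario_config(
      n = n, icc = 0.30, effects = eff_add, model = 2,
      estimators = "lmm", n_sim = 120, seed = 19
    )
    tab <- tidy(run_scenario(cfg))
    tab$reject_rate[tab$term == "beta_a"]
  }, numeric(1))
  expect_gt(rates[2], rates[1])

  # stronger combined effect raises model-3 beta_c power
  r_16 <- tidy(run_scenario(scenario_config(
    n = 30, icc = 0.05, effects = eff_add, model = 3,
    estimators = "lmm", n_sim = 120, seed = 23
  )))
  r_20 <- tidy(run_scenario(scenario_config(
    n = 30, icc = 0.05,
    effects = effect_parameters(beta_a = 0.8, beta_b = 0.8, beta_c = 2.0),
    model = 3, estimators = "lmm", n_sim = 120, seed = 23
  )))
  expect_gte(
    r_20$reject_rate[r_20$term == "beta_c"],
    r_16$reject_rate[r_16$term == "beta_c"]
  )
})

test_that("reproduce_table assembles the full grid with 3-decimal formatting", {
  tab <- reproduce_table(3, n_sim = 4, seed = 2, icc = 0.05, n = 30)
  expect_s3_class(tab$tidy, "tbl_df")
  # 3 models x 3 estimators, 2 or 3 tested coefficients each
  expect_equal(nrow(tab$tidy), 3 * (2 + 3 + 3))
  expect_true(all(grepl("^\\d\\.\\d{3}$", tab$tidy$value |> sprintf(fmt = "%.3f"))))
  expect_true(all(c("icc", "model", "n", "estimator", "term", "value") %in% names(tab$tidy)))
  expect_equal(nrow(tab$formatted), 3)

  t5 <- reproduce_table(5, n_sim = 4, seed = 2, icc = 0.05, n = 30)
  expect_setequal(unique(t5$tidy$estimator), c("lmm", "gee"))
  expect_error(reproduce_table(7), "3, 4, 5, 6")

  path <- withr::local_tempfile(fileext = ".csv")
  write_table_results(tab, path)
  expect_true(file.exists(path))
})

test_that("autoplot methods return ggplot objects", {
  expect_s3_class(autoplot(mbfd_design()), "ggplot")
  cfg <- scenario_config(n = 30, icc = 0.05, model = 1, estimators = "lmm", n_sim = 20, seed = 3)
  expect_s3_class(autoplot(run_scenario(cfg)), "ggplot")
})
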