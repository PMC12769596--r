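#' Specify a Monte Carlo scenario
#'
#' Bundles everything one simulation scenario needs: the design, sample size,
#' variance components, generating effects, the analysis model, the
#' estimators to apply, the replicate count and the master seed. Within a
#' replicate the same simulated dataset is analysed by every requested
#' estimator (common random numbers), and replicate `r` is reproducible in
#' isolation from `(seed, r)`.
#'
#' @param design An [mbfd_design()] grid (default: the standard design).
#' @param n Total participants.
#' @param icc Intraclass correlation of the generating model.
#' @param sigma Residual SD (default 1).
#' @param effects An [effect_parameters()] object (the generating values).
#' @param model Analysis model id: 1, 2 or 3.
#' @param estimators Subset of `c("lmm", "gee", "gee-md")`.
#' @param n_sim Number of Monte Carlo replicates.
#' @param seed Master seed.
#' @param alpha Family-wise level, Bonferroni-split over the model's tested
#'   coefficients (default 0.05).
#' @return A list of class `mbfd_scenario_config`.
#' @export
scenario_config <- function(design = mbfd_design(), n = 30, icc = 0.05,
                            sigma = 1, effects = effect_parameters(),
                            model = 1,
                            estimators = c("lmm", "gee", "gee-md"),
                            n_sim = 5000, seed = 1, alpha = 0.05) {
  validate_mbfd_design(design)
  n <- assert_count(n, "n", min = dplyr::n_distinct(design$sequence))
  n_sim <- assert_count(n_sim, "n_sim")
  if (!is.numeric(icc) || icc < 0 || icc >= 1) abort("`icc` must lie in [0, 1).")
  estimators <- match.arg(estimators, several.ok = TRUE)
  if (!model %in% 1:3) abort("`model` must be 1, 2 or 3.")
  stopifnot(inherits(effects, "mbfd_effects"))
  cfg <- structure(
    list(
      design = design, n = n, icc = icc, sigma = sigma, effects = effects,
      model = model, estimators = estimators, n_sim = n_sim,
      seed = as.integer(seed), alpha = alpha,
      variance = variance_components(icc = icc, sigma = sigma)
    ),
    class = "mbfd_scenario_config"
  )
  cfg$compiled <- compile_scenario(cfg)
  cfg
}

# Precompute everything replicate-independent: per-sequence fixed-effect means
# and model-matrix blocks, so each replicate reduces to an allocation draw,
# Gaussian draws and matrix fits. The replicate data are identical to calling
# randomize() + simulate_trial() with the replicate seed.
compile_scenario <- function(cfg) {
  seqs <- sort(unique(cfg$design$sequence))
  eff <- cfg$effects
  blocks <- lapply(seqs, function(s) {
    rows <- cfg$design[cfg$design$sequence == s, ]
    rows <- rows[order(rows$period), ]
    z_a <- as.integer(rows$condition == "A")
    z_b <- as.integer(rows$condition == "B")
    z_c <- as.integer(rows$condition == "AB")
    x_a <- as.integer(rows$condition %in% c("A", "AB"))
    x_b <- as.integer(rows$condition %in% c("B", "AB"))
    mu <- eff$u + eff$beta_t * rows$period + eff$beta_a * z_a +
      eff$beta_b * z_b + eff$beta_c * z_c
    x <- switch(as.character(cfg$model),
      "1" = cbind(`(Intercept)` = 1, period = rows$period, beta_a = x_a, beta_b = x_b),
      "2" = cbind(
        `(Intercept)` = 1, period = rows$period, beta_a = x_a, beta_b = x_b,
        beta_i = x_a * x_b
      ),
      "3" = cbind(`(Intercept)` = 1, period = rows$period, beta_a = z_a, beta_b = z_b, beta_c = z_c)
    )
    list(mu = mu, x = x, j = nrow(rows))
  })
  hyp <- hypothesis_set(cfg$model, cfg$alpha)
  p <- ncol(blocks[[1]]$x)
  list(
    n_seq = length(seqs),
    j = vapply(blocks, `[[`, integer(1), "j"),
    mu = lapply(blocks, `[[`, "mu"),
    x = lapply(blocks, `[[`, "x"),
    p = p, terms = hyp$terms,
    term_idx = match(hyp$terms, colnames(blocks[[1]]$x)),
    level = hyp$adjusted_level
  )
}

# One replicate on the fast path: returns, per estimator, the tested
# coefficients' estimates, standard errors, df and p-values (or NULL if the
# fit failed / did not converge).
core_replicate <- function(config, replicate_index) {
  cmp <- config$compiled
  r_seed <- derive_seed(config$seed, replicate_index)
  alloc <- randomize_impl(cmp$n_seq, config$n, r_seed)
  js <- cmp$j[alloc]
  draws <- with_seed(derive_seed(r_seed, 1L), list(
    alpha = rnorm(config$n, 0, config$variance$tau),
    eps = rnorm(sum(js), 0, config$variance$sigma)
  ))
  y <- unlist(cmp$mu[alloc], use.names = FALSE) +
    rep.int(draws$alpha, js) + draws$eps
  x <- do.call(rbind, cmp$x[alloc])
  id <- rep.int(seq_len(config$n), js)
  idx <- cmp$term_idx

  extract <- function(fit, v, df = NULL) {
    se <- sqrt(diag(v))[idx]
    est <- fit$coefficients[idx]
    df <- rep_len(df %||% fit$df[idx], length(idx))
    stat <- est / se
    list(
      estimate = est, std.error = se, df = df,
      p.value = 2 * pt(-abs(stat), df)
    )
  }
  out <- list()
  if ("lmm" %in% config$estimators) {
    fit <- tryCatch(suppressWarnings(fit_lmm_matrix(x, y, id, config$model)),
      error = function(e) NULL
    )
    out$lmm <- if (!is.null(fit) && fit$converged) extract(fit, fit$vcov)
  }
  if (any(c("gee", "gee-md") %in% config$estimators)) {
    fit <- tryCatch(suppressWarnings(fit_gee_matrix(x, y, id, config$model)),
      error = function(e) NULL
    )
    ok <- !is.null(fit) && fit$converged
    # canonical references: sandwich -> asymptotic normal, MD -> t(N - p)
    if ("gee" %in% config$estimators) {
      out$gee <- if (ok) extract(fit, fit$vcov_robust, df = Inf)
    }
    if ("gee-md" %in% config$estimators) {
      out$`gee-md` <- if (ok) extract(fit, fit$vcov_md)
    }
  }
  out
}

# Generating value of each reported coefficient.
true_values <- function(effects) {
  c(
    beta_a = effects$beta_a, beta_b = effects$beta_b,
    beta_i = effects$beta_i, beta_c = effects$beta_c
  )
}

#' Run a single Monte Carlo replicate
#'
#' Simulates one trial (randomization and outcomes derived from the master
#' seed and the replicate index), fits the configured model with every
#' requested estimator on the same data, and tests each coefficient in the
#' model's [hypothesis_set()] at the Bonferroni-adjusted level.
#'
#' @param config An [scenario_config()].
#' @param replicate_index Replicate number (1-based).
#' @return A tibble with one row per estimator and tested coefficient:
#'   `replicate`, `estimator`, `term`, `estimate`, `std.error`, `df`,
#'   `p.value`, `reject`, `converged`.
#' @export
run_replicate <- function(config, replicate_index) {
  stopifnot(inherits(config, "mbfd_scenario_config"))
  cmp <- config$compiled
  core <- core_replicate(config, replicate_index)
  rows <- lapply(config$estimators, function(est) {
    res <- core[[est]]
    if (is.null(res)) {
      tibble::tibble(
        estimator = est, term = cmp$terms, estimate = NA_real_,
        std.error = NA_real_, df = NA_real_, p.value = NA_real_,
        reject = NA, converged = FALSE
      )
    } else {
      tibble::tibble(
        estimator = est, term = cmp$terms,
        estimate = unname(res$estimate), std.error = unname(res$std.error),
        df = unname(res$df), p.value = unname(res$p.value),
        reject = unname(res$p.value) < cmp$level, converged = TRUE
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  out$replicate <- replicate_index
  dplyr::relocate(out, "replicate")
}

#' Run a full Monte Carlo scenario
#'
#' Executes [run_replicate()] for every replicate and aggregates: mean
#' estimate and bias per coefficient (with Monte Carlo standard errors),
#' per-coefficient rejection rates (type I error under a null scenario,
#' power otherwise), and the disjunctive "at least one coefficient rejected"
#' rate per estimator. Non-converged replicates are excluded from the
#' denominators and counted; more than 5% exclusions raises a warning that is
#' also recorded in the result.
#'
#' @param config An [scenario_config()].
#' @return An object of class `mbfd_scenario_result`; use [tidy()] for the
#'   per-coefficient table and `$disjunctive` for the family-wise rates.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "mbfd_scenario_config"))
  cmp <- config$compiled
  n_terms <- length(cmp$terms)
  store <- lapply(config$estimators, function(e) {
    list(
      est = matrix(NA_real_, config$n_sim, n_terms),
      p = matrix(NA_real_, config$n_sim, n_terms),
      ok = logical(config$n_sim)
    )
  })
  names(store) <- config$estimators
  for (r in seq_len(config$n_sim)) {
    core <- core_replicate(config, r)
    for (e in config$estimators) {
      res <- core[[e]]
      if (!is.null(res)) {
        store[[e]]$est[r, ] <- res$estimate
        store[[e]]$p[r, ] <- res$p.value
        store[[e]]$ok[r] <- TRUE
      }
    }
  }
  truth <- true_values(config$effects)

  results <- purrr::map2(store, names(store), function(s, e) {
    keep <- s$ok
    n_used <- sum(keep)
    est <- s$est[keep, , drop = FALSE]
    rej <- s$p[keep, , drop = FALSE] < cmp$level
    rate <- colMeans(rej)
    tibble::tibble(
      estimator = e, term = cmp$terms,
      true_value = unname(truth[cmp$terms]),
      n_used = n_used,
      mean_estimate = colMeans(est),
      estimate_mcse = apply(est, 2, sd) / sqrt(n_used),
      reject_rate = rate,
      bias = colMeans(est) - unname(truth[cmp$terms]),
      reject_mcse = sqrt(rate * (1 - rate) / n_used)
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$estimator, .data$term)

  disjunctive <- purrr::map2(store, names(store), function(s, e) {
    keep <- s$ok
    any_rej <- apply(s$p[keep, , drop = FALSE] < cmp$level, 1, any)
    tibble::tibble(
      estimator = e, n_used = sum(keep),
      disjunctive_rate = mean(any_rej),
      disjunctive_mcse = sqrt(mean(any_rej) * (1 - mean(any_rej)) / sum(keep))
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$estimator)

  excl <- tibble::tibble(
    estimator = config$estimators,
    n_excluded = vapply(store, function(s) sum(!s$ok), integer(1))
  )
  high_exclusion <- any(excl$n_excluded > 0.05 * config$n_sim)
  if (high_exclusion) {
    warn("More than 5% of replicates were excluded for non-convergence.")
  }
  structure(
    list(
      results = results, disjunctive = disjunctive, exclusions = excl,
      high_exclusion = high_exclusion, config = config,
      n_sim = config$n_sim, seed = config$seed
    ),
    class = "mbfd_scenario_result"
  )
}

#' @method tidy mbfd_scenario_result
#' @export
tidy.mbfd_scenario_result <- function(x, ...) x$results

#' @method glance mbfd_scenario_result
#' @export
glance.mbfd_scenario_result <- function(x, ...) {
  tibble::tibble(
    n = x$config$n, icc = x$config$icc, model = x$config$model,
    n_sim = x$n_sim, seed = x$seed,
    n_excluded_max = max(c(0L, x$exclusions$n_excluded)),
    high_exclusion = x$high_exclusion
  )
}

#' @export
print.mbfd_scenario_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<mbfd_scenario_result> model %d, N = %d, ICC = %.2f, %d replicates\n",
    cfg$model, cfg$n, cfg$icc, x$n_sim
  ))
  print(as.data.frame(x$results), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot rejection rates of a scenario result
#'
#' @param object An `mbfd_scenario_result`.
#' @param ... Unused.
#' @return A ggplot object: per-coefficient rejection rates by estimator,
#'   with Monte Carlo error bars.
#' @method autoplot mbfd_scenario_result
#' @export
autoplot.mbfd_scenario_result <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(
    x = .data$term, y = .data$reject_rate, fill = .data$estimator
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$reject_rate - .data$reject_mcse,
        ymax = .data$reject_rate + .data$reject_mcse
      ),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::labs(x = "Coefficient", y = "Rejection rate", fill = "Estimator") +
    ggplot2::theme_minimal()
}

#' Combined sequential-intervention effect from a fit
#'
#' The estimand "sequential combination versus standard of care" expressed
#' through each analysis model: `beta_a + beta_b` under the additive Model 1,
#' `beta_a + beta_b + beta_i` under the interaction Model 2, and `beta_c`
#' directly under the multi-arm Model 3. The standard error comes from the
#' matching contrast applied to the fit's covariance (robust or
#' Mancl-DeRouen for GEE fits).
#'
#' @param fit An `mbfd_fit` for model 1, 2 or 3.
#' @param variance For GEE fits: `"robust"` or `"md"`.
#' @return A one-row tibble: `estimate`, `std.error`.
#' @export
combined_effect <- function(fit, variance = c("robust", "md")) {
  variance <- match.arg(variance)
  contrast <- switch(as.character(fit$model),
    "1" = c(0, 0, 1, 1),
    "2" = c(0, 0, 1, 1, 1),
    "3" = c(0, 0, 0, 0, 1),
    abort("`fit` must come from model 1, 2 or 3.")
  )
  v <- if (fit$estimator == "gee") {
    if (variance == "md") fit$vcov_md else fit$vcov_robust
  } else {
    fit$vcov
  }
  tibble::tibble(
    estimate = sum(contrast * fit$coefficients),
    std.error = sqrt(drop(t(contrast) %*% v %*% contrast))
  )
}

#' Reproduce the simulation study's summary grids
#'
#' Runs the full scenario grid behind one of the four headline summary
#' tables and returns it both tidy and formatted:
#' * `table = 3`: type I error per tested coefficient under the null
#'   scenario, for models 1-3, N in \{30, 60, 120\}, LMM / GEE / GEE-MD.
#' * `table = 4`: power under additive effects `(0.8, 0.8, 1.6)`.
#' * `table = 5`: mean coefficient estimates under the interaction scenario
#'   `(0.8, 0.8, 2.0)` (LMM and GEE point estimates).
#' * `table = 6`: power under the interaction scenario.
#'
#' All grids span ICC in \{0.05, 0.10, 0.30\}. Scenario seeds are derived
#' from `seed`, so the grid is reproducible and cells sharing a scenario use
#' common random numbers across estimators.
#'
#' @param table 3, 4, 5 or 6.
#' @param n_sim Replicates per scenario (default 5000; smaller values run a
#'   faster, noisier grid).
#' @param seed Master seed.
#' @param icc,n Optional subsets of the ICC and sample-size grids.
#' @return A list of class `mbfd_table`: `tidy` (one row per
#'   ICC/model/N/estimator/coefficient with the measured quantity and its MC
#'   standard error) and `formatted` (wide, 3-decimal character grid in the
#'   conventional layout).
#' @export
reproduce_table <- function(table, n_sim = 5000, seed = 1,
                            icc = c(0.05, 0.10, 0.30), n = c(30, 60, 120)) {
  if (!table %in% 3:6) abort("`table` must be one of 3, 4, 5, 6.")
  effects <- switch(as.character(table),
    "3" = effect_parameters(),
    "4" = effect_parameters(beta_a = 0.8, beta_b = 0.8, beta_c = 1.6),
    "5" = effect_parameters(beta_a = 0.8, beta_b = 0.8, beta_c = 2.0),
    "6" = effect_parameters(beta_a = 0.8, beta_b = 0.8, beta_c = 2.0)
  )
  estimators <- if (table == 5) c("lmm", "gee") else c("lmm", "gee", "gee-md")
  measure <- if (table == 5) "mean_estimate" else "reject_rate"
  design <- mbfd_design()

  grid <- tidyr::expand_grid(icc = icc, model = 1:3, n = n)
  grid$idx <- seq_len(nrow(grid))
  cells <- purrr::pmap(grid, function(icc, model, n, idx) {
    cfg <- scenario_config(
      design = design, n = n, icc = icc, effects = effects, model = model,
      estimators = estimators, n_sim = n_sim,
      seed = derive_seed(seed, idx)
    )
    res <- run_scenario(cfg)
    dplyr::mutate(res$results, icc = icc, model = model, n = n)
  })
  long <- dplyr::bind_rows(cells) |>
    dplyr::mutate(
      value = .data[[measure]],
      mcse = if (measure == "reject_rate") .data$reject_mcse else .data$estimate_mcse
    ) |>
    dplyr::select(
      "icc", "model", "n", "estimator", "term", "value", "mcse",
      "n_used"
    )

  formatted <- long |>
    dplyr::mutate(value = sprintf("%.3f", .data$value)) |>
    dplyr::select("icc", "model", "n", "estimator", "term", "value") |>
    tidyr::pivot_wider(names_from = c("estimator", "term"), values_from = "value") |>
    dplyr::arrange(.data$icc, .data$model, .data$n)

  structure(
    list(tidy = long, formatted = formatted, table = table, n_sim = n_sim, seed = seed),
    class = "mbfd_table"
  )
}

#' @export
print.mbfd_table <- function(x, ...) {
  cat(sprintf("<mbfd_table> summary grid %d (%d replicates per scenario)\n",
              x$table, x$n_sim))
  print(as.data.frame(x$formatted), row.names = FALSE)
  invisible(x)
}

#' Write a reproduced table to delimited text
#'
#' @param x An `mbfd_table`.
#' @param path_tidy Path for the tidy long-format CSV.
#' @param path_formatted Optional path for the formatted wide grid.
#' @return `x`, invisibly.
#' @export
write_table_results <- function(x, path_tidy, path_formatted = NULL) {
  readr::write_csv(x$tidy, path_tidy)
  if (!is.null(path_formatted)) readr::write_csv(x$formatted, path_formatted)
  invisible(x)
}
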