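#' Convert an intraclass correlation to a random-intercept SD
#'
#' Under the random-intercept model the within-participant correlation of
#' repeated outcomes is `ICC = tau^2 / (tau^2 + sigma^2)`, so the
#' random-intercept standard deviation achieving a target ICC at residual SD
#' `sigma` is `sigma * sqrt(icc / (1 - icc))`.
#'
#' @param icc Target intraclass correlation, in `[0, 1)`.
#' @param sigma Residual standard deviation, positive.
#' @return The random-intercept standard deviation `tau`.
#' @examples
#' icc_to_tau(0.05) # 0.23 to two decimals
#' icc_to_tau(0.30) # 0.65
#' @export
icc_to_tau <- function(icc, sigma = 1) {
  if (!is.numeric(icc) || any(icc < 0) || any(icc >= 1)) {
    abort("`icc` must lie in [0, 1).")
  }
  if (!is.numeric(sigma) || any(sigma <= 0)) {
    abort("`sigma` must be positive.")
  }
  sigma * sqrt(icc / (1 - icc))
}

#' Treatment effect parameters of the data-generating model
#'
#' The outcome model is parameterized on the multi-arm scale: `beta_a` and
#' `beta_b` are the effects of each single intervention versus standard of
#' care, and `beta_c` the effect of the sequential combination versus
#' standard of care. The departure from additivity `beta_i = beta_c -
#' beta_a - beta_b` is derived, linking the interaction and multi-arm
#' parameterizations.
#'
#' @param u Baseline mean (outcome units).
#' @param beta_t Linear time trend per period.
#' @param beta_a,beta_b Single-intervention effects.
#' @param beta_c Sequential-combination effect.
#' @return A list of class `mbfd_effects` with fields `u`, `beta_t`,
#'   `beta_a`, `beta_b`, `beta_c` and derived `beta_i`.
#' @examples
#' effect_parameters(beta_a = 0.8, beta_b = 0.8, beta_c = 2.0)$beta_i # 0.4
#' @export
effect_parameters <- function(u = 0, beta_t = 1, beta_a = 0, beta_b = 0,
                              beta_c = 0) {
  out <- list(
    u = u, beta_t = beta_t, beta_a = beta_a, beta_b = beta_b,
    beta_c = beta_c, beta_i = beta_c - beta_a - beta_b
  )
  structure(out, class = "mbfd_effects")
}

#' Variance components of the random-intercept model
#'
#' Specify either `tau` (random-intercept SD) or `icc`; the other is derived
#' from `icc = tau^2 / (tau^2 + sigma^2)`.
#'
#' @param tau Random-intercept standard deviation (`alpha_i ~ N(0, tau^2)`).
#' @param icc Intraclass correlation in `[0, 1)`.
#' @param sigma Residual standard deviation (`epsilon_ij ~ N(0, sigma^2)`),
#'   default 1.
#' @return A list of class `mbfd_variance` with fields `tau`, `sigma`, `icc`.
#' @examples
#' variance_components(icc = 0.30)
#' @export
variance_components <- function(tau = NULL, icc = NULL, sigma = 1) {
  if (is.null(tau) == is.null(icc)) {
    abort("Supply exactly one of `tau` or `icc`.")
  }
  if (!is.numeric(sigma) || sigma <= 0) abort("`sigma` must be positive.")
  if (is.null(tau)) {
    tau <- icc_to_tau(icc, sigma)
  } else if (!is.numeric(tau) || tau < 0) {
    abort("`tau` must be non-negative.")
  }
  structure(
    list(tau = tau, sigma = sigma, icc = tau^2 / (tau^2 + sigma^2)),
    class = "mbfd_variance"
  )
}

# Long-form schedule for each allocated participant: design grid joined to the
# allocation, with the treatment indicator encodings used by all three models.
schedule_for <- function(design, allocation) {
  allocation |>
    dplyr::inner_join(design, by = "sequence", relationship = "many-to-many") |>
    dplyr::arrange(.data$participant_id, .data$period) |>
    dplyr::mutate(
      x_a = as.integer(.data$condition %in% c("A", "AB")),
      x_b = as.integer(.data$condition %in% c("B", "AB")),
      z_a = as.integer(.data$condition == "A"),
      z_b = as.integer(.data$condition == "B"),
      z_c = as.integer(.data$condition == "AB")
    )
}

#' Simulate trial outcomes from the random-intercept model
#'
#' Generates continuous outcomes on the multi-arm (distinct combined
#' condition) scale:
#' `Y_ij = u + beta_t * j + beta_a * Z_Aij + beta_b * Z_Bij + beta_c * Z_Cij
#'  + alpha_i + epsilon_ij`,
#' with one random intercept `alpha_i ~ N(0, tau^2)` per participant and
#' independent residuals `epsilon_ij ~ N(0, sigma^2)`. The marginal
#' within-participant covariance is therefore compound symmetric,
#' `sigma^2 I + tau^2 11'`.
#'
#' @param design An [mbfd_design()] grid.
#' @param allocation A [randomize()] allocation consistent with `design`.
#' @param effects An [effect_parameters()] object.
#' @param variance A [variance_components()] object.
#' @param seed Integer seed; identical inputs give bit-identical data.
#' @param keep_latent If `TRUE`, retain the latent draws `alpha` and
#'   `epsilon` as columns (useful for testing).
#' @return A tibble of class `mbfd_trial`: one row per participant-period with
#'   columns `participant_id`, `sequence`, `period`, `condition`, the
#'   factorial indicators `x_a`, `x_b`, the mutually exclusive arm indicators
#'   `z_a`, `z_b`, `z_c`, and the outcome `y`.
#' @examples
#' d <- mbfd_design()
#' dat <- simulate_trial(d, randomize(d, 30, seed = 1),
#'   effect_parameters(beta_a = 0.8, beta_b = 0.8, beta_c = 1.6),
#'   variance_components(icc = 0.05), seed = 1
#' )
#' @export
simulate_trial <- function(design, allocation, effects, variance, seed,
                           keep_latent = FALSE) {
  validate_mbfd_design(design)
  stopifnot(inherits(effects, "mbfd_effects"), inherits(variance, "mbfd_variance"))
  n_seq <- dplyr::n_distinct(design$sequence)
  if (!all(allocation$sequence %in% design$sequence)) {
    abort("Allocation refers to sequences absent from the design.")
  }
  dat <- schedule_for(design, allocation)
  n <- nrow(allocation)
  draws <- with_seed(derive_seed(seed, 1L), {
    list(
      alpha = rnorm(n, 0, variance$tau),
      eps = rnorm(nrow(dat), 0, variance$sigma)
    )
  })
  idx <- match(dat$participant_id, allocation$participant_id)
  mu <- effects$u + effects$beta_t * dat$period +
    effects$beta_a * dat$z_a + effects$beta_b * dat$z_b +
    effects$beta_c * dat$z_c
  dat$y <- mu + draws$alpha[idx] + draws$eps
  if (keep_latent) {
    dat$alpha <- draws$alpha[idx]
    dat$epsilon <- draws$eps
  }
  class(dat) <- c("mbfd_trial", class(dat))
  dat
}

#' Read and write trial data as CSV
#'
#' Round-trips the long-format trial records (comma-separated, UTF-8, header
#' row mandatory; periods as integers, conditions in `{C, A, B, AB}`).
#'
#' @param data An `mbfd_trial` tibble (or any data frame with its columns).
#' @param path File path.
#' @return `write_trial_csv()` returns `data` invisibly; `read_trial_csv()`
#'   a validated `mbfd_trial` tibble.
#' @export
write_trial_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  dat <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_integer(),
    sequence = readr::col_integer(),
    period = readr::col_integer(),
    condition = readr::col_character(),
    .default = readr::col_double()
  ))
  validate_trial(dat)
  class(dat) <- c("mbfd_trial", class(dat))
  dat
}

# Schema/invariant checks for user-supplied trial data.
validate_trial <- function(data) {
  req <- c(
    "participant_id", "sequence", "period", "condition",
    "x_a", "x_b", "z_a", "z_b", "z_c", "y"
  )
  missing <- setdiff(req, names(data))
  if (length(missing)) {
    abort(paste0("Trial data lacks columns: ", paste(missing, collapse = ", "), "."))
  }
  bad <- which(!data$condition %in% c("C", "A", "B", "AB"))
  if (length(bad)) {
    abort(sprintf("Row %d: condition must be one of C, A, B, AB.", bad[1]))
  }
  enc <- dplyr::case_when(
    data$condition == "C" ~ data$x_a == 0 & data$x_b == 0 & data$z_a == 0 & data$z_b == 0 & data$z_c == 0,
    data$condition == "A" ~ data$x_a == 1 & data$x_b == 0 & data$z_a == 1 & data$z_b == 0 & data$z_c == 0,
    data$condition == "B" ~ data$x_a == 0 & data$x_b == 1 & data$z_a == 0 & data$z_b == 1 & data$z_c == 0,
    data$condition == "AB" ~ data$x_a == 1 & data$x_b == 1 & data$z_a == 0 & data$z_b == 0 & data$z_c == 1
  )
  if (any(!enc)) {
    abort(sprintf(
      "Row %d: treatment indicators inconsistent with condition %s.",
      which(!enc)[1], data$condition[which(!enc)[1]]
    ))
  }
  invisible(data)
}
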