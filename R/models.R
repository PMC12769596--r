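#' Fixed-effect design matrix for the three MBFD analysis models
#'
#' Builds the fixed-effect matrix and response for one of the three analysis
#' models:
#' * Model 1 (additive): intercept, period, `x_a`, `x_b` — the combined phase
#'   contributes to both factorial indicators.
#' * Model 2 (interaction): Model 1 plus the product `x_a * x_b`, which is 1
#'   only during the combined phase.
#' * Model 3 (multi-arm): intercept, period, and the mutually exclusive arm
#'   indicators `z_a`, `z_b`, `z_c`.
#'
#' Rows are ordered by participant, then period.
#'
#' @param data Trial data with the `mbfd_trial` columns.
#' @param model Model id: 1, 2 or 3.
#' @return A list with elements `x` (matrix with named columns), `y`
#'   (response vector) and `id` (participant id per row).
#' @export
mbfd_model_matrix <- function(data, model) {
  validate_trial(data)
  if (!model %in% 1:3) abort("`model` must be 1, 2 or 3.")
  data <- dplyr::arrange(data, .data$participant_id, .data$period)
  x <- switch(as.character(model),
    "1" = cbind(
      `(Intercept)` = 1, period = data$period,
      beta_a = data$x_a, beta_b = data$x_b
    ),
    "2" = cbind(
      `(Intercept)` = 1, period = data$period,
      beta_a = data$x_a, beta_b = data$x_b, beta_i = data$x_a * data$x_b
    ),
    "3" = cbind(
      `(Intercept)` = 1, period = data$period,
      beta_a = data$z_a, beta_b = data$z_b, beta_c = data$z_c
    )
  )
  list(x = x, y = as.numeric(data$y), id = data$participant_id)
}

# Coefficients tested per model, and the Bonferroni-adjusted level: the 0.05
# family level is split over the 2 (Model 1) or 3 (Models 2-3) tested effects.
#' Hypothesis set for an MBFD analysis model
#'
#' Model 1 tests `beta_a` and `beta_b` at level `0.05/2`; Models 2 and 3 test
#' three coefficients (`beta_i` or `beta_c` in addition) at `0.05/3`.
#'
#' @param model Model id: 1, 2 or 3.
#' @param alpha Family-wise level split across the tests (default 0.05).
#' @return A list with `terms` (tested coefficient names) and
#'   `adjusted_level`.
#' @export
hypothesis_set <- function(model, alpha = 0.05) {
  terms <- switch(as.character(model),
    "1" = c("beta_a", "beta_b"),
    "2" = c("beta_a", "beta_b", "beta_i"),
    "3" = c("beta_a", "beta_b", "beta_c"),
    abort("`model` must be 1, 2 or 3.")
  )
  list(terms = terms, adjusted_level = alpha / length(terms))
}

# Per-cluster sufficient statistics shared by the LMM and GEE solvers.
# Exploits that both the compound-symmetry inverse and the exchangeable
# working-correlation inverse are (scaled) identity minus a rank-one
# per-cluster correction, so everything reduces to cluster sums.
cluster_stats <- function(x, y, id) {
  ord <- order(id)
  if (is.unsorted(id)) {
    x <- x[ord, , drop = FALSE]
    y <- y[ord]
    id <- id[ord]
  }
  f <- factor(id, levels = unique(id))
  list(
    x = x, y = y, f = f,
    xtx = crossprod(x), xty = crossprod(x, y)[, 1], yty = sum(y^2),
    s = rowsum(x, f, reorder = FALSE), # cluster sums of rows of x
    sy = rowsum(y, f, reorder = FALSE)[, 1],
    n_i = as.integer(tabulate(f)),
    n_clusters = nlevels(f), n_obs = length(y), p = ncol(x)
  )
}
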