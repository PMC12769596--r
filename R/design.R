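#' Construct the standard multiple baseline factorial design
#'
#' Builds the six-sequence, five-period standard MBFD: every participant
#' starts under the control condition (standard of care), transitions at a
#' staggered period into a single intervention (A for three sequences, B for
#' the other three), stays on it for exactly one period, and then receives the
#' sequential combination AB until the common exit. The single-intervention
#' phase starts at periods 2, 3 and 4 for the three sequences of each arm, so
#' the combined phase lasts 3, 2 and 1 periods respectively.
#'
#' @return A tibble of class `mbfd_design` in long form with columns
#'   `sequence` (integer), `period` (integer, 1-based; the outcome is measured
#'   once at the end of each period) and `condition` (one of `"C"`, `"A"`,
#'   `"B"`, `"AB"`).
#' @seealso [mbfd_design_extended()] for longer single-intervention phases,
#'   wider staggers and alternative exit policies; [design_summary()];
#'   [randomize()].
#' @examples
#' d <- mbfd_design()
#' design_summary(d)
#' @export
mbfd_design <- function() {
  mbfd_design_extended(
    n_sequences_per_arm = 3L, single_phase_len = 1L,
    stagger_gap = 1L, tail_policy = "common_exit"
  )
}

#' Construct an extended multiple baseline factorial design
#'
#' Generalizes the standard layout: more sequences per arm, a longer
#' single-intervention phase, a wider stagger between the start periods of
#' adjacent sequences, and a choice of exit policy. Under `"common_exit"`
#' every sequence runs to the same final period (so earlier-starting
#' sequences spend longer on the combination); under `"fixed_ab_len"` every
#' sequence receives the combination for exactly one period and exits
#' (a ragged grid).
#'
#' @param n_sequences_per_arm Number of sequences whose first intervention is
#'   A (equally, B); at least 3.
#' @param single_phase_len Number of periods spent on the single intervention
#'   before the combination; at least 1.
#' @param stagger_gap Number of periods between the intervention start of
#'   adjacent sequences; at least 1.
#' @param tail_policy `"common_exit"` or `"fixed_ab_len"` (see Details).
#' @inherit mbfd_design return
#' @examples
#' mbfd_design_extended(3, 2, 1, "common_exit")
#' @export
mbfd_design_extended <- function(n_sequences_per_arm = 3L,
                                 single_phase_len = 1L,
                                 stagger_gap = 1L,
                                 tail_policy = c("common_exit", "fixed_ab_len")) {
  k <- assert_count(n_sequences_per_arm, "n_sequences_per_arm", min = 3L)
  len <- assert_count(single_phase_len, "single_phase_len", min = 1L)
  gap <- assert_count(stagger_gap, "stagger_gap", min = 1L)
  tail_policy <- match.arg(tail_policy)

  starts <- 2L + gap * (seq_len(k) - 1L)
  last_single_end <- max(starts) + len - 1L
  n_periods <- last_single_end + 1L # every sequence gets >= 1 AB period

  rows <- purrr::map2(
    rep(starts, 2L),
    rep(c("A", "B"), each = k),
    function(start, arm) {
      exit <- if (tail_policy == "common_exit") n_periods else start + len
      if (exit < start + len) {
        abort("Invalid design parameters: a sequence would lack an AB period.")
      }
      cond <- c(
        rep("C", start - 1L),
        rep(arm, len),
        rep("AB", exit - (start + len - 1L))
      )
      tibble::tibble(period = seq_along(cond), condition = cond)
    }
  )
  grid <- dplyr::bind_rows(rows, .id = "sequence") |>
    dplyr::mutate(sequence = as.integer(.data$sequence)) |>
    dplyr::select("sequence", "period", "condition")

  new_mbfd_design(grid)
}

new_mbfd_design <- function(grid) {
  grid <- tibble::as_tibble(grid)
  class(grid) <- c("mbfd_design", class(grid))
  validate_mbfd_design(grid)
  grid
}

#' Validate a multiple baseline factorial design grid
#'
#' Checks the structural invariants of an MBFD: at least one leading control
#' period per sequence, monotone phase progression
#' (control, then one single intervention, then the combination, never
#' reverting), at least one combined period per sequence, at least three
#' sequences starting with each intervention, and at least five periods
#' overall. Invalid grids are rejected with an informative error.
#'
#' @param design A long-form design tibble (`sequence`, `period`, `condition`).
#' @return `design`, invisibly, if valid; otherwise an error.
#' @export
validate_mbfd_design <- function(design) {
  req <- c("sequence", "period", "condition")
  if (!all(req %in% names(design))) {
    abort("A design needs columns `sequence`, `period`, `condition`.")
  }
  if (!all(design$condition %in% c("C", "A", "B", "AB"))) {
    abort("Design conditions must be in {C, A, B, AB}.")
  }
  info <- design_summary(design)
  if (max(design$period) < 5L) {
    abort("An MBFD needs at least five periods.")
  }
  by_seq <- split(design[order(design$sequence, design$period), ], design$sequence)
  phase_rank <- c(C = 1L, A = 2L, B = 2L, AB = 3L)
  for (s in by_seq) {
    if (!identical(s$period, seq_len(nrow(s)))) {
      abort(sprintf("Sequence %d: periods must be 1..J without gaps.", s$sequence[1]))
    }
    if (s$condition[1] != "C") {
      abort(sprintf("Sequence %d must begin with a control period.", s$sequence[1]))
    }
    r <- phase_rank[s$condition]
    if (any(diff(r) < 0)) {
      abort(sprintf("Sequence %d reverts to an earlier phase.", s$sequence[1]))
    }
    singles <- unique(s$condition[s$condition %in% c("A", "B")])
    if (length(singles) != 1L) {
      abort(sprintf("Sequence %d must use exactly one single intervention.", s$sequence[1]))
    }
    if (!any(s$condition == "AB")) {
      abort(sprintf("Sequence %d never reaches the combined intervention.", s$sequence[1]))
    }
  }
  n_arm <- table(info$first_intervention)
  if (length(n_arm) < 2L || any(n_arm < 3L)) {
    abort("An MBFD needs at least three sequences per first intervention.")
  }
  invisible(design)
}

#' Summarize a design by sequence
#'
#' @param design An [mbfd_design()] grid.
#' @return A tibble with one row per sequence: `first_intervention` (`"A"` or
#'   `"B"`), `start_period` (first non-control period), `n_single`,
#'   `n_ab` and `n_periods`.
#' @export
design_summary <- function(design) {
  design |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(
      first_intervention = .data$condition[.data$condition %in% c("A", "B")][1],
      start_period = .data$period[match(TRUE, .data$condition != "C")],
      n_single = sum(.data$condition %in% c("A", "B")),
      n_ab = sum(.data$condition == "AB"),
      n_periods = max(.data$period),
      .groups = "drop"
    )
}

#' Randomize participants to design sequences
#'
#' Balanced individual randomization: every sequence receives `floor(N/S)` or
#' `ceiling(N/S)` participants. When N is not a multiple of the number of
#' sequences, the sequences receiving one extra participant are chosen
#' uniformly at random; the assignment of participants to sequence slots is a
#' uniform random permutation. Fully reproducible given `seed`.
#'
#' @param design An [mbfd_design()] grid.
#' @param n Total number of participants (at least one per sequence).
#' @param seed Integer seed controlling the allocation.
#' @return A tibble of class `mbfd_allocation` with columns `participant_id`
#'   and `sequence`.
#' @examples
#' randomize(mbfd_design(), n = 30, seed = 1)
#' @export
randomize <- function(design, n, seed) {
  validate_mbfd_design(design)
  n <- assert_count(n, "n")
  n_seq <- dplyr::n_distinct(design$sequence)
  if (n < n_seq) {
    abort(sprintf(
      "Cannot allocate %d participants to %d sequences: every sequence needs one.",
      n, n_seq
    ))
  }
  out <- tibble::tibble(
    participant_id = seq_len(n),
    sequence = randomize_impl(n_seq, n, seed)
  )
  class(out) <- c("mbfd_allocation", class(out))
  out
}

# Sequence index per participant; shared by randomize() and the simulation
# engine's fast path so both draw identical allocations from the same seed.
randomize_impl <- function(n_seq, n, seed) {
  base <- n %/% n_seq
  rem <- n %% n_seq
  alloc <- with_seed(derive_seed(seed, 0L), {
    sizes <- rep(base, n_seq)
    if (rem > 0L) {
      extra <- sample.int(n_seq, rem)
      sizes[extra] <- sizes[extra] + 1L
    }
    sample(rep.int(seq_len(n_seq), sizes))
  })
  as.integer(alloc)
}

#' @export
print.mbfd_design <- function(x, ...) {
  info <- design_summary(x)
  cat(sprintf(
    "<mbfd_design> %d sequences x up to %d periods (%d A-first, %d B-first)\n",
    nrow(info), max(info$n_periods),
    sum(info$first_intervention == "A"), sum(info$first_intervention == "B")
  ))
  wide <- design_to_wide(x)
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

design_to_wide <- function(design) {
  design |>
    tidyr::pivot_wider(
      names_from = "period", values_from = "condition",
      names_prefix = "period_"
    ) |>
    dplyr::arrange(.data$sequence)
}

#' Read and write design grids as delimited text
#'
#' The on-disk format is a comma-separated grid: one row per sequence, one
#' column per period (header `period_1`, `period_2`, ...), cells in
#' `{C, A, B, AB}` and empty cells after a sequence's exit.
#'
#' @param design An [mbfd_design()] grid.
#' @param path File path.
#' @return `write_design_grid()` returns `design` invisibly;
#'   `read_design_grid()` returns a validated `mbfd_design`.
#' @export
write_design_grid <- function(design, path) {
  validate_mbfd_design(design)
  readr::write_csv(design_to_wide(design), path, na = "")
  invisible(design)
}

#' @rdname write_design_grid
#' @export
read_design_grid <- function(path) {
  wide <- readr::read_csv(path, col_types = readr::cols(
    sequence = readr::col_integer(), .default = readr::col_character()
  ))
  grid <- wide |>
    tidyr::pivot_longer(
      dplyr::starts_with("period_"),
      names_to = "period", names_prefix = "period_",
      values_to = "condition", values_drop_na = TRUE
    ) |>
    dplyr::mutate(period = as.integer(.data$period)) |>
    dplyr::arrange(.data$sequence, .data$period)
  new_mbfd_design(grid)
}

#' Serialize a design to and from JSON
#'
#' @inheritParams write_design_grid
#' @return `design_to_json()` returns a JSON string; `design_from_json()`
#'   returns a validated `mbfd_design`.
#' @export
design_to_json <- function(design) {
  validate_mbfd_design(design)
  jsonlite::toJSON(as.data.frame(design), dataframe = "columns")
}

#' @rdname design_to_json
#' @param json A JSON string produced by `design_to_json()`.
#' @export
design_from_json <- function(json) {
  new_mbfd_design(tibble::as_tibble(jsonlite::fromJSON(json)))
}

#' Plot a design layout
#'
#' Draws the sequence-by-period grid with one tile per measurement interval,
#' coloured by condition, mirroring the conventional multiple-baseline
#' diagram.
#'
#' @param object An [mbfd_design()] grid.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mbfd_design
#' @export
autoplot.mbfd_design <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$period, y = factor(.data$sequence, levels = rev(sort(unique(.data$sequence)))),
    fill = factor(.data$condition, levels = c("C", "A", "B", "AB"))
  )) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.8) +
    ggplot2::scale_fill_manual(
      values = c(C = "#a8d5a2", A = "#f5d76e", B = "#7fb3d5", AB = "#1e6e43"),
      name = "Condition"
    ) +
    ggplot2::labs(x = "Period", y = "Sequence") +
    ggplot2::theme_minimal()
}
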