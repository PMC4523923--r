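#' Build the parameter grid of the robustness sweep
#'
#' Enumerates every combination of average-score threshold `tau`,
#' identification-score threshold `m`, high-count capping on/off and
#' spectral-count normalization on/off. The `tau` values are built by
#' integer index arithmetic (`lo + i * step`), so the default grid
#' 0.8--0.95 in steps of 0.01 yields exactly 16 thresholds and, with five
#' `m` values and both binary axes, 320 combinations. Combinations are
#' enumerated in a canonical order: `tau` varies fastest, then `m`, then
#' the cap flag, then the normalization flag.
#'
#' @param tau_range Numeric triple `(lo, hi, step)` for the score
#'   threshold axis, endpoints included. Default `c(0.8, 0.95, 0.01)`.
#' @param m_values Identification-score thresholds. Default
#'   `c(10, 20, 30, 40, 50)`.
#' @param include_cap_axis,include_norm_axis If `TRUE` (default) the
#'   corresponding binary axis contributes both settings; if `FALSE` only
#'   the "off" setting.
#'
#' @return An object of class `parameter_grid`, with a `combos` tibble
#'   `combo_id, tau, m, cap, norm`.
#' @export
#' @examples
#' nrow(build_parameter_grid()$combos) # 320
build_parameter_grid <- function(tau_range = c(0.8, 0.95, 0.01),
                                 m_values = c(10, 20, 30, 40, 50),
                                 include_cap_axis = TRUE,
                                 include_norm_axis = TRUE) {
  stopifnot(length(tau_range) == 3)
  lo <- tau_range[1]; hi <- tau_range[2]; step <- tau_range[3]
  if (lo > hi) abort("tau range: lo must be <= hi")
  if (step <= 0) abort("tau range: step must be > 0")
  if (length(m_values) == 0) abort("m_values must be non-empty")

  n_steps <- floor((hi - lo) / step + 1e-9)
  tau_values <- lo + (0:n_steps) * step
  cap_flags <- if (include_cap_axis) c(FALSE, TRUE) else FALSE
  norm_flags <- if (include_norm_axis) c(FALSE, TRUE) else FALSE

  combos <- tidyr::expand_grid(norm = norm_flags, cap = cap_flags,
                               m = m_values, tau = tau_values) |>
    select(tau, m, cap, norm) |>
    mutate(combo_id = row_number(), .before = 1)

  structure(
    list(tau_values = tau_values, m_values = m_values,
         cap_flags = cap_flags, norm_flags = norm_flags, combos = combos),
    class = "parameter_grid"
  )
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf(
    "<parameter_grid> %d combinations: %d tau x %d m x %d cap x %d norm\n",
    nrow(x$combos), length(x$tau_values), length(x$m_values),
    length(x$cap_flags), length(x$norm_flags)
  ))
  invisible(x)
}

#' Re-score a screen under every parameter combination
#'
#' Scores the dataset once per distinct `(m, cap, norm)` option set --
#' the score threshold `tau` only decides which scored pairs are *called*
#' -- and records, for every grid combination, the pairs whose average
#' score reaches its `tau` (inclusive).
#'
#' @param table,controls Spectral-count and control tibbles as in
#'   [score_dataset()].
#' @param grid A [build_parameter_grid()] object.
#' @param options Base [scoring_options()]; the sweep overrides
#'   `id_score_min`, `cap_high_counts` and `normalize` per combination.
#'
#' @return An object of class `apms_sweep` holding the grid, the per
#'   option-set score tables (`scores`) and the per-combination call list
#'   (`calls`).
#' @export
run_sweep <- function(table, controls, grid = build_parameter_grid(),
                      options = scoring_options()) {
  stopifnot(inherits(grid, "parameter_grid"))
  opt_sets <- distinct(grid$combos, m, cap, norm)

  scores <- purrr::pmap(opt_sets, function(m, cap, norm) {
    o <- options
    o$id_score_min <- m
    o$cap_high_counts <- cap
    o$normalize <- norm
    score_dataset(table, controls, o) |>
      mutate(m = m, cap = cap, norm = norm, .before = 1)
  }) |>
    purrr::list_rbind()

  calls <- grid$combos |>
    inner_join(scores, by = c("m", "cap", "norm"),
               relationship = "many-to-many") |>
    filter(avg_score >= tau) |>
    select(combo_id, tau, m, cap, norm, bait, prey, avg_score) |>
    arrange(combo_id, bait, prey)

  structure(
    list(grid = grid, scores = scores, calls = calls),
    class = "apms_sweep"
  )
}

#' @export
print.apms_sweep <- function(x, ...) {
  cat(sprintf(
    "<apms_sweep> %d combinations, %d scored pair-settings, %d calls\n",
    nrow(x$grid$combos), nrow(x$scores), nrow(x$calls)
  ))
  invisible(x)
}

#' Per-pair robustness fractions of a sweep
#'
#' For every pair scored in at least one option set, counts the
#' parameter combinations calling the interaction and divides by the
#' total number of combinations. A pair is a candidate if its maximum
#' average score over all combinations exceeds 0.8.
#'
#' @param sweep An [run_sweep()] result.
#'
#' @return A tibble `bait, prey, calls, robustness, max_avg_score,
#'   candidate`, one row per scored pair.
#' @export
robustness_fraction <- function(sweep) {
  stopifnot(inherits(sweep, "apms_sweep"))
  n_combos <- nrow(sweep$grid$combos)
  call_counts <- sweep$calls |> count(bait, prey, name = "calls")
  sweep$scores |>
    group_by(bait, prey) |>
    summarise(max_avg_score = max_or_na(avg_score), .groups = "drop") |>
    left_join(call_counts, by = c("bait", "prey")) |>
    mutate(
      calls = tidyr::replace_na(calls, 0L),
      robustness = calls / n_combos,
      candidate = max_avg_score > 0.8
    ) |>
    select(bait, prey, calls, robustness, max_avg_score, candidate) |>
    arrange(bait, prey)
}

#' Label robustness records as robust or low
#'
#' A candidate pair is robust when it is called in at least half of the
#' parameter combinations (`robustness >= 0.5`), low otherwise.
#'
#' @param records A [robustness_fraction()] tibble.
#'
#' @return The records with a `class` column, `"robust"` or `"low"`.
#' @export
classify_robustness <- function(records) {
  mutate(records, class = if_else(robustness >= 0.5, "robust", "low"))
}

#' @rdname run_sweep
#' @param x An `apms_sweep` object.
#' @param ... Unused.
#' @export
tidy.apms_sweep <- function(x, ...) {
  classify_robustness(robustness_fraction(x))
}

#' @rdname run_sweep
#' @export
glance.apms_sweep <- function(x, ...) {
  rec <- tidy(x)
  tibble(
    n_combos = nrow(x$grid$combos),
    n_pairs = nrow(rec),
    n_candidates = sum(rec$candidate),
    n_robust = sum(rec$candidate & rec$class == "robust"),
    n_calls = nrow(x$calls)
  )
}

#' @rdname run_sweep
#' @param object An `apms_sweep` object.
#' @export
autoplot.apms_sweep <- function(object, ...) {
  rec <- tidy(object)
  ggplot2::ggplot(rec, ggplot2::aes(x = robustness, fill = candidate)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0) +
    ggplot2::labs(
      x = "robustness fraction (calls / parameter combinations)",
      y = "bait-prey pairs", fill = "candidate\n(max score > 0.8)",
      title = "Parameter-sweep robustness of scored interactions"
    ) +
    ggplot2::theme_minimal()
}
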