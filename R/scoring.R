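#' Options for the two-component Poisson interaction scorer
#'
#' @param id_score_min Identification-score threshold: records with
#'   `id_score` below it are discarded before scoring (the search-engine
#'   score axis of the parameter sweep). Default 0 (keep everything).
#' @param normalize If `TRUE`, each purification's counts are rescaled so
#'   its total equals the median purification total of its table, then
#'   rounded to the nearest integer (ties to even).
#' @param cap_high_counts If `TRUE`, counts above the `cap_quantile`
#'   empirical quantile of the retained nonzero counts are replaced by
#'   that quantile (linear-interpolation quantile, then floored).
#' @param prior_true Prior probability of a true interaction,
#'   `pi` in `(0, 1)`. Default 0.1.
#' @param pseudocount Positive pseudocount added to the background-rate
#'   numerator and denominator. Default 0.5.
#' @param cap_quantile Quantile used by the high-count cap. Default 0.95.
#' @param min_enrichment Floor on `lambda_true / lambda_false` (>= 1), so
#'   posteriors stay identifiable for weak pairs. Default 2.
#' @param lambda_floor Floor on the background rate `lambda_false`, a
#'   numerical guard for preys absent everywhere. Default 0.01.
#'
#' @return An object of class `scoring_options` (a named list).
#' @export
scoring_options <- function(id_score_min = 0, normalize = FALSE,
                            cap_high_counts = FALSE, prior_true = 0.1,
                            pseudocount = 0.5, cap_quantile = 0.95,
                            min_enrichment = 2, lambda_floor = 0.01) {
  stopifnot(prior_true > 0, prior_true < 1,
            cap_quantile > 0, cap_quantile < 1,
            pseudocount > 0, min_enrichment >= 1, lambda_floor > 0)
  structure(
    list(id_score_min = id_score_min, normalize = isTRUE(normalize),
         cap_high_counts = isTRUE(cap_high_counts), prior_true = prior_true,
         pseudocount = pseudocount, cap_quantile = cap_quantile,
         min_enrichment = min_enrichment, lambda_floor = lambda_floor),
    class = "scoring_options"
  )
}

#' Posterior probability of a true interaction for one spectral count
#'
#' Evaluates the two-component Poisson posterior
#' \deqn{P(\mathrm{true} \mid x) =
#'   \frac{\pi \, \mathrm{Pois}(x \mid \lambda_t)}
#'        {\pi \, \mathrm{Pois}(x \mid \lambda_t) +
#'         (1 - \pi) \, \mathrm{Pois}(x \mid \lambda_f)}}{
#'   pi*Pois(x|lt) / (pi*Pois(x|lt) + (1-pi)*Pois(x|lf))}
#' in log space for numerical stability. All arguments are vectorised.
#'
#' @param count Observed spectral count(s), non-negative integers.
#' @param lambda_false Background Poisson rate.
#' @param lambda_true Foreground Poisson rate.
#' @param prior_true Prior probability of a true interaction.
#'
#' @return Posterior probabilities in `[0, 1]`.
#' @export
posterior_true <- function(count, lambda_false, lambda_true, prior_true) {
  lt <- dpois(count, lambda_true, log = TRUE) + log(prior_true)
  lf <- dpois(count, lambda_false, log = TRUE) + log1p(-prior_true)
  top <- pmax(lt, lf)
  exp(lt - top) / (exp(lt - top) + exp(lf - top))
}

#' Filter and transform a spectral-count or control table
#'
#' Applies, in order: identification-score filtering (records with
#' `id_score < id_score_min` are dropped), high-count capping (counts above
#' the `cap_quantile` of all retained nonzero counts are replaced by that
#' quantile, floored), and spectral-count normalization (each
#' purification's counts rescaled so its total equals the median
#' purification total of the table, rounded to nearest, ties to even).
#'
#' @param x A spectral-count tibble (`bait, prey, replicate, count,
#'   id_score`) or control tibble (`control_run, prey, count, id_score`).
#' @param options A [scoring_options()] object.
#'
#' @return A tibble of the same shape; a warning is raised if no record
#'   survives the identification-score filter.
#' @export
#' @examples
#' tab <- tibble::tibble(bait = "B1", prey = paste0("P", 1:4),
#'                       replicate = 1L, count = c(1L, 2L, 3L, 100L),
#'                       id_score = 30)
#' apply_filters(tab, scoring_options(cap_high_counts = TRUE))
apply_filters <- function(x, options = scoring_options()) {
  keys <- purif_keys(x)
  out <- filter(x, id_score >= options$id_score_min)
  if (nrow(out) == 0) {
    warn("no records retained after identification-score filtering")
    return(out)
  }
  if (options$cap_high_counts) {
    nz <- out$count[out$count > 0]
    if (length(nz)) {
      cap <- floor(quantile(nz, options$cap_quantile, type = 7, names = FALSE))
      out <- mutate(out, count = pmin(count, cap))
    }
  }
  if (options$normalize) {
    out <- normalize_counts(out, keys, round_counts = TRUE)
  }
  out
}

# rescale each purification's total to the median purification total;
# round_counts = FALSE exposes the pre-rounding values for invariant checks
normalize_counts <- function(x, keys = purif_keys(x), round_counts = TRUE) {
  x <- x |>
    group_by(across(all_of(keys))) |>
    mutate(.total = sum(count)) |>
    ungroup()
  med <- x |>
    distinct(across(all_of(c(keys, ".total")))) |>
    pull(.total) |>
    median()
  x <- x |> mutate(count = count * med / .total) |> select(-.total)
  if (round_counts) x <- mutate(x, count = round(count))
  x
}

#' Estimate the background Poisson rate of a prey
#'
#' The contaminant rate of a prey is estimated from every purification in
#' which it could have appeared spuriously: all control runs, plus all
#' purifications of baits other than the one being scored. With total
#' count `S` over those `n` purifications and pseudocount `a`,
#' `lambda_false = (S + a) / (n + a)`, floored at `lambda_floor`.
#'
#' @param prey Prey id.
#' @param table Filtered spectral-count tibble (filters already applied).
#' @param controls Filtered control tibble.
#' @param options A [scoring_options()] object.
#' @param exclude_bait Bait being scored, whose purifications are left out
#'   of the estimate; `NULL` to use every bait purification.
#'
#' @return The background rate, a positive scalar.
#' @export
estimate_background_rate <- function(prey, table, controls,
                                     options = scoring_options(),
                                     exclude_bait = NULL) {
  other <- if (is.null(exclude_bait)) table else filter(table, bait != exclude_bait)
  n_other <- nrow(distinct(other, bait, replicate))
  n_ctrl <- n_distinct(controls$control_run)
  total <- sum(other$count[other$prey == prey]) +
    sum(controls$count[controls$prey == prey])
  max((total + options$pseudocount) /
        (n_other + n_ctrl + options$pseudocount),
      options$lambda_floor)
}

#' Score every observed bait-prey pair of a screen
#'
#' Applies the filtering options, then assigns each bait-prey pair with at
#' least one nonzero filtered count the probability of a true interaction.
#' For a pair, the foreground rate is
#' `lambda_true = max(mean replicate count, min_enrichment * lambda_false)`
#' with `lambda_false` from [estimate_background_rate()] (computed against
#' all control runs and the other baits' purifications); each replicate of
#' the bait contributes a [posterior_true()] evaluated at its count (0 for
#' replicates where the prey was not observed), and `avg_score` is the
#' arithmetic mean of the replicate posteriors.
#'
#' Purification universes -- which replicate purifications and control
#' runs exist -- are taken from the unfiltered inputs: filtering discards
#' records, not the purifications that produced them.
#'
#' @param table Spectral-count tibble `bait, prey, replicate, count,
#'   id_score`.
#' @param controls Control tibble `control_run, prey, count, id_score`.
#' @param options A [scoring_options()] object.
#' @param keep_replicates If `TRUE`, attach a `replicate_posteriors`
#'   list-column with the per-replicate posteriors.
#'
#' @return A tibble `bait, prey, avg_score, n_replicates, lambda_true,
#'   lambda_false`, one row per scored pair, ordered by bait then prey.
#' @export
score_dataset <- function(table, controls, options = scoring_options(),
                          keep_replicates = FALSE) {
  empty <- tibble(bait = character(), prey = character(),
                  avg_score = numeric(), n_replicates = integer(),
                  lambda_true = numeric(), lambda_false = numeric())
  if (nrow(table) == 0) return(empty)

  # purification design, fixed before filtering
  bait_reps <- distinct(table, bait, replicate)
  n_bait_purifs <- nrow(bait_reps)
  n_ctrl <- n_distinct(controls$control_run)

  ft <- suppressWarnings(apply_filters(table, options))
  fc <- suppressWarnings(apply_filters(controls, options))
  if (nrow(ft) == 0) return(empty)

  ctrl_tot <- fc |> count(prey, wt = count, name = "ctrl_total")
  bait_tot <- ft |> count(prey, wt = count, name = "bait_total")

  pairs <- ft |>
    group_by(bait, prey) |>
    summarise(pair_total = sum(count), .groups = "drop") |>
    filter(pair_total > 0) |>
    left_join(ctrl_tot, by = "prey") |>
    left_join(bait_tot, by = "prey") |>
    mutate(
      ctrl_total = tidyr::replace_na(ctrl_total, 0),
      bait_total = tidyr::replace_na(bait_total, 0),
      other_total = ctrl_total + bait_total - pair_total
    ) |>
    left_join(count(bait_reps, bait, name = "n_replicates"), by = "bait") |>
    mutate(
      n_other = n_ctrl + n_bait_purifs - n_replicates,
      lambda_false = pmax(
        (other_total + options$pseudocount) / (n_other + options$pseudocount),
        options$lambda_floor
      ),
      lambda_true = pmax(pair_total / n_replicates,
                         options$min_enrichment * lambda_false)
    )

  reps <- pairs |>
    select(bait, prey, lambda_false, lambda_true) |>
    inner_join(bait_reps, by = "bait", relationship = "many-to-many") |>
    left_join(select(ft, bait, prey, replicate, count),
              by = c("bait", "prey", "replicate")) |>
    mutate(
      count = tidyr::replace_na(count, 0),
      posterior = posterior_true(count, lambda_false, lambda_true,
                                 options$prior_true)
    )

  out <- reps |>
    group_by(bait, prey) |>
    summarise(avg_score = mean(posterior), n_replicates = n(),
              .groups = "drop")
  if (keep_replicates) {
    posts <- reps |>
      arrange(bait, prey, replicate) |>
      group_by(bait, prey) |>
      summarise(replicate_posteriors = list(posterior), .groups = "drop")
    out <- left_join(out, posts, by = c("bait", "prey"))
  }
  out |>
    left_join(select(pairs, bait, prey, lambda_true, lambda_false),
              by = c("bait", "prey")) |>
    arrange(bait, prey)
}

#' Score a single bait-prey pair
#'
#' Convenience wrapper around [score_dataset()] returning the one row for
#' the requested pair, with the per-replicate posteriors attached. Pairs
#' with no nonzero filtered count are not scored and yield a zero-row
#' tibble.
#'
#' @param bait,prey Ids of the pair to score.
#' @param table,controls,options As in [score_dataset()].
#'
#' @return A one-row tibble (or zero rows if the pair is not scored).
#' @export
score_pair <- function(bait, prey, table, controls,
                       options = scoring_options()) {
  b <- bait
  p <- prey
  score_dataset(table, controls, options, keep_replicates = TRUE) |>
    filter(bait == b, prey == p)
}
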