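edge_class_levels <- c("TAPMS_SUPPORTED", "TAPMS_ROBUST", "TAPMS_LOW",
                       "TAPMS_MARGINAL_SUPPORTED", "EXTERNAL_ONLY")

#' Does a pair have external experimental support?
#'
#' A screen pair is externally supported when the evidence table contains
#' an experimental-channel edge for it at any confidence score -- no
#' threshold is applied for pairs already observed in the screen.
#'
#' @param pairs A tibble with columns `node_a, node_b` (order
#'   irrelevant).
#' @param evidence Evidence tibble `node_a, node_b, score, channel`.
#'
#' @return A logical vector, one element per row of `pairs`.
#' @export
has_external_support <- function(pairs, evidence) {
  if (is.null(evidence) || nrow(evidence) == 0) {
    return(rep(FALSE, nrow(pairs)))
  }
  exp_keys <- evidence |>
    filter(channel == "experimental") |>
    with(pair_key(node_a, node_b))
  pair_key(pairs$node_a, pairs$node_b) %in% exp_keys
}

#' Assign the five-class edge taxonomy to screen pairs
#'
#' Encodes the confidence-level taxonomy of the integrated network:
#' * `TAPMS_SUPPORTED` ("thick green") -- candidate (max average score
#'   > 0.8), robust (robustness >= 0.5), with external experimental
#'   support;
#' * `TAPMS_ROBUST` ("thick black") -- candidate and robust, without
#'   external support;
#' * `TAPMS_LOW` ("thin grey") -- candidate with robustness < 0.5;
#' * `TAPMS_MARGINAL_SUPPORTED` ("dashed green") -- not a candidate, but
#'   maximum average score in the marginal band (0.7, 0.8] and externally
#'   supported;
#' * otherwise no screen edge (`NA`). (`EXTERNAL_ONLY`, "dashed grey",
#'   is reserved for imported evidence-only edges, see
#'   [import_external_edges()].)
#'
#' @param candidate Logical: maximum average score > 0.8 in some
#'   combination.
#' @param robustness Robustness fraction in `[0, 1]`.
#' @param max_avg_score Maximum average score over the sweep.
#' @param supported Logical, from [has_external_support()].
#' @param marginal_band Half-open interval `(lo, hi]` of the marginal
#'   class. Default `c(0.7, 0.8)`.
#'
#' @return A character vector of edge classes, `NA` where no edge is
#'   drawn. All arguments are vectorised.
#' @export
assign_edge_class <- function(candidate, robustness, max_avg_score,
                              supported, marginal_band = c(0.7, 0.8)) {
  robust <- robustness >= 0.5
  case_when(
    candidate & robust & supported ~ "TAPMS_SUPPORTED",
    candidate & robust ~ "TAPMS_ROBUST",
    candidate ~ "TAPMS_LOW",
    !candidate & supported &
      max_avg_score > marginal_band[1] &
      max_avg_score <= marginal_band[2] ~ "TAPMS_MARGINAL_SUPPORTED",
    .default = NA_character_
  )
}

#' Import high-confidence external edges around the screen
#'
#' For pairs *not* observed in the screen, keeps experimental-channel
#' evidence edges with score at or above `min_score` whose endpoints touch
#' the screen: by default at least one endpoint must be a screen node
#' (bait or prey); with `chain = TRUE`, edges may also attach through
#' other kept edges, extending the reachable neighbourhood iteratively.
#'
#' @param screen_nodes Character vector of bait and prey ids observed in
#'   the screen.
#' @param evidence Evidence tibble `node_a, node_b, score, channel`.
#' @param min_score Minimum confidence score for imported edges.
#'   Default 0.9.
#' @param observed_pairs Optional character vector of canonical pair keys
#'   already observed in the screen, to exclude.
#' @param chain If `TRUE`, allow imported nodes to chain through other
#'   imported nodes. Default `FALSE` (one-step attachment).
#'
#' @return A tibble `node_a, node_b, external_score, class` (class
#'   `"EXTERNAL_ONLY"`).
#' @export
import_external_edges <- function(screen_nodes, evidence, min_score = 0.9,
                                  observed_pairs = NULL, chain = FALSE) {
  if (is.null(evidence) || nrow(evidence) == 0) {
    return(tibble(node_a = character(), node_b = character(),
                  external_score = numeric(), class = character()))
  }
  cand <- evidence |>
    filter(channel == "experimental", score >= min_score,
           node_a != node_b) |>
    mutate(key = pair_key(node_a, node_b)) |>
    group_by(key) |>
    slice_max(score, n = 1, with_ties = FALSE) |>
    ungroup()
  if (!is.null(observed_pairs)) {
    cand <- filter(cand, !key %in% observed_pairs)
  }

  if (chain) {
    reachable <- unique(screen_nodes)
    kept_keys <- character()
    repeat {
      hit <- cand$node_a %in% reachable | cand$node_b %in% reachable
      new_keys <- setdiff(cand$key[hit], kept_keys)
      if (length(new_keys) == 0) break
      kept_keys <- c(kept_keys, new_keys)
      reachable <- union(reachable,
                         unique(c(cand$node_a[hit], cand$node_b[hit])))
    }
    kept <- filter(cand, key %in% kept_keys)
  } else {
    kept <- filter(cand,
                   node_a %in% screen_nodes | node_b %in% screen_nodes)
  }
  kept |>
    transmute(node_a, node_b, external_score = score,
              class = "EXTERNAL_ONLY") |>
    arrange(node_a, node_b)
}

#' Assemble the evidence-integrated interaction network
#'
#' Merges the sweep's robustness records with the external evidence table
#' into an undirected, typed network. Reciprocal bait-bait observations
#' are merged keeping the maximum robustness and score; each screen pair
#' is classified with [assign_edge_class()]; external-only edges at or
#' above `min_external_score` are imported around the screen nodes with
#' [import_external_edges()]. Where duplicate edges arise, the
#' highest-precedence class (in the order of the taxonomy) wins. Node and
#' edge orderings are deterministic.
#'
#' @param records A (possibly classified) [robustness_fraction()] tibble.
#' @param evidence Evidence tibble, or `NULL` for a screen-only network.
#' @param baits Character vector of bait ids; defaults to the baits of
#'   `records`.
#' @param min_external_score Import threshold for external-only edges.
#'   Default 0.9.
#' @param marginal_band Marginal score band, see [assign_edge_class()].
#' @param chain_imports Passed to [import_external_edges()] as `chain`.
#'
#' @return An object of class `interaction_network`: a list with `nodes`
#'   (tibble `node, role`) and `edges` (tibble `node_a, node_b, class,
#'   robustness, max_avg_score, external_score`). Only nodes incident to
#'   at least one edge are kept.
#' @export
assemble_network <- function(records, evidence = NULL, baits = NULL,
                             min_external_score = 0.9,
                             marginal_band = c(0.7, 0.8),
                             chain_imports = FALSE) {
  baits <- baits %||% unique(records$bait)
  screen_nodes <- union(unique(records$bait), unique(records$prey))

  merged <- records |>
    filter(bait != prey) |>
    mutate(node_a = pmin(bait, prey), node_b = pmax(bait, prey)) |>
    group_by(node_a, node_b) |>
    summarise(robustness = max_or_na(robustness),
              max_avg_score = max_or_na(max_avg_score),
              candidate = any(candidate), .groups = "drop")

  exp_scores <- if (!is.null(evidence)) {
    evidence |>
      filter(channel == "experimental", node_a != node_b) |>
      mutate(key = pair_key(node_a, node_b)) |>
      group_by(key) |>
      summarise(external_score = max(score), .groups = "drop")
  } else {
    tibble(key = character(), external_score = numeric())
  }

  tap_edges <- merged |>
    mutate(
      key = pair_key(node_a, node_b),
      supported = has_external_support(
        tibble(node_a = node_a, node_b = node_b), evidence),
      class = assign_edge_class(candidate, robustness, max_avg_score,
                                supported, marginal_band)
    ) |>
    filter(!is.na(class)) |>
    left_join(exp_scores, by = "key") |>
    select(node_a, node_b, class, robustness, max_avg_score, external_score)

  ext_edges <- import_external_edges(
    screen_nodes, evidence, min_score = min_external_score,
    observed_pairs = pair_key(merged$node_a, merged$node_b),
    chain = chain_imports
  ) |>
    mutate(robustness = NA_real_, max_avg_score = NA_real_) |>
    select(node_a, node_b, class, robustness, max_avg_score, external_score)

  edges <- bind_rows(tap_edges, ext_edges) |>
    mutate(key = pair_key(node_a, node_b),
           class = factor(class, levels = edge_class_levels)) |>
    arrange(class, node_a, node_b) |>
    group_by(key) |>
    summarise(
      node_a = node_a[1], node_b = node_b[1], class = class[1],
      robustness = max_or_na(robustness),
      max_avg_score = max_or_na(max_avg_score),
      external_score = max_or_na(external_score),
      .groups = "drop"
    ) |>
    mutate(class = as.character(class)) |>
    select(node_a, node_b, class, robustness, max_avg_score,
           external_score) |>
    arrange(factor(class, levels = edge_class_levels), node_a, node_b)

  incident <- unique(c(edges$node_a, edges$node_b))
  nodes <- tibble(node = incident) |>
    mutate(role = case_when(
      node %in% baits ~ "bait",
      node %in% screen_nodes ~ "prey",
      .default = "imported"
    )) |>
    arrange(factor(role, levels = c("bait", "prey", "imported")), node)

  structure(
    list(nodes = nodes, edges = edges, baits = baits,
         thresholds = list(min_external_score = min_external_score,
                           marginal_band = marginal_band,
                           chain_imports = chain_imports)),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    tab <- table(factor(x$edges$class, levels = edge_class_levels))
    for (cl in names(tab)) {
      if (tab[[cl]] > 0) cat(sprintf("  %-26s %d\n", cl, tab[[cl]]))
    }
  }
  invisible(x)
}

#' @rdname assemble_network
#' @param x,object An `interaction_network` object.
#' @param ... Unused.
#' @export
tidy.interaction_network <- function(x, ...) {
  x$edges
}

#' @rdname assemble_network
#' @export
glance.interaction_network <- function(x, ...) {
  cls <- table(factor(x$edges$class, levels = edge_class_levels))
  bind_cols(
    tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
           n_imported = sum(x$nodes$role == "imported")),
    as_tibble(as.list(setNames(as.integer(cls), tolower(names(cls)))))
  )
}

#' @rdname assemble_network
#' @export
autoplot.interaction_network <- function(object, ...) {
  dat <- object$edges |>
    count(class) |>
    mutate(class = factor(class, levels = edge_class_levels))
  ggplot2::ggplot(dat, ggplot2::aes(x = class, y = n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "edges",
                  title = "Interaction-network edge classes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
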