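#' Define anchored clusters of degree-one imported nodes
#'
#' Every imported node whose degree in the network is exactly one and
#' whose sole neighbour is a screen bait or prey is assigned to the
#' cluster anchored at that neighbour. Imported nodes with two or more
#' neighbours, or whose neighbour is itself imported, stay unclustered;
#' anchors without qualifying neighbours yield no cluster. The resulting
#' membership is a partition of the qualifying imported nodes.
#'
#' @param net An [assemble_network()] object.
#'
#' @return A tibble `cluster_id, anchor, member`, one row per cluster
#'   member, ordered by anchor then member.
#' @export
define_clusters <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  empty <- tibble(cluster_id = character(), anchor = character(),
                  member = character())
  if (nrow(net$edges) == 0) return(empty)

  long <- bind_rows(
    transmute(net$edges, node = node_a, neighbor = node_b),
    transmute(net$edges, node = node_b, neighbor = node_a)
  )
  deg <- count(long, node, name = "degree")
  roles <- setNames(net$nodes$role, net$nodes$node)

  long |>
    left_join(deg, by = "node") |>
    filter(degree == 1,
           roles[node] == "imported",
           roles[neighbor] %in% c("bait", "prey")) |>
    transmute(cluster_id = neighbor, anchor = neighbor, member = node) |>
    arrange(anchor, member)
}

#' Hypergeometric term enrichment of one node set
#'
#' For every term of the annotation table, tests over-representation of
#' the term among `members` within `universe` with a one-sided
#' hypergeometric (Fisher) upper-tail p-value, then adjusts across terms
#' with Benjamini-Hochberg. With overlap `k`, term size `K`, member
#' count `n` and universe size `N`, `p = P(X >= k)` for
#' `X ~ Hypergeom(N, K, n)`.
#'
#' @param members Character vector of nodes forming the tested set;
#'   nodes outside `universe` are ignored.
#' @param annotations Annotation tibble `node, term`.
#' @param universe Background node set; defaults to every annotated node.
#'
#' @return A tibble `term, overlap, term_size, p, q`, sorted by `q` then
#'   `p`. Empty member sets yield a zero-row tibble.
#' @export
enrich_terms <- function(members, annotations, universe = NULL) {
  universe <- universe %||% unique(annotations$node)
  members <- intersect(unique(members), universe)
  empty <- tibble(term = character(), overlap = integer(),
                  term_size = integer(), p = numeric(), q = numeric())
  if (length(members) == 0) return(empty)

  ann <- annotations |>
    filter(node %in% universe) |>
    distinct(node, term)
  if (nrow(ann) == 0) return(empty)

  N <- length(universe)
  n_members <- length(members)
  res <- ann |>
    group_by(term) |>
    summarise(term_size = n(),
              overlap = sum(node %in% members), .groups = "drop") |>
    mutate(
      p = phyper(overlap - 1, term_size, N - term_size, n_members,
                 lower.tail = FALSE),
      q = p.adjust(p, method = "BH")
    ) |>
    arrange(q, p, term)
  select(res, term, overlap, term_size, p, q)
}

#' Term enrichment of every anchored cluster
#'
#' Runs [enrich_terms()] on each cluster from [define_clusters()].
#'
#' @param clusters A [define_clusters()] tibble.
#' @param annotations Annotation tibble `node, term`.
#' @param universe Background node set; defaults to every annotated node.
#'
#' @return A tibble `cluster_id, anchor, term, overlap, term_size, p, q`
#'   of class `cluster_enrichment`.
#' @export
enrich_clusters <- function(clusters, annotations, universe = NULL) {
  out <- clusters |>
    group_by(cluster_id, anchor) |>
    summarise(members = list(member), .groups = "drop") |>
    mutate(enrichment = purrr::map(
      members, enrich_terms, annotations = annotations, universe = universe
    )) |>
    select(-members) |>
    tidyr::unnest(enrichment)
  class(out) <- c("cluster_enrichment", class(out))
  out
}

#' Plot cluster enrichment results
#'
#' Bar chart of `-log10(q)` for the top terms of each cluster.
#'
#' @param enrichment An [enrich_clusters()] tibble.
#' @param max_terms Terms shown per cluster. Default 5.
#'
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, max_terms = 5) {
  dat <- enrichment |>
    group_by(cluster_id) |>
    slice_min(q, n = max_terms, with_ties = FALSE) |>
    ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(x = -log10(pmax(q, 1e-300)),
                                    y = stats::reorder(term, -q))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~cluster_id, scales = "free_y") +
    ggplot2::labs(x = expression(-log[10](q)), y = NULL,
                  title = "Term enrichment of anchored clusters") +
    ggplot2::theme_minimal()
}
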