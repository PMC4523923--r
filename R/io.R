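#' Read and write the pipeline's tabular formats
#'
#' Plain TSV dialects with fixed headers: spectral counts
#' (`bait prey replicate count id_score`), control purifications
#' (`control_run prey count id_score`), evidence edges
#' (`node_a node_b score channel`), annotations (`node term`), robustness
#' records and score tables.
#'
#' @param path File path.
#' @param x Tibble to write.
#' @name apmsweep-io
NULL

#' @rdname apmsweep-io
#' @export
read_spectral_counts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    bait = readr::col_character(), prey = readr::col_character(),
    replicate = readr::col_integer(), count = readr::col_double(),
    id_score = readr::col_double()
  ))
}

#' @rdname apmsweep-io
#' @export
read_controls <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    control_run = readr::col_character(), prey = readr::col_character(),
    count = readr::col_double(), id_score = readr::col_double()
  ))
}

#' @rdname apmsweep-io
#' @export
read_evidence <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    node_a = readr::col_character(), node_b = readr::col_character(),
    score = readr::col_double(), channel = readr::col_character()
  ))
}

#' @rdname apmsweep-io
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    node = readr::col_character(), term = readr::col_character()
  ))
}

#' @rdname apmsweep-io
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read and write footprint reads as BED
#'
#' 6-column BED (chrom = gene id, 0-based half-open start/end, name,
#' score, strand), via `rtracklayer`.
#'
#' @param path BED file path.
#' @param reads Read tibble as produced by [simulate_footprints()].
#' @return `read_footprints_bed()` returns a tibble `chrom, start, end,
#'   name, score, strand` with 0-based starts.
#' @export
read_footprints_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = gr$name %||% NA_character_,
    score = as.integer(gr$score %||% 0L),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' @rdname read_footprints_bed
#' @export
write_footprints_bed <- function(reads, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$start + 1L, end = reads$end),
    strand = reads$strand,
    name = reads$name,
    score = reads$score
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write and read an interaction network
#'
#' GraphML carries the full attributed graph (node roles; edge class,
#' robustness, maximum average score, external score) and round-trips
#' through [read_network_graphml()]. The SIF writer emits the
#' `node_a  class  node_b` skeleton plus a companion edge-attribute TSV.
#'
#' @param net An [assemble_network()] object.
#' @param path Output path.
#' @export
write_network_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    d = net$edges, directed = FALSE,
    vertices = net$nodes
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble(
    node = igraph::vertex_attr(g, "name"),
    role = igraph::vertex_attr(g, "role")
  ) |>
    arrange(factor(role, levels = c("bait", "prey", "imported")), node)
  el <- igraph::as_edgelist(g)
  edges <- tibble(
    node_a = pmin(el[, 1], el[, 2]),
    node_b = pmax(el[, 1], el[, 2]),
    class = igraph::edge_attr(g, "class"),
    robustness = igraph::edge_attr(g, "robustness"),
    max_avg_score = igraph::edge_attr(g, "max_avg_score"),
    external_score = igraph::edge_attr(g, "external_score")
  ) |>
    arrange(factor(class, levels = edge_class_levels), node_a, node_b)
  structure(
    list(nodes = nodes, edges = edges,
         baits = nodes$node[nodes$role == "bait"], thresholds = list()),
    class = "interaction_network"
  )
}

#' @rdname write_network_graphml
#' @export
write_network_sif <- function(net, path) {
  sif <- sprintf("%s\t%s\t%s", net$edges$node_a, net$edges$class,
                 net$edges$node_b)
  writeLines(sif, path)
  attr_path <- paste0(tools::file_path_sans_ext(path), "_edges.tsv")
  readr::write_tsv(net$edges, attr_path)
  invisible(c(path, attr_path))
}
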