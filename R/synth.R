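#' Configuration for the synthetic AP-MS screen generator
#'
#' Bundles every knob of the simulated tandem-affinity-purification screen:
#' how many baits, preys, control purifications and replicates to emulate,
#' the Poisson rate of the shared contaminant background, the multiplicative
#' enrichment of planted true interactions, and the identification-score
#' model used for the search-engine-score filtering axis.
#'
#' Counts for a bait--prey pair in one purification are drawn
#' `Poisson(depth * background_rate * r)`, where `depth` is a per-purification
#' log-normal depth factor (so spectral-count normalization has something to
#' correct), and `r` is `enrichment` for planted pairs, 1 for contaminant
#' preys present in that purification, and 0 otherwise. A configurable
#' fraction of preys is "sticky": present in most purifications, including
#' the no-bait controls, which gives the background estimator realistic
#' structure.
#'
#' Identification scores emulate search-engine protein scores, which grow
#' with the number of matched spectra: each record's score is
#' `count * U(id_score_range)`, i.e. a uniform per-spectrum score summed
#' over the record's spectra. A single-spectrum identification therefore
#' spans `id_score_range` (default 5--60), so the score-threshold sweep
#' (10--50) prunes low-count identifications while abundant true
#' interactors survive every threshold, as they do in real searches.
#'
#' @param n_baits,n_preys,n_controls,n_replicates Screen dimensions. All
#'   must be at least 1. Default 8 baits x 200 preys with 4 replicate
#'   purifications per bait and 4 no-bait control runs.
#' @param background_rate Mean spectral count of a contaminant prey per
#'   purification (Poisson rate, at depth factor 1). Must be positive.
#' @param enrichment Multiplicative rate factor for planted true pairs
#'   (>= 1). Default 10.
#' @param planted_density Probability that a given bait-prey pair is a
#'   planted true interaction. Default 0.05.
#' @param id_score_range Length-2 numeric, the per-spectrum identification
#'   score interval. Default `c(5, 60)`.
#' @param sticky_fraction Fraction of preys that behave as sticky
#'   contaminants. Default 0.3.
#' @param sticky_presence,background_presence Per-purification presence
#'   probability of sticky and non-sticky contaminant preys. Defaults 0.9
#'   and 0.25.
#' @param depth_sigma Log-scale standard deviation of the log-normal
#'   per-purification depth factors. Default 0.3.
#' @param seed Integer random seed; every draw of the generator flows from
#'   it, so the same configuration always reproduces the same tables.
#'
#' @return An object of class `synth_config` (a named list).
#' @seealso [simulate_apms()]
#' @export
#' @examples
#' cfg <- synth_config(n_baits = 2, n_preys = 20, seed = 42)
#' sim <- simulate_apms(cfg)
#' head(sim$counts)
synth_config <- function(n_baits = 8, n_preys = 200, n_controls = 4,
                         n_replicates = 4, background_rate = 2,
                         enrichment = 10, planted_density = 0.05,
                         id_score_range = c(5, 60), sticky_fraction = 0.3,
                         sticky_presence = 0.9, background_presence = 0.25,
                         depth_sigma = 0.3, seed = 1L) {
  counts <- c(n_baits = n_baits, n_preys = n_preys,
              n_controls = n_controls, n_replicates = n_replicates)
  if (any(counts < 1) || any(counts != floor(counts))) {
    abort("n_baits, n_preys, n_controls and n_replicates must be integers >= 1")
  }
  if (background_rate <= 0) abort("background_rate must be > 0")
  if (enrichment < 1) abort("enrichment must be >= 1")
  if (planted_density < 0 || planted_density > 1) {
    abort("planted_density must be in [0, 1]")
  }
  if (length(id_score_range) != 2 || diff(id_score_range) < 0 ||
      any(id_score_range < 0)) {
    abort("id_score_range must be a non-negative, non-decreasing interval")
  }
  stopifnot(sticky_fraction >= 0, sticky_fraction <= 1,
            sticky_presence >= 0, sticky_presence <= 1,
            background_presence >= 0, background_presence <= 1,
            depth_sigma >= 0)
  structure(
    list(n_baits = as.integer(n_baits), n_preys = as.integer(n_preys),
         n_controls = as.integer(n_controls),
         n_replicates = as.integer(n_replicates),
         background_rate = background_rate, enrichment = enrichment,
         planted_density = planted_density,
         id_score_range = as.numeric(id_score_range),
         sticky_fraction = sticky_fraction,
         sticky_presence = sticky_presence,
         background_presence = background_presence,
         depth_sigma = depth_sigma, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Simulate a bait-prey spectral-count screen with planted interactions
#'
#' Generates the full input of the scoring pipeline: a bait-side
#' spectral-count table, a no-bait control table, and the ground truth
#' needed for recovery tests. See [synth_config()] for the count model.
#' Records with a zero count are not emitted, mirroring real search
#' output in which only identified proteins appear.
#'
#' @param config A [synth_config()] object.
#'
#' @return A list of class `apms_simulation` with elements
#'   * `counts` -- tibble `bait, prey, replicate, count, id_score`,
#'   * `controls` -- tibble `control_run, prey, count, id_score`,
#'   * `truth` -- list with `true_pairs` (tibble `bait, prey`),
#'     `contaminant_preys`, `sticky_preys`, per-purification `bait_depths`
#'     and `control_depths`, the bait and prey id vectors, and the seed.
#' @export
simulate_apms <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::local_seed(config$seed)

  baits <- sprintf("B%02d", seq_len(config$n_baits))
  preys <- sprintf("P%03d", seq_len(config$n_preys))
  sticky <- sort(sample(preys, round(config$sticky_fraction * config$n_preys)))
  presence <- setNames(
    ifelse(preys %in% sticky, config$sticky_presence,
           config$background_presence),
    preys
  )

  true_pairs <- tidyr::expand_grid(bait = baits, prey = preys)
  true_pairs <- true_pairs[runif(nrow(true_pairs)) < config$planted_density, ]

  bait_depths <- tidyr::expand_grid(
    bait = baits, replicate = seq_len(config$n_replicates)
  ) |>
    mutate(depth = rlnorm(n(), meanlog = 0, sdlog = config$depth_sigma))
  control_depths <- tibble(
    control_run = sprintf("CTRL%02d", seq_len(config$n_controls)),
    depth = rlnorm(config$n_controls, meanlog = 0, sdlog = config$depth_sigma)
  )

  true_key <- paste(true_pairs$bait, true_pairs$prey)
  lo <- config$id_score_range[1]
  hi <- config$id_score_range[2]

  counts <- tidyr::expand_grid(bait_depths, prey = preys) |>
    mutate(
      present = runif(n()) < presence[prey],
      is_true = paste(bait, prey) %in% true_key,
      rate = depth * config$background_rate *
        ifelse(is_true, config$enrichment, as.numeric(present)),
      count = rpois(n(), rate)
    ) |>
    filter(count > 0) |>
    mutate(id_score = count * runif(n(), lo, hi)) |>
    select(bait, prey, replicate, count, id_score)

  controls <- tidyr::expand_grid(control_depths, prey = preys) |>
    mutate(
      present = runif(n()) < presence[prey],
      count = rpois(n(), depth * config$background_rate * as.numeric(present))
    ) |>
    filter(count > 0) |>
    mutate(id_score = count * runif(n(), lo, hi)) |>
    select(control_run, prey, count, id_score)

  structure(
    list(
      counts = counts,
      controls = controls,
      truth = list(
        true_pairs = as_tibble(true_pairs),
        contaminant_preys = preys,
        sticky_preys = sticky,
        bait_depths = bait_depths,
        control_depths = control_depths,
        baits = baits,
        preys = preys,
        seed = config$seed
      ),
      config = config
    ),
    class = "apms_simulation"
  )
}

#' @export
print.apms_simulation <- function(x, ...) {
  cat(sprintf(
    "<apms_simulation> %d baits x %d preys, %d replicates, %d controls (seed %d)\n",
    x$config$n_baits, x$config$n_preys, x$config$n_replicates,
    x$config$n_controls, x$config$seed
  ))
  cat(sprintf("  %d bait-side records, %d control records, %d planted pairs\n",
              nrow(x$counts), nrow(x$controls), nrow(x$truth$true_pairs)))
  invisible(x)
}

#' Simulate an external-evidence edge table
#'
#' Emulates a STRING-like table of node-pair confidences with an evidence
#' channel. Each planted true pair gains an experimental-channel edge with
#' probability `support_prob` (this Bernoulli draw is the generator's first
#' use of the random stream, so it can be replayed independently from the
#' seed). Noise edges connect random screen nodes in a random channel.
#' Optional imported nodes -- ids prefixed `IMP` -- attach to randomly
#' chosen anchor nodes from the screen through high-confidence
#' experimental edges, which is the raw material for degree-one anchored
#' clusters downstream.
#'
#' @param truth The `truth` element of an [simulate_apms()] result (or any
#'   list with `true_pairs`, `baits`, `preys`, `seed`).
#' @param support_prob Probability that a planted pair receives an
#'   experimental-channel edge. Default 0.7.
#' @param noise_edges Number of random noise edges to draw. Default 30.
#' @param n_imported Number of imported (off-screen) nodes. Default 0.
#' @param n_anchors Number of distinct screen nodes the imported nodes
#'   attach to; defaults to about one anchor per five imported nodes.
#' @param min_imported_score Lower bound of the uniform score interval for
#'   imported-node edges. Default 0.9, so imported edges clear the usual
#'   external-import threshold.
#' @param seed Random seed; defaults to the truth's seed.
#'
#' @return A tibble `node_a, node_b, score, channel` with unordered pairs
#'   unique per channel and scores in `[0, 1]`.
#' @export
simulate_evidence <- function(truth, support_prob = 0.7, noise_edges = 30,
                              n_imported = 0, n_anchors = NULL,
                              min_imported_score = 0.9, seed = truth$seed) {
  stopifnot(support_prob >= 0, support_prob <= 1, noise_edges >= 0,
            n_imported >= 0)
  withr::local_seed(seed)

  tp <- truth$true_pairs
  supported <- if (nrow(tp)) runif(nrow(tp)) < support_prob else logical(0)
  true_edges <- tibble(
    node_a = tp$bait[supported], node_b = tp$prey[supported],
    score = runif(sum(supported)), channel = "experimental"
  )

  nodes <- c(truth$baits, truth$preys)
  noise <- tibble(
    node_a = sample(nodes, noise_edges, replace = TRUE),
    node_b = sample(nodes, noise_edges, replace = TRUE),
    score = runif(noise_edges),
    channel = sample(c("experimental", "other"), noise_edges, replace = TRUE)
  ) |>
    filter(node_a != node_b)

  imported <- tibble()
  if (n_imported > 0) {
    n_anchors <- n_anchors %||% max(1L, ceiling(n_imported / 5))
    anchors <- sample(nodes, min(n_anchors, length(nodes)))
    imported <- tibble(
      node_a = sprintf("IMP%02d", seq_len(n_imported)),
      node_b = sample(anchors, n_imported, replace = TRUE),
      score = runif(n_imported, min_imported_score, 1),
      channel = "experimental"
    )
  }

  bind_rows(true_edges, noise, imported) |>
    mutate(key = pair_key(node_a, node_b)) |>
    group_by(key, channel) |>
    slice_max(score, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select(node_a, node_b, score, channel) |>
    arrange(channel, node_a, node_b)
}

#' Simulate ribosome-footprint read positions over a gene
#'
#' Reads fall uniformly downstream of the true translation start, except
#' for a fraction `leak` scattered uniformly over the whole region
#' (background: scanning ribosomes, mapping noise). Coordinates are
#' 0-based half-open; only 5' read starts are modelled.
#'
#' @param gene_length Region length in bp.
#' @param annotated_start Annotated start-codon coordinate (0-based).
#' @param true_start True start-codon coordinate; must satisfy
#'   `annotated_start <= true_start < gene_length`.
#' @param depth Total number of reads (>= 0).
#' @param leak Fraction of reads scattered over the whole region.
#' @param gene_id Region name used as the BED chromosome field.
#' @param seed Random seed.
#'
#' @return A tibble of BED-like records `chrom, start, end, name, score,
#'   strand` with `end = start + 1` (5' ends).
#' @export
simulate_footprints <- function(gene_length = 900, annotated_start = 0,
                                true_start = 108, depth = 5000, leak = 0.01,
                                gene_id = "GENE", seed = 1L) {
  if (depth < 0) abort("depth must be >= 0")
  stopifnot(annotated_start >= 0, annotated_start <= true_start,
            true_start < gene_length, leak >= 0, leak <= 1)
  withr::local_seed(seed)

  n_leak <- rbinom(1, depth, leak)
  starts <- c(
    floor(runif(n_leak, 0, gene_length)),
    floor(runif(depth - n_leak, true_start, gene_length))
  )
  tibble(
    chrom = gene_id,
    start = as.integer(starts),
    end = as.integer(starts) + 1L,
    name = if (depth > 0) sprintf("read%05d", seq_len(depth)) else character(0),
    score = 0L,
    strand = "+"
  )
}

#' Simulate a node-to-term annotation table
#'
#' Draws an annotation table over `nodes` with `n_terms` terms. The first
#' term is the planted term: it annotates the whole `planted_nodes` subset
#' plus background nodes at rate `background_rate`. Every other term
#' annotates each node independently with probability `term_prob`.
#'
#' @param nodes Character vector of node ids (the annotation universe).
#' @param n_terms Total number of terms, including the planted one. With
#'   `n_terms = 0` the table is empty.
#' @param planted_term Id of the planted term. Default `"GO:PLANTED"`.
#' @param planted_nodes Subset of `nodes` the planted term annotates in
#'   full; must be contained in `nodes`.
#' @param background_rate Probability that the planted term also
#'   annotates a node outside `planted_nodes`. Default 0.05.
#' @param term_prob Per-node annotation probability of the non-planted
#'   terms. Default 0.15.
#' @param seed Random seed.
#'
#' @return A tibble `node, term`, one row per annotation.
#' @export
simulate_annotations <- function(nodes, n_terms = 20,
                                 planted_term = "GO:PLANTED",
                                 planted_nodes = character(),
                                 background_rate = 0.05, term_prob = 0.15,
                                 seed = 1L) {
  stopifnot(all(planted_nodes %in% nodes), n_terms >= 0)
  if (n_terms == 0) return(tibble(node = character(), term = character()))
  withr::local_seed(seed)

  planted <- tibble(
    node = union(planted_nodes, nodes[runif(length(nodes)) < background_rate]),
    term = planted_term
  )
  others <- purrr::map_dfr(seq_len(n_terms - 1), function(i) {
    tibble(node = nodes[runif(length(nodes)) < term_prob],
           term = sprintf("GO:%04d", i))
  })
  bind_rows(planted, others) |>
    distinct(node, term) |>
    arrange(term, node)
}
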