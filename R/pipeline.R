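#' Configuration of the end-to-end demonstration pipeline
#'
#' Bundles the settings of every stage: the synthetic screen, the scorer
#' defaults, the sweep grid, network thresholds, enrichment and
#' start-site settings, and one global seed from which every stage's
#' substream seed is derived.
#'
#' @param synth A [synth_config()] for the simulated screen.
#' @param scoring A [scoring_options()] used as the sweep's base options.
#' @param grid List with `tau_range`, `m_values`, `include_cap_axis`,
#'   `include_norm_axis` for [build_parameter_grid()].
#' @param evidence List with `support_prob`, `noise_edges`, `n_imported`
#'   for [simulate_evidence()].
#' @param network List with `min_external_score`, `marginal_band`,
#'   `chain_imports` for [assemble_network()].
#' @param enrichment List with `n_terms`, `background_rate`, `term_prob`
#'   for [simulate_annotations()] and [enrich_clusters()].
#' @param startsite List with `gene_length`, `annotated_start`,
#'   `true_start`, `depth`, `leak`, `window`, `ratio_min`.
#' @param seed Global integer seed.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(
    synth = synth_config(),
    scoring = scoring_options(),
    grid = list(tau_range = c(0.8, 0.95, 0.01),
                m_values = c(10, 20, 30, 40, 50),
                include_cap_axis = TRUE, include_norm_axis = TRUE),
    evidence = list(support_prob = 0.7, noise_edges = 30, n_imported = 25),
    network = list(min_external_score = 0.9, marginal_band = c(0.7, 0.8),
                   chain_imports = FALSE),
    enrichment = list(n_terms = 20, background_rate = 0.05,
                      term_prob = 0.15),
    startsite = list(gene_length = 900, annotated_start = 0,
                     true_start = 108, depth = 5000, leak = 0.01,
                     window = 30, ratio_min = 5),
    seed = 1L) {
  structure(
    list(synth = synth, scoring = scoring, grid = grid,
         evidence = evidence, network = network, enrichment = enrichment,
         startsite = startsite, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; absent
#' keys keep their defaults. The `synth` and `scoring` blocks are passed
#' to [synth_config()] and [scoring_options()] as arguments.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  merge_block <- function(name) {
    utils::modifyList(defaults[[name]], y[[name]] %||% list())
  }
  pipeline_config(
    synth = do.call(synth_config, y$synth %||% list()),
    scoring = do.call(scoring_options, y$scoring %||% list()),
    grid = merge_block("grid"),
    evidence = merge_block("evidence"),
    network = merge_block("network"),
    enrichment = merge_block("enrichment"),
    startsite = merge_block("startsite"),
    seed = y$seed %||% defaults$seed
  )
}

# stage substream seeds, all derived from the one global seed
stage_seeds <- function(seed, stages) {
  withr::with_seed(seed, setNames(sample.int(.Machine$integer.max, length(stages)), stages))
}

#' Run the full demonstration pipeline
#'
#' Executes the six stages -- simulate, score, sweep, network, cluster,
#' startsite -- writing every intermediate as a plain-text file under
#' `outdir` and returning a manifest with the seed, the per-stage
#' parameters, and an MD5 digest of every output file. The same
#' configuration and seed always reproduce identical digests. Each
#' stage's randomness flows from a named substream seed derived from the
#' global seed, so stages can be re-run in isolation.
#'
#' @param config A [pipeline_config()] object.
#' @param outdir Output directory, created if needed.
#' @param quiet If `TRUE`, suppress the per-stage progress lines written
#'   to `stderr`.
#'
#' @return The manifest, invisibly: a list with `seed`, `stages` (name,
#'   parameters, output digests) and `outdir`. Also written as
#'   `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("apmsweep_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- c("simulate", "score", "sweep", "network", "cluster", "startsite")
  seeds <- stage_seeds(config$seed, stages)
  manifest <- list(seed = config$seed, outdir = outdir, stages = list())
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  record <- function(name, params, files) {
    digests <- as.list(tools::md5sum(files))
    names(digests) <- basename(files)
    manifest$stages[[name]] <<- list(name = name, params = params,
                                     outputs = digests)
  }
  run_stage <- function(name, fun) {
    say("[%s] starting (seed %d)", name, seeds[[name]])
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    say("[%s] done in %.1fs", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  # --- simulate: every input the later stages consume ---------------------
  sim <- run_stage("simulate", function() {
    cfg <- config$synth
    cfg$seed <- seeds[["simulate"]]
    sim <- simulate_apms(cfg)
    ev <- simulate_evidence(
      sim$truth, support_prob = config$evidence$support_prob,
      noise_edges = config$evidence$noise_edges,
      n_imported = config$evidence$n_imported
    )
    imported_nodes <- setdiff(unique(c(ev$node_a, ev$node_b)),
                              c(sim$truth$baits, sim$truth$preys))
    # planted cluster: imported nodes sharing the most frequent anchor
    imp_edges <- filter(ev, node_a %in% imported_nodes |
                          node_b %in% imported_nodes)
    anchors <- c(imp_edges$node_b[imp_edges$node_a %in% imported_nodes],
                 imp_edges$node_a[imp_edges$node_b %in% imported_nodes])
    planted_anchor <- if (length(anchors)) names(sort(table(anchors),
                                                     decreasing = TRUE))[1]
                      else character(0)
    planted_nodes <- unique(c(
      imp_edges$node_a[imp_edges$node_b %in% planted_anchor],
      imp_edges$node_b[imp_edges$node_a %in% planted_anchor]
    ))
    planted_nodes <- intersect(planted_nodes, imported_nodes)
    ann <- simulate_annotations(
      nodes = unique(c(sim$truth$baits, sim$truth$preys, imported_nodes)),
      n_terms = config$enrichment$n_terms,
      planted_nodes = planted_nodes,
      background_rate = config$enrichment$background_rate,
      term_prob = config$enrichment$term_prob,
      seed = seeds[["simulate"]]
    )
    ss <- config$startsite
    reads <- simulate_footprints(
      gene_length = ss$gene_length, annotated_start = ss$annotated_start,
      true_start = ss$true_start, depth = ss$depth, leak = ss$leak,
      seed = seeds[["simulate"]]
    )
    files <- file.path(outdir, c("counts.tsv", "controls.tsv",
                                 "evidence.tsv", "annotations.tsv",
                                 "true_pairs.tsv"))
    write_table_tsv(sim$counts, files[1])
    write_table_tsv(sim$controls, files[2])
    write_table_tsv(ev, files[3])
    write_table_tsv(ann, files[4])
    write_table_tsv(sim$truth$true_pairs, files[5])
    bed <- file.path(outdir, "footprints.bed")
    write_footprints_bed(reads, bed)
    record("simulate", list(seed = seeds[["simulate"]],
                            n_baits = cfg$n_baits, n_preys = cfg$n_preys),
           c(files, bed))
    list(sim = sim, evidence = ev, annotations = ann, reads = reads)
  })

  # --- score: one pass at the base options --------------------------------
  scores <- run_stage("score", function() {
    sc <- score_dataset(sim$sim$counts, sim$sim$controls, config$scoring)
    f <- file.path(outdir, "scores.tsv")
    write_table_tsv(select(sc, bait, prey, avg_score, n_replicates), f)
    record("score", list(options = unclass(config$scoring)), f)
    sc
  })

  # --- sweep --------------------------------------------------------------
  records <- run_stage("sweep", function() {
    grid <- build_parameter_grid(
      tau_range = config$grid$tau_range, m_values = config$grid$m_values,
      include_cap_axis = config$grid$include_cap_axis,
      include_norm_axis = config$grid$include_norm_axis
    )
    sw <- run_sweep(sim$sim$counts, sim$sim$controls, grid, config$scoring)
    rec <- tidy(sw)
    f <- file.path(outdir, "robustness.tsv")
    write_table_tsv(rec, f)
    record("sweep", list(n_combos = nrow(grid$combos)), f)
    rec
  })

  # --- network ------------------------------------------------------------
  net <- run_stage("network", function() {
    net <- assemble_network(
      records, sim$evidence,
      min_external_score = config$network$min_external_score,
      marginal_band = config$network$marginal_band,
      chain_imports = config$network$chain_imports
    )
    gml <- file.path(outdir, "network.graphml")
    sif <- file.path(outdir, "network.sif")
    write_network_graphml(net, gml)
    sif_files <- write_network_sif(net, sif)
    record("network",
           list(min_external_score = config$network$min_external_score),
           c(gml, sif_files))
    net
  })

  # --- cluster ------------------------------------------------------------
  run_stage("cluster", function() {
    clusters <- define_clusters(net)
    enr <- enrich_clusters(clusters, sim$annotations)
    f <- file.path(outdir, "enrichment.tsv")
    write_table_tsv(enr, f)
    record("cluster", list(n_clusters = dplyr::n_distinct(clusters$cluster_id)), f)
    enr
  })

  # --- startsite ----------------------------------------------------------
  run_stage("startsite", function() {
    ss <- config$startsite
    track <- bin_reads(
      sim$reads, gene_length = ss$gene_length, window = ss$window,
      annotated_start = ss$annotated_start,
      candidate_starts = c(ss$annotated_start, ss$true_start)
    )
    call <- call_start_codon(track, ratio_min = ss$ratio_min)
    f1 <- file.path(outdir, "start_site.tsv")
    f2 <- file.path(outdir, "footprint_profile.tsv")
    write_table_tsv(glance(call), f1)
    write_table_tsv(tidy(call), f2)
    record("startsite", list(window = ss$window, ratio_min = ss$ratio_min),
           c(f1, f2))
    call
  })

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
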