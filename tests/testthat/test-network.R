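test_that("external support uses the experimental channel at any score", {
  ev <- five_class_evidence()
  pairs <- tibble::tibble(
    node_a = c("B1", "B1", "B1"),
    node_b = c("P1", "P2", "P9")
  )
  expect_identical(has_external_support(pairs, ev), c(TRUE, FALSE, FALSE))
  # order of the pair does not matter
  expect_true(has_external_support(
    tibble::tibble(node_a = "P1", node_b = "B1"), ev
  ))
})

test_that("edge classes cover the discretized state space exactly once", {
  states <- tidyr::expand_grid(
    candidate = c(TRUE, FALSE),
    robustness = c(0.6, 0.5, 0.4),
    max_avg_score = c(0.85, 0.8, 0.75, 0.7, 0.65),
    supported = c(TRUE, FALSE)
  )
  got <- assign_edge_class(states$candidate, states$robustness,
                           states$max_avg_score, states$supported)
  # independent restatement of the legend rules
  expected <- mapply(function(cand, rob, score, sup) {
    if (cand && rob >= 0.5 && sup) return("TAPMS_SUPPORTED")
    if (cand && rob >= 0.5) return("TAPMS_ROBUST")
    if (cand) return("TAPMS_LOW")
    if (!cand && sup && score > 0.7 && score <= 0.8) {
      return("TAPMS_MARGINAL_SUPPORTED")
    }
    NA_character_
  }, states$candidate, states$robustness, states$max_avg_score,
  states$supported)
  expect_identical(got, unname(expected))
  # each state maps to at most one class: assign_edge_class is a function
  expect_identical(length(got), nrow(states))
})

test_that("external import honours threshold and connectivity", {
  ev <- five_class_evidence()
  imp <- import_external_edges(c("B1", "P1", "P2"), ev, min_score = 0.9)
  expect_identical(pair_key_test(imp$node_a, imp$node_b),
                   pair_key_test("P1", "X1"))
  # 0.85 edge and the disconnected 0.99 edge are excluded
  expect_false("X4" %in% c(imp$node_a, imp$node_b))
  expect_false("X2" %in% c(imp$node_a, imp$node_b))

  # chaining brings in edges reachable through kept edges
  chain_ev <- tibble::tibble(
    node_a = c("P1", "X1"), node_b = c("X1", "X2"),
    score = 0.95, channel = "experimental"
  )
  chained <- import_external_edges("P1", chain_ev, chain = TRUE)
  expect_identical(nrow(chained), 2L)
  unchained <- import_external_edges("P1", chain_ev, chain = FALSE)
  expect_identical(nrow(unchained), 1L)
})

test_that("assembly produces one edge of each class on the full fixture", {
  net <- assemble_network(five_class_records(extra_low = TRUE), five_class_evidence())
  # hand-built expectation: class -> unordered pair(s)
  expected <- tibble::tribble(
    ~node_a, ~node_b, ~class,
    "B1", "P1", "TAPMS_SUPPORTED",
    "B1", "P2", "TAPMS_ROBUST",
    "B1", "P3", "TAPMS_LOW",
    "B2", "P4", "TAPMS_LOW",
    "B1", "P4", "TAPMS_MARGINAL_SUPPORTED",
    "P1", "X1", "EXTERNAL_ONLY"
  )
  got <- dplyr::arrange(net$edges[, c("node_a", "node_b", "class")],
                        node_a, node_b)
  expect_identical(got, dplyr::arrange(expected, node_a, node_b))
  expect_setequal(unique(net$edges$class),
                  c("TAPMS_SUPPORTED", "TAPMS_ROBUST", "TAPMS_LOW",
                    "TAPMS_MARGINAL_SUPPORTED", "EXTERNAL_ONLY"))
  # B1-P5 (max score 0.6) draws no edge; imported node has an edge
  expect_false("P5" %in% net$nodes$node)
  expect_identical(net$nodes$role[net$nodes$node == "X1"], "imported")
  expect_true(all(net$edges$node_a != net$edges$node_b))
})

test_that("simple assemblies behave at the boundaries", {
  empty_rec <- five_class_records()[0, ]
  net0 <- assemble_network(empty_rec, NULL)
  expect_identical(nrow(net0$nodes), 0L)
  expect_identical(nrow(net0$edges), 0L)

  one <- tibble::tibble(bait = "B1", prey = "P1", calls = 300L,
                        robustness = 0.94, max_avg_score = 0.95,
                        candidate = TRUE)
  ev <- tibble::tibble(node_a = "B1", node_b = "P1", score = 0.3,
                       channel = "experimental")
  net1 <- assemble_network(one, ev)
  expect_identical(nrow(net1$nodes), 2L)
  expect_identical(net1$edges$class, "TAPMS_SUPPORTED")
})

test_that("reciprocal observations merge keeping the maximum", {
  rec <- tibble::tibble(
    bait = c("A", "B"), prey = c("B", "A"),
    calls = c(100L, 300L), robustness = c(100, 300) / 320,
    max_avg_score = c(0.82, 0.95), candidate = TRUE
  )
  net <- assemble_network(rec, NULL)
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$robustness, 300 / 320)
  expect_equal(net$edges$max_avg_score, 0.95)
  expect_identical(net$edges$class, "TAPMS_ROBUST")
})

test_that("dropping the evidence table degrades classes predictably", {
  with_ev <- assemble_network(five_class_records(extra_low = TRUE), five_class_evidence())
  without <- assemble_network(five_class_records(extra_low = TRUE), NULL)

  key <- function(net) pair_key_test(net$edges$node_a, net$edges$node_b)
  expect_false(any(without$edges$class %in%
                     c("TAPMS_SUPPORTED", "EXTERNAL_ONLY",
                       "TAPMS_MARGINAL_SUPPORTED")))
  supported_pairs <- key(with_ev)[with_ev$edges$class == "TAPMS_SUPPORTED"]
  expect_identical(
    sort(key(without)[without$edges$class == "TAPMS_ROBUST"]),
    sort(union(
      supported_pairs,
      key(with_ev)[with_ev$edges$class == "TAPMS_ROBUST"]
    ))
  )
  dropped_nodes <- setdiff(with_ev$nodes$node, without$nodes$node)
  expect_identical(
    sort(dropped_nodes),
    sort(with_ev$nodes$node[with_ev$nodes$role == "imported"])
  )
})

test_that("the attributed network round-trips through GraphML", {
  net <- assemble_network(five_class_records(extra_low = TRUE), five_class_evidence())
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, path)
  back <- read_network_graphml(path)
  expect_identical(back$nodes, net$nodes)
  expect_identical(back$edges$class, net$edges$class)
  expect_equal(back$edges$robustness, net$edges$robustness)
  expect_equal(back$edges$max_avg_score, net$edges$max_avg_score)
  # NA external scores survive as missing values
  expect_identical(is.na(back$edges$external_score),
                   is.na(net$edges$external_score))

  sif_paths <- write_network_sif(net, withr::local_tempfile(fileext = ".sif"))
  sif <- readLines(sif_paths[1])
  expect_length(sif, nrow(net$edges))
})
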