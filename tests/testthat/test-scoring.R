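make_table <- function(...) tibble::tribble(...)

test_that("filters are the identity when disabled and empty when total", {
  tab <- make_table(
    ~bait, ~prey, ~replicate, ~count, ~id_score,
    "B1", "P1", 1L, 5, 20,
    "B1", "P2", 1L, 3, 45
  )
  expect_identical(apply_filters(tab, scoring_options()), tab)
  expect_warning(
    out <- apply_filters(tab, scoring_options(id_score_min = 50)),
    "no records"
  )
  expect_identical(nrow(out), 0L)
})

test_that("high-count capping replaces extremes by the floored quantile", {
  tab <- tibble::tibble(bait = "B1", prey = paste0("P", 1:4), replicate = 1L,
                        count = c(1, 2, 3, 100), id_score = 30)
  out <- apply_filters(tab, scoring_options(cap_high_counts = TRUE))
  # type-7 quantile of {1,2,3,100} at 0.95: 3 + 0.85 * (100 - 3) = 85.45,
  # floored to 85
  expect_identical(out$count, c(1, 2, 3, 85))
})

test_that("normalization rescales every purification total to the median", {
  tab <- tibble::tibble(
    bait = rep("B1", 6), prey = rep(paste0("P", 1:2), 3),
    replicate = rep(1:3, each = 2),
    count = c(4, 6, 10, 10, 8, 22), id_score = 30
  )
  # scale one purification by an integer factor: pre-rounding totals must
  # come back to the common median
  scaled <- dplyr::mutate(tab, count = ifelse(replicate == 2, count * 3, count))
  for (x in list(tab, scaled)) {
    raw_totals <- x |>
      dplyr::group_by(replicate) |>
      dplyr::summarise(total = sum(count)) |>
      dplyr::pull(total)
    norm <- apmsweep:::normalize_counts(x, round_counts = FALSE)
    totals <- norm |>
      dplyr::group_by(replicate) |>
      dplyr::summarise(total = sum(count)) |>
      dplyr::pull(total)
    expect_equal(totals, rep(median(raw_totals), 3))
  }
  # rounded output is integral
  out <- apply_filters(tab, scoring_options(normalize = TRUE))
  expect_true(all(out$count == round(out$count)))
})

test_that("background rate follows the pooled pseudocount formula", {
  # 4 baits x 3 replicates observed nowhere: excluding the scored bait
  # leaves 9 purifications
  tab <- tidyr::expand_grid(bait = paste0("B", 1:4), replicate = 1:3) |>
    dplyr::mutate(prey = "Pother", count = 1, id_score = 30)
  ctrl0 <- tibble::tibble(control_run = character(), prey = character(),
                          count = numeric(), id_score = numeric())
  expect_equal(
    estimate_background_rate("Pnew", tab, ctrl0, scoring_options(),
                             exclude_bait = "B1"),
    0.5 / 9.5
  )

  # count 3 in each of 4 control runs, no other baits
  one_bait <- dplyr::filter(tab, bait == "B1")
  ctrl <- tibble::tibble(control_run = paste0("C", 1:4), prey = "P1",
                         count = 3, id_score = 30)
  expect_equal(
    estimate_background_rate("P1", one_bait, ctrl, scoring_options(),
                             exclude_bait = "B1"),
    12.5 / 4.5
  )

  # vanishing pseudocount is caught by the rate floor
  opts <- scoring_options(pseudocount = 1e-9)
  expect_equal(
    estimate_background_rate("Pnew", tab, ctrl0, opts, exclude_bait = "B1"),
    opts$lambda_floor
  )
})

test_that("posterior equals the prior at likelihood equality", {
  for (x in c(0, 1, 5, 20)) {
    expect_equal(posterior_true(x, 3, 3, 0.1), 0.1, tolerance = 1e-14)
    expect_equal(posterior_true(x, 3, 3, 0.5), 0.5, tolerance = 1e-14)
  }
})

test_that("score_pair reproduces the closed-form two-Poisson posterior", {
  # controls give lambda_false = (2 + 0.5) / (2 + 0.5) = 1;
  # counts (10, 10, 10, 10) give lambda_true = 10
  tab <- tibble::tibble(bait = "B1", prey = "P1", replicate = 1:4,
                        count = 10, id_score = 30)
  ctrl <- tibble::tibble(control_run = paste0("C", 1:2), prey = "P1",
                         count = 1, id_score = 30)
  res <- score_pair("B1", "P1", tab, ctrl)
  # independent direct evaluation, no dpois
  pois <- function(x, l) exp(-l) * l^x / factorial(x)
  expected <- 0.1 * pois(10, 10) / (0.1 * pois(10, 10) + 0.9 * pois(10, 1))
  expect_equal(res$avg_score, expected, tolerance = 1e-12)
  expect_equal(res$lambda_true, 10)
  expect_equal(res$lambda_false, 1)
  expect_length(res$replicate_posteriors[[1]], 4)
})

test_that("all-zero pairs are excluded from scoring", {
  tab <- tibble::tibble(bait = "B1", prey = c("P1", "P2"), replicate = 1L,
                        count = c(0, 4), id_score = 30)
  ctrl <- tibble::tibble(control_run = "C1", prey = "P1", count = 1,
                         id_score = 30)
  res <- score_dataset(tab, ctrl)
  expect_identical(res$prey, "P2")
  expect_identical(nrow(score_pair("B1", "P1", tab, ctrl)), 0L)
})

test_that("score_dataset returns an empty tibble for an empty screen", {
  empty <- tibble::tibble(bait = character(), prey = character(),
                          replicate = integer(), count = numeric(),
                          id_score = numeric())
  ctrl <- tibble::tibble(control_run = character(), prey = character(),
                         count = numeric(), id_score = numeric())
  expect_identical(nrow(score_dataset(empty, ctrl)), 0L)
})

test_that("a prey matching its control rate scores below the prior", {
  tab <- tibble::tibble(bait = "B1", prey = "P1", replicate = 1:4,
                        count = 5, id_score = 30)
  ctrl <- tibble::tibble(control_run = paste0("C", 1:4), prey = "P1",
                         count = 5, id_score = 30)
  res <- score_dataset(tab, ctrl)
  expect_lt(res$avg_score, scoring_options()$prior_true)
})

test_that("avg_score is invariant to replicate order", {
  sim <- tiny_screen(seed = 21)
  shuffled <- sim$counts[sample(nrow(sim$counts)), ]
  expect_equal(
    score_dataset(sim$counts, sim$controls),
    score_dataset(shuffled, sim$controls)
  )
})

test_that("the single-count posterior is monotone in the count", {
  withr::with_seed(31, {
    for (i in 1:100) {
      lf <- runif(1, 0.05, 10)
      lt <- lf * runif(1, 1.01, 20)
      pi0 <- runif(1, 0.01, 0.99)
      post <- posterior_true(0:50, lf, lt, pi0)
      expect_true(all(diff(post) >= -1e-12))
      expect_true(all(post >= 0 & post <= 1))
    }
  })
})

test_that("planted pairs score above 0.8 in nearly all seeded screens", {
  # the generator plants per-purification depth variation, so the matched
  # analysis scores with spectral-count normalization on
  opts <- scoring_options(normalize = TRUE)
  hits <- 0L
  total <- 0L
  for (s in 1:100) {
    sim <- simulate_apms(synth_config(
      n_baits = 8, n_preys = 200, n_replicates = 4, background_rate = 2,
      enrichment = 10, planted_density = 0.05, seed = s
    ))
    if (nrow(sim$truth$true_pairs) == 0) next
    res <- score_dataset(sim$counts, sim$controls, opts) |>
      dplyr::semi_join(sim$truth$true_pairs, by = c("bait", "prey"))
    hits <- hits + sum(res$avg_score > 0.8)
    total <- total + nrow(sim$truth$true_pairs)
  }
  expect_gte(hits / total, 0.95)
})
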