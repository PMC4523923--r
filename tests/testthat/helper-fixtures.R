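library(dplyr)

`%||%` <- function(a, b) if (is.null(a)) b else a

# small simulated screen for sweep-level tests
tiny_screen <- function(seed = 42, n_baits = 3, n_preys = 10) {
  simulate_apms(synth_config(
    n_baits = n_baits, n_preys = n_preys, n_controls = 2, n_replicates = 3,
    planted_density = 0.15, seed = seed
  ))
}

pair_id <- function(d) paste(d$bait, d$prey)

# unordered pair key, written independently of the package internals
pair_key_test <- function(a, b) paste(pmin(a, b), pmax(a, b))

# hand-constructed robustness records covering all five edge situations;
# with extra_low, P4 carries a second low edge from B2 so dropping the
# evidence table never removes a screen node
five_class_records <- function(extra_low = FALSE) {
  rec <- tibble::tribble(
    ~bait, ~prey, ~calls, ~robustness, ~max_avg_score, ~candidate,
    "B1", "P1", 256L, 0.8, 0.90, TRUE,  # robust + supported
    "B1", "P2", 224L, 0.7, 0.90, TRUE,  # robust, unsupported
    "B1", "P3",  64L, 0.2, 0.85, TRUE,  # candidate, low robustness
    "B1", "P4",   0L, 0.0, 0.75, FALSE, # marginal, supported
    "B1", "P5",   0L, 0.0, 0.60, FALSE  # below every band: no edge
  )
  if (extra_low) {
    rec <- dplyr::bind_rows(rec, tibble::tibble(
      bait = "B2", prey = "P4", calls = 64L, robustness = 0.2,
      max_avg_score = 0.85, candidate = TRUE
    ))
  }
  rec
}

five_class_evidence <- function() {
  tibble::tribble(
    ~node_a, ~node_b, ~score, ~channel,
    "B1", "P1", 0.20, "experimental",  # supports the robust pair, any score
    "B1", "P4", 0.50, "experimental",  # supports the marginal pair
    "P1", "X1", 0.95, "experimental",  # imported, above threshold
    "P2", "X4", 0.85, "experimental",  # below import threshold
    "X2", "X3", 0.99, "experimental",  # disconnected from the screen
    "B1", "P2", 0.99, "other"          # wrong channel: no support
  )
}
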