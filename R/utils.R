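# max() that returns NA instead of warning on empty / all-NA input
max_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else max(x)
}

# canonical key for an unordered node pair
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# purification identifier columns of a spectral-count or control table
purif_keys <- function(x) {
  if (all(c("bait", "replicate") %in% names(x))) {
    c("bait", "replicate")
  } else if ("control_run" %in% names(x)) {
    "control_run"
  } else {
    abort("table must have bait/replicate or control_run columns")
  }
}
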