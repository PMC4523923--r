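#' Bin footprint read starts over a gene region
#'
#' Assigns each read's 5' start position to fixed-width windows over
#' `[0, gene_length)` (0-based half-open): bin `i` counts reads with
#' start in `[i * window, (i + 1) * window)`. The last bin may be
#' shorter when the window does not divide the gene length. The total
#' read count is conserved and the result does not depend on read order.
#'
#' @param reads A tibble with a `start` column of 0-based read start
#'   positions (e.g. from [read_footprints_bed()] or
#'   [simulate_footprints()]), or a bare numeric vector of starts.
#' @param gene_length Region length in bp.
#' @param window Bin width in bp. Default 30.
#' @param gene_id Region name; taken from a `chrom` column when present.
#' @param annotated_start Annotated start-codon coordinate carried on the
#'   track for [call_start_codon()]. Default 0.
#' @param candidate_starts Optional sorted coordinates of candidate start
#'   codons, carried on the track.
#'
#' @return An object of class `footprint_track`: a list with the binning
#'   metadata and a `bins` tibble `bin, bin_start, bin_end, count`.
#' @export
bin_reads <- function(reads, gene_length, window = 30, gene_id = NULL,
                      annotated_start = 0, candidate_starts = NULL) {
  starts <- if (is.data.frame(reads)) reads$start else as.numeric(reads)
  if (is.data.frame(reads) && is.null(gene_id) && "chrom" %in% names(reads)) {
    gene_id <- unique(reads$chrom)[1]
  }
  stopifnot(gene_length > 0, window > 0)
  bad <- starts[starts < 0 | starts >= gene_length]
  if (length(bad)) {
    abort(sprintf(
      "%d read(s) outside [0, %d): %s", length(bad), gene_length,
      paste(utils::head(sort(unique(bad)), 10), collapse = ", ")
    ))
  }

  n_bins <- ceiling(gene_length / window)
  idx <- floor(starts / window)
  counts <- tabulate(idx + 1, nbins = n_bins)
  bins <- tibble(
    bin = seq_len(n_bins) - 1L,
    bin_start = (seq_len(n_bins) - 1L) * window,
    bin_end = pmin(seq_len(n_bins) * window, gene_length),
    count = as.integer(counts)
  )
  structure(
    list(gene_id = gene_id %||% "gene", gene_length = gene_length,
         window = window, bins = bins,
         annotated_start = annotated_start,
         candidate_starts = sort(candidate_starts)),
    class = "footprint_track"
  )
}

#' @export
print.footprint_track <- function(x, ...) {
  cat(sprintf(
    "<footprint_track> %s: %d bp, %d bins of %d bp, %d reads\n",
    x$gene_id, x$gene_length, nrow(x$bins), x$window, sum(x$bins$count)
  ))
  invisible(x)
}

# reads attributed to [lo, hi), allocating straddling bins by bp overlap
# (reads assumed uniform within a bin)
region_reads <- function(track, lo, hi) {
  b <- track$bins
  ov <- pmax(0, pmin(b$bin_end, hi) - pmax(b$bin_start, lo))
  sum(b$count * ov / (b$bin_end - b$bin_start))
}

# mean reads per window-width of region [lo, hi)
region_density <- function(track, lo, hi) {
  if (hi <= lo) return(NA_real_)
  region_reads(track, lo, hi) / ((hi - lo) / track$window)
}

#' Call the supported translation start codon from a footprint track
#'
#' Walks the candidate start codons from upstream to downstream and
#' chooses the most upstream candidate `c` (strictly downstream of the
#' annotated start) whose mean per-bin footprint density downstream of
#' `c` exceeds `ratio_min` times the mean per-bin density over
#' `[annotated_start, c)`. The upstream mean is floored at one pseudoread
#' per bin so an empty upstream leader cannot produce an infinite ratio.
#' If no candidate passes, the annotated start is reported as supported
#' with offset 0.
#'
#' @param track A [bin_reads()] track.
#' @param candidate_starts Candidate start-codon coordinates; defaults to
#'   the track's.
#' @param annotated_start Annotated start coordinate; defaults to the
#'   track's.
#' @param ratio_min Minimum downstream/upstream density ratio. Default 5.
#'
#' @return An object of class `start_site_call` with `chosen_start`,
#'   `offset` (`chosen_start - annotated_start`, bp), `ratio`, a
#'   `candidates` tibble of all evaluated ratios, and the track.
#' @export
call_start_codon <- function(track, candidate_starts = NULL,
                             annotated_start = NULL, ratio_min = 5) {
  stopifnot(inherits(track, "footprint_track"))
  annotated_start <- annotated_start %||% track$annotated_start
  candidate_starts <- sort(candidate_starts %||% track$candidate_starts)
  if (length(candidate_starts) == 0) abort("no candidate start codons")
  if (sum(track$bins$count) == 0) abort("track has no reads")

  cands <- tibble(candidate = candidate_starts) |>
    filter(candidate > annotated_start, candidate < track$gene_length) |>
    mutate(
      upstream_density = purrr::map_dbl(
        candidate, ~ max(region_density(track, annotated_start, .x), 1)),
      downstream_density = purrr::map_dbl(
        candidate, ~ region_density(track, .x, track$gene_length)),
      ratio = downstream_density / upstream_density,
      passed = ratio > ratio_min
    )

  if (any(cands$passed)) {
    hit <- cands[which(cands$passed)[1], ]
    chosen <- hit$candidate
    ratio <- hit$ratio
    supported <- TRUE
  } else {
    chosen <- annotated_start
    ratio <- NA_real_
    supported <- FALSE
  }
  structure(
    list(gene_id = track$gene_id, chosen_start = chosen,
         offset = chosen - annotated_start, ratio = ratio,
         annotated_start = annotated_start, ratio_min = ratio_min,
         alternative_supported = supported, candidates = cands,
         track = track),
    class = "start_site_call"
  )
}

#' @export
print.start_site_call <- function(x, ...) {
  if (x$alternative_supported) {
    cat(sprintf(
      "<start_site_call> %s: corrected start at %d (offset %+d bp, ratio %.1f)\n",
      x$gene_id, x$chosen_start, x$offset, x$ratio
    ))
  } else {
    cat(sprintf("<start_site_call> %s: annotated start supported (offset 0)\n",
                x$gene_id))
  }
  invisible(x)
}

#' @rdname call_start_codon
#' @param x,object A `start_site_call` object.
#' @param ... Unused.
#' @export
tidy.start_site_call <- function(x, ...) {
  x$track$bins
}

#' @rdname call_start_codon
#' @export
glance.start_site_call <- function(x, ...) {
  tibble(gene_id = x$gene_id, chosen_start = x$chosen_start,
         offset = x$offset, ratio = x$ratio,
         alternative_supported = x$alternative_supported,
         total_reads = sum(x$track$bins$count))
}

#' @rdname call_start_codon
#' @export
autoplot.start_site_call <- function(object, ...) {
  bins <- object$track$bins
  ggplot2::ggplot(bins, ggplot2::aes(x = bin_start, y = count)) +
    ggplot2::geom_col(width = object$track$window, just = 0,
                      fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$annotated_start,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$chosen_start,
                        linetype = "dotted") +
    ggplot2::labs(
      x = sprintf("position in %s (bp)", object$gene_id),
      y = sprintf("reads per %d bp bin", object$track$window),
      title = "Footprint density and called translation start",
      subtitle = "dashed: annotated start; dotted: called start"
    ) +
    ggplot2::theme_minimal()
}
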