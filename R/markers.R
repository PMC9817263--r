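#' Per-marker contig counts
#'
#' The number of distinct contigs carrying each marker gene. Because each
#' single-copy gene occurs once per genome, these counts estimate the number
#' of genomes in the community (inflated slightly when genes are fragmented
#' across contigs).
#'
#' @param hits A `marker_hits` object.
#' @return Named integer vector, one entry per marker.
#' @export
marker_contig_counts <- function(hits) {
  stopifnot(inherits(hits, "marker_hits"))
  vapply(hits$hits, length, integer(1))
}

#' Estimate the initial bin number from marker hits
#'
#' Takes the third quartile (linear interpolation over the ascending sorted
#' per-marker contig counts, R's default type-7 quantile) and rounds up.
#' The upper quartile damps the influence of fragmented genes while erring
#' toward more clusters, which the downstream ensemble can dereplicate.
#'
#' @param hits A `marker_hits` object with at least one hit.
#' @return Integer `k0 >= 1`.
#' @export
estimate_initial_bin_number <- function(hits) {
  counts <- marker_contig_counts(hits)
  if (length(counts) == 0L) {
    stop("cannot estimate bin number without marker hits")
  }
  as.integer(ceiling(unname(stats::quantile(counts, 0.75, type = 7))))
}

#' Candidate bin numbers tried during silhouette selection
#'
#' An arithmetic grid of at most 10 values starting at `k0` with step
#' `max(1, ceiling(k0 / 10))` (so the grid spans roughly `k0`..`2 k0`),
#' truncated so every candidate is at most `n_contigs - 1`.
#'
#' @param k0 Initial bin number (>= 1).
#' @param n_contigs Size of the contig universe.
#' @return Ascending integer vector (possibly empty when `n_contigs <= k0`).
#' @export
candidate_bin_numbers <- function(k0, n_contigs) {
  stopifnot(k0 >= 1)
  s <- max(1L, as.integer(ceiling(k0 / 10)))
  ks <- k0 + (0:9) * s
  unique(as.integer(ks[ks <= n_contigs - 1L]))
}

#' Choose the three quartile seed markers
#'
#' For each quartile (Q1, Q2, Q3) of the per-marker contig counts (linear
#' interpolation, rounded to the nearest integer), selects the marker whose
#' count is closest to the target; ties are broken by smaller `gene_length`
#' (the "shortest marker gene" rule), then lexicographic marker id. The
#' contigs carrying the chosen marker become the fixed cluster centers of
#' one partial-seed run.
#'
#' @param hits A `marker_hits` object with at least one hit.
#' @return A `seed_plan` fragment: list with `seed_markers` (named character
#'   vector `Q1`/`Q2`/`Q3`) and `seed_contigs` (marker id -> duplicate-free
#'   contig id vector).
#' @export
choose_seed_markers <- function(hits) {
  counts <- marker_contig_counts(hits)
  if (length(counts) == 0L) stop("no marker hits")
  gl <- hits$gene_length[names(counts)]
  gl[is.na(gl)] <- 0
  targets <- round(unname(stats::quantile(counts, c(0.25, 0.5, 0.75), type = 7)))
  pick <- function(q) {
    o <- order(abs(counts - q), gl, names(counts))
    names(counts)[o[1L]]
  }
  markers <- vapply(targets, pick, character(1))
  names(markers) <- c("Q1", "Q2", "Q3")
  seed_contigs <- lapply(unique(markers), function(m) names(hits$hits[[m]]))
  names(seed_contigs) <- unique(markers)
  list(seed_markers = markers, seed_contigs = seed_contigs)
}

#' Build the full seeding plan for a dataset
#'
#' Combines [estimate_initial_bin_number()], [candidate_bin_numbers()] and
#' [choose_seed_markers()].
#'
#' @param hits A `marker_hits` object.
#' @param n_contigs Size of the contig universe.
#' @return A `seed_plan`: list with `k0`, `candidate_ks`, `seed_markers`,
#'   `seed_contigs`.
#' @export
make_seed_plan <- function(hits, n_contigs) {
  k0 <- estimate_initial_bin_number(hits)
  sm <- choose_seed_markers(hits)
  structure(
    list(k0 = k0,
         candidate_ks = candidate_bin_numbers(k0, n_contigs),
         seed_markers = sm$seed_markers,
         seed_contigs = sm$seed_contigs),
    class = "seed_plan"
  )
}
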