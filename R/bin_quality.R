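#' Define a domain marker set
#'
#' @param name Label, e.g. `"universal"`, `"bacteria"`, `"archaea"`.
#' @param marker_ids Character vector of marker gene ids (non-empty).
#' @return A `domain_marker_set`.
#' @export
domain_marker_set <- function(name, marker_ids) {
  marker_ids <- unique(as.character(marker_ids))
  stopifnot(length(marker_ids) >= 1)
  structure(list(name = name, marker_ids = marker_ids,
                 size = length(marker_ids)),
            class = "domain_marker_set")
}

#' Default domain marker sets for a hit table
#'
#' With `mode = "universal"` (the default, appropriate for synthetic
#' communities where one planted set covers all genomes) every marker in the
#' table forms a single set. With `mode = "bact_arch"` markers whose id
#' starts with `"arch"` form the archaeal set and the rest the bacterial
#' set; bins are scored against both and keep the better score.
#'
#' @param hits A `marker_hits` object.
#' @param mode `"universal"` or `"bact_arch"`.
#' @return List of `domain_marker_set` objects.
#' @export
default_domains <- function(hits, mode = c("universal", "bact_arch")) {
  mode <- match.arg(mode)
  ids <- names(hits$hits)
  if (length(ids) == 0L) stop("empty marker hit table")
  if (mode == "universal") {
    return(list(domain_marker_set("universal", ids)))
  }
  arch <- grepl("^arch", ids)
  out <- list()
  if (any(!arch)) out <- c(out, list(domain_marker_set("bacteria", ids[!arch])))
  if (any(arch)) out <- c(out, list(domain_marker_set("archaea", ids[arch])))
  out
}

#' Estimate completeness, contamination, and score of one bin
#'
#' A per-gene simplification of CheckM-style scoring: for each domain
#' marker set, completeness is the fraction of the set's genes present in
#' the bin at least once, and contamination is the surplus copy count
#' (`sum over genes of max(0, copies - 1)`) normalized by the set size.
#' The bin score is `100 * (completeness - 3 * contamination)`. When
#' several domain sets are supplied the bin keeps the domain giving the
#' highest score.
#'
#' @param contig_ids Character vector of the bin's contigs.
#' @param hits A `marker_hits` object.
#' @param domains List of `domain_marker_set` objects (non-empty).
#' @return A `bin_quality`: list with `completeness` (0..1),
#'   `contamination` (>= 0), `score`, and `domain`.
#' @export
assess_bin <- function(contig_ids, hits, domains) {
  stopifnot(length(domains) >= 1)
  best <- NULL
  for (d in domains) {
    comp <- 0
    cont <- 0
    if (length(contig_ids) > 0L) {
      present <- 0L
      surplus <- 0L
      for (g in d$marker_ids) {
        h <- hits$hits[[g]]
        if (is.null(h)) next
        copies <- sum(h[names(h) %in% contig_ids])
        if (copies >= 1L) {
          present <- present + 1L
          surplus <- surplus + (copies - 1L)
        }
      }
      comp <- present / d$size
      cont <- surplus / d$size
    }
    q <- structure(
      list(completeness = comp, contamination = cont,
           score = 100 * (comp - 3 * cont), domain = d$name),
      class = "bin_quality"
    )
    if (is.null(best) || q$score > best$score) best <- q
  }
  best
}

#' High-quality bin predicate
#'
#' A bin counts as high quality when its score exceeds 10, its
#' contamination is below 15%, and its completeness exceeds 50% — all
#' strict inequalities.
#'
#' @param q A `bin_quality`.
#' @param cfg An [ensemble_config()] supplying the thresholds.
#' @return Logical scalar.
#' @export
is_high_quality <- function(q, cfg = ensemble_config()) {
  q$score > cfg$hq_score && q$contamination < cfg$hq_cont &&
    q$completeness > cfg$hq_comp
}

#' Split highly contaminated, highly complete bins
#'
#' A bin whose contamination is at least 50% and completeness at least 70%
#' (both inclusive) very likely merges several genomes. Such a bin is
#' replaced by sub-bins: the sub-bin count is estimated by the standard
#' bin-number procedure restricted to the bin's contigs and marker hits
#' (quartile k0, candidate grid capped at the bin size, silhouette
#' selection on the bin's combined-feature rows), and the bin's rows are
#' re-clustered with plain weighted k-means++. All other bins pass through
#' untouched, as does a qualifying bin with fewer than 2 contigs or no
#' marker hits (with a warning).
#'
#' @param binning A `binning`.
#' @param features The dataset's `feature_set`.
#' @param hits A `marker_hits` object.
#' @param domains List of `domain_marker_set` objects.
#' @param seed Integer RNG seed.
#' @return A `binning` with the same contig universe (membership is
#'   conserved); split bins get ids `<bin_id>_1`, `<bin_id>_2`, ...
#' @export
split_contaminated_bins <- function(binning, features, hits, domains, seed) {
  bl <- binning_bins(binning)
  seeds <- derive_seeds(seed, paste0("bin", seq_along(bl)))
  assignment <- character(0)
  nms <- character(0)
  for (i in seq_along(bl)) {
    bid <- names(bl)[i]
    contigs <- bl[[i]]
    q <- assess_bin(contigs, hits, domains)
    do_split <- q$contamination >= 0.5 && q$completeness >= 0.7
    if (do_split && length(contigs) < 2L) {
      warning("bin ", bid, " qualifies for splitting but has < 2 contigs")
      do_split <- FALSE
    }
    sub_hits <- NULL
    if (do_split) {
      sub_hits <- .restrict_hits(hits, contigs)
      if (length(sub_hits$hits) == 0L) {
        warning("bin ", bid, " qualifies for splitting but has no marker hits")
        do_split <- FALSE
      }
    }
    if (!do_split) {
      assignment <- c(assignment, stats::setNames(rep(bid, length(contigs)), contigs))
      next
    }
    rows <- match(contigs, features$contig_ids)
    X <- features$X_combo[rows, , drop = FALSE]
    w <- as.numeric(features$lengths[rows])
    k0 <- estimate_initial_bin_number(sub_hits)
    ks <- candidate_bin_numbers(k0, length(contigs))
    ks <- unique(pmin(ks, length(contigs)))
    if (length(ks) == 0L) ks <- min(k0, length(contigs))
    sub_seeds <- derive_seeds(seeds[[i]], c(paste0("k", ks), "final", "subsample"))
    idx <- withr::with_seed(sub_seeds[["subsample"]],
                            sort(sample.int(nrow(X), min(nrow(X), 2000L))))
    best_k <- ks[1L]
    if (length(ks) > 1L) {
      scores <- vapply(ks, function(k) {
        centers <- weighted_kmeanspp_init(X, w, k, seed = sub_seeds[[paste0("k", k)]])
        fit <- weighted_lloyd(X, w, centers)
        .mean_silhouette(X, fit$labels, idx)
      }, 0)
      best_k <- ks[which.max(scores)]
    }
    centers <- weighted_kmeanspp_init(X, w, best_k, seed = sub_seeds[["final"]])
    fit <- weighted_lloyd(X, w, centers)
    assignment <- c(assignment,
                    stats::setNames(paste0(bid, "_", fit$labels), contigs))
  }
  new_binning(assignment, binning$provenance)
}

# Restrict a marker hit table to a set of contigs, dropping hit-less markers.
.restrict_hits <- function(hits, contig_ids) {
  sub <- lapply(hits$hits, function(h) h[names(h) %in% contig_ids])
  sub <- sub[vapply(sub, length, integer(1)) > 0L]
  new_marker_hits(sub, hits$gene_length[names(sub)], hits$domain)
}
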