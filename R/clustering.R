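# Length-weighted k-means++ with partial-seed initialization. Contig length
# is used as the observation weight so a 100 kb contig pulls a center as hard
# as one hundred 1 kb contigs; integer weights are exactly equivalent to row
# duplication.

# Squared Euclidean distances between the rows of X (N x D) and C (K x D).
.dist2 <- function(X, C) {
  d <- matrix(rowSums(X^2), nrow(X), nrow(C)) -
    2 * X %*% t(C) +
    matrix(rowSums(C^2), nrow(X), nrow(C), byrow = TRUE)
  pmax(d, 0)
}

# Derive named substream seeds from a master seed so each run draws from an
# independent, reproducible stream.
derive_seeds <- function(master_seed, names) {
  s <- withr::with_seed(master_seed,
                        sample.int(.Machine$integer.max - 1L, length(names)))
  stats::setNames(s, names)
}

#' Weighted k-means++ initialization with fixed centers
#'
#' The first `l = length(fixed_rows)` centers are the indicated data rows
#' (the "partial seed"); the remaining `K - l` are drawn by D-squared
#' sampling, where a point's selection probability is proportional to
#' `weight x (squared distance to its nearest existing center)`. Points at
#' distance zero (including chosen centers) have probability zero. When the
#' entire remaining D-squared mass is zero but centers are still needed,
#' sampling falls back to weight-proportional draws without replacement.
#'
#' @param X N x D numeric matrix.
#' @param weights N-vector of non-negative weights with positive sum.
#' @param K Number of centers, `1 <= K <= N`.
#' @param fixed_rows Integer row indices of the pre-designated centers
#'   (distinct, `length(fixed_rows) <= K`).
#' @param seed Optional integer; when given, sampling runs under this seed
#'   without disturbing the caller's RNG state.
#' @return K x D center matrix with attribute `"rows"` giving, for each
#'   center, the index of the data row it was copied from.
#' @export
weighted_kmeanspp_init <- function(X, weights, K, fixed_rows = integer(0),
                                   seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
      weighted_kmeanspp_init(X, weights, K, fixed_rows)))
  }
  N <- nrow(X)
  if (K > N) stop("K exceeds the number of points")
  stopifnot(K >= 1, all(weights >= 0), sum(weights) > 0,
            !anyDuplicated(fixed_rows), length(fixed_rows) <= K)
  chosen <- as.integer(fixed_rows)
  if (length(chosen) == 0L) {
    p <- weights
    if (sum(p) == 0) p <- rep(1, N)
    chosen <- sample.int(N, 1L, prob = p)
  }
  while (length(chosen) < K) {
    d2 <- .dist2(X, X[chosen, , drop = FALSE])
    dmin <- apply(d2, 1L, min)
    p <- weights * dmin
    if (sum(p) == 0) {
      remaining <- setdiff(seq_len(N), chosen)
      w <- weights[remaining]
      if (sum(w) == 0) w <- rep(1, length(remaining))
      chosen <- c(chosen, remaining[sample.int(length(remaining), 1L, prob = w)])
    } else {
      chosen <- c(chosen, sample.int(N, 1L, prob = p))
    }
  }
  centers <- X[chosen, , drop = FALSE]
  rownames(centers) <- NULL
  attr(centers, "rows") <- chosen
  centers
}

#' Weighted Lloyd iterations
#'
#' Alternates nearest-center assignment and weighted-mean center updates
#' until the maximum center displacement drops below `tol` or `max_iter`
#' is reached. An empty cluster is re-seeded at the point with the largest
#' weighted squared distance to its current center. The weighted inertia is
#' non-increasing across iterations.
#'
#' @param X N x D numeric matrix (finite entries).
#' @param weights N-vector of non-negative weights with positive sum.
#' @param centers Initial K x D center matrix.
#' @param tol Convergence tolerance on the maximum center displacement
#'   (Euclidean norm); default 1e-4.
#' @param max_iter Iteration cap; default 300.
#' @return A `kmeans_result`: list with `labels` (1..K), `centers`,
#'   `inertia` (weighted within-cluster sum of squared distances),
#'   `n_iter`, `inertia_trace`, and `converged`.
#' @export
weighted_lloyd <- function(X, weights, centers, tol = 1e-4, max_iter = 300L) {
  if (any(!is.finite(X)) || any(!is.finite(centers))) {
    stop("non-finite entries in data or centers")
  }
  stopifnot(all(weights >= 0), sum(weights) > 0)
  N <- nrow(X)
  K <- nrow(centers)
  trace <- numeric(0)
  labels <- integer(N)
  for (iter in seq_len(max_iter)) {
    d2 <- .dist2(X, centers)
    labels <- max.col(-d2, ties.method = "first")
    own_d2 <- d2[cbind(seq_len(N), labels)]
    empty <- setdiff(seq_len(K), unique(labels))
    for (k in empty) {
      # steal the worst-fitting point (largest weighted squared distance)
      cand <- which(tabulate(labels, K)[labels] > 1L)
      if (length(cand) == 0L) cand <- seq_len(N)
      i <- cand[which.max(weights[cand] * own_d2[cand])]
      labels[i] <- k
      own_d2[i] <- 0
    }
    present <- sort(unique(labels))
    sums <- rowsum(X * weights, labels)      # rows ordered by sorted label
    wsum <- rowsum(weights, labels)[, 1L]
    wz <- wsum == 0                          # all-zero-weight cluster: plain mean
    if (any(wz)) {
      sums[wz, ] <- rowsum(X, labels)[wz, , drop = FALSE]
      wsum[wz] <- rowsum(rep(1, N), labels)[wz, 1L]
    }
    # clusters that remained empty despite re-seeding keep their old center
    upd <- centers
    upd[present, ] <- sums / wsum
    shift <- sqrt(max(rowSums((upd - centers)^2)))
    centers <- upd
    inertia <- sum(weights * .dist2(X, centers)[cbind(seq_len(N), labels)])
    trace <- c(trace, inertia)
    if (shift < tol) break
  }
  structure(
    list(labels = labels, centers = centers, inertia = inertia,
         n_iter = iter, inertia_trace = trace, converged = shift < tol),
    class = "kmeans_result"
  )
}

# Mean silhouette width of `labels` over the rows `idx` of X (Euclidean,
# unweighted). Returns -Inf when fewer than 2 clusters survive in the
# subsample, so such a candidate can never win.
.mean_silhouette <- function(X, labels, idx) {
  l <- labels[idx]
  if (length(unique(l)) < 2L) return(-Inf)
  sil <- cluster::silhouette(l, stats::dist(X[idx, , drop = FALSE]))
  mean(sil[, "sil_width"])
}

#' Select the bin number by silhouette on the combined feature matrix
#'
#' Runs plain weighted k-means++ on `X_combo` for every candidate bin
#' number and returns the candidate with the largest mean silhouette
#' coefficient (Euclidean, unweighted, computed on one uniformly subsampled
#' set of at most `max_silhouette_n` contigs shared across candidates).
#' Candidates `>= N` are skipped; ties go to the smallest candidate.
#'
#' @param features A `feature_set`.
#' @param plan A `seed_plan` (its `candidate_ks` are tried).
#' @param seed Master seed for subsampling and the per-candidate runs.
#' @param weights Optional clustering weights (defaults to contig lengths).
#' @param max_silhouette_n Subsample cap, default 2000.
#' @return The selected integer bin number `K`.
#' @export
select_bin_number <- function(features, plan, seed, weights = NULL,
                              max_silhouette_n = 2000L) {
  X <- features$X_combo
  N <- nrow(X)
  if (is.null(weights)) weights <- as.numeric(features$lengths)
  ks <- plan$candidate_ks[plan$candidate_ks < N]
  if (length(ks) == 0L) stop("no feasible candidate bin number (N too small)")
  if (length(ks) == 1L) return(as.integer(ks))
  seeds <- derive_seeds(seed, c("subsample", paste0("k", ks)))
  idx <- withr::with_seed(seeds[["subsample"]],
                          sort(sample.int(N, min(N, max_silhouette_n))))
  scores <- vapply(seq_along(ks), function(i) {
    k <- ks[i]
    centers <- weighted_kmeanspp_init(X, weights, k,
                                      seed = seeds[[paste0("k", k)]])
    fit <- weighted_lloyd(X, weights, centers)
    .mean_silhouette(X, fit$labels, idx)
  }, 0)
  as.integer(ks[which.max(scores)])
}

#' Partial-seed weighted k-means
#'
#' The rows in `seed_rows` (contigs carrying one chosen single-copy marker,
#' hence presumed to lie in different genomes) become fixed initial centers;
#' k-means++ samples the remaining `K - l` centers; Lloyd then runs freely
#' (seeds fix the initialization only, centers are not pinned). When
#' `l >= K` the run degenerates to "seed k-means": all `l` rows are the
#' centers and `K` is expanded to `l`. With `l = 0` this is plain weighted
#' k-means++.
#'
#' @param X Feature matrix (rows aligned with `contig_ids`).
#' @param weights Clustering weights.
#' @param K Target number of bins.
#' @param seed_rows Integer row indices of the seed contigs.
#' @param contig_ids Contig ids labelling the rows of `X`.
#' @param seed Integer RNG seed for the run.
#' @param provenance Optional provenance list stored on the result.
#' @return A `binning` whose bin ids are `"c1" .. "cK"`; the fitted
#'   `kmeans_result` is attached as attribute `"fit"`.
#' @export
partial_seed_kmeans <- function(X, weights, K, seed_rows, contig_ids, seed,
                                provenance = list()) {
  N <- nrow(X)
  stopifnot(K >= 1)
  seed_rows <- as.integer(seed_rows)
  if (length(seed_rows) > 0 && (min(seed_rows) < 1 || max(seed_rows) > N)) {
    stop("seed rows out of range")
  }
  l <- length(seed_rows)
  if (l >= K) {
    K <- l
    centers <- X[seed_rows, , drop = FALSE]
  } else {
    centers <- weighted_kmeanspp_init(X, weights, K, fixed_rows = seed_rows,
                                      seed = seed)
  }
  fit <- weighted_lloyd(X, weights, centers)
  keep <- fit$labels  # some clusters may be absent after Lloyd re-seeding
  assignment <- stats::setNames(paste0("c", keep), contig_ids)
  provenance$seed <- seed
  b <- new_binning(assignment, provenance)
  attr(b, "fit") <- fit
  b
}

#' Generate the twelve component binnings
#'
#' For each of the three feature matrices (`combo`, `cov`, `com`) this runs
#' three partial-seed k-means (seeded by the Q1/Q2/Q3 quartile markers) and
#' one plain weighted k-means++, all with the shared bin number `K` —
#' 12 binnings total. Each run draws from its own named RNG substream of
#' the master seed, so disabling one run never perturbs the others.
#'
#' @param features A `feature_set`.
#' @param plan A `seed_plan` carrying the three seed markers.
#' @param K The bin number shared across runs.
#' @param seed Master seed.
#' @param weights Optional clustering weights (default: contig lengths;
#'   pass `rep(1, N)` to disable length weighting).
#' @return List of 12 `binning` objects with provenance
#'   `<feature>/<Q1|Q2|Q3|plain>`.
#' @export
generate_component_binnings <- function(features, plan, K, seed,
                                        weights = NULL) {
  stopifnot(length(plan$seed_markers) == 3L)
  if (is.null(weights)) weights <- as.numeric(features$lengths)
  feats <- c(combo = "X_combo", cov = "X_cov", com = "X_com")
  inits <- c("Q1", "Q2", "Q3", "plain")
  run_names <- as.vector(outer(names(feats), inits, paste, sep = "/"))
  seeds <- derive_seeds(seed, run_names)
  out <- list()
  for (f in names(feats)) {
    X <- features[[feats[[f]]]]
    for (init in inits) {
      run <- paste(f, init, sep = "/")
      if (init == "plain") {
        rows <- integer(0)
      } else {
        marker <- plan$seed_markers[[init]]
        rows <- match(plan$seed_contigs[[marker]], features$contig_ids)
        rows <- rows[!is.na(rows)]
      }
      out[[run]] <- partial_seed_kmeans(
        X, weights, K, rows, features$contig_ids, seeds[[run]],
        provenance = list(feature = f, init = init, label = run))
    }
  }
  out
}
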