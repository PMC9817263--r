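# Weighted k-means++ and partial-seed clustering. Oracles: closed-form
# means on tiny 1-D instances, exhaustive partition enumeration, and
# single-move local-optimality checks.

test_that("D-squared sampling never selects zero-probability points", {
  X <- matrix(c(0, 10), ncol = 1)
  for (s in 1:10) {
    ctr <- weighted_kmeanspp_init(X, c(1, 1), K = 2, seed = s)
    # whichever point is drawn first, the other has all the D^2 mass
    expect_setequal(attr(ctr, "rows"), c(1L, 2L))
  }

  # a zero-weight point is never sampled as a center
  X3 <- matrix(c(0, 5, 10), ncol = 1)
  for (s in 1:20) {
    ctr <- weighted_kmeanspp_init(X3, c(1, 0, 1), K = 2, seed = s)
    expect_false(2L %in% attr(ctr, "rows"))
  }
})

test_that("fixed centers are honoured and exhaust sampling when l = K", {
  set.seed(123)
  X <- matrix(rnorm(20), ncol = 2)
  rng_before <- .Random.seed
  ctr <- weighted_kmeanspp_init(X, rep(1, 10), K = 3, fixed_rows = c(4L, 7L, 9L))
  expect_identical(.Random.seed, rng_before)  # nothing sampled
  expect_equal(ctr, X[c(4, 7, 9), ], ignore_attr = TRUE)
  expect_error(weighted_kmeanspp_init(X, rep(1, 10), K = 11), "exceeds")
})

test_that("Lloyd reaches the closed-form optimum on separated 1-D pairs", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  fit <- weighted_lloyd(X, rep(1, 4), matrix(c(0.5, 10.5), ncol = 1))
  expect_equal(sort(fit$centers[, 1]), c(0.5, 10.5))
  expect_equal(fit$inertia, 1.0)  # 4 points at squared distance 0.25
  expect_identical(fit$labels, c(1L, 1L, 2L, 2L))
  expect_true(fit$converged)
})

test_that("integer weights are equivalent to row duplication", {
  Xw <- matrix(c(0, 1, 10), ncol = 1)
  Xd <- matrix(c(0, 1, 1, 10), ncol = 1)
  init <- matrix(c(0.2, 9.0), ncol = 1)
  fw <- weighted_lloyd(Xw, c(1, 2, 1), init)
  fd <- weighted_lloyd(Xd, rep(1, 4), init)
  expect_equal(fw$centers, fd$centers, tolerance = 1e-9)
  expect_equal(fw$inertia, fd$inertia, tolerance = 1e-9)
})

test_that("K = 1 yields the weighted mean and inertia is non-increasing", {
  withr::with_seed(3, {
    X <- matrix(rnorm(40), ncol = 2)
    w <- runif(20, 0.5, 5)
    fit <- weighted_lloyd(X, w, X[1, , drop = FALSE])
    expect_equal(unname(fit$centers[1, ]), unname(colSums(X * w) / sum(w)),
                 tolerance = 1e-9)

    for (rep in 1:5) {
      Xr <- matrix(rnorm(60), ncol = 2)
      wr <- runif(30, 0.1, 10)
      init <- weighted_kmeanspp_init(Xr, wr, 4, seed = rep)
      tr <- weighted_lloyd(Xr, wr, init)$inertia_trace
      expect_true(all(diff(tr) <= 1e-9))
    }
  })
})

test_that("converged assignments are Lloyd-local optima (N <= 8)", {
  # Lloyd fixed point: centers are the weighted means of their clusters and
  # no single-label move against those centers lowers the inertia. (Moves
  # that also re-compute the means — Hartigan moves — can still improve;
  # Lloyd does not guarantee against those.)
  withr::with_seed(11, {
    for (rep in 1:8) {
      N <- sample(4:8, 1)
      K <- sample(2:3, 1)
      X <- matrix(runif(N, 0, 20), ncol = 1)
      w <- runif(N, 0.5, 3)
      init <- weighted_kmeanspp_init(X, w, K, seed = rep)
      fit <- weighted_lloyd(X, w, init)
      for (k in unique(fit$labels)) {
        idx <- fit$labels == k
        expect_equal(unname(fit$centers[k, ]),
                     unname(colSums(X[idx, , drop = FALSE] * w[idx]) / sum(w[idx])),
                     tolerance = 1e-6)
      }
      base <- fixed_center_inertia(X, w, fit$labels, fit$centers)
      for (i in seq_len(N)) {
        for (k in setdiff(unique(fit$labels), fit$labels[i])) {
          moved <- fit$labels
          moved[i] <- k
          expect_gte(fixed_center_inertia(X, w, moved, fit$centers),
                     base - 1e-9)
        }
      }
    }
  })
})

test_that("partial seed recovers the exhaustive-optimum 3-partition", {
  X <- matrix(c(0, 1, 10, 11, 20, 21), ncol = 1)
  w <- rep(1, 6)
  b <- partial_seed_kmeans(X, w, K = 3, seed_rows = c(1L, 3L),
                           contig_ids = paste0("p", 1:6), seed = 1)
  got <- unname(split(paste0("p", 1:6), b$assignment[paste0("p", 1:6)]))
  expect_setequal(lapply(got, sort),
                  list(c("p1", "p2"), c("p3", "p4"), c("p5", "p6")))

  # exhaustive oracle: no 3-partition has lower (equal-weight) inertia
  best <- Inf
  for (l1 in 1:3) for (l2 in 1:3) for (l3 in 1:3) for (l4 in 1:3) {
    labs <- c(1L, l1, l2, l3, l4, 3L)
    if (length(unique(labs)) < 3L) next
    best <- min(best, labelling_inertia(X, w, labs))
  }
  expect_equal(labelling_inertia(X, w, as.integer(factor(b$assignment))), best)
})

test_that("l >= K expands K; l = 0 reduces to plain weighted k-means++", {
  X <- matrix(c(0, 1, 10, 11, 20, 21), ncol = 1)
  w <- rep(1, 6)
  ids <- paste0("p", 1:6)
  # seed k-means degenerate case: 3 seeds with K = 2 -> 3 bins
  b <- partial_seed_kmeans(X, w, K = 2, seed_rows = c(1L, 3L, 5L),
                           contig_ids = ids, seed = 4)
  expect_identical(length(unique(b$assignment)), 3L)

  # l = 0: identical to running init + Lloyd by hand under the same seed
  b0 <- partial_seed_kmeans(X, w, K = 3, seed_rows = integer(0),
                            contig_ids = ids, seed = 9)
  manual <- weighted_lloyd(X, w, weighted_kmeanspp_init(X, w, 3, seed = 9))
  expect_identical(as.integer(factor(b0$assignment[ids])),
                   as.integer(factor(manual$labels)))

  expect_error(partial_seed_kmeans(X, w, 2, seed_rows = 99L,
                                   contig_ids = ids, seed = 1),
               "out of range")
})

test_that("silhouette selection finds the true blob count", {
  blobs <- make_blobs(n_per = 30, seed = 2)
  fs <- fake_feature_set(blobs$X)
  plan <- list(candidate_ks = c(2L, 3L, 4L))
  K <- select_bin_number(fs, plan, seed = 5)
  expect_identical(K, 2L)

  # independent check: the k = 2 clustering's mean silhouette beats the
  # alternatives, using a naive silhouette implementation
  sil <- vapply(2:4, function(k) {
    ctr <- weighted_kmeanspp_init(blobs$X, rep(1, 60), k, seed = 5)
    naive_mean_silhouette(blobs$X, weighted_lloyd(blobs$X, rep(1, 60), ctr)$labels)
  }, 0)
  expect_identical(which.max(sil), 1L)

  # a single feasible candidate is returned without comparison
  expect_identical(select_bin_number(fs, list(candidate_ks = 2L), seed = 1), 2L)
  # infeasible candidates (k >= N) are skipped
  tiny <- fake_feature_set(matrix(c(0, 0.1, 9), ncol = 1))
  expect_identical(select_bin_number(tiny, list(candidate_ks = c(2L, 5L)),
                                     seed = 1), 2L)
})

test_that("twelve component binnings are generated deterministically", {
  cs <- small_sim(seed = 21)
  fs <- build_feature_set(cs$contigs, cs$coverage)
  plan <- make_seed_plan(cs$hits, length(cs$contigs))
  comp <- generate_component_binnings(fs, plan, K = 5, seed = 77)
  expect_length(comp, 12L)
  feats <- vapply(comp, function(b) b$provenance$feature, character(1))
  expect_equal(unname(table(feats)[c("com", "combo", "cov")]),
               rep(4L, 3), ignore_attr = TRUE)
  inits <- vapply(comp, function(b) b$provenance$init, character(1))
  expect_equal(sum(inits == "plain"), 3L)

  comp2 <- generate_component_binnings(fs, plan, K = 5, seed = 77)
  for (nm in names(comp)) {
    expect_identical(comp[[nm]]$assignment, comp2[[nm]]$assignment)
  }

  # coinciding Q1/Q2 seed markers still yield two (identical) runs
  plan$seed_markers[["Q2"]] <- plan$seed_markers[["Q1"]]
  comp3 <- generate_component_binnings(fs, plan, K = 5, seed = 77)
  expect_length(comp3, 12L)
})
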