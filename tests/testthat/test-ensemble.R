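# Greedy dereplication and intersection refinement. The oracle re-runs
# selection from scratch each round (no incremental caching) and, for the
# first pick, enumerates all candidates.

# Test-local reference implementation of greedy selection.
oracle_greedy <- function(bins, hits, domains, cfg, lengths) {
  selected <- list()
  repeat {
    quals <- lapply(bins, assess_bin, hits = hits, domains = domains)
    ok <- which(vapply(quals, is_high_quality, TRUE, cfg = cfg))
    if (length(ok) == 0L) break
    scores <- vapply(quals[ok], `[[`, 0, "score")
    bp <- vapply(bins[ok], function(cs) sum(lengths[cs]), 0)
    w <- ok[order(-scores, -bp, names(bins)[ok])][1L]
    selected[[names(bins)[w]]] <- bins[[w]]
    winner <- bins[[w]]
    bins <- bins[-w]
    bins <- lapply(bins, setdiff, y = winner)
    bins <- bins[vapply(bins, length, integer(1)) > 0L]
  }
  selected
}

# Wrap named bin contig-sets as one binning per bin so sources are stable.
as_binnings <- function(bins) {
  lapply(names(bins), function(nm) {
    b <- new_binning(setNames(rep("b", length(bins[[nm]])), bins[[nm]]))
    b$provenance$label <- nm
    b
  })
}

test_that("greedy selection removes contigs and re-scores survivors", {
  m <- paste0("m", 1:10)
  dom <- list(domain_marker_set("universal", m))
  # ten contigs, one marker each; candidate X holds 8, candidate Y holds 6
  # of the same contigs -> after X is taken, Y collapses below threshold
  hits <- toy_hits(setNames(as.list(sprintf("c%02d", 1:10)), m))
  lengths <- setNames(rep(1000, 10), sprintf("c%02d", 1:10))
  bins <- list(X = sprintf("c%02d", 1:8), Y = sprintf("c%02d", 1:6))
  cfg <- ensemble_config(min_refined_bp = 0)

  got <- greedy_select(as_binnings(bins), hits, dom, cfg, lengths)
  sel <- attr(got, "selection")
  expect_identical(nrow(sel), 1L)
  expect_identical(sel$source, "X/b")
  expect_equal(sel$score, 80)
  expect_setequal(names(got$assignment), bins$X)

  # matches the from-scratch oracle
  o <- oracle_greedy(bins, hits, dom, cfg, lengths)
  expect_identical(names(o), "X")
})

test_that("greedy matches the brute-force oracle on random small pools", {
  m <- paste0("m", 1:12)
  dom <- list(domain_marker_set("universal", m))
  universe <- sprintf("c%02d", 1:12)
  hits <- toy_hits(setNames(as.list(universe), m))
  lengths <- setNames(seq(1000, 2100, by = 100), universe)
  cfg <- ensemble_config(min_refined_bp = 0)
  withr::with_seed(19, {
    for (rep in 1:15) {
      n_bins <- sample(2:6, 1)
      bins <- lapply(seq_len(n_bins), function(i) {
        sample(universe, sample(4:10, 1))
      })
      names(bins) <- paste0("B", seq_len(n_bins))
      got <- greedy_select(as_binnings(bins), hits, dom, cfg, lengths)
      sel <- attr(got, "selection")
      o <- oracle_greedy(bins, hits, dom, cfg, lengths)
      expect_identical(sub("/b$", "", sel$source), as.character(names(o)))
      # final bins are always pairwise disjoint
      expect_identical(anyDuplicated(names(got$assignment)), 0L)
    }
  })
})

test_that("greedy handles the trivial pool shapes", {
  m <- paste0("m", 1:10)
  dom <- list(domain_marker_set("universal", m))
  hits <- toy_hits(setNames(as.list(sprintf("c%02d", 1:10)), m))
  lengths <- setNames(rep(500, 10), sprintf("c%02d", 1:10))
  cfg <- ensemble_config(min_refined_bp = 0)

  # nothing qualifies -> empty output
  weak <- list(W = sprintf("c%02d", 1:3))  # completeness 0.3
  got <- greedy_select(as_binnings(weak), hits, dom, cfg, lengths)
  expect_length(got$assignment, 0L)

  # two disjoint qualifying bins are both selected, highest score first:
  # every marker occurs once in P's contigs and once in Q's, so both bins
  # are complete and uncontaminated; the bp tie-break puts P first
  two <- list(P = sprintf("c%02d", 1:7), Q = sprintf("c%02d", 8:10))
  hits2 <- toy_hits(setNames(lapply(1:10, function(i) {
    c(sprintf("c%02d", (i %% 7) + 1), sprintf("c%02d", 8 + (i %% 3)))
  }), m))
  got2 <- greedy_select(as_binnings(two), hits2, dom, cfg, lengths)
  sel2 <- attr(got2, "selection")
  expect_identical(nrow(sel2), 2L)
  expect_true(sel2$score[1] >= sel2$score[2])
  expect_setequal(sub("/b$", "", sel2$source), c("P", "Q"))
})

test_that("refine_intersection groups contigs by label tuples", {
  lengths <- setNames(rep(100, 4), paste0("c", 1:4))
  A <- new_binning(c(c1 = "a1", c2 = "a1", c3 = "a1"))
  B <- new_binning(c(c1 = "b1", c2 = "b1", c3 = "b2"))
  r <- refine_intersection(list(A, B), 0, lengths)
  got <- unname(lapply(binning_bins(r), sort))
  expect_setequal(got, list(c("c1", "c2"), "c3"))

  # identical inputs: refinement is the input filtered by min_refined_bp
  r2 <- refine_intersection(list(A, A), 250, lengths)
  expect_setequal(unname(lapply(binning_bins(r2), sort)),
                  list(c("c1", "c2", "c3")))
  r3 <- refine_intersection(list(B, B), 150, lengths)
  expect_setequal(unname(lapply(binning_bins(r3), sort)),
                  list(c("c1", "c2")))  # b2 (100 bp) filtered out

  # a contig unassigned in any input is dropped
  A4 <- new_binning(c(c1 = "a1", c2 = "a1", c4 = "a2"))
  r4 <- refine_intersection(list(A4, B), 0, lengths)
  expect_false("c4" %in% names(r4$assignment))
})

test_that("stage1 is idempotent on four identical perfect binnings", {
  cs <- small_sim(seed = 13)
  truth <- setNames(cs$sim$truth$genome_id, cs$sim$truth$contig_id)
  perfect <- new_binning(truth[names(cs$contigs)])
  perfect$provenance$label <- "perfect"
  dom <- default_domains(cs$hits)
  cfg <- ensemble_config(min_refined_bp = 0)
  out <- stage1(list(perfect, perfect, perfect, perfect), cs$hits, dom, cfg,
                cs$lengths, label = "A")
  got <- unname(lapply(binning_bins(out), sort))
  want <- unname(lapply(binning_bins(perfect), sort))
  expect_setequal(got, want)
})

test_that("stage2 with an empty track C equals ab_only on (A, B)", {
  cs <- small_sim(seed = 17)
  truth <- setNames(cs$sim$truth$genome_id, cs$sim$truth$contig_id)
  A <- new_binning(truth[names(cs$contigs)])
  # B: same bins under different ids, with one genome split in two
  lab <- truth[names(cs$contigs)]
  first <- sort(unique(lab))[1]
  idx <- which(lab == first)
  lab[idx[seq_len(floor(length(idx) / 2))]] <- paste0(first, "_half")
  B <- new_binning(paste0("B_", lab) |> setNames(names(lab)))
  empty <- new_binning(setNames(character(0), character(0)))
  dom <- default_domains(cs$hits)
  cfg_full <- ensemble_config(min_refined_bp = 0)
  cfg_ab <- ensemble_config(min_refined_bp = 0,
                            stage2_combinations = "ab_only")
  outC <- stage2(A, B, empty, cs$hits, dom, cfg_full, cs$lengths)
  outAB <- stage2(A, B, empty, cs$hits, dom, cfg_ab, cs$lengths)
  expect_identical(outC$assignment, outAB$assignment)
  expect_identical(attr(outC, "selection")$source,
                   attr(outAB, "selection")$source)
})

test_that("adding a candidate binning does not lose high-score bins", {
  # non-adversarial fixture: B adds a disjoint genome's bin
  m <- paste0("m", 1:10)
  dom <- list(domain_marker_set("universal", m))
  universe <- sprintf("c%02d", 1:10)
  hits <- toy_hits(setNames(as.list(universe), m))
  lengths <- setNames(rep(800, 10), universe)
  cfg <- ensemble_config(min_refined_bp = 0)
  A <- as_binnings(list(A1 = universe[1:6]))
  B <- as_binnings(list(B1 = universe[7:10]))
  n1 <- nrow(attr(greedy_select(A, hits, dom, cfg, lengths), "selection"))
  n2 <- nrow(attr(greedy_select(c(A, B), hits, dom, cfg, lengths), "selection"))
  expect_gte(n2, n1)
})
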