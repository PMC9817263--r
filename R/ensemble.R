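#' Ensemble configuration
#'
#' @param min_refined_bp Minimum total length (bp) of an intersection-refined
#'   bin; the default 524288 bp is Binning_refiner's published default.
#'   Desk-scale synthetic runs use much smaller values.
#' @param hq_score High-quality score threshold (strict `>`), default 10.
#' @param hq_cont High-quality contamination threshold (strict `<`),
#'   default 0.15.
#' @param hq_comp High-quality completeness threshold (strict `>`),
#'   default 0.5.
#' @param stage2_combinations `"pairs_and_triple"` (candidate pool = the
#'   three per-feature ensembles plus all pairwise refinements and the
#'   triple refinement) or `"ab_only"` (combo and coverage tracks plus
#'   their refinement only).
#' @return An `ensemble_config`.
#' @export
ensemble_config <- function(min_refined_bp = 524288, hq_score = 10,
                            hq_cont = 0.15, hq_comp = 0.5,
                            stage2_combinations = c("pairs_and_triple", "ab_only")) {
  stopifnot(min_refined_bp >= 0)
  structure(
    list(min_refined_bp = min_refined_bp, hq_score = hq_score,
         hq_cont = hq_cont, hq_comp = hq_comp,
         stage2_combinations = match.arg(stage2_combinations)),
    class = "ensemble_config"
  )
}

#' Greedy dereplication of candidate bins by marker-gene score
#'
#' Pools every bin of every candidate binning, scores them with
#' [assess_bin()], and repeats: select the highest-scoring bin among those
#' passing [is_high_quality()] (ties: larger total bp, then lexicographic
#' source string), emit it, remove its contigs from every remaining
#' candidate, and rescore only the candidates that lost contigs. Stops when
#' no candidate qualifies. Output bins are pairwise disjoint and each
#' passed the high-quality predicate at its moment of selection.
#'
#' @param binnings List of `binning` objects over one contig universe.
#' @param hits A `marker_hits` object.
#' @param domains List of `domain_marker_set` objects.
#' @param cfg An [ensemble_config()].
#' @param lengths Named contig lengths in bp (tie-breaking).
#' @return A `binning` with bins named `bin.1`, `bin.2`, ... in selection
#'   order; the per-bin selection record (source, score, completeness,
#'   contamination, bp) is attached as attribute `"selection"`.
#' @export
greedy_select <- function(binnings, hits, domains, cfg, lengths) {
  cand <- list()
  for (b in binnings) {
    src <- provenance_string(b)
    bl <- binning_bins(b)
    for (bid in names(bl)) cand[[paste0(src, "/", bid)]] <- bl[[bid]]
  }
  qual <- lapply(cand, assess_bin, hits = hits, domains = domains)
  selected <- list()
  info <- list()
  while (length(cand) > 0L) {
    ok <- which(vapply(qual, is_high_quality, TRUE, cfg = cfg))
    if (length(ok) == 0L) break
    scores <- vapply(qual[ok], `[[`, 0, "score")
    bp <- vapply(cand[ok], function(cs) sum(lengths[cs]), 0)
    w <- ok[order(-scores, -bp, names(cand)[ok])][1L]
    winner <- cand[[w]]
    rank <- length(selected) + 1L
    selected[[paste0("bin.", rank)]] <- winner
    q <- qual[[w]]
    info[[rank]] <- data.frame(
      bin_id = paste0("bin.", rank), source = names(cand)[w],
      score = q$score, completeness = q$completeness,
      contamination = q$contamination, domain = q$domain,
      n_contigs = length(winner), total_bp = sum(lengths[winner]),
      stringsAsFactors = FALSE)
    cand[[w]] <- NULL
    qual[[w]] <- NULL
    if (length(cand) > 0L) {
      touched <- vapply(cand, function(cs) any(cs %in% winner), TRUE)
      for (i in which(touched)) {
        cand[[i]] <- setdiff(cand[[i]], winner)
        qual[[i]] <- assess_bin(cand[[i]], hits, domains)
      }
      empty <- vapply(cand, length, integer(1)) == 0L
      cand <- cand[!empty]
      qual <- qual[!empty]
    }
  }
  assignment <- character(0)
  for (bid in names(selected)) {
    assignment <- c(assignment,
                    stats::setNames(rep(bid, length(selected[[bid]])),
                                    selected[[bid]]))
  }
  out <- new_binning(assignment, provenance = list(label = "greedy"))
  attr(out, "selection") <- if (length(info) > 0L) do.call(rbind, info) else
    data.frame(bin_id = character(0), source = character(0),
               score = numeric(0), completeness = numeric(0),
               contamination = numeric(0), domain = character(0),
               n_contigs = integer(0), total_bp = numeric(0))
  out
}

#' Intersection refinement of two or more binnings
#'
#' Each contig assigned in all input binnings is keyed by its tuple of bin
#' labels; every distinct tuple whose contig set totals at least
#' `min_refined_bp` becomes a refined bin. Contigs unassigned in any input
#' are dropped (strict intersection semantics).
#'
#' @param binnings List of at least two `binning` objects.
#' @param min_refined_bp Minimum total bp of a refined bin.
#' @param lengths Named contig lengths in bp.
#' @return A `binning` with bins named `r1`, `r2`, ... (label tuples sorted).
#' @export
refine_intersection <- function(binnings, min_refined_bp, lengths) {
  stopifnot(length(binnings) >= 2L)
  assigned <- lapply(binnings, `[[`, "assignment")
  common <- Reduce(intersect, lapply(assigned, names))
  if (length(common) == 0L) {
    return(new_binning(stats::setNames(character(0), character(0)),
                       provenance = list(label = "refined")))
  }
  keymat <- vapply(assigned, function(a) unname(a[common]), character(length(common)))
  if (is.null(dim(keymat))) keymat <- matrix(keymat, nrow = 1L)
  key <- apply(keymat, 1L, paste, collapse = "")
  groups <- split(common, key)
  groups <- groups[order(names(groups))]
  keep <- vapply(groups, function(cs) sum(lengths[cs]) >= min_refined_bp, TRUE)
  groups <- groups[keep]
  assignment <- character(0)
  for (i in seq_along(groups)) {
    assignment <- c(assignment,
                    stats::setNames(rep(paste0("r", i), length(groups[[i]])),
                                    groups[[i]]))
  }
  new_binning(assignment, provenance = list(label = "refined"))
}

#' Stage 1: per-feature-track greedy ensemble
#'
#' Integrates the four post-split component binnings of one feature track
#' (three partial-seed runs plus the plain k-means++ run) with
#' [greedy_select()], yielding the track's ensemble ("MetabinA" for the
#' combined features, "MetabinB" for coverage, "MetabinC" for composition).
#'
#' @param components List of 4 `binning` objects of one feature track.
#' @inheritParams greedy_select
#' @param label Provenance label for the output.
#' @return A `binning`.
#' @export
stage1 <- function(components, hits, domains, cfg, lengths, label = "stage1") {
  stopifnot(length(components) == 4L)
  out <- greedy_select(components, hits, domains, cfg, lengths)
  out$provenance$label <- label
  out
}

#' Stage 2: cross-track refinement and final greedy selection
#'
#' Builds the candidate pool from the three stage-1 ensembles plus their
#' Binning_refiner-style intersections — all three pairs and the triple in
#' `"pairs_and_triple"` mode, or only tracks A/B and their pair in
#' `"ab_only"` mode — and applies [greedy_select()] once more. An empty
#' input track simply contributes empty refinements.
#'
#' @param metabinA,metabinB,metabinC The three stage-1 `binning`s (combined,
#'   coverage, composition feature tracks).
#' @inheritParams greedy_select
#' @return The final `binning` (disjoint bins `bin.1`, `bin.2`, ...), with
#'   the selection record attached as attribute `"selection"`.
#' @export
stage2 <- function(metabinA, metabinB, metabinC, hits, domains, cfg, lengths) {
  relabel <- function(b, lab) { b$provenance$label <- lab; b }
  A <- relabel(metabinA, "A"); B <- relabel(metabinB, "B")
  C <- relabel(metabinC, "C")
  mrb <- cfg$min_refined_bp
  if (cfg$stage2_combinations == "ab_only") {
    pool <- list(A, B, relabel(refine_intersection(list(A, B), mrb, lengths), "AB"))
  } else {
    pool <- list(
      A, B, C,
      relabel(refine_intersection(list(A, B), mrb, lengths), "AB"),
      relabel(refine_intersection(list(A, C), mrb, lengths), "AC"),
      relabel(refine_intersection(list(B, C), mrb, lengths), "BC"),
      relabel(refine_intersection(list(A, B, C), mrb, lengths), "ABC"))
  }
  greedy_select(pool, hits, domains, cfg, lengths)
}

#' Run the full binning pipeline
#'
#' Executes load -> features -> seed plan -> bin-number selection -> 12
#' component binnings -> contamination splitting -> per-track stage-1
#' ensembles -> stage-2 integration -> output, writing `bins.tsv`, one
#' FASTA per final bin, and a `report.json` with the run provenance into
#' `out_dir`.
#'
#' @param contigs_path FASTA of assembled contigs.
#' @param depth_path Depth table (jgi or plain dialect, auto-detected).
#' @param markers_path Marker-gene hit table.
#' @param out_dir Output directory.
#' @param cfg An [ensemble_config()].
#' @param master_seed Integer master seed; every random choice derives
#'   from it.
#' @param min_contig_length Strict contig length cutoff in bp.
#' @param length_weights Use contig lengths as clustering weights
#'   (default TRUE; FALSE reproduces the "no length weighting" ablation).
#' @param domain_mode `"universal"` or `"bact_arch"` (see
#'   [default_domains()]).
#' @return Invisibly, a list with the final `binning`, the selection table,
#'   and the report list.
#' @export
run_pipeline <- function(contigs_path, depth_path, markers_path, out_dir,
                         cfg = ensemble_config(), master_seed = 1L,
                         min_contig_length = 1000,
                         length_weights = TRUE,
                         domain_mode = c("universal", "bact_arch")) {
  domain_mode <- match.arg(domain_mode)
  contigs <- load_contigs(contigs_path, min_contig_length)
  coverage <- load_depth_table(depth_path, contigs)
  hits <- load_marker_hits(markers_path, contigs)
  if (length(hits$hits) == 0L) {
    stop("marker hit table is empty; cannot estimate the bin number")
  }
  domains <- default_domains(hits, domain_mode)
  features <- build_feature_set(contigs, coverage)
  lengths <- features$lengths
  weights <- if (length_weights) as.numeric(lengths) else rep(1, length(lengths))

  plan <- make_seed_plan(hits, length(contigs))
  seeds <- derive_seeds(master_seed, c("binnum", "components", "split"))
  K <- select_bin_number(features, plan, seeds[["binnum"]], weights = weights)
  components <- generate_component_binnings(features, plan, K,
                                            seeds[["components"]],
                                            weights = weights)
  split_seeds <- derive_seeds(seeds[["split"]], names(components))
  components <- lapply(names(components), function(nm) {
    split_contaminated_bins(components[[nm]], features, hits, domains,
                            split_seeds[[nm]])
  })
  names(components) <- vapply(components, provenance_string, character(1))

  track <- function(f) components[grep(paste0("^", f, "/"), names(components))]
  mA <- stage1(track("combo"), hits, domains, cfg, lengths, "A")
  mB <- stage1(track("cov"), hits, domains, cfg, lengths, "B")
  mC <- stage1(track("com"), hits, domains, cfg, lengths, "C")
  final <- stage2(mA, mB, mC, hits, domains, cfg, lengths)

  stopifnot(!anyDuplicated(names(final$assignment)))
  write_binning(final, out_dir, contigs)
  selection <- attr(final, "selection")
  report <- list(
    n_contigs = length(contigs),
    n_samples = length(coverage$sample_ids),
    k0 = plan$k0,
    candidate_ks = plan$candidate_ks,
    K = K,
    seed_markers = as.list(plan$seed_markers),
    master_seed = master_seed,
    length_weights = length_weights,
    config = unclass(cfg),
    component_bin_counts = vapply(components,
                                  function(b) length(unique(b$assignment)),
                                  integer(1)),
    stage1_bin_counts = c(A = length(unique(mA$assignment)),
                          B = length(unique(mB$assignment)),
                          C = length(unique(mC$assignment))),
    n_final_bins = length(unique(final$assignment)),
    final_bins = selection
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(binning = final, selection = selection, report = report))
}
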