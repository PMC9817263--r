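# AMBER-style evaluation against a gold-standard contig -> genome mapping.
# Contamination at the bin level is reported as 1 - purity.

# Accept either a data.frame(contig_id, genome_id) or a named vector.
.as_truth <- function(truth) {
  if (is.data.frame(truth)) {
    return(stats::setNames(as.character(truth$genome_id),
                           as.character(truth$contig_id)))
  }
  truth
}

#' Assess predicted bins against ground truth
#'
#' Each bin is mapped to the genome contributing the most base pairs
#' (ties: lexicographic genome id). Purity is the mapped genome's bp in
#' the bin over the bin's total bp; completeness is the mapped genome's bp
#' in the bin over that genome's total bp.
#'
#' @param pred A `binning`.
#' @param truth Gold standard: data.frame with `contig_id`, `genome_id`
#'   columns, or a named character vector contig id -> genome id. Every
#'   predicted contig must be labelled.
#' @param lengths Named contig lengths in bp.
#' @return data.frame with columns `bin_id`, `mapped_genome`, `purity`,
#'   `completeness`, `bin_bp`.
#' @export
assess_bins <- function(pred, truth, lengths) {
  truth <- .as_truth(truth)
  bl <- binning_bins(pred)
  if (length(bl) == 0L) {
    return(data.frame(bin_id = character(0), mapped_genome = character(0),
                      purity = numeric(0), completeness = numeric(0),
                      bin_bp = numeric(0)))
  }
  missing <- setdiff(names(pred$assignment), names(truth))
  if (length(missing) > 0L) {
    stop("predicted contig(s) missing from the gold standard: ", missing[1L])
  }
  genome_bp <- vapply(split(lengths[names(truth)], truth), sum, 0)
  out <- lapply(names(bl), function(bid) {
    cs <- bl[[bid]]
    overlap <- vapply(split(lengths[cs], truth[cs]), sum, 0)
    overlap <- overlap[order(-overlap, names(overlap))]
    g <- names(overlap)[1L]
    bin_bp <- sum(lengths[cs])
    data.frame(bin_id = bid, mapped_genome = g,
               purity = overlap[[1L]] / bin_bp,
               completeness = overlap[[1L]] / genome_bp[[g]],
               bin_bp = bin_bp, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Count bins per quality tier
#'
#' The six tiers cross completeness thresholds {50%, 70%, 90%} with
#' contamination thresholds {10%, 5%}, contamination = 1 - purity, all
#' inequalities strict (`comp > t` and `cont < c`).
#'
#' @param assessments Output of [assess_bins()].
#' @return Named integer vector of the six tier counts, e.g.
#'   `comp>0.9_cont<0.05` is the near-complete tier.
#' @export
count_quality_tiers <- function(assessments) {
  comp <- assessments$completeness
  cont <- 1 - assessments$purity
  out <- integer(0)
  for (cc in c(0.10, 0.05)) {
    for (tc in c(0.5, 0.7, 0.9)) {
      out[sprintf("comp>%.1f_cont<%.2f", tc, cc)] <-
        sum(comp > tc & cont < cc)
    }
  }
  out
}

#' Base-pair-weighted adjusted Rand index
#'
#' ARI between the predicted bins and the gold-standard genomes, computed
#' over assigned contigs only, with each contig contributing its length in
#' bp as multiplicity. Also reports the percentage of gold-standard base
#' pairs assigned by the prediction.
#'
#' @inheritParams assess_bins
#' @return List with `ari` (in `[-1, 1]`) and `assigned_bp_pct`.
#' @export
adjusted_rand_index_bp <- function(pred, truth, lengths) {
  truth <- .as_truth(truth)
  assigned <- names(pred$assignment)
  if (length(assigned) == 0L) stop("no assigned contigs; ARI undefined")
  missing <- setdiff(assigned, names(truth))
  if (length(missing) > 0L) {
    stop("predicted contig(s) missing from the gold standard: ", missing[1L])
  }
  w <- lengths[assigned]
  tab <- tapply(w, list(pred$assignment[assigned], truth[assigned]), sum,
                default = 0)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  a <- rowSums(tab)
  b <- colSums(tab)
  sum_a <- sum(comb2(a))
  sum_b <- sum(comb2(b))
  total <- comb2(sum(tab))
  expected <- sum_a * sum_b / total
  maxidx <- (sum_a + sum_b) / 2
  ari <- if (maxidx == expected) 1 else (sum_ij - expected) / (maxidx - expected)
  list(ari = ari,
       assigned_bp_pct = 100 * sum(w) / sum(lengths[names(truth)]))
}
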