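#' Canonical (reverse-complement-folded) tetramer index
#'
#' A tetramer and its reverse complement are indistinguishable on an
#' unoriented contig, so the 256 tetramers collapse into 136 classes
#' (16 palindromes plus 120 complementary pairs). The class representative
#' is the lexicographic minimum of the pair.
#'
#' @return Character vector of the 136 canonical tetramers, sorted.
#' @export
canonical_tetramer_index <- function() {
  sort(unique(.tetramer_canonical_map()))
}

# All 256 tetramers in the order Biostrings::oligonucleotideFrequency
# reports them (lexicographic), mapped to their canonical representative.
.tetramer_canonical_map <- function() {
  if (!is.null(.eb_cache$canon_map)) return(.eb_cache$canon_map)
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, stringsAsFactors = FALSE)[, 4:1]
  tets <- sort(apply(g, 1L, paste0, collapse = ""))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(tets)))
  canon <- stats::setNames(pmin(tets, rc), tets)
  .eb_cache$canon_map <- canon
  canon
}

# 256 x 136 indicator matrix folding raw tetramer counts into classes.
.tetramer_fold_matrix <- function() {
  if (!is.null(.eb_cache$fold)) return(.eb_cache$fold)
  canon <- .tetramer_canonical_map()
  classes <- sort(unique(canon))
  m <- matrix(0, nrow = length(canon), ncol = length(classes),
              dimnames = list(names(canon), classes))
  m[cbind(seq_along(canon), match(canon, classes))] <- 1
  .eb_cache$fold <- m
  m
}

.eb_cache <- new.env(parent = emptyenv())

#' Tetranucleotide composition vector of one sequence
#'
#' Counts sliding 4-mer windows (step 1) made only of A/C/G/T — windows
#' touching an N or other ambiguity code are skipped entirely — folds them
#' into the 136 canonical classes, adds a pseudocount of 1 per class, and
#' normalizes. A sequence with no valid window (too short or all-N) yields
#' the uniform vector.
#'
#' @param sequence Nucleotide string (IUPAC alphabet).
#' @return Named numeric vector of length 136 summing to 1.
#' @export
composition_vector <- function(sequence) {
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(sequence), 4L)
  folded <- as.vector(counts %*% .tetramer_fold_matrix())
  names(folded) <- canonical_tetramer_index()
  (folded + 1) / (sum(counts) + length(folded))
}

#' Build the three per-contig feature matrices
#'
#' The coverage block is the depth matrix plus a 0.01 pseudocount, each
#' sample column divided by its column sum (library-size normalization),
#' then each row divided by its row sum. The composition block is the
#' canonical-tetramer frequency vector per contig. All three matrices are
#' natural-log transformed:
#' `X_cov = ln(cov block)`, `X_com = ln(com block)`,
#' `X_combo = ln([cov block | com block])`.
#'
#' @param contigs Named [Biostrings::DNAStringSet] (the filtered universe).
#' @param coverage A `coverage_table` row-aligned to `contigs`.
#' @return A `feature_set`: list with `contig_ids`, `X_combo` (N x (M+T)),
#'   `X_cov` (N x M), `X_com` (N x T), `lengths` (bp), and `T` (= 136).
#' @export
build_feature_set <- function(contigs, coverage) {
  stopifnot(inherits(coverage, "coverage_table"))
  if (!identical(names(contigs), coverage$contig_ids)) {
    stop("coverage rows are not aligned to the contig universe")
  }
  depth <- coverage$depth
  if (anyNA(depth) || any(!is.finite(depth))) stop("non-finite depth values")

  covb <- depth + 0.01
  covb <- sweep(covb, 2L, colSums(covb), "/")
  covb <- covb / rowSums(covb)

  counts <- Biostrings::oligonucleotideFrequency(contigs, 4L)
  folded <- counts %*% .tetramer_fold_matrix()
  comb <- (folded + 1) / (rowSums(counts) + ncol(folded))
  rownames(comb) <- rownames(covb) <- names(contigs)

  structure(
    list(
      contig_ids = names(contigs),
      X_combo = log(cbind(covb, comb)),
      X_cov = log(covb),
      X_com = log(comb),
      lengths = contig_lengths(contigs),
      T = ncol(comb)
    ),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat("feature_set:", length(x$contig_ids), "contigs,",
      ncol(x$X_cov), "samples,", x$T, "tetramer classes\n")
  invisible(x)
}

#' Export a feature matrix as TSV (debugging aid)
#' @param features A `feature_set`.
#' @param which One of `"combo"`, `"cov"`, `"com"`.
#' @param path Output path.
#' @export
write_features <- function(features, which = c("combo", "cov", "com"), path) {
  which <- match.arg(which)
  m <- features[[paste0("X_", which)]]
  df <- data.frame(contig_id = features$contig_ids,
                   signif(m, 9), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
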