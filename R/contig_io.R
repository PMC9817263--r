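#' Read assembled contigs from a FASTA file
#'
#' Loads contigs, uppercases the sequences, and drops every contig whose
#' length is not strictly greater than `min_contig_length`. Short contigs are
#' the classic source of noisy composition/coverage signal, so binning
#' pipelines exclude them up front; the default cutoff of 1000 bp is the
#' field's conventional choice.
#'
#' @param fasta_path Path to a (plain or gzipped) FASTA file.
#' @param min_contig_length Strict length cutoff in bp; contigs with
#'   `length > min_contig_length` are kept. Must be >= 0.
#' @return A named [Biostrings::DNAStringSet] holding the surviving contigs
#'   in original file order. Names are the FASTA ids up to the first
#'   whitespace and must be unique.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", strrep("ACGT", 300), ">c2", strrep("AC", 100)), fa)
#' contigs <- load_contigs(fa, min_contig_length = 1000)
#' names(contigs)
#' @export
load_contigs <- function(fasta_path, min_contig_length = 1000) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  stopifnot(min_contig_length >= 0)
  # Biostrings silently skips letters outside the IUPAC alphabet (with a
  # warning); promote that to the hard error the contract demands.
  seqs <- withCallingHandlers(
    Biostrings::readDNAStringSet(fasta_path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("non-IUPAC letters in FASTA: ", fasta_path, call. = FALSE)
      }
    })
  if (length(seqs) == 0L) {
    warning("FASTA file contains no sequences: ", fasta_path)
    return(seqs)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(names(seqs) == "")) stop("FASTA record with empty id")
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup) > 0L) {
    stop("duplicate contig id(s): ", paste(dup, collapse = ", "))
  }
  # Re-build through character to normalise case; DNAStringSet validates the
  # alphabet (IUPAC codes only) on construction.
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  seqs[Biostrings::width(seqs) > min_contig_length]
}

#' Per-contig lengths in bp
#'
#' @param contigs A named [Biostrings::DNAStringSet].
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(contigs) {
  stats::setNames(Biostrings::width(contigs), names(contigs))
}

#' Read a per-contig, per-sample mean depth table
#'
#' Supports two dialects: `"jgi"`, the output of
#' `jgi_summarize_bam_contig_depths` (columns `contigName`, `contigLen`,
#' `totalAvgDepth`, then alternating per-sample depth and depth-variance
#' columns; the variance columns are parsed and discarded), and `"plain"`,
#' a contig-id column followed by one numeric column per sample.
#' `"auto"` sniffs the header.
#'
#' @param path Path to a tab-delimited table with a header row.
#' @param contigs The contig universe as returned by [load_contigs()]; rows
#'   are reordered to match it. Table rows for contigs not in the universe
#'   (e.g. filtered-out short contigs) are silently dropped; contigs missing
#'   from the table are a hard error.
#' @param dialect One of `"auto"`, `"jgi"`, `"plain"`.
#' @return A `coverage_table`: list with `contig_ids`, `sample_ids`, and the
#'   N x M `depth` matrix (rownames = contig ids).
#' @export
load_depth_table <- function(path, contigs, dialect = c("auto", "jgi", "plain")) {
  dialect <- match.arg(dialect)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (dialect == "auto") {
    dialect <- if (all(c("contigName", "totalAvgDepth") %in% names(dt))) "jgi" else "plain"
  }
  if (dialect == "jgi") {
    required <- c("contigName", "contigLen", "totalAvgDepth")
    if (!all(required %in% names(dt))) {
      stop("jgi depth table must have columns ", paste(required, collapse = ", "))
    }
    ids <- as.character(dt[["contigName"]])
    value_cols <- setdiff(names(dt), required)
    sample_cols <- value_cols[!grepl("-var$", value_cols)]
  } else {
    ids <- as.character(dt[[1L]])
    sample_cols <- names(dt)[-1L]
  }
  if (length(sample_cols) == 0L) stop("depth table has no sample columns (M = 0)")
  depth <- as.matrix(dt[, sample_cols, drop = FALSE])
  storage.mode(depth) <- "double"
  if (anyNA(depth)) stop("depth table contains non-numeric or missing values")
  if (any(depth < 0)) stop("depth table contains negative depths")
  rownames(depth) <- ids

  universe <- names(contigs)
  missing <- setdiff(universe, ids)
  if (length(missing) > 0L) {
    stop("contig(s) missing from depth table: ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  depth <- depth[universe, , drop = FALSE]
  structure(
    list(contig_ids = universe, sample_ids = sample_cols, depth = depth),
    class = "coverage_table"
  )
}

#' Read a single-copy marker-gene hit table
#'
#' The table abstracts an upstream gene-prediction + HMM-search step: each
#' row records one marker gene observed on one contig with a copy count.
#' Columns `marker_id`, `contig_id`, `copy_count` are required; an optional
#' `gene_length` column (or sidecar table with columns `marker_id`,
#' `gene_length`) supplies the marker model length used by the
#' shortest-gene tie-break when choosing seed markers.
#'
#' @param path Path to the tab-delimited hit table (header row required).
#' @param contigs The contig universe; hits on contigs outside it are
#'   dropped with a message (they typically sit on filtered short contigs).
#' @param gene_length_path Optional sidecar TSV with `marker_id`,
#'   `gene_length` columns.
#' @param domain Label for the marker collection, e.g. `"universal"`.
#' @return A `marker_hits` object: list with `hits` (named list: marker id
#'   -> named integer vector contig id -> copy count, contigs sorted),
#'   `gene_length` (named numeric, 0 when unknown), and `domain`.
#' @export
load_marker_hits <- function(path, contigs, gene_length_path = NULL,
                             domain = "universal") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0L) {
    return(new_marker_hits(list(), numeric(0), domain))
  }
  required <- c("marker_id", "contig_id", "copy_count")
  if (!all(required %in% names(dt))) {
    stop("marker hit table must have columns ", paste(required, collapse = ", "))
  }
  if (any(dt$copy_count < 1)) stop("marker hit table contains copy_count < 1")

  keep <- dt$contig_id %in% names(contigs)
  if (any(!keep)) {
    message(sum(!keep), " marker hit row(s) on contigs outside the universe dropped")
  }
  dt <- dt[keep, , drop = FALSE]

  gene_length <- numeric(0)
  if ("gene_length" %in% names(dt)) {
    gl <- dt[!duplicated(dt$marker_id), c("marker_id", "gene_length")]
    gene_length <- stats::setNames(as.numeric(gl$gene_length), gl$marker_id)
  }
  if (!is.null(gene_length_path)) {
    gl <- data.table::fread(gene_length_path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    gene_length <- stats::setNames(as.numeric(gl$gene_length), gl$marker_id)
  }

  hits <- lapply(split(dt, dt$marker_id), function(d) {
    counts <- tapply(as.integer(d$copy_count), d$contig_id, sum)
    v <- stats::setNames(as.integer(counts), names(counts))
    v[order(names(v))]
  })
  hits <- hits[order(names(hits))]
  gl_full <- stats::setNames(rep(0, length(hits)), names(hits))
  gl_full[intersect(names(gene_length), names(gl_full))] <-
    gene_length[intersect(names(gene_length), names(gl_full))]
  new_marker_hits(hits, gl_full, domain)
}

#' Construct a marker hit table in memory
#'
#' @param hits Named list: marker id -> named integer vector of copy counts
#'   keyed by contig id.
#' @param gene_length Named numeric vector of marker model lengths (0 when
#'   unknown).
#' @param domain Label for the marker collection.
#' @return A `marker_hits` object.
#' @export
new_marker_hits <- function(hits, gene_length, domain = "universal") {
  structure(list(hits = hits, gene_length = gene_length, domain = domain),
            class = "marker_hits")
}

#' Construct a binning from a contig -> bin assignment
#'
#' @param assignment Named character vector mapping contig id to bin id.
#' @param provenance Free-form list recording how the binning was produced
#'   (feature matrix, initialization, RNG seed, stage); `provenance$label`
#'   is used as the source prefix in ensemble tie-breaking.
#' @return A `binning` object.
#' @export
new_binning <- function(assignment, provenance = list()) {
  if (length(assignment) == 0L) {
    assignment <- stats::setNames(character(0), character(0))
  }
  assignment <- assignment[order(names(assignment))]
  if (anyDuplicated(names(assignment))) {
    stop("binning assigns a contig to more than one bin")
  }
  structure(list(assignment = assignment, provenance = provenance),
            class = "binning")
}

#' Bins of a binning as a named list of contig id vectors
#' @param binning A `binning` object.
#' @return Named list: bin id -> character vector of contig ids.
#' @export
binning_bins <- function(binning) {
  if (length(binning$assignment) == 0L) return(stats::setNames(list(), character(0)))
  split(names(binning$assignment), binning$assignment)
}

#' @export
print.binning <- function(x, ...) {
  cat("binning:", length(unique(x$assignment)), "bins over",
      length(x$assignment), "contigs\n")
  if (!is.null(x$provenance$label)) cat("  provenance:", x$provenance$label, "\n")
  invisible(x)
}

provenance_string <- function(binning) {
  p <- binning$provenance
  if (!is.null(p$label)) return(p$label)
  if (!is.null(p$feature)) return(paste(p$feature, p$init, sep = "/"))
  "binning"
}

#' Write a binning to disk
#'
#' Emits `bins.tsv` (two columns, `contig_id` and `bin_id`, covering exactly
#' the binned contigs) plus one FASTA per bin named `<bin_id>.fa`.
#'
#' @param binning A `binning` object; bins must be disjoint.
#' @param out_dir Output directory (created if needed).
#' @param contigs The contig universe holding the sequences.
#' @return Invisibly, the path of the TSV.
#' @export
write_binning <- function(binning, out_dir, contigs) {
  stopifnot(inherits(binning, "binning"))
  if (anyDuplicated(names(binning$assignment))) {
    stop("bins are not disjoint")
  }
  bad <- setdiff(names(binning$assignment), names(contigs))
  if (length(bad) > 0L) stop("binned contig(s) not in universe: ", bad[1L])
  bin_ids <- unique(binning$assignment)
  if (any(grepl("[/\\\\]", bin_ids))) {
    stop("bin id contains a path separator: ",
         bin_ids[grepl("[/\\\\]", bin_ids)][1L])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(out_dir, "bins.tsv")
  df <- data.frame(contig_id = names(binning$assignment),
                   bin_id = unname(binning$assignment))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  for (b in split(df$contig_id, df$bin_id)) {
    bid <- binning$assignment[[b[1L]]]
    Biostrings::writeXStringSet(contigs[b], file.path(out_dir, paste0(bid, ".fa")))
  }
  invisible(tsv)
}

#' Read a binning written by [write_binning()] (or any contig_id/bin_id TSV)
#' @param path Path to the two-column TSV.
#' @return A `binning` object.
#' @export
read_binning <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0L) {
    return(new_binning(stats::setNames(character(0), character(0))))
  }
  new_binning(stats::setNames(as.character(dt[[2L]]), as.character(dt[[1L]])))
}
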