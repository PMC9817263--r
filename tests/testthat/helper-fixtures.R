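# Shared fixture builders. Everything is generated in code at test time;
# no data files ship with the package.

# Write a named character vector of sequences as a temporary FASTA.
write_tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  lines <- character(0)
  for (i in seq_along(seqs)) {
    lines <- c(lines, paste0(">", names(seqs)[i]), seqs[[i]])
  }
  writeLines(lines, path)
  path
}

# Write a plain-dialect depth table for a named depth matrix.
write_tmp_depth <- function(depth) {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(contig_id = rownames(depth), depth, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Write a marker hit TSV from a data.frame-like list of rows.
write_tmp_markers <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Build a marker_hits object from a list marker -> contig id vector
# (copy count 1 each unless `copies` overrides) plus optional gene lengths.
toy_hits <- function(contig_lists, gene_length = NULL, copies = NULL) {
  hits <- lapply(names(contig_lists), function(m) {
    cs <- contig_lists[[m]]
    cp <- if (is.null(copies[[m]])) rep(1L, length(cs)) else copies[[m]]
    v <- setNames(as.integer(cp), cs)
    v[order(names(v))]
  })
  names(hits) <- names(contig_lists)
  hits <- hits[order(names(hits))]
  gl <- setNames(rep(0, length(hits)), names(hits))
  if (!is.null(gene_length)) gl[names(gene_length)] <- gene_length
  ensemblebin::new_marker_hits(hits, gl)
}

# Minimal feature_set wrapper around a bare matrix (used by clustering and
# splitting tests that do not need real sequences).
fake_feature_set <- function(X, lengths = NULL, ids = NULL) {
  if (is.null(ids)) ids <- paste0("c", seq_len(nrow(X)))
  if (is.null(lengths)) lengths <- setNames(rep(1, nrow(X)), ids)
  structure(list(contig_ids = ids, X_combo = X, X_cov = X, X_com = X,
                 lengths = setNames(lengths, ids), T = ncol(X)),
            class = "feature_set")
}

# Two well-separated isotropic 2-D blobs.
make_blobs <- function(n_per = 30, centers = list(c(0, 0), c(10, 10)),
                       sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(centers, function(ctr) {
      cbind(rnorm(n_per, ctr[1], sd), rnorm(n_per, ctr[2], sd))
    }))
    labels <- rep(seq_along(centers), each = n_per)
    list(X = X, labels = labels)
  })
}

# A small simulated community for integration-style tests.
small_sim <- function(seed = 7, n_genomes = 5, out_dir = tempfile(), ...) {
  spec <- community_spec(n_genomes = n_genomes, genome_length_bp = 30000L,
                         n_samples = 4L, contig_mean_bp = 5000,
                         n_markers = 12L, seed = seed, ...)
  sim <- simulate_community(spec, out_dir)
  contigs <- load_contigs(sim$paths[["contigs"]])
  coverage <- load_depth_table(sim$paths[["depth"]], contigs)
  hits <- load_marker_hits(sim$paths[["markers"]], contigs)
  list(spec = spec, sim = sim, contigs = contigs, coverage = coverage,
       hits = hits, lengths = contig_lengths(contigs))
}

# Ground-truth high-quality bin count (the Table-style ">50% comp <10% cont"
# tier) of one binning.
truth_hq_count <- function(binning, truth, lengths) {
  ass <- assess_bins(binning, truth, lengths)
  sum(ass$completeness > 0.5 & (1 - ass$purity) < 0.10)
}

# Independent mean-silhouette implementation (plain loops, no cluster pkg).
naive_mean_silhouette <- function(X, labels) {
  d <- as.matrix(dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(k) {
      mean(d[i, labels == k])
    }, 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Weighted inertia of a labelling with centers held fixed (the objective
# Lloyd assignment steps minimize; single-label moves against it verify
# Lloyd-local optimality).
fixed_center_inertia <- function(X, weights, labels, centers) {
  d2 <- rowSums((X - centers[labels, , drop = FALSE])^2)
  sum(weights * d2)
}

# Weighted inertia of a labelling with centers at the weighted means.
labelling_inertia <- function(X, weights, labels) {
  total <- 0
  for (k in unique(labels)) {
    idx <- which(labels == k)
    ctr <- colSums(X[idx, , drop = FALSE] * weights[idx]) / sum(weights[idx])
    total <- total + sum(weights[idx] *
                           rowSums(sweep(X[idx, , drop = FALSE], 2, ctr)^2))
  }
  total
}
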