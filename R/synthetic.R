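#' Specify a synthetic metagenomic community
#'
#' The simulator stands in for a CAMI-style benchmark at desk scale: each
#' genome is an order-1 Markov nucleotide chain whose transition rows are
#' drawn from a Dirichlet, giving it a genome-specific tetramer signature;
#' genomes are fragmented into lognormally sized contigs; per-sample depths
#' follow a per-genome, per-sample lognormal abundance times multiplicative
#' lognormal noise; and exactly one copy of each single-copy marker gene is
#' planted per genome on a uniformly chosen contig (optionally recorded as
#' fragmented across two contigs).
#'
#' @param n_genomes Number of genomes G (>= 2).
#' @param genome_length_bp Length of each genome in bp.
#' @param n_samples Number of samples M (>= 1).
#' @param contig_mean_bp Mean of the lognormal contig-length distribution.
#' @param contig_sigma Lognormal sigma of contig lengths.
#' @param min_contig_length Lower truncation of contig lengths (bp); all
#'   emitted contigs are strictly longer, so none are lost at load time.
#' @param abundance_meanlog,abundance_sdlog Per-genome per-sample lognormal
#'   abundance parameters (depth units).
#' @param dirichlet_alpha Concentration of the Dirichlet from which each
#'   genome's 4x4 transition-matrix rows are drawn; smaller values give
#'   more skewed, hence more separable, composition signatures.
#' @param n_markers Number of single-copy marker genes planted per genome.
#' @param marker_fragmentation_prob Probability that a planted marker is
#'   recorded on two contigs of its genome, emulating genes fragmented by
#'   assembly.
#' @param depth_noise_cv Coefficient of variation of the multiplicative
#'   depth noise.
#' @param seed Integer seed; the whole community is a deterministic
#'   function of the spec including this seed.
#' @return A `community_spec` list.
#' @export
community_spec <- function(n_genomes = 20L, genome_length_bp = 200000L,
                           n_samples = 10L, contig_mean_bp = 10000,
                           contig_sigma = 0.4, min_contig_length = 1000L,
                           abundance_meanlog = 2, abundance_sdlog = 1,
                           dirichlet_alpha = 0.5, n_markers = 40L,
                           marker_fragmentation_prob = 0,
                           depth_noise_cv = 0.1, seed = 1L) {
  spec <- list(n_genomes = as.integer(n_genomes),
               genome_length_bp = as.integer(genome_length_bp),
               n_samples = as.integer(n_samples),
               contig_mean_bp = contig_mean_bp,
               contig_sigma = contig_sigma,
               min_contig_length = as.integer(min_contig_length),
               abundance_meanlog = abundance_meanlog,
               abundance_sdlog = abundance_sdlog,
               dirichlet_alpha = dirichlet_alpha,
               n_markers = as.integer(n_markers),
               marker_fragmentation_prob = marker_fragmentation_prob,
               depth_noise_cv = depth_noise_cv,
               seed = as.integer(seed))
  stopifnot(spec$n_genomes >= 2, spec$n_samples >= 1,
            spec$marker_fragmentation_prob >= 0,
            spec$marker_fragmentation_prob <= 1)
  if (spec$genome_length_bp <= spec$min_contig_length) {
    stop("genome shorter than the minimum contig length")
  }
  structure(spec, class = "community_spec")
}

# Draw one genome sequence: Dirichlet transition rows, then a Markov chain.
.simulate_genome_sequence <- function(n, alpha) {
  P <- matrix(stats::rgamma(16L, shape = alpha), 4L, 4L)
  P <- P / rowSums(P)
  cum <- t(apply(P, 1L, cumsum))
  states <- markov_chain_states(n, cum, stats::runif(n))
  paste(c("A", "C", "G", "T")[states], collapse = "")
}

# Cut a genome into contig lengths: lognormal draws truncated below at
# min_len + 1; a trailing remainder shorter than that is merged into the
# previous contig so every emitted contig survives the load filter and
# total bp is conserved.
.fragment_lengths <- function(genome_len, mean_bp, sigma, min_len) {
  meanlog <- log(mean_bp) - sigma^2 / 2
  lens <- integer(0)
  remaining <- genome_len
  while (remaining > 0L) {
    l <- as.integer(round(stats::rlnorm(1L, meanlog, sigma)))
    l <- max(l, min_len + 1L)
    if (l >= remaining) {
      if (remaining <= min_len && length(lens) > 0L) {
        lens[length(lens)] <- lens[length(lens)] + remaining
      } else {
        lens <- c(lens, remaining)
      }
      remaining <- 0L
    } else {
      lens <- c(lens, l)
      remaining <- remaining - l
    }
  }
  lens
}

#' Simulate a community and write its input files
#'
#' Writes `contigs.fa`, `depth.tsv`, `markers.tsv`, and `truth.tsv`
#' (contig_id, genome_id) into `out_dir`. Byte-identical output for
#' identical specs.
#'
#' @param spec A [community_spec()].
#' @param out_dir Output directory (created if needed).
#' @param dialect Depth-table dialect to write, `"plain"` or `"jgi"`.
#' @return List with `paths` (named: contigs, depth, markers, truth),
#'   `truth` (data.frame contig_id/genome_id), `genome_bp` (named vector),
#'   and the `spec`.
#' @export
simulate_community <- function(spec, out_dir, dialect = c("plain", "jgi")) {
  stopifnot(inherits(spec, "community_spec"))
  dialect <- match.arg(dialect)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(spec$seed, {
    G <- spec$n_genomes
    genome_ids <- sprintf("genome_%02d", seq_len(G))
    seqs <- character(0)
    contig_ids <- character(0)
    contig_genome <- character(0)
    contig_len <- integer(0)
    for (g in seq_len(G)) {
      gseq <- .simulate_genome_sequence(spec$genome_length_bp,
                                        spec$dirichlet_alpha)
      lens <- .fragment_lengths(spec$genome_length_bp, spec$contig_mean_bp,
                                spec$contig_sigma, spec$min_contig_length)
      stops <- cumsum(lens)
      starts <- c(1L, utils::head(stops, -1L) + 1L)
      ids <- sprintf("g%02d_c%03d", g, seq_along(lens))
      seqs <- c(seqs, substring(gseq, starts, stops))
      contig_ids <- c(contig_ids, ids)
      contig_genome <- c(contig_genome, rep(genome_ids[g], length(lens)))
      contig_len <- c(contig_len, lens)
    }
    N <- length(contig_ids)

    abundance <- matrix(
      stats::rlnorm(G * spec$n_samples, spec$abundance_meanlog,
                    spec$abundance_sdlog),
      nrow = G, dimnames = list(genome_ids, NULL))
    cv <- spec$depth_noise_cv
    sdlog <- sqrt(log(1 + cv^2))
    noise <- matrix(stats::rlnorm(N * spec$n_samples, -sdlog^2 / 2, sdlog),
                    nrow = N)
    depth <- abundance[contig_genome, , drop = FALSE] * noise
    colnames(depth) <- sprintf("S%02d", seq_len(spec$n_samples))

    marker_ids <- sprintf("marker_%03d", seq_len(spec$n_markers))
    gene_length <- sample(300:3000, spec$n_markers, replace = TRUE)
    rows <- list()
    by_genome <- split(seq_len(N), contig_genome)
    for (g in genome_ids) {
      gi <- by_genome[[g]]
      for (m in seq_len(spec$n_markers)) {
        ci <- gi[sample.int(length(gi), 1L)]
        frag <- length(gi) >= 2L &&
          stats::runif(1L) < spec$marker_fragmentation_prob
        hit_contigs <- contig_ids[ci]
        if (frag) {
          others <- setdiff(gi, ci)
          ci2 <- others[sample.int(length(others), 1L)]
          hit_contigs <- c(hit_contigs, contig_ids[ci2])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          marker_id = marker_ids[m], contig_id = hit_contigs,
          copy_count = 1L, gene_length = gene_length[m],
          stringsAsFactors = FALSE)
      }
    }
    markers <- do.call(rbind, rows)

    paths <- c(contigs = file.path(out_dir, "contigs.fa"),
               depth = file.path(out_dir, "depth.tsv"),
               markers = file.path(out_dir, "markers.tsv"),
               truth = file.path(out_dir, "truth.tsv"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(seqs, contig_ids)),
      paths[["contigs"]])
    if (dialect == "plain") {
      df <- data.frame(contig_id = contig_ids, depth, check.names = FALSE)
    } else {
      samples <- colnames(depth)
      df <- data.frame(contigName = contig_ids, contigLen = contig_len,
                       totalAvgDepth = rowSums(depth), check.names = FALSE)
      for (s in samples) {
        df[[paste0(s, ".bam")]] <- depth[, s]
        df[[paste0(s, ".bam-var")]] <- (depth[, s] * cv)^2
      }
    }
    utils::write.table(df, paths[["depth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(markers, paths[["markers"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth <- data.frame(contig_id = contig_ids, genome_id = contig_genome,
                        stringsAsFactors = FALSE)
    utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    genome_bp <- vapply(split(contig_len, contig_genome), sum, 0)
    list(paths = paths, truth = truth, genome_bp = genome_bp, spec = spec)
  })
}

#' Build a merged-bin fixture for the contamination splitter
#'
#' Simulates a community, loads its inputs, and returns a binning whose
#' first bin unites the contigs of the first two genomes (holding two full
#' single-copy marker sets, hence completeness 1 and contamination 1)
#' while every other genome forms a correct bin.
#'
#' @param spec A [community_spec()].
#' @param out_dir Directory for the simulated input files.
#' @return List with `binning` (the deliberately merged binning),
#'   `contigs`, `coverage`, `hits`, `features`, `truth`, `genome_bp`,
#'   `merged_genomes` (the two united genome ids), and `sim`.
#' @export
make_merged_bin_fixture <- function(spec, out_dir) {
  sim <- simulate_community(spec, out_dir)
  contigs <- load_contigs(sim$paths[["contigs"]], spec$min_contig_length)
  coverage <- load_depth_table(sim$paths[["depth"]], contigs)
  hits <- load_marker_hits(sim$paths[["markers"]], contigs)
  features <- build_feature_set(contigs, coverage)
  truth <- stats::setNames(sim$truth$genome_id, sim$truth$contig_id)
  merged <- sort(unique(truth))[1:2]
  bin_of <- ifelse(truth %in% merged, "merged", truth)
  binning <- new_binning(stats::setNames(bin_of, names(truth)),
                         provenance = list(label = "fixture"))
  list(binning = binning, contigs = contigs, coverage = coverage,
       hits = hits, features = features, truth = sim$truth,
       genome_bp = sim$genome_bp, merged_genomes = merged, sim = sim)
}
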