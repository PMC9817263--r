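---
title: "Methods: marker-seeded ensemble contig binning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-seeded ensemble contig binning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensemblebin)
```

# The problem

Metagenomic assembly yields contigs from many genomes mixed together.
Binning groups contigs into putative genomes (MAGs) using two signals:
**composition** (tetranucleotide frequencies, a genome-specific signature)
and **coverage** (mean read depth per sample; contigs from one genome
co-vary in abundance across samples). No single clustering of one feature
representation is reliable across community structures, so `ensemblebin`
generates a *diverse set* of component binnings and then integrates them,
scoring candidate bins with single-copy marker genes (SCGs) — genes present
exactly once in essentially every genome of a clade, so that missing genes
measure incompleteness and surplus copies measure contamination.

# Feature construction

For `N` contigs, `M` samples, and `T = 136` canonical tetramers, three
matrices are built:

* coverage block: depth + 0.01 (pseudocount), per-sample column
  normalization (library size), then per-contig row normalization;
* composition block: sliding 4-mer counts (windows containing any
  non-ACGT base are skipped), folded into reverse-complement classes,
  +1 pseudocount per class, row-normalized;
* `X_cov = ln(cov)`, `X_com = ln(com)`, `X_combo = ln([cov | com])`.

The tetramers are folded because an unoriented contig cannot distinguish a
4-mer from its reverse complement; 256 words collapse into
`(256 - 16)/2 + 16 = 136` classes. With a single sample (`M = 1`) the
normalization collapses the coverage block to a constant, which is the
honest statement that one sample's depth carries no *relative* information;
binning then rests on composition alone. We deliberately do not
length-correct depths (they are already per-base means) and apply no PCA.

# Bin-number estimation

For each marker gene `g`, let `c_g` be the number of distinct contigs
carrying it. In an ideal assembly `c_g` equals the number of genomes;
fragmentation inflates it and incomplete marker carriage deflates it. The
initial bin number `k0` is the **third quartile** of `{c_g}` (linear
interpolation over the ascending values — R's type-7 quantile — then
`ceiling`). Ceiling errs toward more clusters, which the ensemble stage can
dereplicate, whereas an under-split merge is harder to repair. Candidates
`k0, k0 + s, …` (step `s = max(1, ceil(k0/10))`, at most 10 values, all
`< N`) are each clustered on `X_combo`, and the candidate with the highest
mean silhouette wins (Euclidean, unweighted, one shared subsample of at
most 2000 contigs so candidates see identical data; ties go to the
smallest k). One `K` is shared by all twelve runs: estimating it once on
the combined features keeps the component binnings comparable and saves
eleven silhouette scans; the ensemble, not `K`, is the instrument that
reconciles disagreement between tracks.

# Partial-seed weighted k-means++

Contigs carrying one chosen SCG should lie in distinct genomes, so they
make ideal initial centers. For each quartile target (Q1, Q2, Q3 of
`{c_g}`, nearest integer), the marker with the closest `c_g` is chosen —
ties broken by smaller gene length ("shortest marker gene", as in MaxBin's
seeding), then lexicographic id. Its `l` contigs fix the first `l` centers;
standard D²-weighted k-means++ samples the remaining `K − l`, with each
point's probability proportional to `weight × D²`. Seeds fix the
*initialization only*: Lloyd iterations move all centers freely. If
`l ≥ K`, the run degenerates to "seed k-means" with `K := l`.

Contig length in bp is the observation weight throughout (a 100 kb contig
counts as a hundred 1 kb ones); integer weights are exactly equivalent to
row duplication, which the tests assert. Lloyd runs to `tol = 1e-4` on the
maximum center displacement or 300 iterations; an empty cluster is
re-seeded at the point with the largest weighted squared distance to its
center. Per feature matrix there are 3 partial-seed runs plus one plain
k-means++ run: 12 component binnings, each on its own named RNG substream
of the master seed, so ablating one run never shifts another's draws.

**A note on local optimality.** A converged Lloyd assignment satisfies:
centers are the weighted means of their clusters, and no single-label move
lowers the inertia *with centers held fixed*. It need not be stable against
moves that also re-compute the means (Hartigan's criterion); a 1-D
counterexample with 8 weighted points appears in the test suite. The
local-optimum checks therefore test the former, which is what Lloyd
guarantees.

# Quality scoring and splitting

Bin quality uses a per-gene simplification of CheckM's strategy: for a
domain marker set of size `S`, completeness is the fraction of the set's
genes present at least once, contamination is `Σ_g max(0, copies_g − 1)/S`,
and the **bin score** is

```
score = 100 × (completeness − 3 × contamination)
```

A bin is *high quality* when score > 10, contamination < 15%, and
completeness > 50% (all strict). Several domain sets (e.g. bacterial and
archaeal) may be supplied; a bin keeps its best-scoring domain. This
per-gene model deliberately drops CheckM's collocated-set machinery: the
package consumes an abstract hit table rather than lineage HMMs, and the
ensemble logic only requires a consistent, monotone quality functional.
Thresholds may therefore shift slightly against CheckM's set-based values —
the one intentional simplification of the method, and the reason marker
hit tables are an explicit input.

Before integration, any component bin with contamination ≥ 50% **and**
completeness ≥ 70% (both inclusive) — the signature of several merged
genomes — is split: the bin-number procedure is re-run on the bin's own
contigs and marker hits, and its `X_combo` rows are re-clustered with plain
weighted k-means++. Bins below either threshold, with fewer than two
contigs, or without marker hits pass through untouched.

# Two-stage ensemble

**Stage 1** (per feature track): the four post-split binnings of one track
enter greedy selection — repeatedly take the highest-scoring bin that
passes the high-quality predicate (ties: larger total bp, then
lexicographic source), remove its contigs from every remaining candidate,
and re-score only the candidates that lost contigs. The result is
"MetabinA/B/C" for the combined/coverage/composition tracks.

**Stage 2**: candidate pool = {A, B, C} plus their intersection
refinements — contigs are keyed by their tuple of bin labels across
binnings, and every tuple group with total length ≥ `min_refined_bp`
becomes a refined (low-contamination) candidate bin. The default pool uses
all three pairs and the triple; `ab_only` mode restricts to {A, B, AB} for
ablation. The same greedy selection runs once more; final bins are named
`bin.<rank>` in selection order and are pairwise disjoint by construction.

`min_refined_bp` defaults to 524288 bp (Binning_refiner's published
default). Desk-scale synthetic genomes are smaller than that, so the tests
and examples use ~10 kb; the parameter is a floor on how small a refined
fragment is worth keeping, not a tuning knob of the method.

# The synthetic community

`simulate_community()` emulates exactly what the pipeline consumes:

* each genome is an order-1 Markov chain whose 4×4 transition rows are
  drawn from `Dirichlet(alpha)` — `alpha = 0.5` gives clearly distinct
  tetramer signatures; `alpha → ∞` erases composition signal (used by the
  coverage-trend test);
* genomes fragment into lognormal contigs (mean 10 kb, σ = 0.4, truncated
  above the 1000 bp load filter so no bp are lost);
* depth of contig *i* in sample *j* is a per-genome per-sample lognormal
  abundance (meanlog 2, sdlog 1 by default) times multiplicative lognormal
  noise with CV 0.1 — realistic short-read depth variability after
  `jgi_summarize_bam_contig_depths`-style averaging;
* exactly one copy of each of 40 markers is planted per genome on a
  uniform contig; with probability `marker_fragmentation_prob` a marker is
  recorded on two contigs, emulating assembly fragmentation of genes; gene
  lengths are uniform on [300, 3000] to exercise the shortest-gene
  tie-break.

What the generator does **not** model: strain-level variation, shared or
horizontally transferred sequence between genomes, uneven genome sizes,
plasmids/viruses, chimeric contigs, or read-level error. A green
end-to-end test therefore establishes that the machinery is implemented
coherently and recovers planted structure — not that real-assembly
performance matches any published benchmark.

# Numerical and design choices

* Quartile convention: type-7 (linear interpolation); `ceiling` for `k0`,
  nearest integer for seed-marker targets. The method statement fixes
  neither; these choices are frozen and tested.
* Degenerate D² mass (all remaining points at distance 0): fall back to
  weight-proportional sampling without replacement.
* Ties in nearest-center assignment go to the lowest center index;
  silhouette ties to the smallest candidate k; greedy ties to larger bp
  then lexicographic source — every tie-break is deterministic, so a
  master seed fixes the entire pipeline output byte-for-byte on a given
  platform (floating-point reductions may differ across BLAS builds).
* Empty marker table: the pipeline refuses to run (there is no defensible
  bin-number estimate without markers).
* Sub-1000 bp contigs are dropped at load time and never rescued into
  bins; their depth rows and marker hits are silently ignored.

# Known limitations

* Per-gene (not collocated-set) completeness/contamination; see above.
* Silhouette selection on a 2000-contig subsample can be noisy for very
  uneven communities; the partial-seed design intentionally reduces the
  damage of a misestimated `K`.
* Greedy selection is not globally optimal (it matches the brute-force
  greedy oracle, not an exhaustive search over all selections), and adding
  candidate binnings is not guaranteed to improve results on adversarial
  inputs.
* The CLI's config file is JSON, not YAML.
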