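---
title: "Structural-variant fingerprints in gut-microbiome MAGs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural-variant fingerprints in gut-microbiome MAGs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`magsv` implements an analysis pipeline for structural variation (SV) among
metagenome-assembled genomes (MAGs) of the same bacterial species across
human gut microbiome samples: MAG quality scoring and representative
selection, pairwise SV calling with contig-end filtering and per-megabase
normalisation, spanning-read validation with long reads, inter- versus
intra-individual fingerprint statistics, an SV-stratified
bacteria-metabolite-phenotype association cascade, and Fisher enrichment of
SV-affected genes. A synthetic-data module generates every input with full
planted truth, so the whole pipeline is exercised end to end against known
answers. Upstream steps (assembly, binning, dereplication, taxonomy,
gene/KO annotation, LC-MS processing) are out of scope; their outputs are
the package's inputs.

# MAG quality and representative selection

Each MAG is scored as

$$\mathrm{Score} = \mathrm{Completeness} - 5\,\mathrm{Contamination} + 0.5\,\log_{10} \mathrm{N50},$$

with completeness and contamination on the 0-100 scale (the 1/-5 weights
only make sense there) and N50 the largest contig length $L$ such that
contigs of length $\ge L$ hold at least half the assembly. The log base is
not universal across tools; we use base 10, the convention of dRep-style
genome scoring, and record it here because it only rescales the N50 term.
MAGs pass QC when completeness is strictly above 70% and contamination
strictly below 10%. Ties in representative selection are broken by higher
completeness, then lower contamination, then lexicographic id, so selection
is deterministic. Coding density sums ORF lengths literally (overlapping
ORFs counted twice); a `merge_overlaps` flag unions them instead.

# SV calling from collinear blocks

The caller consumes collinear alignment blocks: either PAF records from an
external whole-genome aligner, or the package's anchor aligner, which is
intended for desk-scale synthetic genomes. The anchor aligner takes exact
k-mers (default k = 21) that are unique in each genome — MUM-style anchors —
and chains anchors lying on one diagonal into maximal blocks.

Between consecutive same-strand blocks, a reference gap exceeding the query
gap by at least `min_sv_len` is a deletion of the difference; the converse
is an insertion. A minus-strand block flanked by plus-strand blocks is an
inversion. Three numerical choices matter:

* **`min_sv_len` = 50 bp.** The SV floor; shorter events are indels outside
  the package's scope. 50 bp matches the convention of MUM-based SV callers
  for bacterial genomes.
* **`max_gap` = 40 bp.** An inversion does not shift the alignment
  diagonal, so the chain gap tolerance must stay below `min_sv_len` or
  chains would run straight across short inversions. 40 bp tolerates anchor
  droughts from repeated k-mers while breaking at every callable SV.
  A consequence is that inversions shorter than `min_chain_bp` (default 50)
  cannot be typed; with the default length model the shortest planted SVs
  are 50 bp, and the short inversion peak sits at 140-160 bp.
* **`overlap_tol` = 25 bp.** When the first bases of an inserted sequence
  happen to match the reference bases after the junction, blocks extend a
  few bases past the true breakpoint and consecutive blocks can overlap
  slightly. Overlaps up to `overlap_tol` are trimmed left-aligned (the
  standard normalisation of breakpoint ambiguity); larger overlaps indicate
  malformed input and raise an error.

Calls with any breakpoint closer than `end_margin` (default 10 bp) to a
contig terminus of either genome are kept in the output but flagged
`filtered`, reason `"contig_end"`, so the filter is auditable rather than
silent. Counts are normalised as retained calls × 10^6 / genome size
(SVs per Mb). Calls longer than 500 bp form the "large" class.

Truth matching (`compare_to_truth`) accepts a call when type, reference
start (± 25 bp) and length (± max(25 bp, 5%)) agree; the tolerance absorbs
the ± k anchor jitter at breakpoints.

# Spanning-read validation

A read supports a call when its mapped interval covers the breakpoints plus
a 100 bp flank on each side, on the genome that carries the allele: the
reference for deletions (the deleted sequence exists there), the query for
insertions, and either genome for inversions (each carries its own
orientation; the larger of the two counts is thresholded). A call is
*supported* with at least `min_support` = 2 spanning reads ("multiple"
reads). The internal read mapper samples k-mers along the read (stride 50),
looks them up in the genome's unique-k-mer index and votes on (contig,
diagonal, strand); it maps error-free and substitution-noised reads well,
but indel-type read errors shift diagonals and reduce its sensitivity —
for real ONT data a dedicated long-read mapper's PAF should be supplied
instead via the `alignments` argument.

# Fingerprint statistics

Pairwise per-Mb SV rates between same-species MAGs are labelled
inter-individual or intra-individual from a sample-to-individual map and
compared with a two-sided Wilcoxon rank-sum test (exact enumeration up to
combined n = 12 without ties, otherwise normal approximation with tie and
continuity corrections). Presence/absence feature profiles (e.g.
prophage or CRISPR-spacer repertoires) are compared with binary Jaccard
distances — two all-empty profiles get distance 0 by default ("identical
emptiness"), configurable to NA — ordinated by classical PCoA
(double-centred Gram matrix, top-k non-negative eigenpairs; negative
eigenvalues are dropped with a warning), and two ordinations are compared
by Procrustes superimposition with a permutation test: both configurations
are scaled to unit trace, m² is the minimised residual sum of squares,
the correlation is √(1−m²), and p = (1 + #{permuted m² ≤ observed}) /
(n_perm + 1) permuting the rows of the second configuration. With the
conventional 999 permutations the smallest attainable p is exactly 0.001.
The ordination feeding Procrustes is not uniquely dictated by practice;
classical PCoA on Jaccard distances is the recorded choice here.

# Association cascade

Three occurrence filters run in order, each logged per feature:

1. species kept when present (abundance > 0) in ≥ 50% of samples;
2. SV (KO) columns of retained species kept when both genotype groups each
   hold ≥ 20% of the species' *present* samples — the denominator is
   present samples because genotype is undefined where the species is
   absent;
3. metabolites kept when observed in > 90% of samples.

Screening computes Spearman correlations (midranks; exact permutation p for
n ≤ 9 without ties, otherwise the t approximation) between species
abundance and each target over samples where the species is present, and
applies Benjamini-Hochberg adjustment within one target block (metabolites
and phenotype are separate families, as fecal/urine/serum panels would be);
pairs with q < 0.1 are significant. Samples where a species is absent are
excluded from its correlations rather than entered as zeros, matching
presence/absence genotype semantics; `include-as-zero` is deliberately not
the default because zero-inflation would manufacture rank correlations.

Significant pairs are dissected by SV genotype: present samples split into
SV0 (gene intact) and SV1 (gene disrupted), Spearman recomputed per
subgroup with raw (un-readjusted) p-values, and the verdict is *confounded*
when the screen passed (q < 0.1), SV0 stays significant (p < 0.05) and SV1
loses significance (p > 0.05). Subgroups below n = 3 yield NA results and a
`not_confounded` verdict with a reason. The post-hoc covariate control
(`partial_spearman`) midrank-transforms both variables, residualises on the
covariates (age/sex/BMI) with an intercept by least squares, and tests the
residual Pearson correlation with n − c − 2 degrees of freedom.

Two statistical facts shaped the tests of this cascade. First, with a
single true pair among ~60 screened pairs, the BH screen itself has only
~0.6 power at the planted effect (overall rho is diluted to ~0.35 by the
unaffected SV1 subgroup, and q = p·m/rank exacts a multiplicity price), so
dissection power is assessed conditional on screen passage — which is also
the dissection operation's precondition. Second, BH adjustment is not
idempotent: re-adjusting an already-adjusted monotone list can lift its
smallest entries (the minimised quantity q₍ⱼ₎·m/j is attained at j = m),
so the tested invariants are q ≥ p, monotonicity in sorted-p order, and
agreement with a hand step-up oracle.

# Enrichment of SV-affected genes

A gene is SV-affected when a retained call's breakpoint (either reference
coordinate) falls inside its gene body, [start, end) — gene-body only, no
promoter logic, because bacterial TSS annotation is not reliably available.
For each pathway a 2×2 table contrasts the foreground (SV-affected genes)
against the background *minus* the foreground (configurable to the full
background), split by pathway membership; two-sided Fisher exact p-values
(conditional hypergeometric, summing tables no more probable than the
observed one) are BH-adjusted across pathways. The sample odds ratio ad/bc
is reported (infinite when bc = 0); a zero margin yields p = 1 with a
warning. The background is gene-level by default; collapsing to unique KOs
is a caller-side choice of input.

# The synthetic-data module

The generator defines the study conditions the pipeline is tested under:

* **Genomes.** I.i.d. bases at a target GC (default 0.45, typical of gut
  Firmicutes), one or more linear contigs. Real MAGs have repeats, skew and
  gene structure that i.i.d. sequence lacks; what passing tests show is
  that the caller's logic is correct, not that unique-anchor alignment
  would suffice on repeat-rich real genomes (there, PAF input from a
  production aligner is the intended path).
* **SVs.** Planted insertions/deletions/inversions at a type mix of
  0.45/0.45/0.10 (insertions and deletions near-equal and dominant,
  inversions rare), with lengths from a three-part mixture: uniform peaks
  on 140-160 bp and 1050-1150 bp (weights 0.45 each) and a 10% log-uniform
  tail to 5 kb, floor 50 bp. The two peaks emulate the observed bimodal SV
  length distribution attributed to mobile-element activity; the mixture is
  a stand-in for an unknown generative mechanism, not a claim about it.
  Placement is rejection-sampled: interior (≥ 200 bp from contig ends),
  pairwise gaps ≥ 200 bp (2× the validation flank). Inserted sequence is
  random at the genome's GC and screened against sharing any 21-mer with
  its flanks, so placement is unambiguous for the anchor aligner.
* **Reads.** Lognormal lengths with mean 5683 bp (the ONT read-length scale
  this pipeline targets) and sd 3000 bp, truncated at contig ends (MAG
  contigs are linear), flat quality, optional substitution/indel noise up
  to 20% per base; error-free by default, since validation is specified on
  clean reads. Read count is depth × genome size / mean length, so total
  bases land within a few percent of the requested depth.
* **Individuals.** Each individual gets an independent planted SV set at
  8.35 SVs/Mb against the common reference, so two individuals differ at
  ~16.7 SVs/Mb (the between-individual density this analysis is calibrated
  to), while repeat samples of one individual share an identical genome —
  within-individual rate exactly 0, reflecting the short-horizon stability
  of gut bacterial genome structure.
* **Cohort.** 100 samples, 6 species (each present in a sample with
  probability 0.9), 10 metabolites with 5% missing-completely-at-random
  dropout (only a presence filter is specified, so MCAR is the simplest
  faithful choice), one SV (KO) column per species — mirroring the
  dissected one-KO-per-species cases this analysis is about — with SV1
  prevalence 0.4 among present samples, and 3 planted confounded triples
  with SV0 Spearman ≈ 0.7. Metabolite concentrations are exponentiated
  latents (Spearman is invariant to the monotone transform). The phenotype
  is a negative-weighted noisy function of the first two planted
  metabolites' latents, sized so bacteria-phenotype rank correlations land
  near −0.3 to −0.4, the magnitude of the glucose associations this
  emulates. One KO column per species is deliberate: additional null KO
  columns inside a truly-correlated species receive false "confounded"
  verdicts at a high rate (~0.3 per column), because the smaller SV1
  subgroup often lacks the power to retain its (real) correlation — a
  caveat that applies to the method itself, not only to the simulation.

All generators are pure functions of their seed; the caller's RNG state is
saved and restored.

# Problem sizes used in the checks

The shipped checks run the caller on a 1 Mb, 2-contig genome with 200
planted SVs (recall and precision ≥ 0.95 per type, with exact reciprocity
and length-conservation invariants); validation on a 500 kb genome, 100
SVs, depth 20 per genome (≥ 97% of retained calls supported); statistical
kernels against exhaustive or 10^5-resample oracles (Fisher over all 2×2
tables with total ≤ 30, Wilcoxon over all shapes with combined n ≤ 12);
the association cascade over 500 null cohorts (mean false-discovery
proportion at q < 0.1 stays ≤ 0.15) and 100 planted cohorts (conditional
dissection power ≥ 0.90); and Procrustes on rotated and permuted
30-sample configurations (floor p = 0.001; null rejection between 2% and
10% at α = 0.05). These sizes were chosen as the smallest at which the
binomial noise of each property is well inside its asserted band.

# Known limitations

* The anchor aligner assumes near-identical genomes with unique k-mers; it
  is not a general-purpose aligner and will fragment on repeat-rich or
  diverged sequences. PAF ingestion is the path for real data.
* The read mapper degrades under indel-type read noise (diagonal drift);
  supply external alignments for noisy reads.
* Substitution-like double gaps (simultaneous reference and query gaps of
  similar size) are not typed; only the dominant side is called, and only
  when the difference reaches `min_sv_len`.
* Terminal strand flips (a minus block at a contig end) are not typed as
  inversions.
* The cohort generator plants monotone dependencies only; non-monotone
  bacteria-metabolite relationships are outside what these tests exercise.
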