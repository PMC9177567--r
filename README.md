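# magsv

Structural-variant (SV) analysis for metagenome-assembled genomes (MAGs) of
the human gut microbiome, as an R package plus a numbered analysis workflow.

Long-read (ONT) hybrid assembly makes it possible to compare whole genomes
of the *same bacterial species* across people, where insertions, deletions
and inversions tens of bp to several kb long turn out to be highly distinct
between individuals and stable within one individual over time — a genomic
"fingerprint" — and to stratify bacteria–metabolite–phenotype associations
by whether a strain's gene is disrupted by an SV. `magsv` is for
bioinformaticians and statistical ecologists who want that analysis chain as
tested, reusable functions: it takes assemblies (FASTA/PAF), long reads
(FASTQ), gene models (GFF3 with `KO=` tags) and cohort matrices (TSV), and
ships a synthetic-data module that generates all of these with planted
truth, so every stage is verifiable end to end.

## What it computes

* **MAG quality and representative selection** — N50, the genome score
  `Score = Completeness − 5·Contamination + 0.5·log10(N50)` (0–100 scales),
  the QC rule completeness > 70% and contamination < 10%, and coding
  density.
* **SV calling** — from collinear alignment blocks (built-in unique-k-mer
  anchor aligner for desk-scale genomes, or PAF from a production aligner):
  deletions/insertions from reference/query gap differences ≥ 50 bp,
  inversions from strand-flipped blocks; calls with breakpoints within
  10 bp of a contig end are flagged, not dropped; counts normalised as
  SVs per Mb; the > 500 bp class reported separately.
* **Spanning-read validation** — a call is supported when ≥ 2 reads cover
  its breakpoints ± 100 bp on the allele-carrying genome.
* **Fingerprint statistics** — inter- vs intra-individual per-Mb SV rates
  with a two-sided Wilcoxon rank-sum test; binary Jaccard distances; PCoA;
  Procrustes superimposition with a permutation test (`protest`, 999
  permutations, so min p = 0.001).
* **SV-stratified associations** — occurrence filters (species ≥ 50% of
  samples; both SV genotype groups ≥ 20% of the species' present samples;
  metabolites observed in > 90%), Spearman screening with BH FDR < 0.1,
  then dissection of each significant pair by SV genotype: *confounded*
  when the SV-free subgroup (SV0) stays significant (p < 0.05) while the
  SV-carrying subgroup (SV1) loses significance (p > 0.05); plus partial
  Spearman controlling age/sex/BMI.
* **Enrichment** — Fisher's exact test per pathway of SV-affected genes
  (bodies containing SV breakpoints) against the background gene set, BH
  across pathways.

## Worked example

The `analysis/` scripts run the whole study on synthetic data and narrate
what they find (`Rscript analysis/01_simulate.R`, then `02`–`06`; outputs
land under `results/`). An abridged session:

```r
library(magsv)

ref <- simulate_reference_genome(5e5, n_contigs = 2, gc = 0.45, seed = 1)
pl  <- plant_svs(ref, n_svs = 100, seed = 2)       # truth recorded
calls <- call_svs(anchor_align(ref, pl$query))
compare_to_truth(calls, pl$truth)$recall
#> insertion  deletion inversion   overall
#>         1         1         1         1

co  <- simulate_cohort(seed = 21)                  # 3 planted triples
cas <- association_cascade(co)
subset(cas$dissection, verdict == "confounded",
       c(species, target, ko, rho_sv0, p_sv0, rho_sv1, p_sv1))
#>   species target     ko rho_sv0   p_sv0 rho_sv1 p_sv1
#>      sp02  met02 K00201    0.66 4.5e-06    0.05  0.74
#>      sp03  met03 K00301    0.74 9.8e-10    0.22  0.23
```

The dissection reads exactly like the biology it models: the
species–metabolite correlation is carried by the SV-free strains (SV0,
p ≪ 0.05) and abolished where the gene is disrupted (SV1, p > 0.05). On
this seed the screen recovers two of the three planted triples — the third
pays the Benjamini–Hochberg multiplicity price at the screen stage — and
the downstream scripts print 100% spanning-read support for the calls
(depth 20), an inter-individual median of ~13–17 SVs/Mb against an
intra-individual median of 0 (Wilcoxon p = 6e-05), and a Procrustes
coupling of two feature layers at the permutation floor p = 0.001.

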