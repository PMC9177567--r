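#!/usr/bin/env Rscript
# SV fingerprints: per-Mb SV rates between MAG pairs from different
# individuals versus repeat samples of the same individual, plus
# Jaccard/PCoA/Procrustes coupling of two presence/absence feature layers
# (prophage-like and CRISPR-spacer-like profiles of the same samples).

library(magsv)
dir.create("results", showWarnings = FALSE)

ref <- simulate_reference_genome(3e5, gc = 0.45, seed = 11)
ig <- simulate_individual_genomes(ref, n_individuals = 6,
                                  samples_per_individual = 2,
                                  sv_rate_per_mb = 8.35, seed = 12)
rates <- pairwise_sv_rates(ig$genomes, species = "speciesA")
cl <- classify_pairs(rates, setNames(ig$sample_info$individual,
                                     ig$sample_info$sample_id))
write.table(cl, "results/pairwise_rates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
inter <- cl$rate_per_mb[cl$comparison_class == "inter_individual"]
intra <- cl$rate_per_mb[cl$comparison_class == "intra_individual"]
w <- wilcoxon_rank_sum(inter, intra)
message(sprintf(paste0("SV rates per Mb: inter-individual median %.1f (n=%d), ",
                       "intra-individual median %.1f (n=%d), Wilcoxon p = %.2g"),
                median(inter), length(inter), median(intra), length(intra), w$p))

# two coupled binary feature layers over the same 30 samples
set.seed(13)
n <- 30; f <- 40
base_p <- matrix(runif(n * f) < rep(runif(n, 0.15, 0.6), f), n, f) * 1
layer2 <- base_p
flip <- matrix(runif(n * f) < 0.1, n, f)
layer2[flip] <- 1 - layer2[flip]
o1 <- suppressWarnings(pcoa(jaccard_distance_matrix(base_p), 2))
o2 <- suppressWarnings(pcoa(jaccard_distance_matrix(layer2), 2))
pt <- protest_test(o1, o2, n_perm = 999, seed = 14)
message(sprintf("Procrustes coupling of the two layers: correlation %.3f, p = %.3g (999 permutations)",
                pt$correlation, pt$p))
writeLines(jsonlite::toJSON(c(list(median_inter = median(inter),
                                   median_intra = median(intra),
                                   wilcoxon_p = w$p), pt),
                            auto_unbox = TRUE, digits = NA),
           "results/fingerprint.json")
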