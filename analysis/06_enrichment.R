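#!/usr/bin/env Rscript
# Pathway enrichment of SV-affected genes: genes whose bodies contain SV
# breakpoints (foreground) against all genes of the reference MAG
# (background), Fisher's exact test with BH across pathways.

library(magsv)
dir.create("results", showWarnings = FALSE)

ref <- read_genome_fasta("results/reference.fasta")
gm <- simulate_gene_models(ref, n_pathways = 5)
write_gff3_genes(gm$genes, "results/genes.gff3")

calls <- read.delim("results/sv_calls.tsv")
calls$ref_start <- calls$ref_start - 1L
aff <- sv_affected_genes(calls, gm$genes)
message("SV-affected genes: ", nrow(aff), " of ", nrow(gm$genes))

en <- enrichment(aff$gene_id, gm$genes$gene_id,
                 data.frame(gene = gm$genes$gene_id,
                            pathway = gm$pathway_map$pathway))
write.table(en, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("Top pathway: ", en$pathway[1], " (p = ", signif(en$p[1], 3),
        ", q = ", signif(en$q[1], 3), ")")
message("With randomly placed SVs no pathway is expected below q = 0.1; ",
        sum(en$q < 0.1), " pathway(s) reached it here")
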