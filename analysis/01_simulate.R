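#!/usr/bin/env Rscript
# Simulate the study inputs: a reference MAG, a same-species query MAG with
# planted SVs (bimodal lengths: ~140-160 bp and ~1050-1150 bp peaks), and
# ONT-like long reads (mean 5683 bp) from both genomes.

library(magsv)

dir.create("results", showWarnings = FALSE)

ref <- simulate_reference_genome(5e5, n_contigs = 2, gc = 0.45, seed = 1)
message("Reference MAG: ", length(ref), " contigs, ", genome_size(ref), " bp")

pl <- plant_svs(ref, n_svs = 100, seed = 2)
message("Planted ", nrow(pl$truth), " SVs: ",
        paste(names(table(pl$truth$sv_type)), table(pl$truth$sv_type),
              collapse = ", ", sep = "="))

write_genome_fasta(ref, "results/reference.fasta")
write_genome_fasta(pl$query, "results/query.fasta")
write.table(pl$truth[, setdiff(names(pl$truth), "inserted_seq")],
            "results/truth_svs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
saveRDS(pl, "results/planted.rds")   # local pipeline state for later steps

reads_ref <- simulate_long_reads(ref, depth = 20, seed = 3)
reads_query <- simulate_long_reads(pl$query, depth = 20, seed = 4)
message("Simulated ", length(reads_ref$sequences), " + ",
        length(reads_query$sequences), " reads, mean length ",
        round(mean(nchar(c(reads_ref$sequences, reads_query$sequences)))),
        " bp")
write_reads_fastq(reads_ref, "results/reads_reference.fastq")
write_reads_fastq(reads_query, "results/reads_query.fastq")
saveRDS(list(reference = reads_ref, query = reads_query),
        "results/reads.rds")

message("Done: inputs under results/")
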