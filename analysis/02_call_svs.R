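#!/usr/bin/env Rscript
# Call SVs between the representative (reference) and query MAGs from
# collinear anchor blocks, apply the contig-end filter, summarise types and
# lengths, and score the calls against the planted truth.

library(magsv)

pl <- readRDS("results/planted.rds")
ref <- read_genome_fasta("results/reference.fasta")
query <- read_genome_fasta("results/query.fasta")

blocks <- anchor_align(ref, query)
message("Alignment: ", nrow(blocks), " collinear blocks")

calls <- call_svs(blocks)
write_sv_table(calls, "results/sv_calls.tsv")
sm <- summarize_svs(calls)
message("Calls (retained): ",
        paste(names(sm$counts), sm$counts, collapse = ", ", sep = "="),
        "; filtered at contig ends: ", sum(calls$filtered))
message("Large (>500 bp) fractions: ",
        paste(names(sm$large_fraction), round(sm$large_fraction, 3),
              collapse = ", ", sep = "="))
message("SV rate: ", round(sv_rate_per_mb(calls, genome_size(query)), 2),
        " per Mb")

cmp <- compare_to_truth(calls, pl$truth)
message("Recall vs planted truth: ",
        paste(names(cmp$recall), round(cmp$recall, 3), collapse = ", ", sep = "="))
message("Precision: ",
        paste(names(cmp$precision), round(cmp$precision, 3), collapse = ", ", sep = "="))

res <- data.frame(metric = c(paste0("recall_", names(cmp$recall)),
                             paste0("precision_", names(cmp$precision))),
                  value = c(cmp$recall, cmp$precision))
write.table(res, "results/sv_truth_metrics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
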