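# File I/O: FASTA/FASTQ via Biostrings; GFF3 and TSV exports.
# Exported tables use 1-based inclusive coordinates; everything internal is
# 0-based half-open.

#' Write a genome assembly to FASTA
#' @param genome a `genome_assembly`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read a genome assembly from FASTA
#' @param path FASTA file.
#' @return a `genome_assembly`.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(dss)
  names(seqs) <- sub("\\s.*$", "", names(dss))
  genome_assembly(seqs)
}

#' Write a read set to FASTQ (flat quality)
#' @param reads a `read_set`.
#' @param path output file.
#' @param quality flat per-base quality character (default "I", Q40).
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path, quality = "I") {
  seqs <- reads$sequences
  # plain four-line records; long-read records exceed the line-buffer limits
  # of some binary FASTQ writers
  recs <- as.vector(rbind(paste0("@", names(seqs)),
                          unname(seqs),
                          "+",
                          vapply(nchar(seqs), function(n) strrep(quality, n),
                                 character(1))))
  writeLines(recs, path)
  invisible(path)
}

#' Write synthetic gene models as GFF3
#'
#' CDS features with `ID` and `KO` attributes; coordinates converted to the
#' 1-based inclusive GFF3 convention.
#'
#' @param genes data.frame(contig, start, end, strand, gene_id, ko) from
#'   [simulate_gene_models()] (0-based half-open).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tmagsv\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;KO=%s",
                     genes$contig, genes$start + 1L, genes$end, genes$strand,
                     genes$gene_id, genes$ko))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models with KO tags from GFF3
#'
#' Reads CDS/gene features and extracts `ID` and `KO` attributes, returning
#' 0-based half-open intervals.
#'
#' @param path GFF3 file.
#' @return data.frame(contig, start, end, strand, gene_id, ko).
#' @export
read_gff3_genes <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  f <- f[vapply(f, length, 0L) >= 9L]
  if (!length(f)) stop("no feature line in ", path)
  get_attr <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attr))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  attrs <- vapply(f, `[[`, "", 9L)
  data.frame(contig = vapply(f, `[[`, "", 1L),
             start = as.integer(vapply(f, `[[`, "", 4L)) - 1L,
             end = as.integer(vapply(f, `[[`, "", 5L)),
             strand = vapply(f, `[[`, "", 7L),
             gene_id = get_attr(attrs, "ID"),
             ko = get_attr(attrs, "KO"),
             stringsAsFactors = FALSE)
}

#' Export an SV call table as TSV (1-based inclusive coordinates)
#'
#' @param calls call table from [call_svs()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_sv_table <- function(calls, path) {
  out <- calls
  # 1-based inclusive: start+1; zero-width intervals keep start = end+1 form
  out$ref_start <- out$ref_start + 1L
  out$query_start <- out$query_start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise SV rates across sample genomes of one species
#'
#' Calls SVs for every unordered pair of sample genomes (first of the pair as
#' reference) and reports the retained-call rate per Mb, normalised by the
#' query genome size.
#'
#' @param genomes named list of `genome_assembly` objects (one per sample).
#' @param species species label carried into the output.
#' @param ... passed to [call_svs()].
#' @return data.frame(species, sample_a, sample_b, rate_per_mb).
#' @export
pairwise_sv_rates <- function(genomes, species = "species", ...) {
  ids <- names(genomes)
  stopifnot(length(ids) >= 2L)
  out <- NULL
  for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
    blocks <- anchor_align(genomes[[i]], genomes[[j]])
    calls <- call_svs(blocks, ...)
    out <- rbind(out, data.frame(
      species = species, sample_a = ids[i], sample_b = ids[j],
      rate_per_mb = sv_rate_per_mb(calls, genome_size(genomes[[j]])),
      stringsAsFactors = FALSE))
  }
  out
}
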