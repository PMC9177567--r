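#' Spanning-read support for one SV call
#'
#' A read supports an SV when its aligned interval on the allele-carrying
#' genome covers the SV breakpoints plus `flank` bp on each side: the
#' reference interval for a deletion (the deleted sequence lives on the
#' reference), the query interval for an insertion, and either genome for an
#' inversion (each genome carries its own orientation; the larger of the two
#' counts is thresholded).
#'
#' @param sv one row of a [call_svs()] table.
#' @param read_alignments data.frame(genome, contig, start, end) of read
#'   mapping intervals, `genome` in {"reference", "query"} (0-based,
#'   half-open), e.g. from [map_reads()] on each genome.
#' @param flank required flanking coverage in bp (> 0, default 100).
#' @param min_support reads required to call the SV supported (default 2,
#'   i.e. "multiple" reads).
#' @return data.frame(sv_id, supporting_reads_ref, supporting_reads_query,
#'   supported).
#' @export
spanning_support <- function(sv, read_alignments, flank = 100L,
                             min_support = 2L) {
  if (flank <= 0) stop("flank must be > 0")
  count_span <- function(genome, contig, lo, hi) {
    a <- read_alignments[read_alignments$genome == genome &
                           read_alignments$contig == contig, , drop = FALSE]
    sum(a$start <= lo & a$end >= hi)
  }
  n_ref <- count_span("reference", sv$ref_contig,
                      sv$ref_start - flank, sv$ref_end + flank)
  n_query <- count_span("query", sv$query_contig,
                        sv$query_start - flank, sv$query_end + flank)
  carrier <- switch(sv$sv_type,
                    deletion = n_ref,
                    insertion = n_query,
                    inversion = max(n_ref, n_query))
  data.frame(sv_id = sv$sv_id, supporting_reads_ref = n_ref,
             supporting_reads_query = n_query,
             supported = carrier >= min_support, stringsAsFactors = FALSE)
}

#' Validate SV calls with spanning long reads
#'
#' Maps reads to the reference and query genomes (internal anchor mapper) and
#' computes spanning support for every retained (unfiltered) call.
#'
#' @param calls call table from [call_svs()].
#' @param reads a `read_set`, or list(reference = read_set, query = read_set)
#'   when separate read sets were generated per genome; a single read set is
#'   mapped against both genomes.
#' @param reference,query the two `genome_assembly` objects.
#' @param flank,min_support see [spanning_support()].
#' @param alignments optional precomputed data.frame(genome, contig, start,
#'   end); when given, `reads`/genomes are not touched.
#' @return list(table = per-call validation table,
#'   supported_fraction = share of retained calls supported, NA when there
#'   are no retained calls).
#' @export
validate_svs <- function(calls, reads = NULL, reference = NULL, query = NULL,
                         flank = 100L, min_support = 2L, alignments = NULL) {
  if (is.null(alignments)) {
    if (is.list(reads) && !inherits(reads, "read_set")) {
      aln_r <- map_reads(reads$reference, reference)
      aln_q <- map_reads(reads$query, query)
    } else {
      aln_r <- map_reads(reads, reference)
      aln_q <- map_reads(reads, query)
    }
    alignments <- rbind(
      if (nrow(aln_r)) cbind(genome = "reference", aln_r[, c("contig", "start", "end")]),
      if (nrow(aln_q)) cbind(genome = "query", aln_q[, c("contig", "start", "end")]))
    if (is.null(alignments) || !nrow(alignments)) {
      warning("no mappable reads; all calls unsupported")
      alignments <- data.frame(genome = character(0), contig = character(0),
                               start = integer(0), end = integer(0))
    }
  }
  kept <- calls[!calls$filtered, , drop = FALSE]
  if (!nrow(kept))
    return(list(table = data.frame(), supported_fraction = NA_real_))
  tab <- do.call(rbind, lapply(seq_len(nrow(kept)), function(i)
    spanning_support(kept[i, ], alignments, flank, min_support)))
  list(table = tab, supported_fraction = mean(tab$supported))
}
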