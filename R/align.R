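# Anchor-based whole-genome alignment and read mapping.
#
# Exact k-mer matches that are unique in each sequence (MUM-like anchors)
# are chained by diagonal into maximal collinear blocks. This is a desk-scale
# substrate for same-species MAG comparison; for real-scale data precomputed
# PAF alignments can be ingested instead (see read_paf_blocks).

# anchors between one reference contig and one query contig:
# data.frame(i = ref 0-based k-mer start, j = query 0-based start, strand)
.contig_anchors <- function(refseq, queryseq, k) {
  rc <- encode_kmers(refseq, k)
  ri <- .unique_code_idx(rc)
  if (!length(ri)) return(NULL)
  qf <- encode_kmers(queryseq, k)
  qr <- encode_kmers(revcomp(queryseq), k)
  qi_f <- .unique_code_idx(qf)
  qi_r <- .unique_code_idx(qr)
  # drop query k-mers present on both strands (ambiguous orientation)
  both <- intersect(qf[qi_f], qr[qi_r])
  if (length(both)) {
    qi_f <- qi_f[!(qf[qi_f] %in% both)]
    qi_r <- qi_r[!(qr[qi_r] %in% both)]
  }
  Lq <- nchar(queryseq)
  out <- NULL
  mf <- match(rc[ri], qf[qi_f])
  hit <- which(!is.na(mf))
  if (length(hit))
    out <- data.frame(i = ri[hit] - 1L, j = qi_f[mf[hit]] - 1L, strand = "+",
                      stringsAsFactors = FALSE)
  mr <- match(rc[ri], qr[qi_r])
  hit <- which(!is.na(mr))
  if (length(hit)) {
    p <- qi_r[mr[hit]] - 1L                 # position on reverse-complement
    out <- rbind(out, data.frame(i = ri[hit] - 1L, j = Lq - k - p,
                                 strand = "-", stringsAsFactors = FALSE))
  }
  out
}

# chain anchors on identical diagonals into blocks
.chain_anchors <- function(anc, k, max_gap) {
  d <- ifelse(anc$strand == "+", anc$i - anc$j, anc$i + anc$j)
  o <- order(anc$strand, d, anc$i)
  anc <- anc[o, , drop = FALSE]; d <- d[o]
  newgrp <- c(TRUE, anc$strand[-1L] != anc$strand[-nrow(anc)] |
                d[-1L] != d[-nrow(anc)] |
                diff(anc$i) > max_gap)
  g <- cumsum(newgrp)
  blocks <- do.call(rbind, lapply(split(seq_len(nrow(anc)), g), function(idx) {
    a <- anc[idx, , drop = FALSE]
    data.frame(ref_start = min(a$i), ref_end = max(a$i) + k,
               query_start = min(a$j), query_end = max(a$j) + k,
               strand = a$strand[1L], n_matches = nrow(a),
               stringsAsFactors = FALSE)
  }))
  rownames(blocks) <- NULL
  blocks
}

#' Align two genomes into collinear blocks
#'
#' Unique exact k-mer anchors on both strands are chained into maximal
#' collinear blocks (identical diagonal, anchor gaps below `max_gap`).
#' Blocks spanning less than `min_chain_bp` on the reference are dropped.
#' For identical genomes this returns one full-length block per contig.
#'
#' `max_gap` must stay below the SV caller's `min_sv_len`: an inversion does
#' not shift the alignment diagonal, so a larger gap tolerance would chain
#' straight across short inversions. The default (40) tolerates anchor
#' droughts from repeated k-mers while breaking at any callable SV.
#' Consequently inversions shorter than `min_chain_bp` are not recoverable
#' as strand-flipped blocks.
#'
#' @param reference,query `genome_assembly` objects.
#' @param k anchor k-mer size (>= 15, <= 26; default 21).
#' @param min_chain_bp minimum block span on the reference (default 50, the SV length floor, so the shortest callable inversion keeps its block).
#' @param max_gap maximum anchor gap inside one block (default 40).
#' @return data.frame of blocks (ref_contig, ref_start, ref_end, query_contig,
#'   query_start, query_end, strand, n_matches; 0-based half-open), sorted by
#'   ref_contig then ref_start, with contig lengths attached as attributes
#'   `ref_lengths` and `query_lengths`.
#' @export
anchor_align <- function(reference, query, k = 21L, min_chain_bp = 50L,
                         max_gap = 40L) {
  stopifnot(inherits(reference, "genome_assembly"),
            inherits(query, "genome_assembly"))
  if (k < 15L || k > 26L) stop("k must lie in [15, 26]")
  if (!genome_size(reference) || !genome_size(query)) stop("empty genome")
  blocks <- NULL
  for (rn in names(reference)) for (qn in names(query)) {
    anc <- .contig_anchors(unclass(reference)[[rn]], unclass(query)[[qn]], k)
    if (is.null(anc) || !nrow(anc)) next
    b <- .chain_anchors(anc, k, max_gap)
    b <- b[b$ref_end - b$ref_start >= min_chain_bp, , drop = FALSE]
    if (!nrow(b)) next
    b$ref_contig <- rn; b$query_contig <- qn
    blocks <- rbind(blocks, b)
  }
  if (is.null(blocks))
    blocks <- data.frame(ref_contig = character(0), ref_start = integer(0),
                         ref_end = integer(0), query_contig = character(0),
                         query_start = integer(0), query_end = integer(0),
                         strand = character(0), n_matches = integer(0))
  blocks <- blocks[order(blocks$ref_contig, blocks$ref_start),
                   c("ref_contig", "ref_start", "ref_end", "query_contig",
                     "query_start", "query_end", "strand", "n_matches")]
  rownames(blocks) <- NULL
  attr(blocks, "ref_lengths") <- nchar(unclass(reference))
  attr(blocks, "query_lengths") <- nchar(unclass(query))
  blocks
}

#' Read alignment blocks from a PAF file
#'
#' Maps PAF columns 1-12 onto the block table consumed by [call_svs()]
#' (query/target naming follows PAF; the PAF *target* becomes the reference).
#'
#' @param path PAF file path.
#' @return block data.frame as from [anchor_align()], with contig lengths
#'   attached.
#' @export
read_paf_blocks <- function(path) {
  paf <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           fill = TRUE, header = FALSE)[, 1:12]
  names(paf) <- c("qname", "qlen", "qstart", "qend", "strand",
                  "tname", "tlen", "tstart", "tend", "nmatch", "alen", "mapq")
  blocks <- data.frame(ref_contig = paf$tname, ref_start = paf$tstart,
                       ref_end = paf$tend, query_contig = paf$qname,
                       query_start = paf$qstart, query_end = paf$qend,
                       strand = paf$strand, n_matches = paf$nmatch,
                       stringsAsFactors = FALSE)
  blocks <- blocks[order(blocks$ref_contig, blocks$ref_start), ]
  rownames(blocks) <- NULL
  attr(blocks, "ref_lengths") <-
    stats::setNames(paf$tlen, paf$tname)[!duplicated(paf$tname)]
  attr(blocks, "query_lengths") <-
    stats::setNames(paf$qlen, paf$qname)[!duplicated(paf$qname)]
  blocks
}

#' Map long reads to a genome by k-mer anchor voting
#'
#' Each read's sampled k-mers are looked up in an index of the genome's
#' unique k-mers; the (contig, diagonal, strand) with most votes determines
#' the mapped interval. Reads with fewer than `min_votes` agreeing anchors
#' are unmapped.
#'
#' @param reads a `read_set` (or named character vector of sequences).
#' @param genome a `genome_assembly`.
#' @param k k-mer size (default 17).
#' @param stride sample a k-mer every `stride` bases of the read (default 50).
#' @param min_votes minimum agreeing anchors (default 3).
#' @return data.frame(read_id, contig, start, end, strand, votes) with
#'   0-based half-open mapped intervals; unmapped reads are omitted.
#' @export
map_reads <- function(reads, genome, k = 17L, stride = 50L, min_votes = 3L) {
  seqs <- if (inherits(reads, "read_set")) reads$sequences else reads
  stopifnot(inherits(genome, "genome_assembly"), length(seqs) >= 1L)

  # genome index over unique k-mers
  idx_code <- numeric(0); idx_pos <- integer(0); idx_contig <- integer(0)
  for (ci in seq_along(genome)) {
    codes <- encode_kmers(unclass(genome)[[ci]], k)
    u <- .unique_code_idx(codes)
    idx_code <- c(idx_code, codes[u])
    idx_pos <- c(idx_pos, u - 1L)
    idx_contig <- c(idx_contig, rep(ci, length(u)))
  }
  o <- order(idx_code)
  idx_code <- idx_code[o]; idx_pos <- idx_pos[o]; idx_contig <- idx_contig[o]

  # read k-mers, both strands, all reads at once
  rk <- lapply(seq_along(seqs), function(ri) {
    s <- seqs[[ri]]
    n <- nchar(s)
    if (n < k) return(NULL)
    at <- seq(0L, n - k, by = stride)
    cf <- encode_kmers(s, k)[at + 1L]
    cr <- encode_kmers(revcomp(s), k)[at + 1L]
    # rpos is the k-mer offset within the oriented (strand-matched) read, so
    # genome_pos - rpos is one consistent diagonal for a co-linear read
    rbind(data.frame(ri = ri, rpos = at, code = cf, strand = "+",
                     stringsAsFactors = FALSE),
          data.frame(ri = ri, rpos = at, code = cr, strand = "-",
                     stringsAsFactors = FALSE))
  })
  rk <- data.table::rbindlist(rk)
  rk <- rk[!is.na(rk$code), ]
  if (!nrow(rk)) return(.empty_mapping())
  hit <- findInterval(rk$code, idx_code)
  ok <- hit >= 1L & idx_code[pmax(hit, 1L)] == rk$code
  rk <- rk[ok, ]; hit <- hit[ok]
  if (!nrow(rk)) return(.empty_mapping())
  rk$contig <- idx_contig[hit]
  rk$diag <- idx_pos[hit] - rk$rpos

  dt <- data.table::as.data.table(rk)
  votes <- dt[, .N, by = c("ri", "strand", "contig", "diag")]
  best <- votes[order(-votes$N), ]
  best <- best[!duplicated(best$ri), ]
  best <- best[best$N >= min_votes, ]
  if (!nrow(best)) return(.empty_mapping())

  rl <- nchar(seqs)[best$ri]
  clen <- nchar(unclass(genome))[best$contig]
  start <- pmax(0L, best$diag)
  end <- pmin(clen, best$diag + rl)
  data.frame(read_id = names(seqs)[best$ri],
             contig = names(genome)[best$contig],
             start = as.integer(start), end = as.integer(end),
             strand = best$strand, votes = best$N,
             stringsAsFactors = FALSE)
}

.empty_mapping <- function() {
  data.frame(read_id = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             votes = integer(0), stringsAsFactors = FALSE)
}
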