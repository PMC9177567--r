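#' Call structural variants from collinear alignment blocks
#'
#' Between consecutive same-strand (+) blocks sharing reference and query
#' contigs, a reference gap exceeding the query gap by at least `min_sv_len`
#' is a deletion of (ref_gap - query_gap) bp; the converse is an insertion.
#' A minus-strand block flanked by plus-strand blocks on both sides is an
#' inversion of that block's length (terminal strand flips are not typed).
#' Calls with a breakpoint within `end_margin` bp of any contig terminus of
#' either genome are emitted with `filtered = TRUE`, reason `"contig_end"`,
#' rather than dropped, so the filter is auditable.
#'
#' @param blocks block table from [anchor_align()] or [read_paf_blocks()],
#'   sorted by ref_contig, ref_start, non-overlapping per genome.
#' @param min_sv_len minimum SV length to call (default 50 bp).
#' @param end_margin contig-end exclusion margin (default 10 bp).
#' @param large_threshold length above which a call is "large"
#'   (default 500 bp).
#' @param ref_lengths,query_lengths named contig-length vectors; taken from
#'   the block table's attributes when omitted.
#' @param overlap_tol consecutive blocks overlapping by at most this many bp
#'   (breakpoint ambiguity from chance junction matches) are trimmed
#'   left-aligned; larger overlaps are a contract error (default 25).
#' @return data.frame of calls: sv_id, sv_type, ref_contig, ref_start,
#'   ref_end, query_contig, query_start, query_end, length_bp, is_large,
#'   filtered, reason (0-based, half-open coordinates).
#' @export
call_svs <- function(blocks, min_sv_len = 50L, end_margin = 10L,
                     large_threshold = 500L,
                     ref_lengths = attr(blocks, "ref_lengths"),
                     query_lengths = attr(blocks, "query_lengths"),
                     overlap_tol = 25L) {
  if (is.null(ref_lengths) || is.null(query_lengths))
    stop("contig lengths are required (attach or pass ref_lengths/query_lengths)")
  calls <- NULL
  add_call <- function(type, rc, rs, re, qc, qs, qe, len) {
    calls <<- rbind(calls, data.frame(
      sv_type = type, ref_contig = rc, ref_start = rs, ref_end = re,
      query_contig = qc, query_start = qs, query_end = qe,
      length_bp = len, stringsAsFactors = FALSE))
  }

  for (key in unique(paste(blocks$ref_contig, blocks$query_contig))) {
    b <- blocks[paste(blocks$ref_contig, blocks$query_contig) == key, ,
                drop = FALSE]
    b <- b[order(b$ref_start), , drop = FALSE]
    if (nrow(b) > 1L) {
      # trim small breakpoint-ambiguity overlaps (left-aligned); a block pair
      # is trimmed on both genomes at once to keep its diagonal intact
      for (i in 2:nrow(b)) {
        o_ref <- b$ref_end[i - 1L] - b$ref_start[i]
        o_query <- if (b$strand[i - 1L] == "+" && b$strand[i] == "+")
          b$query_end[i - 1L] - b$query_start[i] else 0L
        o <- max(o_ref, o_query, 0L)
        if (o == 0L) next
        if (o > overlap_tol) stop("blocks overlap by ", o,
                                  " bp (> overlap_tol); malformed input")
        b$ref_end[i - 1L] <- b$ref_end[i - 1L] - o
        if (b$strand[i - 1L] == "+")
          b$query_end[i - 1L] <- b$query_end[i - 1L] - o
        else
          b$query_start[i - 1L] <- b$query_start[i - 1L] + o
      }
      if (any(diff(b$ref_start) < 0)) stop("blocks must be sorted by ref_start")
      if (any(b$ref_start[-1L] < b$ref_end[-nrow(b)]))
        stop("blocks overlap on the reference")
    }
    # inversions: '-' blocks with '+' neighbours on both sides
    if (nrow(b) >= 3L) {
      for (m in which(b$strand == "-")) {
        if (m == 1L || m == nrow(b)) next
        if (b$strand[m - 1L] == "+" && b$strand[m + 1L] == "+") {
          len <- b$ref_end[m] - b$ref_start[m]
          if (len >= max(min_sv_len, 50L))
            add_call("inversion", b$ref_contig[m], b$ref_start[m], b$ref_end[m],
                     b$query_contig[m], b$query_start[m], b$query_end[m], len)
        }
      }
    }
    # indels between consecutive '+' blocks (ignoring interleaved '-' blocks)
    plus <- which(b$strand == "+")
    if (length(plus) > 1L) {
      for (t in seq_len(length(plus) - 1L)) {
        p <- plus[t]; q <- plus[t + 1L]
        if (q - p > 1L && any(b$strand[(p + 1L):(q - 1L)] == "-")) next
        ref_gap <- b$ref_start[q] - b$ref_end[p]
        query_gap <- b$query_start[q] - b$query_end[p]
        if (query_gap < 0) next   # rearrangement; not a pure indel
        diffgap <- ref_gap - query_gap
        if (diffgap >= min_sv_len) {
          add_call("deletion", b$ref_contig[p], b$ref_end[p],
                   b$ref_end[p] + diffgap, b$query_contig[p],
                   b$query_end[p], b$query_end[p], diffgap)
        } else if (-diffgap >= min_sv_len) {
          add_call("insertion", b$ref_contig[p], b$ref_end[p], b$ref_end[p],
                   b$query_contig[p], b$query_end[p],
                   b$query_end[p] - diffgap, -diffgap)
        }
      }
    }
  }

  if (is.null(calls))
    calls <- data.frame(sv_type = character(0), ref_contig = character(0),
                        ref_start = integer(0), ref_end = integer(0),
                        query_contig = character(0), query_start = integer(0),
                        query_end = integer(0), length_bp = integer(0),
                        stringsAsFactors = FALSE)
  calls <- calls[order(calls$ref_contig, calls$ref_start), , drop = FALSE]
  calls$sv_id <- sprintf("sv%04d", seq_len(nrow(calls)))
  calls$is_large <- calls$length_bp > large_threshold

  near_end <- function(pos, len) pos < end_margin | (len - pos) < end_margin
  rl <- ref_lengths[calls$ref_contig]
  ql <- query_lengths[calls$query_contig]
  calls$filtered <- near_end(calls$ref_start, rl) | near_end(calls$ref_end, rl) |
    near_end(calls$query_start, ql) | near_end(calls$query_end, ql)
  calls$reason <- ifelse(calls$filtered, "contig_end", NA_character_)
  rownames(calls) <- NULL
  calls[, c("sv_id", "sv_type", "ref_contig", "ref_start", "ref_end",
            "query_contig", "query_start", "query_end", "length_bp",
            "is_large", "filtered", "reason")]
}

#' SV rate per megabase
#'
#' @param calls SV call table; only retained (unfiltered) calls are counted.
#' @param genome_size genome size in bp (> 0).
#' @return retained calls x 1e6 / genome_size.
#' @export
sv_rate_per_mb <- function(calls, genome_size) {
  if (genome_size <= 0) stop("genome_size must be > 0")
  sum(!calls$filtered) * 1e6 / genome_size
}

#' Summarise SV calls
#'
#' @param calls SV call table from [call_svs()].
#' @param large_threshold length threshold for the large class (default 500).
#' @return list with `counts` (per-type retained counts), `large_counts`,
#'   `large_fraction` and `lengths` (named list of retained lengths per type).
#' @export
summarize_svs <- function(calls, large_threshold = 500L) {
  types <- c("insertion", "deletion", "inversion")
  kept <- calls[!calls$filtered, , drop = FALSE]
  counts <- vapply(types, function(t) sum(kept$sv_type == t), 0L)
  large <- vapply(types, function(t)
    sum(kept$sv_type == t & kept$length_bp > large_threshold), 0L)
  list(counts = counts, large_counts = large,
       large_fraction = ifelse(counts > 0, large / counts, NA_real_),
       lengths = lapply(stats::setNames(types, types),
                        function(t) kept$length_bp[kept$sv_type == t]))
}

#' Match SV calls against a planted truth set
#'
#' A call matches a truth record when the types agree, the reference start
#' lies within `tol_bp`, and the lengths differ by at most
#' max(`tol_bp`, 5% of the truth length). Matching is greedy one-to-one.
#' Only retained (unfiltered) calls are considered.
#'
#' @param calls call table from [call_svs()].
#' @param truth truth table from [plant_svs()].
#' @param tol_bp breakpoint/length tolerance in bp (default 25).
#' @return list with per-type and overall `recall` and `precision`, and the
#'   matched pair table.
#' @export
compare_to_truth <- function(calls, truth, tol_bp = 25L) {
  kept <- calls[!calls$filtered, , drop = FALSE]
  matched_call <- rep(FALSE, nrow(kept))
  matched_truth <- rep(FALSE, nrow(truth))
  pairs <- NULL
  for (i in seq_len(nrow(truth))) {
    cand <- which(!matched_call &
                    kept$sv_type == truth$sv_type[i] &
                    kept$ref_contig == truth$ref_contig[i] &
                    abs(kept$ref_start - truth$ref_start[i]) <= tol_bp &
                    abs(kept$length_bp - truth$length_bp[i]) <=
                      pmax(tol_bp, 0.05 * truth$length_bp[i]))
    if (length(cand)) {
      j <- cand[which.min(abs(kept$ref_start[cand] - truth$ref_start[i]))]
      matched_call[j] <- TRUE; matched_truth[i] <- TRUE
      pairs <- rbind(pairs, data.frame(truth_id = truth$sv_id[i],
                                       call_id = kept$sv_id[j],
                                       stringsAsFactors = FALSE))
    }
  }
  types <- c("insertion", "deletion", "inversion")
  per_type <- function(v, type_vec, ok) {
    n <- sum(type_vec == v)
    if (n == 0) NA_real_ else sum(ok[type_vec == v]) / n
  }
  list(recall = c(vapply(types, per_type, 0, truth$sv_type, matched_truth),
                  overall = if (nrow(truth)) mean(matched_truth) else NA_real_),
       precision = c(vapply(types, per_type, 0, kept$sv_type, matched_call),
                     overall = if (nrow(kept)) mean(matched_call) else NA_real_),
       pairs = pairs)
}
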