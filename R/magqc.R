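#' Contig N50
#'
#' The largest length L such that contigs of length >= L together contain at
#' least half of the total assembly length.
#'
#' @param lengths positive integer contig lengths.
#' @return N50 in bp.
#' @export
contig_n50 <- function(lengths) {
  if (!length(lengths) || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("lengths must be a non-empty vector of positive numbers")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' MAG quality score
#'
#' Score = completeness - 5 x contamination + 0.5 x log10(N50), with
#' completeness and contamination on the 0-100 percentage scale. The log
#' base (10) follows the dRep scoring convention; it only rescales the N50
#' term.
#'
#' @param completeness percentage in [0, 100].
#' @param contamination percentage in [0, 100].
#' @param n50 contig N50 in bp (>= 1).
#' @return numeric score (vectorised).
#' @export
mag_score <- function(completeness, contamination, n50) {
  if (any(n50 < 1)) stop("n50 must be >= 1")
  if (any(completeness < 0 | completeness > 100) ||
      any(contamination < 0 | contamination > 100))
    stop("completeness and contamination must lie in [0, 100]")
  completeness - 5 * contamination + 0.5 * log10(n50)
}

#' Build a table of MAG records
#'
#' @param mag_id character ids.
#' @param completeness,contamination percentages in [0, 100].
#' @param contig_lengths list of positive integer vectors, one per MAG.
#' @return data.frame with derived n50 and score columns.
#' @export
mag_records <- function(mag_id, completeness, contamination, contig_lengths) {
  stopifnot(length(mag_id) == length(completeness),
            length(mag_id) == length(contamination),
            length(mag_id) == length(contig_lengths))
  n50 <- vapply(contig_lengths, contig_n50, 0)
  data.frame(mag_id = mag_id, completeness = completeness,
             contamination = contamination, n50 = n50,
             score = mag_score(completeness, contamination, n50),
             stringsAsFactors = FALSE)
}

#' Select the representative MAG
#'
#' Highest score wins; ties broken by higher completeness, then lower
#' contamination, then lexicographically smaller id.
#'
#' @param mags data.frame with columns mag_id, completeness, contamination,
#'   score (e.g. from [mag_records()]).
#' @return the representative mag_id.
#' @export
select_representative <- function(mags) {
  if (!nrow(mags)) stop("empty MAG list")
  o <- order(-mags$score, -mags$completeness, mags$contamination, mags$mag_id)
  mags$mag_id[o[1L]]
}

#' Quality-filter MAGs
#'
#' Keeps MAGs with completeness strictly above 70% and contamination strictly
#' below 10%.
#'
#' @param mags data.frame with completeness and contamination columns.
#' @param min_completeness,max_contamination thresholds (defaults 70, 10).
#' @return the retained subset (same columns).
#' @export
qc_filter <- function(mags, min_completeness = 70, max_contamination = 10) {
  mags[mags$completeness > min_completeness &
         mags$contamination < max_contamination, , drop = FALSE]
}

#' Coding density of a genome
#'
#' Summed ORF length divided by genome length. By default overlapping ORFs
#' are summed literally; `merge_overlaps = TRUE` unions them first.
#'
#' @param orf_intervals data.frame with columns contig, start, end
#'   (0-based, half-open).
#' @param genome_length total genome length in bp (> 0).
#' @param merge_overlaps union overlapping intervals per contig before
#'   summing.
#' @return coding density fraction.
#' @export
coding_density <- function(orf_intervals, genome_length,
                           merge_overlaps = FALSE) {
  if (genome_length <= 0) stop("genome_length must be > 0")
  if (!nrow(orf_intervals)) return(0)
  stopifnot(all(orf_intervals$end > orf_intervals$start))
  if (!merge_overlaps)
    return(sum(orf_intervals$end - orf_intervals$start) / genome_length)
  tot <- 0
  for (cn in unique(orf_intervals$contig)) {
    iv <- orf_intervals[orf_intervals$contig == cn, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    cur_s <- iv$start[1L]; cur_e <- iv$end[1L]
    for (i in seq_len(nrow(iv))[-1L]) {
      if (iv$start[i] <= cur_e) cur_e <- max(cur_e, iv$end[i])
      else { tot <- tot + cur_e - cur_s; cur_s <- iv$start[i]; cur_e <- iv$end[i] }
    }
    tot <- tot + cur_e - cur_s
  }
  tot / genome_length
}
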