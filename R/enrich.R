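#' Fisher's exact test on a 2x2 table
#'
#' Two-sided conditional hypergeometric p (sum of tables with probability at
#' most the observed one); sample odds ratio ad/bc (infinite when bc = 0).
#' A zero margin yields p = 1 by convention, with a warning.
#'
#' @param a,b,c,d non-negative integer cell counts, rows = groups,
#'   columns = in/out of category.
#' @return list(odds_ratio, p).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  if (min(a + b, c + d, a + c, b + d) == 0) {
    warning("zero margin; p = 1 by convention")
    return(list(odds_ratio = or, p = 1))
  }
  ft <- stats::fisher.test(matrix(c(a, c, b, d), 2L), alternative = "two.sided")
  list(odds_ratio = or, p = ft$p.value)
}

#' Genes affected by SV breakpoints
#'
#' A gene is SV-affected when any breakpoint (ref_start or ref_end) of a
#' retained call lies inside its gene-body interval [start, end) on the
#' reference (0-based, half-open; gene-body only, no promoter logic).
#'
#' @param calls call table from [call_svs()]; filtered calls are ignored.
#' @param gene_models data.frame(contig, start, end, gene_id, ko), 0-based
#'   half-open on reference coordinates (e.g. from [simulate_gene_models()]
#'   or [read_gff3_genes()]).
#' @return data.frame(gene_id, ko) of affected genes (unique).
#' @export
sv_affected_genes <- function(calls, gene_models) {
  req <- c("contig", "start", "end", "gene_id", "ko")
  if (!all(req %in% names(gene_models)))
    stop("gene_models must have columns ", paste(req, collapse = ", "))
  kept <- calls[!calls$filtered, , drop = FALSE]
  bp <- unique(data.frame(contig = rep(kept$ref_contig, 2L),
                          pos = c(kept$ref_start, kept$ref_end)))
  hit <- logical(nrow(gene_models))
  for (i in seq_len(nrow(bp))) {
    hit <- hit | (gene_models$contig == bp$contig[i] &
                    gene_models$start <= bp$pos[i] &
                    bp$pos[i] < gene_models$end)
  }
  unique(gene_models[hit, c("gene_id", "ko"), drop = FALSE])
}

#' Pathway enrichment of SV-affected genes (Fisher's exact test)
#'
#' For each pathway, a 2x2 table contrasts the foreground (SV-affected)
#' genes against the background minus the foreground, split by pathway
#' membership; Fisher two-sided p-values are BH-adjusted across pathways and
#' records are sorted by p. Multi-pathway genes contribute to each mapped
#' pathway.
#'
#' @param foreground_genes character vector (subset of `background_genes`).
#' @param background_genes character vector of all genes.
#' @param gene_to_pathways data.frame(gene, pathway), many-to-many.
#' @param contrast `"exclusive"` (foreground vs background - foreground,
#'   default) or `"full"` (foreground vs full background).
#' @return data.frame(pathway, fg_in, fg_out, bg_in, bg_out, odds_ratio,
#'   p, q) sorted by p.
#' @export
enrichment <- function(foreground_genes, background_genes, gene_to_pathways,
                       contrast = c("exclusive", "full")) {
  contrast <- match.arg(contrast)
  fg <- unique(foreground_genes); bg <- unique(background_genes)
  if (!all(fg %in% bg)) stop("foreground must be a subset of the background")
  if (!nrow(gene_to_pathways)) stop("empty gene-to-pathway map")
  other <- if (contrast == "exclusive") setdiff(bg, fg) else bg
  out <- NULL
  for (pw in unique(gene_to_pathways$pathway)) {
    inpw <- gene_to_pathways$gene[gene_to_pathways$pathway == pw]
    fg_in <- sum(fg %in% inpw); fg_out <- length(fg) - fg_in
    bg_in <- sum(other %in% inpw); bg_out <- length(other) - bg_in
    ft <- suppressWarnings(fisher_exact_2x2(fg_in, fg_out, bg_in, bg_out))
    out <- rbind(out, data.frame(pathway = pw, fg_in = fg_in, fg_out = fg_out,
                                 bg_in = bg_in, bg_out = bg_out,
                                 odds_ratio = ft$odds_ratio, p = ft$p,
                                 stringsAsFactors = FALSE))
  }
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}
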