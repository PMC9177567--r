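# run expr with a fixed RNG seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Construct a genome assembly
#'
#' A genome assembly is a named character vector of contig sequences
#' (alphabet ACGT) with class `genome_assembly`. All coordinates used by the
#' package are 0-based, half-open; exported tables convert to 1-based
#' inclusive.
#'
#' @param contigs named character vector of contig sequences.
#' @return a `genome_assembly` object.
#' @export
genome_assembly <- function(contigs) {
  stopifnot(is.character(contigs), length(contigs) >= 1L)
  if (is.null(names(contigs)))
    names(contigs) <- paste0("contig_", seq_along(contigs))
  if (any(grepl("[^ACGT]", contigs)))
    stop("contig sequences must be over the alphabet {A,C,G,T}")
  structure(contigs, class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("genome_assembly: %d contig(s), %s bp total\n",
              length(x), format(genome_size(x), big.mark = ",")))
  invisible(x)
}

#' Total genome size in bp
#' @param genome a `genome_assembly`.
#' @return integer total length.
#' @export
genome_size <- function(genome) sum(nchar(unclass(genome)))

#' Simulate a random reference genome
#'
#' Draws i.i.d. bases at a target GC content, split into `n_contigs` contigs
#' of (near-)equal length. Deterministic for a fixed seed.
#'
#' @param length_bp total genome length (>= 1000 per contig).
#' @param n_contigs number of contigs.
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed.
#' @return a `genome_assembly`.
#' @export
simulate_reference_genome <- function(length_bp, n_contigs = 1L, gc = 0.5,
                                      seed = 1L) {
  if (!is.numeric(length_bp) || length_bp < n_contigs * 1000)
    stop("length_bp must be >= n_contigs * 1000")
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) stop("gc must lie in (0, 1)")
  with_seed(seed, {
    lens <- rep(length_bp %/% n_contigs, n_contigs)
    lens[seq_len(length_bp %% n_contigs)] <- lens[seq_len(length_bp %% n_contigs)] + 1L
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    contigs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    names(contigs) <- paste0("contig_", seq_len(n_contigs))
    genome_assembly(contigs)
  })
}

#' SV length mixture model
#'
#' Lengths are drawn from a three-component mixture: a short peak (default
#' uniform on 140-160 bp), a long peak (default uniform on 1050-1150 bp),
#' and a log-uniform tail up to `max_len`. All sampled lengths are at least
#' `min_len`.
#'
#' @param short_range,long_range two-element integer ranges of the peaks.
#' @param weights mixture weights (short, long, tail); normalised internally.
#' @param max_len upper bound of the tail component.
#' @param min_len minimum SV length (default 50).
#' @return an `sv_length_model` object.
#' @export
sv_length_model <- function(short_range = c(140L, 160L),
                            long_range = c(1050L, 1150L),
                            weights = c(0.45, 0.45, 0.10),
                            max_len = 5000L, min_len = 50L) {
  stopifnot(length(weights) == 3L, all(weights >= 0), sum(weights) > 0,
            min_len >= 1, max_len >= min_len,
            short_range[1] >= min_len, long_range[1] >= min_len)
  structure(list(short_range = as.integer(short_range),
                 long_range = as.integer(long_range),
                 weights = weights / sum(weights),
                 max_len = as.integer(max_len),
                 min_len = as.integer(min_len)),
            class = "sv_length_model")
}

#' Sample SV lengths from a length model
#' @param model an [sv_length_model()].
#' @param n number of lengths.
#' @return integer vector of lengths (all >= `model$min_len`).
#' @export
sample_sv_lengths <- function(model, n) {
  comp <- sample.int(3L, n, replace = TRUE, prob = model$weights)
  len <- integer(n)
  ns <- sum(comp == 1L); nl <- sum(comp == 2L); nt <- sum(comp == 3L)
  runif_range <- function(n, r) r[1] + sample.int(r[2] - r[1] + 1L, n,
                                                  replace = TRUE) - 1L
  if (ns) len[comp == 1L] <- runif_range(ns, model$short_range)
  if (nl) len[comp == 2L] <- runif_range(nl, model$long_range)
  if (nt) len[comp == 3L] <- pmax(model$min_len, round(exp(stats::runif(
    nt, log(model$min_len), log(model$max_len)))))
  pmax(len, model$min_len)
}

# random sequence at a given GC, avoiding any shared k-mer with `avoid`
.random_insert_seq <- function(len, gc, avoid, k = 21L, cap = 50L) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  avoid_codes <- if (nchar(avoid) >= k)
    c(encode_kmers(avoid, k), encode_kmers(revcomp(avoid), k)) else numeric(0)
  for (i in seq_len(cap)) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
               collapse = "")
    if (len < k || !length(avoid_codes) ||
        !any(encode_kmers(s, k) %in% avoid_codes)) return(s)
  }
  s
}

#' Plant structural variants into a reference genome
#'
#' Places `n_svs` non-overlapping insertions, deletions and inversions into a
#' copy of `reference` and returns the edited query genome together with a
#' truth table holding both reference and query coordinates (0-based,
#' half-open). Insertions add novel sequence at the genome's GC (screened
#' against sharing any 21-mer with the flanks), deletions remove reference
#' sequence, inversions reverse-complement an interval. Planted SVs are
#' interior (>= 2 x `flank` from contig ends) and separated by
#' >= 2 x `flank` bp.
#'
#' @param reference a `genome_assembly`.
#' @param n_svs number of SVs to plant.
#' @param type_mix probabilities for (insertion, deletion, inversion).
#' @param length_model an [sv_length_model()].
#' @param seed integer seed (NULL to use the current RNG state).
#' @param flank flank unit for placement margins (default 100 bp).
#' @param retry_cap rejection-sampling retries before a placement error.
#' @return list with `query` (a `genome_assembly`) and `truth` (data.frame:
#'   sv_id, sv_type, ref_contig, ref_start, ref_end, query_contig,
#'   query_start, query_end, length_bp, inserted_seq, payload_seed).
#' @export
plant_svs <- function(reference, n_svs,
                      type_mix = c(insertion = 0.45, deletion = 0.45,
                                   inversion = 0.10),
                      length_model = sv_length_model(),
                      seed = NULL, flank = 100L, retry_cap = 1000L) {
  stopifnot(inherits(reference, "genome_assembly"), n_svs >= 0)
  with_seed(seed, {
    empty <- data.frame(sv_id = character(0), sv_type = character(0),
                        ref_contig = character(0), ref_start = integer(0),
                        ref_end = integer(0), query_contig = character(0),
                        query_start = integer(0), query_end = integer(0),
                        length_bp = integer(0), inserted_seq = character(0),
                        payload_seed = integer(0), stringsAsFactors = FALSE)
    if (n_svs == 0L)
      return(list(query = reference, truth = empty))

    types <- sample(c("insertion", "deletion", "inversion"), n_svs,
                    replace = TRUE, prob = type_mix)
    lens <- sample_sv_lengths(length_model, n_svs)
    lens[types == "inversion"] <- pmax(50L, lens[types == "inversion"])
    clens <- nchar(unclass(reference))
    margin <- 2L * flank
    gap <- 2L * flank
    gc <- mean(strsplit(paste(unclass(reference), collapse = ""), "")[[1]] %in%
                 c("G", "C"))

    placed <- vector("list", n_svs)
    occupied <- lapply(seq_along(reference), function(i) cbind(start = integer(0), end = integer(0)))
    names(occupied) <- names(reference)
    for (i in seq_len(n_svs)) {
      span <- if (types[i] == "insertion") 0L else lens[i]
      ok <- FALSE
      for (try in seq_len(retry_cap)) {
        ci <- sample.int(length(reference), 1L, prob = clens)
        L <- clens[ci]
        lo <- margin; hi <- L - margin - span
        if (hi <= lo) next
        pos <- sample(lo:hi, 1L)
        occ <- occupied[[ci]]
        if (nrow(occ) && any(pos - gap < occ[, "end"] &
                             pos + span + gap > occ[, "start"])) next
        occupied[[ci]] <- rbind(occ, c(pos, pos + span))
        placed[[i]] <- list(contig = names(reference)[ci], pos = pos)
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place all SVs without overlap; ",
                    "reduce n_svs or SV lengths")
    }

    truth <- data.frame(
      sv_type = types,
      ref_contig = vapply(placed, `[[`, "", "contig"),
      ref_start = vapply(placed, function(p) p$pos, 0),
      length_bp = lens, stringsAsFactors = FALSE)
    truth <- truth[order(truth$ref_contig, truth$ref_start), , drop = FALSE]
    truth$sv_id <- sprintf("truth%04d", seq_len(n_svs))
    truth$payload_seed <- NA_integer_
    truth$inserted_seq <- NA_character_

    query <- unclass(reference)
    truth$ref_end <- truth$query_start <- truth$query_end <- NA_integer_
    truth$query_contig <- truth$ref_contig
    for (cn in unique(truth$ref_contig)) {
      idx <- which(truth$ref_contig == cn)
      refseq <- unclass(reference)[[cn]]
      parts <- character(0)
      cursor <- 0L   # 0-based position on reference consumed so far
      offset <- 0L   # query_pos - ref_pos at current cursor
      for (j in idx) {
        p <- truth$ref_start[j]
        parts <- c(parts, substr(refseq, cursor + 1L, p))
        if (truth$sv_type[j] == "insertion") {
          pseed <- sample.int(.Machine$integer.max, 1L)
          fl <- substr(refseq, max(1L, p - 2L * flank + 1L), min(nchar(refseq), p + 2L * flank))
          ins <- with_seed(pseed, .random_insert_seq(truth$length_bp[j], gc, fl))
          parts <- c(parts, ins)
          truth$ref_end[j] <- p
          truth$query_start[j] <- p + offset
          truth$query_end[j] <- p + offset + truth$length_bp[j]
          truth$inserted_seq[j] <- ins
          truth$payload_seed[j] <- pseed
          offset <- offset + truth$length_bp[j]
          cursor <- p
        } else if (truth$sv_type[j] == "deletion") {
          truth$ref_end[j] <- p + truth$length_bp[j]
          truth$query_start[j] <- truth$query_end[j] <- p + offset
          offset <- offset - truth$length_bp[j]
          cursor <- p + truth$length_bp[j]
        } else { # inversion
          seg <- substr(refseq, p + 1L, p + truth$length_bp[j])
          parts <- c(parts, revcomp(seg))
          truth$ref_end[j] <- p + truth$length_bp[j]
          truth$query_start[j] <- p + offset
          truth$query_end[j] <- p + offset + truth$length_bp[j]
          cursor <- p + truth$length_bp[j]
        }
      }
      parts <- c(parts, substr(refseq, cursor + 1L, nchar(refseq)))
      query[[cn]] <- paste(parts, collapse = "")
    }
    truth <- truth[, c("sv_id", "sv_type", "ref_contig", "ref_start",
                       "ref_end", "query_contig", "query_start", "query_end",
                       "length_bp", "inserted_seq", "payload_seed")]
    rownames(truth) <- NULL
    list(query = genome_assembly(query), truth = truth)
  })
}

#' Long-read simulation parameters
#'
#' ONT-like read model: lognormal lengths with a given mean and sd,
#' truncated at contig ends (no circularity), flat quality, optional
#' per-base substitution/insertion/deletion errors.
#'
#' @param mean_len mean read length in bp (default 5683).
#' @param sd_len standard deviation of read length.
#' @param min_len minimum emitted read length (default 200 = 2 x default flank).
#' @param sub_rate,ins_rate,del_rate per-base error rates in [0, 0.2].
#' @return a `read_params` list.
#' @export
read_params <- function(mean_len = 5683, sd_len = 3000, min_len = 200,
                        sub_rate = 0, ins_rate = 0, del_rate = 0) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates > 0.2))
    stop("error rates must lie in [0, 0.2]")
  stopifnot(mean_len > 0, sd_len >= 0, min_len >= 1)
  list(mean_len = mean_len, sd_len = sd_len, min_len = min_len,
       sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate)
}

.mutate_read <- function(seq, params) {
  if (params$sub_rate <= 0 && params$ins_rate <= 0 && params$del_rate <= 0)
    return(seq)
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  if (params$sub_rate > 0) {
    hit <- which(stats::runif(n) < params$sub_rate)
    if (length(hit)) {
      alt <- vapply(b[hit], function(x) sample(setdiff(c("A","C","G","T"), x), 1L),
                    character(1))
      b[hit] <- alt
    }
  }
  if (params$del_rate > 0) b <- b[stats::runif(length(b)) >= params$del_rate]
  if (params$ins_rate > 0) {
    nins <- stats::rbinom(1L, length(b), params$ins_rate)
    if (nins > 0) {
      at <- sort(sample.int(length(b), nins, replace = TRUE))
      ins <- sample(c("A","C","G","T"), nins, replace = TRUE)
      out <- character(length(b) + nins)
      out[at + seq_len(nins)] <- ins
      out[-(at + seq_len(nins))] <- b
      b <- out
    }
  }
  paste(b, collapse = "")
}

#' Simulate ONT-like long reads from a genome
#'
#' Read count is chosen so total bases approximate `depth` x genome size.
#' Each read records its true origin (contig, 0-based start, strand) in the
#' read table and FASTQ header for oracle use; the mapper never reads it.
#'
#' @param genome a `genome_assembly`.
#' @param depth target sequencing depth (> 0).
#' @param params a [read_params()] list.
#' @param seed integer seed.
#' @return a `read_set`: list(sequences = named character vector,
#'   info = data.frame(read_id, contig, start, end, strand), params).
#' @export
simulate_long_reads <- function(genome, depth, params = read_params(),
                                seed = 1L) {
  stopifnot(inherits(genome, "genome_assembly"), depth > 0)
  if (params$mean_len >= max(nchar(unclass(genome))))
    stop("mean read length must be below the longest contig")
  with_seed(seed, {
    G <- genome_size(genome)
    n_reads <- max(1L, round(depth * G / params$mean_len))
    clens <- nchar(unclass(genome))
    sdlog <- sqrt(log(1 + (params$sd_len / params$mean_len)^2))
    meanlog <- log(params$mean_len) - sdlog^2 / 2
    ids <- contig <- strand <- seqs <- character(n_reads)
    start <- end <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      repeat {
        ci <- sample.int(length(genome), 1L, prob = clens)
        L <- clens[ci]
        s <- sample.int(L, 1L) - 1L
        tlen <- max(params$min_len, round(stats::rlnorm(1L, meanlog, sdlog)))
        e <- min(L, s + tlen)
        if (e - s >= params$min_len) break
      }
      raw <- substr(unclass(genome)[[ci]], s + 1L, e)
      raw <- .mutate_read(raw, params)
      st <- sample(c("+", "-"), 1L)
      seqs[i] <- if (st == "-") revcomp(raw) else raw
      ids[i] <- sprintf("read%06d src=%s pos=%d strand=%s", i,
                        names(genome)[ci], s, st)
      contig[i] <- names(genome)[ci]; start[i] <- s; end[i] <- e; strand[i] <- st
    }
    names(seqs) <- ids
    structure(list(sequences = seqs,
                   info = data.frame(read_id = ids, contig = contig,
                                     start = start, end = end, strand = strand,
                                     stringsAsFactors = FALSE),
                   params = params),
              class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads, %s bp total (mean %.0f bp)\n",
              length(x$sequences), format(sum(nchar(x$sequences)), big.mark = ","),
              mean(nchar(x$sequences))))
  invisible(x)
}

#' Simulate per-individual genomes for SV fingerprinting
#'
#' Each individual receives its own planted SV set at a per-genome density of
#' `sv_rate_per_mb` (Poisson count), so two individuals differ at roughly
#' twice that density; all samples from one individual share an identical
#' genome (within-individual SV rate 0, mirroring the stability of genome
#' structure over short time series).
#'
#' @param reference a `genome_assembly`.
#' @param n_individuals number of individuals.
#' @param samples_per_individual samples (time points) per individual.
#' @param sv_rate_per_mb expected planted SVs per Mb per individual
#'   (default 8.35, i.e. ~16.7 SVs/Mb between two individuals).
#' @param seed integer seed.
#' @param ... passed to [plant_svs()].
#' @return list(genomes = named list of `genome_assembly`,
#'   sample_info = data.frame(sample_id, individual),
#'   truth = named list of truth tables per individual).
#' @export
simulate_individual_genomes <- function(reference, n_individuals = 6L,
                                        samples_per_individual = 1L,
                                        sv_rate_per_mb = 8.35, seed = 1L, ...) {
  stopifnot(n_individuals >= 2L, samples_per_individual >= 1L)
  with_seed(seed, {
    G <- genome_size(reference)
    genomes <- list(); info <- NULL; truths <- list()
    for (i in seq_len(n_individuals)) {
      n_sv <- stats::rpois(1L, sv_rate_per_mb * G / 1e6)
      pl <- plant_svs(reference, n_sv, seed = NULL, ...)
      truths[[sprintf("ind%02d", i)]] <- pl$truth
      for (s in seq_len(samples_per_individual)) {
        sid <- sprintf("ind%02d_t%02d", i, s)
        genomes[[sid]] <- pl$query
        info <- rbind(info, data.frame(sample_id = sid,
                                       individual = sprintf("ind%02d", i),
                                       stringsAsFactors = FALSE))
      }
    }
    list(genomes = genomes, sample_info = info, truth = truths)
  })
}

#' Tile synthetic gene models along a genome
#'
#' Produces non-overlapping gene intervals (0-based, half-open) with unique
#' KO labels and a KO-to-pathway map, for enrichment analyses on synthetic
#' data.
#'
#' @param genome a `genome_assembly`.
#' @param gene_len gene body length (bp).
#' @param intergenic gap between consecutive genes (bp).
#' @param n_pathways number of synthetic pathways to cycle KOs through.
#' @return list(genes = data.frame(contig, start, end, strand, gene_id, ko),
#'   pathway_map = data.frame(ko, pathway)).
#' @export
simulate_gene_models <- function(genome, gene_len = 900L, intergenic = 100L,
                                 n_pathways = 5L) {
  stopifnot(inherits(genome, "genome_assembly"), gene_len >= 1, intergenic >= 0)
  genes <- NULL
  gi <- 0L
  for (cn in names(genome)) {
    L <- nchar(unclass(genome)[[cn]])
    starts <- seq(intergenic, L - gene_len, by = gene_len + intergenic)
    if (!length(starts)) next
    df <- data.frame(contig = cn, start = as.integer(starts),
                     end = as.integer(starts + gene_len), strand = "+",
                     stringsAsFactors = FALSE)
    df$gene_id <- sprintf("gene_%05d", gi + seq_len(nrow(df)))
    df$ko <- sprintf("K%05d", gi + seq_len(nrow(df)))
    gi <- gi + nrow(df)
    genes <- rbind(genes, df)
  }
  if (is.null(genes)) stop("no gene fits in the genome; reduce gene_len")
  pathway_map <- data.frame(
    ko = genes$ko,
    pathway = sprintf("path%02d", (seq_len(nrow(genes)) - 1L) %% n_pathways + 1L),
    stringsAsFactors = FALSE)
  list(genes = genes, pathway_map = pathway_map)
}
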