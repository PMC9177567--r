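# Independent oracles used to freeze expected values. These deliberately use
# different machinery than the implementation under test.

# reconstruct a query genome by applying a planted truth table to the
# reference with Biostrings::replaceAt (the package edits via substring
# splicing, so this is an independent route)
apply_truth_svs <- function(reference, truth) {
  out <- lapply(names(reference), function(cn) {
    s <- Biostrings::DNAString(unclass(reference)[[cn]])
    tr <- truth[truth$ref_contig == cn, , drop = FALSE]
    if (!nrow(tr)) return(as.character(s))
    at <- IRanges::IRanges(start = tr$ref_start + 1L, end = tr$ref_end)
    value <- character(nrow(tr))
    value[tr$sv_type == "insertion"] <- tr$inserted_seq[tr$sv_type == "insertion"]
    value[tr$sv_type == "deletion"] <- ""
    inv <- which(tr$sv_type == "inversion")
    if (length(inv))
      value[inv] <- as.character(Biostrings::reverseComplement(
        Biostrings::extractAt(s, at[inv])))
    as.character(Biostrings::replaceAt(s, at, Biostrings::DNAStringSet(value)))
  })
  names(out) <- names(reference)
  unlist(out)
}

# N50 by brute force over the definition: largest L in the length set such
# that contigs >= L sum to >= half the total
n50_brute <- function(lengths) {
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= sum(lengths) / 2) return(L)
  stop("unreachable")
}

# exact two-sided Mann-Whitney p by enumerating all rank assignments
wilcoxon_enum_p <- function(x, y) {
  n <- length(x) + length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  combos <- utils::combn(n, length(x))
  r_all <- rank(c(x, y))
  u_all <- apply(combos, 2, function(idx)
    sum(r_all[idx]) - length(x) * (length(x) + 1) / 2)
  p_lo <- mean(u_all <= u_obs); p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# two-sided Fisher p by direct hypergeometric enumeration
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up by hand
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m); out[o] <- pmin(q, 1)
  out
}

# Monte-Carlo permutation p for Spearman (two-sided, proportion form)
spearman_perm_p <- function(x, y, B = 1e5, seed = 1) {
  set.seed(seed)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  n <- length(x)
  perms <- matrix(ry[vapply(seq_len(B), function(i) sample.int(n),
                            integer(n))], nrow = n)
  rx0 <- rx - mean(rx)
  denom <- sqrt(sum(rx0^2)) * sqrt(sum((ry - mean(ry))^2))
  rho_perm <- colSums(rx0 * (perms - mean(ry))) / denom
  mean(abs(rho_perm) >= abs(rho_obs) - 1e-12)
}

# binary Jaccard distance matrix from bit rows (independent of vegan)
jaccard_bits <- function(rows, nbits) {
  n <- length(rows)
  d <- matrix(0, n, n)
  popcount <- function(v) vapply(v, function(x) sum(bitwAnd(x, 2^(0:(nbits - 1))) > 0), 0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- popcount(bitwOr(rows[i], rows[j]))
    if (u == 0) d[i, j] <- 0
    else d[i, j] <- 1 - popcount(bitwAnd(rows[i], rows[j])) / u
  }
  d
}

# small planted-SV fixture shared across alignment/caller tests
make_sv_fixture <- function(genome_seed = 7, sv_seed = 11, length_bp = 2e5,
                            n_svs = 40) {
  ref <- simulate_reference_genome(length_bp, 1, 0.45, seed = genome_seed)
  pl <- plant_svs(ref, n_svs, seed = sv_seed)
  list(ref = ref, query = pl$query, truth = pl$truth)
}
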