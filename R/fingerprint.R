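#' Label pairwise SV rates as inter- or intra-individual
#'
#' @param sv_rates data.frame(species, sample_a, sample_b, rate_per_mb).
#' @param sample_to_individual named character vector mapping sample id to
#'   individual id.
#' @return the input with a `comparison_class` column
#'   ("inter_individual"/"intra_individual").
#' @export
classify_pairs <- function(sv_rates, sample_to_individual) {
  miss <- setdiff(c(sv_rates$sample_a, sv_rates$sample_b),
                  names(sample_to_individual))
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  same <- sample_to_individual[sv_rates$sample_a] ==
    sample_to_individual[sv_rates$sample_b]
  sv_rates$comparison_class <- ifelse(same, "intra_individual",
                                      "inter_individual")
  sv_rates
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when the combined sample size is at most
#' `exact_threshold` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y non-empty numeric vectors.
#' @param exact_threshold combined-n switch for the exact test (default 12).
#' @return list(statistic = Mann-Whitney U for `x`, p = two-sided p-value).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_threshold = 12L) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y)) <= exact_threshold && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Jaccard distance matrix on binary presence/absence profiles
#'
#' d(a, b) = 1 - |A intersect B| / |A union B| over feature sets. Pairs of
#' all-empty rows get distance 0 ("identical emptiness") by default, or NA.
#'
#' @param presence sample x feature binary matrix (0/1).
#' @param empty_pair distance assigned when both rows are empty
#'   (0, the default, or NA).
#' @return symmetric distance matrix with zero diagonal.
#' @export
jaccard_distance_matrix <- function(presence, empty_pair = 0) {
  m <- as.matrix(presence)
  if (!all(m %in% c(0, 1))) stop("presence matrix must be binary")
  # vegdist warns about all-empty rows; their pairs are defined explicitly
  # below, so the warning is moot here
  d <- as.matrix(suppressWarnings(
    vegan::vegdist(m, method = "jaccard", binary = TRUE)))
  rs <- rowSums(m)
  both_empty <- outer(rs == 0, rs == 0, `&`)
  d[both_empty] <- empty_pair
  diag(d) <- 0
  d
}

#' Principal-coordinates analysis (classical scaling)
#'
#' Double-centres the squared-distance Gram matrix and keeps the top-k
#' non-negative eigenpairs. When fewer than `k` positive eigenvalues exist,
#' k is reduced with a warning; negative eigenvalues are dropped with a
#' warning.
#'
#' @param distances symmetric distance matrix with zero diagonal.
#' @param k number of dimensions.
#' @return an `ordination`: list(coordinates = n x k matrix,
#'   eigenvalues = non-increasing, non-negative length-k vector).
#' @export
pcoa <- function(distances, k = 2L) {
  d <- as.matrix(distances)
  stopifnot(isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
            all(abs(diag(d)) < 1e-12))
  if (all(d == 0)) {
    return(structure(list(coordinates = matrix(0, nrow(d), k,
                                               dimnames = list(rownames(d), NULL)),
                          eigenvalues = rep(0, k)), class = "ordination"))
  }
  cs <- stats::cmdscale(d, k = min(k, nrow(d) - 1L), eig = TRUE)
  eig <- cs$eig
  if (any(eig < -1e-8 * max(abs(eig))))
    warning("negative eigenvalues dropped (non-Euclidean distances)")
  npos <- sum(eig > 1e-8 * max(abs(eig)))
  if (npos < k) {
    warning(sprintf("k reduced from %d to %d positive eigenvalue(s)", k, npos))
    k <- npos
  }
  structure(list(coordinates = cs$points[, seq_len(k), drop = FALSE],
                 eigenvalues = eig[seq_len(k)]),
            class = "ordination")
}

#' Procrustes permutation test (protest)
#'
#' Superimposes configuration Y onto X by translation, scaling and rotation
#' after scaling both to unit trace; m2 is the minimised residual sum of
#' squares, the Procrustes correlation is sqrt(1 - m2), and the p-value is
#' (1 + #{permuted m2 <= observed}) / (n_perm + 1), permuting the row order
#' of Y. The minimum attainable p with 999 permutations is 0.001.
#'
#' @param X,Y `ordination` objects (or coordinate matrices) over the same
#'   samples (>= 3).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream (mandatory for
#'   reproducibility).
#' @return list(m2, correlation, p, n_perm).
#' @export
protest_test <- function(X, Y, n_perm = 999L, seed = 1L) {
  xm <- if (inherits(X, "ordination")) X$coordinates else as.matrix(X)
  ym <- if (inherits(Y, "ordination")) Y$coordinates else as.matrix(Y)
  if (nrow(xm) < 3L) stop("protest needs at least 3 samples")
  if (nrow(xm) != nrow(ym)) stop("X and Y must have the same samples")
  pr <- with_seed(seed,
                  vegan::protest(xm, ym, permutations = n_perm,
                                 symmetric = TRUE))
  list(m2 = unname(pr$ss), correlation = unname(pr$t0),
       p = unname(pr$signif), n_perm = n_perm)
}
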