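test_that("pair classification counts inter and intra pairs correctly", {
  map <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B", s5 = "C")
  mk <- function(ids) {
    pr <- t(utils::combn(ids, 2))
    data.frame(species = "sp", sample_a = pr[, 1], sample_b = pr[, 2],
               rate_per_mb = 1)
  }
  cl2 <- classify_pairs(mk(c("s1", "s2")), map)
  expect_identical(cl2$comparison_class, "intra_individual")
  cl3 <- classify_pairs(mk(c("s1", "s3", "s5")), map)
  expect_identical(unique(cl3$comparison_class), "inter_individual")
  cl4 <- classify_pairs(mk(c("s1", "s2", "s3", "s4")), map)
  expect_equal(sum(cl4$comparison_class == "intra_individual"), 2L)
  expect_equal(sum(cl4$comparison_class == "inter_individual"), 4L)
  expect_error(classify_pairs(mk(c("s1", "zz")), map), "zz")
})

test_that("rank-sum test matches exhaustive enumeration and handles edge cases", {
  expect_warning(res <- wilcoxon_rank_sum(c(2, 2), c(2, 2)), "identical")
  expect_equal(res$p, 1)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p, 1 / 3)
  x <- c(5, 9, 12); y <- c(1, 2, 20, 30)
  expect_equal(wilcoxon_rank_sum(x, y)$p, wilcoxon_enum_p(x, y))
  # same values in both groups: distribution symmetric, p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
})

test_that("Jaccard distances match a bit-level oracle and the metric axioms", {
  p <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0))
  d <- jaccard_distance_matrix(p)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 1 - 1 / 3)
  disj <- rbind(x = c(1, 0), y = c(0, 1))
  expect_equal(jaccard_distance_matrix(disj)["x", "y"], 1)

  # all 3-row binary matrices over <= 6 features, via bit enumeration
  for (nbits in c(3L, 6L)) {
    rows <- 0:(2^nbits - 1)
    dd <- jaccard_bits(rows, nbits)
    # triangle inequality over every triple of profiles
    for (i in seq_along(rows)) {
      through <- outer(dd[i, ], dd[i, ], `+`)
      expect_true(all(dd <= through + 1e-12))
    }
    # the package function agrees with the oracle on the full profile matrix
    pm <- t(vapply(rows, function(r) as.integer(bitwAnd(r, 2^(0:(nbits - 1))) > 0),
                   integer(nbits)))
    expect_equal(unname(jaccard_distance_matrix(pm)), dd, tolerance = 1e-12)
  }

  # empty-vs-empty convention
  ee <- rbind(c(0, 0), c(0, 0))
  expect_equal(jaccard_distance_matrix(ee)[1, 2], 0)
  expect_true(is.na(jaccard_distance_matrix(ee, empty_pair = NA)[1, 2]))
})

test_that("classical PCoA reproduces Euclidean configurations", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  o <- suppressWarnings(pcoa(d, 1))
  got <- as.vector(dist(o$coordinates))
  expect_equal(sort(got), c(1, 1, 2), tolerance = 1e-9)

  z <- matrix(0, 4, 4)
  oz <- pcoa(z, 2)
  expect_true(all(oz$coordinates == 0))

  set.seed(5)
  pts <- matrix(rnorm(40), 20, 2)
  de <- as.matrix(dist(pts))
  oe <- pcoa(de, 2)
  expect_equal(as.vector(dist(oe$coordinates)), as.vector(dist(pts)),
               tolerance = 1e-8)
  expect_true(all(diff(oe$eigenvalues) <= 1e-9))
  expect_lt(max(abs(colMeans(oe$coordinates))), 1e-9)
  expect_warning(pcoa(de, 10), "reduced")
})

test_that("protest is scale-invariant with the permutation-floor p-value", {
  set.seed(9)
  X <- matrix(rnorm(60), 30, 2)
  th <- 1.1; R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  pt <- protest_test(X, X %*% R, n_perm = 999, seed = 2)
  expect_equal(pt$correlation, 1, tolerance = 1e-10)
  expect_equal(pt$m2, 0, tolerance = 1e-10)
  expect_equal(pt$p, 0.001)

  pt2 <- protest_test(X, 2 * (X %*% R), n_perm = 999, seed = 2)
  expect_equal(pt2$m2, pt$m2, tolerance = 1e-12)
  expect_equal(pt2$p, pt$p)
  expect_error(protest_test(X[1:2, ], X[1:2, ]), "3 samples")
})

test_that("inter-individual SV rates dominate intra-individual rates", {
  ref <- simulate_reference_genome(150000, 1, 0.45, seed = 2)
  ig <- simulate_individual_genomes(ref, n_individuals = 3,
                                    samples_per_individual = 2,
                                    sv_rate_per_mb = 40, seed = 3)
  rates <- pairwise_sv_rates(ig$genomes)
  cl <- classify_pairs(rates, stats::setNames(ig$sample_info$individual,
                                              ig$sample_info$sample_id))
  inter <- cl$rate_per_mb[cl$comparison_class == "inter_individual"]
  intra <- cl$rate_per_mb[cl$comparison_class == "intra_individual"]
  expect_true(all(intra == 0))      # identical genomes within an individual
  expect_true(all(inter > 0))
  expect_lt(wilcoxon_rank_sum(inter, intra)$p, 0.01)
})
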