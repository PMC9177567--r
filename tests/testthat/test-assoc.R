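test_that("the three occurrence filters straddle their thresholds as specified", {
  n <- 100L
  samples <- sprintf("S%03d", 1:n)
  mk_ab <- function(n_present) c(rep(1, n_present), rep(0, n - n_present))
  ab <- cbind(sp_lo = mk_ab(49), sp_hi = mk_ab(50), sp_all = mk_ab(100))
  rownames(ab) <- samples

  # SV columns on sp_all (present in all 100): group fractions 19/81 vs 21/79
  sv <- cbind(`sp_all|K1` = c(rep(1, 19), rep(0, 81)),
              `sp_all|K2` = c(rep(1, 21), rep(0, 79)),
              `sp_lo|K3` = c(rep(1, 25), rep(0, 24), rep(NA, 51)))
  rownames(sv) <- samples

  met <- cbind(m_lo = c(rep(1, 90), rep(NA, 10)),   # present in exactly 90%
               m_hi = c(rep(1, 91), rep(NA, 9)))
  rownames(met) <- samples

  bundle <- list(abundance = ab, sv_genotype = sv, metabolites = met,
                 phenotype = stats::setNames(rnorm(n), samples),
                 covariates = data.frame(age = rep(40, n), row.names = samples))
  fc <- filter_cohort(bundle)
  expect_identical(colnames(fc$abundance), c("sp_hi", "sp_all"))
  expect_identical(colnames(fc$sv_genotype), "sp_all|K2")
  expect_identical(colnames(fc$metabolites), "m_hi")
  lg <- fc$filter_log
  expect_false(lg$kept[lg$feature == "sp_lo"])
  expect_false(lg$kept[lg$feature == "sp_all|K1"])
  expect_false(lg$kept[lg$feature == "m_lo"])

  none <- bundle; none$abundance <- ab[, "sp_lo", drop = FALSE]
  expect_error(filter_cohort(none), "no species")
})

test_that("Spearman rho and p match hand oracles", {
  expect_equal(spearman(c(1, 2, 3), c(10, 20, 30))$rho, 1)
  expect_equal(spearman(c(1, 2, 3), c(30, 20, 10))$rho, -1)

  # midrank Pearson by hand for a tied example
  x <- c(1, 2, 2, 4); y <- c(3, 1, 4, 4)
  expect_equal(spearman(x, y)$rho, stats::cor(rank(x), rank(y)))

  # permutation oracle at n = 20 (asymptotic t approximation target)
  set.seed(11)
  x <- rnorm(20); y <- rnorm(20)
  expect_lt(abs(spearman(x, y)$p - spearman_perm_p(x, y)), 0.01)

  expect_warning(res <- spearman(rep(1, 10), rnorm(10)), "variance")
  expect_true(is.na(res$rho))
  expect_error(spearman(1:2, 1:2), "3")
})

test_that("BH adjustment matches hand step-up and its invariants", {
  expect_equal(bh_adjust(0.07), 0.07)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.001, 0.9)), c(0.002, 0.9))
  set.seed(3)
  for (i in 1:10) {
    p <- runif(sample(2:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_by_hand(p))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("screening flags planted pairs and controls the null FDP", {
  co <- simulate_cohort(n_samples = 100, confounded_triples = 3, seed = 21)
  fc <- filter_cohort(co)
  sc <- screen_pairs(fc)
  planted <- paste(co$truth$species, co$truth$metabolite)
  flagged <- paste(sc$species, sc$target)[sc$significant]
  expect_gte(sum(planted %in% flagged), 2L)

  # phenotype screen picks up a species wired through planted metabolites,
  # with the glucose-like negative sign
  scp <- screen_pairs(fc, targets = "phenotype")
  hit <- scp$significant & scp$species %in% co$truth$species
  expect_true(any(hit))
  expect_lt(min(scp$rho_all[hit]), 0)

  # modest null calibration (the full 500-replicate run lives in the
  # acceptance suite): no systematic inflation at q < 0.1
  fdp <- vapply(1:60, function(s) {
    fc0 <- filter_cohort(simulate_cohort(effect_size = 0, seed = 1000 + s))
    sc0 <- screen_pairs(fc0)
    mean(sc0$significant)
  }, 0)
  expect_lte(mean(fdp > 0), 0.2)
})

test_that("SV dissection recovers a strongly planted confounded triple", {
  # dissection power is conditional on the pair passing the screen (the
  # dissection stage's precondition); the screen itself pays a BH
  # multiplicity price with a single planted pair in the family
  res <- vapply(1:25, function(s) {
    co <- simulate_cohort(n_samples = 100, confounded_triples = 1,
                          sv1_prob = 0.5, seed = 3000 + s)
    cas <- association_cascade(co)
    tr <- co$truth
    sc <- cas$screen
    passed <- any(sc$significant & sc$species == tr$species &
                    sc$target == tr$metabolite)
    conf <- any(cas$dissection$verdict == "confounded" &
                  cas$dissection$species == tr$species &
                  cas$dissection$target == tr$metabolite &
                  cas$dissection$ko == tr$ko)
    c(passed, conf)
  }, logical(2))
  expect_gte(sum(res[2, ]) / sum(res[1, ]), 0.8)
})

test_that("end-to-end cascade recovers planted triples with few false verdicts", {
  runs <- vapply(1:50, function(s) {
    co <- simulate_cohort(seed = 5000 + s)
    cas <- association_cascade(co)
    di <- cas$dissection
    key <- paste(di$species, di$target, di$ko)
    truth_key <- paste(co$truth$species, co$truth$metabolite, co$truth$ko)
    n_true <- sum(truth_key %in% key[di$verdict == "confounded"])
    n_false <- sum(di$verdict == "confounded" &
                     !(key %in% truth_key))
    c(recovered = n_true, false = n_false)
  }, numeric(2))
  ok <- runs["recovered", ] >= 2 & runs["false", ] <= 1
  expect_gte(mean(ok), 0.8)
})

test_that("partial Spearman residualisation behaves at both extremes", {
  set.seed(7)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  # constant covariate: identical to plain Spearman (the redundant column is
  # dropped with a warning)
  ps <- suppressWarnings(partial_spearman(x, y, matrix(1, 50, 1)))
  expect_equal(ps$rho, spearman(x, y)$rho, tolerance = 1e-12)

  # controlling for a covariate identical to y removes the correlation up to
  # the nonlinear rank residue
  expect_warning(ps2 <- partial_spearman(x, y, cbind(y, y)), "collinear")
  expect_lt(abs(ps2$rho), 0.15)

  # common cause: marginal correlation vanishes after control
  reps <- vapply(1:12, function(s) {
    set.seed(400 + s)
    z <- rnorm(200)
    x <- z + rnorm(200); y <- z + rnorm(200)
    c(marginal = spearman(x, y)$rho,
      partial = partial_spearman(x, y, cbind(z))$rho)
  }, numeric(2))
  expect_gt(min(reps["marginal", ]), 0.25)
  expect_lt(max(abs(reps["partial", ])), 0.15)
})
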