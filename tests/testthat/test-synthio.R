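test_that("reference genome simulation is deterministic, conserving and on-target GC", {
  g1 <- simulate_reference_genome(10000, 1, 0.5, seed = 1)
  g2 <- simulate_reference_genome(10000, 1, 0.5, seed = 1)
  expect_identical(unclass(g1), unclass(g2))

  g <- simulate_reference_genome(10000, 2, 0.5, seed = 3)
  expect_equal(genome_size(g), 10000)
  expect_equal(length(g), 2L)

  big <- simulate_reference_genome(1e6, 1, 0.3, seed = 7)
  gc <- sum(strsplit(unclass(big)[[1]], "")[[1]] %in% c("G", "C")) / 1e6
  # binomial sd at n = 1e6 is ~0.00046; +-0.01 is a >20 sigma band
  expect_lt(abs(gc - 0.3), 0.01)

  expect_error(simulate_reference_genome(500, 1, 0.5), "1000")
  expect_error(simulate_reference_genome(10000, 1, gc = 1.2), "gc")
})

test_that("planted SVs reproduce the query genome under an independent applier", {
  skip_if_not_installed("IRanges")
  fx <- make_sv_fixture(length_bp = 1e5, n_svs = 25)
  rebuilt <- apply_truth_svs(fx$ref, fx$truth)
  expect_identical(rebuilt, unclass(fx$query))
})

test_that("plant_svs bookkeeping: identity, length conservation, coordinates", {
  ref <- simulate_reference_genome(50000, 1, 0.5, seed = 2)
  none <- plant_svs(ref, 0, seed = 1)
  expect_identical(unclass(none$query), unclass(ref))
  expect_equal(nrow(none$truth), 0L)

  # force one deletion of a known length via a degenerate length model
  lm1 <- sv_length_model(short_range = c(600L, 600L), long_range = c(600L, 600L),
                         weights = c(1, 0, 0))
  one <- plant_svs(ref, 1, type_mix = c(0, 1, 0), length_model = lm1, seed = 5)
  expect_equal(genome_size(one$query), genome_size(ref) - 600L)
  expect_equal(one$truth$ref_end - one$truth$ref_start, 600L)
  expect_equal(one$truth$query_start, one$truth$query_end)

  # query coordinates map back to reference through cumulative indel offsets
  fx <- make_sv_fixture(length_bp = 1e5, n_svs = 30)
  tr <- fx$truth[order(fx$truth$ref_start), ]
  offset <- 0L
  for (i in seq_len(nrow(tr))) {
    expect_equal(tr$query_start[i], tr$ref_start[i] + offset)
    if (tr$sv_type[i] == "insertion") offset <- offset + tr$length_bp[i]
    if (tr$sv_type[i] == "deletion") offset <- offset - tr$length_bp[i]
  }
})

test_that("planted SV lengths are bimodal in the configured windows", {
  lm <- sv_length_model(weights = c(0.5, 0.5, 0))
  set.seed(42)
  lens <- sample_sv_lengths(lm, 200)
  n_short <- sum(lens >= 140 & lens <= 160)
  n_long <- sum(lens >= 1050 & lens <= 1150)
  expect_equal(n_short + n_long, 200L)
  # multinomial 3-sigma band around the 100/100 expectation
  expect_lt(abs(n_short - 100), 3 * sqrt(200 * 0.25))
  expect_true(all(lens >= 50))
})

test_that("long-read simulation hits depth, respects origin and is deterministic", {
  g <- simulate_reference_genome(100000, 1, 0.5, seed = 9)
  rs <- simulate_long_reads(g, 20, seed = 1)
  total <- sum(nchar(rs$sequences))
  expect_gte(total, 1.8e6); expect_lte(total, 2.2e6)

  rs2 <- simulate_long_reads(g, 20, seed = 1)
  expect_identical(rs$sequences, rs2$sequences)

  # zero-noise reads are exact substrings at their recorded origin
  info <- rs$info[1:25, ]
  for (i in seq_len(nrow(info))) {
    frag <- substr(unclass(g)[[info$contig[i]]], info$start[i] + 1L, info$end[i])
    seq_i <- rs$sequences[[info$read_id[i]]]
    if (info$strand[i] == "-") frag <- magsv:::revcomp(frag)
    expect_identical(seq_i, frag)
  }
  expect_error(read_params(sub_rate = 0.5), "0.2")
})

test_that("cohort generator: genotype NA pattern matches species absence and truth wiring", {
  co <- simulate_cohort(n_samples = 60, seed = 3)
  for (j in colnames(co$sv_genotype)) {
    sp <- sub("\\|.*$", "", j)
    expect_identical(is.na(co$sv_genotype[, j]), co$abundance[, sp] == 0)
  }
  expect_true(all(co$truth$metabolite %in% colnames(co$metabolites)))
  expect_true(all(co$truth$species %in% colnames(co$abundance)))
  expect_true(all(paste0(co$truth$species, "|", co$truth$ko) %in%
                    colnames(co$sv_genotype)))
  expect_error(simulate_cohort(n_samples = 20), ">= 40")
  expect_error(simulate_cohort(confounded_triples = 100), "exceeds")
})

test_that("planted SV0-only correlation holds in the generating model", {
  co <- simulate_cohort(n_samples = 200, confounded_triples = 1, seed = 8)
  tr <- co$truth[1, ]
  svcol <- paste0(tr$species, "|", tr$ko)
  g <- co$sv_genotype[, svcol]
  ab <- co$abundance[, tr$species]
  met <- co$metabolites[, tr$metabolite]
  sv0 <- !is.na(g) & g == 0 & !is.na(met)
  sv1 <- !is.na(g) & g == 1 & !is.na(met)
  r0 <- cor(ab[sv0], met[sv0], method = "spearman")
  r1 <- cor(ab[sv1], met[sv1], method = "spearman")
  expect_gt(r0, 0.5)          # target 0.7, generous sampling band
  expect_lt(abs(r1), 0.35)    # no dependence planted in SV1
})
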