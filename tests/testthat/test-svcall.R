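test_that("identical genomes give one full-length block per contig and no calls", {
  g <- simulate_reference_genome(40000, 2, 0.5, seed = 4)
  bl <- anchor_align(g, g)
  expect_equal(nrow(bl), 2L)
  expect_equal(bl$ref_start, c(0L, 0L))
  expect_equal(bl$ref_end, unname(nchar(unclass(g))))
  expect_identical(bl$strand, c("+", "+"))
  expect_equal(nrow(call_svs(bl)), 0L)
})

test_that("an inverted interval yields three blocks with a minus-strand middle", {
  g <- simulate_reference_genome(30000, 1, 0.5, seed = 6)
  s <- unclass(g)[[1]]
  inv_start <- 14000L; inv_len <- 2000L
  q <- paste0(substr(s, 1, inv_start),
              magsv:::revcomp(substr(s, inv_start + 1L, inv_start + inv_len)),
              substr(s, inv_start + inv_len + 1L, nchar(s)))
  bl <- anchor_align(g, genome_assembly(c(contig_1 = q)))
  expect_equal(nrow(bl), 3L)
  expect_identical(bl$strand, c("+", "-", "+"))
  expect_lt(abs(bl$ref_start[2] - inv_start), 5)
  expect_lt(abs(bl$ref_end[2] - (inv_start + inv_len)), 5)
  calls <- call_svs(bl)
  expect_identical(calls$sv_type, "inversion")
  expect_lt(abs(calls$length_bp - inv_len), 10)
})

test_that("a planted deletion produces two blocks and one large deletion call", {
  g <- simulate_reference_genome(30000, 1, 0.5, seed = 8)
  s <- unclass(g)[[1]]
  del_start <- 12000L; del_len <- 600L
  q <- paste0(substr(s, 1, del_start), substr(s, del_start + del_len + 1L, nchar(s)))
  bl <- anchor_align(g, genome_assembly(c(contig_1 = q)))
  expect_equal(nrow(bl), 2L)
  ref_gap <- bl$ref_start[2] - bl$ref_end[1]
  query_gap <- bl$query_start[2] - bl$query_end[1]
  expect_lt(abs(ref_gap - 600L), 5)
  expect_lte(abs(query_gap), 4)
  calls <- call_svs(bl)
  expect_identical(calls$sv_type, "deletion")
  expect_lt(abs(calls$length_bp - 600L), 5)
  expect_true(calls$is_large)
  expect_false(calls$filtered)
})

test_that("calls near contig ends are flagged, not dropped, and the margin is monotone", {
  # a 200 bp deletion whose left breakpoint sits 5 bp from the contig start
  bl <- data.frame(ref_contig = "c1", ref_start = c(0L, 205L),
                   ref_end = c(5L, 1000L), query_contig = "c1",
                   query_start = c(0L, 5L), query_end = c(5L, 800L),
                   strand = "+", n_matches = c(5L, 795L))
  calls <- call_svs(bl, ref_lengths = c(c1 = 1000L),
                    query_lengths = c(c1 = 800L))
  del <- calls[calls$sv_type == "deletion", ]
  expect_equal(nrow(del), 1L)
  expect_true(del$filtered)
  expect_identical(del$reason, "contig_end")

  fx <- make_sv_fixture(length_bp = 1e5, n_svs = 20)
  bl <- anchor_align(fx$ref, fx$query)
  kept <- vapply(c(0L, 10L, 200L, 2000L), function(m)
    sum(!call_svs(bl, end_margin = m)$filtered), 0L)
  expect_true(all(diff(kept) <= 0))
})

test_that("calls below min_sv_len are suppressed", {
  g <- simulate_reference_genome(30000, 1, 0.5, seed = 14)
  s <- unclass(g)[[1]]
  q <- paste0(substr(s, 1, 15000), substr(s, 15041, nchar(s)))  # 40 bp deletion
  bl <- anchor_align(g, genome_assembly(c(contig_1 = q)), min_chain_bp = 30,
                     max_gap = 30)
  expect_equal(nrow(call_svs(bl, min_sv_len = 50)), 0L)
  expect_equal(nrow(call_svs(bl, min_sv_len = 30)), 1L)
})

test_that("planted truth is recovered and reciprocity/conservation hold", {
  fx <- make_sv_fixture(length_bp = 2e5, n_svs = 40)
  calls <- call_svs(anchor_align(fx$ref, fx$query))
  cmp <- compare_to_truth(calls, fx$truth)
  expect_gte(cmp$recall[["overall"]], 0.95)
  expect_gte(cmp$precision[["overall"]], 0.95)

  # per-type counts equal planted counts on clean data
  sm <- summarize_svs(calls)
  expect_equal(unname(sm$counts[c("insertion", "deletion", "inversion")]),
               unname(as.vector(table(factor(fx$truth$sv_type,
                                             c("insertion", "deletion", "inversion"))))))

  # swapping genomes maps insertions <-> deletions with identical lengths
  rev_calls <- call_svs(anchor_align(fx$query, fx$ref))
  expect_equal(sort(rev_calls$length_bp[rev_calls$sv_type == "deletion"]),
               sort(calls$length_bp[calls$sv_type == "insertion"]))
  expect_equal(sort(rev_calls$length_bp[rev_calls$sv_type == "insertion"]),
               sort(calls$length_bp[calls$sv_type == "deletion"]))
  expect_equal(sum(rev_calls$sv_type == "inversion"),
               sum(calls$sv_type == "inversion"))

  # net inserted minus deleted length equals the genome size difference
  expect_equal(sum(calls$length_bp[calls$sv_type == "insertion"]) -
                 sum(calls$length_bp[calls$sv_type == "deletion"]),
               genome_size(fx$query) - genome_size(fx$ref))
})

test_that("SV rate per Mb is simple normalisation of retained calls", {
  calls <- data.frame(sv_id = sprintf("sv%02d", 1:12),
                      filtered = rep(c(FALSE, TRUE), c(10, 2)))
  expect_equal(sv_rate_per_mb(calls, 2e6), 5)
  expect_equal(sv_rate_per_mb(calls[0, ], 2e6), 0)
  expect_equal(sv_rate_per_mb(data.frame(filtered = rep(FALSE, 33)), 1976543),
               33 * 1e6 / 1976543)
  expect_error(sv_rate_per_mb(calls, 0), "genome_size")
})

test_that("summaries partition retained calls by type and large class", {
  empty <- data.frame(sv_type = character(0), length_bp = integer(0),
                      filtered = logical(0))
  sm <- summarize_svs(empty)
  expect_true(all(sm$counts == 0))

  calls <- data.frame(sv_type = rep("insertion", 3),
                      length_bp = c(100, 600, 700), filtered = FALSE)
  sm <- summarize_svs(calls)
  expect_equal(unname(sm$large_fraction[["insertion"]]), 2 / 3)
})

test_that("PAF round-trip feeds the caller identically to native blocks", {
  fx <- make_sv_fixture(length_bp = 5e4, n_svs = 10)
  bl <- anchor_align(fx$ref, fx$query)
  paf <- tempfile(fileext = ".paf")
  ql <- attr(bl, "query_lengths"); rl <- attr(bl, "ref_lengths")
  writeLines(sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t60",
                     bl$query_contig, ql[bl$query_contig], bl$query_start,
                     bl$query_end, bl$strand, bl$ref_contig,
                     rl[bl$ref_contig], bl$ref_start, bl$ref_end,
                     bl$n_matches, bl$ref_end - bl$ref_start), paf)
  bl2 <- read_paf_blocks(paf)
  expect_equal(call_svs(bl2)[, 1:10], call_svs(bl)[, 1:10])
})
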