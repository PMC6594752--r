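test_that("seed_bins finds significant bins, respects direction, concatenates runs", {
  pair <- mk_block_pair(len = 4000L, block = c(1000L, 1300L))
  seeds <- seed_bins(pair$a, pair$b, 100, 0.05, "A_greater")
  expect_equal(nrow(seeds), 1L)
  expect_equal(seeds$start, 1000L)   # three adjacent significant bins -> one candidate
  expect_equal(seeds$end, 1300L)
  # wrong direction: nothing
  expect_equal(nrow(seed_bins(pair$a, pair$b, 100, 0.05, "B_greater")), 0L)
  # swapped samples with swapped direction give the same region
  swapped <- seed_bins(pair$b, pair$a, 100, 0.05, "B_greater")
  expect_equal(swapped[, .(chrom, start, end)], seeds[, .(chrom, start, end)])
})

test_that("filter_candidates keeps whole-region diff >= 0.2 inclusively", {
  cand <- data.table(chrom = "chr1", start = c(0L, 100L, 200L),
                     end = c(100L, 200L, 300L), diff = c(0.25, 0.19, 0.2))
  expect_equal(filter_candidates(cand, 0.2)$start, c(0L, 200L))
  expect_equal(nrow(filter_candidates(cand[0], 0.2)), 0L)
})

test_that("merge_regions obeys the inclusive gap rule at the boundary", {
  m <- merge_regions(mk_regions(c(100, 340), c(150, 390)), 200)
  expect_equal(nrow(m), 1L)           # gap 190 merges
  expect_equal(c(m$start, m$end), c(100L, 390L))
  m2 <- merge_regions(mk_regions(c(100, 350), c(150, 400)), 200)
  expect_equal(nrow(m2), 1L)          # gap exactly 200 merges (inclusive)
  m3 <- merge_regions(mk_regions(c(100, 351), c(150, 401)), 200)
  expect_equal(nrow(m3), 2L)          # gap 201 does not
  single <- merge_regions(mk_regions(500, 600), 200)
  expect_equal(c(single$start, single$end), c(500L, 600L))
})

test_that("merge_regions is idempotent and order-invariant", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(2:25, 1)
    starts <- sort(sample(0:5000, n))
    regs <- data.table(chrom = sample(c("chr1", "chr2"), n, TRUE),
                       start = starts, end = starts + sample(20:150, n, TRUE))
    m1 <- merge_regions(regs, 100)
    expect_equal(merge_regions(m1, 100)[, .(chrom, start, end)],
                 m1[, .(chrom, start, end)])
    shuffled <- regs[sample(.N)]
    expect_equal(merge_regions(shuffled, 100)[, .(chrom, start, end)],
                 m1[, .(chrom, start, end)])
  }
})

test_that("merged statistics are recomputed over the whole span from raw counts", {
  # two candidate fragments with an intervening unmethylated-in-A stretch:
  # span recomputation must include the gap's counts
  pos <- seq.int(0L, 499L, by = 10L)
  a_p <- ifelse(pos < 100 | pos >= 300, 0.9, 0.5)   # gap [100,300) lower in A
  a <- mk_meth(data.table(chrom = "chr1", pos = pos, strand = "+", context = "CG",
                          n_meth = as.integer(round(20 * a_p)),
                          n_unmeth = as.integer(20 - round(20 * a_p))),
               "A", c(chr1 = 500))
  b <- mk_meth(data.table(chrom = "chr1", pos = pos, strand = "+", context = "CG",
                          n_meth = 2L, n_unmeth = 18L), "B", c(chr1 = 500))
  frags <- mk_regions(c(0, 300), c(100, 500))
  merged <- merge_regions(frags, 300, a, b)
  expect_equal(nrow(merged), 1L)
  whole <- region_stats(mk_regions(0, 500), a, b)
  expect_equal(merged$frac_a, whole$frac_a)
  expect_equal(merged$p, whole$p)
  # pooled fraction reflects the gap (0.5 stretch pulls it below 0.9)
  expect_lt(merged$frac_a, 0.9)
})

test_that("finalize_dmrs applies length, diff and p gates as printed", {
  pair <- mk_block_pair(len = 2000L, block = c(500L, 900L))
  # 90 bp region: dropped on length despite huge signal
  short <- finalize_dmrs(mk_regions(500, 590), pair$a, pair$b,
                         min_len = 100, min_diff = 0.2, p_max = 0.01)
  expect_equal(nrow(short), 0L)
  ok <- finalize_dmrs(mk_regions(500, 900), pair$a, pair$b)
  expect_equal(nrow(ok), 1L)
  expect_gt(ok$diff, 0.2)
  # diff gate is strict: planted diff exactly 0.2 fails "> 0.2"
  flat <- mk_block_pair(len = 2000L, p_a = 0.5, p_b = 0.3, block = c(0L, 2000L))
  at_gate <- finalize_dmrs(mk_regions(500, 900), flat$a, flat$b)
  expect_equal(nrow(at_gate), 0L)
})

test_that("procedure A recovers a planted block and is silent on null input", {
  pair <- mk_block_pair(len = 8000L, p_a = 0.9, p_b = 0.3,
                        block = c(3000L, 3400L))
  dmrs <- call_dme_targets(pair$a, pair$b)
  expect_equal(nrow(dmrs), 1L)
  ovl <- min(dmrs$end, 3400) - max(dmrs$start, 3000)
  expect_gte(ovl / 400, 0.8)
  # identical methylomes: nothing
  expect_equal(nrow(call_dme_targets(pair$a, pair$a)), 0L)
  # block below the candidate diff gate: nothing
  weak <- mk_block_pair(len = 8000L, p_a = 0.9, p_b = 0.8, block = c(3000L, 3400L))
  expect_equal(nrow(call_dme_targets(weak$a, weak$b)), 0L)
})

test_that("procedure C equals procedure A with samples swapped", {
  pair <- mk_block_pair(len = 6000L, p_a = 0.9, p_b = 0.3, block = c(2000L, 2500L))
  # hypermethylation in "h1_vc" relative to "wt_vc"
  hyper <- call_h1_hyperdmrs(pair$a, pair$b)
  direct <- call_dme_targets(pair$a, pair$b)
  expect_equal(hyper, direct)
})

test_that("DME sites: seeds above 0.5, merge within 200 bp, site gates, anchors", {
  # two strong valleys 150 bp apart merge into one site
  pos <- seq.int(0L, 1999L, by = 10L)
  p_b <- rep(0.9, length(pos))
  p_b[pos >= 500 & pos < 600] <- 0.2
  p_b[pos >= 750 & pos < 850] <- 0.2
  a <- mk_meth(data.table(chrom = "chr1", pos = pos, strand = "+", context = "CG",
                          n_meth = 18L, n_unmeth = 2L), "A", c(chr1 = 2000))
  b <- mk_meth(data.table(chrom = "chr1", pos = pos, strand = "+", context = "CG",
                          n_meth = as.integer(round(20 * p_b)),
                          n_unmeth = as.integer(20 - round(20 * p_b))),
               "B", c(chr1 = 2000))
  sites <- call_dme_sites(a, b)
  expect_equal(nrow(sites), 1L)
  expect_lte(sites$start, 500L)
  expect_gte(sites$end, 850L)
  expect_gt(sites$diff, 0.2)
  expect_lt(sites$p, 1e-4)
  # uniform diff 0.4 never seeds (seed gate is 0.5)
  mild <- mk_block_pair(len = 2000L, p_a = 0.9, p_b = 0.5, block = c(0L, 2000L))
  expect_equal(nrow(call_dme_sites(mild$a, mild$b)), 0L)
})

test_that("anchor is the most demethylated qualifying cytosine, leftmost on ties", {
  mk_pair_site <- function(b_meth) {
    pos <- seq.int(0L, 199L, by = 20L)
    a <- mk_meth(data.table(chrom = "chr1", pos = pos, strand = "+", context = "CG",
                            n_meth = 15L, n_unmeth = 0L), "A", c(chr1 = 200))
    b <- mk_meth(data.table(chrom = "chr1", pos = pos, strand = "+", context = "CG",
                            n_meth = b_meth, n_unmeth = 15L - b_meth),
                 "B", c(chr1 = 200))
    list(a = a, b = b)
  }
  # site fractions in B: one clear minimum at pos 80
  bm <- c(8L, 8L, 8L, 8L, 1L, 8L, 8L, 8L, 8L, 8L)
  pr <- mk_pair_site(bm)
  anc <- anchor_cytosine(mk_regions(0, 200), pr$a, pr$b)
  expect_equal(anc$anchor_pos, 80L)
  expect_equal(anc$anchor_diff, 1 - 1 / 15)
  # tie at pos 40 and 120 -> leftmost wins
  bm_tie <- c(8L, 8L, 1L, 8L, 8L, 8L, 1L, 8L, 8L, 8L)
  pr2 <- mk_pair_site(bm_tie)
  expect_equal(anchor_cytosine(mk_regions(0, 200), pr2$a, pr2$b)$anchor_pos, 40L)
})

test_that("anchor coverage gate excludes the best cytosine when undersequenced", {
  pos <- c(50L, 100L)
  a <- mk_meth(data.table(chrom = "chr1", pos = pos, strand = "+", context = "CG",
                          n_meth = c(8L, 15L), n_unmeth = c(0L, 0L)),
               "A", c(chr1 = 200))
  b <- mk_meth(data.table(chrom = "chr1", pos = pos, strand = "+", context = "CG",
                          n_meth = c(0L, 3L), n_unmeth = c(8L, 12L)),
               "B", c(chr1 = 200))
  # pos 50 has the larger diff (1.0) but coverage 8 < 10: pos 100 wins
  anc <- anchor_cytosine(mk_regions(0, 200), a, b)
  expect_equal(anc$anchor_pos, 100L)
  # no qualifying cytosine at all -> NA anchor
  none <- anchor_cytosine(mk_regions(150, 200), a, b)
  expect_true(is.na(none$anchor_pos))
})

test_that("raising p_max or lowering min_diff never loses final DMRs", {
  set.seed(21)
  pos <- seq.int(0L, 9999L, by = 12L)
  pa <- rbinom(length(pos), 15, 0.75)
  pb <- rbinom(length(pos), 15, pmax(0.1, 0.75 - 0.45 * sin(pos / 400)^2))
  a <- mk_meth(data.table(chrom = "chr1", pos = pos, strand = "+", context = "CG",
                          n_meth = pa, n_unmeth = 15L - pa), "A", c(chr1 = 10000))
  b <- mk_meth(data.table(chrom = "chr1", pos = pos, strand = "+", context = "CG",
                          n_meth = pb, n_unmeth = 15L - pb), "B", c(chr1 = 10000))
  cand <- filter_candidates(seed_bins(a, b, 100, 0.05, "A_greater"), 0.2)
  merged <- merge_regions(cand, 300, a, b)
  n_base <- nrow(finalize_dmrs(merged, a, b, 100, 0.2, 0.01))
  expect_gte(nrow(finalize_dmrs(merged, a, b, 100, 0.2, 0.05)), n_base)
  expect_gte(nrow(finalize_dmrs(merged, a, b, 100, 0.1, 0.01)), n_base)
})

test_that("every final region passes an independent gate audit", {
  pair <- mk_block_pair(len = 8000L, p_a = 0.9, p_b = 0.25, block = c(2000L, 2600L))
  dmrs <- call_dme_targets(pair$a, pair$b)
  audit <- audit_dmr_gates(dmrs, pair$a, pair$b)
  expect_true(all(audit$pass))
})
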