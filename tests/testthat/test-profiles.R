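test_that("ends_profile is flat on uniform methylation and reflects minus strand", {
  m <- mk_uniform(len = 10000L, step = 10L, p = 0.8, cov = 20L)
  el_plus <- data.table(id = "e1", chrom = "chr1", start = 4000L, end = 6000L,
                        strand = "+", tss = 4000L, tts = 5999L)
  prof <- ends_profile(el_plus, m, "CG", bin_bp = 100, flank_bp = 1000)
  expect_true(all(abs(prof$value - 0.8) < 1e-9))   # deterministic counts: exactly flat
  expect_equal(sort(unique(prof$alignment)), c("TSS", "TTS"))
  expect_equal(range(prof$offset), c(-1000L, 900L))
  # the same element on the minus strand gives the identical profile (the
  # fixture is symmetric, so reflection must leave values unchanged)
  el_minus <- copy(el_plus)[, `:=`(strand = "-", tss = 5999L, tts = 4000L)]
  prof_m <- ends_profile(el_minus, m, "CG", bin_bp = 100, flank_bp = 1000)
  expect_equal(prof_m$value, prof$value)
})

test_that("ends_profile pools counts across elements (pooling invariance)", {
  m <- mk_uniform(len = 20000L, step = 10L, p = 0.6, cov = 10L)
  els <- data.table(id = c("a", "b"), chrom = "chr1",
                    start = c(2000L, 12000L), end = c(4000L, 14000L),
                    strand = "+", tss = c(2000L, 12000L), tts = c(3999L, 13999L))
  both <- ends_profile(els, m, "CG", 100, 1000)
  pa <- ends_profile(els[1], m, "CG", 100, 1000)
  pb <- ends_profile(els[2], m, "CG", 100, 1000)
  joined <- merge(pa, pb, by = c("alignment", "offset"))
  joined[, pooled := (n_meth.x + n_meth.y) / (n_total.x + n_total.y)]
  cmp <- merge(both, joined, by = c("alignment", "offset"))
  expect_equal(cmp$value, cmp$pooled)
  expect_true(all(both$n_elements == 2L))
})

test_that("a planted TSS valley puts the profile minimum next to the TSS", {
  cfg <- sim_config(seed = 303, chrom_lengths = c(chr1 = 400000L),
                    n_te = 8L, n_gene = 0L,
                    group_counts = c(I = 0L, II = 4L, III = 4L, IV = 0L),
                    dme_n = 0L)
  bundle <- simulate_bundle(cfg)
  tes <- bundle$elements[id %in% bundle$truth_sites$te_id]
  prof <- ends_profile(tes, bundle$vc, "CG", bin_bp = 100, flank_bp = 1000)
  tss_prof <- prof[alignment == "TSS" & !is.na(value)]
  min_off <- tss_prof[which.min(value), offset]
  expect_lte(abs(min_off), 100)   # minimum in a TSS-adjacent bin
  # sperm shows no such dip: at the TSS-adjacent bins it stays near the
  # heterochromatic baseline while the VC drops far below it
  prof_sp <- ends_profile(tes, bundle$sperm, "CG", bin_bp = 100, flank_bp = 1000)
  near <- function(p) p[alignment == "TSS" & offset %in% c(-100L, 0L), value]
  expect_true(all(near(prof_sp) > 0.8))
  expect_true(all(near(prof) < near(prof_sp) - 0.3))
})

test_that("anchor_profile deepens with planted depth and reports gaps as NA", {
  # two groups of anchored sites with different planted depths
  pos <- seq.int(0L, 3999L, by = 10L)
  depth <- function(anchors, delta) {
    p <- rep(0.9, length(pos))
    for (a in anchors) {
      d <- delta * pmax(0, 1 - abs(pos - a) / 100)
      p <- pmin(p, 0.9 - d)
    }
    p
  }
  pb <- depth(c(500L, 1500L), 0.7)
  pb <- pmin(pb, depth(c(2500L, 3500L), 0.35) + 0)
  a <- mk_meth(data.table(chrom = "chr1", pos = pos, strand = "+", context = "CG",
                          n_meth = 18L, n_unmeth = 2L), "A", c(chr1 = 4000))
  b <- mk_meth(data.table(chrom = "chr1", pos = pos, strand = "+", context = "CG",
                          n_meth = as.integer(round(20 * pb)),
                          n_unmeth = as.integer(20 - round(20 * pb))),
               "B", c(chr1 = 4000))
  sites <- data.table(chrom = "chr1",
                      start = c(400L, 1400L, 2400L, 3400L),
                      end = c(600L, 1600L, 2600L, 3600L),
                      anchor_pos = c(500L, 1500L, 2500L, 3500L),
                      group = c(1L, 1L, 2L, 2L))
  prof <- anchor_profile(sites, a, b, bin_bp = 10, flank_bp = 200)
  d1 <- prof[group == 1 & offset == 0, diff]
  d2 <- prof[group == 2 & offset == 0, diff]
  expect_gt(d1, d2)          # deeper planted group is deeper at the anchor
  expect_gt(d2, 0.1)
  # uncovered bins are NA, not zero: restrict to a window with no sites
  sparse <- anchor_profile(data.table(chrom = "chr1", start = 0L, end = 10L,
                                      anchor_pos = 5L, group = 1L),
                           mk_meth(data.table(chrom = "chr1", pos = 3L, strand = "+",
                                              context = "CG", n_meth = 5L, n_unmeth = 5L),
                                   "A", c(chr1 = 4000)),
                           mk_meth(data.table(chrom = "chr1", pos = 900L, strand = "+",
                                              context = "CG", n_meth = 5L, n_unmeth = 5L),
                                   "B", c(chr1 = 4000)),
                           bin_bp = 10, flank_bp = 50)
  expect_true(all(is.na(sparse[offset != -10, diff])))
  # sites without anchors are skipped with a message
  expect_message(
    anchor_profile(data.table(chrom = "chr1", start = 0L, end = 10L,
                              anchor_pos = NA_integer_, group = 1L),
                   a, b, bin_bp = 10, flank_bp = 50),
    "without an anchor")
})

test_that("region_mean_score is the length-weighted mean and NA off-track", {
  tr <- data.table(chrom = "chr1", start = c(0L, 100L), end = c(100L, 200L),
                   score = c(2.0, 6.0))
  expect_equal(region_mean_score(tr, mk_regions(10, 60)), 2.0)
  expect_equal(region_mean_score(tr, mk_regions(50, 150)), 4.0)
  expect_equal(region_mean_score(tr, mk_regions(90, 190)),
               (2.0 * 10 + 6.0 * 90) / 100)
  expect_true(is.na(region_mean_score(tr, mk_regions(500, 600))))
  expect_equal(region_mean_score(tr, mk_regions(c(10, 50), c(60, 150))),
               c(2.0, 4.0))
})
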