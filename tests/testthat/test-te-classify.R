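test_that("superloci are refined by TE overlap and leaf CG methylation", {
  leaf <- mk_uniform(len = 10000L, step = 10L, p = 0.85, cov = 20L)
  # make [4000, 6000) unmethylated in leaves (a TE-like gene)
  leaf$sites[pos >= 4000 & pos < 6000, `:=`(n_meth = 1L, n_unmeth = 19L)]
  sl <- data.table(id = c("sl1", "sl2", "sl3"), chrom = "chr1",
                   start = c(1000L, 4200L, 8000L), end = c(2000L, 5200L, 9000L),
                   strand = "+", tss = c(1000L, 4200L, 8000L),
                   tts = c(1999L, 5199L, 8999L))
  tes <- mk_regions(c(900, 4100), c(2100, 5300))
  tes[, id := c("te1", "te2")]
  kept <- refine_te_transcripts(sl, tes, leaf, min_cg = 0.7)
  # sl1: TE overlap + leaf CG 0.85 -> kept; sl2: TE overlap but leaf CG 0.05
  # -> excluded; sl3: no TE overlap -> excluded
  expect_equal(kept$id, "sl1")
  expect_gt(kept$leaf_cg, 0.7)
})

test_that("activation, expression and differential calls follow the printed gates", {
  expr <- data.table(id = paste0("te", 1:5),
                     tpm_pollen = c(10, 8, 50, 4, 6),
                     fold_change = c(6.0, 4.9, 100, 5.0, 2.0),
                     lrt_p = c(0.01, 0.001, 0.06, 0.04, 0.04))
  act <- call_activated_tes(expr, fc_min = 5, p_max = 0.05)
  # te1: fc 6, p 0.01 -> in; te2: fc 4.9 -> out; te3: p 0.06 -> out;
  # te4: fc exactly 5 ("at least five times") -> in; te5: fc 2 -> out
  expect_setequal(act, c("te1", "te4"))
  expr_na <- rbind(expr, data.table(id = "te6", tpm_pollen = 9,
                                    fold_change = 10, lrt_p = NA_real_))
  expect_message(act2 <- call_activated_tes(expr_na), "missing p")
  expect_setequal(act2, act)

  genes <- data.table(id = paste0("g", 1:3), tpm_pollen = c(5.1, 5.0, 0.2),
                      fold_change = 1, lrt_p = 0.5)
  expect_equal(call_expressed_genes(genes, 5), "g1")   # "more than five" is strict

  de <- data.table(id = paste0("e", 1:4), tpm_wt = 1,
                   fold_change = c(2.0, 0.4, 1.5, 3.0),
                   lrt_p = c(0.04, 0.01, 0.01, 0.5))
  res <- call_differential(de, fc_min = 2, p_max = 0.05)
  expect_equal(res$up, "e1")      # |fc| 2.0 at p 0.04 is differential
  expect_equal(res$down, "e2")    # fc 0.4 is the down direction
})

test_that("superfamily enrichment matches the enumeration oracle and flags depletion", {
  tes <- data.table(id = sprintf("te%02d", 1:40),
                    superfamily = rep(c("Gypsy", "Copia", "LINE", "SINE"), each = 10))
  # all 8 activated TEs are Gypsy
  act <- sprintf("te%02d", 1:8)
  enr <- superfamily_enrichment(act, tes)
  gy <- enr[superfamily == "Gypsy"]
  expect_equal(gy$p, stats::fisher.test(matrix(c(8, 0, 2, 30), 2))$p.value,
               tolerance = 1e-9)
  expect_equal(gy$direction, "enriched")
  expect_equal(enr[superfamily == "LINE", direction], "depleted")
  # no activated TEs: all p = 1
  none <- superfamily_enrichment(character(0), tes)
  expect_true(all(none$p == 1))
})

test_that("null activated sets give approximately nominal enrichment rate", {
  # activated TEs drawn uniformly: the per-family Fisher p should be
  # super-uniform (conservative), so p < 0.01 must be rare
  set.seed(5)
  tes <- data.table(id = sprintf("te%03d", 1:200),
                    superfamily = sample(c("Gypsy", "Copia", "LINE", "MuDR"),
                                         200, TRUE))
  hits <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    act <- sample(tes$id, 20)
    hits <- hits + sum(superfamily_enrichment(act, tes)$p < 0.01)
  }
  # 4 families x 200 draws at alpha 0.01 -> expect <= 8 under exact
  # uniformity; allow generous slack above that
  expect_lte(hits, 20L)
})

test_that("proximity flags use the inclusive 500 bp rule from the TSS point", {
  tes <- data.table(id = c("a", "b", "c"), chrom = "chr1",
                    start = c(950L, 950L, 950L), end = c(3000L, 3000L, 3000L),
                    strand = "+", tss = c(1000L, 1000L, 1000L))
  expect_true(proximity_flags(tes[1], mk_regions(990, 1100))$overlap)
  fl <- proximity_flags(tes[1], mk_regions(1500, 1600))
  expect_false(fl$overlap)
  expect_true(fl$within)                         # gap exactly 500, inclusive
  expect_equal(fl$dist, 500)
  fl2 <- proximity_flags(tes[1], mk_regions(1501, 1600))
  expect_false(fl2$within)                       # 501 bp away: both false
  # upstream side and translation invariance
  fl3 <- proximity_flags(tes[1], mk_regions(400, 500))
  expect_equal(fl3$dist, 501)
  shift <- 10000L
  fl_shift <- proximity_flags(copy(tes)[, `:=`(start = start + shift,
                                               end = end + shift,
                                               tss = tss + shift)],
                              mk_regions(1500 + shift, 1600 + shift))
  expect_equal(fl_shift$within, rep(TRUE, 3))
})

test_that("TSS heatmap applies per-context thresholds exactly", {
  # contexts engineered to planted pooled differences over [tss-500, tss+500)
  mk_ctx <- function(p_by_ctx, sample) {
    rows <- rbindlist(lapply(names(p_by_ctx), function(ctx) {
      pos <- seq.int(500L, 1499L, by = 20L) + switch(ctx, CG = 0L, CHG = 3L, CHH = 7L)
      data.table(chrom = "chr1", pos = pos, strand = "+", context = ctx,
                 n_meth = as.integer(round(200 * p_by_ctx[[ctx]])),
                 n_unmeth = as.integer(200 - round(200 * p_by_ctx[[ctx]])))
    }))
    mk_meth(rows, sample, c(chr1 = 3000))
  }
  te <- data.table(id = "te1", chrom = "chr1", start = 900L, end = 2500L,
                   strand = "+", tss = 1000L)
  # CG diff 0.25 (significant), CHG diff 0.05 (< 0.1), CHH diff 0.04 (< 0.05)
  a <- mk_ctx(c(CG = 0.80, CHG = 0.45, CHH = 0.14), "A")
  b <- mk_ctx(c(CG = 0.55, CHG = 0.40, CHH = 0.10), "B")
  hm <- tss_methylation_heatmap(te, a, b, halfwidth = 500)
  expect_true(hm$sig_cg)
  expect_false(hm$sig_chg)
  expect_false(hm$sig_chh)   # diff 0.04 below 0.05 no matter how small p is
  expect_true(hm$hypermeth)
  expect_equal(hm$diff_cg, 0.25, tolerance = 1e-9)
  # CG diff above threshold but p above 0.001 -> not significant
  low <- function(m, sample) mk_meth(data.table(chrom = "chr1", pos = 1200L,
                                                strand = "+", context = "CG",
                                                n_meth = m, n_unmeth = 20L - m),
                                     sample, c(chr1 = 3000))
  hm2 <- tss_methylation_heatmap(te, low(16L, "A2"), low(11L, "B2"))
  expect_equal(hm2$diff_cg, 0.25, tolerance = 1e-9)
  expect_gt(hm2$p_cg, 0.001)
  expect_false(hm2$sig_cg)
})

test_that("classify_groups implements the mechanistic rule table exhaustively", {
  flags <- CJ(h1_repressed = c(TRUE, FALSE),
              dme_target_within_500bp = c(TRUE, FALSE),
              hypermeth_in_h1 = c(TRUE, FALSE),
              hyperdmr_within_500bp = c(TRUE, FALSE),
              dme_hyper_within_500bp = c(TRUE, FALSE))
  flags <- flags[!(dme_hyper_within_500bp & !(dme_target_within_500bp & hyperdmr_within_500bp))]
  flags[, id := sprintf("te%02d", .I)]
  out <- classify_groups(flags)
  # spot checks of the published rules
  expect_equal(out[h1_repressed & hypermeth_in_h1 & !dme_target_within_500bp][1, group], "II")
  expect_equal(out[!h1_repressed & dme_target_within_500bp][1, group], "I")
  expect_equal(unique(out[h1_repressed & dme_target_within_500bp &
                            !hypermeth_in_h1 & !hyperdmr_within_500bp, group]), "III")
  expect_equal(unique(out[h1_repressed & !dme_target_within_500bp &
                            !hypermeth_in_h1 & !dme_hyper_within_500bp, group]), "IV")
  expect_equal(unique(out[!h1_repressed & !dme_target_within_500bp, group]),
               "unclassified")
  # total and deterministic: every combination gets exactly one label
  expect_true(all(out$group %in% c("I", "II", "III", "IV", "unclassified")))
  expect_equal(classify_groups(flags)$group, out$group)
  expect_error(classify_groups(flags[, !"hypermeth_in_h1"]), "hypermeth_in_h1")
})
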