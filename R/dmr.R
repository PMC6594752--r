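# Region calling: Procedure A (VC DME targets: CG hypomethylation in the VC
# relative to sperm), Procedure C (H1 hyperDMRs: the same gates comparing the
# H1-expressing VC against the wild-type VC), and Procedure B (strict "DME
# sites" seeded from 50-bp windows, with a most-demethylated-cytosine anchor
# and an H3K9me2 group per site). All region procedures are CG-context.

# Pooled counts / fraction / diff / Fisher p of both samples over arbitrary
# spans, recomputed from the raw cytosine counts (not aggregated from parts),
# so intervening non-seed sequence inside a merged span counts.
region_stats <- function(regions, meth_a, meth_b, context_ = "CG") {
  reg <- as.data.table(regions)[, .(chrom = as.character(chrom),
                                    start = as.integer(start),
                                    end = as.integer(end))]
  reg[, rid := .I]
  pool <- function(meth, label) {
    key <- copy(reg)[, `:=`(istart = start, iend = end - 1L)]
    setkey(key, chrom, istart, iend)
    s <- meth$sites[context == context_, .(chrom, istart = pos, iend = pos,
                                           n_meth, n_unmeth)]
    if (nrow(s) == 0L) {
      agg <- data.table(rid = reg$rid, m = 0L, u = 0L)
    } else {
      ov <- foverlaps(s, key, by.x = c("chrom", "istart", "iend"), type = "within", nomatch = NULL)
      agg <- ov[, .(m = sum(n_meth), u = sum(n_unmeth)), by = rid]
      agg <- agg[data.table(rid = reg$rid), on = "rid"]
      agg[is.na(m), `:=`(m = 0L, u = 0L)]
    }
    setnames(agg, c("m", "u"), paste0(c("n_meth_", "n_unmeth_"), label))
    agg
  }
  out <- Reduce(function(x, y) merge(x, y, by = "rid"),
                list(reg, pool(meth_a, "a"), pool(meth_b, "b")))
  setorder(out, rid)
  out[, `:=`(
    frac_a = fifelse(n_meth_a + n_unmeth_a > 0L, n_meth_a / (n_meth_a + n_unmeth_a), NA_real_),
    frac_b = fifelse(n_meth_b + n_unmeth_b > 0L, n_meth_b / (n_meth_b + n_unmeth_b), NA_real_))]
  out[, `:=`(diff = frac_a - frac_b,
             p = fisher_exact_2x2(n_meth_a, n_unmeth_a, n_meth_b, n_unmeth_b),
             length = end - start)]
  out[, rid := NULL]
  out[]
}

#' Seed candidate DMRs from binned Fisher tests
#'
#' Tiles the genome into disjoint bins (default 100 bp), Fisher-tests the
#' pooled CG counts of the two samples per bin, keeps bins with p below
#' `p_seed` and a difference in the requested direction, and concatenates runs
#' of adjacent kept bins into candidate regions. This binned seeding stage
#' feeds the candidate filter, merge and final gates of the region procedures.
#'
#' @param meth_a,meth_b [methylome]s (A is the putatively hypermethylated
#'   sample under `direction = "A_greater"`).
#' @param bin_bp Bin width.
#' @param p_seed Per-bin Fisher p cutoff.
#' @param direction `"A_greater"` (keep bins with frac A > frac B) or
#'   `"B_greater"`.
#' @param context Sequence context (CG for all published procedures).
#' @return `data.table` of candidate regions with pooled counts and stats.
#' @export
seed_bins <- function(meth_a, meth_b,
                      bin_bp = default_thresholds()$seed_bin_bp,
                      p_seed = default_thresholds()$seed_p,
                      direction = c("A_greater", "B_greater"),
                      context = "CG") {
  direction <- match.arg(direction)
  tab <- window_table(meth_a, meth_b, bin_bp, context)
  if (nrow(tab) == 0L) {
    warning("no ", context, " sites in either methylome; no seeds")
    return(empty_regions())
  }
  keep <- tab[!is.na(diff) & p < p_seed &
                (if (direction == "A_greater") diff > 0 else diff < 0)]
  if (nrow(keep) == 0L) return(empty_regions())
  # concatenate runs of adjacent kept bins
  setorder(keep, chrom, start)
  keep[, run := cumsum(c(1L, as.integer(chrom[-1] != chrom[-.N] |
                                          start[-1] != end[-.N])))]
  cand <- keep[, .(chrom = chrom[1], start = min(start), end = max(end)),
               by = run][, run := NULL]
  out <- region_stats(cand, meth_a, meth_b, context)
  out[, provenance := "candidate"]
  out[]
}

empty_regions <- function() {
  data.table(chrom = character(), start = integer(), end = integer(),
             n_meth_a = integer(), n_unmeth_a = integer(),
             n_meth_b = integer(), n_unmeth_b = integer(),
             frac_a = numeric(), frac_b = numeric(), diff = numeric(),
             p = numeric(), length = integer(), provenance = character())
}

#' Filter candidate regions on whole-region methylation difference
#'
#' Keeps candidates whose whole-region pooled fractional-methylation
#' difference is at least `min_diff` (inclusive).
#'
#' @param candidates Output of [seed_bins()].
#' @param min_diff Minimum pooled difference (default 0.2).
#' @return Filtered `data.table`.
#' @export
filter_candidates <- function(candidates, min_diff = default_thresholds()$candidate_min_diff) {
  out <- as.data.table(candidates)[!is.na(diff) & diff >= min_diff]
  out[]
}

#' Merge nearby regions
#'
#' Regions whose gap to the previous region (`next start − previous end`) is
#' at most `max_gap_bp` (inclusive) are unioned into their joint span. When
#' the methylomes are supplied, pooled statistics of merged regions are
#' recomputed from raw counts across the whole merged span; otherwise counts
#' of the parts are summed (sufficient when the parts tile the span, e.g.
#' pure interval arithmetic in tests). Unsorted input is sorted internally.
#' Idempotent: merging an already-merged set changes nothing.
#'
#' @param regions `data.table` with `chrom`, `start`, `end` (and count columns
#'   if present).
#' @param max_gap_bp Maximum gap to merge across, inclusive.
#' @param meth_a,meth_b Optional [methylome]s for recomputation.
#' @param context Sequence context for recomputation.
#' @return Merged `data.table`.
#' @export
merge_regions <- function(regions, max_gap_bp, meth_a = NULL, meth_b = NULL,
                          context = "CG") {
  reg <- as.data.table(regions)
  if (nrow(reg) <= 1L) {
    out <- copy(reg)
  } else {
    setorder(reg, chrom, start)
    # gap of a region is its start minus the rightmost end seen so far on the
    # chromosome (-Inf at each chromosome's first region, forcing a new group)
    reg[, grp := cumsum(start - cummax_by_run(end, chrom) > max_gap_bp)]
    count_cols <- intersect(c("n_meth_a", "n_unmeth_a", "n_meth_b", "n_unmeth_b"),
                            names(reg))
    out <- reg[, c(.(chrom = chrom[1], start = min(start), end = max(end)),
                   lapply(.SD, sum)),
               by = grp, .SDcols = count_cols][, grp := NULL]
  }
  if (!is.null(meth_a) && !is.null(meth_b)) {
    out <- region_stats(out[, .(chrom, start, end)], meth_a, meth_b, context)
  } else if (all(c("n_meth_a", "n_unmeth_a", "n_meth_b", "n_unmeth_b") %in% names(out))) {
    out[, `:=`(
      frac_a = fifelse(n_meth_a + n_unmeth_a > 0, n_meth_a / (n_meth_a + n_unmeth_a), NA_real_),
      frac_b = fifelse(n_meth_b + n_unmeth_b > 0, n_meth_b / (n_meth_b + n_unmeth_b), NA_real_),
      length = end - start)]
    out[, diff := frac_a - frac_b]
    out[, p := fisher_exact_2x2(n_meth_a, n_unmeth_a, n_meth_b, n_unmeth_b)]
  }
  if (nrow(out)) out[, provenance := "merged"]
  setorder(out, chrom, start)
  out[]
}

# running maximum of prior ends within each chromosome run, shifted by one:
# gap for row i is start[i] - max(end[1..i-1]) within the chromosome, which for
# sorted possibly-nested regions is the correct "distance to anything before".
cummax_by_run <- function(end, chrom) {
  prev <- shift(end)
  run_new <- c(TRUE, chrom[-1] != chrom[-length(chrom)])
  out <- numeric(length(end))
  cur <- -Inf
  for (i in seq_along(end)) {
    if (run_new[i]) cur <- -Inf
    out[i] <- cur
    cur <- max(cur, end[i])
  }
  out
}

#' Apply the final DMR gates
#'
#' Recomputes pooled statistics over each merged span from raw counts and
#' keeps regions that (i) cover at least `min_len` bp, (ii) have pooled
#' difference strictly greater than `min_diff`, and (iii) have two-sided
#' Fisher p strictly below `p_max`.
#'
#' @param merged Merged regions (`chrom`, `start`, `end`).
#' @param meth_a,meth_b [methylome]s.
#' @param min_len Minimum length in bp (default 100).
#' @param min_diff Minimum pooled difference, strict (default 0.2).
#' @param p_max Fisher p cutoff, strict (default 0.01).
#' @param context Sequence context.
#' @return Final `data.table` of regions, sorted by (chrom, start).
#' @export
finalize_dmrs <- function(merged, meth_a, meth_b,
                          min_len = default_thresholds()$final_min_len_bp,
                          min_diff = default_thresholds()$final_min_diff_a,
                          p_max = default_thresholds()$final_p_a,
                          context = "CG") {
  stopifnot(p_max > 0, p_max < 1)
  if (nrow(merged) == 0L) return(empty_regions())
  st <- region_stats(as.data.table(merged)[, .(chrom, start, end)],
                     meth_a, meth_b, context)
  out <- st[length >= min_len & !is.na(diff) & diff > min_diff & p < p_max]
  out[, provenance := "final"]
  setorder(out, chrom, start)
  out[]
}

#' Call CG-hypomethylated DMRs (VC DME targets / H1 hyperDMRs)
#'
#' The full region procedure: binned Fisher seeding (100-bp bins, p < 0.05)
#' with sample A hypermethylated, candidate filter (whole-region difference at
#' least 0.2), merging within 300 bp, and the final gates (length at least
#' 100 bp, difference > 0.2, Fisher p < 0.01), all on pooled CG counts.
#'
#' Called with A = sperm and B = wild-type VC this yields VC DME targets;
#' [call_h1_hyperdmrs()] applies the identical criteria with A = the VC of
#' H1-expressing plants and B = the wild-type VC.
#'
#' @param meth_a,meth_b [methylome]s; A is the hypermethylated sample.
#' @param cfg Threshold registry, see [default_thresholds()].
#' @return `data.table` of final regions, deterministic (chrom, start) order.
#' @export
call_dme_targets <- function(meth_a, meth_b, cfg = default_thresholds()) {
  cand <- seed_bins(meth_a, meth_b, cfg$seed_bin_bp, cfg$seed_p, "A_greater")
  cand <- filter_candidates(cand, cfg$candidate_min_diff)
  merged <- merge_regions(cand, cfg$merge_gap_a_bp, meth_a, meth_b)
  finalize_dmrs(merged, meth_a, meth_b, cfg$final_min_len_bp,
                cfg$final_min_diff_a, cfg$final_p_a)
}

#' @rdname call_dme_targets
#' @param meth_h1_vc Methylome of the VC from H1-expressing plants.
#' @param meth_wt_vc Methylome of the wild-type VC.
#' @export
call_h1_hyperdmrs <- function(meth_h1_vc, meth_wt_vc, cfg = default_thresholds()) {
  call_dme_targets(meth_h1_vc, meth_wt_vc, cfg)
}

#' Call strict DME sites with anchors (Procedure B)
#'
#' Individual hypomethylation sites: 50-bp windows with CG difference
#' (sperm − VC) > 0.5 and Fisher p < 0.001 are the seeds; seeds within 200 bp
#' are merged; merged sites are retained when the whole-site pooled difference
#' is > 0.2 with Fisher p < 1e-4. Each retained site is annotated with its
#' most demethylated cytosine ([anchor_cytosine()]) and, when an H3K9me2
#' score track is given, the site's length-weighted mean score and its group
#' under the five-level stratification.
#'
#' @param meth_sperm,meth_vc [methylome]s of sperm and the wild-type VC.
#' @param cfg Threshold registry.
#' @param h3k9me2 Optional score track (`data.table` from [read_score_track()]).
#' @return `data.table` of sites with anchor and (optionally) group columns.
#' @export
call_dme_sites <- function(meth_sperm, meth_vc, cfg = default_thresholds(),
                           h3k9me2 = NULL) {
  tab <- window_table(meth_sperm, meth_vc, cfg$window_width_bp, "CG")
  seeds <- tab[!is.na(diff) & diff > cfg$site_seed_diff & p < cfg$site_seed_p,
               .(chrom, start, end)]
  merged <- merge_regions(seeds, cfg$merge_gap_b_bp, meth_sperm, meth_vc)
  if (nrow(merged) == 0L) {
    sites <- empty_regions()
  } else {
    st <- region_stats(merged[, .(chrom, start, end)], meth_sperm, meth_vc)
    sites <- st[!is.na(diff) & diff > cfg$site_final_diff & p < cfg$site_final_p]
    sites[, provenance := "final"]
  }
  setorder(sites, chrom, start)
  anchors <- anchor_cytosine(sites, meth_sperm, meth_vc, cfg)
  sites <- cbind(sites, anchors)
  if (!is.null(h3k9me2) && nrow(sites)) {
    sites[, h3k9me2_score := region_mean_score(h3k9me2, sites)]
    sites[, group := fifelse(is.finite(h3k9me2_score),
                             score_quantile_group(fifelse(is.finite(h3k9me2_score),
                                                          h3k9me2_score, 0),
                                                  cfg$h3k9me2_bounds),
                             NA_integer_)]
  }
  sites[]
}

#' Most demethylated cytosine of each site
#'
#' Within each site, among CG cytosines with per-cytosine difference
#' (sperm − VC) > 0.2, per-cytosine Fisher p < 0.001, and coverage of at
#' least 10 sequenced calls in each sample, returns the cytosine with the
#' greatest difference (ties broken by leftmost position); `NA` when no
#' cytosine qualifies.
#'
#' @param sites `data.table` with `chrom`, `start`, `end` (one row per site).
#' @param meth_sperm,meth_vc [methylome]s.
#' @param cfg Threshold registry (`anchor_min_diff`, `anchor_p`,
#'   `anchor_min_cov`).
#' @return `data.table` with one row per input site: `anchor_pos` (0-based),
#'   `anchor_diff`, `anchor_p`.
#' @export
anchor_cytosine <- function(sites, meth_sperm, meth_vc, cfg = default_thresholds()) {
  n <- nrow(sites)
  out <- data.table(anchor_pos = rep(NA_integer_, n),
                    anchor_diff = rep(NA_real_, n),
                    anchor_p = rep(NA_real_, n))
  if (n == 0L) return(out)
  reg <- as.data.table(sites)[, .(chrom, istart = as.integer(start),
                                  iend = as.integer(end) - 1L)]
  reg[, rid := .I]
  setkey(reg, chrom, istart, iend)
  grab <- function(meth) {
    meth$sites[context == "CG",
               .(chrom, istart = pos, iend = pos, strand, n_meth, n_unmeth)]
  }
  sp <- foverlaps(grab(meth_sperm), reg, by.x = c("chrom", "istart", "iend"), type = "within", nomatch = NULL)
  vc <- foverlaps(grab(meth_vc), reg, by.x = c("chrom", "istart", "iend"), type = "within", nomatch = NULL)
  cyt <- merge(sp[, .(rid, chrom, pos = i.istart, strand, m_a = n_meth, u_a = n_unmeth)],
               vc[, .(rid, chrom, pos = i.istart, strand, m_b = n_meth, u_b = n_unmeth)],
               by = c("rid", "chrom", "pos", "strand"))
  if (nrow(cyt) == 0L) return(out)
  cyt <- cyt[m_a + u_a >= cfg$anchor_min_cov & m_b + u_b >= cfg$anchor_min_cov]
  if (nrow(cyt) == 0L) return(out)
  cyt[, diff := m_a / (m_a + u_a) - m_b / (m_b + u_b)]
  cyt <- cyt[diff > cfg$anchor_min_diff]
  if (nrow(cyt) == 0L) return(out)
  cyt[, p := fisher_exact_2x2(m_a, u_a, m_b, u_b)]
  cyt <- cyt[p < cfg$anchor_p]
  if (nrow(cyt) == 0L) return(out)
  setorder(cyt, rid, -diff, pos)
  best <- cyt[, .SD[1], by = rid]
  out[best$rid, `:=`(anchor_pos = best$pos, anchor_diff = best$diff,
                     anchor_p = best$p)]
  out[]
}

#' Audit final regions against their gates
#'
#' Independently re-tests every emitted region from the raw cytosine counts:
#' recomputes pooled fractions, difference and Fisher p over the span and
#' checks length >= `min_len`, diff > `min_diff`, p < `p_max`. A sound caller
#' produces zero violations; the audit is the self-consistency check run by
#' the test-suite and the acceptance script.
#'
#' @param regions Final regions from a calling procedure.
#' @param meth_a,meth_b The same [methylome]s the procedure was run on.
#' @param min_len,min_diff,p_max The procedure's gates.
#' @param context Sequence context.
#' @return `data.table` with recomputed stats and a logical `pass` per region.
#' @export
audit_dmr_gates <- function(regions, meth_a, meth_b,
                            min_len = default_thresholds()$final_min_len_bp,
                            min_diff = default_thresholds()$final_min_diff_a,
                            p_max = default_thresholds()$final_p_a,
                            context = "CG") {
  if (nrow(regions) == 0L) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      pass = logical()))
  }
  st <- region_stats(as.data.table(regions)[, .(chrom, start, end)],
                     meth_a, meth_b, context)
  st[, pass := length >= min_len & !is.na(diff) & diff > min_diff & p < p_max]
  st[]
}
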