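# TE-transcript refinement, activation / repression calls from expression
# tables, superfamily enrichment, DME-target proximity flags, the TSS-centred
# differential-methylation heatmap, and the Group I-IV mechanistic classifier
# of vegetative-cell-activated TEs.

#' Refine assembled superloci to TE transcripts
#'
#' Keeps assembled transcript units (superloci) that overlap a TE annotation
#' by at least 1 bp and whose whole-transcript pooled CG methylation in
#' rosette leaves is at least `min_cg` — removing TE-like genes, which are
#' unmethylated in leaves. Superloci with no leaf CG coverage are excluded
#' and counted.
#'
#' @param superloci Annotation table (as from [read_annotation()]).
#' @param te_annotation TE annotation table.
#' @param leaf_methylome [methylome] of rosette leaves.
#' @param min_cg Minimum pooled leaf CG fraction (default 0.7).
#' @return The retained subset of `superloci`, with a `leaf_cg` column.
#' @export
refine_te_transcripts <- function(superloci, te_annotation, leaf_methylome,
                                  min_cg = default_thresholds()$leaf_cg_min) {
  sl <- as.data.table(superloci)
  if (nrow(sl) == 0L) return(sl)
  te <- as.data.table(te_annotation)[, .(chrom, istart = start, iend = end - 1L)]
  key <- sl[, .(chrom, istart = start, iend = end - 1L, id)]
  setkey(te, chrom, istart, iend)
  hits <- unique(foverlaps(key, te, by.x = c("chrom", "istart", "iend"), type = "any", nomatch = NULL)$id)
  st <- region_stats(sl[, .(chrom, start, end)],
                     leaf_methylome, leaf_methylome)
  sl[, leaf_cg := st$frac_a]
  n_uncov <- sum(sl$id %in% hits & is.na(sl$leaf_cg))
  if (n_uncov) message(n_uncov, " TE-overlapping superloci had no leaf CG coverage; excluded")
  out <- sl[id %in% hits & !is.na(leaf_cg) & leaf_cg >= min_cg]
  out[]
}

#' Call VC-activated TEs from a pollen-vs-leaf expression table
#'
#' TEs transcribed at least `fc_min`-fold more in wild-type pollen than
#' leaves with a likelihood-ratio-test p below `p_max`. Records with a
#' missing p-value are skipped with a message.
#'
#' @param expr Expression table ([read_expression()] layout) with
#'   `fold_change` = pollen / leaf.
#' @param fc_min Minimum fold change, inclusive (default 5).
#' @param p_max LRT p cutoff, strict (default 0.05).
#' @return Character vector of activated element ids.
#' @export
call_activated_tes <- function(expr, fc_min = default_thresholds()$activation_fc,
                               p_max = default_thresholds()$de_p) {
  e <- as.data.table(expr)
  n_skip <- sum(is.na(e$lrt_p))
  if (n_skip) message("skipping ", n_skip, " record(s) with missing p-value")
  e <- e[!is.na(lrt_p)]
  e[fold_change >= fc_min & lrt_p < p_max, id]
}

#' Expressed genes by TPM
#' @param expr Expression table; the first `tpm_` column is used unless
#'   `sample` names one.
#' @param tpm_min Minimum TPM, strict (default 5: "more than five").
#' @param sample Optional sample suffix of the `tpm_<sample>` column.
#' @return Character vector of expressed ids.
#' @export
call_expressed_genes <- function(expr, tpm_min = default_thresholds()$expressed_tpm,
                                 sample = NULL) {
  e <- as.data.table(expr)
  col <- if (is.null(sample)) grep("^tpm_", names(e), value = TRUE)[1]
         else paste0("tpm_", sample)
  if (!col %in% names(e)) stop("no column ", col, " in expression table")
  e[e[[col]] > tpm_min, id]
}

#' Differentially expressed elements
#'
#' Elements with fold change at least `fc_min` in either direction (a fold
#' change of `x` and of `1/x` are equally extreme) and p below `p_max`,
#' split by direction.
#'
#' @param expr Expression table with `fold_change` (treatment / control).
#' @param fc_min Minimum fold change, inclusive (default 2).
#' @param p_max p cutoff, strict (default 0.05).
#' @return List with character vectors `down` (fold change <= 1/fc_min) and
#'   `up` (>= fc_min).
#' @export
call_differential <- function(expr, fc_min = default_thresholds()$de_fc,
                              p_max = default_thresholds()$de_p) {
  e <- as.data.table(expr)[!is.na(lrt_p) & lrt_p < p_max]
  list(down = e[fold_change <= 1 / fc_min, id],
       up = e[fold_change >= fc_min, id])
}

#' Superfamily enrichment among activated TEs
#'
#' For each TE superfamily, a two-sided Fisher exact test of the 2x2 table
#' (activated vs not) x (in family vs not), with the direction of the odds
#' ratio reported as enriched / depleted.
#'
#' @param activated_ids Ids of activated TEs.
#' @param all_tes Annotation table of every TE, with `superfamily`
#'   (missing labels count as `"unknown"`).
#' @return `data.table`: `superfamily`, counts, `p`, `direction`.
#' @export
superfamily_enrichment <- function(activated_ids, all_tes) {
  te <- as.data.table(all_tes)
  te[is.na(superfamily) | superfamily == "", superfamily := "unknown"]
  te[, activated := id %in% activated_ids]
  n_act <- sum(te$activated)
  n_tot <- nrow(te)
  out <- te[, .(act_in = sum(activated), tot_in = .N), by = superfamily]
  out[, `:=`(act_out = n_act - act_in,
             notact_in = tot_in - act_in,
             notact_out = (n_tot - tot_in) - (n_act - act_in))]
  out[, p := fisher_exact_2x2(act_in, act_out, notact_in, notact_out)]
  if (n_act == 0L) {
    out[, `:=`(p = 1, direction = "none")]
  } else {
    # odds direction: family share among activated vs among all TEs
    out[, direction := fifelse(act_in / n_act > tot_in / n_tot,
                               "enriched", "depleted")]
  }
  setorder(out, p)
  out[]
}

#' DMR proximity flags for element TSSs
#'
#' For each element, whether its TSS lies inside a region of `dmr_set`
#' (overlap), and whether the nearest region edge is within `max_dist` bp of
#' the TSS (inclusive; overlap counts as distance 0).
#'
#' @param elements Annotation table with `tss` (0-based point).
#' @param dmr_set Regions (`chrom`, `start`, `end`).
#' @param max_dist Maximum TSS-to-region distance in bp (default 500).
#' @return `data.table`: `id`, `overlap`, `within`, `dist` (`NA` when the
#'   chromosome has no regions).
#' @export
proximity_flags <- function(elements, dmr_set, max_dist = default_thresholds()$tss_proximity_bp) {
  el <- as.data.table(elements)
  dmr <- as.data.table(dmr_set)
  res <- data.table(id = el$id, overlap = FALSE, within = FALSE, dist = NA_real_)
  if (nrow(el) == 0L || nrow(dmr) == 0L) return(res[])
  for (i in seq_len(nrow(el))) {
    d <- dmr[chrom == el$chrom[i]]
    if (nrow(d) == 0L) next
    tss <- el$tss[i]
    # distance from the TSS point to each region [start, end): 0 if inside
    dist <- pmax(0, pmax(d$start - tss, tss - (d$end - 1L)))
    res$dist[i] <- min(dist)
    res$overlap[i] <- any(tss >= d$start & tss < d$end)
    res$within[i] <- min(dist) <= max_dist
  }
  res[]
}

#' TSS-centred differential-methylation heatmap
#'
#' For each element and each context, the pooled methylation difference
#' (sample A − sample B) over the window `[tss − halfwidth, tss + halfwidth)`
#' with its Fisher p, and a significance flag: p < `p_max` AND diff greater
#' than the context threshold (CG 0.2, CHG 0.1, CHH 0.05). Rows are sorted in
#' descending CG difference within the significant and non-significant
#' partitions, mirroring the heatmap layout. Elements with no coverage in a
#' context keep `NA` difference.
#'
#' @param elements Annotation table with `tss`.
#' @param meth_a,meth_b [methylome]s (A − B; A is the putatively
#'   hypermethylated sample).
#' @param halfwidth Half-window in bp (default 500, i.e. a 1000-bp window).
#' @param thresholds Named context difference thresholds.
#' @param p_max Fisher p cutoff, strict (default 0.001).
#' @return `data.table`, one row per element: per-context `diff_`, `p_`,
#'   `sig_` columns and `hypermeth` (significant in at least one context).
#' @export
tss_methylation_heatmap <- function(elements, meth_a, meth_b,
                                    halfwidth = default_thresholds()$tss_heatmap_halfwidth_bp,
                                    thresholds = default_thresholds()$heatmap_diff,
                                    p_max = default_thresholds()$heatmap_p) {
  el <- as.data.table(elements)
  win <- el[, .(chrom, start = pmax(0L, tss - as.integer(halfwidth)),
                end = tss + as.integer(halfwidth))]
  out <- data.table(id = el$id)
  for (ctx in CONTEXTS) {
    st <- region_stats(win, meth_a, meth_b, ctx)
    out[, (paste0("diff_", tolower(ctx))) := st$diff]
    out[, (paste0("p_", tolower(ctx))) := st$p]
    out[, (paste0("sig_", tolower(ctx))) :=
          !is.na(st$diff) & st$diff > thresholds[[ctx]] & st$p < p_max]
  }
  out[, hypermeth := sig_cg | sig_chg | sig_chh]
  setorder(out, -hypermeth, -diff_cg, na.last = TRUE)
  out[]
}

#' Assemble per-TE mechanistic flags
#'
#' Computes, for a set of VC-activated TEs, every flag the Group I-IV
#' classifier consumes: H1 repression (down-regulated when H1 is expressed in
#' the VC), DME-target proximity and TSS overlap, TSS hypermethylation in the
#' H1-expressing VC in any context, H1-hyperDMR proximity, and whether a
#' TSS-proximal DME target is itself an H1 hyperDMR (region-level restoration).
#'
#' @param tes Annotation table of VC-activated TEs.
#' @param expr_h1 Expression table of the H1-expressing line vs wild type
#'   (`fold_change` = H1 / WT).
#' @param dme_targets Regions from [call_dme_targets()].
#' @param hyperdmrs Regions from [call_h1_hyperdmrs()].
#' @param meth_h1_vc,meth_wt_vc [methylome]s of the H1-expressing and
#'   wild-type VC.
#' @param cfg Threshold registry.
#' @return `data.table`, one row per TE, with logical flag columns.
#' @export
build_element_calls <- function(tes, expr_h1, dme_targets, hyperdmrs,
                                meth_h1_vc, meth_wt_vc,
                                cfg = default_thresholds()) {
  te <- as.data.table(tes)
  de <- call_differential(expr_h1, cfg$de_fc, cfg$de_p)
  prox_dme <- proximity_flags(te, dme_targets, cfg$tss_proximity_bp)
  prox_hyper <- proximity_flags(te, hyperdmrs, cfg$tss_proximity_bp)
  hm <- tss_methylation_heatmap(te, meth_h1_vc, meth_wt_vc,
                                cfg$tss_heatmap_halfwidth_bp,
                                cfg$heatmap_diff, cfg$heatmap_p)
  # DME targets near the TSS that are themselves hypermethylated when H1 is
  # present, i.e. overlap an H1 hyperDMR
  dme_hyper <- dme_overlapping_hyper(dme_targets, hyperdmrs)
  prox_dme_hyper <- proximity_flags(te, dme_hyper, cfg$tss_proximity_bp)
  calls <- data.table(
    id = te$id,
    activated = TRUE,
    h1_repressed = te$id %in% de$down,
    dme_target_within_500bp = prox_dme$within,
    dme_target_overlapping_tss = prox_dme$overlap,
    hypermeth_in_h1 = hm[match(te$id, hm$id), hypermeth],
    hyperdmr_within_500bp = prox_hyper$within,
    dme_hyper_within_500bp = prox_dme_hyper$within)
  calls[]
}

# subset of DME targets that overlap (>= 1 bp) an H1 hyperDMR
dme_overlapping_hyper <- function(dme_targets, hyperdmrs) {
  d <- as.data.table(dme_targets)
  h <- as.data.table(hyperdmrs)
  if (nrow(d) == 0L || nrow(h) == 0L) return(d[0])
  hk <- h[, .(chrom, istart = start, iend = end - 1L)]
  setkey(hk, chrom, istart, iend)
  ov <- foverlaps(d[, .(chrom, istart = start, iend = end - 1L, row = .I)],
                  hk, by.x = c("chrom", "istart", "iend"), type = "any", nomatch = NULL)
  d[sort(unique(ov$row))]
}

#' Classify VC-activated TEs into mechanistic Groups I-IV
#'
#' Deterministic rule table over the flags of [build_element_calls()]:
#' \describe{
#'   \item{Group I}{not H1-repressed, DME target within 500 bp of the TSS —
#'     activated by DME demethylation regardless of H1.}
#'   \item{Group II}{H1-repressed AND (TSS hypermethylated in the
#'     H1-expressing VC in any context, OR a TSS-proximal DME target that is
#'     itself an H1 hyperDMR) — H1 blocks DME, so its depletion is required
#'     for demethylation and activation.}
#'   \item{Group III}{H1-repressed, DME target near the TSS, but no
#'     hypermethylation and no H1 hyperDMR near the TSS — demethylated by DME
#'     even with H1 present, yet transcription still requires H1 depletion.}
#'   \item{Group IV}{H1-repressed, no DME target near the TSS, no
#'     hypermethylation — activation independent of DME demethylation.}
#' }
#' Any other flag combination is `unclassified`. Groups are mutually
#' exclusive and every element receives exactly one label.
#'
#' @param element_calls `data.table` from [build_element_calls()].
#' @return The input with a `group` column
#'   (`I`/`II`/`III`/`IV`/`unclassified`).
#' @export
classify_groups <- function(element_calls) {
  ec <- as.data.table(element_calls)
  req <- c("h1_repressed", "dme_target_within_500bp", "hypermeth_in_h1",
           "hyperdmr_within_500bp", "dme_hyper_within_500bp")
  for (col in req) {
    if (!col %in% names(ec)) stop("element calls lack flag: ", col)
    if (anyNA(ec[[col]])) {
      stop("missing ", col, " flag for element ",
           ec$id[which(is.na(ec[[col]]))[1]])
    }
  }
  ec[, group := "unclassified"]
  ec[!(h1_repressed) & dme_target_within_500bp, group := "I"]
  ec[(h1_repressed) & (hypermeth_in_h1 | dme_hyper_within_500bp), group := "II"]
  ec[(h1_repressed) & group != "II" & dme_target_within_500bp &
       !hypermeth_in_h1 & !hyperdmr_within_500bp, group := "III"]
  ec[(h1_repressed) & group == "unclassified" & !dme_target_within_500bp &
       !hypermeth_in_h1, group := "IV"]
  ec[]
}
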