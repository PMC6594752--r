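# Metaplot engines: ends analysis (fixed-width bins around aligned TSS / TTS,
# 5'->3' in element orientation) and anchor-aligned difference profiles of DME
# sites stratified by H3K9me2 group. Per-bin values are pooled-count fractions
# across all contributing elements, consistent with the region convention.

#' Ends analysis: methylation profile around aligned element starts and ends
#'
#' Lays fixed-width bins (default 100 bp) around each element's TSS and,
#' separately, its TTS, oriented 5'→3' so minus-strand elements are
#' reflected, and pools the context-matched cytosine counts of all elements
#' per bin. Offsets are bin start positions relative to the alignment point
#' (which is a bin boundary); negative offsets are upstream of the TSS (or
#' inside the element, for the TTS panel).
#'
#' @param elements Annotation table from [read_annotation()] (strand `"."`
#'   elements are excluded, with a message).
#' @param meth A [methylome].
#' @param context Sequence context.
#' @param bin_bp Bin width.
#' @param flank_bp Half-window around the alignment point; must be a multiple
#'   of `bin_bp`.
#' @return `data.table` with columns `alignment` (`TSS`/`TTS`), `offset`,
#'   `n_meth`, `n_total`, `value` (pooled fraction, `NA` when uncovered) and
#'   `n_elements` (elements contributing at least one sequenced call).
#' @export
ends_profile <- function(elements, meth, context,
                         bin_bp = default_thresholds()$ends_bin_bp,
                         flank_bp = default_thresholds()$ends_flank_bp) {
  stopifnot(bin_bp > 0, flank_bp %% bin_bp == 0)
  el <- as.data.table(elements)
  n_drop <- sum(el$strand == ".")
  if (n_drop) {
    message("excluding ", n_drop, " unstranded element(s) from ends profile")
    el <- el[strand != "."]
  }
  ctx <- context   # avoid capture by the data.table column of the same name
  s <- meth$sites[context == ctx, .(chrom, pos, n_meth, n_unmeth)]
  rbindlist(lapply(c("TSS", "TTS"), function(al) {
    pt <- if (al == "TSS") el$tss else el$tts
    win <- data.table(chrom = el$chrom, id = el$id, strand = el$strand,
                      point = pt,
                      istart = pmax(0L, pt - flank_bp),
                      iend = pt + flank_bp - 1L)
    setkey(win, chrom, istart, iend)
    ov <- foverlaps(s[, .(chrom, istart = pos, iend = pos, n_meth, n_unmeth)],
                    win, by.x = c("chrom", "istart", "iend"), type = "within",
                    nomatch = NULL)
    if (nrow(ov) == 0L) {
      return(data.table(alignment = character(), offset = integer(),
                        n_meth = integer(), n_total = integer(),
                        value = numeric(), n_elements = integer()))
    }
    ov[, rel := fifelse(strand == "-", point - i.istart, i.istart - point)]
    ov <- ov[rel >= -flank_bp & rel < flank_bp]
    ov[, offset := (rel %/% bin_bp) * bin_bp]
    prof <- ov[, .(n_meth = sum(n_meth),
                   n_total = sum(n_meth) + sum(n_unmeth),
                   n_elements = uniqueN(id[n_meth + n_unmeth > 0])),
               by = offset]
    prof[, `:=`(alignment = al,
                value = fifelse(n_total > 0L, n_meth / n_total, NA_real_))]
    setorder(prof, offset)
    setcolorder(prof, c("alignment", "offset", "n_meth", "n_total", "value",
                        "n_elements"))
    prof
  }))
}

#' Anchor-aligned methylation-difference profile by H3K9me2 group
#'
#' Aligns DME sites at their most demethylated cytosine and, per H3K9me2
#' group and per fixed-width bin (default 10 bp) of distance from the anchor,
#' computes the pooled-count CG methylation difference (sample A − sample B)
#' across all sites of the group. Sites without an anchor are skipped (count
#' reported via message); bins with no coverage in a sample have `NA`
#' difference, not zero.
#'
#' @param sites Output of [call_dme_sites()] with `anchor_pos` and `group`
#'   columns (sites with `NA` group are pooled under group 0 if present).
#' @param meth_a,meth_b [methylome]s (A − B is reported).
#' @param bin_bp Bin width.
#' @param flank_bp Half-window around the anchor; multiple of `bin_bp`.
#' @param context Sequence context.
#' @return `data.table`: `group`, `offset`, pooled counts, `frac_a`, `frac_b`,
#'   `diff`, `n_sites`.
#' @export
anchor_profile <- function(sites, meth_a, meth_b,
                           bin_bp = default_thresholds()$anchor_profile_bin_bp,
                           flank_bp = default_thresholds()$anchor_profile_flank_bp,
                           context = "CG") {
  stopifnot(bin_bp > 0, flank_bp %% bin_bp == 0)
  st <- as.data.table(sites)
  if (!"group" %in% names(st)) st[, group := 1L]
  n_skip <- sum(is.na(st$anchor_pos))
  if (n_skip) message("skipping ", n_skip, " site(s) without an anchor")
  st <- st[!is.na(anchor_pos)]
  if (nrow(st) == 0L) {
    return(data.table(group = integer(), offset = integer(),
                      n_meth_a = integer(), n_total_a = integer(),
                      n_meth_b = integer(), n_total_b = integer(),
                      frac_a = numeric(), frac_b = numeric(),
                      diff = numeric(), n_sites = integer()))
  }
  win <- st[, .(chrom, group, site_id = .I, anchor = anchor_pos,
                istart = pmax(0L, anchor_pos - flank_bp),
                iend = anchor_pos + flank_bp - 1L)]
  setkey(win, chrom, istart, iend)
  ctx <- context
  pool <- function(meth, label) {
    s <- meth$sites[context == ctx,
                    .(chrom, istart = pos, iend = pos, n_meth, n_unmeth)]
    ov <- foverlaps(s, win, by.x = c("chrom", "istart", "iend"), type = "within", nomatch = NULL)
    ov[, rel := i.istart - anchor]
    ov <- ov[rel >= -flank_bp & rel < flank_bp]
    ov[, offset := (rel %/% bin_bp) * bin_bp]
    agg <- ov[, .(m = sum(n_meth), tot = sum(n_meth) + sum(n_unmeth),
                  ns = uniqueN(site_id)),
              by = .(group, offset)]
    setnames(agg, c("m", "tot", "ns"),
             c(paste0("n_meth_", label), paste0("n_total_", label),
               paste0("n_sites_", label)))
    agg
  }
  out <- merge(pool(meth_a, "a"), pool(meth_b, "b"),
               by = c("group", "offset"), all = TRUE)
  for (col in c("n_meth_a", "n_total_a", "n_meth_b", "n_total_b")) {
    set(out, which(is.na(out[[col]])), col, 0L)
  }
  out[, `:=`(frac_a = fifelse(n_total_a > 0L, n_meth_a / n_total_a, NA_real_),
             frac_b = fifelse(n_total_b > 0L, n_meth_b / n_total_b, NA_real_))]
  out[, diff := frac_a - frac_b]
  out[, n_sites := pmax(fifelse(is.na(n_sites_a), 0L, n_sites_a),
                        fifelse(is.na(n_sites_b), 0L, n_sites_b))]
  out[, c("n_sites_a", "n_sites_b") := NULL]
  setorder(out, group, offset)
  out[]
}

#' Length-weighted mean track score over intervals
#'
#' Mean of a score track (e.g. H3K9me2 ChIP enrichment) over each query
#' interval, weighting each overlapping track segment by the overlap length;
#' `NA` for intervals with no track coverage.
#'
#' @param track Score track (`data.table` from [read_score_track()]).
#' @param intervals `data.table` with `chrom`, `start`, `end` (one row per
#'   query), or a single interval.
#' @return Numeric vector, one mean score per query interval.
#' @export
region_mean_score <- function(track, intervals) {
  q <- as.data.table(intervals)[, .(chrom = as.character(chrom),
                                    start = as.integer(start),
                                    end = as.integer(end))]
  q[, qid := .I]
  key <- copy(q)[, `:=`(istart = start, iend = end - 1L)]
  setkey(key, chrom, istart, iend)
  tr <- as.data.table(track)[, .(chrom, istart = start, iend = end - 1L,
                                 tstart = start, tend = end, score)]
  ov <- foverlaps(tr, key, by.x = c("chrom", "istart", "iend"), type = "any", nomatch = NULL)
  res <- rep(NA_real_, nrow(q))
  if (nrow(ov)) {
    ov[, w := pmin(end, tend) - pmax(start, tstart)]
    agg <- ov[w > 0, .(score = sum(score * w) / sum(w)), by = qid]
    res[agg$qid] <- agg$score
  }
  res
}
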