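# Synthetic methylome bundle: a small diploid-free genome with heterochromatic
# and euchromatic compartments, TE and gene annotations, four per-cytosine
# methylomes (sperm, wild-type VC, H1-expressing VC, leaf) with binomially
# sampled counts, planted valley-shaped hypomethylation at DME target loci,
# H1-dependent restoration at a heterochromatic subset, a compartment-
# correlated H3K9me2 track, expression tables consistent with the planted
# Group I-IV memberships, and truth tables so every caller can be scored.

#' Simulation configuration
#'
#' All knobs of the synthetic bundle, with defaults emulating the study
#' conditions: a ~2 Mb two-chromosome genome, 40% pericentromeric
#' heterochromatin, CG/CHG/CHH baselines of 0.9/0.6/0.15 in heterochromatin
#' and 0.05/0.02/0.02 in euchromatin, 20x mean Poisson coverage, 200
#' background hypomethylation valleys (CG peak depth 0.6, half-width 200 bp,
#' CHG/CHH valleys weaker), H1-dependent restoration at half of the
#' heterochromatic background valleys, and TE-TSS valleys (half-width 400 bp)
#' whose restoration and expression follow the planted Group I-IV labels.
#'
#' Valleys are triangular (linear taper of the methylation deficit to zero at
#' the half-width) with a sharply demethylated core: CG sites within
#' `core_halfwidth` of the planted peak cytosine drop to near-complete
#' demethylation (0.05), emulating the single-nucleotide hypomethylation
#' maxima observed at DME sites and making the most demethylated cytosine a
#' well-defined target for anchor recovery.
#'
#' @param seed Integer RNG seed; fixes the full bundle.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param het_fraction Fraction of each chromosome occupied by a central
#'   heterochromatic block.
#' @param n_te,n_gene Element counts.
#' @param group_counts Named counts of planted Group I-IV TEs (the activated
#'   TEs); remaining TEs are inactive. Ignored (zeroed) when `n_te = 0`.
#' @param baseline Per-compartment, per-context methylation levels.
#' @param site_density Cytosines per bp for each context.
#' @param mean_depth Mean Poisson sequencing depth per cytosine per sample.
#' @param dme_n Number of background (TE-free, heterochromatic)
#'   hypomethylation valleys.
#' @param valley_halfwidth,te_valley_halfwidth Valley half-widths (bp) for
#'   background and TE-TSS valleys.
#' @param peak_delta Peak methylation deficit per context.
#' @param core_halfwidth Half-width (bp) of the sharply demethylated CG core
#'   at the peak cytosine.
#' @param te_flank_methylated Distance (bp) that TE-body methylation spreads
#'   into the flanking sequence.
#' @param h1_restored_fraction Fraction of background heterochromatic valleys
#'   restored to the sperm-like level in the H1-expressing VC.
#' @param activation_fold,repression_fold Planted expression fold changes
#'   (pollen/leaf for activated TEs; WT/H1 for H1-repressed TEs).
#' @param expr_noise_sd Lognormal sd of multiplicative expression noise.
#' @param h3k9me2_bin,h3k9me2_het_mean,h3k9me2_eu_mean H3K9me2 track bin
#'   width and compartment score means.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 1200000L, chr2 = 800000L),
                       het_fraction = 0.4,
                       n_te = 60L, n_gene = 40L,
                       group_counts = c(I = 10L, II = 10L, III = 10L, IV = 10L),
                       baseline = list(het = c(CG = 0.9, CHG = 0.6, CHH = 0.15),
                                       eu = c(CG = 0.05, CHG = 0.02, CHH = 0.02)),
                       site_density = c(CG = 1 / 10, CHG = 1 / 15, CHH = 1 / 8),
                       mean_depth = 20,
                       dme_n = 200L,
                       valley_halfwidth = 200L,
                       te_valley_halfwidth = 400L,
                       peak_delta = c(CG = 0.6, CHG = 0.3, CHH = 0.1),
                       core_halfwidth = 10L,
                       te_flank_methylated = 600L,
                       h1_restored_fraction = 0.5,
                       activation_fold = 50,
                       repression_fold = 10,
                       expr_noise_sd = 0.1,
                       h3k9me2_bin = 1000L,
                       h3k9me2_het_mean = 12,
                       h3k9me2_eu_mean = 1.5) {
  if (n_te == 0L) group_counts[] <- 0L
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              het_fraction = het_fraction, n_te = as.integer(n_te),
              n_gene = as.integer(n_gene), group_counts = group_counts,
              baseline = baseline, site_density = site_density,
              mean_depth = mean_depth, dme_n = as.integer(dme_n),
              valley_halfwidth = as.integer(valley_halfwidth),
              te_valley_halfwidth = as.integer(te_valley_halfwidth),
              peak_delta = peak_delta, core_halfwidth = as.integer(core_halfwidth),
              te_flank_methylated = as.integer(te_flank_methylated),
              h1_restored_fraction = h1_restored_fraction,
              activation_fold = activation_fold,
              repression_fold = repression_fold,
              expr_noise_sd = expr_noise_sd,
              h3k9me2_bin = as.integer(h3k9me2_bin),
              h3k9me2_het_mean = h3k9me2_het_mean,
              h3k9me2_eu_mean = h3k9me2_eu_mean)
  probs <- c(unlist(baseline), h1_restored_fraction, het_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(peak_delta < 0 | peak_delta > 1)) stop("peak_delta must lie in [0, 1]")
  if (sum(group_counts) > n_te) stop("more grouped TEs than TEs")
  structure(cfg, class = "sim_config")
}

# heterochromatic block per chromosome (central, covering het_fraction)
het_blocks <- function(cfg) {
  rbindlist(lapply(names(cfg$chrom_lengths), function(ch) {
    len <- cfg$chrom_lengths[[ch]]
    w <- round(len * cfg$het_fraction)
    s <- round((len - w) / 2)
    data.table(chrom = ch, start = as.integer(s), end = as.integer(s + w))
  }))
}

# sequential packing of elements into compartment arms, round-robin over arms
place_elements <- function(arms, n, len_range, spacing, prefix) {
  if (n == 0L) {
    return(data.table(id = character(), chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  cursors <- arms$start + 1000L
  out <- vector("list", n)
  arm_i <- 0L
  placed <- 0L
  tries <- 0L
  while (placed < n && tries < n * 10L) {
    tries <- tries + 1L
    arm_i <- (arm_i %% nrow(arms)) + 1L
    len <- as.integer(round(runif(1, len_range[1], len_range[2])))
    s <- cursors[arm_i] + as.integer(round(runif(1, 0, 500)))
    if (s + len > arms$end[arm_i] - 1000L) next
    placed <- placed + 1L
    out[[placed]] <- data.table(id = sprintf("%s%03d", prefix, placed),
                                chrom = arms$chrom[arm_i],
                                start = s, end = s + len,
                                strand = sample(c("+", "-"), 1))
    cursors[arm_i] <- s + len + spacing
  }
  if (placed < n) stop("infeasible config: could not place ", n, " elements (",
                       prefix, ") in the available compartment space")
  rbindlist(out[seq_len(placed)])
}

#' Simulate a methylome analysis bundle
#'
#' Generates the full synthetic input set in memory; see [sim_config()] for
#' the model. Identical configurations (including the seed) produce identical
#' bundles.
#'
#' @param cfg A [sim_config()].
#' @return List with: `sperm`, `vc`, `h1_vc`, `leaf` ([methylome]s),
#'   `elements` (annotation table of TEs and genes with superfamilies),
#'   `h3k9me2` (score track), `expr_te_pollen_leaf`, `expr_te_h1`,
#'   `expr_gene` (expression tables), `truth_sites`, `truth_tes` (truth
#'   tables) and `config`.
#' @export
simulate_bundle <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  het <- het_blocks(cfg)

  ## --- elements -----------------------------------------------------------
  eu_arms <- rbindlist(lapply(names(cfg$chrom_lengths), function(ch) {
    len <- cfg$chrom_lengths[[ch]]
    hb <- het[chrom == ch]
    data.table(chrom = ch, start = c(0L, hb$end), end = c(hb$start, len))
  }))
  n_act <- sum(cfg$group_counts)
  n_het_act <- sum(cfg$group_counts[c("II", "III", "IV")])
  n_eu_act <- cfg$group_counts[["I"]]
  n_inactive <- cfg$n_te - n_act
  n_inact_het <- n_inactive %/% 2L
  n_inact_eu <- n_inactive - n_inact_het
  te_het <- place_elements(het, n_het_act + n_inact_het, c(2000, 4000), 8000L, "TEH")
  te_eu <- place_elements(eu_arms, n_eu_act + n_inact_eu, c(2000, 4000), 8000L, "TEE")
  genes <- place_elements(eu_arms, cfg$n_gene, c(1000, 3000), 4000L, "GEN")
  # group assignment: het TEs take II/III/IV then inactive; eu TEs take I
  te_het[, group := c(rep(c("II", "III", "IV"),
                          times = cfg$group_counts[c("II", "III", "IV")]),
                      rep("none", n_inact_het))]
  te_eu[, group := c(rep("I", n_eu_act), rep("none", n_inact_eu))]
  tes <- rbind(te_het, te_eu)
  tes[, kind := "TE"]
  tes[, superfamily := fifelse(group %in% c("II", "III", "IV"),
                               sample(c("Gypsy", "Copia"), .N, TRUE, c(0.6, 0.4)),
                        fifelse(group == "I", "MuDR",
                                sample(c("LINE", "SINE", "HAT", "Copia"), .N, TRUE)))]
  genes[, `:=`(group = "none", kind = "gene", superfamily = "unknown")]
  tes[, tss := fifelse(strand == "-", end - 1L, start)]
  tes[, tts := fifelse(strand == "-", start, end - 1L)]
  genes[, tss := fifelse(strand == "-", end - 1L, start)]
  genes[, tts := fifelse(strand == "-", start, end - 1L)]
  elements <- rbind(tes, genes)
  setorder(elements, chrom, start)

  ## --- valleys ------------------------------------------------------------
  hw_te <- cfg$te_valley_halfwidth
  te_val <- tes[group %in% c("I", "II", "III")]
  valleys <- if (nrow(te_val)) {
    data.table(chrom = te_val$chrom, center = te_val$tss, halfwidth = hw_te,
               restored = te_val$group == "II", te_id = te_val$id,
               compartment = fifelse(te_val$group == "I", "eu", "het"))
  } else {
    data.table(chrom = character(), center = integer(), halfwidth = integer(),
               restored = logical(), te_id = character(), compartment = character())
  }
  if (cfg$dme_n > 0L) {
    # background valley slots: heterochromatin clear of TEs and their valleys
    avoid <- copy(tes)[, `:=`(start = start - (hw_te + 1200L), end = end + hw_te + 1200L)]
    slots <- rbindlist(lapply(seq_len(nrow(het)), function(i) {
      ch <- het$chrom[i]
      centers <- seq.int(het$start[i] + cfg$valley_halfwidth + 600L,
                         het$end[i] - cfg$valley_halfwidth - 600L, by = 2000L)
      data.table(chrom = ch, center = as.integer(centers))
    }))
    av <- avoid[, .(chrom, start, end)]
    if (nrow(av)) {
      bad <- rep(FALSE, nrow(slots))
      for (i in seq_len(nrow(av))) {
        bad <- bad | (slots$chrom == av$chrom[i] &
                        slots$center >= av$start[i] & slots$center < av$end[i])
      }
      slots <- slots[!bad]
    }
    if (nrow(slots) < cfg$dme_n) {
      stop("infeasible config: ", cfg$dme_n, " background valleys requested but only ",
           nrow(slots), " heterochromatic slots available")
    }
    pick <- sort(sample.int(nrow(slots), cfg$dme_n))
    bg <- slots[pick]
    bg[, `:=`(halfwidth = cfg$valley_halfwidth,
              restored = runif(.N) < cfg$h1_restored_fraction,
              te_id = NA_character_, compartment = "het")]
    valleys <- rbind(valleys, bg)
  }

  ## --- cytosine sites -----------------------------------------------------
  dens <- cfg$site_density
  sites <- rbindlist(lapply(names(cfg$chrom_lengths), function(ch) {
    len <- cfg$chrom_lengths[[ch]]
    n_by_ctx <- round(len * dens[CONTEXTS])
    pos <- sample.int(len, sum(n_by_ctx)) - 1L   # unique -> unique keys
    data.table(chrom = ch, pos = pos,
               strand = sample(c("+", "-"), length(pos), TRUE),
               context = rep(CONTEXTS, times = n_by_ctx))
  }))
  setorder(sites, chrom, pos)

  # compartment: central het block, or inside a TE body (TEs are methylated
  # wherever they sit)
  sites[, in_het := FALSE]
  for (i in seq_len(nrow(het))) {
    sites[chrom == het$chrom[i] & pos >= het$start[i] & pos < het$end[i],
          in_het := TRUE]
  }
  # TE bodies are methylated wherever they sit, and methylation spreads a
  # short distance into the flanks (so TSS-centred valleys sit on methylated
  # ground even for euchromatic TEs)
  for (i in seq_len(nrow(tes))) {
    sites[chrom == tes$chrom[i] & pos >= tes$start[i] - cfg$te_flank_methylated &
            pos < tes$end[i] + cfg$te_flank_methylated, in_het := TRUE]
  }
  base_het <- cfg$baseline$het
  base_eu <- cfg$baseline$eu
  sites[, p_sperm := fifelse(in_het, base_het[context], base_eu[context])]

  # WT VC: sperm baseline minus the valley deficit; sharply demethylated CG core
  sites[, p_vc := p_sperm]
  if (nrow(valleys)) {
    valleys[, peak_pos := NA_integer_]
    for (i in seq_len(nrow(valleys))) {
      v <- valleys[i]
      idx <- sites[, .I[chrom == v$chrom & abs(pos - v$center) <= v$halfwidth]]
      if (!length(idx)) next
      sub <- sites[idx]
      # demethylation only removes existing methylation: cytosines that are
      # essentially unmethylated in sperm (euchromatic flanks) are untouched
      elig <- sub$p_sperm >= 0.2
      # planted peak cytosine: the demethylatable CG site nearest the center
      cg <- sub[elig & context == "CG"]
      if (nrow(cg) == 0L) next
      peak <- cg$pos[which.min(abs(cg$pos - v$center))]
      set(valleys, i, "peak_pos", as.integer(peak))
      delta <- cfg$peak_delta[sub$context] * pmax(0, 1 - abs(sub$pos - peak) / v$halfwidth)
      p_new <- fifelse(elig, pmax(sub$p_sperm - delta, 0.02), sub$p_vc)
      core <- elig & sub$context == "CG" & abs(sub$pos - peak) <= cfg$core_halfwidth &
        cfg$peak_delta[["CG"]] > 0
      p_new[core] <- pmin(p_new[core], 0.05)
      set(sites, idx, "p_vc", p_new)
    }
    valleys <- valleys[!is.na(peak_pos)]
  }
  # H1-expressing VC: valley restored to the sperm-like level at restored loci
  sites[, p_h1 := p_vc]
  if (nrow(valleys)) {
    for (i in which(valleys$restored)) {
      v <- valleys[i]
      sites[chrom == v$chrom & abs(pos - v$center) <= v$halfwidth, p_h1 := p_sperm]
    }
  }
  sites[, p_leaf := p_sperm]

  draw_methylome <- function(pcol, sample_id) {
    cov <- rpois(nrow(sites), cfg$mean_depth)
    m <- rbinom(nrow(sites), cov, sites[[pcol]])
    methylome(sites[, .(chrom, pos, strand, context)][, `:=`(n_meth = m, n_unmeth = cov - m)],
              sample_id, cfg$chrom_lengths)
  }
  sperm <- draw_methylome("p_sperm", "sperm")
  vc <- draw_methylome("p_vc", "VC")
  h1_vc <- draw_methylome("p_h1", "pVC_H1_VC")
  leaf <- draw_methylome("p_leaf", "leaf")

  ## --- H3K9me2 track ------------------------------------------------------
  track <- tile_windows(cfg$chrom_lengths, cfg$h3k9me2_bin)
  track[, mid := (start + end) %/% 2]
  track[, is_het := FALSE]
  for (i in seq_len(nrow(het))) {
    track[chrom == het$chrom[i] & mid >= het$start[i] & mid < het$end[i], is_het := TRUE]
  }
  track[, score := fifelse(is_het,
                           pmax(0, rnorm(.N, cfg$h3k9me2_het_mean, 1.0)),
                           pmax(0, rnorm(.N, cfg$h3k9me2_eu_mean, 0.4)))]
  track[, c("mid", "is_het") := NULL]

  ## --- expression tables --------------------------------------------------
  lnoise <- function(n) exp(rnorm(n, 0, cfg$expr_noise_sd))
  te_tab <- copy(tes)[, activated := group != "none"]
  tpm_leaf <- round(0.2 * lnoise(nrow(te_tab)), 3)
  fc_pl <- fifelse(te_tab$activated, cfg$activation_fold * lnoise(nrow(te_tab)),
                   lnoise(nrow(te_tab)))
  expr_te_pollen_leaf <- data.table(
    id = te_tab$id, tpm_pollen = round(tpm_leaf * fc_pl, 3), tpm_leaf = tpm_leaf,
    fold_change = round(fc_pl, 4),
    lrt_p = fifelse(te_tab$activated, 10^-runif(nrow(te_tab), 4, 8),
                    runif(nrow(te_tab), 0.1, 1)))
  repressed <- te_tab$group %in% c("II", "III", "IV")
  tpm_wt <- round(fifelse(te_tab$activated, 10, 0.2) * lnoise(nrow(te_tab)), 3)
  fc_h1 <- fifelse(repressed, (1 / cfg$repression_fold) * lnoise(nrow(te_tab)),
                   lnoise(nrow(te_tab)))
  expr_te_h1 <- data.table(
    id = te_tab$id, tpm_wt = tpm_wt, tpm_h1 = round(tpm_wt * fc_h1, 3),
    fold_change = round(fc_h1, 4),
    lrt_p = fifelse(repressed, 10^-runif(nrow(te_tab), 4, 8),
                    runif(nrow(te_tab), 0.1, 1)))
  expressed_gene <- seq_len(nrow(genes)) <= nrow(genes) %/% 2
  tpm_gene <- round(fifelse(expressed_gene, 30 * lnoise(nrow(genes)),
                            0.5 * lnoise(nrow(genes))), 3)
  expr_gene <- data.table(id = genes$id, tpm_pollen = tpm_gene,
                          fold_change = round(lnoise(nrow(genes)), 4),
                          lrt_p = runif(nrow(genes), 0.1, 1))

  ## --- truth tables -------------------------------------------------------
  truth_sites <- if (nrow(valleys)) {
    valleys[, .(site_id = sprintf("DME%04d", .I), chrom,
                start = pmax(0L, center - halfwidth), end = center + halfwidth + 1L,
                peak_pos, restored, compartment, te_id)]
  } else {
    data.table(site_id = character(), chrom = character(), start = integer(),
               end = integer(), peak_pos = integer(), restored = logical(),
               compartment = character(), te_id = character())
  }
  truth_tes <- te_tab[, .(id, group, activated, repressed = group %in% c("II", "III", "IV"))]

  list(sperm = sperm, vc = vc, h1_vc = h1_vc, leaf = leaf,
       elements = elements, h3k9me2 = track,
       expr_te_pollen_leaf = expr_te_pollen_leaf, expr_te_h1 = expr_te_h1,
       expr_gene = expr_gene, truth_sites = truth_sites,
       truth_tes = truth_tes, config = cfg)
}

#' Write a simulated bundle to disk
#'
#' Emits every component in the formats the readers consume: four cytosine
#' reports, a GFF3 annotation (with `superfamily` attributes), a bedGraph
#' H3K9me2 track, three expression TSVs and two truth TSVs.
#'
#' @param bundle Output of [simulate_bundle()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_sim_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outdir, x)
  write_cytosine_report(bundle$sperm, fp("sperm.cx.tsv"))
  write_cytosine_report(bundle$vc, fp("vc.cx.tsv"))
  write_cytosine_report(bundle$h1_vc, fp("h1_vc.cx.tsv"))
  write_cytosine_report(bundle$leaf, fp("leaf.cx.tsv"))
  el <- bundle$elements
  gff <- sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\tID=%s;superfamily=%s",
                 el$chrom, fifelse(el$kind == "gene", "gene", "TE"),
                 el$start + 1L, el$end, el$strand, el$id, el$superfamily)
  writeLines(c("##gff-version 3", gff), fp("elements.gff3"))
  tr <- bundle$h3k9me2
  fwrite(tr[, .(chrom, start, end, score = round(score, 4))],
         fp("h3k9me2.bedGraph"), sep = "\t", col.names = FALSE)
  fwrite(bundle$expr_te_pollen_leaf, fp("expr_te_pollen_leaf.tsv"), sep = "\t")
  fwrite(bundle$expr_te_h1, fp("expr_te_h1.tsv"), sep = "\t")
  fwrite(bundle$expr_gene, fp("expr_gene.tsv"), sep = "\t")
  fwrite(bundle$truth_sites, fp("truth_sites.tsv"), sep = "\t")
  fwrite(bundle$truth_tes, fp("truth_tes.tsv"), sep = "\t")
  invisible(outdir)
}

#' Score called regions against planted truth
#'
#' Matches calls to truth intervals by at least 1 bp of overlap. Precision is
#' the fraction of calls overlapping a truth interval (`NA` when there are no
#' calls), recall the fraction of truth intervals hit. When calls carry an
#' `anchor_pos` and the truth a `peak_pos`, the absolute anchor-to-peak
#' distance is reported per matched truth interval (taking the best-matching
#' call).
#'
#' @param calls Regions (`chrom`, `start`, `end`, optionally `anchor_pos`).
#' @param truth Truth intervals (`chrom`, `start`, `end`, optionally
#'   `peak_pos`).
#' @param anchor_tol Distance (bp) defining "anchor recovered".
#' @return List: `n_calls`, `n_truth`, `precision`, `recall`, `anchor_dist`
#'   (vector, one per matched truth with a defined anchor) and
#'   `anchor_within` (fraction of those within `anchor_tol`).
#' @export
evaluate_recovery <- function(calls, truth, anchor_tol = 10) {
  calls <- as.data.table(calls)
  truth <- as.data.table(truth)
  res <- list(n_calls = nrow(calls), n_truth = nrow(truth),
              precision = NA_real_, recall = NA_real_,
              anchor_dist = numeric(0), anchor_within = NA_real_)
  if (nrow(truth) == 0L) return(res)
  if (nrow(calls) == 0L) {
    res$recall <- 0
    return(res)
  }
  tk <- truth[, .(chrom, istart = start, iend = end - 1L, tid = .I)]
  setkey(tk, chrom, istart, iend)
  ov <- foverlaps(calls[, .(chrom, istart = start, iend = end - 1L, cid = .I)],
                  tk, by.x = c("chrom", "istart", "iend"), type = "any", nomatch = NULL)
  res$precision <- uniqueN(ov$cid) / nrow(calls)
  res$recall <- uniqueN(ov$tid) / nrow(truth)
  if ("anchor_pos" %in% names(calls) && "peak_pos" %in% names(truth) && nrow(ov)) {
    m <- ov[, .(tid, cid)]
    m[, anchor := calls$anchor_pos[cid]]
    m[, peak := truth$peak_pos[tid]]
    m <- m[!is.na(anchor) & !is.na(peak)]
    if (nrow(m)) {
      m[, dist := abs(anchor - peak)]
      best <- m[, .(dist = min(dist)), by = tid]
      res$anchor_dist <- best$dist
      res$anchor_within <- mean(best$dist <= anchor_tol)
    }
  }
  res
}
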