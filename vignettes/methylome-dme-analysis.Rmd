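---
title: "Calling DME targets, H1 hyperDMRs and TE activation classes from pollen methylomes"
author: "vcdme authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling DME targets, H1 hyperDMRs and TE activation classes from pollen methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcdme)
library(data.table)
```

## The biological problem

In *Arabidopsis* pollen, the vegetative cell (VC) — the cell that grows the
pollen tube and engulfs the two sperm cells — loses histone H1 during
development and is then extensively CG-demethylated by the DNA glycosylase
DME. Because essentially all CG hypomethylation in the VC relative to sperm
is DME-dependent, regions significantly less CG-methylated in the VC than in
sperm mark DME's genomic targets. Heterochromatic transposable elements (TEs)
near such targets can become transcriptionally activated in the VC, and
ectopically retaining H1 in the VC blocks DME at heterochromatic targets,
re-methylating and re-silencing a subset of these TEs.

This package implements the comparative-methylome computations that underlie
this analysis as a reusable, tested pipeline: windowed Fisher-exact
differential methylation, three region-calling procedures, metaplot engines,
and the mechanistic classification of VC-activated TEs — together with a
synthetic methylome generator that makes every stage verifiable at desk
scale, without any sequencing data.

## The statistical model

All quantities derive from per-cytosine counts $(m_i, u_i)$ of methylated and
unmethylated calls in one sequence context (CG, CHG or CHH). The fractional
methylation of any site set $S$ is the *pooled* ratio

$$\hat p(S) = \frac{\sum_{i \in S} m_i}{\sum_{i \in S} (m_i + u_i)},$$

never the mean of per-site fractions — pooling is additive under
partitioning and robust to uneven coverage, and it is undefined (not zero)
when the pooled coverage is zero. Two samples are compared over the same
span with the difference $\hat p_A - \hat p_B$ and a two-sided Fisher exact
test on the pooled $2\times2$ table. The test sums hypergeometric
probabilities of all tables with the observed margins whose probability does
not exceed that of the observed table (relative tolerance $1+10^{-7}$, the
conventional choice, so results match `stats::fisher.test` to near machine
precision); a table with no observations is non-significant by convention
($p = 1$). The implementation is vectorized because every procedure tests
tens of thousands of windows.

## The three region procedures

**Procedure A — VC DME targets.** Disjoint 100-bp bins are Fisher-tested on
pooled CG counts (sperm vs VC); bins with $p < 0.05$ and sperm-ward
difference seed candidates, runs of adjacent seed bins are concatenated, and
candidates are kept when the whole-candidate pooled difference is at least
0.2. Candidates within 300 bp are merged, statistics are *recomputed from
raw counts over the merged span* (so intervening non-seed sequence counts),
and merged regions pass when they cover at least 100 bp with difference
$> 0.2$ and $p < 0.01$. The binned seeding stage is this package's stand-in
for an HMM-based external segmenter whose printed settings ($p = 0.05$,
bin 100) it honours; the downstream gates are unchanged and dominate the
final call set.

**Procedure C — H1 hyperDMRs.** Identical gates, comparing the VC of
H1-expressing plants against the wild-type VC; regions hypermethylated when
H1 is present mark DME targets that require H1 depletion.

**Procedure B — DME sites.** A stricter single-site procedure: 50-bp windows
with CG difference $> 0.5$ and $p < 0.001$ are merged within 200 bp and
retained when the whole-site difference is $> 0.2$ with $p < 10^{-4}$. Each
site is annotated with its *most demethylated cytosine* (anchor): among CG
cytosines with per-cytosine difference $> 0.2$, $p < 0.001$ and at least 10
sequenced calls *in each sample*, the one with maximal difference, leftmost
on ties. Sites are stratified into five H3K9me2 groups by their
length-weighted mean track score with left-closed bounds
$[2.5, 4.3, 6.5, 10.5]$.

Inequalities follow the printed thresholds exactly: "at least 0.2" is
$\ge$, "$>0.2$" and "$p<0.01$" are strict. Merge gaps are measured
end-to-start and inclusive (a 200-bp gap merges under a 200-bp rule). Every
final region can be re-tested from raw counts with `audit_dmr_gates()`;
the test-suite requires zero violations.

## Metaplots

`ends_profile()` aligns elements at the TSS (and separately the TTS), lays
fixed-width bins 5'→3' in element orientation (minus-strand elements are
reflected; the alignment point is a bin boundary), and reports per-bin
pooled fractions across all contributing elements. `anchor_profile()` does
the same around site anchors, per H3K9me2 group, reporting the pooled
difference. Defaults are 100-bp bins with 2000-bp flanks for ends analysis
and 10-bp bins with 500-bp flanks for anchor profiles; the figures these
emulate do not print their extents, so the flanks are package choices.
Uncovered bins are `NA`, never zero. Per-bin pooling across elements (not a
mean of per-element profiles) keeps the two engines consistent with the
region convention; a per-element average can be recovered from the emitted
counts if wanted for sensitivity checks.

## Density-plot differences

`density_differences()` reproduces the windowed filtering behind
kernel-density comparisons: 50-bp windows kept when **both** samples have at
least 20 informative sequenced calls (call counts, not distinct positions —
consistent with the "sequenced at least 10 times" anchor language) and the
level reaches the context threshold (CG 0.5, with 0.7 as the stricter
variant; CHG 0.4; CHH 0.1) in **at least one** sample. The informative
filter is applied to both samples because a difference is undefined unless
both fractions are estimable; the level filter is either-sample by
construction. Both choices are configurable.

## TE classification

From expression tables (external quantification; fold change and
likelihood-ratio-test p-values are inputs), `call_activated_tes()` applies
the activation gate (fold $\ge 5$ pollen/leaf, $p < 0.05$; a fold-$>2$
variant is available via the `fc_min` argument because both readings appear
in the source analyses — the Methods value 5 is the default),
`call_differential()` the $\ge 2$-fold differential gate, and
`call_expressed_genes()` the TPM $> 5$ gate. `refine_te_transcripts()`
removes TE-like genes from assembled superloci (TE overlap $\ge 1$ bp and
leaf CG $\ge 0.7$). `tss_methylation_heatmap()` tests the 1000-bp window
centred on each TSS per context (significant when $p < 0.001$ *and* the
difference exceeds 0.2 / 0.1 / 0.05 for CG / CHG / CHH).

`classify_groups()` is a total, deterministic rule table over per-TE flags:

| Group | H1-repressed | DME target ≤ 500 bp of TSS | TSS hypermethylated or DME target is a hyperDMR |
|-------|--------------|---------------------------|--------------------------------------------------|
| I     | no           | yes                       | —                                                |
| II    | yes          | —                         | yes                                              |
| III   | yes          | yes                       | no (and no hyperDMR near the TSS)                |
| IV    | yes          | no                        | no                                               |

Anything else is `unclassified`. "Within 500 bp" is inclusive, measured
from the TSS point to the nearest region edge; overlap counts as distance
zero. TSS hypermethylation in any one context suffices. The "DME target
that is itself a hyperDMR" clause uses region overlap ($\ge 1$ bp) with the
same 500-bp TSS proximity, since no separate distance is printed for it.

## The synthetic generator

`simulate_bundle()` produces the full input set from a `sim_config()`:

* **Genome and compartments.** Two chromosomes totalling 2 Mb, with a
  central heterochromatic block covering 40% of each chromosome —
  a desk-scale caricature of pericentromeric organisation.
* **Cytosines.** Context site densities of 1/10 (CG), 1/15 (CHG) and 1/8
  (CHH) per bp at unique positions with random strands; contexts are
  assigned by density, not derived from sequence (no FASTA exists).
* **Methylation.** Heterochromatic baselines 0.9 / 0.6 / 0.15 and
  euchromatic 0.05 / 0.02 / 0.02 (CG / CHG / CHH). TE bodies are
  methylated wherever they sit, with spreading 600 bp into the flanks so
  TSS-centred valleys rest on methylated ground even for euchromatic TEs.
  Coverage is Poisson (mean 20) per cytosine per sample and methylated
  calls are Binomial(coverage, level): count noise is exactly the
  binomial-sampling noise the Fisher machinery assumes.
* **Valleys.** 200 background valleys (half-width 200 bp) in TE-free
  heterochromatin plus one valley at each Group I–III TE TSS (half-width
  400 bp, so that restoring one moves the pooled difference over the
  1000-bp TSS window past the CG hypermethylation gate). The deficit
  tapers linearly to zero at the half-width (peak 0.6 / 0.3 / 0.1 by
  context) and applies only to cytosines with sperm methylation $\ge 0.2$:
  demethylation removes existing methylation and leaves unmethylated
  euchromatin untouched. CG sites within 10 bp of the planted peak
  cytosine drop to near-complete demethylation (0.05). This sharp core
  emulates the single-nucleotide hypomethylation maxima visible at DME
  sites; under a pure 200-bp linear taper, neighbouring cytosines differ
  by under 0.03 in expected difference, which 20× binomial noise (per-site
  sd ≈ 0.11) swamps, and no caller could localize an anchor that the data
  do not define.
* **H1 restoration.** The H1-expressing VC restores the sperm-like level
  at all Group II TE valleys and at half of the heterochromatic background
  valleys; everything else keeps the wild-type VC profile. The leaf
  methylome is sperm-like (TEs fully methylated), which exercises the
  leaf-CG ≥ 0.7 refinement filter.
* **H3K9me2.** 1-kb bins scoring Normal(12, 1) in heterochromatin and
  Normal(1.5, 0.4) elsewhere (truncated at 0), so heterochromatic sites
  fall in the top stratification group and euchromatic sites in the
  bottom one.
* **Expression.** Activated TEs get a planted pollen/leaf fold of 50 and
  tiny LRT p-values; H1-repressed TEs (Groups II–IV) a planted H1/WT fold
  of 1/10; inactive elements folds near 1 with non-significant p. A 10%
  lognormal noise keeps the tables away from exact ties without
  threatening the thresholds.

Everything is a deterministic function of the seed. The truth tables list
each valley's span, peak cytosine, restoration status and TE association,
and each TE's planted group, so `evaluate_recovery()` can score any caller
(matching by ≥ 1 bp overlap; anchor error is the distance from the called
anchor to the planted peak).

### What the simulations do and do not show

The generator reproduces the statistical structure the procedures assume —
binomial count noise at fixed per-site levels, compartmentalised baselines,
valley-shaped hypomethylation, compartment-correlated H3K9me2 — but not
sequence-driven context, mappability or coverage biases, bisulfite
non-conversion, partial demethylation heterogeneity between cells, or the
long-tailed TE length and nesting structure of a real genome. Passing
recovery tests therefore validates the *implementation* of the procedures
under their own model; it does not certify performance on real bisulfite
data, where boundary effects and coverage artefacts are harsher.

## Study-scale results computed by this package

Under the default conditions (2 Mb, 20×, 200 background valleys of peak
depth 0.6), the test-suite and `scripts/acceptance.R` recompute: DME-site
precision and recall ≥ 0.95 with ~96% of anchors within 10 bp of the
planted peak; zero Procedure-B sites and at most one Procedure-A region per
run on difference-free simulations; zero gate-audit violations; and exact
recovery of all planted Group I–IV labels. At 5× coverage, recall degrades
(reported, not gated). These problem sizes are the package's chosen
benchmark conditions; all of them rerun from scratch in a few minutes.

## Numerical and degenerate-input conventions

* Internal coordinates are 0-based half-open; cytosine reports are 1-based
  (Bismark convention) and converted on read; BED/bedGraph are taken as
  0-based. GFF3 is 1-based inclusive and converted.
* Opposite-strand CG cytosines are *not* pooled into symmetric dyads; each
  strand is a separate observation — the conservative reading of
  strand-resolved reports, and configurable upstream by pre-pooling the
  input if a user prefers dyads.
* Group bounds are left-closed: a score exactly 2.5 joins the 2.5–4.3 group.
* A zero-information Fisher table (and a window uncovered in a sample)
  yields $p = 1$ / `NA` level — non-significance, never a phantom signal.
* Anchor ties break leftmost; all outputs sort by (chrom, start); no stage
  of region calling uses randomness.
* Elements without strand keep `"."`, use start as TSS for proximity, and
  are excluded from strand-sensitive profiles (with a message).

## Limitations

The seeding stage of Procedure A is a binned stand-in, not an HMM segmenter,
so exact DMR boundaries will differ from segmenter-based calls even where
the final gate set agrees. CHG/CHH region calling is deliberately absent
(the published region procedures are CG-only; the other contexts enter only
window and heatmap analyses). Expression quantification, read alignment and
transcript assembly are out of scope: their outputs are inputs here.
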