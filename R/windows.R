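#' Tile a genome into fixed-width windows
#'
#' Disjoint adjacent windows `[0,w), [w,2w), ...` per chromosome; the final
#' partial window is retained, so the tiling covers every base exactly once.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param width Window width in bp (> 0).
#' @return `data.table` with columns `chrom`, `start`, `end`, ordered.
#' @export
#' @examples
#' tile_windows(c(chr1 = 120), 50)
tile_windows <- function(chrom_lengths, width) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0) {
    stop("window width must be a positive number")
  }
  width <- as.integer(width)
  out <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq.int(0L, len - 1L, by = width)
    data.table(chrom = ch, start = starts, end = pmin(starts + width, len))
  }))
  setorder(out, chrom, start)
  out[]
}

# Pool one methylome's context-matched counts into fixed-width tiles.
# Returns window index (start %/% width), pooled counts per (chrom, wstart).
pool_into_tiles <- function(meth, width, context_) {
  s <- meth$sites[context == context_]
  if (nrow(s) == 0L) {
    return(data.table(chrom = character(), wstart = integer(),
                      n_meth = integer(), n_unmeth = integer()))
  }
  s[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
    by = .(chrom, wstart = (pos %/% width) * width)]
}

#' Per-window differential-methylation table
#'
#' Pools each sample's context-matched cytosine counts into the given
#' fixed-width tiling and computes, per window with coverage in either sample,
#' pooled fractions, the difference A − B, and a two-sided Fisher exact
#' p-value on the pooled 2x2 count table. Windows with no sequenced calls in
#' either sample are omitted; a window covered in only one sample is reported
#' with the other fraction `NA` (and p = 1), so difference-based consumers can
#' exclude it.
#'
#' @param meth_a,meth_b [methylome]s sharing chromosome lengths.
#' @param width Window width in bp (windows are the [tile_windows()] tiling).
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @return `data.table`: `chrom`, `start`, `end`, `n_meth_a`, `n_unmeth_a`,
#'   `n_meth_b`, `n_unmeth_b`, `informative_a`, `informative_b`, `frac_a`,
#'   `frac_b`, `diff`, `p`.
#' @export
window_table <- function(meth_a, meth_b, width, context) {
  if (!context %in% CONTEXTS) stop("unknown context: ", context)
  if (!identical(sort(names(meth_a$chrom_lengths)), sort(names(meth_b$chrom_lengths)))) {
    stop("methylomes do not share chromosomes")
  }
  width <- as.integer(width)
  ta <- pool_into_tiles(meth_a, width, context)
  tb <- pool_into_tiles(meth_b, width, context)
  tab <- merge(ta, tb, by = c("chrom", "wstart"), all = TRUE,
               suffixes = c("_a", "_b"))
  for (col in c("n_meth_a", "n_unmeth_a", "n_meth_b", "n_unmeth_b")) {
    set(tab, which(is.na(tab[[col]])), col, 0L)
  }
  cl <- meth_a$chrom_lengths
  tab[, `:=`(start = wstart,
             end = pmin(wstart + width, cl[chrom]),
             informative_a = n_meth_a + n_unmeth_a,
             informative_b = n_meth_b + n_unmeth_b)]
  tab[, `:=`(frac_a = fifelse(informative_a > 0L, n_meth_a / informative_a, NA_real_),
             frac_b = fifelse(informative_b > 0L, n_meth_b / informative_b, NA_real_))]
  tab[, diff := frac_a - frac_b]
  tab[, p := fisher_exact_2x2(n_meth_a, n_unmeth_a, n_meth_b, n_unmeth_b)]
  tab[, wstart := NULL]
  setorder(tab, chrom, start)
  setcolorder(tab, c("chrom", "start", "end"))
  tab[]
}

#' Per-window methylation differences for density plots
#'
#' The windowed differences underlying kernel-density comparisons of two
#' methylomes: 50-bp (by default) windows are kept when BOTH samples have at
#' least `min_informative` sequenced calls of the context and the fractional
#' methylation reaches `min_level` in at least one of the samples; for kept
#' windows the difference A − B is returned.
#'
#' @param meth_a,meth_b [methylome]s.
#' @param context Sequence context; also selects the default `min_level`
#'   (CG 0.5, CHG 0.4, CHH 0.1).
#' @param min_informative Minimum sequenced calls per window in each sample.
#' @param min_level Minimum fractional methylation in at least one sample.
#' @param width Window width in bp.
#' @return `data.table` of kept windows with their `diff` column; the raw
#'   diffs are `$diff`.
#' @export
density_differences <- function(meth_a, meth_b, context,
                                min_informative = default_thresholds()$density_min_informative,
                                min_level = default_thresholds()$density_min_level[[context]],
                                width = default_thresholds()$window_width_bp) {
  stopifnot(min_informative >= 1, min_level >= 0, min_level <= 1)
  tab <- window_table(meth_a, meth_b, width, context)
  tab[informative_a >= min_informative & informative_b >= min_informative &
        pmax(frac_a, frac_b) >= min_level]
}
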