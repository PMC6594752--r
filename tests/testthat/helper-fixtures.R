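library(data.table)

# methylome from a compact spec: one row per cytosine
mk_meth <- function(df, sample_id = "A", chrom_lengths = NULL) {
  methylome(as.data.table(df), sample_id, chrom_lengths)
}

# uniform-methylation methylome: CG sites every `step` bp on chr1, all at
# level p with fixed coverage (deterministic counts: round(cov * p))
mk_uniform <- function(len = 2000L, step = 10L, p = 0.8, cov = 20L,
                       context = "CG", sample_id = "A") {
  pos <- seq.int(0L, len - 1L, by = step)
  mk_meth(data.table(chrom = "chr1", pos = pos,
                     strand = rep(c("+", "-"), length.out = length(pos)),
                     context = context,
                     n_meth = as.integer(round(cov * p)),
                     n_unmeth = as.integer(cov - round(cov * p))),
          sample_id, c(chr1 = len))
}

# pair of methylomes identical except over [start, end) where B's CG level is
# p_b instead of p_a (deterministic counts; used for planted-block tests)
mk_block_pair <- function(len = 4000L, step = 10L, p_a = 0.9, p_b = 0.3,
                          block = c(1000L, 1400L), cov = 20L) {
  pos <- seq.int(0L, len - 1L, by = step)
  base <- data.table(chrom = "chr1", pos = pos,
                     strand = rep(c("+", "-"), length.out = length(pos)),
                     context = "CG")
  a <- copy(base)[, `:=`(n_meth = as.integer(round(cov * p_a)),
                         n_unmeth = as.integer(cov - round(cov * p_a)))]
  b <- copy(base)
  inblk <- b$pos >= block[1] & b$pos < block[2]
  pb <- ifelse(inblk, p_b, p_a)
  b[, `:=`(n_meth = as.integer(round(cov * pb)),
           n_unmeth = as.integer(cov - round(cov * pb)))]
  list(a = mk_meth(a, "A", c(chr1 = len)), b = mk_meth(b, "B", c(chr1 = len)))
}

# small deterministic region table
mk_regions <- function(starts, ends, chrom = "chr1") {
  data.table(chrom = chrom, start = as.integer(starts), end = as.integer(ends))
}
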