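#' @import data.table
#' @importFrom stats dhyper rbinom rpois rnorm runif setNames
#' @importFrom utils head tail
NULL

# Internal coordinates are 0-based half-open throughout; cytosine-report input
# positions are 1-based (Bismark) and converted on read.

CONTEXTS <- c("CG", "CHG", "CHH")

#' Construct a methylome
#'
#' A methylome is one cell type's collection of per-cytosine methylation
#' observations, stored as a `data.table` keyed by (chrom, pos, strand) with
#' 0-based positions, plus the chromosome lengths of its genome.
#'
#' @param sites A data.frame/data.table with columns `chrom`, `pos` (0-based),
#'   `strand` (`+`/`-`), `context` (`CG`/`CHG`/`CHH`), `n_meth`, `n_unmeth`.
#' @param sample_id Label for the cell type (e.g. `"sperm"`, `"VC"`).
#' @param chrom_lengths Named integer vector of chromosome lengths. If `NULL`,
#'   inferred as `max(pos) + 1` per chromosome.
#' @return An object of class `methylome`.
#' @export
#' @examples
#' m <- methylome(
#'   data.frame(chrom = "chr1", pos = c(10, 12), strand = "+",
#'              context = "CG", n_meth = c(5, 0), n_unmeth = c(5, 10)),
#'   sample_id = "sperm", chrom_lengths = c(chr1 = 100))
#' m
methylome <- function(sites, sample_id, chrom_lengths = NULL) {
  sites <- as.data.table(sites)
  req <- c("chrom", "pos", "strand", "context", "n_meth", "n_unmeth")
  missing_cols <- setdiff(req, names(sites))
  if (length(missing_cols)) {
    stop("methylome sites lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  sites <- sites[, req, with = FALSE]
  sites[, `:=`(chrom = as.character(chrom), pos = as.integer(pos),
               strand = as.character(strand), context = as.character(context),
               n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth))]
  if (nrow(sites)) {
    if (anyNA(sites)) stop("methylome sites contain NA values")
    if (any(sites$n_meth < 0L) || any(sites$n_unmeth < 0L)) {
      stop("negative methylation counts")
    }
    bad_ctx <- setdiff(unique(sites$context), CONTEXTS)
    if (length(bad_ctx)) stop("unknown context label(s): ", paste(bad_ctx, collapse = ", "))
    if (!all(sites$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (anyDuplicated(sites, by = c("chrom", "pos", "strand"))) {
      stop("duplicate (chrom, pos, strand) keys in methylome")
    }
  }
  if (is.null(chrom_lengths)) {
    if (nrow(sites)) {
      cl <- sites[, .(len = max(pos) + 1L), by = chrom]
      chrom_lengths <- setNames(cl$len, cl$chrom)
    } else {
      chrom_lengths <- integer(0)
    }
  }
  chrom_lengths <- setNames(as.integer(chrom_lengths), names(chrom_lengths))
  if (nrow(sites)) {
    unknown <- setdiff(unique(sites$chrom), names(chrom_lengths))
    if (length(unknown)) stop("sites on chromosome(s) absent from chrom_lengths: ",
                              paste(unknown, collapse = ", "))
    over <- sites[pos >= chrom_lengths[chrom] | pos < 0L]
    if (nrow(over)) stop("site position outside chromosome bounds (e.g. ",
                         over$chrom[1], ":", over$pos[1], ")")
  }
  setkey(sites, chrom, pos, strand)
  structure(list(sample_id = sample_id, sites = sites,
                 chrom_lengths = chrom_lengths),
            class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  cov <- x$sites$n_meth + x$sites$n_unmeth
  cat("<methylome> sample:", x$sample_id,
      "|", nrow(x$sites), "cytosines on", length(x$chrom_lengths),
      "chromosome(s)\n")
  if (nrow(x$sites)) {
    tab <- x$sites[, .N, by = context]
    cat("  contexts:", paste(sprintf("%s=%d", tab$context, tab$N), collapse = " "),
        sprintf("| mean coverage %.1f\n", mean(cov)))
  }
  invisible(x)
}

#' Pooled fractional methylation
#'
#' Fractional methylation of a set of cytosines computed from pooled counts:
#' total methylated calls over total calls, optionally restricted to one
#' sequence context. Pooling (rather than averaging per-site fractions) is the
#' convention used for every region-level quantity in this package; it is
#' robust to uneven coverage and additive under partitioning.
#'
#' @param sites data.frame/data.table of cytosine sites with `n_meth`,
#'   `n_unmeth` and (if `context` is given) `context` columns.
#' @param context Optional context label to filter on (`"CG"`, `"CHG"`, `"CHH"`).
#' @return Fraction in `[0, 1]`, or `NA_real_` when the pooled coverage is zero
#'   (an undefined level, distinct from 0).
#' @export
#' @examples
#' s <- data.frame(context = "CG", n_meth = c(5, 0), n_unmeth = c(5, 10))
#' pooled_fraction(s, "CG")  # 5/20 = 0.25
pooled_fraction <- function(sites, context = NULL) {
  sites <- as.data.table(sites)
  if (!is.null(context)) {
    if (!context %in% CONTEXTS) stop("unknown context: ", context)
    ctx <- context
    sites <- sites[sites[["context"]] == ctx]
  }
  if (nrow(sites) && (any(sites$n_meth < 0) || any(sites$n_unmeth < 0))) {
    stop("negative methylation counts")
  }
  tot <- sum(sites$n_meth) + sum(sites$n_unmeth)
  if (tot == 0) return(NA_real_)
  sum(sites$n_meth) / tot
}

#' Assign scores to ordered groups
#'
#' Partitions the real line into `length(bounds) + 1` left-closed groups
#' (`[b[k-1], b[k])`) and returns, for each score, the 1-based group index.
#' Used to stratify DME sites into five H3K9me2-level groups with the default
#' bounds 2.5, 4.3, 6.5, 10.5.
#'
#' @param score Numeric vector of scores (finite).
#' @param bounds Strictly increasing numeric vector of group boundaries.
#' @return Integer vector of group indices in `1..(length(bounds)+1)`.
#' @export
#' @examples
#' score_quantile_group(c(1, 3, 11), c(2.5, 4.3, 6.5, 10.5))  # 1 2 5
score_quantile_group <- function(score, bounds) {
  if (is.unsorted(bounds, strictly = TRUE)) stop("bounds must be strictly increasing")
  if (any(!is.finite(score))) stop("non-finite score")
  # left-closed convention: score equal to a bound falls in the upper group
  findInterval(score, bounds, left.open = FALSE) + 1L
}

# Pooled counts of one methylome over a genomic span [start, end), one context.
# Returns list(n_meth, n_unmeth). Internal workhorse for region statistics.
region_counts <- function(meth, chrom_, start_, end_, context_) {
  s <- meth$sites[.(chrom_)][pos >= start_ & pos < end_ & context == context_]
  list(n_meth = sum(s$n_meth, na.rm = TRUE), n_unmeth = sum(s$n_unmeth, na.rm = TRUE))
}
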