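#' Read a Bismark-style cytosine report
#'
#' Parses the tab-separated per-cytosine report (chromosome, 1-based position,
#' strand, methylated count, unmethylated count, context, and an optional
#' seventh trinucleotide column which is ignored). The 6- and 7-column
#' dialects are auto-detected; gzip-compressed files are read transparently.
#' Positions are converted to the package's internal 0-based convention.
#' `CpG` is normalized to `CG`.
#'
#' @param path Path to the report (optionally `.gz`).
#' @param sample_id Label for the resulting methylome.
#' @param chrom_lengths Optional named vector of chromosome lengths; inferred
#'   from the data when `NULL`.
#' @return A [methylome].
#' @export
read_cytosine_report <- function(path, sample_id, chrom_lengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- if (file.size(path) == 0L) data.table() else tryCatch(
    fread(path, header = FALSE, sep = "\t", colClasses = list(character = 1),
          showProgress = FALSE),
    error = function(e) stop("failed to parse cytosine report ", path, ": ",
                             conditionMessage(e)))
  if (nrow(dt) == 0L) {
    warning("empty cytosine report: ", path)
    return(methylome(data.table(chrom = character(), pos = integer(),
                                strand = character(), context = character(),
                                n_meth = integer(), n_unmeth = integer()),
                     sample_id, chrom_lengths))
  }
  if (!ncol(dt) %in% c(6L, 7L)) {
    stop("cytosine report must have 6 or 7 tab-separated columns, found ",
         ncol(dt), " in ", path)
  }
  setnames(dt, 1:6, c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context"))
  for (col in c("pos", "n_meth", "n_unmeth")) {
    v <- suppressWarnings(as.integer(dt[[col]]))
    bad <- which(is.na(v) & !is.na(dt[[col]]) | is.na(dt[[col]]))
    if (length(bad)) {
      stop("malformed ", col, " at line ", bad[1], " of ", path,
           " (value '", dt[[col]][bad[1]], "')")
    }
    set(dt, j = col, value = v)
  }
  dt[, context := toupper(as.character(context))]
  dt[context == "CPG", context := "CG"]
  bad_ctx <- which(!dt$context %in% CONTEXTS)
  if (length(bad_ctx)) {
    stop("unknown context '", dt$context[bad_ctx[1]], "' at line ", bad_ctx[1],
         " of ", path)
  }
  bad_strand <- which(!dt$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop("bad strand '", dt$strand[bad_strand[1]], "' at line ", bad_strand[1],
         " of ", path)
  }
  dup <- which(duplicated(dt, by = c("chrom", "pos", "strand")))
  if (length(dup)) {
    stop("duplicate (chrom, pos, strand) at line ", dup[1], " of ", path)
  }
  dt[, pos := pos - 1L]   # 1-based report -> 0-based internal
  methylome(dt[, .(chrom, pos, strand, context, n_meth, n_unmeth)],
            sample_id, chrom_lengths)
}

#' Write a methylome as a cytosine report
#'
#' Inverse of [read_cytosine_report()]: emits the 7-column dialect with
#' 1-based positions and a placeholder trinucleotide column.
#'
#' @param meth A [methylome].
#' @param path Output path (plain text; add `.gz` for gzip).
#' @export
write_cytosine_report <- function(meth, path) {
  out <- copy(meth$sites)
  setorder(out, chrom, pos, strand)
  out <- out[, .(chrom, pos = pos + 1L, strand, n_meth, n_unmeth, context,
                 tri = context)]
  fwrite(out, path, sep = "\t", col.names = FALSE, compress = "auto")
  invisible(path)
}

#' Read a TE/gene annotation (GFF3 or BED)
#'
#' Returns one row per element with 0-based half-open coordinates, the kind
#' (`TE` or `gene`, from the GFF3 `type` column or a BED `kind` heuristic),
#' the superfamily (GFF3 attribute `superfamily`, or column 7 of an extended
#' BED; `"unknown"` when absent) and strand-derived TSS/TTS positions
#' (0-based point coordinates: for `+` elements tss = start, tts = end − 1;
#' for `-` elements tss = end − 1, tts = start). Elements without strand are
#' kept with strand `"."` and tss = start, with a message.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file.
#' @return `data.table` with columns `id`, `chrom`, `start`, `end`, `strand`,
#'   `kind`, `superfamily`, `tss`, `tts`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  is_bed <- grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)
  if (is_bed) {
    dt <- fread(path, header = FALSE, sep = "\t", showProgress = FALSE)
    if (ncol(dt) < 6L) stop("BED annotation needs at least 6 columns: ", path)
    el <- data.table(
      id = as.character(dt[[4]]), chrom = as.character(dt[[1]]),
      start = as.integer(dt[[2]]), end = as.integer(dt[[3]]),
      strand = as.character(dt[[6]]),
      kind = "TE",
      superfamily = if (ncol(dt) >= 7L) as.character(dt[[7]]) else NA_character_)
  } else {
    gr <- rtracklayer::import(path)
    mc <- S4Vectors::mcols(gr)
    id <- if ("ID" %in% names(mc)) as.character(mc$ID)
          else if ("Name" %in% names(mc)) as.character(mc$Name)
          else paste0("elem_", seq_along(gr))
    type <- if ("type" %in% names(mc)) as.character(mc$type) else "TE"
    el <- data.table(
      id = id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # GFF3 1-based inclusive -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      kind = ifelse(grepl("gene", type, ignore.case = TRUE), "gene", "TE"),
      superfamily = if ("superfamily" %in% names(mc)) as.character(mc$superfamily)
                    else NA_character_)
  }
  if (any(el$start >= el$end)) {
    bad <- el[start >= end][1]
    stop("empty or inverted interval for element '", bad$id, "' (",
         bad$start, " >= ", bad$end, ")")
  }
  el[is.na(superfamily) | superfamily == "", superfamily := "unknown"]
  el[strand == "*", strand := "."]
  n_nostrand <- sum(el$strand == ".")
  if (n_nostrand) {
    message(n_nostrand, " element(s) without strand kept with strand '.' and tss = start")
  }
  el[, tss := fifelse(strand == "-", end - 1L, start)]
  el[, tts := fifelse(strand == "-", start, end - 1L)]
  setorder(el, chrom, start)
  el[]
}

#' Read a bedGraph score track
#'
#' @param path bedGraph file (chrom, 0-based start, end, score). Intervals must
#'   be non-overlapping within each chromosome and scores finite.
#' @return `data.table` with columns `chrom`, `start`, `end`, `score`, sorted.
#' @export
read_score_track <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   score = as.numeric(S4Vectors::mcols(gr)$score))
  if (anyNA(dt$score) || any(!is.finite(dt$score))) {
    stop("non-numeric or missing score in ", path)
  }
  setorder(dt, chrom, start)
  ovl <- dt[, any(start[-1] < head(end, -1)), by = chrom]$V1
  if (any(ovl)) stop("overlapping intervals in score track ", path)
  dt[]
}

#' Write DMRs / DME sites as a BED-like TSV
#'
#' Columns: chrom, start, end, length, pooled counts per sample, fractional
#' methylation per sample, difference and Fisher p, sorted by (chrom, start).
#' Anchor and H3K9me2-group columns present in the input (Procedure B output)
#' are carried through. Counts are included so that [read_dmrs()] round-trips
#' the regions exactly.
#'
#' @param regions `data.table` of finalized regions (see [call_dme_targets()]).
#' @param path Output path.
#' @export
write_dmrs <- function(regions, path) {
  base_cols <- c("chrom", "start", "end", "length",
                 "n_meth_a", "n_unmeth_a", "n_meth_b", "n_unmeth_b",
                 "frac_a", "frac_b", "diff", "p")
  extra <- intersect(c("anchor_pos", "anchor_diff", "anchor_p",
                       "h3k9me2_score", "group"), names(regions))
  out <- as.data.table(regions)
  if (nrow(out) == 0L) {
    out <- setnames(as.data.table(matrix(nrow = 0, ncol = length(base_cols) + length(extra))),
                    c(base_cols, extra))
  } else {
    if (!"length" %in% names(out)) out[, length := end - start]
    missing_cols <- setdiff(base_cols, names(out))
    if (length(missing_cols)) stop("regions lack column(s): ",
                                   paste(missing_cols, collapse = ", "))
    out <- out[, c(base_cols, extra), with = FALSE]
    setorder(out, chrom, start)
  }
  fwrite(out, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read a DMR table written by [write_dmrs()]
#' @param path Path to the TSV.
#' @return `data.table` of regions.
#' @export
read_dmrs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", showProgress = FALSE)
  setorder(dt, chrom, start)
  dt[]
}

#' Read an expression table
#'
#' TSV with columns `id`, one or more `tpm_<sample>` columns, `fold_change`
#' and `lrt_p` (likelihood-ratio-test p-value from the upstream
#' quantification), as produced by external transcript quantification.
#'
#' @param path Path to the TSV.
#' @return `data.table`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", showProgress = FALSE)
  req <- c("id", "fold_change", "lrt_p")
  missing_cols <- setdiff(req, names(dt))
  if (length(missing_cols)) stop("expression table lacks column(s): ",
                                 paste(missing_cols, collapse = ", "))
  if (!any(grepl("^tpm_", names(dt)))) stop("expression table has no tpm_<sample> column")
  dt[]
}
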