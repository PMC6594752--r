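#' Default analysis thresholds
#'
#' Registry of every tunable cutoff used by the pipeline, with defaults equal
#' to the published analysis settings. Downstream functions take individual
#' arguments that default to entries of this list, so a single edited copy of
#' the registry (or a YAML override file, see [read_thresholds()]) reconfigures
#' the whole pipeline consistently.
#'
#' Groups of settings:
#' \describe{
#'   \item{DMR calling (Procedure A / C)}{`seed_bin_bp` (100), `seed_p` (0.05):
#'     binned Fisher seeding; `candidate_min_diff` (0.2): whole-candidate
#'     pooled-fraction difference; `merge_gap_a_bp` (300); `final_min_len_bp`
#'     (100), `final_p_a` (0.01), `final_min_diff_a` (0.2): final gates.}
#'   \item{DME sites (Procedure B)}{`window_width_bp` (50), `site_seed_diff`
#'     (0.5), `site_seed_p` (0.001), `merge_gap_b_bp` (200), `site_final_diff`
#'     (0.2), `site_final_p` (1e-4).}
#'   \item{Anchors}{`anchor_min_diff` (0.2), `anchor_p` (0.001),
#'     `anchor_min_cov` (10 reads in each sample).}
#'   \item{H3K9me2 stratification}{`h3k9me2_bounds` (2.5, 4.3, 6.5, 10.5),
#'     defining five left-closed groups.}
#'   \item{Profiles}{`ends_bin_bp` (100), `ends_flank_bp` (2000),
#'     `anchor_profile_bin_bp` (10), `anchor_profile_flank_bp` (500).}
#'   \item{Density plots}{`density_min_informative` (20 sequenced calls in both
#'     samples), `density_min_level` (CG 0.5, CHG 0.4, CHH 0.1; the stricter CG
#'     alternative 0.7 is available as `density_min_level_cg_strict`).}
#'   \item{TE classification}{`tss_proximity_bp` (500), `tss_heatmap_halfwidth_bp`
#'     (500), `heatmap_diff` (CG 0.2, CHG 0.1, CHH 0.05), `heatmap_p` (0.001),
#'     `activation_fc` (5), `de_fc` (2), `de_p` (0.05), `expressed_tpm` (5),
#'     `leaf_cg_min` (0.7).}
#' }
#'
#' @return Named list of thresholds.
#' @export
#' @examples
#' cfg <- default_thresholds()
#' cfg$site_seed_diff
default_thresholds <- function() {
  list(
    window_width_bp        = 50L,
    seed_bin_bp            = 100L,
    seed_p                 = 0.05,
    candidate_min_diff     = 0.2,
    merge_gap_a_bp         = 300L,
    final_min_len_bp       = 100L,
    final_p_a              = 0.01,
    final_min_diff_a       = 0.2,
    site_seed_diff         = 0.5,
    site_seed_p            = 0.001,
    merge_gap_b_bp         = 200L,
    site_final_diff        = 0.2,
    site_final_p           = 1e-4,
    anchor_min_diff        = 0.2,
    anchor_p               = 0.001,
    anchor_min_cov         = 10L,
    h3k9me2_bounds         = c(2.5, 4.3, 6.5, 10.5),
    ends_bin_bp            = 100L,
    ends_flank_bp          = 2000L,
    anchor_profile_bin_bp  = 10L,
    anchor_profile_flank_bp = 500L,
    density_min_informative = 20L,
    density_min_level      = c(CG = 0.5, CHG = 0.4, CHH = 0.1),
    density_min_level_cg_strict = 0.7,
    tss_proximity_bp       = 500L,
    tss_heatmap_halfwidth_bp = 500L,
    heatmap_diff           = c(CG = 0.2, CHG = 0.1, CHH = 0.05),
    heatmap_p              = 0.001,
    activation_fc          = 5,
    de_fc                  = 2,
    de_p                   = 0.05,
    expressed_tpm          = 5,
    leaf_cg_min            = 0.7
  )
}

#' Read a threshold configuration file
#'
#' Loads a YAML file whose keys mirror [default_thresholds()]; keys absent from
#' the file keep their defaults, unknown keys are an error (they are almost
#' certainly typos).
#'
#' @param path Path to a YAML file.
#' @return Named list with the same structure as [default_thresholds()].
#' @export
read_thresholds <- function(path) {
  stopifnot(file.exists(path))
  user <- yaml::read_yaml(path)
  cfg <- default_thresholds()
  if (is.null(user)) return(cfg)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) {
    stop("unknown threshold key(s): ", paste(bad, collapse = ", "))
  }
  for (k in names(user)) {
    v <- user[[k]]
    tmpl <- cfg[[k]]
    if (!is.null(names(tmpl))) {
      v <- unlist(v)
      missing_names <- setdiff(names(tmpl), names(v))
      v <- c(v, tmpl[missing_names])[names(tmpl)]
    }
    cfg[[k]] <- v
  }
  validate_thresholds(cfg)
  cfg
}

validate_thresholds <- function(cfg) {
  scalars <- setdiff(names(cfg), c("h3k9me2_bounds", "density_min_level", "heatmap_diff"))
  for (k in scalars) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || !is.finite(cfg[[k]]) ||
        cfg[[k]] <= 0) {
      stop("threshold '", k, "' must be a single positive finite number")
    }
  }
  b <- cfg$h3k9me2_bounds
  if (!is.numeric(b) || length(b) < 1L || any(!is.finite(b)) || is.unsorted(b, strictly = TRUE)) {
    stop("h3k9me2_bounds must be strictly increasing finite numbers")
  }
  for (k in c("density_min_level", "heatmap_diff")) {
    v <- cfg[[k]]
    if (!all(c("CG", "CHG", "CHH") %in% names(v)) || any(v <= 0)) {
      stop("threshold '", k, "' must name positive values for CG, CHG, CHH")
    }
  }
  invisible(cfg)
}
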