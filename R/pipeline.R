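#' One-call NCLDV abundance estimation for a set of samples
#'
#' Chains the marker route end to end: six-frame peptide extraction,
#' profile scanning, binning (by profile group, or by 2bLCA when
#' `assignments` are supplied), per-sample densities, the
#' NCLDV:prokaryote density ratio, and — when cell counts are given —
#' the rescaled absolute genome concentration.
#'
#' @param reads Tibble of reads (`read_id`, `sample_id`, `seq`),
#'   typically already deduplicated.
#' @param profiles A [marker_profiles()] object.
#' @param sample_stats Tibble with `sample_id`, `total_bp`.
#' @param cell_counts Optional cell-count tibble for rescaling.
#' @param assignments Optional [classify_bin()] output for 2bLCA
#'   binning.
#' @param bin_by `"profile"` or `"2blca"`.
#' @param mode Across-marker summary (default `"mean"`).
#' @param normalised Use alignment-length-normalised densities.
#' @param max_evalue Marker scan threshold (default 1e-3).
#' @param min_len_aa,min_overlap Peptide extraction / scan parameters.
#' @param passthrough Pre-filter pass-through fraction (default 0.9).
#' @return List with `hits`, `densities`, `ratios` and (if counts were
#'   given) `estimates` (an `ncldv_abundance` tibble).
#' @export
estimate_ncldv_abundance <- function(reads, profiles, sample_stats,
                                     cell_counts = NULL,
                                     assignments = NULL,
                                     bin_by = c("profile", "2blca"),
                                     mode = "mean", normalised = FALSE,
                                     max_evalue = 1e-3, min_len_aa = 20L,
                                     min_overlap = 30L,
                                     passthrough = 0.9) {
  bin_by <- match.arg(bin_by)
  peps <- six_frame_orfs(reads, min_len_aa = min_len_aa)
  hits <- scan_markers(peps, profiles, max_evalue = max_evalue,
                       min_overlap = min_overlap)
  hits <- bin_marker_hits(hits, assignments, by = bin_by)
  dens <- marker_density(hits, sample_stats, profiles)
  ratios <- abundance_ratio(dens, mode = mode, normalised = normalised)
  out <- list(hits = hits, densities = dens, ratios = ratios)
  if (!is.null(cell_counts)) {
    out$estimates <- absolute_abundance(ratios, cell_counts,
                                        passthrough = passthrough)
  }
  out
}
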