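#' Analysis configuration
#'
#' Collects every numeric parameter of the pipeline in one validated list.
#' Defaults are the values used throughout the analysis: a 300 bp
#' co-association window (maximum summit distance of 150 bp), a Poisson null
#' scaled by ~250,000 accessible (DNaseI-hypersensitive) 150 bp regions,
#' significance at a co-association score (signed -log10 Bonferroni-corrected
#' p) above 100 together with an anchor-share above 10%, motif enrichment
#' called below p = 1e-10, and the replicate-curation, promoter-window,
#' pathway-filter and DEG thresholds listed below.
#'
#' @param overlap_half_window Maximum distance (bp) between two summits for
#'   them to count as overlapping; the counting window is twice this, centered
#'   on a summit.
#' @param accessible_regions_n Number of 150 bp accessible regions used as the
#'   scale of the Poisson null.
#' @param motif_p_threshold Significance threshold for global/local motif
#'   enrichment p-values.
#' @param coassoc_score_threshold Significance threshold (strict) on the
#'   co-association score.
#' @param nfyb_share_threshold Minimum (strict) fraction of anchor (NF-YB)
#'   peaks shared with a factor for a significant call.
#' @param group1_min_factor_share Strict lower bound on the factor-peak share
#'   overlapping the anchor for Group 1.
#' @param group3_max_factor_share Strict upper bound on the factor-peak share
#'   for Group 3.
#' @param min_peaks_replicate Minimum peak count for a replicate to survive
#'   curation.
#' @param replicate_overlap_keep Minimum (strict) pairwise replicate summit
#'   overlap for a duplicate group to be kept.
#' @param minima_overlap_discard Replicates with fewer than this fraction of
#'   the next-larger replicate's peaks are discarded.
#' @param promoter_window_pathways Promoter window around the TSS, in
#'   strand-oriented bp, used for target-gene assignment (upstream negative).
#' @param promoter_window_tfbs Proximal promoter window used for TFBS
#'   enrichment.
#' @param pathway_p_threshold Maximum ORA p-value for a pathway to be kept.
#' @param pathway_max_background Maximum pathway background gene count.
#' @param deg_fdr,deg_abs_lfc Strict DEG thresholds (FDR < deg_fdr and
#'   |log2FC| > deg_abs_lfc).
#' @param segmentation_bin Chromatin segmentation bin width (bp).
#' @param min_ccaat_score Minimum normalized CCAAT match score for a region to
#'   enter the positional-bias analysis.
#' @param random_seed Integer seed recorded in outputs.
#'
#' @return A list of class \code{nfy_config}.
#' @export
analysis_config <- function(overlap_half_window = 150L,
                            accessible_regions_n = 250000L,
                            motif_p_threshold = 1e-10,
                            coassoc_score_threshold = 100,
                            nfyb_share_threshold = 0.10,
                            group1_min_factor_share = 0.20,
                            group3_max_factor_share = 0.05,
                            min_peaks_replicate = 10000L,
                            replicate_overlap_keep = 0.66,
                            minima_overlap_discard = 0.50,
                            promoter_window_pathways = c(-1000L, 100L),
                            promoter_window_tfbs = c(-450L, 50L),
                            pathway_p_threshold = 1e-5,
                            pathway_max_background = 200L,
                            deg_fdr = 0.01,
                            deg_abs_lfc = 1.0,
                            segmentation_bin = 200L,
                            min_ccaat_score = 0.8,
                            random_seed = 1L) {
  cfg <- list(
    overlap_half_window = as.integer(overlap_half_window),
    accessible_regions_n = as.numeric(accessible_regions_n),
    motif_p_threshold = motif_p_threshold,
    coassoc_score_threshold = coassoc_score_threshold,
    nfyb_share_threshold = nfyb_share_threshold,
    group1_min_factor_share = group1_min_factor_share,
    group3_max_factor_share = group3_max_factor_share,
    min_peaks_replicate = as.integer(min_peaks_replicate),
    replicate_overlap_keep = replicate_overlap_keep,
    minima_overlap_discard = minima_overlap_discard,
    promoter_window_pathways = as.integer(promoter_window_pathways),
    promoter_window_tfbs = as.integer(promoter_window_tfbs),
    pathway_p_threshold = pathway_p_threshold,
    pathway_max_background = as.integer(pathway_max_background),
    deg_fdr = deg_fdr,
    deg_abs_lfc = deg_abs_lfc,
    segmentation_bin = as.integer(segmentation_bin),
    min_ccaat_score = min_ccaat_score,
    random_seed = as.integer(random_seed)
  )
  thresholds <- c(cfg$overlap_half_window, cfg$accessible_regions_n,
                  cfg$motif_p_threshold, cfg$coassoc_score_threshold,
                  cfg$min_peaks_replicate, cfg$pathway_p_threshold,
                  cfg$pathway_max_background, cfg$deg_fdr, cfg$deg_abs_lfc,
                  cfg$segmentation_bin)
  if (any(thresholds <= 0)) stop("all thresholds must be positive")
  shares <- c(cfg$nfyb_share_threshold, cfg$group1_min_factor_share,
              cfg$group3_max_factor_share, cfg$replicate_overlap_keep,
              cfg$minima_overlap_discard)
  if (any(shares < 0 | shares > 1)) stop("share thresholds must lie in [0, 1]")
  for (w in list(cfg$promoter_window_pathways, cfg$promoter_window_tfbs)) {
    if (length(w) != 2L || w[1] >= w[2]) stop("promoter windows must be (upstream, downstream) with upstream < downstream")
  }
  class(cfg) <- "nfy_config"
  cfg
}

#' @export
print.nfy_config <- function(x, ...) {
  cat("<nfy_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

# Smallest positive (subnormal) double: the floor applied to p-values before
# -log10, giving the score ceiling of floor(-log10(2^-1074)) = 323.
.P_FLOOR <- 2^-1074

#' Clamped -log10 transform
#'
#' p-values are clamped below at the smallest positive subnormal double
#' (2^-1074) before taking -log10, so that fully underflowed p-values map to
#' the finite score ceiling of ~323.3 rather than Inf.
#'
#' @param p Numeric vector of p-values.
#' @return -log10 of the clamped values.
#' @export
neg_log10 <- function(p) {
  -log10(pmax(p, .P_FLOOR))
}
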