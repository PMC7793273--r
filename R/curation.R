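# Dataset curation: reduce a manifest of ChIP-seq experiments to one kept
# dataset per factor per cell line, mirroring the replicate-filtering
# workflow used for the ENCODE peak collections.

#' Summit-overlap concordance between two replicates
#'
#' The fraction of summits of the smaller replicate lying within the
#' co-association window (150 bp maximum summit distance) of some summit of
#' the larger. Defining the denominator on the smaller set is the most
#' conservative symmetric choice.
#'
#' @param a,b Non-empty \code{PeakSet}s.
#' @param cfg \code{\link{analysis_config}}.
#' @return Fraction in [0, 1].
#' @export
replicate_overlap <- function(a, b, cfg = analysis_config()) {
  stopifnot(inherits(a, "PeakSet"), inherits(b, "PeakSet"))
  if (!nrow(a$peaks) || !nrow(b$peaks)) stop("replicate peak sets must be non-empty")
  if (nrow(a$peaks) > nrow(b$peaks)) { tmp <- a; a <- b; b <- tmp }
  mean(.summits_hit(a$peaks$chrom, a$peaks$summit,
                    b$peaks$chrom, b$peaks$summit,
                    cfg$overlap_half_window))
}

#' Curate an experiment manifest
#'
#' Applies the replicate-curation workflow, in order:
#' \enumerate{
#'   \item Treated experiments are split into a side channel (they bypass
#'     the remaining stages and are kept, labelled by treatment).
#'   \item Within each (factor, cell line) duplicate group, tagged-protein
#'     experiments are removed when an untagged one exists.
#'   \item Replicates with fewer than \code{min_peaks_replicate} peaks, or
#'     with fewer than half the peaks of the next-larger replicate of the
#'     same factor/cell line (the "minima"), are discarded.
#'   \item Surviving duplicate groups are kept only if some replicate pair
#'     has summit concordance strictly above \code{replicate_overlap_keep}
#'     (66%); the member with the most peaks is then kept. Groups failing
#'     the gate are dropped entirely.
#' }
#' Singleton groups (unique experiments) bypass stages 3-4: with no
#' replicate to compare against they enter the pipeline directly.
#'
#' @param manifest data.frame with columns experiment_id, factor, cell_line,
#'   is_tagged (logical), treated (logical).
#' @param peaks Named list of \code{PeakSet}s, names = experiment ids.
#' @param cfg \code{\link{analysis_config}}.
#' @return Object of class \code{CurationReport}: \code{kept} (experiment
#'   ids), \code{treated} (side channel ids), \code{dropped} (data.frame id
#'   / reason), \code{counts_by_stage}.
#' @export
curate <- function(manifest, peaks, cfg = analysis_config()) {
  req <- c("experiment_id", "factor", "cell_line", "is_tagged", "treated")
  stopifnot(all(req %in% names(manifest)))
  if (anyDuplicated(manifest$experiment_id)) stop("duplicate experiment_id in manifest")
  dangling <- setdiff(manifest$experiment_id, names(peaks))
  if (length(dangling)) {
    stop("manifest entries without a peak set: ", paste(dangling, collapse = ", "))
  }
  dropped <- data.frame(experiment_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop <- function(ids, reason) {
    if (length(ids)) {
      dropped <<- rbind(dropped, data.frame(experiment_id = ids, reason = reason,
                                            stringsAsFactors = FALSE))
    }
  }
  stage_counts <- c(input = nrow(manifest))

  treated_ids <- manifest$experiment_id[manifest$treated]
  main <- manifest[!manifest$treated, , drop = FALSE]
  stage_counts["after_treated_split"] <- nrow(main)

  main$n_peaks <- vapply(main$experiment_id,
                         function(id) nrow(peaks[[id]]$peaks), 1L)
  groups <- split(main, paste(main$factor, main$cell_line, sep = "\r"))
  kept <- character()
  for (g in groups) {
    # stage 2: tagged removal within duplicate groups
    if (nrow(g) > 1L && any(!g$is_tagged) && any(g$is_tagged)) {
      drop(g$experiment_id[g$is_tagged], "tagged_duplicate")
      g <- g[!g$is_tagged, , drop = FALSE]
    }
    if (nrow(g) == 1L) { kept <- c(kept, g$experiment_id); next }
    # stage 3: minima by peak count, assessed against the next-larger
    # replicate of the same factor/cell line
    g <- g[order(g$n_peaks), , drop = FALSE]
    minima <- vapply(seq_len(nrow(g)), function(i) {
      if (g$n_peaks[i] < cfg$min_peaks_replicate) return(TRUE)
      larger <- g$n_peaks[g$n_peaks > g$n_peaks[i]]
      length(larger) > 0L &&
        g$n_peaks[i] < cfg$minima_overlap_discard * min(larger)
    }, TRUE)
    drop(g$experiment_id[minima], "minima_low_peaks")
    g <- g[!minima, , drop = FALSE]
    if (!nrow(g)) next
    if (nrow(g) == 1L) { kept <- c(kept, g$experiment_id); next }
    # stage 4: concordance gate, then keep the largest member
    ids <- g$experiment_id
    best <- 0
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      best <- max(best, replicate_overlap(peaks[[ids[i]]], peaks[[ids[j]]], cfg))
    }
    if (best > cfg$replicate_overlap_keep) {
      winner <- g$experiment_id[which.max(g$n_peaks)]
      kept <- c(kept, winner)
      drop(setdiff(ids, winner), "replicate_not_largest")
    } else {
      drop(ids, "low_replicate_concordance")
    }
  }
  stage_counts["after_tagged"] <- stage_counts["after_treated_split"] -
    sum(dropped$reason == "tagged_duplicate")
  stage_counts["after_minima"] <- stage_counts["after_tagged"] -
    sum(dropped$reason == "minima_low_peaks")
  stage_counts["kept"] <- length(kept)
  structure(list(kept = sort(kept), treated = sort(treated_ids),
                 dropped = dropped, counts_by_stage = stage_counts),
            class = "CurationReport")
}

#' @export
print.CurationReport <- function(x, ...) {
  cat("<CurationReport>\n")
  cat("  kept:   ", length(x$kept), "\n")
  cat("  treated:", length(x$treated), "(side channel)\n")
  cat("  dropped:", nrow(x$dropped), "\n")
  if (nrow(x$dropped)) {
    tab <- table(x$dropped$reason)
    for (r in names(tab)) cat(sprintf("    %-28s %d\n", r, tab[[r]]))
  }
  invisible(x)
}
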