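# Four-group partner classification: combine the CCAAT enrichment class
# with the overlap shares against the NF-YB anchor.

#' Assign a factor to one of the four co-association groups
#'
#' Rules, applied in order on the per-cell-line records of one factor
#' (a dataset analyzed under treatment is classified as its own factor,
#' e.g. \code{IRF1_0}):
#' \enumerate{
#'   \item \strong{Group 1}: some cell line has \emph{global} CCAAT
#'     enrichment (primary or secondary) and factor share
#'     (fraction of the factor's peaks overlapping NF-YB) strictly above
#'     20%.
#'   \item \strong{Group 2}: some cell line has CCAAT enrichment (any
#'     class) and factor share in (5%, 20%] -- a share of exactly 20%
#'     lands here, not in Group 1.
#'   \item \strong{Group 3}: CCAAT enrichment present but the maximum
#'     factor share across cell lines is at most 5% (the borderline 5%
#'     overlap belongs here, with the factors avoiding the anchor).
#'   \item \strong{Group 4}: no CCAAT enrichment anywhere, but some cell
#'     line has NF-YB share (fraction of NF-YB peaks overlapping the
#'     factor) strictly above 10% with co-association score above 100.
#' }
#' A factor matching none of these gets group \code{"none"}. The
#' "in at least one dataset" quantifier is used for Groups 1, 2 and 4; Group
#' 3 bounds the maximum share, consistent with single-cell-line factors
#' landing there.
#'
#' @param factor Factor name.
#' @param records data.frame with one row per cell line: \code{cell_line},
#'   \code{enrichment_class} (a \code{\link{classify_ccaat}} class),
#'   \code{factor_share}, \code{nfyb_share}, \code{coassoc_score}.
#' @param cfg \code{\link{analysis_config}}.
#' @return List of class \code{GroupAssignment}: \code{factor},
#'   \code{group} (integer 1-4 or \code{"none"}),
#'   \code{qualifying_cell_lines}, \code{rationale}.
#' @export
assign_group <- function(factor, records, cfg = analysis_config()) {
  req <- c("cell_line", "enrichment_class", "factor_share", "nfyb_share",
           "coassoc_score")
  stopifnot(all(req %in% names(records)), nrow(records) >= 1L)
  enriched <- is_ccaat_enriched(records$enrichment_class)
  global <- is_ccaat_enriched(records$enrichment_class, global_only = TRUE)
  fs <- records$factor_share
  done <- function(group, hits, why) {
    structure(list(factor = factor, group = group,
                   qualifying_cell_lines = records$cell_line[hits],
                   rationale = sprintf("%s [%s]", why,
                                       paste(records$cell_line[hits],
                                             collapse = ", "))),
              class = "GroupAssignment")
  }
  g1 <- global & fs > cfg$group1_min_factor_share
  if (any(g1, na.rm = TRUE)) {
    return(done(1L, which(g1), "global CCAAT enrichment with factor share > 20%"))
  }
  g2 <- enriched & fs > cfg$group3_max_factor_share &
    fs <= cfg$group1_min_factor_share
  if (any(g2, na.rm = TRUE)) {
    return(done(2L, which(g2), "CCAAT enrichment with factor share in (5%, 20%]"))
  }
  if (any(enriched) &&
      max(fs[!is.na(fs)]) <= cfg$group3_max_factor_share) {
    return(done(3L, which(enriched), "CCAAT enrichment with all factor shares <= 5%"))
  }
  g4 <- !enriched & records$nfyb_share > cfg$nfyb_share_threshold &
    records$coassoc_score > cfg$coassoc_score_threshold
  if (!any(enriched) && any(g4, na.rm = TRUE)) {
    return(done(4L, which(g4),
                "no CCAAT enrichment; NF-YB share > 10% with score > 100"))
  }
  done("none", integer(0), "no group rule satisfied")
}

#' @export
print.GroupAssignment <- function(x, ...) {
  cat(sprintf("<GroupAssignment> %s -> group %s (%s)\n",
              x$factor, x$group, x$rationale))
  invisible(x)
}

#' Classify a table of factors into groups
#'
#' @param summaries data.frame with columns factor plus the per-cell-line
#'   record columns of \code{\link{assign_group}}; one row per
#'   factor/cell-line.
#' @param cfg \code{\link{analysis_config}}.
#' @return data.frame: factor, group, qualifying_cell_lines, rationale.
#' @export
assign_groups <- function(summaries, cfg = analysis_config()) {
  stopifnot("factor" %in% names(summaries))
  out <- lapply(split(summaries, summaries$factor), function(rec) {
    a <- assign_group(rec$factor[1], rec, cfg)
    data.frame(factor = a$factor, group = as.character(a$group),
               qualifying_cell_lines = paste(a$qualifying_cell_lines,
                                             collapse = ","),
               rationale = a$rationale, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
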