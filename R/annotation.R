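# Chromatin-state distributions, promoter/target-gene assignment, and
# pathway over-representation with the filtering and merging rules of the
# pipeline.

#' Chromatin-state distribution of a peak set
#'
#' Maps each summit to the 200 bp segmentation bin containing it (half-open
#' intervals: a summit at a bin boundary belongs to the bin starting
#' there). With \code{scope_filter}, only summits within the co-association
#' window of the anchor's summits are counted (the "co-bound with NF-YB"
#' scope). Summits in unsegmented territory are reported separately as
#' \code{unannotated}; fractions are normalized over assigned summits.
#'
#' @param ps A \code{PeakSet}.
#' @param seg A \code{ChromatinSegmentation}.
#' @param scope_filter Optional anchor \code{PeakSet}.
#' @param cfg \code{\link{analysis_config}}.
#' @return List of class \code{StateDistribution}: \code{factor},
#'   \code{scope}, \code{counts} (named, one entry per state label),
#'   \code{fractions}, \code{n_unannotated}.
#' @export
state_distribution <- function(ps, seg, scope_filter = NULL,
                               cfg = analysis_config()) {
  stopifnot(inherits(ps, "PeakSet"), inherits(seg, "ChromatinSegmentation"))
  p <- ps$peaks
  if (!is.null(scope_filter)) {
    hit <- .summits_hit(p$chrom, p$summit,
                        scope_filter$peaks$chrom, scope_filter$peaks$summit,
                        cfg$overlap_half_window)
    p <- p[hit, , drop = FALSE]
  }
  labels <- seg$state_labels
  counts <- stats::setNames(integer(length(labels)), labels)
  unann <- 0L
  segs <- seg$segments
  for (ch in unique(p$chrom)) {
    s <- segs[segs$chrom == ch, , drop = FALSE]
    pos <- p$summit[p$chrom == ch]
    if (!nrow(s)) { unann <- unann + length(pos); next }
    idx <- findInterval(pos, s$start)
    inside <- idx >= 1L & pos < s$end[pmax(idx, 1L)]
    unann <- unann + sum(!inside)
    st <- s$state[idx[inside]]
    tab <- table(st)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  total <- sum(counts)
  structure(list(factor = ps$factor,
                 scope = if (is.null(scope_filter)) "all_peaks"
                         else paste0("co_bound_with_", scope_filter$factor),
                 counts = counts,
                 fractions = if (total) counts / total else counts * NA_real_,
                 n_unannotated = unann),
            class = "StateDistribution")
}

#' Target genes of a co-bound peak set
#'
#' A gene is a target when some summit falls inside its promoter window,
#' defined in strand-oriented coordinates around the TSS and inclusive at
#' both ends: on the + strand \code{[TSS + window[1], TSS + window[2]]}
#' (window (-1000, +100) by default), mirrored on the - strand.
#'
#' @param co_bound A \code{PeakSet} (typically already restricted to the
#'   anchor).
#' @param ann Gene annotation data.frame (gene_id, chrom, tss, strand).
#' @param window Length-2 integer vector, upstream (negative) and
#'   downstream offsets; defaults to the pathway-analysis promoter window.
#' @param cfg \code{\link{analysis_config}}.
#' @return List of class \code{TargetGeneSet}: \code{factor},
#'   \code{genes} (character vector of gene ids).
#' @export
promoter_targets <- function(co_bound, ann,
                             window = NULL, cfg = analysis_config()) {
  stopifnot(inherits(co_bound, "PeakSet"))
  if (is.null(window)) window <- cfg$promoter_window_pathways
  plus <- ann$strand == "+"
  lo <- ifelse(plus, ann$tss + window[1], ann$tss - window[2])
  hi <- ifelse(plus, ann$tss + window[2], ann$tss - window[1])
  p <- co_bound$peaks
  genes <- character(0)
  for (ch in unique(ann$chrom)) {
    gi <- which(ann$chrom == ch)
    pos <- sort(p$summit[p$chrom == ch])
    if (!length(pos) || !length(gi)) next
    # a gene is hit if any summit lies in [lo, hi]
    n_before_lo <- findInterval(lo[gi] - 1L, pos)
    n_before_hi <- findInterval(hi[gi], pos)
    genes <- c(genes, ann$gene_id[gi[n_before_hi > n_before_lo]])
  }
  structure(list(factor = co_bound$factor, genes = sort(unique(genes))),
            class = "TargetGeneSet")
}

#' Hypergeometric over-representation of pathways in a target gene set
#'
#' One-sided (upper tail) hypergeometric test of the overlap between the
#' target set and each pathway, within the given gene universe. The reported
#' \code{background_size} is the pathway's full gene count (the quantity the
#' size filter applies to); the test itself uses the membership restricted
#' to the universe.
#'
#' @param targets A \code{TargetGeneSet} or character vector of gene ids.
#' @param pathways Named list of pathway gene-id vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param universe Character vector of gene ids (default: union of pathway
#'   members; normally the annotated genes).
#' @return data.frame: pathway_id, background_size, n_universe, overlap, p,
#'   genes (comma-joined overlap gene ids).
#' @export
pathway_ora <- function(targets, pathways, universe) {
  if (inherits(targets, "TargetGeneSet")) targets <- targets$genes
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  targets <- intersect(targets, universe)
  k <- length(targets)
  rows <- lapply(names(pathways), function(id) {
    full <- unique(pathways[[id]])
    set <- intersect(full, universe)
    m <- length(set)
    q <- length(intersect(targets, set))
    p <- if (m == 0L) 1 else
      stats::phyper(q - 1, m, length(universe) - m, k, lower.tail = FALSE)
    data.frame(pathway_id = id, background_size = length(full),
               n_universe = m, overlap = q, p = p,
               genes = paste(sort(intersect(targets, set)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the filtered, merged pathway-membership matrix
#'
#' Keeps a pathway only if some factor reaches p <
#' \code{pathway_p_threshold} (1e-5) and the pathway's background gene count
#' is at most \code{pathway_max_background} (200). Pathways characterized by
#' identical gene sets are merged into the most general one -- the one with
#' the largest background size, ties broken lexicographically by id -- and
#' the merged ids are retained as provenance; the representative's per-factor
#' p is the minimum over the merged rows. The result is order-independent in
#' the input rows.
#'
#' @param results Named list (factor -> \code{\link{pathway_ora}} result).
#' @param pathways Named list of pathway gene sets (for the identity
#'   merging; a pathway's identity is its full gene set).
#' @param cfg \code{\link{analysis_config}}.
#' @return List of class \code{PathwayMatrix}: \code{p} (pathway x factor
#'   matrix of p-values), \code{membership} (binary matrix, p < threshold),
#'   \code{background_size} (named), \code{merged_from} (named list),
#'   \code{factor_order} (factors ranked by ascending number of associated
#'   pathways).
#' @export
build_pathway_matrix <- function(results, pathways, cfg = analysis_config()) {
  stopifnot(length(results) >= 1L, !is.null(names(results)))
  factors <- sort(names(results))
  ids <- sort(unique(unlist(lapply(results, `[[`, "pathway_id"))))
  pm <- matrix(1, length(ids), length(factors), dimnames = list(ids, factors))
  bg <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (f in factors) {
    r <- results[[f]]
    pm[r$pathway_id, f] <- r$p
    bg[r$pathway_id] <- r$background_size
  }
  keep <- apply(pm, 1, min) < cfg$pathway_p_threshold &
    bg <= cfg$pathway_max_background
  pm <- pm[keep, , drop = FALSE]
  bg <- bg[keep]
  ids <- ids[keep]
  if (!length(ids)) {
    empty <- matrix(numeric(0), 0, length(factors),
                    dimnames = list(character(0), factors))
    return(structure(list(p = empty, membership = empty,
                          background_size = integer(0),
                          merged_from = list(), factor_order = factors),
                     class = "PathwayMatrix"))
  }
  # merge pathways with identical full gene sets
  sig <- vapply(ids, function(id) {
    paste(sort(unique(pathways[[id]])), collapse = "|")
  }, "")
  merged_from <- list()
  rep_rows <- vapply(split(ids, sig), function(group) {
    group <- group[order(-bg[group], group)]
    group[1]
  }, "")
  pm2 <- do.call(rbind, lapply(rep_rows, function(repr) {
    group <- ids[sig == sig[match(repr, ids)]]
    apply(pm[group, , drop = FALSE], 2, min)
  }))
  rownames(pm2) <- rep_rows
  colnames(pm2) <- factors
  for (repr in rep_rows) {
    group <- ids[sig == sig[match(repr, ids)]]
    merged_from[[repr]] <- setdiff(group, repr)
  }
  ord <- order(rownames(pm2))
  pm2 <- pm2[ord, , drop = FALSE]
  membership <- (pm2 < cfg$pathway_p_threshold) * 1L
  n_per_factor <- colSums(membership)
  structure(list(p = pm2, membership = membership,
                 background_size = bg[rownames(pm2)],
                 merged_from = merged_from[rownames(pm2)],
                 factor_order = factors[order(n_per_factor, factors)]),
            class = "PathwayMatrix")
}
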