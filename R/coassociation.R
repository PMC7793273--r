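# Core co-association statistic: windowed summit-overlap counts scored
# against a Poisson null over ~250k accessible regions.

# For each query summit, is there a subject summit on the same chromosome
# within +/- half_window? Sorted-merge via findInterval; each query summit
# counted at most once no matter how many subject summits are nearby.
.summits_hit <- function(q_chrom, q_pos, s_chrom, s_pos, half_window) {
  hit <- logical(length(q_pos))
  if (!length(q_pos) || !length(s_pos)) return(hit)
  for (ch in intersect(unique(q_chrom), unique(s_chrom))) {
    qi <- which(q_chrom == ch)
    sp <- sort(s_pos[s_chrom == ch])
    idx <- findInterval(q_pos[qi], sp)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(sp))
    hit[qi] <- (abs(q_pos[qi] - sp[lo]) <= half_window & idx >= 1L) |
      (abs(sp[hi] - q_pos[qi]) <= half_window)
  }
  hit
}

#' Windowed summit-overlap count for an ordered factor pair
#'
#' Counts the summits of \code{a} that fall within a window of
#' \code{2 * overlap_half_window} bp (default 300 bp) centered on any summit
#' of \code{b} on the same chromosome, i.e. a maximum summit distance of
#' 150 bp, bounds inclusive. Each summit of \code{a} is counted at most once.
#' The reciprocal count (summits of \code{b} near \code{a}) is always
#' reported as well, since the statistic is ordered but both shares are
#' interpreted.
#'
#' @param a,b \code{PeakSet}s, summit-sorted (the constructor guarantees it).
#' @param cfg \code{\link{analysis_config}}.
#' @return List of class \code{OverlapCount}: factor names, \code{n_a},
#'   \code{n_b}, \code{k} (a summits near b), \code{k_b} (reciprocal),
#'   \code{share_a = k / n_a}, \code{share_b = k_b / n_b}.
#' @export
count_overlap <- function(a, b, cfg = analysis_config()) {
  stopifnot(inherits(a, "PeakSet"), inherits(b, "PeakSet"))
  w <- cfg$overlap_half_window
  k <- sum(.summits_hit(a$peaks$chrom, a$peaks$summit,
                        b$peaks$chrom, b$peaks$summit, w))
  k_b <- sum(.summits_hit(b$peaks$chrom, b$peaks$summit,
                          a$peaks$chrom, a$peaks$summit, w))
  n_a <- nrow(a$peaks); n_b <- nrow(b$peaks)
  structure(list(factor_a = a$factor, factor_b = b$factor,
                 n_a = n_a, n_b = n_b, k = k, k_b = k_b,
                 share_a = if (n_a) k / n_a else NA_real_,
                 share_b = if (n_b) k_b / n_b else NA_real_),
            class = "OverlapCount")
}

#' Poisson co-association score
#'
#' Significance of an observed summit overlap under a Poisson null in which
#' the genome offers \code{N = accessible_regions_n} equally likely 150 bp
#' accessible slots, so the expected overlap of two sets of \code{n_a} and
#' \code{n_b} peaks is \code{lambda = n_a * n_b / N}. The upper tail
#' \code{P(X >= k)} is used when the overlap is at or above expectation, the
#' lower tail \code{P(X <= k)} (with the final score negated) when it is
#' depleted. p-values are Bonferroni-corrected by \code{n_tests}, clamped
#' below at the smallest positive subnormal double, and reported as the
#' signed \code{-log10}; fully underflowed overlaps therefore hit the integer
#' score ceiling of 323.
#'
#' @param counts An \code{OverlapCount}.
#' @param n_tests Bonferroni universe (number of ordered pairs evaluated).
#' @param cfg \code{\link{analysis_config}}; supplies
#'   \code{accessible_regions_n}.
#' @param n_accessible Override for the null scale (used by the anchored
#'   mode, where the anchor's peak count takes the role of N).
#' @return List of class \code{CoassocResult} with \code{lambda_exp},
#'   \code{p_raw}, \code{p_bonf}, signed \code{score} and the input counts.
#' @export
poisson_score <- function(counts, n_tests = 1L, cfg = analysis_config(),
                          n_accessible = NULL) {
  stopifnot(inherits(counts, "OverlapCount"), n_tests >= 1L)
  N <- if (is.null(n_accessible)) cfg$accessible_regions_n else n_accessible
  if (is.null(N) || N <= 0) stop("accessible-region count must be positive")
  lambda <- counts$n_a * counts$n_b / N
  k <- counts$k
  enriched <- k >= lambda
  p_raw <- if (enriched) {
    stats::ppois(k - 1, lambda, lower.tail = FALSE)
  } else {
    stats::ppois(k, lambda, lower.tail = TRUE)
  }
  p_bonf <- min(1, p_raw * n_tests)
  score <- (if (enriched) 1 else -1) * neg_log10(p_bonf)
  structure(list(counts = counts, lambda_exp = lambda,
                 p_raw = p_raw, p_bonf = p_bonf,
                 score = score, degenerate = FALSE),
            class = "CoassocResult")
}

#' Significance call for a co-association result
#'
#' An overlap is significant when the score strictly exceeds the score
#' threshold (100) and the anchor share strictly exceeds the share threshold
#' (10% of the anchor's peaks shared with the factor).
#'
#' @param result A \code{CoassocResult}.
#' @param anchor_share Fraction of anchor (NF-YB) peaks shared with the
#'   factor.
#' @param cfg \code{\link{analysis_config}}.
#' @return Logical flag.
#' @export
significance_call <- function(result, anchor_share, cfg = analysis_config()) {
  stopifnot(inherits(result, "CoassocResult"))
  isTRUE(result$score > cfg$coassoc_score_threshold) &&
    isTRUE(anchor_share > cfg$nfyb_share_threshold)
}

# Subset a PeakSet to summits lying within the window of an anchor set.
.restrict_to_anchor <- function(ps, anchor, cfg) {
  hit <- .summits_hit(ps$peaks$chrom, ps$peaks$summit,
                      anchor$peaks$chrom, anchor$peaks$summit,
                      cfg$overlap_half_window)
  out <- ps
  out$peaks <- ps$peaks[hit, , drop = FALSE]
  rownames(out$peaks) <- NULL
  out
}

#' Anchored (NF-YB-restricted) co-association
#'
#' Restricts both factors to the summits overlapping the anchor (NF-YB)
#' set, counts their overlap there, and scores it with the anchor's peak
#' count as the Poisson null scale. If either restriction is empty the
#' result is degenerate: k = 0, score 0.
#'
#' @param a,b \code{PeakSet}s.
#' @param anchor Non-empty anchor \code{PeakSet}.
#' @param cfg \code{\link{analysis_config}}.
#' @param n_tests Bonferroni universe.
#' @return A \code{CoassocResult}; \code{$degenerate} flags the empty case.
#' @export
anchored_overlap <- function(a, b, anchor, cfg = analysis_config(),
                             n_tests = 1L) {
  stopifnot(inherits(anchor, "PeakSet"))
  if (!nrow(anchor$peaks)) stop("anchor peak set is empty")
  ra <- .restrict_to_anchor(a, anchor, cfg)
  rb <- .restrict_to_anchor(b, anchor, cfg)
  cnt <- count_overlap(ra, rb, cfg)
  if (!nrow(ra$peaks) || !nrow(rb$peaks)) {
    res <- structure(list(counts = cnt, lambda_exp = 0,
                          p_raw = 1, p_bonf = 1, score = 0,
                          degenerate = TRUE),
                     class = "CoassocResult")
    return(res)
  }
  poisson_score(cnt, n_tests = n_tests, cfg = cfg,
                n_accessible = nrow(anchor$peaks))
}

#' Pairwise co-association matrix
#'
#' Scores every ordered pair of peak sets and assembles the signed-score
#' matrix used for clustering. The diagonal holds the maximum attainable
#' (clamp-ceiling) score. By default the Bonferroni universe is the number
#' of ordered off-diagonal pairs in the run.
#'
#' @param peaksets Named list of \code{PeakSet}s (names = factors).
#' @param cfg \code{\link{analysis_config}}.
#' @param anchor Optional anchor \code{PeakSet}; when given, all pairs are
#'   computed in anchored mode.
#' @param n_tests Bonferroni universe; default all ordered off-diagonal
#'   pairs.
#' @return List of class \code{CoassocMatrix}: \code{scores} (square signed
#'   matrix), \code{pairs} (long-format data.frame of counts, shares,
#'   lambda, p and score), \code{mode}, \code{n_tests}.
#' @export
coassoc_matrix <- function(peaksets, cfg = analysis_config(),
                           anchor = NULL, n_tests = NULL) {
  stopifnot(length(peaksets) >= 1L)
  if (is.null(names(peaksets))) {
    names(peaksets) <- vapply(peaksets, function(p) p$factor, "")
  }
  fac <- names(peaksets)
  n <- length(fac)
  if (is.null(n_tests)) n_tests <- max(1L, n * (n - 1L))
  scores <- matrix(neg_log10(0), n, n, dimnames = list(fac, fac))
  rows <- vector("list", n * (n - 1L))
  ri <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    res <- if (is.null(anchor)) {
      poisson_score(count_overlap(peaksets[[i]], peaksets[[j]], cfg),
                    n_tests = n_tests, cfg = cfg)
    } else {
      anchored_overlap(peaksets[[i]], peaksets[[j]], anchor, cfg,
                       n_tests = n_tests)
    }
    scores[i, j] <- res$score
    ri <- ri + 1L
    rows[[ri]] <- data.frame(
      factor_a = fac[i], factor_b = fac[j],
      n_a = res$counts$n_a, n_b = res$counts$n_b,
      k = res$counts$k, share_a = res$counts$share_a,
      share_b = res$counts$share_b, lambda = res$lambda_exp,
      p_bonf = res$p_bonf, score = res$score,
      degenerate = res$degenerate, stringsAsFactors = FALSE)
  }
  structure(list(scores = scores,
                 pairs = do.call(rbind, rows),
                 mode = if (is.null(anchor)) "global" else
                   paste0("anchored(", anchor$factor, ")"),
                 n_tests = n_tests),
            class = "CoassocMatrix")
}

#' Hierarchical clustering of a score matrix
#'
#' Clusters the rows of a signed-score matrix with distance
#' \code{1 - Pearson correlation} and centroid linkage, the combination used
#' for all heatmaps in this pipeline. Centroid linkage over a correlation
#' distance is not geometrically well-founded (it is defined for squared
#' Euclidean distances); it is implemented exactly as specified, with
#' average linkage available via \code{method}. Constant rows carry no
#' correlation information and are dropped with a warning. Rows are
#' pre-sorted by name so that leaf order is deterministic under ties.
#'
#' @param m A \code{CoassocMatrix} or a plain numeric matrix with row names.
#' @param method Linkage method, \code{"centroid"} (default) or
#'   \code{"average"}.
#' @return List: \code{hclust}, \code{order} (leaf labels), \code{matrix}
#'   (input reordered), \code{newick} (dendrogram as a Newick string),
#'   \code{dropped} (constant rows).
#' @export
cluster_matrix <- function(m, method = c("centroid", "average")) {
  method <- match.arg(method)
  scores <- if (inherits(m, "CoassocMatrix")) m$scores else as.matrix(m)
  if (is.null(rownames(scores))) stop("matrix must have row names")
  scores <- scores[order(rownames(scores)), , drop = FALSE]
  sds <- apply(scores, 1, stats::sd)
  dropped <- rownames(scores)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant rows: ", paste(dropped, collapse = ", "))
    scores <- scores[sds > 0, , drop = FALSE]
  }
  if (nrow(scores) < 2L) stop("need >= 2 non-constant rows to cluster")
  d <- stats::as.dist(1 - stats::cor(t(scores)))
  hc <- stats::hclust(d, method = method)
  ord <- hc$labels[hc$order]
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, order = ord,
                 matrix = scores[ord, , drop = FALSE],
                 newick = ape::write.tree(phy),
                 dropped = dropped),
            class = "CoassocClustering")
}

#' Write the long-format pair table of a \code{CoassocMatrix} as TSV
#' @param m A \code{CoassocMatrix}.
#' @param path Output path.
#' @export
write_coassoc_pairs <- function(m, path) {
  stopifnot(inherits(m, "CoassocMatrix"))
  utils::write.table(m$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
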