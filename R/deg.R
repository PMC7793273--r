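# Downstream of differential expression: DEG partitioning, pairwise Fisher
# co-regulation statistics, and the clustered activation/repression
# matrices.

#' Partition a DEG table into UP / DOWN / neutral
#'
#' Strict thresholds: UP means FDR < \code{deg_fdr} and log2FC >
#' \code{deg_abs_lfc}; DOWN mirrors it. A gene at exactly the fold-change
#' threshold is neutral. Genes with missing FDR are neutral.
#'
#' @param deg data.frame with gene_id, log2FoldChange, padj.
#' @param cfg \code{\link{analysis_config}}.
#' @return List of class \code{DegPartition}: \code{up}, \code{down},
#'   \code{neutral} (gene-id vectors, disjoint, union = all genes).
#' @export
partition_degs <- function(deg, cfg = analysis_config()) {
  stopifnot(all(c("gene_id", "log2FoldChange", "padj") %in% names(deg)))
  sig <- !is.na(deg$padj) & deg$padj < cfg$deg_fdr
  up <- sig & deg$log2FoldChange > cfg$deg_abs_lfc
  down <- sig & deg$log2FoldChange < -cfg$deg_abs_lfc
  structure(list(up = deg$gene_id[up], down = deg$gene_id[down],
                 neutral = deg$gene_id[!(up | down)]),
            class = "DegPartition")
}

#' @export
print.DegPartition <- function(x, ...) {
  cat(sprintf("<DegPartition> %d up / %d down / %d neutral\n",
              length(x$up), length(x$down), length(x$neutral)))
  invisible(x)
}

#' Pairwise Fisher test of co-regulation
#'
#' Builds the 2x2 table of membership in two factors' regulated gene sets
#' within a state universe (the UP or DOWN DEG set) and computes the
#' two-sided Fisher exact p (point-probability method, as in
#' \code{\link[stats]{fisher.test}}). The score is -log10(p) with the same
#' subnormal clamp used for co-association. Symmetric in the two factors.
#'
#' @param a_targets,b_targets Gene-id vectors (regulated by factor a / b).
#' @param universe Gene-id vector, the state's DEG universe.
#' @return List of class \code{FisherCoregResult}: \code{table} (2x2),
#'   \code{p}, \code{neg_log10_p}.
#' @export
fisher_coreg <- function(a_targets, b_targets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty state universe")
  a <- universe %in% a_targets
  b <- universe %in% b_targets
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                nrow = 2,
                dimnames = list(a = c("in", "out"), b = c("in", "out")))
  p <- stats::fisher.test(tab)$p.value
  structure(list(table = tab, p = p, neg_log10_p = neg_log10(p)),
            class = "FisherCoregResult")
}

#' All-pairs Fisher co-regulation for one state
#'
#' @param targets Named list: factor -> regulated gene ids in this state
#'   (e.g. the intersection of the factor's target genes with the UP set).
#' @param universe The state's DEG universe.
#' @param state Label recorded in the output ("UP" or "DOWN").
#' @return data.frame of unordered pairs with the 2x2 counts, p and
#'   neg_log10_p.
#' @export
fisher_coreg_all <- function(targets, universe, state = "UP") {
  fac <- sort(names(targets))
  rows <- list()
  for (i in seq_along(fac)) for (j in seq_along(fac)) {
    if (i >= j) next
    r <- fisher_coreg(targets[[fac[i]]], targets[[fac[j]]], universe)
    rows[[length(rows) + 1L]] <- data.frame(
      state = state, factor_a = fac[i], factor_b = fac[j],
      both = r$table[1, 1], a_only = r$table[2, 1],
      b_only = r$table[1, 2], neither = r$table[2, 2],
      p = r$p, neg_log10_p = r$neg_log10_p, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Clustered co-regulation matrix for one state
#'
#' Assembles the symmetric factor x factor matrix of -log10 Fisher p-values
#' (diagonal at the clamp ceiling) and clusters it with the same Pearson /
#' centroid procedure used for co-association
#' (\code{\link{cluster_matrix}}). Separate calls produce the UP and DOWN
#' views.
#'
#' @param pairs A \code{\link{fisher_coreg_all}} result.
#' @param method Linkage method forwarded to \code{cluster_matrix}.
#' @return A \code{cluster_matrix} result (plus \code{$scores}).
#' @export
coreg_heatmap <- function(pairs, method = "centroid") {
  fac <- sort(unique(c(pairs$factor_a, pairs$factor_b)))
  m <- matrix(neg_log10(0), length(fac), length(fac),
              dimnames = list(fac, fac))
  for (r in seq_len(nrow(pairs))) {
    m[pairs$factor_a[r], pairs$factor_b[r]] <- pairs$neg_log10_p[r]
    m[pairs$factor_b[r], pairs$factor_a[r]] <- pairs$neg_log10_p[r]
  }
  out <- cluster_matrix(m, method = method)
  out$scores <- m
  out
}

#' Expression shift of the partner factors themselves
#'
#' Extracts each factor's own log2 fold change and FDR from the DEG table
#' and flags factors whose |log2FC| is at least 0.5 -- the band outside
#' which expression changes of the partners could confound binding-based
#' conclusions. Unresolvable symbols are listed, not fatal.
#'
#' @param deg DEG data.frame (gene_id, log2FoldChange, padj).
#' @param factor_list Character vector of factor gene symbols.
#' @param flag_abs_lfc Flag threshold on |log2FC|.
#' @return data.frame: factor, log2FoldChange, padj, flagged, missing.
#' @export
expression_shift_report <- function(deg, factor_list, flag_abs_lfc = 0.5) {
  idx <- match(factor_list, deg$gene_id)
  out <- data.frame(factor = factor_list,
                    log2FoldChange = deg$log2FoldChange[idx],
                    padj = deg$padj[idx],
                    missing = is.na(idx), stringsAsFactors = FALSE)
  out$flagged <- !out$missing & abs(out$log2FoldChange) >= flag_abs_lfc
  out
}
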