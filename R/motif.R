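# PWM scanning and enrichment semantics: log-odds best-hit scores on 150 bp
# summit-centered windows, a global test against an accessible-region
# background, a local test against immediately flanking windows, the CCAAT
# enrichment classifier, and motif-to-CCAAT positional bias.

.BASES <- c("A", "C", "G", "T")

# 0-based half-open substring of a named sequence vector
.subseq <- function(seqs, chrom, start, end) {
  substr(seqs[[chrom]], start + 1L, end)
}

#' Log-odds score matrix of a PFM
#'
#' Counts are lifted by a pseudocount of \code{pseudo_frac} times the column
#' total per cell (avoiding -Inf on zero counts), converted to frequencies
#' and compared against the background base composition.
#'
#' @param x A \code{PWM}.
#' @param background Base composition (A, C, G, T), default uniform.
#' @param pseudo_frac Pseudocount as a fraction of the column total.
#' @return 4 x L matrix of log2 odds.
#' @export
pwm_log_odds <- function(x, background = rep(0.25, 4), pseudo_frac = 0.01) {
  stopifnot(inherits(x, "PWM"))
  counts <- x$counts
  tot <- colSums(counts)
  counts <- sweep(counts, 2, pseudo_frac * tot, `+`)
  freq <- sweep(counts, 2, colSums(counts), `/`)
  log2(freq / background)
}

# reverse-complement of a log-odds matrix: complement rows, reverse columns
.lo_revcomp <- function(lo) {
  m <- lo[c("T", "G", "C", "A"), rev(seq_len(ncol(lo))), drop = FALSE]
  rownames(m) <- .BASES
  m
}

#' Scan fixed-width windows with a PWM
#'
#' Both strands are scanned at every offset with log-odds scores; the best
#' hit per window is kept with its 0-based start offset and strand. Scores
#' are min-max normalized per matrix, so a perfect consensus match scores
#' exactly 1 and the anti-consensus exactly 0. Ties prefer the plus strand,
#' then the leftmost offset.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param windows data.frame with chrom, start, end (0-based half-open),
#'   all the same width.
#' @param x A \code{PWM}.
#' @param background Base composition for the log-odds.
#' @return data.frame: the windows plus best_score, best_pos, best_strand.
#' @export
scan_windows <- function(seqs, windows, x, background = rep(0.25, 4)) {
  stopifnot(inherits(x, "PWM"))
  lo <- pwm_log_odds(x, background)
  lo_rc <- .lo_revcomp(lo)
  L <- ncol(lo)
  smin <- sum(apply(lo, 2, min)); smax <- sum(apply(lo, 2, max))
  if (smax <= smin) stop("degenerate matrix: constant score")
  n <- nrow(windows)
  widths <- windows$end - windows$start
  if (length(unique(widths)) != 1L) stop("windows must share one width")
  W <- widths[1]
  if (W < L) stop("window narrower than the motif")
  if (any(windows$start < 0) ||
      any(windows$end > vapply(seqs, nchar, 1L)[windows$chrom])) {
    stop("window outside chromosome bounds; clip windows before scanning")
  }
  strs <- vapply(seq_len(n), function(i) {
    .subseq(seqs, windows$chrom[i], windows$start[i], windows$end[i])
  }, "")
  code <- matrix(match(unlist(strsplit(strs, "")), .BASES), nrow = n, byrow = TRUE)
  n_off <- W - L + 1L
  best_score <- rep(-Inf, n); best_pos <- integer(n); best_strand <- rep("+", n)
  for (strand in c("+", "-")) {
    mat <- if (strand == "+") lo else lo_rc
    for (o in seq_len(n_off)) {
      s <- rowSums(matrix(mat[cbind(as.vector(code[, o:(o + L - 1L), drop = FALSE]),
                                    rep(seq_len(L), each = n))],
                          nrow = n))
      better <- s > best_score + 1e-12
      best_score[better] <- s[better]
      best_pos[better] <- o - 1L
      best_strand[better] <- strand
    }
  }
  out <- windows
  out$best_score <- (best_score - smin) / (smax - smin)
  out$best_pos <- best_pos
  out$best_strand <- best_strand
  out
}

#' Summit-centered scan windows for a peak set
#'
#' Builds the 150 bp windows centered on each summit (summit at offset
#' \code{width \%/\% 2}). Windows running off a chromosome end are clipped
#' away and flagged: scanning requires full-width windows.
#'
#' @param ps A \code{PeakSet}.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param width Window width (bp), default 150.
#' @param shift Signed shift of the whole window (used for flanks).
#' @return data.frame chrom/start/end/summit with attribute
#'   \code{n_clipped}.
#' @export
summit_windows <- function(ps, chrom_sizes, width = 150L, shift = 0L) {
  stopifnot(inherits(ps, "PeakSet"))
  p <- ps$peaks
  start <- p$summit - width %/% 2L + shift
  end <- start + width
  lim <- chrom_sizes[p$chrom]
  ok <- start >= 0L & end <= lim
  out <- data.frame(chrom = p$chrom[ok], start = start[ok], end = end[ok],
                    summit = p$summit[ok], stringsAsFactors = FALSE)
  attr(out, "n_clipped") <- sum(!ok)
  out
}

#' Scan the summit regions of a peak set
#'
#' Convenience wrapper: 150 bp summit-centered windows scanned on both
#' strands; see \code{\link{scan_windows}}.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param ps A \code{PeakSet}.
#' @param x A \code{PWM}.
#' @param cfg \code{\link{analysis_config}} (window = 150 bp).
#' @return As \code{\link{scan_windows}}.
#' @export
scan_regions <- function(seqs, ps, x, cfg = analysis_config()) {
  sizes <- vapply(seqs, nchar, 1L)
  w <- summit_windows(ps, sizes, width = 150L)
  scan_windows(seqs, w, x)
}

#' Global motif enrichment
#'
#' One-sided test that the mean best score in peak regions exceeds the mean
#' over a genomic background of accessible regions: by default a z-test on
#' the mean using the background variance; with \code{method =
#' "permutation"} and a full background sample, an exact resampling p-value.
#'
#' @param scores Numeric vector of best scores in peak regions (or a
#'   \code{scan_windows} result).
#' @param background Either a numeric vector of best scores on background
#'   accessible regions, or a list with \code{mean} and \code{var}.
#' @param method "z" or "permutation".
#' @param n_perm Resamples for the permutation method.
#' @param cfg \code{\link{analysis_config}}.
#' @return One-sided p-value.
#' @export
global_enrichment <- function(scores, background, method = c("z", "permutation"),
                              n_perm = 2000L, cfg = analysis_config()) {
  method <- match.arg(method)
  if (is.data.frame(scores)) scores <- scores$best_score
  if (is.data.frame(background)) background <- background$best_score
  if (is.list(background) && !is.null(background$mean)) {
    mu <- background$mean; v <- background$var; sample_bg <- NULL
  } else {
    sample_bg <- as.numeric(background)
    mu <- mean(sample_bg); v <- stats::var(sample_bg)
  }
  if (!is.finite(v) || v <= 0) stop("background variance must be positive")
  if (method == "permutation") {
    if (is.null(sample_bg)) stop("permutation method needs a full background sample")
    obs <- mean(scores)
    perms <- vapply(seq_len(n_perm), function(i) {
      mean(sample(sample_bg, length(scores), replace = TRUE))
    }, 1)
    return((1 + sum(perms >= obs)) / (n_perm + 1))
  }
  z <- (mean(scores) - mu) / sqrt(v / length(scores))
  stats::pnorm(z, lower.tail = FALSE)
}

#' Local motif enrichment
#'
#' One-sided paired test that the best score in the summit-centered window
#' exceeds the mean best score of the two immediately flanking windows of
#' the same width (5' and 3').
#'
#' @param central,flank5,flank3 Numeric vectors (or \code{scan_windows}
#'   results) of best scores for the central and flanking windows, aligned
#'   by region.
#' @param cfg \code{\link{analysis_config}}.
#' @return One-sided p-value.
#' @export
local_enrichment <- function(central, flank5, flank3, cfg = analysis_config()) {
  if (is.data.frame(central)) central <- central$best_score
  if (is.data.frame(flank5)) flank5 <- flank5$best_score
  if (is.data.frame(flank3)) flank3 <- flank3$best_score
  if (length(central) != length(flank5) || length(central) != length(flank3)) {
    stop("central and flank score vectors must have equal length")
  }
  diffs <- central - (flank5 + flank3) / 2
  if (stats::sd(diffs) == 0) return(if (mean(diffs) > 0) 0 else 1)
  stats::t.test(diffs, alternative = "greater")$p.value
}

#' Classify CCAAT enrichment for one factor
#'
#' Applies the three-tier reading of motif enrichment: CCAAT globally
#' significant and top-ranked among all matrices tested =>
#' \code{global_primary}; globally significant but outranked by another
#' matrix (typically the factor's own) => \code{global_secondary}; only
#' locally significant => \code{local_only}; otherwise \code{none}.
#' Significance is p < \code{motif_p_threshold} (1e-10); rank is by
#' ascending global p.
#'
#' @param results data.frame with columns matrix_id, global_p, local_p (one
#'   row per matrix tested for the factor).
#' @param ccaat_id Matrix id of the CCAAT box (default "MA0060.1").
#' @param cfg \code{\link{analysis_config}}.
#' @return List of class \code{MotifEnrichment}: the CCAAT row's p-values,
#'   \code{rank_global} and \code{enrichment_class}.
#' @export
classify_ccaat <- function(results, ccaat_id = "MA0060.1",
                           cfg = analysis_config()) {
  stopifnot(all(c("matrix_id", "global_p", "local_p") %in% names(results)))
  if (!ccaat_id %in% results$matrix_id) {
    stop("CCAAT matrix ", ccaat_id, " not among the tested matrices")
  }
  row <- results[results$matrix_id == ccaat_id, , drop = FALSE][1, ]
  rank_global <- rank(results$global_p, ties.method = "min")[
    match(ccaat_id, results$matrix_id)]
  thr <- cfg$motif_p_threshold
  cls <- if (row$global_p < thr) {
    if (rank_global == 1L) "global_primary" else "global_secondary"
  } else if (row$local_p < thr) {
    "local_only"
  } else {
    "none"
  }
  structure(list(matrix_id = ccaat_id, global_p = row$global_p,
                 local_p = row$local_p, rank_global = as.integer(rank_global),
                 enrichment_class = cls),
            class = "MotifEnrichment")
}

#' Whether an enrichment class counts as CCAAT-enriched
#' @param class Character: an \code{enrichment_class} value.
#' @param global_only If TRUE, only global classes qualify.
#' @export
is_ccaat_enriched <- function(class, global_only = FALSE) {
  if (global_only) class %in% c("global_primary", "global_secondary")
  else class %in% c("global_primary", "global_secondary", "local_only")
}

#' Motif-to-CCAAT positional bias in co-bound regions
#'
#' For each co-bound 150 bp region, the best CCAAT hit is located; regions
#' whose CCAAT score falls below \code{min_ccaat_score} (0.8 normalized) are
#' excluded and counted. The reference point is the middle A of the CCAAT
#' pentanucleotide within the matched window, orientation-corrected. The
#' signed distance is (TF motif center) - (middle A position) on the
#' CCAAT-defining strand, negative when the TF motif lies 5' of CCAAT.
#' Distances are rounded to integers (even-width partner motifs have
#' half-base centers). TF hits whose motif window overlaps the matched
#' CCAAT window are excluded (such "hits" are usually the CCAAT sequence
#' itself rescored by the partner matrix; overlapping-site geometries are
#' outside this analysis), and the same offsets are removed from the null
#' support. Non-uniformity is assessed by a chi-square test of the offset
#' histogram against a uniform distribution over each region's attainable
#' non-overlapping offsets; a bias is called at p <
#' \code{motif_p_threshold}.
#'
#' @param co_bound A \code{PeakSet} of co-bound regions (e.g. the factor's
#'   summits restricted to the anchor), or a window data.frame.
#' @param seqs Named character vector of chromosome sequences.
#' @param tf_pwm Partner-factor \code{PWM}.
#' @param ccaat_pwm CCAAT-box \code{PWM}.
#' @param cfg \code{\link{analysis_config}}.
#' @return List of class \code{PositionalBias}: \code{offsets} (per-region
#'   signed distances), \code{mode_offset}, \code{orientation_split} (table
#'   of TF strand relative to the CCAAT strand), \code{bias_p},
#'   \code{biased} flag, \code{n_excluded}.
#' @export
positional_bias <- function(co_bound, seqs, tf_pwm, ccaat_pwm,
                            cfg = analysis_config()) {
  windows <- if (inherits(co_bound, "PeakSet")) {
    summit_windows(co_bound, vapply(seqs, nchar, 1L), width = 150L)
  } else co_bound
  if (!nrow(windows)) stop("no co-bound regions to analyze")
  cc <- scan_windows(seqs, windows, ccaat_pwm)
  tf <- scan_windows(seqs, windows, tf_pwm)
  keep <- cc$best_score >= cfg$min_ccaat_score
  n_excluded <- sum(!keep)
  cc <- cc[keep, , drop = FALSE]; tf <- tf[keep, , drop = FALSE]
  if (!nrow(cc)) stop("no region carries a CCAAT match above the score floor")
  a_off <- ccaat_middle_a(ccaat_pwm)
  Lc <- ccaat_pwm$length; Lt <- tf_pwm$length
  mid_a <- ifelse(cc$best_strand == "+",
                  cc$best_pos + a_off,
                  cc$best_pos + (Lc - 1L - a_off))
  tf_center <- tf$best_pos + (Lt - 1) / 2
  d <- tf_center - mid_a
  d <- ifelse(cc$best_strand == "-", -d, d)
  d <- round(d)
  # offsets whose TF window would overlap the matched CCAAT window (same
  # interval in sign-corrected d-space for either CCAAT strand)
  h <- (Lt - 1) / 2
  collide_lo <- floor(-a_off - h); collide_hi <- ceiling(Lc - 1 - a_off + h)
  overlap_hit <- d >= collide_lo & d <= collide_hi
  n_overlapping <- sum(overlap_hit)
  cc <- cc[!overlap_hit, , drop = FALSE]
  tf <- tf[!overlap_hit, , drop = FALSE]
  mid_a <- mid_a[!overlap_hit]
  d <- d[!overlap_hit]
  if (!length(d)) stop("all TF hits overlap the CCAAT window")
  # attainable offset range per region: the TF-motif center can sit anywhere
  # in [(Lt-1)/2, W-Lt+(Lt-1)/2]; subtract the observed middle-A position
  # and correct the sign on minus-strand CCAAT hits
  W <- windows$end[1] - windows$start[1]
  cmin <- (Lt - 1) / 2; cmax <- W - Lt + (Lt - 1) / 2
  lo_i <- round(ifelse(cc$best_strand == "-", -(cmax - mid_a), cmin - mid_a))
  hi_i <- round(ifelse(cc$best_strand == "-", -(cmin - mid_a), cmax - mid_a))
  d <- pmin(pmax(d, lo_i), hi_i)
  d_lo <- min(lo_i); d_hi <- max(hi_i)
  support <- seq(d_lo, d_hi)
  in_collide <- support >= collide_lo & support <= collide_hi
  counts <- tabulate(d - d_lo + 1L, nbins = length(support))
  # null: per region, uniform over its attainable non-overlapping offsets
  probs <- rowSums(vapply(seq_along(lo_i), function(i) {
    ok <- support >= lo_i[i] & support <= hi_i[i] & !in_collide
    ok / sum(ok)
  }, numeric(length(support)))) / length(lo_i)
  # aggregate support into contiguous bins with expected count >= 5 so the
  # chi-square approximation holds at modest n; a sharp planted mode still
  # dominates its bin
  n_obs <- length(d)
  bin_id <- integer(length(support))
  cur <- 1L; acc <- 0
  for (b in seq_along(support)) {
    bin_id[b] <- cur
    acc <- acc + probs[b]
    if (acc * n_obs >= 5 && b < length(support)) { cur <- cur + 1L; acc <- 0 }
  }
  counts_b <- as.numeric(tapply(counts, bin_id, sum))
  probs_b <- as.numeric(tapply(probs, bin_id, sum))
  keep_bins <- probs_b > 0
  bias_p <- if (sum(keep_bins) < 2L) 1 else suppressWarnings(
    stats::chisq.test(counts_b[keep_bins], p = probs_b[keep_bins],
                      rescale.p = TRUE)$p.value)
  mode_offset <- support[which.max(counts)]
  same <- ifelse(tf$best_strand == cc$best_strand, "same", "opposite")
  structure(list(offsets = d, mode_offset = mode_offset,
                 orientation_split = table(same),
                 bias_p = bias_p,
                 biased = is.finite(bias_p) && bias_p < cfg$motif_p_threshold,
                 n_excluded = n_excluded,
                 n_overlapping = n_overlapping),
            class = "PositionalBias")
}

#' @export
print.PositionalBias <- function(x, ...) {
  cat(sprintf("<PositionalBias> n=%d regions, mode %+d bp, p=%.3g%s (%d excluded)\n",
              length(x$offsets), x$mode_offset, x$bias_p,
              if (x$biased) " [biased]" else "", x$n_excluded))
  invisible(x)
}
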