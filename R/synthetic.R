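# Synthetic-data generators. Every pipeline input can be produced here with
# planted structure (pairwise co-association rates, motif offsets from the
# CCAAT middle A, DEG target-set overlaps) so each downstream stage has
# ground truth to recover.

.REGION_WIDTH <- 150L
.SUMMIT_JITTER <- 50L

# One global seed fans out to per-stage child seeds by a fixed derivation,
# so individual stages are reproducible in isolation. Offsets are small
# primes; the result stays far below .Machine$integer.max for any seed the
# pipeline accepts.
child_seed <- function(seed, stage) {
  offsets <- c(genome = 104729L, peaks = 1299709L, sequence = 15485863L,
               deg = 32452843L, demo = 49979687L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]] %% 1000L +
    match(stage, names(offsets))
}

#' Generate a synthetic genome with accessible regions
#'
#' Chromosomes of equal length carrying \code{n_accessible} disjoint 150 bp
#' accessible regions (the synthetic analogue of DNaseI-hypersensitive
#' sites), placed uniformly at random by the spacing method: the free space
#' left after reserving the region widths is split by sorted uniform draws.
#' Regions are kept at least \code{min_gap} bp apart (default 101), so that
#' two summits jittered by up to +/- 50 bp from the centers of distinct
#' regions can never fall within the 150 bp co-association window of each
#' other -- planted overlap fractions are then recovered exactly, not just
#' in expectation.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_len Length of each chromosome (bp).
#' @param n_accessible Total number of accessible regions.
#' @param seed Integer seed; the layout is reproducible bit-for-bit.
#' @param min_gap Minimum distance (bp) between consecutive regions.
#' @return Object of class \code{SyntheticGenome}: \code{chrom_sizes},
#'   \code{accessible_regions} (data.frame chrom/start/end), and a slot for
#'   \code{sequence} filled by \code{\link{plant_sequences}}.
#' @export
make_genome <- function(n_chroms, chrom_len, n_accessible, seed = 1L,
                        min_gap = 101L) {
  stopifnot(n_chroms >= 1L, chrom_len > 0, n_accessible >= 1L, min_gap >= 0L)
  chroms <- sprintf("chr%d", seq_len(n_chroms))
  pitch <- .REGION_WIDTH + min_gap
  cap <- (chrom_len + min_gap) %/% pitch
  if (n_accessible > cap * n_chroms) {
    stop(sprintf("cannot pack %d disjoint %d bp regions into %d x %d bp",
                 n_accessible, .REGION_WIDTH, n_chroms, chrom_len))
  }
  per <- rep(n_accessible %/% n_chroms, n_chroms)
  extra <- n_accessible %% n_chroms
  if (extra) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  if (any(per > cap)) stop("infeasible per-chromosome packing")
  set.seed(as.integer(seed))
  regions <- do.call(rbind, lapply(seq_len(n_chroms), function(i) {
    n_i <- per[i]
    if (!n_i) return(NULL)
    free <- chrom_len - (n_i * pitch - min_gap)
    slack <- floor(sort(stats::runif(n_i, 0, free)))
    start <- as.integer(slack + (seq_len(n_i) - 1L) * pitch)
    data.frame(chrom = chroms[i], start = start,
               end = start + .REGION_WIDTH, stringsAsFactors = FALSE)
  }))
  rownames(regions) <- NULL
  structure(list(chrom_sizes = stats::setNames(rep(chrom_len, n_chroms), chroms),
                 accessible_regions = regions,
                 sequence = NULL, seed = as.integer(seed)),
            class = "SyntheticGenome")
}

#' @export
print.SyntheticGenome <- function(x, ...) {
  cat(sprintf("<SyntheticGenome> %d chromosome(s), %d accessible regions%s\n",
              length(x$chrom_sizes), nrow(x$accessible_regions),
              if (is.null(x$sequence)) "" else ", with sequence"))
  invisible(x)
}

#' Plant peak sets with pairwise co-association
#'
#' Summits are sampled from accessible-region centers with uniform jitter of
#' +/- 50 bp, which keeps two summits planted in the same region within
#' 100 bp of each other -- inside the 150 bp co-association window with
#' margin. For each ordered pair (i, j) with i < j, a fraction
#' \code{coassoc[i, j]} of factor j's summits is placed in regions already
#' used by factor i; the remaining summits go to regions untouched by any
#' earlier factor, so planted shares are recovered by the overlap counter up
#' to sampling noise from incidentally adjacent regions.
#'
#' @param genome A \code{\link{make_genome}} result.
#' @param factors Character vector of factor names.
#' @param peaks_per_factor Summits per factor (single value or per-factor).
#' @param coassoc Symmetric matrix of planted overlap fractions in [0, 1]
#'   (dimnames = factors); only the upper triangle relative to factor order
#'   is used for planting.
#' @param cell_line Cell-line label for the generated sets.
#' @param seed Integer seed.
#' @return List with \code{peaksets} (named list of \code{PeakSet}s) and
#'   \code{truth} (per-factor region indices plus the planting parameters).
#' @export
plant_peaksets <- function(genome, factors, peaks_per_factor,
                           coassoc = NULL, cell_line = "synthetic",
                           seed = 1L) {
  stopifnot(inherits(genome, "SyntheticGenome"))
  nf <- length(factors)
  m <- rep_len(as.integer(peaks_per_factor), nf)
  regions <- genome$accessible_regions
  n_reg <- nrow(regions)
  if (any(m > n_reg)) stop("peaks_per_factor exceeds the number of accessible regions")
  if (is.null(coassoc)) {
    coassoc <- matrix(0, nf, nf, dimnames = list(factors, factors))
  }
  coassoc <- coassoc[factors, factors, drop = FALSE]
  if (any(coassoc < 0 | coassoc > 1)) stop("overlap fractions must lie in [0, 1]")
  if (any(abs(coassoc - t(coassoc)) > 1e-12)) stop("coassoc matrix must be symmetric")
  set.seed(as.integer(seed))
  assigned <- vector("list", nf)
  names(assigned) <- factors
  used_any <- logical(n_reg)
  for (j in seq_len(nf)) {
    want <- integer(0)
    pool_used <- logical(n_reg)
    if (j > 1L) {
      shared_n <- vapply(seq_len(j - 1L), function(i) {
        as.integer(round(coassoc[i, j] * m[j]))
      }, 1L)
      if (sum(shared_n) > m[j]) {
        stop(sprintf("factor %s: planted fractions demand %d shared summits but only %d peaks",
                     factors[j], sum(shared_n), m[j]))
      }
      for (i in seq_len(j - 1L)) {
        if (!shared_n[i]) next
        avail <- setdiff(assigned[[i]], which(pool_used))
        if (length(avail) < shared_n[i]) {
          stop(sprintf("factor %s: not enough free regions of %s to plant overlap",
                       factors[j], factors[i]))
        }
        take <- if (length(avail) == 1L) avail else sample(avail, shared_n[i])
        want <- c(want, take)
        pool_used[take] <- TRUE
      }
    }
    n_free <- m[j] - length(want)
    if (n_free > 0L) {
      fresh <- which(!used_any & !pool_used)
      if (length(fresh) < n_free) stop("not enough untouched regions; enlarge the genome")
      want <- c(want, sample(fresh, n_free))
    }
    assigned[[j]] <- sort(want)
    used_any[want] <- TRUE
  }
  peaksets <- lapply(seq_len(nf), function(j) {
    idx <- assigned[[j]]
    center <- regions$start[idx] + .REGION_WIDTH %/% 2L
    jitter <- sample.int(2L * .SUMMIT_JITTER + 1L, length(idx),
                         replace = TRUE) - .SUMMIT_JITTER - 1L
    summit <- pmax(center + jitter, 0L)
    peak_set(data.frame(chrom = regions$chrom[idx],
                        start = pmax(summit - 75L, 0L),
                        end = summit + 75L,
                        name = sprintf("%s_%d", factors[j], seq_along(idx)),
                        signal = 1, summit = summit,
                        stringsAsFactors = FALSE),
             factor = factors[j], cell_line = cell_line,
             experiment_id = sprintf("SYN_%s_%s", cell_line, factors[j]))
  })
  names(peaksets) <- factors
  list(peaksets = peaksets,
       truth = list(regions = assigned, coassoc = coassoc,
                    peaks_per_factor = m, seed = as.integer(seed)))
}

#' Locate the middle A of the CCAAT pentanucleotide in a matrix
#'
#' Finds \code{CCAAT} in the consensus of the matrix and returns the 0-based
#' column offset of its central base (the third position of the
#' pentanucleotide), the reference point for all positional-bias distances.
#'
#' @param ccaat A CCAAT-box \code{PWM}.
#' @return Integer 0-based offset within the matrix.
#' @export
ccaat_middle_a <- function(ccaat) {
  cons <- pwm_consensus(ccaat)
  at <- regexpr("CCAAT", cons, fixed = TRUE)
  if (at < 0) stop("no CCAAT pentanucleotide in the consensus of ", ccaat$matrix_id)
  as.integer(at) - 1L + 2L
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a nucleotide string
#' @param s Character scalar over A/C/G/T.
#' @export
revcomp <- function(s) {
  paste(rev(.COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
}

#' Plant motif arrangements into a synthetic genome sequence
#'
#' Fills every chromosome with i.i.d. uniform background sequence, then, for
#' each plant specification, writes motif consensus sequences into a
#' fraction of accessible regions: the CCAAT consensus is placed so that its
#' middle A sits at the region center, and (optionally) a partner motif
#' consensus is placed at a stated signed offset -- measured from the
#' partner-motif center to the CCAAT middle A, negative meaning the partner
#' motif lies 5' of CCAAT on the CCAAT-defining (+) strand.
#'
#' @param genome A \code{SyntheticGenome}.
#' @param ccaat CCAAT-box \code{PWM} (consensus must contain CCAAT).
#' @param plants List of plant specs, each a list with elements:
#'   \code{fraction} (of the candidate regions to plant), optional
#'   \code{pwm} (partner \code{PWM}; \code{NULL} plants CCAAT alone),
#'   \code{offset} (signed bp, partner center minus middle A),
#'   \code{orientation} (\code{"+"} or \code{"-"}, strand of the partner
#'   consensus), optional \code{regions} (integer indices of candidate
#'   accessible regions; default all), optional \code{ccaat = FALSE} to
#'   plant the partner motif alone (offset still measured from the region
#'   center, where a CCAAT middle A planted by another spec would sit).
#' @param seed Integer seed.
#' @return The genome with \code{$sequence} (named character vector) and
#'   \code{$plant_log} (data.frame: region index, plant id, offset,
#'   orientation, ccaat_mid absolute position).
#' @export
plant_sequences <- function(genome, ccaat, plants = list(), seed = 1L) {
  stopifnot(inherits(genome, "SyntheticGenome"), inherits(ccaat, "PWM"))
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  # sequences held as per-base character vectors while planting (in-place
  # slice assignment), collapsed to strings at the end
  seqv <- lapply(names(genome$chrom_sizes), function(ch) {
    sample(bases, genome$chrom_sizes[[ch]], replace = TRUE)
  })
  names(seqv) <- names(genome$chrom_sizes)
  regions <- genome$accessible_regions
  a_off <- ccaat_middle_a(ccaat)
  ccons <- pwm_consensus(ccaat)
  log <- list()
  for (pi in seq_along(plants)) {
    sp <- plants[[pi]]
    cand <- if (is.null(sp$regions)) seq_len(nrow(regions)) else sp$regions
    n_plant <- as.integer(round(sp$fraction * length(cand)))
    if (!n_plant) next
    idx <- if (length(cand) == 1L) cand else sample(cand, n_plant)
    for (r in idx) {
      ch <- regions$chrom[r]
      center <- regions$start[r] + .REGION_WIDTH %/% 2L  # 0-based absolute
      if (!identical(sp$ccaat, FALSE)) {
        c_start <- center - a_off
        if (c_start < regions$start[r] ||
            c_start + nchar(ccons) > regions$end[r]) {
          stop("CCAAT placement outside region ", r)
        }
        seqv[[ch]][(c_start + 1L):(c_start + nchar(ccons))] <-
          strsplit(ccons, "")[[1]]
      }
      offset <- NA_integer_; orient <- NA_character_
      if (!is.null(sp$pwm)) {
        tcons <- pwm_consensus(sp$pwm)
        lt <- nchar(tcons)
        offset <- as.integer(sp$offset)
        orient <- if (is.null(sp$orientation)) "+" else sp$orientation
        t_start <- center + offset - (lt - 1L) %/% 2L
        if (t_start < regions$start[r] || t_start + lt > regions$end[r]) {
          stop(sprintf("partner motif at offset %d falls outside region %d",
                       offset, r))
        }
        written <- if (orient == "-") revcomp(tcons) else tcons
        seqv[[ch]][(t_start + 1L):(t_start + lt)] <- strsplit(written, "")[[1]]
      }
      log[[length(log) + 1L]] <- data.frame(
        region = r, plant = pi, offset = offset, orientation = orient,
        ccaat_mid = center, stringsAsFactors = FALSE)
    }
  }
  genome$sequence <- vapply(seqv, paste, "", collapse = "")
  genome$plant_log <- if (length(log)) do.call(rbind, log) else NULL
  genome
}

#' Plant a differential-expression table with per-factor target sets
#'
#' Generates a DESeq2-shaped table in which exactly
#' \code{round(frac_up * n_genes)} genes pass the UP thresholds
#' (FDR < 0.01, log2FC > 1), the mirrored count passes DOWN, and the rest
#' are neutral. Per-factor target gene sets are drawn with planted pairwise
#' overlap fractions (fraction of factor j's targets shared with factor i),
#' following the same sequential scheme as \code{\link{plant_peaksets}}.
#'
#' @param n_genes Number of genes.
#' @param frac_up,frac_down Fractions of UP / DOWN genes;
#'   \code{frac_up + frac_down <= 1}.
#' @param factors Character vector of factor names (may be empty).
#' @param target_size Targets per factor.
#' @param overlaps Symmetric matrix of planted pairwise target-overlap
#'   fractions (as in \code{plant_peaksets}); \code{NULL} for independent
#'   sets.
#' @param seed Integer seed.
#' @param cfg \code{\link{analysis_config}} (supplies the DEG thresholds the
#'   planted values must clear).
#' @return List: \code{deg} (data.frame gene_id / log2FoldChange / padj),
#'   \code{targets} (named list of gene-id vectors), \code{truth}.
#' @export
plant_deg_tables <- function(n_genes, frac_up, frac_down,
                             factors = character(), target_size = 0L,
                             overlaps = NULL, seed = 1L,
                             cfg = analysis_config()) {
  stopifnot(n_genes >= 1L, frac_up >= 0, frac_down >= 0)
  if (frac_up + frac_down > 1) stop("frac_up + frac_down must not exceed 1")
  set.seed(as.integer(seed))
  n_up <- as.integer(round(frac_up * n_genes))
  n_down <- as.integer(round(frac_down * n_genes))
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  state <- rep("neutral", n_genes)
  state[seq_len(n_up)] <- "up"
  if (n_down) state[n_up + seq_len(n_down)] <- "down"
  state <- sample(state)  # shuffle gene identities
  lfc <- numeric(n_genes); fdr <- numeric(n_genes)
  up <- state == "up"; down <- state == "down"; neu <- state == "neutral"
  lfc[up] <- stats::runif(sum(up), cfg$deg_abs_lfc + 0.01, 4)
  lfc[down] <- -stats::runif(sum(down), cfg$deg_abs_lfc + 0.01, 4)
  lfc[neu] <- stats::runif(sum(neu), -cfg$deg_abs_lfc + 0.05,
                           cfg$deg_abs_lfc - 0.05)
  fdr[up | down] <- stats::runif(sum(up | down), 0, cfg$deg_fdr * 0.9)
  fdr[neu] <- stats::runif(sum(neu), cfg$deg_fdr * 2, 1)
  deg <- data.frame(gene_id = gene_id, log2FoldChange = lfc, padj = fdr,
                    stringsAsFactors = FALSE)
  targets <- list()
  if (length(factors) && target_size > 0L) {
    if (target_size > n_genes) stop("target_size exceeds n_genes")
    nf <- length(factors)
    if (is.null(overlaps)) {
      overlaps <- matrix(0, nf, nf, dimnames = list(factors, factors))
    }
    overlaps <- overlaps[factors, factors, drop = FALSE]
    if (any(abs(overlaps - t(overlaps)) > 1e-12)) stop("overlaps must be symmetric")
    assigned <- vector("list", nf); names(assigned) <- factors
    used_any <- logical(n_genes)
    for (j in seq_len(nf)) {
      want <- integer(0); pool_used <- logical(n_genes)
      if (j > 1L) {
        shared_n <- vapply(seq_len(j - 1L), function(i) {
          as.integer(round(overlaps[i, j] * target_size))
        }, 1L)
        if (sum(shared_n) > target_size) {
          stop("factor ", factors[j], ": overlap demands exceed target_size")
        }
        for (i in seq_len(j - 1L)) {
          if (!shared_n[i]) next
          avail <- setdiff(assigned[[i]], which(pool_used))
          if (length(avail) < shared_n[i]) stop("cannot satisfy planted target overlaps")
          take <- if (length(avail) == 1L) avail else sample(avail, shared_n[i])
          want <- c(want, take); pool_used[take] <- TRUE
        }
      }
      n_free <- target_size - length(want)
      if (n_free > 0L) {
        fresh <- which(!used_any & !pool_used)
        if (length(fresh) < n_free) {
          # fall back to any unclaimed-in-this-factor gene
          fresh <- which(!pool_used & !seq_len(n_genes) %in% want)
        }
        want <- c(want, sample(fresh, n_free))
      }
      assigned[[j]] <- sort(want); used_any[want] <- TRUE
    }
    targets <- lapply(assigned, function(i) gene_id[i])
  }
  list(deg = deg, targets = targets,
       truth = list(state = stats::setNames(state, gene_id),
                    n_up = n_up, n_down = n_down, overlaps = overlaps,
                    seed = as.integer(seed)))
}

#' A synthetic CCAAT-box position frequency matrix
#'
#' A 16-column PFM, constructed in code for this package (not the JASPAR
#' matrix), whose consensus carries the CCAAT pentanucleotide at columns
#' 2-6 followed by moderately informative positions -- wide enough to mimic
#' the long NF-Y binding matrix, with the pentanucleotide core toward the
#' 5' edge so that upstream partner-motif spacings (the -10/-12 bp
#' arrangements) do not overlap the matrix window. Labelled with the
#' conventional CCAAT-box accession so it slots into the pipeline wherever
#' the CCAAT matrix id is expected.
#'
#' @return A \code{PWM} with \code{matrix_id = "MA0060.1"}.
#' @export
synthetic_ccaat_pwm <- function() {
  # columns:        1   C   C   A   A   T   7   8   9  10  11  12  13  14  15  16
  counts <- rbind(
    A = c(30,  3,  2, 94, 91,  2, 42, 25, 20, 40, 30, 20, 55, 25, 30, 25),
    C = c(25, 92, 94,  2,  3,  4, 23, 30, 40, 20, 20, 40, 15, 25, 20, 30),
    G = c(20,  2,  3,  2,  2,  2, 20, 25, 20, 20, 35, 20, 15, 30, 25, 20),
    T = c(25,  3,  1,  2,  4, 92, 15, 20, 20, 20, 15, 20, 15, 20, 25, 25))
  pwm("MA0060.1", "CCAAT-box (synthetic)", counts)
}

#' A synthetic partner-TF position frequency matrix
#'
#' An odd-width (9 bp) informative PFM used as the generic partner motif in
#' synthetic genomes; odd width keeps planted center-to-middle-A distances
#' integral. Column profiles are deliberately heterogeneous (as in real
#' PFMs) so that match scores are near-continuous and best-hit ties rare.
#'
#' @param name Factor name to attach.
#' @param seed Seed controlling which consensus is drawn.
#' @return A \code{PWM}.
#' @export
synthetic_tf_pwm <- function(name = "TF1", seed = 1L) {
  set.seed(as.integer(seed))
  width <- 9L
  cons <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
  counts <- matrix(sample(1:9, 4L * width, replace = TRUE), 4, width,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(cons, rownames(counts)), seq_len(width))] <-
    sample(70:95, width, replace = TRUE)
  pwm(sprintf("SYN%04d.1", (as.integer(seed) %% 9999L) + 1L), name, counts)
}
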