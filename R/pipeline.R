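# End-to-end orchestration: compose curation -> co-association -> motif
# enrichment -> group classification -> chromatin/pathway annotation ->
# DEG co-regulation, plus a fully synthetic demo cosmos with planted
# Group 1-4 archetypes.

.write_tsv <- function(x, out_dir, name, seed = NULL) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, name)
  con <- file(path, "w")
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", seed), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full pipeline on prepared inputs
#'
#' Executes the stages in dependency order: \code{curate} ->
#' \code{coassoc} (global and anchored) -> \code{motifs} ->
#' \code{classify} -> \code{states} / \code{targets} / \code{pathways} ->
#' \code{coreg}. Stages can be toggled; requesting a stage whose
#' prerequisite is disabled raises an error naming the missing stage. All
#' tabular outputs are written to \code{out_dir} (when given) with the seed
#' in a header line.
#'
#' @param inputs List with components (all optional except as required by
#'   the enabled stages): \code{manifest} + \code{peaks} (for curate);
#'   \code{peaksets} (named list, incl. the anchor) + \code{anchor_factor};
#'   \code{enrichment} (data.frame factor/cell_line/enrichment_class, e.g.
#'   from \code{\link{demo_motif_enrichment}}); \code{segmentation};
#'   \code{annotation}; \code{pathways} (gene-set list); \code{deg}
#'   (DEG table) + \code{deg_targets} (named list of per-factor regulated
#'   gene ids).
#' @param cfg \code{\link{analysis_config}}.
#' @param out_dir Output directory or \code{NULL}.
#' @param stages Character vector of stages to run.
#' @param seed Seed recorded in output headers.
#' @return Named list of stage results.
#' @export
run_all <- function(inputs, cfg = analysis_config(), out_dir = NULL,
                    stages = c("curate", "coassoc", "classify", "states",
                               "targets", "pathways", "coreg"),
                    seed = cfg$random_seed) {
  res <- list()
  need <- function(stage, dep) {
    if (!dep %in% stages) {
      stop(sprintf("stage '%s' requires stage '%s', which is not enabled",
                   stage, dep))
    }
  }
  if ("curate" %in% stages) {
    res$curation <- curate(inputs$manifest, inputs$peaks, cfg)
    .write_tsv(data.frame(experiment_id = res$curation$kept, status = "kept"),
               out_dir, "curation_kept.tsv", seed)
    .write_tsv(res$curation$dropped, out_dir, "curation_dropped.tsv", seed)
  }
  anchor <- NULL
  if ("coassoc" %in% stages) {
    ps <- inputs$peaksets
    if (is.null(ps)) stop("stage 'coassoc' needs inputs$peaksets")
    anchor <- ps[[inputs$anchor_factor]]
    if (is.null(anchor)) stop("anchor factor not found among peak sets")
    res$coassoc <- coassoc_matrix(ps, cfg)
    res$coassoc_anchored <- coassoc_matrix(ps[names(ps) != inputs$anchor_factor],
                                           cfg, anchor = anchor)
    .write_tsv(res$coassoc$pairs, out_dir, "coassoc_pairs.tsv", seed)
    .write_tsv(res$coassoc_anchored$pairs, out_dir,
               "coassoc_anchored_pairs.tsv", seed)
    if (nrow(res$coassoc$scores) >= 3L) {
      cl <- cluster_matrix(res$coassoc$scores)
      res$coassoc_clustering <- cl
      if (!is.null(out_dir)) {
        writeLines(cl$newick, file.path(out_dir, "coassoc_dendrogram.nwk"))
      }
    }
  }
  if ("classify" %in% stages) {
    need("classify", "coassoc")
    if (is.null(inputs$enrichment)) stop("stage 'classify' needs inputs$enrichment")
    pairs <- res$coassoc$pairs
    af <- inputs$anchor_factor
    shares <- pairs[pairs$factor_b == af & pairs$factor_a != af,
                    c("factor_a", "share_a")]
    recip <- pairs[pairs$factor_a == af & pairs$factor_b != af,
                   c("factor_b", "share_b", "score")]
    enr <- inputs$enrichment
    enr$factor_share <- shares$share_a[match(enr$factor, shares$factor_a)]
    enr$nfyb_share <- recip$share_b[match(enr$factor, recip$factor_b)]
    enr$coassoc_score <- recip$score[match(enr$factor, recip$factor_b)]
    res$groups <- assign_groups(enr, cfg)
    .write_tsv(res$groups, out_dir, "groups.tsv", seed)
  }
  if ("states" %in% stages) {
    need("states", "coassoc")
    if (is.null(inputs$segmentation)) stop("stage 'states' needs inputs$segmentation")
    ps <- inputs$peaksets
    dists <- lapply(names(ps), function(f) {
      d_all <- state_distribution(ps[[f]], inputs$segmentation, NULL, cfg)
      d_co <- state_distribution(ps[[f]], inputs$segmentation, anchor, cfg)
      rbind(data.frame(factor = f, scope = "all_peaks",
                       state = names(d_all$fractions),
                       fraction = as.numeric(d_all$fractions)),
            data.frame(factor = f, scope = "co_bound",
                       state = names(d_co$fractions),
                       fraction = as.numeric(d_co$fractions)))
    })
    res$states <- do.call(rbind, dists)
    .write_tsv(res$states, out_dir, "chromatin_states.tsv", seed)
  }
  if ("targets" %in% stages) {
    need("targets", "coassoc")
    if (is.null(inputs$annotation)) stop("stage 'targets' needs inputs$annotation")
    ps <- inputs$peaksets
    res$targets <- lapply(ps[names(ps) != inputs$anchor_factor], function(p) {
      promoter_targets(.restrict_to_anchor(p, anchor, cfg),
                       inputs$annotation, cfg$promoter_window_pathways, cfg)
    })
    tg <- do.call(rbind, lapply(res$targets, function(t) {
      if (!length(t$genes)) return(NULL)
      data.frame(factor = t$factor, gene_id = t$genes)
    }))
    .write_tsv(tg, out_dir, "target_genes.tsv", seed)
  }
  if ("pathways" %in% stages) {
    need("pathways", "targets")
    if (is.null(inputs$pathways)) stop("stage 'pathways' needs inputs$pathways")
    universe <- inputs$annotation$gene_id
    ora <- lapply(res$targets, pathway_ora, pathways = inputs$pathways,
                  universe = universe)
    res$pathway_matrix <- build_pathway_matrix(ora, inputs$pathways, cfg)
    .write_tsv(data.frame(pathway = rownames(res$pathway_matrix$membership),
                          res$pathway_matrix$membership,
                          check.names = FALSE),
               out_dir, "pathway_matrix.tsv", seed)
  }
  if ("coreg" %in% stages) {
    if (is.null(inputs$deg) || is.null(inputs$deg_targets)) {
      stop("stage 'coreg' needs inputs$deg and inputs$deg_targets")
    }
    part <- partition_degs(inputs$deg, cfg)
    res$deg_partition <- part
    state_tab <- list(UP = part$up, DOWN = part$down)
    res$coreg <- lapply(names(state_tab), function(st) {
      uni <- state_tab[[st]]
      tgt <- lapply(inputs$deg_targets, intersect, y = uni)
      fisher_coreg_all(tgt, uni, state = st)
    })
    names(res$coreg) <- names(state_tab)
    .write_tsv(do.call(rbind, res$coreg), out_dir, "coreg_pairs.tsv", seed)
    res$coreg_clustering <- lapply(res$coreg, function(p) {
      tryCatch(coreg_heatmap(p), error = function(e) NULL,
               warning = function(w) suppressWarnings(coreg_heatmap(p)))
    })
  }
  res
}

# ---------------------------------------------------------------------------
# Demo cosmos: 12 partner factors with planted Group 1-4 archetypes plus an
# NF-YB anchor, in three synthetic cell lines.

#' Ground-truth design of the demo cosmos
#'
#' Twelve partner factors, three per group: planted factor shares against
#' the NF-YB anchor, the planted CCAAT enrichment mode, and one factor
#' (TF02) additionally planted with its motif 11 bp upstream of the CCAAT
#' middle A -- the classic TALE-family arrangement.
#'
#' @return data.frame: factor, group, ccaat_mode, share, posbias_offset.
#' @export
demo_truth <- function() {
  data.frame(
    factor = sprintf("TF%02d", 1:12),
    group = rep(1:4, each = 3),
    ccaat_mode = c("global_primary", "global_secondary", "global_secondary",
                   "local_only", "local_only", "global_secondary",
                   "global_primary", "global_primary", "global_secondary",
                   "none", "none", "none"),
    share = c(0.50, 0.30, 0.90,
              0.12, 0.15, 0.19,
              0.01, 0.02, 0.03,
              0.35, 0.30, 0.40),
    posbias_offset = c(NA, -11L, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

# Motif-enrichment stage of the demo: plant CCAAT (and each factor's own
# motif) into per-factor region blocks of a sequence genome, scan, and
# classify. Background accessible regions carry a basal CCAAT rate so that
# local-only factors (planted at the basal rate centrally, nothing in
# flanks) are locally but not globally enriched.

#' Demo motif-enrichment stage
#'
#' Generates one small sequence genome per cell line, plants CCAAT and
#' partner-motif consensus sequences according to the demo design, scans
#' summit windows, flanks and the shared accessible-region background, and
#' classifies every factor's CCAAT enrichment.
#'
#' @param truth \code{\link{demo_truth}} design (or a subset of its rows).
#' @param cell_lines Character vector of cell-line names.
#' @param n_central Regions scanned per factor.
#' @param n_background Background accessible regions per cell line.
#' @param basal_ccaat Basal CCAAT rate of accessible background regions.
#' @param seed Integer seed.
#' @param cfg \code{\link{analysis_config}}.
#' @return List: \code{enrichment} (data.frame factor / cell_line /
#'   enrichment_class / global_p / local_p), \code{posbias} (named list of
#'   \code{\link{positional_bias}} results for factors with a planted
#'   offset, first cell line only).
#' @export
demo_motif_enrichment <- function(truth = demo_truth(),
                                  cell_lines = c("CL1", "CL2", "CL3"),
                                  n_central = 250L, n_background = 300L,
                                  basal_ccaat = 0.30, seed = 1L,
                                  cfg = analysis_config()) {
  ccaat <- synthetic_ccaat_pwm()
  own_pwms <- lapply(seq_len(nrow(truth)), function(i) {
    synthetic_tf_pwm(truth$factor[i], seed = 100L + i)
  })
  names(own_pwms) <- truth$factor
  nf <- nrow(truth)
  rows <- list(); posbias <- list()
  for (ci in seq_along(cell_lines)) {
    cl <- cell_lines[ci]
    n_reg <- nf * n_central + n_background
    genome <- make_genome(1L, n_reg * 1200L, n_reg,
                          seed = child_seed(seed, "genome") + ci)
    blocks <- split(seq_len(n_reg),
                    rep(c(truth$factor, ".bg"),
                        c(rep(n_central, nf), n_background)))
    # flank windows extend 150 bp past the region; drop regions too close
    # to a chromosome edge
    chrom_len <- genome$chrom_sizes[[1]]
    valid <- which(genome$accessible_regions$start >= 150L &
                   genome$accessible_regions$end <= chrom_len - 150L)
    blocks <- lapply(blocks, intersect, y = valid)
    plants <- list()
    for (i in seq_len(nf)) {
      mode <- truth$ccaat_mode[i]
      fac <- truth$factor[i]
      regs <- blocks[[fac]]
      frac_ccaat <- switch(mode, global_primary = 0.9,
                           global_secondary = 0.6,
                           local_only = basal_ccaat, none = 0)
      if (frac_ccaat > 0) {
        if (!is.na(truth$posbias_offset[i])) {
          plants[[length(plants) + 1L]] <- list(
            pwm = own_pwms[[fac]], offset = truth$posbias_offset[i],
            orientation = "+", fraction = frac_ccaat, regions = regs)
        } else {
          plants[[length(plants) + 1L]] <- list(
            pwm = NULL, fraction = frac_ccaat, regions = regs)
        }
      }
      if (mode == "global_secondary" && is.na(truth$posbias_offset[i])) {
        # the factor's own motif dominates; plant it independently of CCAAT
        plants[[length(plants) + 1L]] <- list(
          pwm = own_pwms[[fac]], offset = 40L, orientation = "+",
          fraction = 0.95, regions = regs)
      }
    }
    plants[[length(plants) + 1L]] <- list(pwm = NULL, fraction = basal_ccaat,
                                          regions = blocks[[".bg"]])
    genome <- plant_sequences(genome, ccaat, plants,
                              seed = child_seed(seed, "sequence") + ci)
    seqs <- genome$sequence
    regions <- genome$accessible_regions
    win_of <- function(idx, shift = 0L) {
      data.frame(chrom = regions$chrom[idx],
                 start = regions$start[idx] + shift,
                 end = regions$end[idx] + shift, stringsAsFactors = FALSE)
    }
    bg_ccaat <- scan_windows(seqs, win_of(blocks[[".bg"]]), ccaat)
    for (i in seq_len(nf)) {
      fac <- truth$factor[i]
      regs <- blocks[[fac]]
      central <- win_of(regs)
      cc_central <- scan_windows(seqs, central, ccaat)
      cc_f5 <- scan_windows(seqs, win_of(regs, -150L), ccaat)
      cc_f3 <- scan_windows(seqs, win_of(regs, 150L), ccaat)
      own_central <- scan_windows(seqs, central, own_pwms[[fac]])
      bg_own <- scan_windows(seqs, win_of(blocks[[".bg"]]), own_pwms[[fac]])
      results <- data.frame(
        matrix_id = c(ccaat$matrix_id, own_pwms[[fac]]$matrix_id),
        global_p = c(global_enrichment(cc_central, bg_ccaat, cfg = cfg),
                     global_enrichment(own_central, bg_own, cfg = cfg)),
        local_p = c(local_enrichment(cc_central, cc_f5, cc_f3, cfg),
                    NA_real_))
      cls <- classify_ccaat(results, ccaat$matrix_id, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        factor = fac, cell_line = cl,
        enrichment_class = cls$enrichment_class,
        global_p = cls$global_p, local_p = cls$local_p,
        stringsAsFactors = FALSE)
      if (ci == 1L && !is.na(truth$posbias_offset[i])) {
        posbias[[fac]] <- positional_bias(central, seqs, own_pwms[[fac]],
                                          ccaat, cfg)
      }
    }
  }
  list(enrichment = do.call(rbind, rows), posbias = posbias,
       ccaat = ccaat, own_pwms = own_pwms)
}

#' Run the synthetic demo cosmos end to end
#'
#' Generates three synthetic "cell lines" sharing the twelve-factor design
#' of \code{\link{demo_truth}} plus an NF-YB anchor, runs every pipeline
#' stage, and compares the recovered group assignments with the planted
#' ones. The demo uses a config whose replicate-curation floor is scaled to
#' its peak counts.
#'
#' @param seed Integer seed; everything downstream derives from it.
#' @param out_dir Optional output directory for the stage TSVs.
#' @param n_peaks Peaks per partner factor.
#' @param n_anchor Peaks of the NF-YB anchor.
#' @return List: \code{truth}, \code{groups}, \code{misclassified} (factor
#'   names), \code{posbias}, \code{enrichment}, \code{stage_results}.
#' @export
run_demo <- function(seed = 42L, out_dir = NULL,
                     n_peaks = 1500L, n_anchor = 3000L) {
  truth <- demo_truth()
  cfg <- analysis_config(min_peaks_replicate = max(100L, n_peaks %/% 3L),
                         random_seed = as.integer(seed))
  cell_lines <- c("CL1", "CL2", "CL3")
  factors <- c("NF-YB", truth$factor)
  nf <- length(factors)
  co <- matrix(0, nf, nf, dimnames = list(factors, factors))
  co["NF-YB", truth$factor] <- truth$share
  co[truth$factor, "NF-YB"] <- truth$share

  # co-association genome: sparse, no sequence needed
  genome <- make_genome(4L, 10000000L, 20000L,
                        seed = child_seed(seed, "genome"))
  per_cl <- lapply(seq_along(cell_lines), function(ci) {
    plant_peaksets(genome, factors,
                   peaks_per_factor = c(n_anchor, rep(n_peaks, nf - 1L)),
                   coassoc = co, cell_line = cell_lines[ci],
                   seed = child_seed(seed, "peaks") + ci)
  })
  names(per_cl) <- cell_lines
  peaksets <- per_cl[[1]]$peaksets

  # curation showcase: the first cell line's sets plus planted duplicates
  manifest <- data.frame(
    experiment_id = sprintf("EXP_%s", factors), factor = factors,
    cell_line = "CL1", is_tagged = FALSE, treated = FALSE,
    stringsAsFactors = FALSE)
  peaks_by_id <- stats::setNames(peaksets, manifest$experiment_id)
  subsample_ps <- function(ps, frac, id) {
    set.seed(child_seed(seed, "peaks") + 977L)
    keep <- sort(sample(nrow(ps$peaks), round(frac * nrow(ps$peaks))))
    out <- ps; out$peaks <- ps$peaks[keep, , drop = FALSE]
    out$experiment_id <- id
    out
  }
  extra <- data.frame(
    experiment_id = c("EXP_TF01_tag", "EXP_TF04_rep2", "EXP_TF07_small",
                      "EXP_TF10_treated"),
    factor = c("TF01", "TF04", "TF07", "TF10"),
    cell_line = "CL1",
    is_tagged = c(TRUE, FALSE, FALSE, FALSE),
    treated = c(FALSE, FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  manifest <- rbind(manifest, extra)
  peaks_by_id$EXP_TF01_tag <- subsample_ps(peaksets$TF01, 0.9, "EXP_TF01_tag")
  peaks_by_id$EXP_TF01_tag$is_tagged <- TRUE
  peaks_by_id$EXP_TF04_rep2 <- subsample_ps(peaksets$TF04, 0.8, "EXP_TF04_rep2")
  peaks_by_id$EXP_TF07_small <- subsample_ps(peaksets$TF07, 0.05, "EXP_TF07_small")
  peaks_by_id$EXP_TF10_treated <- subsample_ps(peaksets$TF10, 0.7, "EXP_TF10_treated")

  # motif enrichment on separate sequence genomes
  motifs <- demo_motif_enrichment(truth, cell_lines, seed = seed, cfg = cfg)

  # toy chromatin segmentation over the peak genome
  state_labels <- c("TssA", "TssFlnk", "TssFlnkU", "TssFlnkD", "Tx", "TxWk",
                    "EnhG1", "EnhG2", "EnhA1", "EnhA2", "EnhWk", "ZNF/Rpts",
                    "Het", "TssBiv", "EnhBiv", "ReprPC", "ReprPCWk", "Quies")
  set.seed(child_seed(seed, "genome") + 7L)
  seg_bins <- do.call(rbind, lapply(names(genome$chrom_sizes), function(ch) {
    starts <- seq(0L, genome$chrom_sizes[[ch]] - 200L, by = 200L)
    data.frame(chrom = ch, start = starts, end = starts + 200L,
               state = sample(state_labels, length(starts), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  segmentation <- chromatin_segmentation(seg_bins)

  # toy gene annotation at accessible-region centers + pathway sets
  set.seed(child_seed(seed, "genome") + 11L)
  reg <- genome$accessible_regions
  gidx <- sort(sample(nrow(reg), 3000L))
  annotation <- data.frame(
    gene_id = sprintf("G%05d", seq_along(gidx)),
    chrom = reg$chrom[gidx],
    tss = reg$start[gidx] + 75L,
    strand = sample(c("+", "-"), length(gidx), replace = TRUE),
    stringsAsFactors = FALSE)
  # pathway sets: a planted enriched pathway per Group 1 factor (drawn from
  # genes at that factor's anchor-shared regions) plus random ones
  region_of_gene <- gidx
  tr <- per_cl[[1]]$truth$regions
  pathways <- lapply(1:16, function(i) sample(annotation$gene_id, 60L))
  names(pathways) <- sprintf("PW%02d", 1:16)
  for (i in 1:3) {
    fac <- truth$factor[i]
    shared <- intersect(tr[[fac]], tr[["NF-YB"]])
    hit_genes <- annotation$gene_id[region_of_gene %in% shared]
    if (length(hit_genes) >= 25L) {
      pathways[[sprintf("PW_%s", fac)]] <-
        c(sample(hit_genes, 25L), sample(annotation$gene_id, 30L))
    }
  }

  # DEG stage with planted target overlaps among the Group 1 trio
  ov <- matrix(0, 12, 12, dimnames = list(truth$factor, truth$factor))
  ov[1:3, 1:3] <- 0.45; diag(ov) <- 0
  degs <- plant_deg_tables(4000L, 0.2, 0.2, factors = truth$factor,
                           target_size = 300L, overlaps = ov,
                           seed = child_seed(seed, "deg"), cfg = cfg)

  inputs <- list(manifest = manifest, peaks = peaks_by_id,
                 peaksets = peaksets, anchor_factor = "NF-YB",
                 enrichment = motifs$enrichment,
                 segmentation = segmentation, annotation = annotation,
                 pathways = pathways, deg = degs$deg,
                 deg_targets = degs$targets)
  stage_results <- run_all(inputs, cfg, out_dir, seed = seed)

  recovered <- stage_results$groups
  cmp <- merge(truth[, c("factor", "group")], recovered, by = "factor")
  mis <- cmp$factor[as.character(cmp$group.x) != cmp$group.y]
  list(truth = truth, groups = recovered, misclassified = mis,
       posbias = motifs$posbias, enrichment = motifs$enrichment,
       stage_results = stage_results, cfg = cfg, seed = as.integer(seed))
}
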