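#!/usr/bin/env Rscript
# Stage 06 -- chromatin states, target genes and pathway enrichment.
#
# Overlays a toy 18-state segmentation on the peak genome, splits each
# factor's summit state distribution by scope (all peaks vs co-bound with
# NF-YB), assigns target genes through the (-1000, +100) promoter window,
# and builds the filtered/merged pathway-membership matrix (ORA p < 1e-5,
# background <= 200, identical gene sets merged).

suppressPackageStartupMessages(library(nfyregulome))

SEED <- 42L
in_dir <- "scratch/synthetic_inputs"
manifest <- read.table("results/manifest.tsv", sep = "\t", header = TRUE)
kept <- read.table("results/curation_kept.tsv", sep = "\t", header = TRUE)
manifest <- manifest[manifest$experiment_id %in% kept$experiment_id, ]
peaksets <- lapply(seq_len(nrow(manifest)), function(i) {
  read_narrowpeak(file.path(in_dir, paste0(manifest$experiment_id[i], ".narrowPeak")),
                  factor = manifest$factor[i], cell_line = manifest$cell_line[i])
})
names(peaksets) <- manifest$factor
anchor <- peaksets[["NF-YB"]]
cfg <- analysis_config()

# toy segmentation: the full genome in 200 bp bins with 18 mnemonics
genome <- make_genome(4L, 10000000L, 20000L, seed = SEED)  # same layout as 01
labels <- c("TssA", "TssFlnk", "TssFlnkU", "TssFlnkD", "Tx", "TxWk",
            "EnhG1", "EnhG2", "EnhA1", "EnhA2", "EnhWk", "ZNF/Rpts",
            "Het", "TssBiv", "EnhBiv", "ReprPC", "ReprPCWk", "Quies")
set.seed(SEED + 7L)
seg <- chromatin_segmentation(do.call(rbind, lapply(names(genome$chrom_sizes),
  function(ch) {
    starts <- seq(0L, genome$chrom_sizes[[ch]] - 200L, by = 200L)
    data.frame(chrom = ch, start = starts, end = starts + 200L,
               state = sample(labels, length(starts), replace = TRUE))
  })))

dists <- do.call(rbind, lapply(names(peaksets), function(f) {
  all <- state_distribution(peaksets[[f]], seg, NULL, cfg)
  cob <- state_distribution(peaksets[[f]], seg, anchor, cfg)
  rbind(data.frame(factor = f, scope = "all_peaks", state = names(all$fractions),
                   fraction = as.numeric(all$fractions)),
        data.frame(factor = f, scope = "co_bound", state = names(cob$fractions),
                   fraction = as.numeric(cob$fractions)))
}))
write.table(dists, "results/chromatin_states.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# toy gene annotation at a sample of accessible-region centers, plus
# pathway sets enriched in the Group 1 factors' targets
set.seed(SEED + 11L)
reg <- genome$accessible_regions
gidx <- sort(sample(nrow(reg), 3000L))
ann <- data.frame(gene_id = sprintf("G%05d", seq_along(gidx)),
                  chrom = reg$chrom[gidx], tss = reg$start[gidx] + 75L,
                  strand = sample(c("+", "-"), length(gidx), replace = TRUE))

targets <- lapply(peaksets[names(peaksets) != "NF-YB"], function(p) {
  promoter_targets(nfyregulome:::.restrict_to_anchor(p, anchor, cfg), ann,
                   cfg$promoter_window_pathways, cfg)
})
tg_tab <- do.call(rbind, lapply(targets, function(t) {
  if (!length(t$genes)) return(NULL)
  data.frame(factor = t$factor, gene_id = t$genes)
}))
write.table(tg_tab, "results/target_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("Target genes per factor (promoter window -1000/+100):")
print(vapply(targets, function(t) length(t$genes), 1L))

pathways <- lapply(1:16, function(i) sample(ann$gene_id, 60L))
names(pathways) <- sprintf("PW%02d", 1:16)
for (f in c("TF01", "TF02", "TF03")) {
  hits <- targets[[f]]$genes
  if (length(hits) >= 25L) {
    pathways[[paste0("PW_", f)]] <- c(sample(hits, 25L),
                                      sample(ann$gene_id, 30L))
  }
}
ora <- lapply(targets, pathway_ora, pathways = pathways, universe = ann$gene_id)
pm <- build_pathway_matrix(ora, pathways, cfg)
write.table(data.frame(pathway = rownames(pm$membership), pm$membership,
                       check.names = FALSE),
            "results/pathway_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("Pathways surviving the p/background filters and merging: ",
        nrow(pm$membership),
        " (planted: the PW_TF0x sets); factor order by pathway count: ",
        paste(pm$factor_order, collapse = " < "))
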