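#!/usr/bin/env Rscript
# Stage 03 -- co-association scoring.
#
# Computes the pairwise summit-overlap statistic for every kept experiment
# against every other: signed -log10 Bonferroni-corrected Poisson scores on
# the 250,000-accessible-region null, in both global and NF-YB-anchored
# mode, then clusters the global score matrix (Pearson distance, centroid
# linkage). The planted shares should reappear in the share_a column of the
# NF-YB pairs, and self-comparisons in the matrix diagonal sit at the
# score ceiling (323).

suppressPackageStartupMessages(library(nfyregulome))

in_dir <- "scratch/synthetic_inputs"
kept <- read.table("results/curation_kept.tsv", sep = "\t", header = TRUE)
manifest <- read.table("results/manifest.tsv", sep = "\t", header = TRUE)
manifest <- manifest[manifest$experiment_id %in% kept$experiment_id, ]

peaksets <- lapply(seq_len(nrow(manifest)), function(i) {
  read_narrowpeak(file.path(in_dir, paste0(manifest$experiment_id[i], ".narrowPeak")),
                  factor = manifest$factor[i], cell_line = manifest$cell_line[i])
})
names(peaksets) <- manifest$factor

cfg <- analysis_config()
m <- coassoc_matrix(peaksets, cfg)
m_anch <- coassoc_matrix(peaksets[names(peaksets) != "NF-YB"], cfg,
                         anchor = peaksets[["NF-YB"]])
cl <- cluster_matrix(m$scores)

write_coassoc_pairs(m, "results/coassoc_pairs.tsv")
write_coassoc_pairs(m_anch, "results/coassoc_anchored_pairs.tsv")
write.table(data.frame(factor = rownames(cl$matrix), cl$matrix,
                       check.names = FALSE),
            "results/coassoc_matrix_ordered.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(cl$newick, "results/coassoc_dendrogram.nwk")

nfyb <- m$pairs[m$pairs$factor_b == "NF-YB", c("factor_a", "share_a", "score")]
message("Shares of factor peaks overlapping NF-YB (planted design 0.01-0.90):")
print(nfyb[order(nfyb$factor_a), ], row.names = FALSE)
message("Significant pairs (score > 100, anchor share > 10%): ",
        sum(m$pairs$score > cfg$coassoc_score_threshold &
              m$pairs$share_b > cfg$nfyb_share_threshold))
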