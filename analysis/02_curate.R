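#!/usr/bin/env Rscript
# Stage 02 -- curate the experiment manifest.
#
# Applies the replicate-curation workflow (treated side channel, tagged
# removal, minima filter, 66% concordance gate) to the simulated manifest
# and reports what survived. Expected outcome on the planted design: the
# tagged TF01 duplicate and the tiny TF07 replicate drop, the larger TF04
# replicate wins its concordance gate, the treated TF10 dataset is
# side-channelled, and one experiment per factor remains.

suppressPackageStartupMessages(library(nfyregulome))

in_dir <- "scratch/synthetic_inputs"
manifest <- read.table("results/manifest.tsv", sep = "\t", header = TRUE)
peaks <- lapply(seq_len(nrow(manifest)), function(i) {
  read_narrowpeak(file.path(in_dir, paste0(manifest$experiment_id[i], ".narrowPeak")),
                  factor = manifest$factor[i],
                  cell_line = manifest$cell_line[i],
                  experiment_id = manifest$experiment_id[i],
                  is_tagged = manifest$is_tagged[i])
})
names(peaks) <- manifest$experiment_id

cfg <- analysis_config(min_peaks_replicate = 500L)  # floor scaled to the cosmos
report <- curate(manifest, peaks, cfg)
print(report)

write.table(data.frame(experiment_id = report$kept, status = "kept"),
            "results/curation_kept.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(report$dropped, "results/curation_dropped.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Kept ", length(report$kept), " experiments; side-channelled ",
        length(report$treated), " treated; dropped ", nrow(report$dropped))
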