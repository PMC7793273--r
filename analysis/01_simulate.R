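#!/usr/bin/env Rscript
# Stage 01 -- simulate the study cosmos.
#
# Builds the synthetic inputs every later stage consumes: a sparse genome
# with 20,000 accessible regions, an NF-YB anchor (3,000 summits) and twelve
# partner factors (1,500 summits each) with planted overlap shares matching
# the four co-association archetypes (three factors per group), plus the
# replicate/tagged/treated extras that exercise curation. Peak sets are
# written as narrowPeak under scratch/ (bulky intermediates); the manifest
# and the ground-truth design go to results/.

suppressPackageStartupMessages(library(nfyregulome))

SEED <- 42L
in_dir <- "scratch/synthetic_inputs"
dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

truth <- demo_truth()
message("Design: ", nrow(truth), " partner factors, groups ",
        paste(unique(truth$group), collapse = "/"),
        "; planted shares ", paste(truth$share, collapse = ", "))

factors <- c("NF-YB", truth$factor)
co <- matrix(0, length(factors), length(factors),
             dimnames = list(factors, factors))
co["NF-YB", truth$factor] <- truth$share
co[truth$factor, "NF-YB"] <- truth$share

genome <- make_genome(4L, 10000000L, 20000L, seed = SEED)
pp <- plant_peaksets(genome, factors,
                     peaks_per_factor = c(3000L, rep(1500L, nrow(truth))),
                     coassoc = co, cell_line = "CL1", seed = SEED + 1L)

manifest <- data.frame(experiment_id = sprintf("EXP_%s", factors),
                       factor = factors, cell_line = "CL1",
                       is_tagged = FALSE, treated = FALSE)
for (f in factors) {
  write_narrowpeak(pp$peaksets[[f]],
                   file.path(in_dir, sprintf("EXP_%s.narrowPeak", f)))
}

# curation extras: a tagged duplicate, a concordant second replicate, a
# minima replicate, and a treated dataset
subsample <- function(ps, frac, id) {
  keep <- sort(sample(nrow(ps$peaks), round(frac * nrow(ps$peaks))))
  ps$peaks <- ps$peaks[keep, , drop = FALSE]
  ps$experiment_id <- id
  ps
}
set.seed(SEED + 2L)
extras <- list(
  EXP_TF01_tag = subsample(pp$peaksets$TF01, 0.9, "EXP_TF01_tag"),
  EXP_TF04_rep2 = subsample(pp$peaksets$TF04, 0.8, "EXP_TF04_rep2"),
  EXP_TF07_small = subsample(pp$peaksets$TF07, 0.05, "EXP_TF07_small"),
  EXP_TF10_treated = subsample(pp$peaksets$TF10, 0.7, "EXP_TF10_treated"))
for (id in names(extras)) {
  write_narrowpeak(extras[[id]], file.path(in_dir, paste0(id, ".narrowPeak")))
}
manifest <- rbind(manifest, data.frame(
  experiment_id = names(extras),
  factor = c("TF01", "TF04", "TF07", "TF10"), cell_line = "CL1",
  is_tagged = c(TRUE, FALSE, FALSE, FALSE),
  treated = c(FALSE, FALSE, FALSE, TRUE)))

write.table(manifest, "results/manifest.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(truth, "results/planted_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(list(seed = SEED, n_factors = nrow(truth),
                          n_accessible = 20000L,
                          peaks_per_factor = 1500L, anchor_peaks = 3000L),
                     "results/simulation_params.json", auto_unbox = TRUE)
message("Wrote ", nrow(manifest), " experiments to ", in_dir,
        " and the manifest/truth tables to results/")
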