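#!/usr/bin/env Rscript
# Classify each sample's reads into small-RNA classes (miRNA, excluded
# structural RNAs, piRNA, siRNA candidates, unassigned) and tabulate the
# apportioned length histograms — the per-sample small-RNA profile and the
# size distribution of the transposon-associated reads.

suppressMessages({ library(pirnakit); library(data.table) })

stages <- c("PVS", "Egg", "Emb", "Nym")
summary <- rbindlist(lapply(stages, function(stage) {
  d <- file.path("results", paste0("input_", stage))
  reads <- read_alignment_table(file.path(d, "reads.bed"))
  ann <- fread(file.path(d, "annotations.tsv"))
  total <- uniqueN(reads$read_id)
  cs <- class_summary(reads, ann)
  fwrite(cs, file.path(d, "class_summary.tsv"), sep = "\t")
  fwrite(length_histogram(reads, total),
         file.path(d, "length_hist_all.tsv"), sep = "\t")
  fwrite(length_histogram(reads, total, te_only = TRUE, annotations = ann),
         file.path(d, "length_hist_te.tsv"), sep = "\t")
  cat(sprintf("%s: piRNA %.1f%%, siRNA %.1f%%, miRNA %.1f%% of %d reads\n",
              stage,
              cs[class == "piRNA"]$percent,
              cs[class == "siRNA_candidate"]$percent,
              cs[class == "miRNA"]$percent, total))
  data.table(sample = stage, cs)
}))
fwrite(summary, "results/class_summary_all.tsv", sep = "\t")
cat("per-class summaries written to results/class_summary_all.tsv\n")
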