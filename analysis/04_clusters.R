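#!/usr/bin/env Rscript
# Call piRNA clusters per sample from uniquely mapping piRNAs (5 kb
# windows, 1 kb steps, density > 5 reads/kb, coverage >= 12%, unions
# < 20 kb apart combined), classify their strandness with the 75% rule,
# rank them by productivity, and count HTT copies inserted in them.

suppressMessages({ library(pirnakit); library(data.table) })

stages <- c("PVS", "Egg", "Emb", "Nym")
for (stage in stages) {
  d <- file.path("results", paste0("input_", stage))
  reads <- read_alignment_table(file.path(d, "reads.bed"))
  ann <- fread(file.path(d, "annotations.tsv"))
  genome <- read_fasta(file.path(d, "genome.fa"))
  sizes <- setNames(nchar(genome), names(genome))
  total <- uniqueN(reads$read_id)
  lab <- classify_reads(reads, ann, scaffold_sizes = sizes)
  upirna <- reads[lab == "piRNA" & mapping_count == 1L]
  cl <- call_clusters(upirna, sizes, mapped_total = total)
  write_bed(cl, file.path(d, "clusters.bed"))
  fwrite(cl, file.path(d, "clusters.tsv"), sep = "\t")
  share <- cumulative_share(cl)
  htt <- count_htt_copies_in_clusters(ann[is_htt == TRUE], cl)
  ori <- te_orientation_in_clusters(ann, cl)
  fwrite(ori, file.path(d, "cluster_te_orientation.tsv"), sep = "\t")
  cat(sprintf(
    "%s: %d clusters (%d uni-strand), top cluster holds %.0f%% of in-cluster piRNAs, %d HTT copies inside\n",
    stage, nrow(cl), sum(cl$strandness != "unbiased"),
    100 * share[1], sum(htt$n_in_clusters)))
}
cat("cluster calls written under results/input_*/clusters.{bed,tsv}\n")
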