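#!/usr/bin/env Rscript
# Positional enrichment analyses on the cohort's interval data:
#   (i)  hexamer occupancy inside the peak set vs all promoters;
#   (ii) chromatin states as association features (states instead of
#        hexamers through the same meta + permutation machinery);
#   (iii) hexamer occupancy inside each chromatin state's promoter
#        segments, genome-wide and responsive-vs-control.

library(hexameta)

dir.create("results/regions", recursive = TRUE, showWarnings = FALSE)
promoters <- read_promoters_fasta("results/cohort/promoters.fa")
man <- read.delim("results/cohort/manifest.tsv")
datasets <- lapply(seq_len(nrow(man)), function(i) {
  read_deg_table(file.path("results/cohort", man$path[i]),
                 universe = promoters$gene_id,
                 dataset_id = man$dataset_id[i],
                 timepoint_h = man$timepoint_h[i])
})

# (i) peak enrichment
peaks <- peak_enrichment("results/cohort/peaks.bed",
                         "results/cohort/genome.fa", promoters)
write.table(peaks, "results/regions/peak_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- peaks[peaks$significant, ]
cat(sprintf("Peak enrichment: %d hexamers significant at FWER < 0.05; top:\n",
            nrow(sig)))
print(head(sig[order(sig$p), c("hexamer", "occupied_fg", "total_fg", "p",
                               "fwer_p")], 5), row.names = FALSE)

# (ii) chromatin states as association features
segs <- state_segments(promoters, "results/cohort/states.bed")
sp <- state_presence(segs, promoters$gene_id)
st_assoc <- state_association(datasets, sp, M = 1000, rng_seed = 2)
write.table(st_assoc$permutation, "results/regions/state_association.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nChromatin-state association (state as feature):\n")
print(st_assoc$permutation[, c("hexamer", "status", "meta_p", "perm_p",
                               "selected")], row.names = FALSE)

# (iii) hexamer enrichment within state segments
at_rich <- c("AAAAAA", "ATATAT", "TATAAA", "AATTAA")
gw <- do.call(rbind, lapply(sort(unique(segs$state)), function(s) {
  state_hexamer_enrichment(at_rich, s, segs, promoters,
                           mode = "genomewide")
}))
write.table(gw, "results/regions/state_hexamer_genomewide.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nA/T-rich hexamer enrichment by chromatin state (genome-wide):\n")
print(gw[, c("hexamer", "region_label", "p", "fwer_p", "significant")],
      row.names = FALSE)

sets <- build_gene_sets(datasets)
print(sets)
rc <- do.call(rbind, lapply(sort(unique(segs$state)), function(s) {
  state_hexamer_enrichment(at_rich, s, segs, promoters,
                           mode = "responsive_vs_control", sets = sets)
}))
write.table(rc, "results/regions/state_hexamer_responsive.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nSame comparison, responsive vs control gene segments:\n")
print(rc[, c("hexamer", "region_label", "p", "fwer_p", "significant")],
      row.names = FALSE)
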