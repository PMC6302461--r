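#!/usr/bin/env Rscript

# Step 2: ingest the study through the file readers, apply the two contact
# filters (drop intra-chromosomal pairs closer than 1 kb; drop n <= 5),
# restrict to inter-chromosomal interactions, label every interaction
# against every factor's binding bins, and compute the overlapping-ratio
# curves over thresholds 6..100.

suppressPackageStartupMessages(library(tfhic))

layout <- load_chrom_sizes("results/data/chrom.sizes")
records <- read_contacts("results/data/contacts.tsv", layout)
iset <- bin_contacts(records, layout, 1000)
message(sprintf("ingested %d records -> %d bin pairs", nrow(records), nrow(iset$interactions)))

iset <- filter_interactions(iset, min_reads = 6, min_separation_bins = 2)
message(sprintf(
  "filters removed %d close intra pairs and %d low-read pairs",
  iset$provenance$removed_distance, iset$provenance$removed_low_reads
))
iset <- subset_interactions(iset, "inter")
message(sprintf("analysing %d inter-chromosomal interactions", nrow(iset$interactions)))

tfbs <- read_tfbs("results/data/tfbs.bed", layout)
map <- mark_bins(tfbs, layout, 1000)
labels <- label_interactions(iset, map)
message(sprintf(
  "%d factors; %.1f%% of (interaction, factor) pairs positive",
  ncol(labels$labels), 100 * mean(labels$labels)
))

curves <- ratio_curves(labels, 6:100)
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write_interactions(iset, "results/tables/interactions_filtered.tsv")
utils::write.table(as.data.frame(curves), "results/tables/ratio_curves.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
message("wrote interactions_filtered.tsv and ratio_curves.tsv under results/tables/")
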