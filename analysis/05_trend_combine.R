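#!/usr/bin/env Rscript

# Step 5: trend-test comparison, two-method intersection, and link export.
# The trend-in-proportions test is run per factor over the same five read
# ranges as the elastic net; as expected it calls many more factors (it
# cannot separate stable from increasing trends), which is why the
# intersection of the two primary methods is the headline candidate set.
# High-intensity interactions of the combined factors are exported as BEDPE
# at T = 20 and T = 40 for circos-style rendering.

suppressPackageStartupMessages(library(tfhic))

layout <- load_chrom_sizes("results/data/chrom.sizes")
iset <- subset_interactions(
  filter_interactions(
    bin_contacts(read_contacts("results/data/contacts.tsv", layout), layout, 1000)
  ),
  "inter"
)
map <- mark_bins(read_tfbs("results/data/tfbs.bed", layout), layout, 1000)
labels <- label_interactions(iset, map)
curves <- ratio_curves(labels, 6:100)

trend <- run_trend_scan(curves)
n_sig <- sum(trend$summary$testable & trend$summary$min_p_adj < 0.05, na.rm = TRUE)
n_up <- sum(trend$summary$testable & trend$summary$min_p_adj < 0.05 &
  trend$summary$direction > 0, na.rm = TRUE)
message(sprintf(
  "trend test: %d of %d factors significant after Bonferroni (%d increasing)",
  n_sig, nrow(trend$summary), n_up
))

chisq_sig <- readLines("results/tables/chisq_significant.txt")
sel <- readLines("results/tables/enet_selected.txt")
bs_table <- utils::read.delim("results/tables/enet_selection.tsv")
combined <- combine_methods(chisq_sig, sel)
# order the intersection by elastic-net support
ord <- order(-bs_table$total[match(combined$intersection, bs_table$tf)],
  combined$intersection
)
combined$intersection <- combined$intersection[ord]
message(sprintf(
  "combined candidates (both methods): %s",
  paste(combined$intersection, collapse = ", ")
))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
utils::write.table(trend$tests, "results/tables/trend_tests.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
utils::write.table(combined$evidence, "results/tables/combined_evidence.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
for (Tt in c(20, 40)) {
  export_links(labels, combined$intersection, Tt,
    path = sprintf("results/tables/links_T%d.bedpe", Tt)
  )
}
message("wrote trend_tests.tsv, combined_evidence.tsv, links_T20/T40.bedpe")
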