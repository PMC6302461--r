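#!/usr/bin/env Rscript

# Step 4: bootstrapped elastic-net selection. The response is the read
# level n and the predictors are every factor's overlapping ratio at
# threshold n; for each of the five ranges 6..40 .. 6..60 the rows are
# resampled with replacement 500 times and refitted (mixing 0.5, penalty by
# 10-fold CV). Factors kept in more than 5% of fits (> 25 per range or
# > 125 of 2,500 overall) are selected. Takes a few minutes.

suppressPackageStartupMessages(library(tfhic))

layout <- load_chrom_sizes("results/data/chrom.sizes")
iset <- subset_interactions(
  filter_interactions(
    bin_contacts(read_contacts("results/data/contacts.tsv", layout), layout, 1000)
  ),
  "inter"
)
map <- mark_bins(read_tfbs("results/data/tfbs.bed", layout), layout, 1000)
curves <- ratio_curves(label_interactions(iset, map), 6:100)

bs <- bootstrap_select(curves, B = 500, threshold = 0.05, mixing = 0.5,
  folds = 10, seed = 1
)
sel <- selected_tfs(bs)
message(sprintf(
  "%d factor(s) pass the 5%% rule (> %g per range or > %g in total)",
  length(sel), bs$params$per_range_cutoff, bs$params$total_cutoff
))
top <- bs$selection[order(-bs$selection$total), ][1:10, c("tf", "total", "mean_beta")]
message("top 10 by total selection count:")
message(paste(utils::capture.output(print(top, row.names = FALSE)), collapse = "\n"))

truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)$truth
planted <- truth$tf[truth$planted]
message(sprintf("recall of planted factors: %.2f", mean(planted %in% sel)))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
utils::write.table(bs$selection, "results/tables/enet_selection.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
writeLines(sel, "results/tables/enet_selected.txt")
message("wrote enet_selection.tsv and enet_selected.txt")
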