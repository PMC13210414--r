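#!/usr/bin/env Rscript

# Step 5: metrics, cross-modality aggregation, parsimony model selection,
# per-class recall at the chosen feature count, feature-stability counts
# and the accuracy-vs-feature-count figures.

library(painconn)

sweep <- readRDS("scratch/sweep.rds")

summ <- summarise_sweep(sweep)
write.table(summ, "results/metrics_by_cell.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

agg <- aggregate_modalities(sweep)
write.table(agg, "results/aggregate_by_k.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

decision <- parsimony_select(agg, hp_threshold = 50, tolerance_pp = 1.0)
jsonlite::write_json(
  list(chosen_k = decision$chosen_k,
       hp_threshold = decision$hp_threshold,
       tolerance_pp = decision$tolerance_pp,
       trace = decision$trace),
  "results/parsimony.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("Parsimony-selected feature count: ",
        ifelse(is.na(decision$chosen_k), "none (no grid value stabilises)",
               decision$chosen_k))

k_report <- if (is.na(decision$chosen_k)) max(sweep$grid) else decision$chosen_k
pc <- per_class_recall_table(sweep, k_report)
write.table(pc, "results/per_class_recall.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("Per-class recall at k = ", k_report, ":")
print(pc, digits = 3)

stab <- stability_counts(sweep, top_m = 10)
top5 <- do.call(rbind, lapply(split(stab, stab$modality), head, 5))
write.table(top5, "results/stability_top.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("Most stable top-10 MI features per modality:")
print(top5, row.names = FALSE)

plot_sweep(sweep, "results/figures")
message("Figures and underlying tables in results/figures/")
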