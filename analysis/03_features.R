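#!/usr/bin/env Rscript

# Step 3: compute the four connectivity matrices per trial (Pearson
# correlation, partial correlation, band-averaged coherence, pairwise
# Granger causality) and vectorise them into the canonical 1380-feature
# table, one table per haemoglobin modality.

library(painconn)

trials <- readRDS("scratch/trials.rds")

for (modality in c("HbO2", "HHb", "HbT")) {
  t0 <- Sys.time()
  tab <- features_for_dataset(trials, modality)
  stopifnot(ncol(tab) == 1382)
  out <- sprintf("scratch/features_%s.tsv", tolower(modality))
  write.table(tab, out, sep = "\t", row.names = FALSE, quote = FALSE)
  message(modality, ": ", nrow(tab), " trials x ", ncol(tab) - 2,
          " features (", round(as.numeric(Sys.time() - t0, units = "secs")),
          " s) -> ", out)
}
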