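#!/usr/bin/env Rscript
# Predict the protein variant catalog produced by slippage edits at the run.
# Output: results/02_variants.tsv

suppressMessages(library(slipscan))
dir.create("results", showWarnings = FALSE)

gene <- design_gene()
pv <- predict_variants(gene$cds, gene$run, k_set = -2:3)
print(as.data.frame(pv))
cat(sprintf(
  "k=0 -> %d aa (%.0f kDa, truncated); k=+1 -> %d aa (%.0f kDa, restored)\n",
  pv$length_aa[pv$k == 0], pv$mw_kda[pv$k == 0],
  pv$length_aa[pv$k == 1], pv$mw_kda[pv$k == 1]))

write_tsv_report(pv, "results/02_variants.tsv",
                 params = list(k_set = -2:3), seed = gene$design$seed)
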