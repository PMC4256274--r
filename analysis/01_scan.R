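#!/usr/bin/env Rscript
# Scan the packaged sequences for slippery sites.
#
# Inputs: the 56-nt synthetic RNA control (the RT-PCR specificity control)
# and the default designed gene emulating the studied architecture.
# Output: results/01_sites.tsv, results/01_runs.tsv

suppressMessages(library(slipscan))
dir.create("results", showWarnings = FALSE)
seed <- 1L

rna <- cds("GCCGGCUAUUAUGAGGCGUUUAAAAAAAAAAAUGGGUCCGGGGCUGAUGCUGUUAG",
           id = "synthetic-56nt", source = "synthetic RNA control")
runs <- find_runs(rna, base = "A", min_length = 8)
cat(sprintf("56-nt control: %d nt, longest A-run %d nt\n",
            rna$length, max(runs$length)))

gene <- design_gene()  # 807-aa truncated ORF, 11-A run, 28-nt spacer
sites <- call_slippery_sites(gene$cds)
cat(sprintf("designed gene: run of %d As ends %d nt upstream of the stop at nt %d; restoring edits: %s\n",
            sites$run_length, sites$distance, sites$stop_start,
            paste(sites$restoring_edits[[1]], collapse = ",")))

write_tsv_report(runs, "results/01_runs.tsv",
                 params = list(min_run_length = 8), seed = seed)
write_tsv_report(sites, "results/01_sites.tsv",
                 params = list(config = "defaults"), seed = seed)
write_fasta(gene$cds, "results/01_designed_gene.fasta")
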