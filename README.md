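# slipscan

Analysis of transcriptional slippage (reiterative transcription) at poly-A
tracts in bacterial coding sequences.

Some bacterial genes look broken: the annotated ORF ends at a premature
in-frame stop codon, yet the full-length protein is still made. One rescue
mechanism is transcriptional slippage — within a homopolymeric run the RNA
polymerase realigns the nascent RNA on its DNA template and inserts (or
deletes) untemplated nucleotides, so a fraction of transcripts carry a net
+1 insertion that shifts translation into a downstream frame lacking the
stop. The T6SS membrane gene *tssM* of *Citrobacter rodentium* is the
motivating case: an 11-adenosine run ends 28 nt upstream of a premature
amber stop, and slippage produces both an 807-aa truncated and a 1,129-aa
full-length variant at a characteristic molar ratio.

`slipscan` implements the computational side of that analysis for anyone
studying recoding at homopolymer runs:

- **Scan** — maximal A/T homopolymer runs, premature in-frame stops, and
  candidate slippery sites whose restoring edits k (net inserted As) are
  determined by edit-and-translate (`find_runs`, `find_premature_stop`,
  `call_slippery_sites`, `screen_family`).
- **Predict** — the protein length/mass variant catalog produced by each
  edit k (`apply_slippage_edit`, `predict_variants`, `protein_mw`).
- **Masses** — average-mass ladders of RT-PCR amplicons differing by single
  A (sense) or T (antisense) residues, and assignment of measured ESI/MS
  neutral masses to A counts with percentage error (`build_ladder`,
  `assign_peaks`, `oligo_average_mass`).
- **Quantify** — frameshift frequency from western band intensities
  (f = I_slip / (I_long + I_short)) and from the three-construct GFP
  reporter scheme (f = (f_test − f_neg) / (f_max − f_neg)), with
  OD600/blank normalization (`western_frequency`, `gfp_frequency`,
  `relative_fluorescence`, `aggregate_estimates`).
- **Simulate** — designed slippery-site genes and a stochastic
  per-transcript slippage model with noisy western/reporter readouts, so
  every stage is testable end to end (`design_gene`,
  `simulate_transcription`, `simulate_western`, `simulate_reporters`).

## Worked example

```r
library(slipscan)

gene <- design_gene()                  # emulates the studied architecture
sites <- call_slippery_sites(gene$cds)
sites[, c("run_length", "stop_start", "distance")]
#>   run_length stop_start distance
#> 1         11       2422       28

predict_variants(gene$cds, gene$run, k_set = -1:1)
#>   k length_aa  mw_kda terminated full_length_restored
#>  -1       799  87.769       TRUE                FALSE
#>   0       807  88.605       TRUE                FALSE
#>   1      1129 123.898       TRUE                 TRUE

western_frequency(band_quant("wt", intensity_long = 1, intensity_short = 3,
                             slippage_product = "long"))
#> <frameshift_estimate> f = 0.2500 (western), other:slippage ratio 3.00:1
```

The scanner finds one candidate site: an 11-A run whose last base sits 28 nt
upstream of the premature stop codon beginning at nt 2,422. Unedited
transcripts (k = 0) give the 807-aa truncated product (~89 kDa); a single
untemplated A (k = +1) shifts translation into the open +1 frame and yields
the 1,129-aa full-length product (~124 kDa). A western lane in which the
long (slippage) band carries one third the intensity of the short band
estimates a frameshift frequency of 25%, i.e. a 3:1 short:long molar ratio.

The numbered scripts under `analysis/` run the whole workflow (scan →
variants → mass ladder → frequency estimates → parameter-recovery sweep) and
write their tables to `results/`.

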