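---
title: "Detecting and quantifying transcriptional slippage at poly-A tracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying transcriptional slippage at poly-A tracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slipscan)
```

## The problem and the model

Homopolymeric runs are slippery for RNA polymerase: the nascent RNA can
realign on its DNA template inside the run, so a fraction of transcripts
carry untemplated insertions (or deletions) of the run base. When a poly-A
run sits a short distance upstream of a premature in-frame stop codon, a net
+1 insertion shifts translation into a downstream frame that may lack the
stop, producing a full-length protein from a gene whose annotated ORF is
truncated. The result is a heterogeneous mRNA population (run sizes spread
around the genomic count) and two (or more) protein length variants whose
molar ratio reflects the slippage frequency.

`slipscan` treats this as four computational questions:

1. **Where could slippage rescue a gene?** A candidate *slippery site* is a
   maximal A/T run (length ≥ `min_run_length`) whose 3′ end lies within
   `max_distance` nt of the first premature frame-0 stop. For each candidate
   the *restoring edit set* is determined empirically: each k in `k_set` is
   applied to the transcript and the edit is restoring iff translation of
   the edited transcript extends past the premature stop codon. There is no
   heuristic frame arithmetic — restoration is always decided by
   edit-and-translate, which handles edits that create new stops.
2. **What proteins result?** `predict_variants()` translates each k-edited
   transcript from nt 1 to its first stop and reports length and average
   molecular mass.
3. **Can slippage be seen directly on the mRNA?** Amplicons spanning the run
   form a mass ladder spaced by one dA residue (sense strand) or one dT
   residue (antisense); measured ESI/MS neutral masses are assigned to the
   nearest ladder entry with a percentage error.
4. **How often does it happen?** Two estimators: the western estimator
   `f = I_slip / (I_long + I_short)` on band intensities, and the GFP
   reporter estimator `f = (f_test − f_neg) / (f_max − f_neg)` on
   normalized fluorescence of the three-construct scheme (negative control
   with the stop in frame; +1 reporter; frame-restored 100% reference).

## Conventions and parameters

**Coordinates** are 1-based and inclusive on the coding strand. A stop-codon
*position* is the position of its first nucleotide. With this convention a
truncated product of L aa has its stop at nt 3L + 1: an 807-aa product
implies a stop codon at nt 2,422–2,424 and a 2,424-nt ORF including the
stop. (Quoted stop positions in the literature are sometimes the last nt of
the final sense codon, here 2,421 = 807 × 3; the package stores the first nt
of the stop codon and documents the arithmetic so both readings reconcile.)

**Run-to-stop distance** is the count of nucleotides strictly between the
run's last base and the stop codon's first base. The characterised site —
run ending at nt 2,393, stop starting at nt 2,422 — has distance 28 under
this convention.

**Scanner defaults.** `min_run_length = 8` captures the two characterised
sites (9 and 11 As) with margin while excluding the ubiquitous short runs;
`max_distance = 60` doubles the one measured distance (28 nt) for recall;
`k_set = {−2, −1, +1, +2}` covers single and double slippage events in both
directions. All are `scan_config()` parameters. T-runs on the coding strand
are reported as potential template-strand slippage; no strand inference is
attempted.

**Edit placement.** Insertions inside a homopolymer are indistinguishable at
the sequence level, so edits are canonically applied at the run's 3′ end and
`edit_position` records the last original run base. Consequently k and −k
compose to the identity, and k and k + 3 differ by exactly one residue
(one in-frame AAA codon, a lysine) whenever neither edit creates a stop.

**Masses.** Protein masses use standard average amino-acid residue masses
plus one water, in kDa; average (not monoisotopic) masses match how
SDS-PAGE apparent sizes and deconvoluted ESI masses are quoted. Oligo
masses use average nucleotide-residue masses (dA 313.21, dC 289.18,
dG 329.21, dT 304.20 Da; the residue is the nucleoside monophosphate minus
water) plus one water for a 5′-hydroxyl terminus, plus one HPO3 (79.98 Da)
for a 5′-phosphate; neutral species are assumed (instrument software is
taken to have deconvoluted charge states). PCR products are modelled as two
independent single strands with 5′-hydroxyl ends, matching standard
unphosphorylated primers; both choices are arguments. The default peak
tolerance of 0.02% is deliberately loose relative to typical oligo ESI
accuracy and is configurable. Since primer sequences for the real amplicon
are not modelled, amplicon bounds are user-specified coordinates; the
analysis scripts use a 56-nt window bracketing the run, the layout of the
real RT-PCR product.

**Western estimator assumption.** Band intensity is taken proportional to
molecule count: both variants carry a single N-terminal epitope, so no
length correction is applied. The estimator is invariant under common
scaling of the two intensities, and the reported ratio is
other-product : slippage-product, consistent with `ratio = (1 − f) / f`.

**Fluorescence normalization.** Relative fluorescence is
`(raw_f − blank_f) / (od600 − blank_od)`: both the blank fluorescence and
blank absorbance are subtracted before division. The order of blank
subtraction is stated here because the operation is ambiguous in prose
descriptions; it is fixed, tested, and scale-invariant in the corrected
signal. Reporter noise can push `f_test` slightly below `f_neg`, so
out-of-range GFP estimates are clamped to [0, 1] with a warning rather than
erroring.

## The synthetic-data generator

`design_gene()` constructs genes with the studied architecture: an ORF of
`upstream_codons` codons, a poly-A run of `run_length` at a codon boundary,
a `spacer_nt` spacer, a premature amber (TAG) stop in frame 0, and
`plus1_orf_codons` codons readable in the +1 frame past that stop before a
designed +1-frame terminator. `run_length + spacer_nt` must be a multiple of
3 so the designed stop is in frame. The defaults (794 upstream codons, run
of 11, spacer 28, 321 +1-frame codons) are forced by the characterised
gene's printed anatomy: they yield exactly an 807-aa truncated product from
a 2,424-nt ORF, a 1,129-aa +1-restored product, and a run ending 28 nt
upstream of the stop. Construction is by bounded rejection sampling against
explicit invariants — first frame-0 stop at the designed position, no
unintended scannable A/T run, +1 frame open exactly to the designed
terminus — and is deterministic under the design seed. With
`plus1_orf_codons = 0` the +1 frame is closed by a designed stop inside the
spacer, giving verifiably non-restorable fixtures.

`simulate_transcription()` draws a single net edit k per transcript from a
`slippage_model()` over k ∈ {−1..+4} — a support spanning run sizes 10–15
around a native 11-A run. The default places 0.25 on k = +1 and the rest on
k = 0. Drawing one net k per transcript is a deliberate simplification of
per-step polymerase realignment: it reproduces a heterogeneous A-count
population and keeps the model identifiable, but it does not model the
kinetics of realignment, and the real per-k species distribution is an
input, never an estimate. `simulate_western()` applies multiplicative
lognormal noise (`exp(N(0, σ²))`, default σ = 0.05) to pooled
restored/non-restored counts; `simulate_reporters()` places the three
constructs at background, background + f·span, and background + span with
additive Gaussian noise per replicate (σ expressed as a fraction of the
span, default 0.05; background 100 A.U. and span 2,000 A.U. give a
reference ~20-fold over background, a qualitative not quantitative match to
real reporter magnitudes).

What the simulations do *not* emulate: RT-PCR/polymerase artifacts,
length-dependent transfer or detection efficiency on blots, reporter
maturation kinetics, and any coupling between slippage and growth
condition. Passing tests therefore validate the estimators and the
pipeline's internal consistency, not instrument-level realism.

## Numerical choices and degenerate inputs

- Translation stops at the first stop codon; a trailing partial codon is
  ignored; U is mapped to T for codon lookup (amino-acid assignments of the
  bacterial code, NCBI table 11, which coincide with the standard code).
- A stop in the final complete codon is a normal terminator:
  `find_premature_stop()` returns `NA` for it, and warns only when the frame
  contains no stop at all.
- Sites are ranked by distance ascending, then run length descending, making
  output order deterministic when several runs precede one stop.
- `screen_family()` refuses fewer than 3 members (a median of 2 is not a
  family reference); a member is abnormal-length below 0.8 × the family
  median.
- Oligo masses are reported to 0.01 Da; empty proteins mass 0 with a
  warning; both-bands-zero lanes and `f_max ≤ f_neg` reporter sets are
  errors (the estimate is undefined, not zero).
- Every stochastic function takes an explicit seed and restores the RNG
  state afterwards; identical seeds give byte-identical outputs, which the
  test suite checks on written files.

## Problem sizes used in validation

The test suite validates restoring-edit calls against an exhaustive
edit-and-translate oracle on 200 randomly designed small genes (5–25
upstream codons), and parameter recovery for p(+1) ∈ {0.05, 0.1, 0.2, 0.25,
0.5} at 10,000 transcripts per condition, checked within 3 binomial
standard errors with noiseless readouts (the binomial transcript sampling is
the stochastic element under test; noisy-readout recovery is exercised
separately at its own propagated tolerance). These sizes make the full
suite run in well under a minute while keeping the binomial tolerance
tight (±1.3 percentage points at p = 0.25).

## Known limitations

- The scanner considers a single premature stop per gene (the first); genes
  with several in-frame stops rescued by successive edits are out of scope.
- Restoration is defined against translation from nt 1 of the supplied CDS;
  internal starts and ribosome-level (translational) frameshifting signals
  such as Shine–Dalgarno-like elements or secondary structure are
  deliberately not modelled.
- Mass prediction covers clean single strands; adducts, salt clusters and
  isotopic fine structure are not modelled, so `assign_peaks()` expects
  deconvoluted neutral masses.
- The western estimator's no-length-correction assumption fails for
  C-terminal epitopes or strongly length-biased transfer; in that case
  intensities must be corrected before `band_quant()`.
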