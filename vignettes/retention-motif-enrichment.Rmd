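---
title: "Nuclear-retention ranking and accessibility-weighted motif enrichment"
author: "retmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear-retention ranking and accessibility-weighted motif enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retmotif)
```

## The biological question and the model

Innate-immune stimulation (e.g. LPS on macrophages) induces a burst of
inflammatory mRNAs that are transcribed in the nucleus and must be exported
to the cytoplasm for translation. When an export-promoting factor is knocked
out, affected transcripts accumulate in the nucleus. Given abundances
measured separately in nuclear (N) and cytoplasmic (C) fractions of
wild-type (WT) and knockout (KO) cells, the per-transcript quantities are

* retention ratio: \(R = N / C\), computed per genotype at a chosen
  stimulated timepoint;
* retention index: \(I = R_{KO} / R_{WT}\), the factor by which the
  knockout increases nuclear retention.

LPS-induced transcripts (whole-cell WT fold change from baseline at least a
threshold) are ranked by decreasing \(I\). The top transcripts form the
*positive set* (export depends on the factor); induced transcripts with
\(I\) near 1 form the *negative set* (distribution unaffected). The
enrichment question is then: does a candidate RNA-binding-protein motif
discriminate positive from negative 3'UTRs beyond what sequence composition
alone explains?

## Tunable parameters and their defaults

| parameter | default | meaning |
|---|---|---|
| `fc_threshold` | 2 | whole-cell WT fold change calling a transcript induced (linear scale) |
| `eps` | 1.0 | pseudocount added to N and C (relative-abundance units) before ratios; stabilizes weakly expressed transcripts and makes \(R = 1\) when both compartments are empty |
| `positive_size` | 70 | size of the positive set (clamped with a warning when fewer transcripts are induced) |
| `negative_threshold` | 1.1 | maximum index for membership in the negative set |
| `lps_timepoint` | last label | single stimulated timepoint used for \(R\) and \(I\) |
| replicate summary | arithmetic mean | linear-scale mean over replicates (geometric mean available) |
| `folds` | 5 | cross-validation folds for the penalty selection |

The data provide no intrinsic criterion for the induction threshold or the
negative-set ceiling, so both are configuration, not constants: 2-fold is
the conventional induction call, and \(I \le 1.1\) operationalizes
"distribution not affected" while leaving a buffer zone (1.1 < I below the
positive cut) that belongs to neither set. Where several stimulated
timepoints exist, a single user-selected one is used rather than averaging
across times; averaging ratios across timepoints with different induction
kinetics would mix different export regimes. Ranking ties are broken by
transcript id so the partition is reproducible.

## Motif scoring with accessibility weighting

Motifs are IUPAC patterns over RNA (e.g. the SRSF1 site `KGRWGSM`;
K = G/U, R = G/A, W = A/U, S = G/C, M = A/C — 32 concrete heptamers). A
*site* is a perfect match of the pattern in the regulatory region
(overlapping sites all count; an `N` in the sequence matches no pattern
position). The region score is

\[ \mathrm{score} = \sum_{\text{sites}} \overline{p_{\text{unpaired}}} \]

the sum over sites of the mean single-base unpaired probability of the
site's bases; a region with no site scores 0. Accessibility comes from
per-transcript tracks produced by an external local-folding tool and read
through a file interface (the `_lunp` dialect: `#` comments, then
whitespace-separated `position value` rows, 1-based positions, u = 1
column). Folding is deliberately not performed in-package; a typical recipe
for generating tracks is

```sh
RNAplfold -W 200 -L 150 -u 1 < transcript.fa   # one _lunp file per transcript
```

run on the *whole* transcript (not the excised region) so bases near the
start and stop codons fold in their true context. When no tracks are
supplied, a uniform provider assigns probability 1 to every base, and the
region score reduces exactly to the raw hit count. Missing track positions
are dropped from a site's mean; a site with no present value contributes 0.
These missing-data rules are package choices for robustness at sequence
ends, not properties of the data.

One isoform per gene — the longest mature mRNA, ties to the smaller
transcript id — defines the sequence; coordinates are 0-based half-open
throughout.

## The enrichment regression and nested test

For one motif, the feature table over positive ∪ negative transcripts
contains: the motif score; one column per *control dinucleotide* — every
dinucleotide contained in the motif's expansion (10 of them for `KGRWGSM`),
counted with overlaps in the region; and the region length. Controls are
plain counts by default (a frequency option divides by length): counts are
the most direct reading of "composition the motif could be confounded
with", and length is included separately so the count columns need not
carry it.

Features are standardized to zero mean and unit variance, then labels are
fit by L1-penalized logistic regression over the standard 100-value
geometric penalty path (down to `lambda_max * 1e-4`, or `* 0.01` when there
are fewer rows than columns). The penalty is selected by 5-fold
cross-validation — folds stratified by label and drawn from the supplied
seed, generalization error the mean held-out binomial deviance — with ties
resolved toward the stronger penalty. Features with non-zero coefficients
at the selected penalty (|w| > 1e-9 on the standardized scale) are the
selected set.

If the motif score is not selected, the motif is reported as not enriched
with p = 1. Otherwise two *unpenalized* logistic models are fit on the raw
features — full (all selected features) and reduced (selected controls
only, intercept always present) — and compared by

\[ \Lambda = 2(\ell_{\text{full}} - \ell_{\text{reduced}}) \sim \chi^2_1 . \]

The degrees of freedom are fixed at 1 because a motif contributes exactly
one score column. Across a motif collection each motif is tested
independently with its own controls; raw p-values are primary and
Benjamini–Hochberg q-values are reported alongside.

Two caveats are inherent to the procedure and documented rather than
"fixed". First, the test is *post-selection*: the same data choose the
features and evaluate the motif, so null p-values need not be uniform. The
test suite measures the empirical fraction of p < 0.05 on label-permuted
data (printed when the suite runs; 0.02 in the 50-permutation check, well
inside the 0.25 sanity bound — selection usually removes the motif under
the null, making the observed behaviour conservative, but this is an
empirical observation, not a guarantee). Second, strongly planted signals
separate the classes perfectly; the unpenalized refit is then run to its
iteration cap, flagged (`separation`), and the p-value marked as an upper
bound — the statistic is finite only because iteration stops, but the
qualitative conclusion (reject) is unaffected.

## RIP-qPCR quantification

Validation by RNA immunoprecipitation is quantified exactly by the
ΔΔCt arithmetic, base 2 throughout:

\[ \Delta Ct = Ct_{\text{RIP}} - \bigl(Ct_{\text{input}} -
   \log_2(\text{fraction of input saved})\bigr), \quad
   \Delta\Delta Ct = \Delta Ct_{\text{RIP}} - \Delta Ct_{\text{NS}}, \quad
   \text{fold} = 2^{-\Delta\Delta Ct} . \]

Replicate Cts (comma-separated in the input TSV) are averaged before
normalization. Shared input Ct and saved fraction cancel in ΔΔCt, which the
tests verify as an exact identity. No amplification-efficiency correction
is applied.

## What the synthetic generator does and does not emulate

The generator exists so every stage can be checked against planted truth:

* **Sequences**: i.i.d. uniform-composition transcripts (fixed 50-nt 5'UTR,
  300-nt CDS, 3'UTRs normal around 300 nt), with a configurable number of
  non-overlapping motif k-mers (default 4) written into positive 3'UTRs and
  a low background planting rate (default 0.2 sites/kb) everywhere.
* **Expression**: log-normal baseline (median 100 relative units, sdlog 1);
  stimulation multiplies induced transcripts (40% of the transcriptome by
  default) by 8; every transcript splits 30:70 nuclear:cytoplasmic — an
  arbitrary but exposed baseline, since only ratios of ratios matter — and
  planted targets under KO + stimulation have their nuclear share rescaled
  so the noiseless index equals the retention multiplier (default 3);
  replicate noise is multiplicative log-normal (sd 0.3 on log2).
* **RIP tables**: Cts constructed to invert to a known enrichment exactly,
  plus Gaussian Ct noise (sd 0.2).

All generators are pure functions of (parameters, seed) and leave the
caller's RNG stream untouched. Real data differ in ways the generator does
not attempt to copy: non-uniform base composition (so chance motif-match
rates differ), correlated probe-level noise, isoform mixtures, partial
fractionation purity, and RNA structure (uniform accessibility is the test
default). Passing tests therefore demonstrate correctness of the
computations and recoverability of planted effects, not biological
performance on microarray data.

## Numerical and degenerate-input conventions

* Pseudocount `eps = 1` enters both numerator and denominator of every
  abundance ratio; with `eps = 0` on strictly positive data, \(I\) is
  exactly invariant to rescaling all samples of one genotype.
* Empty regions (e.g. a transcript with no annotated 3'UTR) stay in the
  feature table with all-zero features and trigger a warning; transcripts
  missing annotation are skipped at load time with a warning.
* A feature table whose columns are all constant yields an empty selection
  (and hence p = 1) without attempting a penalized fit.
* Unparseable sequence characters become `N` (match nothing) rather than
  errors; out-of-range track probabilities and positions are errors.
* Logistic refits run up to 100 iterations (1000 with a relaxed tolerance
  as fallback); a reduced model that still fails to converge is an error,
  not a silent result.

## Problem sizes used by the test suite

The validation suite runs the scanner-vs-oracle comparison on 1,000 random
(sequence, motif) pairs, the planted-enrichment benchmark at 70 + 200
transcripts with ~300-nt 3'UTRs, retention recovery at 500 transcripts over
5 seeds, the permutation null at 50 relabelings of the benchmark table, and
RIP recovery at 100 targets — sizes chosen so each documented tolerance is
informative while the full suite stays quick to run on a laptop.

## Known limitations

* The negative set is defined by a threshold on \(I\), not by a formal
  test of "no change"; transcripts with noisy small indices can enter it.
* One motif = one score column; a catalogue motif with several variants
  would need one test per variant (df stays 1 each) or an extension.
* The LRT p-value is post-selection (see above) and, under separation, an
  upper bound.
* Only u = 1 (single-base) accessibility is supported; wider unpaired
  windows are out of scope.
* No probe-level microarray processing: the pipeline starts from a
  normalized linear-scale abundance matrix.
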