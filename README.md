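# retmotif

Tools for asking two linked questions about compartment-resolved
transcriptomes of stimulated wild-type (WT) and knockout (KO) cells:

1. **Which induced mRNAs does the knockout trap in the nucleus?**
   For each transcript the nuclear-retention ratio is `R = N / C` (nuclear
   over cytoplasmic abundance) and the impact of the knockout is the
   retention index

   `I = R_KO / R_WT`

   `I > 1` means loss of the factor shifts the transcript toward the
   nucleus. Induced transcripts (whole-cell fold change ≥ 2 by default) are
   ranked by `I`; the top 70 form the *positive* set, induced transcripts
   with `I ≤ 1.1` form the *negative* set.

2. **Does an RNA-binding-protein motif mark the retained transcripts?**
   Each 3'UTR (or 5'UTR/CDS) is scored for an IUPAC motif by summing, over
   all perfect matches, the site accessibility — the mean single-base
   unpaired probability of the site (uniform when no structure tracks are
   supplied; regions without a match score 0). The motif score competes
   against control features (counts of every dinucleotide contained in the
   motif, plus region length) in a Lasso-penalized logistic regression of
   positive vs negative labels, with the penalty chosen by 5-fold
   cross-validation. If the motif score survives selection, two unpenalized
   nested logistic models (with and without it) are compared by a
   likelihood-ratio test: `LRT = 2(ℓ_full − ℓ_reduced) ~ χ²(df = 1)`.

A ΔΔCt module quantifies RIP-qPCR validation experiments
(`ΔCt = Ct_RIP − (Ct_input − log2(fraction saved))`,
`fold enrichment = 2^(−ΔΔCt)`), and a synthetic-data generator plants known
retention multipliers, motif sites and enrichments so the whole pipeline is
testable end to end.

## Worked example

```r
library(retmotif)

# synthetic compartment-resolved expression: 500 transcripts, 200 induced,
# 70 with a planted retention multiplier of 3 in the KO
g    <- generate_expression(500, seed = 1)
rt   <- retention_table(g$matrix)
part <- rank_and_partition(rt)
head(rt[order(rt$rank), c("transcript_id", "R_WT", "R_KO", "I", "rank")], 3)
#>    transcript_id   R_WT  R_KO     I rank
#> 63         T0063 0.4033 1.823 4.519    1
#> 31         T0031 0.4040 1.821 4.507    2
#> 8          T0008 0.3450 1.552 4.497    3
length(part$positive_ids)   # 70
```

The top-ranked transcripts are planted targets: their KO retention ratio is
roughly three times the WT one. Testing the SRSF1 site `KGRWGSM`
(K = G/U, R = G/A, W = A/U, S = G/C, M = A/C) on sequences with planted
3'UTR sites:

```r
motif <- iupac_motif("SRSF1_1", "SRSF1", "KGRWGSM")
pos   <- sprintf("T%04d", 1:70)
tx    <- generate_transcripts(270, motif = motif, positive_ids = pos, seed = 1)
partn <- structure(list(positive_ids = pos,
                        negative_ids = sprintf("T%04d", 71:270),
                        parameters = list()), class = "gene_set_partition")
res <- test_motif_enrichment(partn, tx$records, motif, seed = 1)
res$lrt_statistic   # 277.12
res$p_value         # 3.19e-62  (chi-square, df = 1)
```

The motif score is selected by the Lasso and the nested test rejects
decisively — four planted sites per positive 3'UTR against ~0.6 chance
matches per background 3'UTR is an overwhelming signal. RIP-qPCR
quantification follows the printed ΔΔCt arithmetic exactly:

```r
rip <- generate_rip_table(c("Cxcl1", "Tnf"), c(12, 6), ct_noise_sd = 0, seed = 1)
rip_analysis(rip$table)
#>   target_id dct_rip dct_ns   ddct fold_enrichment
#> 1     Cxcl1   4.415      8 -3.585              12
#> 2       Tnf   5.415      8 -2.585               6
```

`run_pipeline()` (or the `inst/cli/retmotif.R` script's `run-all`
subcommand) chains every stage from FASTA + expression TSVs to retention,
partition and enrichment reports plus a reproducibility manifest.

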