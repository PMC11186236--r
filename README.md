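# omicsMR

Multi-omics Mendelian randomization for drug-target prioritization.

## What it does, and for whom

Genetic epidemiologists screening circulating proteins as candidate drug
targets for a disease need more than one line of causal evidence: a
protein-level effect, transcript-level corroboration, and proof that the
protein and disease signals share a causal variant rather than sitting on
linked ones. omicsMR implements that whole evidence chain for GWAS
summary statistics — no individual-level data required — together with a
seeded simulator of regional summary statistics so every stage can be
exercised and validated offline. The motivating application is chronic
kidney disease screened against plasma-proteome GWAS panels, but the
machinery is disease-agnostic.

The stages, each exposed as a documented function over S4 containers:

| Stage | Function(s) | Core statistic |
|---|---|---|
| Input & harmonization | `readSumStats`, `harmonize`, `cisWindow` | allele alignment incl. frequency-resolved palindromes |
| Instruments | `selectInstruments`, `clumpVariants`, `fStatistic`, `steigerFilter` | F = (β/se)², Steiger r² = t²/(t²+n−2) |
| Two-sample MR | `waldRatio`, `mrIVW`, `mrEgger`, `runProteinMR` | β̂ = Σwβx βy / Σwβx², Cochran's Q, Egger intercept |
| Transcript MR | `topEqtl`, `smrTest`, `heidiTest`, `runGeneSMR` | T_SMR = z₁²z₂²/(z₁²+z₂²); HEIDI weighted-χ² tail by Imhof inversion |
| Colocalization | `labf`, `colocalize` | Wakefield lABF = ½(log(1−r)+rz²); PPH0–PPH4 |
| Synthesis | `bhFDR`, `fixedEffectMeta`, `countReplications`, `assignTier` | BH q-values; tiers 1/2/3 |
| Simulation | `simScenario`, `simulateRegion`, `simulatePanel` | b̂ ~ MVN(Rβ, R/n_eff) under AR(1) LD |
| Orchestration | `runPanelAnalysis`, `runPipeline`, `exportPanel` | config-driven, byte-reproducible |

Evidence tiers follow the triangulation grading: tier 1 = significant MR
(FDR q < 0.05 in ≥ 1 protein source) plus passing SMR/HEIDI plus
colocalization; tier 2 = MR plus exactly one of the two; tier 3 = MR only.

## Worked example

Simulate a 4-protein discovery panel in which one locus carries a true
mediated effect (variant → expression → protein → outcome, θ = 0.2
log-odds per SD protein) and three are null, then run the full pipeline:

```r
library(omicsMR)
pan <- simulatePanel(k = 4, mix = c(null = 0.75, mediated = 0.25), seed = 3)
res <- runPanelAnalysis(pan)
res$evidence[, c("protein_id", "tier", "n_sig_sources", "passed_smr",
                 "passed_coloc", "replication_count", "combined_or")]
#>   protein_id tier n_sig_sources passed_smr passed_coloc replication_count combined_or
#> 1  protein_4    1             3       TRUE         TRUE                17      1.2117
#> 2  protein_2 none             0      FALSE        FALSE                 6      0.9947
#> 3  protein_3 none             0      FALSE        FALSE                 5      0.9968
#> 4  protein_1 none             0      FALSE        FALSE                 2      1.0016
```

`protein_4` is the planted mediated locus (`pan$truth`): it is significant
in all three pseudo-sources, passes SMR/HEIDI and colocalization — hence
tier 1 — replicates in all 17 panel outcomes, and its combined odds ratio
1.21 per SD matches exp(0.2) = 1.22 up to sampling noise. The null loci
stay untiered with odds ratios at 1. (Their nonzero replication counts
illustrate a documented caveat: unclumped correlated instruments make the
per-outcome p-values anti-conservative; tiering is protected by the
SMR and colocalization gates.)

The same panel can be written to disk (`exportPanel(pan, "panel_dir")`)
and rerun file-driven:

```r
runPipeline("panel_dir/run.yaml", "pipeline_out")
```

which validates every referenced path, writes per-stage TSVs
(`mr_per_source.tsv`, `smr.tsv`, `coloc.tsv`, `replication.tsv`,
`evidence.tsv`), a provenance record and a run log, and reproduces
`evidence.tsv` byte-identically on rerun.

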