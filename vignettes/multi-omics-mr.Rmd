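---
title: "Triangulating drug targets with multi-omics Mendelian randomization"
author: "omicsMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating drug targets with multi-omics Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsMR)
```

## The problem

Circulating proteins are attractive drug targets, but observational
protein-disease associations are confounded. Two-sample Mendelian
randomization (MR) instruments each protein with its cis-acting protein
quantitative trait loci (cis-pQTLs): because alleles are randomized at
conception, a variant that raises the protein and also raises disease risk
supports a causal protein effect, provided the variant acts on the disease
only through the protein. omicsMR implements the full evidence chain of
such a discovery design for a binary disease outcome (the motivating
application is chronic kidney disease, with kidney-function and clinical
replication outcomes): instrument selection, two-sample MR across several
independent pQTL sources, transcript-level corroboration by summary-data
MR (SMR) with the HEIDI linkage test, Bayesian colocalization, fixed-effect
meta-analysis, FDR gating, replication counting, and a three-tier evidence
grade. A seeded simulator of regional GWAS summary statistics under LD
makes every stage testable without any external download.

## Models and estimators

**Instruments.** cis-pQTLs are variants within 1 Mb of the gene encoding
the protein (both window boundaries inclusive; distance measured from the
gene body, not the TSS) passing the source's own significance threshold —
1.8e-9, 1.004e-11 and 1.7e-11 for the three emulated plasma-proteome
sources. The principal analysis keeps all such variants; LD clumping
(greedy, lowest p first, removing neighbours within 10,000 kb at
r² > 0.01) and sentinel-only selection are sensitivity switches, mirroring
the design this package operationalizes. Instrument strength is the
approximate per-variant F-statistic `(beta/se)^2` with F ≤ 10 flagged
weak. The Steiger filter removes variants whose pseudo-variance-explained
`t²/(t²+n−2)` is not strictly larger on the exposure side than on the
outcome side; the same approximation is used for binary traits (with their
total sample size), a documented simplification, and ties are dropped as
the conservative choice.

**Two-sample estimators.** With harmonized per-variant effects `(bx, by)`
and outcome standard errors `sy`:

* Wald ratio (single instrument): `by/bx`, first-order delta SE
  `sy/|bx|`; a flag enables the second-order SE adding
  `by²·sx²/bx⁴` under the root. The second-order form tracks the
  Monte-Carlo SD of the ratio to about 2% when the denominator CV is 10%
  and tightens as instruments strengthen.
* Fixed-effect IVW: `sum(w·bx·by)/sum(w·bx²)` with `w = 1/sy²`,
  SE `1/sqrt(sum(w·bx²))` — the weighted regression through the origin.
  Cochran's Q with k−1 df quantifies ratio heterogeneity; it is always
  reported and never used to drop instruments, matching the reporting
  convention of the design.
* MR-Egger: weighted regression with free intercept after orienting all
  exposure effects nonnegative; slope and intercept are tested against a t
  reference with k−2 df (small-k honesty); an intercept p < 0.05 flags
  directional pleiotropy. Fixed-effect (rather than multiplicative
  random-effects) weighting is used throughout and recorded in metadata.

A caveat the tests make explicit: with all cis-pQTLs of an LD-dense locus
used unclumped, IVW standard errors ignore instrument correlation and the
per-source test is anti-conservative. Calibration claims are therefore
made (and verified) on loci with independent instruments; the unclumped
principal analysis inherits its robustness from the downstream gates
(SMR/HEIDI, colocalization) exactly as in the emulated design.

**SMR and HEIDI.** The transcript-level test instruments expression with
the single top cis-eQTL (p < 5e-8): `b_smr = b_zy/b_zx` and
`T_smr = z_zx²·z_zy²/(z_zx²+z_zy²)` referred to chi-square(1). HEIDI asks
whether neighbouring SNPs tell the same story: candidates with eQTL
p < 1.57e-3 and r² to the top SNP in [0.05, 0.9] (at most 20 SNPs, at
least 3 including the top) contribute deviations
`d_i = b_xy(i) − b_xy(top)` whose covariance follows by first-order delta
propagation with within-cohort LD-induced covariances
(`cov(b_zy(i), b_zy(j)) ≈ r_ij·se_i·se_j`; the eQTL and outcome cohorts
are independent, so no cross terms). The statistic `sum(z_d²)` is referred
to a weighted sum of chi-square(1) with weights equal to the eigenvalues
of the z_d correlation matrix. The tail probability is computed by Imhof's
numerical inversion of the characteristic function, evaluated on a
segmented Simpson grid (a dense head segment resolving the integrand's
features near the origin, and a tail segment gridded to the oscillation
period, truncated where the half-oscillation envelope falls below 1e-10).
A two-moment Satterthwaite scaled chi-square is retained as the deep-tail
(p < 1e-9) shortcut and as a fallback; it was rejected as the primary
method because its mid-distribution error reaches several percent on
realistic eigenvalue spectra, far beyond the 0.005 absolute agreement with
an independent inversion oracle that this package's tests demand. A HEIDI
p below 0.01 is called linkage and the gene does not pass SMR. Because a
per-dataset SMR significance convention is genuinely ambiguous (raw 0.05
versus Bonferroni across tested genes), both flags are emitted;
tier assignment uses the raw flag.

**Colocalization.** Per variant, Wakefield-style log approximate Bayes
factors `0.5·(log(1−r) + r·z²)` with `r = w²/(w²+se²)` and prior effect
SDs w = 0.15 (quantitative) / 0.2 (case-control); per-hypothesis masses
with priors p1 = p2 = 1e-4, p12 = 1e-5 over H0 (no association), H1/H2
(one trait), H3 (distinct variants), H4 (shared variant). All mass
arithmetic is in log space with log-sum-exp; the H3 mass is accumulated
over explicit ordered pairs i ≠ j, never by subtracting nearly equal
sums, and the stabilized form is test-checked against a naive double loop.
PPH4 > 0.8 is called colocalized, PPH4 > 0.5 moderate; tiering counts
moderate colocalization as passed (the emulated design graded moderately
colocalized proteins as passing), while both levels are retained in the
output. With fewer than two shared variants H3 is undefined and posteriors
are renormalized over the remaining hypotheses with a status note. Either
trait order gives the same posteriors up to prior labels.

**Evidence synthesis.** Benjamini-Hochberg q-values are computed within
each protein source separately (the emulated design corrected per-source
panels); q < 0.05 in at least one source makes a protein MR-significant.
When additionally at least two sources provide estimates, they are
combined by fixed-effect inverse-variance meta-analysis; otherwise the
best single-source estimate is reported. BH was chosen over the empirical
FDR tool used in the original design for determinism; the design's own
calibration (q < 0.05 roughly matching p < 5e-4) serves as a sanity
cross-check. Replication over a 17-outcome panel (3 further disease GWAS,
4 kidney-function outcomes, 4 filtration-slope strata, 6 clinical types)
counts outcomes with p < 0.05 whose effect, mapped through the outcome's
declared polarity (−1 where a negative beta means increased risk, e.g.
filtration rate and its slope), agrees in sign with the principal
estimate. Tiers: 1 = MR + SMR + colocalization; 2 = MR plus exactly one;
3 = MR only; no MR significance, no tier.

## The synthetic-data generator

Summary statistics are simulated at the summary level (RSS-style): for a
locus of m = 200 variants with AR(1) LD `R_ij = rho^|i−j|`, rho = 0.9, the
marginal effect vector is `b = R·beta_joint` and the sampled estimate is
`MVN(b, R/n_eff)` on the standardized scale, se = `1/sqrt(n_eff)`; binary
outcomes use the effective sample size `4/(1/ncase+1/nctrl)` on the
log-odds scale (an approximation, stated as such). Defaults encode the
emulated study: protein GWAS n = 35,000 (the three pseudo-sources redraw
the locus at 35,359 / 10,708 / 54,219 with their own thresholds), blood
eQTL n = 31,000, outcome 41,395 cases / 439,303 controls, protein-outcome
effect theta = 0.2 log-odds per SD, variant effects a = e = 0.3 SD per
allele, direct variant-outcome effect c = 0.15. Architectures: `null`
(instruments but theta = 0), `causal`/`mediated` (shared causal variant),
`linkage` (outcome signal at a second variant, by default 3 positions away,
r² ≈ 0.53), `pleiotropy` (extra direct effect at the causal variant), and
`reverse` (the variant drives the outcome with effect a and the protein
responds with theta·a). Alleles are A/C with 15% palindromic A/T variants
and EAF ~ U(0.05, 0.5), so harmonization — including frequency-based
resolution of palindromes outside the ambiguous 0.42–0.58 band — is
genuinely exercised. All randomness derives from one integer seed with
fixed per-table offsets, so identical scenarios are byte-identical and
partial re-runs reproduce.

What the generator does *not* emulate: realistic allele-frequency spectra,
effect-size/frequency coupling, sample overlap between cohorts,
imputation noise, or multi-signal loci. Passing tests therefore certify
the estimators and the pipeline logic under the stated generative model,
not robustness to those real-data complications.

## Numerical and design choices

* Coordinates are 1-based inclusive; BED input is converted on read when
  declared 0-based half-open.
* Missing p-values are reconstructed from beta/se via the normal tail;
  supplied p-values disagreeing with |beta/se| by more than two orders of
  magnitude warn but are never dropped (many sources round p).
* Indels and multi-allelic records are dropped with a distinct reason
  code; tables keep a per-reason drop log in their metadata.
* The palindrome ambiguity band (0.42–0.58) is a convention knob, exposed
  in `harmonize()` and `pipelineSettings()`, since the original design is
  silent on palindromic handling.
* Ties: clumping breaks p ties by (chrom, pos); the top eQTL breaks p
  ties by larger |z| then position; Steiger ties drop the variant.
* MR p-values are floored at the smallest positive double rather than
  printed as 0.
* Colocalization uses the beta/SE parameterization only — one code path,
  exactly comparable to the quadrature oracle.
* Pipeline configs are declarative YAML; stage outputs are plain TSV
  written before the next stage consumes them, and a rerun on unchanged
  inputs reproduces `evidence.tsv` byte-identically.

## Problem sizes used by the test suite

Oracle comparisons run on 100 random instrument sets; calibration uses
1,000 replicates per test (10 independent instruments for IVW/Egger, the
default 200-variant locus for HEIDI); recovery 500 replicates at 5
instruments; colocalization discrimination 200 replicates per
architecture; Steiger removal 500 reverse-scenario replicates; end-to-end
tier recovery 100 panels of 10 loci each for the mediated-locus and
all-null designs (tier recovery panels omit the replication outcomes,
which do not enter tier assignment; the full 17-outcome panel is exercised
in the pipeline tests and the acceptance script's final pass). These sizes
keep the whole suite within a few minutes while leaving Monte-Carlo error
well inside the asserted bounds.

## A worked run

```{r example, eval = FALSE}
pan <- simulatePanel(k = 4, mix = c(null = 0.75, mediated = 0.25), seed = 3)
res <- runPanelAnalysis(pan)
res$evidence[, c("protein_id", "tier", "n_sig_sources",
                 "passed_smr", "passed_coloc", "replication_count")]
```

The mediated locus reaches tier 1 with a full replication count; the null
loci stay untiered. The same panel can be written to disk with
`exportPanel()` and rerun file-driven via `runPipeline()`, which
reproduces the in-memory result byte-identically.

## Limitations

Beyond the generator's simplifications listed above: no multivariable or
median/mode MR estimators (out of scope by design), no LD estimation from
genotype panels (LD is always supplied), no proxy-variant lookup, no
liftover or strand inference from a reference genome, and single-signal
colocalization only. The per-source IVW with unclumped correlated
instruments is anti-conservative, as noted; users wanting calibrated
per-source inference should enable clumping.
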