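---
title: "Prioritizing disease genes from cis-eQTL instruments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing disease genes from cis-eQTL instruments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A variant that regulates a gene's expression in a disease-relevant cell
type (a cis-eQTL) can serve as an instrument for asking whether that
gene's expression causally influences disease risk. Two failure modes
dominate in practice. First, *confounding by LD*: the instrumental
variant may merely be correlated with a distinct causal variant, so a
significant Mendelian-randomization (MR) estimate is not causal
evidence by itself. Second, *masking*: a strong disease signal
independent of the eQTL can hide a genuine shared signal from standard
colocalization, which assumes a single causal variant per region.

`cismr` implements the full summary-statistics workflow that addresses
both: cis-eQTL instrument selection, Wald/IVW MR, Wakefield
approximate-Bayes-factor colocalization, approximate conditional
analysis from marginal statistics plus a reference LD panel
(COJO-style), pairwise conditional colocalization (PWCoCo), regional
pleiotropy and novelty assessment, phenome-wide colocalization scans,
and a fixed-effect meta-analysis replication arm — together with a
synthetic-data generator that plants known causal structure so every
stage can be validated against ground truth.

# The procedure

## Instruments

Per gene and eQTL dataset: variants within ±1 Mb of the TSS with
p < 5×10⁻⁸, outside the MHC (chr6:25,726,063–33,400,644), greedily
LD-clumped at r² < 0.1 (smallest p first; ties broken by position then
alleles, so clumping is order-invariant), harmonized to the outcome on
(chrom, pos) with allele reconciliation — palindromic A/T and C/G
variants are dropped rather than frequency-resolved — then screened at
F = (β/se)² > 10 and a Steiger directionality test at p < 0.05.
The Steiger test compares variance explained r² = z²/(z² + n) between
exposure and outcome (effective n = 4/(1/n_case + 1/n_control) for
binary outcomes) via Fisher-z transformed |correlations| with variances
1/(n−3); ties resolve against the exposure→outcome direction. Analysis
is restricted to protein-coding genes.

## MR

Single-variant instruments use the Wald ratio β = β_out/β_exp with the
first-order delta SE, se_out/|β_exp|; multi-variant instruments use
fixed-effect inverse-variance weighting of the variant-level ratios,
with Cochran's Q and I² = max(0, (Q−(k−1))/Q) reported but heterogeneous
variants never removed. All p-values are two-sided normal. Significance
is Bonferroni-corrected per dataset for the number of genes tested in
that dataset. The first-order SE ignores exposure uncertainty; it is
faithful only when the instrument's z-statistic is much larger than the
outcome's (see *Parameter-recovery study design* below). Correlation
between clumped variants (r² up to 0.1) is ignored in IVW weighting, a
documented approximation.

## Colocalization

Per variant, the Wakefield log approximate Bayes factor is
labf = ½(log(1−r) + z²r) with r = W/(se² + W), prior effect variance
W = 0.15² for quantitative traits and 0.2² (log-odds) for case-control
traits. With per-SNP priors p1 = p2 = 1×10⁻⁴ and p12 = 5×10⁻⁵, the five
posterior probabilities are computed in log space; the H3 term
log(exp(S1+S2) − exp(S12)) uses `log1p` for stability and is set to
−∞ for single-variant regions. `coloc_abf()` is exactly equivalent to
brute-force enumeration over all per-SNP configuration pairs (tested to
1e-9 on 500 random regions).

## Conditional analysis

With D_j = 2f_j(1−f_j)n_j and B_jk = r_jk√(D_jD_k) from panel LD, joint
estimates solve B·β_J = D·β. The implied phenotypic sum of squares is
taken per variant as y'y_j = D_j(se_j²(n_j−2) + β_j²) (median across the
model's variants), which makes a single-variant joint model reproduce
its marginal β and se exactly; residual df is n−k−1. Conditional
statistics for variant j given model C use the block-inverse form, with
the conditional SE built from the variant's own marginal residual
variance (se_j²D_j/denom_j): this deliberately ignores the variance
*explained* by the conditioning signals — second-order for GWAS-scale
effects — and in exchange makes conditioning on an orthogonal variant an
exact no-op. Stepwise selection seeds with the smallest marginal p below
5×10⁻⁸, alternates forward addition of the smallest conditional p with
backward elimination of joint p above the cutoff, skips candidates with
reference r² ≥ 0.9 against the model, and caps the model at 10 signals.
Variants whose reported allele frequency disagrees with the panel by
more than 0.2 are excluded from conditional analysis with a message.

## PWCoCo

Marginal colocalization first (±500 kb around the top instrument). If
PPH4 < 0.8, signals are selected per trait; each trait contributes its
marginal track plus, for k ≥ 2 signals, one track per signal obtained by
conditioning on the other k−1. Colocalization runs for every track
combination and the maximum-PPH4 entry decides, at threshold 0.8 with
0.7 and 0.9 reported as alternates. The within-PWCoCo selection cutoff
is 5×10⁻⁸, matching instrument-level stringency; it is configurable.

## Prioritization and replication

Passing results (MR-significant and colocalized) are grouped by
single-linkage chaining of instrument positions at ±250 kb; regions
with ≥2 unique passing genes are flagged as horizontal pleiotropy. A
gene is novel iff every instrument is both > 250 kb from *and* r² < 0.2
with every known disease variant (the strict AND reading) and the gene
is not on a caller-supplied exclusion list from earlier MR studies.
Prioritized = passing ∧ lone-in-region ∧ novel, with ledgers computed
independently per PPH4 threshold; passing sets are nested across
thresholds by construction. Direction concordance across passing
datasets is reported (discordance does not veto prioritization).
PheWAS scans query the smallest-exposure-p instrument against each
phenotype, run PWCoCo only below p < 5×10⁻⁵, and pass iff both that
threshold and PPH4 ≥ 0.8 hold. Replication re-selects instruments from
a separate eQTL source, meta-analyzes two outcome GWAS by
inverse-variance fixed effect (METAL's effect-size scheme), and reports
sign concordance at the p < 0.1 reporting threshold.

# The synthetic-data generator

`simulate_panel()` draws two haplotypes per individual from a latent
Gaussian thresholded at MAF-matched quantiles; within a block the
latent process is AR(1) with parameter ρ (default 0.97), across blocks
independent. Thresholding attenuates correlation, so dosage LD runs
below the latent ρ; at ρ = 0.97 adjacent common variants reach
r² ≈ 0.7, the regime needed to study confounding by LD, and at ρ = 0.9
the attainable maximum is only ≈ 0.5. `simulate_eqtl_sumstats()` draws
an independent cohort from the same population and computes per-variant
marginal regressions of an expression trait whose causal variants
jointly explain `eqtl_h2`. `simulate_gwas_sumstats()` uses the
summary-level model z ~ MVN(Rλ, R) with λ_j = √n_eff·γ_j at causal
variants (γ the liability-scale standardized effect) — preserving the
LD/z structure that colocalization and conditional analysis consume
without simulating half a million individuals; R is repaired by
eigenvalue clipping at 1e-8 if needed. Defaults mirror a large
autoimmune case-control GWAS (18,942 cases / 501,638 controls,
n_eff ≈ 73,000) and immune-cell eQTL studies of ~500 donors.

Scenario semantics:

* **null** — no disease causal variant and θ = 0; causal eQTLs exist
  iff `eqtl_h2 > 0` (so the same scenario serves both "no instruments"
  fixtures and MR null-calibration runs, which need instruments).
* **shared_causal** — one variant drives expression and disease
  (default disease variance 5×10⁻⁴, z ≈ 5.9 at n_eff = 70,000).
* **distinct_causal** — the causal pair is chosen as the within-block
  pair with empirical r² closest to the target (default 0.7),
  preferring separated pairs among near-ties.
* **masked_secondary** — a strong independent signal (variance 2×10⁻³,
  z ≈ 12) in another LD block plus a weaker shared signal. The shared
  signal's default variance is 9×10⁻⁴ (z ≈ 8): the conditioning step
  can only recover a secondary signal that is itself reliably
  genome-wide significant, and at z ≈ 5.9 the detection probability at
  the 5×10⁻⁸ cutoff is only ≈ 0.68.
* **horizontal_pleiotropy** — one variant drives two genes' expression
  and disease.
* **vertical_causal** — variant → expression → disease with log-odds θ
  per SD of expression; GWAS λ at the eQTLs is exactly θ-scaled, so the
  Wald/IVW estimand equals θ.

What the generator does **not** emulate: real haplotype mosaics (LD is
monotone within a block, so equal-r² pairs have near-proportional LD
profiles — harder for colocalization than real data, where profiles
differ more), trans-eQTLs, imputation uncertainty, allele-frequency
divergence between panel and study, sample overlap, and population
structure. Passing tests therefore demonstrate the machinery's
correctness and its operating characteristics under a clean LD model,
not performance on real cohorts.

# Parameter-recovery study design

The IVW coverage check uses a deliberately strong-instrument design: an
expression study of n = 10,000 with eqtl_h2 = 0.3 (instrument z ≈ 65)
against a modest GWAS of n_eff ≈ 5,000 (outcome z ≈ 12), θ = 0.3,
instruments filtered at F > 30. With the first-order Wald SE the
estimator's true coefficient of variation is √(cv_out² + cv_exp²) while
the reported one is cv_out alone, so nominal 95% coverage is approached
only when cv_exp ≪ cv_out; at these sizes the expected coverage is
≈ 0.95. A large-GWAS/small-eQTL design would show marked undercoverage
for exactly this reason — a property of the standard first-order SE,
not of the implementation.

# A structural limit of single-variant colocalization

For two distinct causal variants at LD r², the mismatched variant's
expected log-ABF deficit is at most ½z²(1−r²). The shared hypothesis
enjoys a prior-odds advantage of log(p12/(p1·p2)) ≈ 8.5 nats under the
default priors. At r² = 0.7 with z ≈ 5.9 the deficit (≈ 5.3 nats)
cannot overcome that advantage, so the model itself concludes H4 most
of the time — a known blind spot of single-causal-variant
colocalization under tight LD, and the reason conditional approaches
exist (they help with *multiple* signals, not with this two-variant
ambiguity). The package reports the measured false-colocalization rate
honestly; discrimination at r² = 0.7 would require substantially
stronger signals (½z²(1−r²) ≳ 10 needs z ≳ 8.2).

# Problem sizes used in validation

The test-suite and acceptance script run: 500 enumeration regions of
≤ 6 variants; 100 in-sample cohorts (n = 2,000, 20 variants) for the
joint-estimation/OLS comparison; 200 replicates each for the shared and
distinct colocalization scenarios and for MR parameter recovery; 100
masked-secondary replicates; 1,000 null gene-outcome pairs; 200 random
clumping sets; and 20 (tests) or 10 (script) replicates of the planted
50-gene study (1,920 variants, 1,500-individual panel). These sizes
were chosen to give stable Monte-Carlo estimates of each rate at
desk scale.

# Known limitations

* LD is block-AR(1); no mosaic or long-range structure.
* IVW ignores residual correlation among clumped variants.
* The conditional SE ignores variance explained by conditioning
  signals (exact for orthogonal conditioning, slightly conservative
  otherwise).
* Liability-scale effects are treated as exactly normal through the
  summary-level MVN model; no case-control ascertainment beyond the
  effective-sample-size approximation.
* Novelty's LD rule requires known variants to be present in the
  reference panel; absent ones contribute the distance rule only.
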