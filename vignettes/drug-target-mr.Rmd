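---
title: "Drug-target Mendelian randomization with colocalization: models and methods"
author: "drugTargetMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

Antidiabetic drugs lower blood glucose through specific protein targets
(sulfonylureas through the KATP channel subunits encoded by KCNJ11 and
ABCC8, GLP-1 analogues through GLP1R, thiazolidinediones through PPARG, and
so on). Whether pharmacological glucose lowering also changes stroke risk
is hard to read off trials. Drug-target Mendelian randomization (MR)
proxies the drug effect with genetic variants in or near the target's
encoding gene that associate with the biomarker the drug moves: people
carrying glucose-lowering alleles at the target locus experience a
lifelong, randomized nudge in the same direction the drug pushes. Comparing
their stroke risk estimates the causal effect of target-mediated glucose
lowering, free of the confounding that plagues observational prescribing
data.

`drugTargetMR` implements the full summary-statistics workflow:
cis-instrument selection, allele harmonization, causal-effect estimation
with heterogeneity and pleiotropy diagnostics, Bayesian colocalization of
the exposure and outcome association signals, a validation path for
correlated instruments, positive-control direction checks, and a synthetic
two-sample GWAS generator with known ground truth so that every stage is
testable without access-managed cohort data.

## Instrument selection

Two rule sets are implemented, mirroring common discovery and validation
practice:

* **Discovery** (`selectInstrumentsDiscovery()`): variants within ±2,500 bp
  of the encoding gene(s), Benjamini–Hochberg FDR < 0.05 on the biomarker
  association, palindromic (A/T, C/G) variants removed, then greedy LD
  clumping at r² = 0.01 within a 500 kb window. The FDR is computed within
  the pooled cis-window variant set of a drug class: the family being
  controlled is "cis-variants of this target", which matches how a
  cis-window screen is read.
* **Validation** (`selectInstrumentsValidation()`): a wider ±100 kb window,
  a strict p < 1 × 10⁻⁵ cut, palindrome removal, and clumping at the
  permissive r² = 0.40, deliberately retaining instruments in weak mutual
  LD to capture more biomarker variance. The surviving LD submatrix is
  attached because downstream estimation must account for the correlation.

All thresholds are strict inequalities, and clumping removes a neighbour
only when its r² with the index variant *exceeds* the threshold, so a pair
at exactly r² = 0.40 is retained in validation mode. Clump distance is
measured between variant positions (center-to-center); p-value ties break
by position and then variant id, making selection fully deterministic.
Designated proxy variants (a literature-validated proxy such as rs757110
for sulfonylureas) are never silently merged into a filtered set: they are
always emitted as a separate `designated_proxy` instrument set, whether or
not they pass the filters, so their evidence is auditable on its own.

Harmonization (`harmonizePair()`) orients outcome effects to the exposure's
effect allele, negating the outcome beta (and complementing the allele
frequency) when the allele labels are swapped. Ambiguity is resolved by
exclusion, not inference: palindromic variants and allele sets that do not
match even after a swap are dropped with a logged reason, and strand
relabelling is never attempted. Every input variant lands either in the
harmonized set or in the exclusion log, an invariant the tests enforce.

## Estimation

With instrument $j$ carrying exposure effect $\hat\beta_{Xj}$ (SE
$\sigma_{Xj}$) and outcome effect $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$):

* **Wald ratio** (one instrument): $\hat\theta = \hat\beta_Y/\hat\beta_X$
  with first-order delta-method SE $\sigma_Y/|\hat\beta_X|$. The
  second-order SE (adding the $\hat\beta_Y^2\sigma_X^2/\hat\beta_X^4$ term)
  is available behind `secondOrder = TRUE` but off by default, matching the
  two-sample convention of treating the exposure effect as fixed.
* **IVW** (`ivw()`): zero-intercept weighted regression of outcome on
  exposure effects, weights $1/\sigma_{Yj}^2$. The random-effects variant —
  the primary analysis — uses the multiplicative convention, inflating the
  fixed-effect SE by $\max\{1, \sqrt{Q/(J-1)}\}$. Nothing shrinks below the
  fixed-effect SE, and the point estimate is unchanged.
* **Cochran's Q** (`cochranQ()`): $Q=\sum_j w_j(\hat\theta_j-\hat\theta)^2$
  with $\hat\theta_j$ the per-SNP ratios and
  $w_j=(\hat\beta_{Xj}/\sigma_{Yj})^2$, referred to $\chi^2_{J-1}$.
* **MR-Egger** (`mrEgger()`): the same weighted regression with a free
  intercept after orienting every $\hat\beta_{Xj}\ge 0$; a non-zero
  intercept signals directional pleiotropy. Egger standard errors carry the
  weighted residual variance on $J-2$ degrees of freedom and p-values use
  the matching t reference — the convention of the standard two-sample MR
  software. This is a deliberate exception to the normal reference used
  elsewhere: with the 3–10 instruments typical of a cis-window, a normal
  reference on a variance estimated from $J-2$ residual degrees of freedom
  would reject a true null intercept at roughly 8–9% instead of 5%, and
  simulation confirms the t reference restores nominal calibration.
* **Correlated instruments** (`ivwCorrelated()`): generalized least squares
  through the origin with
  $\Omega_{jk}=\sigma_{Yj}\sigma_{Yk}\rho_{jk}$, giving
  $\hat\theta=(\beta_X^\top\Omega^{-1}\beta_X)^{-1}
  \beta_X^\top\Omega^{-1}\beta_Y$. When $\Omega$'s condition number exceeds
  10¹⁰ the diagonal is regularized by 10⁻⁸. Because it is unsettled whether
  heterogeneity inflation should also apply here, the model-based SE drives
  the reported p-value and a Q-inflated SE is reported alongside in
  `seThetaInflated`.

Confidence intervals use the fixed multiplier 1.959964 (t-quantiles for
Egger); all other p-values use the standard normal reference. Estimates are
reported per unit *decrement* of the biomarker
(`rescalePerUnitDecrement()`), matching the drug's direction of action:
theta and its bounds are negated (bounds swapped), odds ratios
re-exponentiated, p-values untouched. The HbA1c-scale label for metformin
("6.75 mmol/mol (1.09%)") is carried verbatim as a unit label; no unit
conversion is attempted because none is derivable from summary statistics.
Multiplicity over the three stroke outcomes uses Bonferroni:
`bonferroniThreshold(0.05, 3)` ≈ 0.017.

## Colocalization

A significant MR signal can still be driven by LD between the instrument
and a distinct causal variant for the outcome. The five-hypothesis
approximate-Bayes-factor framework (`colocABF()`) asks whether the exposure
and outcome associations in the gene region share one causal variant,
assuming at most one causal variant per trait: H0 no association, H1/H2
association with one trait only, H3 both traits via distinct variants, H4
both via a shared variant. Per-variant Wakefield log approximate Bayes
factors,
$\log\mathrm{ABF} = \tfrac12\log\frac{V}{V+W} + \frac{Z^2}{2}\frac{W}{V+W}$,
feed prior-weighted hypothesis sums accumulated entirely in log space
(log-sum-exp), so regions with $Z$ scores in the forties do not overflow.
Priors default to the conventional p1 = p2 = 10⁻⁴ and p12 = 10⁻⁵; the
effect prior SD W defaults to 0.15 for quantitative traits and 0.20 for
binary (log-OR) traits. Evidence for colocalization is declared when
PP.H4 strictly exceeds 0.7. Single-variant regions are legal (the H3 sum is
empty, so PP.H3 = 0). H1/H2 labels follow the argument order and swap under
trait relabeling; outputs carry an explicit region label for that reason.
The implementation is checked against a brute-force enumeration over every
single-variant and ordered variant-pair configuration, computed with plain
products, to 10⁻¹⁰ per posterior.

## The synthetic study generator

`simulateSummaryPair()` builds a two-sample study with known truth:

* **Genotypes**: two haplotype matrices of AR(1)-correlated standard
  normals (correlation `ldDecay`, default 0.9, per adjacent variant pair)
  thresholded at the MAF quantile and summed to 0/1/2 dosages — adequate
  for summary-level behaviour at a fraction of the cost of population
  simulation. MAFs are uniform on (0.05, 0.5).
* **Exposure**: genetic value plus unit-variance Gaussian noise (blood
  glucose has an SD near 1 mmol/L); default per-allele causal effect
  0.1 mmol/L, a strong cis signal. Marginal per-variant effects come from
  simple regression.
* **Outcome**: binary, drawn from a logistic model whose log odds add
  `theta ×` (genetic exposure value) to an intercept set from the baseline
  prevalence (default 0.09, the case fraction of the large stroke GWAS
  meta-analyses) plus optional direct variant effects with SD
  `pleiotropySd` (0 = valid instruments; balanced pleiotropy when
  positive). Default theta is a log-OR of 0.4 per 1 mmol/L increment,
  consistent with published glucose–ischemic-stroke MR estimates near
  RR 1.5 per mmol/L. Summary statistics come from per-variant logistic
  score regression, the large-sample equivalent of how stroke GWAS log-ORs
  arise, vectorized across variants.
* **Colocalization truth**: `sharedCausal = FALSE` moves the outcome's
  regional signal (same per-allele magnitude) to a variant whose nominal
  r² with every exposure causal variant is below 0.05.
* **Controls**: `simulateDrugTargetStudy()` adds one quantitative outcome
  per control trait with a stated signed effect per unit exposure
  *decrement* (e.g. type 2 diabetes −, BMI +), so direction checks have
  known truth. Controls are simulated as quantitative traits for
  uniformity; only the sign enters the positive-control decision.
* **Determinism**: a single master seed feeds fixed substreams (variant
  frame, exposure cohort, outcome cohort, one per control trait); repeated
  calls are bit-identical, and ~15% of non-causal variants receive
  palindromic allele pairs so harmonization exclusions are exercised.
  Causal variants are always non-palindromic, otherwise the signal the
  study is built around would be discarded by design.

What the generator does *not* emulate: realistic allele-frequency spectra,
genome-wide scale, population stratification, sample overlap between
exposure and outcome cohorts, or LD estimated with error from a reference
panel. The reported LD matrix is the nominal AR(1) correlation; dosage
correlation after MAF thresholding is slightly attenuated relative to it.
Passing calibration on these studies therefore demonstrates correctness of
the estimators and decision rules under the stated model, not robustness
to the full messiness of cohort data.

## Numerical and design choices

* Duplicate variant ids on input default to an error (`keep_first` is
  opt-in) because silent duplicates corrupt clumping.
* Missing allele frequency is tolerated: once palindromes are excluded it
  is not needed for harmonization.
* Variants missing from the outcome GWAS are dropped with reason
  `missing_in_outcome`; no proxy lookup is attempted.
* Zero exposure effects make ratio estimates undefined and raise errors
  rather than propagating infinities; exact-interpolation Egger fits floor
  the residual variance at the smallest positive double to keep SEs
  positive.
* Generated p-values are floored at the smallest normalized double so
  extreme signals stay within the (0, 1] contract.
* The pipeline isolates failures per drug class (one class with no
  surviving instruments never aborts the others) and gates colocalization
  on the Bonferroni flag, the formal version of running colocalization
  only for MR-significant targets. Whether the designated proxy must also
  pass the discovery filters is left open in the source material; here it
  never has to, and it is never merged.
* Report rendering writes no timestamps, so a rerun under the same
  configuration and seed is byte-identical.

## Problem sizes used in the shipped checks

The packaged calibration checks run at desk scale, chosen to give stable
Monte-Carlo estimates in minutes on one CPU: estimator recovery uses 1,000
replicates of 10 independent valid instruments (per-allele effects 0.06 to
0.24 mmol/L, theta = −0.3, two cohorts of 20,000); the Egger intercept
calibration uses 2,000 balanced-pleiotropy replicates of the same design
with direct-effect SD 0.03 (comparable to the outcome SEs); colocalization
calibration uses 200 shared- and 200 distinct-causal regions of 100
variants at strong signal (per-allele 0.5 mmol/L, theta = −0.8, cohorts of
20,000). `scripts/acceptance.R` recomputes the same quantities at reduced
replicate counts.

## Limitations

Beyond the generator's simplifications above: no weighted-median or modal
estimators, no MR-PRESSO outlier removal, no Steiger directionality
filtering, no SuSiE-style multi-causal colocalization, no LD-aware
fine-mapping, and no F-statistic weak-instrument screen — the workflow
implements exactly the discovery/validation/colocalization design it
mirrors. Real-data use requires externally supplied LD (reference-panel
derived) on the same allele frame as the summary statistics, and genome
builds must agree between datasets (no liftover is provided).
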