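---
title: "Methods: cross-species metabolomic aging-signature reversal analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species metabolomic aging-signature reversal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Aging shifts the circulating metabolome in a coordinated way: in aged mice
most serum metabolites — lipids especially — decrease in concentration,
while in older humans most increase. A candidate gerotherapeutic is
interesting not because it moves any single metabolite, but because it
moves the *profile* against the direction of aging. `rejuvmet` packages
the statistics needed to quantify that claim end to end, from a raw
samples-by-metabolites concentration table to a per-treatment
"rejuvenation" score, dose–response curves, survival contrast, and
cross-species integration.

# Models and procedures

## Preprocessing

Concentrations (µM) are log2-transformed for all modelling; a zero or
negative concentration is a data error, not a value to be silently mapped
to `-Inf`, and raises an error naming the offending cells. Outlier
samples are screened by the mean metabolite z-score: each feature is
z-scored across samples (n−1 denominator; zero-variance features
contribute z = 0), each sample's score is the mean over its non-missing
features, and samples with |mean z| > 3 are flagged and excluded from
model fits (they remain in the written QC table). The z-score is computed
on the log2 scale, consistent with "log2-transformed for analysis"; the
natural scale would let high-abundance lipids dominate.

Metabolite-class totals are sums of member concentrations on the
*natural* scale — summing log-values would be dimensionally meaningless —
with missing members simply absent from the sum and all-missing cells
missing. Class totals are then log2-ed when used as model outcomes (a
config switch in principle; the log2 default keeps class models
comparable with the per-feature models).

## Differential abundance with empirical-Bayes moderation

Per feature, an ordinary least-squares model with group-means coding plus
numeric covariates (mouse: body weight; human: subject fixed-effect
blocks for the longitudinal design) is fitted on that feature's
non-missing samples (row deletion; no imputation). Features with fewer
usable samples than design columns plus one residual df are skipped and
reported.

Moderation borrows strength across features. Writing `s²_g` for the
residual variance on `d_g` df, the prior `(d₀, s₀²)` is estimated by
moment-matching of `e_g = log s²_g − ψ(d_g/2) + log(d_g/2)`, whose
theoretical mean and variance under a scaled-F model are
`log s₀² + ψ(d₀/2) − log(d₀/2)` and `ψ′(d_g/2) + ψ′(d₀/2)`. The trigamma
inversion uses a Newton iteration (relative tolerance 1e-13); a
non-positive excess variance gives `d₀ = ∞` and pure pooling
(`s̃² = s₀²`), logged rather than raised. The moderated statistic is
`t_g = β̂_g / (u_g^{1/2} s̃_g)` with `s̃²_g = (d₀ s₀² + d_g s²_g)/(d₀ +
d_g)`, referred two-sided to a t-distribution on `d₀ + d_g` df capped at
the pooled residual df — the cap is part of the published framework and
binds exactly when `d₀` is very large. BH adjustment is the step-up
procedure with monotonicity enforcement; Fisher combination across two
comparisons refers `−2(ln p₁ + ln p₂)` to χ² with 4 df and leaves the
subsequent BH to the caller.

The human "ID" term is implemented as fixed subject-indicator columns
(the literal reading of a model listing Treatment, BMI and ID as terms).
Note that BMI is constant within subject and therefore collinear with the
blocks; pooled human contrasts in the pipeline block on subject and omit
BMI. A duplicate-correlation random-subject variant is deliberately out
of scope.

## Signature reversal scores

A signature and a treatment effect are both per-feature effect vectors;
their score is Spearman's ρ over the exact-name intersection of their
features (average ranks for ties), with the two-sided p-value from
`t = ρ √((n−2)/(1−ρ²))` on n−2 df. An exact-permutation option exists for
tiny panels (the t-approximation is the default because it is what the
standard correlation routines report). Families of scores (one treatment
per forest-plot row) are BH-adjusted together. Per-subject human scores
correlate each subject's change from their *own* baseline (log2FC =
visit − baseline on the log2 scale) against the external β-age
coefficients; a subject-visit with an all-zero change vector yields a
missing score with a recorded reason, and a missing baseline is an error
naming the subject.

Because Spearman's ρ is scale-free, β-age (per year) and log2FC need no
rescaling before correlation.

**A calibration caveat worth knowing.** When the aging signature and the
treatment effect are both *estimated* against the same control group
(old-vs-young and treated-vs-old sharing the old controls), the shared
control-mean noise enters the two estimates with opposite signs and
induces a negative correlation even when the true effects are
independent. On pure-noise arms at this package's default design the
artifact alone produces ρ around −0.3 to −0.4. The Spearman p-value is
calibrated for independent inputs, so the package's null-calibration
tests score the estimated treatment effect against the generator's *true*
aging signature; users comparing two estimated effect vectors that share
samples should interpret weakly negative scores with this artifact in
mind (or estimate the signature on disjoint controls).

## Dose–response mixed models

All dose models are random-intercept LMMs fitted by maximum likelihood —
not REML — because deviances are compared across fixed-effect structures.
With variance ratio λ = σ²_subject/σ²_resid the marginal covariance is
σ²_resid·Σ(λ), Σ block-diagonal with `I + λJ` per subject, so for fixed λ
the GLS fixed effects and σ²_resid have closed forms and the fit is a
bounded one-dimensional search over log λ (interval e⁻²⁰…e¹⁵, tolerance
1e-10). The λ = 0 boundary is always evaluated and must be *strictly*
beaten (by more than 1e-8 log-likelihood) — with one observation per
subject the profile likelihood is flat in λ and the fit then reduces
exactly to OLS, which is how the mouse class model (one serum sample per
mouse, `(1|ID)` in the formula) is honoured without being identifiable.
Wald z tests are reported for fixed effects; Satterthwaite or
Kenward–Roger corrections are out of scope. A residual-variance floor at
machine epsilon keeps degenerate constant-outcome fits finite.

Dose enters in raw mg (0/25/50/100), matching `dose + dose²`; an
orthogonal-polynomial recoding is available for conditioning. Order
selection fits all candidate orders on identical observations and takes
the lowest ML deviance, reporting AIC/BIC alongside. Deviance is monotone
non-increasing across nested orders, so this rule is only discriminating
because the cubic is typically unfittable: per-subject scores exist only
at post-baseline visits, i.e. at 3 distinct doses, and orders above
(distinct doses − 1) are excluded with a warning. When placebo subjects
are modelled at dose 0 (the default; they are excludable by subsetting
the rows passed in), 4 distinct doses exist and the saturated cubic will
win a raw deviance comparison — the selection table's AIC/BIC columns are
the informative ones there.

## Survival and osmolality

Kaplan–Meier curves use the product-limit estimator with simultaneous
handling of tied events and the standard convention that censoring at an
event time is processed after the events. The log-rank test compares
observed and hypergeometrically expected events over k groups with the
full covariance, χ² on k−1 df (asymptotic; no exact small-sample
option, matching the standard survival routines). Calculated serum
osmolality uses the dominant clinical convention
`2·Na [mmol/L] + glucose/18 + BUN/2.8 [mg/dL]` → mOsm/kg; the formula
choice is a design decision since only the quantity, not the formula, is
standard in the source literature for this analysis.

## Integration

The correlation network computes all pairwise Spearman ρ between
condition effect vectors over shared features, BH across the pairs, edges
flagged significant at q < 0.05, and a 2-D layout by classical MDS of the
*signed* distance 1 − ρ so anticorrelated conditions (aging vs treatment)
sit far apart — the distance choice is ours; the layout convention (MDS)
and threshold come with the figure being emulated. Constant effect
vectors give undefined (flagged) edges rather than errors.

The PCA z-scales each condition's effect vector by its own SD *without
centering* — equalizing β-age and log2FC scales while preserving the
global shift — and decomposes the conditions × features matrix by SVD.
Variance fractions are squared singular values over their sum; with
uncentered data the first component typically captures the
everything-moves-together axis that is the biological point.

## Preranked enrichment

The enrichment score is the signed extremum of the weighted running sum
(increment `|stat|^w / Σ|stat|^w` at members, decrement `1/(N−m)`
elsewhere; w = 1 default). Ranking ties are broken lexicographically by
feature id for determinism. p-values are gene-label permutations —
appropriate because the input is a preranked effect vector, not
per-sample data — two-sided, with the `(1 + hits)/(1 + n_perm)` floor,
and BH across sets. The multilevel adaptive refinement of the reference
tool is out of scope.

# The synthetic world

The generators state a world and the defaults *are* that world; they were
chosen once, from the emulated designs, and are not tuned to test
outcomes.

* **Mouse**: arms young WT 7, old WT control 10 / losartan 14, AT1KO
  control 8 / losartan 5, AT2KO control 7 / losartan 6; 122 quantifiable
  features in panel-realistic class proportions (roughly 40% PC, 21% AC,
  11% each AA and biogenic amines, 8% SM, 7% LysoPC, one hexose).
  Aging affects half the features with mean log2FC −0.3 (uniform ±50%
  spread); losartan reverses half the affected features at strength 0.5,
  attenuated ×0.5 in AT1-knockouts and ×0 in AT2-knockouts (the
  qualitative receptor-dependence pattern; the multipliers are free
  parameters, not literature claims). Measurement noise is 0.5 log2
  units, with a shared per-sample-per-class latent shift at half that SD
  providing class-structured covariance. The lowest 2% of each feature's
  values are recorded as missing (below-LOD); missingness, not zero, is
  the contract all downstream stages honour. Body weight ~ N(30, 3) g,
  +3 g in aged animals.
* **Human**: 9 placebo and 7 treated men aged 70–85, BMI ~ N(27, 4),
  visits every 8 weeks at doses 0/25/50/100 mg (placebo stays at 0).
  Aging *increases* affected features, mean +0.03 log2 per year. The
  per-dose reversal magnitude is `0.4·d − 0.004·d²` "years of aging
  reversed": 7.5 years at 25 mg, 10 at 50, 0 at 100 — the U-shape the
  dose-response module must recover. Subject random intercepts (SD 0.3
  log2) induce the within-subject correlation the LMM models; visit noise
  is 0.3 log2 units.
* **External β-age** is the true per-feature aging effect plus N(0,
  error_sd) noise with nominal SE/p — emulating coefficients imported
  from an independent cohort on the same platform.
* **Survival**: exponential times, 19 treated at hazard 0.004/day vs 14
  controls at 0.012/day, administratively censored at 60 days.
* **Clinical panel**: Na ~ N(140, 2) mmol/L, glucose ~ N(95, 10) mg/dL,
  BUN ~ N(16, 4) mg/dL (standard physiologic ranges; needed only as a
  test bed), sodium shifted along the quadratic dose shape.

Every generator is a pure function of its config including the seed.

**What a green test does and does not establish.** The generators emulate
the *statistical structure* the analysis assumes: effect directions and
sparsity, class covariance, within-subject correlation, LOD missingness,
dose shape. They do not emulate batch effects, drift, non-lognormal
heavy tails, correlated missingness, panel-specific analyte behaviour, or
any real biology; passing tests establish that the estimators recover
what the stated world injects, not that the emulated study's scientific
conclusions are correct.

# Numerical choices

* BH is sort-based O(m log m) with cummin enforcement; verified against
  the O(m²) definitional oracle.
* Spearman ρ is ranks-then-product-moment in double precision; agreement
  with an independent rank-then-`cor` route is to 1e-14 (summation order
  differs).
* The LMM search interval covers λ from ~2e-9 to ~3e6; hitting the upper
  bound marks the fit non-converged. Deviance = −2·log-likelihood (ML).
* Feature-name matching everywhere is exact string equality after
  whitespace trimming — the panels being harmonized share one naming
  scheme.
* CSV uses the empty cell as the missing token; round trips are lossless
  at 15 significant digits.
* Enrichment ranking ties break lexicographically; permutation draws are
  seeded per set size.

# Known limitations

* The shared-control correlation artifact described above is a property
  of the design, not of the implementation; group-level scores between
  contrasts sharing samples are biased negative under the null.
* Wald inference for LMM fixed effects is first-order; with few subjects
  the p-values are anti-conservative.
* The fixed-block treatment of subject effects in pooled human contrasts
  conditions on subjects and cannot use between-subject covariates.
* Proteome tables are consumed as abundance CSVs; acquisition-level
  processing is out of scope, as are pathway-network and PPI
  visualisations.
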