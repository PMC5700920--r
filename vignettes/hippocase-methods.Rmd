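---
title: "Methods: single-case and group inference for hippocampal subfield volumetry and MRS"
author: "hippocase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-case and group inference for hippocampal subfield volumetry and MRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In pre-surgical evaluation of temporal lobe epilepsy (TLE), ultra-high-field
(7T) imaging yields two families of quantitative hippocampal measures per
patient: manually segmented subfield volumes (CA1, CA2, CA3, dentate gyrus,
subiculum; mm³ per hemisphere) and single-voxel MRS metabolite
concentrations (tNAA, Glu, Gln, tCho, tCr, Ins; µmol/g per hemisphere).
Cohorts are small — on the order of a dozen patients and a dozen controls —
and the clinically relevant question is usually about *one* patient: do this
person's measures deviate from the healthy range, and on which side?
`hippocase` implements the full chain from measurement tables to
per-patient inference: deterministic corrections, a sign-flipping
permutation test of each patient against the control group, family-wise
error control, laterality-concordance labelling, group-level statistics,
and a synthetic cohort generator that makes every stage testable without
any clinical data.

## Derived measures

**Head-size correction.** Total hippocampal volume covaries with total
brain volume (TBV). The correction is the covariance method: in an
independent reference cohort, ordinary least squares of total hippocampal
volume on TBV is fitted separately per (sex, hemisphere) cell, and each
study subject's total is adjusted as
`Adjusted = Observed − slope × (TBV_subject − TBV_mean)`, using the cell's
slope and mean reference TBV. Centering on the cell's own mean keeps the
adjustment an exact identity for a subject at the reference mean. The cell
mean is used because the source protocol fits cell-wise regressions without
stating which mean it centers on; per-cell centering is the only choice
that preserves that identity.

**Subfield scaling.** Subfields are rescaled by one common factor so that
their ratios are untouched. The default factor is `adjusted/observed`,
which makes the scaled subfields sum exactly to the adjusted total. The
protocol that inspired this stage verbally describes the inverse ratio
(`observed/adjusted`); taken literally, that direction *enlarges* the
subfields of larger-brained subjects and inverts the correction. Both
directions are implemented (`scaling_mode` in `analysis_config()`); the
default is the one that accomplishes head-size normalization.

**MRS corrections and QC.** CSF contributes no metabolite signal, so
measured concentrations are rescaled to the tissue fraction:
`c / (1 − FCSF)`, defined for `FCSF ∈ [0, 1)`. Estimation quality is
screened with Cramér–Rao lower bounds: a metabolite with CRLB > 50%
(strictly greater) in a record is not reliably detected there, and a
metabolite enters cohort statistics only if it passes in both hemispheres
of every non-excluded participant — the wholesale rule under which GABA
and lactate typically drop out at 7T in this region. CRLBs between 25% and
50% are kept but logged at warning level.

**Asymmetry.** For every subfield and reportable metabolite the laterality
index is `(L − R) / ((L + R)/2)`: 0 for symmetry, bounded by ±2,
antisymmetric under hemisphere swap. Asymmetry indices can be ≤ 0 and are
therefore *never* Box-Cox transformed by default.

## The single-case test

**Statistic.** For a patient value `x` and `n` controls the statistic is
the standardized case deviation
`T = (x − mean(controls)) / (sd(controls) √(1 + 1/n))` — the
Crawford–Howell case-indicator contrast, i.e. the GLM t for a
one-observation group against `n` controls.

**Null by sign flipping.** With a dozen controls, exchanging the case
label over the `n+1` subjects allows only `n+1` distinct arrangements, so
the attainable p is floored at `1/(n+1)`. Sign flipping multiplies the
shuffling count: pool case and controls, subtract the pooled mean, and
treat the `n+1` residuals as symmetric about zero — an assumption the
Box-Cox step exists to make plausible. The default scheme
(`shuffle = "perm_flip"`) combines label permutations *and* sign flips,
the composite scheme permutation-GLM software uses when both exchangeable
and independent-symmetric errors are assumed. Because `T` is invariant to
rearrangements among the control slots, the distinct shufflings reduce to
(which residual occupies the case slot) × (sign pattern):
`(n+1)·2^(n+1)` pseudo-samples, enumerated exhaustively whenever
`2^(n+1) ≤ n_max_exhaustive`, otherwise sampled `n_mc` times with a fixed
seed.

**Why the permutation component is load-bearing.** A pure flips-only
reconstruction (`shuffle = "flip_only"`, retained for reference and
oracle-tested) keeps the case's own residual attached to the case slot in
every pseudo-sample. When the case is truly abnormal that residual is
huge, so every element of the "null" inherits the observed effect and the
null distribution scales with it. Measured at `n = 10`: the flips-only
test cannot reject at α = 0.05 *at all* under the null (every attainable p
exceeds 0.05 — it is radically conservative) and detects a 4 SD shift in
only ~10% of cases. With label exchange included, the case slot usually
receives an ordinary residual, the null stays t-like, and the same 4 SD
shift is detected in ~86% of cases while the type-I error stays at
0.046–0.052 through the full Box-Cox-then-flip path. The flips-only mode
should be viewed as a contract artefact, not an analysis option.

**p-value conventions.** Exhaustive enumeration includes the identity
shuffling in numerator and denominator, so p is never 0 and the two-tailed
floor is `2/null_size`; Monte-Carlo sampling uses `(b+1)/(m+1)`. Ties
(|T*| equal to |T| within a 1e-8 relative tolerance) count toward the
numerator — conservative and standard. Two-tailed testing is the default,
with the direction (`decreased`/`increased`) always reported; one-tailed
tests use the signed statistic in the observed direction.

**Box-Cox preconditioning.** Volume and concentration variables are
transformed by `(x^λ − 1)/λ` (log at λ = 0) with λ fitted by profile
maximum likelihood on the pooled case + controls sample of each variable,
over λ ∈ [−5, 5]. Pooled fitting is the stated protocol; it costs a little
power against extreme cases (the fitted λ partially "normalizes" the
outlier — λ pins at the boundary in ~20% of strong-effect simulations) but
the permutation test retains ~86% power at 4 SD, and pooled fitting
measured slightly *better* than controls-only fitting in that scenario, so
the stated rule is kept. Age is not a nuisance covariate by default (the
design is age-matched); `age_residualize` residualizes transformed values
on age first for sensitivity analyses.

**Families and FWE.** The battery families mirror the analysis blocks:
subfield volumes (both hemispheres, ≤ 10), metabolite concentrations
(≤ 12), subfield asymmetries (≤ 5), metabolite asymmetries (≤ 6); the
recorded `family_size` is the count of *testable* variables. Bonferroni
(`p ≤ α/family_size`) is the default. A permutation-native max-statistic
correction is provided: the family's maximum |T| over shufflings shared
across variables gives each variable a joint-null `p_fwe`; its familywise
error is calibrated (measured 0.03–0.07 at α = 0.05 on independent nulls).

**Concordance labels.** Per patient and modality, significant uncorrected
findings are attributed to hemispheres (`left.*`/`right.*` variables to
their own side; a significant asymmetry to the left if decreased, right if
increased). No lateralized finding → `uninformative`; findings confined to
the EEG-onset side → `concordant`; confined to the opposite side →
`discordant`; both sides → `bilateral`, which counts as concordant when
the EEG onset itself is bilateral. One edge is not fixed by any source:
bilateral EEG onset with strictly unilateral findings is labelled
`discordant` here, since the imaging failed to reproduce half of the
electrographic picture. Unknown laterality withholds the label with a
reason.

## Group-level statistics

Normality is gated per group with Shapiro–Wilk at α = 0.05; a variable
failing in either group is Box-Cox transformed *jointly* across groups (a
per-group transform would destroy comparability). Group comparisons are
ANCOVAs controlling for age (`value ~ age + group`); for this one-factor,
one-covariate design type-I and type-III sums of squares coincide. If age
is collinear with group the covariate is dropped with a warning — which is
also the only construction under which the ANCOVA F can *exactly* equal
the two-sample pooled-variance F, because retaining any covariate changes
the error degrees of freedom from N−2 to N−3 (an irreducible
(N−3)/(N−2) factor).

Before ipsilateral/contralateral pooling, control left/right symmetry is
gated with a paired t-test; asymmetric variables (p < 0.05) are excluded
from pooled analyses but still analyzed per hemisphere. Clinical
correlations are Pearson: two-tailed by default, one-tailed fixed to the
positive direction for volume–memory pairs (atrophy is not expected to
improve memory), and age-adjusted partial correlations (residualize both
variables on age, t on n−3 df) for epilepsy-duration associations. No
multiplicity correction is applied at group level; every results header
records this.

**Reliability.** Repeat segmentations (two time points) are summarized by
a repeated-measures ANOVA with within-subject factors time and subregion
(F, p for time and time × subregion) and by the intraclass correlation for
consistency of single measurements — ICC(3,1), two-way mixed — with its
Shrout–Fleiss F-based 95% CI, overall (units = subject × subregion) and
per subregion. The ICC model is a package choice (the conventional
intra-rater form) and is recorded in the report. Memory impairment on
neuropsychological tests is flagged at z ≤ −1.34 (inclusive).

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, so
that calibration, power and recovery are measurable: control TBV by sex
(F 1.10 L, M 1.25 L means, SD 0.1 L), total hippocampal volume tracking
TBV at a configurable slope (default 0.002 mm³/mm³), subfield volumes as
fixed proportions of the latent total times positive noise, metabolites
from a lognormal family (default; strictly positive and right-skewed, so
the Box-Cox stage is never vacuous), beta-distributed CSF fractions,
CRLB draws that push GABA and lactate over the 50% rejection bound,
age-matched groups, and missing hemispheres injected at a configurable
rate (default 4%, about one hemisphere per 24). Default subfield and
metabolite means (CA1 1300, CA2 120, CA3 100, DG 800, subiculum 450 mm³;
tNAA 10.5, Glu 8.5, Gln 3.0, tCho 2.0, tCr 8.0, Ins 6.5 µmol/g; CVs 8%
and 10%) are plausible placeholders for 7T hippocampal data, documented
as configuration rather than claims.

Injected patient effects are multiplicative factors or `sd_shift`s; the
latter are calibrated in units of the target variable's *actual*
control-law SD (for subfields that includes the shared latent-total noise,
a factor √1.25 over the configured CV), so "a 4 SD reduction" means four
empirical standard deviations of the analyzed variable. Every injected
effect is recorded in a ground-truth ledger; `score_recovery()` computes
sensitivity (detected with the right direction), specificity on untouched
variables, and laterality accuracy by majority of significant lateralized
findings.

What a green test does *not* establish: the generator draws independent
noise per subfield and metabolite, so it does not emulate inter-subfield
correlations, segmentation-rater bias, spectral-fit covariance between
metabolites, scanner drift, or any spatial structure. Calibration and
power results transfer to real data only insofar as residual symmetry
after Box-Cox is plausible there.

## Numerical choices

Exhaustive enumeration is used up to `n_max_exhaustive = 32768` sign
patterns (14 controls); beyond that, `n_mc = 10000` seeded draws with the
`(b+1)/(m+1)` estimator. Per-test Monte-Carlo seeds derive
deterministically from the config seed. Tie comparisons use a 1e-8
relative tolerance. Measurement tables are written at full precision
(`%.17g`) so write → read → write is byte-identical; the run manifest
hashes config, input hashes and result tables (not the timestamp), so
reruns are hash-stable. Degenerate inputs are handled explicitly: a voxel
that is all CSF, zero control variance, constant paired differences
(symmetry gate at the test floor), identical repeat segmentations
(ICC = 1 with a zero-width CI), and a covariate fully explained by age
(partial correlation 0).

## Known limitations

The test's small-sample type-I error through the composite path measures
0.046–0.052 at n = 10 controls — calibrated, but the plug-in pooled mean
makes sign-flip reconstruction only asymptotically exact; at much smaller
n the approximation degrades. The max-statistic correction requires
controls complete across the family. The CLI consumes JSON configuration
(no YAML parser is assumed on the host). Image-space inference,
segmentation itself, spectral fitting and relaxation corrections are out
of scope: the pipeline begins at measurement tables.
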