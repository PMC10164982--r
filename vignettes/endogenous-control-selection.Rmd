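---
title: "Selecting endogenous controls and quantifying miRNA expression with mirnorm"
author: "mirnorm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting endogenous controls and quantifying miRNA expression with mirnorm}
  %\VignetteEncoding{UTF-8}
---

## The problem

Relative quantification of miRNA expression by qPCR stands or falls with the
normalizer. A target's Ct value is only interpretable relative to an
endogenous control measured in the same sample; if that control itself
varies between samples or between disease groups, every downstream fold
change inherits the distortion. There is no universally accepted miRNA
normalizer, so a careful study selects its own: candidate controls are
measured across the cohort, their stability is scored by several
established statistics, the scores are aggregated, and the winner (often a
geometric-mean combination of two candidates) is used for the 2^-ddCt
analysis of the targets. `mirnorm` implements this whole workflow — candidate
screening from small-RNA-seq counts, four stability statistics, rank
aggregation, CV-based exclusion, inter-run calibration, 2^-ddCt fold
changes, and a logistic diagnostic panel with ROC evaluation — together with
synthetic-data generators that plant a known truth so every stage can be
tested end to end.

## Data model and preprocessing

Ct values (quantification cycles) are treated throughout as what they are
physically: a log2-scale measure of abundance, with *lower* Ct meaning
*higher* expression. The replicate-level generative model behind
`simulate_ct_dataset()` is

    Ct[g, s, r] = baseline[g] + a[s] + beta[g] * I(tumor[s])
                  + delta[run(s)] + eps[g, s, r]

with per-sample effects `a ~ N(0, sample_effect_sd)`, per-gene group shifts
`beta` (cycles; negative = up in tumors), per-run offsets `delta`, and
replicate noise `eps ~ N(0, replicate_sd[g])`. Values above the detection
limit (default 40 cycles) are recorded as *undetected* — a distinct marker,
never a numeric 40 — so the discard rule stays testable. Each run carries
one pooled inter-run calibrator whose Ct is the mean gene baseline plus the
run offset.

Preprocessing follows the order **collapse → detection filter →
calibrate**:

* `collapse_replicates()` averages the detected replicates (arithmetic
  mean, the qPCR convention; median available) and flags cells whose
  replicate SD exceeds `max_sd` (default 0.5 cycles).
* `detection_filter()` discards a gene that fails detection in *any*
  cohort sample. This strict reading matches how validation cohorts
  actually discard assays; a tolerance fraction is configurable. Whether
  the original workflow filtered before or after calibration is not
  documented anywhere we could find; filtering first avoids calibrating
  assays that are about to be dropped, and with per-gene calibration the
  order does not change retained genes' values.
* `interrun_calibrate()` centres each gene's calibrator Ct across runs and
  subtracts the run-specific deviation from every sample of that run.
  Calibration is per gene, not one global per-run constant, because assays
  have independent efficiencies; in a noise-free simulation this removes
  the planted offsets exactly (up to the common mean offset, which cancels
  in every downstream ratio).

`delta_ct()` normalizes targets as `dCt = Ct_target − N_s`, where `N_s` is
the control's Ct, or the per-sample **geometric mean of the Ct values** for
a multi-gene control. Ct is already log-scale, so the field's "combine by
geometric mean" rule applied to Ct values is a convention rather than an
algebraic necessity; we follow it deliberately because candidate
*combinations* are built the same way, and the two must agree. One
consequence worth knowing: with a multi-gene control, dCt is invariant
under a global additive Ct shift only to first order (the geometric mean of
shifted Cts is not exactly the shifted geometric mean); the deviation is a
few thousandths of a cycle at realistic Ct levels, and exact for
single-gene controls.

## The four stability statistics

All four are computed on Ct directly (log2 scale), with sample SDs using
the n−1 denominator.

**geNorm (M value).** For genes j, k the pairwise variation is
`SD_s(Ct_j − Ct_k)`, the SD of a log2 expression ratio; `M_j` is the mean
over partners. The iterative pass removes the argmax-M gene and recomputes
until two genes remain; these cannot be separated by a pairwise criterion
and share ranks 1–2 (1.5 each, consistent with average-rank ties). The
`V(n/n+1)` series — the SD across samples of the difference between
log-scale normalization factors built from the top n and n+1 genes — is
reported as is; we deliberately do not automate the usual `V < 0.15`
stopping heuristic, leaving the gene-count decision to the analyst.

**NormFinder.** A model-based variance decomposition on the two-way layout
within each group. With k genes and residual mean squares `s2[g]`, the
bias-corrected intra-group variance is

    sigma2[g] = k / (k − 2) * (s2[g] − mean(s2) / (k − 1))

floored at zero (we derived the correction from
`E[s2_g] = sigma2_g (1 − 2/k) + mean(sigma2)/k`). The inter-group
difference `d[g]` (the gene's centred group mean) is shrunk toward zero by
the empirical-Bayes factor `gamma2 / (gamma2 + sigma2[g]/n_i)`; when both
`gamma2` and the sampling variance are zero the factor is defined as 0,
not 0/0 (an earlier draft returned NaN here, which silently ranked the
*most* stable candidates last). The stability value combines the two
sources with equal group weights, `rho = mean_i(|d~| + sqrt(sigma2/n_i))`;
where the original description leaves the combination weight implicit,
equal weighting is our documented choice. Two caveats follow directly from
the model: the per-sample centring absorbs the *average* group shift, so a
zero-shift gene surrounded by same-signed shifters will look
group-different; and feeding the model a candidate set containing
geometric-mean combinations *and* their members violates its independence
assumption, which costs some rank precision among near-duplicates (see the
scenario notes below).

**BestKeeper.** The index is the per-sample geometric mean of candidate
Cts; each candidate is described by `SD(Ct)`, `CV = 100·SD/mean(Ct)` and
the Pearson correlation with the index. The aggregation key is SD
(ascending) rather than r, because RefFinder-style aggregation needs a
single ascending-stability key per method; a constant gene has undefined r
but legitimately ranks best by SD.

**Comparative delta-Ct.** `stability_j = mean_k SD_s(Ct_j − Ct_k)` — the
un-iterated cousin of the M value: if the Ct difference of two genes is
constant across samples, both are stable.

## Aggregation, combinations, and the CV rule

`aggregate_ranks()` ranks candidates within each method (average ranks for
ties; geNorm contributes its exclusion-order rank) and takes the geometric
mean of the four ranks — the "comprehensive stability value", invariant to
any monotone transform of a method's statistic and bounded by the smallest
and largest per-method rank. `make_combinations()` appends all k-subsets
(default pairs) as geometric-mean pseudo-genes so singles and combinations
compete in one ranking.

`cv_of_candidates()` computes `CV = 100 · SD(dCt) / |mean(dCt)|` over
control samples. What the candidate's dCt is taken against is genuinely
ambiguous when the candidate *is* the prospective control, so both
readings are implemented: `"self-vs-calibrator"` (default; the candidate's
Ct against the pooled inter-run calibrator of its run — the pool is the
one sample type measured on every run) and `"targets-vs-candidate"`
(target dCt normalized to the candidate, pooled). The absolute value in
the denominator is deliberate: mean dCt can be negative, and a candidate
whose mean dCt sits near zero produces the CV explosions (> 200%) that
motivate the exclusion rule; such candidates are flagged
(`near_zero_mean`, threshold 0.05 cycles) rather than silently inverted.
`select_endogenous_control()` excludes CV > 200% (configurable), then
takes the lowest stability value, breaking ties by lower CV, and reports a
shortlist at stability value < 5.

## Sequencing screens and the DE consensus

`rpm_normalize()` scales each sample to reads-per-million.
`expression_filter()` removes isoforms with zero counts in every sample.
`ec_candidate_screen()` discards miRNAs with mean RPM below 100 or
|log2FC| above 2 and ranks the survivors by |log2FC| ascending — a
normalizer screen must be two-sided, so "fold change above 2" is read as
magnitude; the abundance gate is interpreted on the RPM scale (the
raw-count reading is configurable). Group fold changes use a 0.5
pseudocount on both group means. `de_consensus()` intersects the
significant sets of several externally produced DE tables (edgeR, voom,
DESeq2 style — consumed as generic `id/baseMean/log2FC/pvalue/padj`
tables, never reimplemented) and removes intersection members whose
baseMean falls below 100.

## Relative quantification and the panel

`ddct_fold_change()` references each sample's dCt to the control-group
mean; the group-level fold change is `2^−mean(ddCt_tumor)` — a
geometric-mean-type summary, chosen over the arithmetic mean of per-sample
fold changes because fold changes are ratios (the alternative is a
one-line change and documented here so nobody mistakes it for the only
option). Reported fold changes use the signed convention: ratios below 1
become negative reciprocals (0.25 → −4), so |FC| is always ≥ 1 and
down-regulation reads naturally. Group testing follows the
normality-dispatch recipe: Shapiro–Wilk on each group of (log-scale)
values, Student's t-test (equal variances) if both pass at 0.05, otherwise
Mann–Whitney U; either group failing triggers the nonparametric branch —
the conservative reading. Significance requires p < 0.05 *and* |FC| ≥ 2;
raw p-values drive the call (as is common in validation-cohort reports),
with BH-adjusted values reported alongside for transparency.

`fit_panel()` fits a maximum-likelihood logistic regression of group on
per-sample log2 relative expression (−ddCt) of the panel miRNAs — a convex
problem, hence deterministic. Under perfect separation the ML estimate
diverges; the fit is flagged and refitted with a small ridge penalty
(lambda 1e-3, intercept unpenalized) so scores stay finite — flagged, not
hidden, because separation usually means the in-sample performance
estimate is optimistic. `roc_curve()` sweeps thresholds over the unique
scores; the trapezoid AUC equals the concordance statistic (ties counted
1/2), which the tests verify exhaustively. `confusion_at_cutoff()` counts
a score equal to the cutoff as positive (the boundary must go somewhere;
this choice is asserted in tests). Like the cohort studies it mirrors, the
panel is fitted and evaluated on the same samples — there is no
cross-validation here, and in-sample sensitivity/specificity/AUC should be
read as optimistic by construction.

## What the generators emulate, and what they do not

`simulate_study()` bundles the scenario the analysis scripts and the
pipeline run on: a 30 + 30 cohort, triplicate qPCR over 4 runs with
N(0, 0.5)-cycle run offsets (between-run magnitudes are rarely published;
0.5 cycles is a realistic instrument-to-instrument scale and
configurable), 8 candidate controls, 5 targets with planted fold changes
4, 4 and 1/8 (plus two nulls), one candidate forced above the detection
limit, and a count matrix structured like a real miRNome — a few dominant
stable species carrying most of the library, mid-abundance background with
small group drifts, a handful of strong changers, and silent isoforms.

Scenario-design notes that took actual thought:

* *Instability is planted as per-gene noise, not group shifts.* A
  candidate set where the unstable genes share large same-signed shifts
  forms a mutually consistent block that pairwise statistics reward, and
  the shift average leaks into NormFinder's sample centring; large
  opposite shifts cancel inside a geometric-mean combination and create a
  legitimately stable pseudo-gene. Either way the "planted stable pair"
  would no longer be the unique truth. Elevated per-gene noise
  destabilizes all four statistics coherently and keeps the truth unique.
* *The stable pair carries a 0.45-cycle noise floor.* With pure
  0.2-cycle triplicate noise, a stable single and the stable pair differ
  by ~0.03 cycles of effective noise — below what n = 60 samples can
  resolve, making "the combination beats its own member" a coin toss. A
  per-gene technical-plus-biological floor of 0.45 cycles (entirely
  realistic for FFPE material) makes the combination's averaging advantage
  real. Even so, recovery is ~97 of 100 seeds, not 100: the remaining
  misses are genuine small-sample rank flips among near-duplicate
  candidates, and we report them rather than engineering them away.
* *Counts must represent a whole library.* RPM divides by the realized
  column total, so a simulated matrix covering a few percent of the
  library transmits every planted up-regulation into an apparent global
  down-shift of everything else (an early version of the scenario produced
  exactly this compositional artifact). The dominant stable species keep
  the totals compositionally stable, as they do in real miRNomes.

What the generators do *not* emulate: amplification-efficiency
differences between assays (no Pfaffl correction anywhere), sequencing-read
structure (counts are drawn at the matrix level), isomiR collapsing,
batch structure beyond run offsets, and any dependence between the qPCR
and sequencing noise of the same miRNA. Passing the planted-truth tests
therefore demonstrates that the *computations* recover what the model
plants — not that the model captures everything FFPE cohorts do.

## Numerical conventions, in one place

* Undetected Ct: `NA` throughout; never a numeric sentinel.
* Sample SD: n−1 denominator everywhere.
* Ties in ranks: average rank; geNorm's terminal pair 1.5/1.5.
* NormFinder variances floored at 0; shrinkage factor 0 when its
  denominator is 0.
* CV denominator: |mean|, with a 0.05-cycle near-zero flag.
* log2FC pseudocount: 0.5 on both group means.
* Probability cutoff: score ≥ cutoff is positive.
* Shapiro–Wilk on a constant group: treated as non-normal rather than an
  error.
* All simulation entry points take a `seed` and restore the caller's RNG
  state; identical seeds give byte-identical outputs, which the pipeline
  report test checks literally.

## Problem sizes used by the test-suite and acceptance runs

The oracle-equivalence checks run on 5-gene × 6-sample instances against
brute-force reimplementations (agreement to 1e-12). Planted-truth
recovery uses 100 seeded cohorts of 30 + 30 for both the rank-last and
pair-selection properties; the type-I-error check runs 2000 null
comparisons at n = 30 + 30. These sizes were chosen so the whole suite
exercises every claim in well under a minute per property while keeping
Monte-Carlo error comfortably inside the asserted margins.

## Known limitations

The four stability statistics are described only qualitatively in most
applied papers; where variants exist we follow the original algorithm
publications and say so in the function documentation, but divergences
between web implementations and the originals cannot be ruled out. The
NormFinder caveats above mean its ranks among near-duplicate candidates
(combinations plus their members) carry little information. CV-based
exclusion depends on the candidate's distance from the calibrator pool's
level, so it punishes candidates whose abundance happens to sit near the
pool average — that is a property of the published rule, not of this
implementation. And everything the panel reports is in-sample.
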