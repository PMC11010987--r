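---
title: "Composite methylation risk scores from bias-based preamplification ddPCR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite methylation risk scores from bias-based preamplification ddPCR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrisk)
```

## The problem this package models

Total serum PSA cannot separate benign prostatic hyperplasia (BPH) from
prostate carcinoma inside the diagnostic grey zone of 2–15 ng/mL, which is
where most unnecessary prostate biopsies originate. Hypermethylated CpG
islands shed into blood plasma as cell-free DNA (cfDNA) offer an orthogonal
signal: tumour-derived fragments carry methylation marks that healthy
plasma background (mostly white-blood-cell DNA) lacks. The analytical chain
is:

1. **Marker discovery** on array beta values: find CpGs hypermethylated in
   tumour tissue against every relevant normal tissue, with near-zero
   methylation in white blood cells and healthy serum.
2. **Bias-based preamplification**: a PCR step whose primers and conditions
   amplify bisulphite-retained (methylated) template far more efficiently
   than unmethylated template, lifting rare tumour fragments above the
   detection floor.
3. **Droplet digital PCR (ddPCR)**: partition the reaction into ~20,000
   droplets, count two-channel fluorescence-positive droplets (FAM =
   methylated, HEX = unmethylated), and invert the positive fraction
   through Poisson occupancy statistics into copies/mL plasma.
4. **Composite risk scoring**: combine four methylation markers
   (*RASSF1A*, *MIR129-2*, *NRIP3*, *SOX8*) with cfDNA load, age, and
   optionally the percent free PSA (QfPSA) into an integer score, with
   cutoffs calibrated so no clinically significant tumour is missed.
5. **Cohort evaluation**: group tests via a normality/homoscedasticity
   decision tree, sensitivity/specificity, ROC/AUC, and biopsy-avoidance
   fractions.

Patient-level data behind the original study are not redistributable, so
the package ships a synthetic-cohort generator that reproduces the
*published group summaries*; every pipeline stage is exercised and tested
against that generator plus closed-form oracles.

## The measurement model

### Droplet partitioning and Poisson inversion

A well holds $n$ droplets (default 20,000, droplet volume 0.85 nL —
typical for the emulated instrument class). $C$ template molecules are
partitioned uniformly at random, so the per-droplet count is approximately
Poisson with occupancy $\lambda = C/n$ and

$$\Pr(\text{droplet positive}) = 1 - e^{-\lambda},
\qquad \hat\lambda = -\ln(1 - k/n),$$

where $k$ is the positive-droplet count. Copies in the reaction are
$\hat\lambda n$; the plasma-level quantity is

$$\text{copies/mL} = \hat\lambda\, n \cdot
\frac{V_\text{eluate}}{V_\text{input}} \cdot \frac{1}{g} \cdot
\frac{1}{V_\text{plasma}},$$

with the default volume chain 40 µL extraction eluate concentrated to
12 µL, 4 µL loaded per well, and $g$ the effective preamplification gain.
Whether published copies/mL figures are corrected for preamplification gain
is ambiguous in the source material; the package defaults to $g = 1$
(volumes-only rescaling) and exposes `preamp_gain` so either convention is
expressible. A saturated well ($k = n$) raises an error instructing
dilution rather than returning an infinite estimate.

### Amplitude model, baseline, and classification

Simulated droplets emit cluster-centred Gaussian amplitudes (negative
~1000 RFU, positive ~5000/4200 RFU on FAM/HEX, SD 100 RFU) plus a per-well
per-channel baseline offset (SD 50 RFU). A configurable `rain_fraction`
(default 2%) of droplets takes intermediate amplitudes, drawn uniformly
between the inter-cluster midpoint and the droplet's *own* cluster centre.
Keeping rain on its own side of the midpoint is a deliberate design
choice: it reproduces the visual artefact of intermediate droplets while
leaving the positive count a sufficient statistic, so estimator-recovery
tests can be held to exact binomial theory. Real rain can straddle the
threshold; the package does not claim to model instrument-specific gating
of such droplets (see Limitations).

Normalization estimates the well-specific baseline in two passes: the
median of droplets below the channel's 60th amplitude percentile locates
the negative cluster (negatives dominate at the low occupancies typical of
cfDNA), then the median over all droplets within five MADs of that
location re-centres the estimate without the truncation bias of the first
pass. Classification then thresholds at the midpoint of the two k-means
cluster locations, where each location is the *median* of its assigned
droplets (medians and MADs, not means and variances, so rain cannot drag
the centres). A well whose cluster separation is below 10 within-cluster
MADs is treated as single-cluster and yields zero positives — this gate is
what keeps template-free wells from producing phantom positives out of
rain. A fixed RFU threshold can always be supplied instead.

### Positive-call rule

A sample × marker combination is called positive only when at least two
replicate wells each show **more than five** positive methylated-channel
droplets. The rule deliberately discards marginal signals, because the
strongly methylation-biased preamplification would otherwise promote
single-molecule noise into calls.

## The preamplification bias model

Each cycle multiplies methylated template by $(1 + E_m)$ and unmethylated
template by $(1 + E_u)$, $0 \le E_u \le E_m \le 1$. After $c$ cycles the
bias statistic is

$$B = 100 \cdot \frac{N_m}{N_m + N_u}, \qquad
N_x = N_{0,x}(1 + E_x)^c .$$

The stochastic variant realises the same model as a branching process (per
cycle, each molecule duplicates with probability $E$), and its mean
matches the deterministic law — a property the test suite checks at 1,000
replicates to 2%.

Conditions are screened against three feasibility criteria on the 50 + 50
copy methylation standard: bias strictly above 90%, amplitude proxies
above configurable floors, and at least 500 unmethylated copies remaining
after preamplification (the unmethylated channel is the internal control
against false positives from exclusively methylation-specific
amplification). Annealing temperature and Mg²⁺ concentration are carried
as metadata only: the source material reports the efficiency–condition
relationship only as figures, so the model is parameterised directly by
$(E_m, E_u)$. The bias statistic is computed at $c = 12$ cycles
throughout — the cycle count at which the statistic is defined — even
though the full thermal protocol runs more cycles; the count is
configurable. The mean occupancy guard `cpd_check()` enforces the strict
copies-per-droplet ceiling of 6.

## Marker selection on beta values

`probe_contrasts()` compares tumour tissue against each normal tissue per
probe: `delta_beta` (difference of means) and a two-sample p-value.
Welch's *t* is the default test — the source material never names the test
behind its significance threshold, and Welch is robust to the unequal
variances typical of beta values; groups with fewer than five samples fall
back to a label-permutation test (999 permutations, deterministic seed).
Raw p-values are filtered at `alpha = 0.001` with **no multiple-testing
correction**, matching the published selection; a Bonferroni option exists
but is off by default. Constant probes take the convention
`delta = 0, p = 1`; missing betas are dropped pairwise, never imputed.

`select_markers()` keeps probes significant and hypermethylated
(`delta_beta > 0.2` by default) in *every* contrast, except contrasts
listed in `allowed_exceptions` — a mechanism that records, rather than
guesses, the published decision to carry one marker despite an elevated
normal-liver contrast. Background means in white blood cells and control
serum must stay at or below `max_background_beta = 0.10`, motivated by the
published healthy-background ranges (roughly 2–6% in serum, 3–9% in white
blood cells). Survivors are ranked by their worst-case margin (minimum
delta across non-exempt contrasts), ties broken by probe id.

## The composite risk scores

Four variants share one functional form: an additive threshold-count
score. Component $j$ with cutoff $\theta_j$ contributes a point when the
patient's value exceeds $\theta_j$ in its risk direction — strictly above
for methylated copies/mL, cfDNA load and age; strictly below for QfPSA.
The call is positive (biopsy indicated) when the score reaches the
decision threshold $\tau$: 3 of 6 components for the PSA-independent
piRISK variants, 4 of 7 for the PSA-dependent PRISK variants (which add
QfPSA). The published material prints integer decision cutoffs ("< 3",
"< 4") but not the score's functional form or component cutoffs (they live
in an unavailable appendix); the equal-weight count-of-exceedances form is
therefore a documented reconstruction, and whether marker positivity
should instead use the binary droplet-call is configurable through which
columns the model is given.

### Calibration

`risk_model()` calibrates $\theta$ under a hard constraint: 100%
sensitivity on the variant's target set (clinically significant plus
indolent tumours for variants 1, clinically significant only for variants
2), maximising BPH specificity among admissible parameterisations.
Candidate cutoffs are midpoints between consecutive order statistics of
each component (plus flanking values): for a step-function score the
optimum always lies between observed values, so this grid is lossless.

When the candidate grid has at most `exact_limit` (20,000) combinations
the search is exhaustive. Otherwise a deterministic multi-start coordinate
descent runs from (i) per-component marginal 100%-sensitivity cutoffs,
(ii) the all-flags parameterisation, (iii) every single-component rule
(one component decides at its marginal cutoff, $\tau - 1$ fillers flag
everyone), and (iv) every two-component rule. Starts (iii) guarantee the
fitted score never does worse than the best single component — in
particular PRISK2 can never undercut QfPSA alone. Each one-dimensional
move maximises specificity and, among ties, minimises the total number of
flags raised on BPH patients; this secondary objective gives saturated
configurations a descent direction and decreases monotonically, so the
search terminates. Remaining ties prefer more conservative positivity
(larger cutoffs for "above" components, smaller for QfPSA), then component
order, making the fit invariant to patient ordering. Every accepted state
satisfies the sensitivity constraint, which is re-asserted on the final
model. Heuristic descent can still return a locally optimal specificity;
tests compare it against an exhaustive oracle wherever the oracle is
computable.

## What the synthetic generator emulates — and what it does not

Group sizes default to the published cohort (90 controls, 40 BPH, 7
indolent, 32 clinically significant). Where group summaries are published
they are used verbatim: ages 67.4 ± 10.5 (BPH) and 71.8 ± 9.7 (PCa) years,
cfDNA 22.0 ± 17.7 / 47.4 ± 84.0 / 75.0 ± 135.6 ng/mL, *MIR129-2*
107.7 ± 151.1 / 172.0 ± 206.4 copies/mL, *CCDC181* 128.6 ± 529.9 /
108.5 ± 399.7 copies/mL (the marker that inverts between BPH and PCa and
is excluded from the scores). Remaining marker/group means are package
defaults chosen once to respect the published qualitative ordering
control < BPH < PCa.

Marker copies/mL and cfDNA are **zero-inflated log-normals**: every
published SD exceeds its mean, which rules out a normal model, and
methylated markers are genuinely absent in a fraction of samples. The
mixture is reparameterised so its overall mean and SD equal the configured
values exactly (this requires the zero fraction to stay below
$s^2/(s^2+m^2)$, which every published pair satisfies at the defaults
0.50/0.25/0.15/0.10 for control/BPH/indolent/cs). Ages are truncated
normals — [18, 30] years for controls (young blood donors recruited to
minimise undetected malignancy), [40, 95] for patients; tPSA is uniform on
the group's grey-zone interval (indolent disease below 10 ng/mL); QfPSA is
a truncated normal with group means descending from control to clinically
significant disease, consistent with low free-PSA fractions marking
malignancy.

Not emulated: inter-marker correlation within a patient (not published;
markers are drawn independently, and the generator accepts no copula in
this release), longitudinal follow-up and the late-diagnosed patients,
serum-versus-plasma matrix effects, and sequence-level artefacts of
bisulphite conversion. Passing tests on this generator therefore
demonstrate the *pipeline's* correctness and the scores' behaviour under
the published group distributions — not clinical performance on real
patients, where inter-marker dependence and pre-analytics will matter.

## Numerical choices and degenerate inputs

- Truncated-normal draws use inverse-CDF sampling (exact, no rejection
  loop); a zero SD collapses to the clamped mean.
- Extraction recovery and bisulphite survival act as one binomial thinning
  with probability `recovery * survival` (defaults 0.8 and 0.7).
- Duplicate wells are two independent partitioning realisations of the
  same underlying sample, each with its own eluate-loading draw.
- The simulator's default effective preamplification gains (64× methylated,
  4× unmethylated) are deliberately modest so default wells stay below the
  copies-per-droplet ceiling.
- `poisson_concentration()` errors on $k = n$; `fractional_abundance()`
  and the bias are undefined-as-error when both channels/templates are
  zero; `cpd_check()` uses the strict inequality (CPD = 6.0 fails).
- The gate tests of the evaluation decision tree run per group
  (Shapiro–Wilk) and median-centred (Levene); the published enumeration
  omits the non-normal homoscedastic combination, which this package
  routes to Kruskal–Wallis/Conover as the conservative completion.
  Games–Howell and Conover post hoc tests are computed from their standard
  formulas (studentized range / rank-based *t*), as no installed package
  was adopted for them; post hoc tests run only when the omnibus test is
  significant at 0.05.
- `roc_auc()` sweeps thresholds over unique score values with ties as
  simultaneous steps; on integer composite scores the curve is coarse and
  the AUC should not be over-interpreted. The AUC equals the
  concordant-pair fraction (rank-sum identity), which the tests verify
  exhaustively for small instances.

## Problem sizes used by the test suite

The suite checks estimator recovery at occupancies
$\lambda \in \{0.01, 0.1, 0.5, 1, 3\}$ with 200 replicate wells of 20,000
droplets each against 99% binomial-theory bands; branching-process means
at 1,000 replicates (2%); bias monotonicity over 1,000 random parameter
draws; condition screening against a brute-force re-check on 100 random
grids; calibration on 50 synthetic cohorts at the published group sizes
with the 100%-sensitivity constraint asserted on each, plus
exhaustive-oracle agreement on cohorts of up to 8 patients; the AUC
identity exhaustively over all labelings for up to 8 samples; and planted-
probe recovery on 50-probe matrices. These sizes were chosen as the
smallest that make the binomial/permutation bands sharp enough to be
informative.

## Known limitations

- The count-form score and its equal component weights are a
  reconstruction; published cutoff values are not reproducible.
- Coordinate-descent calibration is exact only when the candidate grid is
  small; otherwise it is a (well-started, deterministic) heuristic.
- The rain model never straddles the classification boundary, so
  misclassification from true intermediate droplets is not simulated.
- Published cohort AUCs (0.72–0.83) depend on unavailable patient-level
  data and are not reproduction targets; the package reports AUCs only on
  its own synthetic cohorts.
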