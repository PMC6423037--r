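---
title: "Methods: models, parameters and design choices in somatrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in somatrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(somatrace)
```

`somatrace` screens for recombinant bovine somatotropin (rbST) use from
milk-somatic-cell qPCR panels. This vignette documents the models behind
each stage, the parameters that matter, the numerical choices, and what the
synthetic-study generator does and does not emulate.

# The longitudinal design

Study day 0 is the day of the first dose; the conditioning period runs on
negative days. The default `StudyDesign()` encodes 3 control and 6 treated
cows, 12 doses of 500 mg every 14 days with a single 28-day gap between
doses 5 and 6 (so dose 6 falls on day 84 and dose 12 on day 168), 18
conditioning days and 54 follow-up days — a 240-day recording window — and
36 transcriptomic sampling days. The sampling grid includes every day the
reference experiment names in its text (−10, 1, 2, 3, 9, 14, 17, 23, 28,
30, 35, 44, 53, 57, 84, 91, 115, 219) and fills the remainder at roughly
weekly spacing; this is the package's own reconstruction, chosen once.

Treatment cycles are uniform 14-day bins by default (cycle 0 is the
conditioning window). The printed cycle table of the reference experiment
uses slightly irregular edges around the gap (e.g. days 43–57 and 58–70);
because no binning rule is stated, `assignCycle()` defaults to uniform bins
and accepts an explicit edge list for exact reproduction.

# The synthetic-study generator

The generator exists so that every downstream stage has ground truth. Its
defaults are the package's encoding of the reference experiment's reported
findings; they are study conditions, not tuning knobs.

**Expression.** For animal $a$, day $t$, gene $g$:
$$\log_{10} x = \mu_g + u_{ag} + \ell_{at} + \log_{10} k_g(\tau(t)) +
\varepsilon,\qquad \varepsilon \sim N(0, \sigma_g^2),$$
with gene baseline $\mu_g$, between-animal effect
$u_{ag}\sim N(0, 0.08^2)$, a per-sample RNA/cDNA loading effect
$\ell_{at}\sim N(0, 0.15^2)$ shared by all genes of a sample (it cancels in
reference-normalised ratios but produces the strong between-gene Cq
correlation that reference-gene validation relies on), and the dose
response $k_g$.

**Dose-response kernel.** $k(\tau) = 1 + A\,g(\tau)$ where $g$ is zero
before the onset, rises as a saturating exponential (time constant
`riseTau`) normalised to 1 at the peak day, and decays exponentially
(`washoutTau`) afterwards; with the default peaks near day 8–9 and washout
constants of 4–4.5 days the effect is below 5% of its peak by 28 days
post-dose, matching the observed return to control levels at day 84 (28
days after dose 5). Only the most recent dose acts (no accumulation).

Amplitudes are anchored to printed group means: IGF-1R has a fast rise
(onset 0, `riseTau` 0.55) and amplitude 3.5, reproducing the day-1
treated/control group-mean ratio of ≈3.9 (0.348 vs 0.0898); CCND1, TNF and
IL-1β peak in the second week with amplitudes 4–5. The weak responders
SIRT2, TPD52L2 and EEF1G respond only to a random subset of doses
(per-dose Bernoulli, shared across animals, probabilities 0.15–0.2 ≈ 2 of
12 doses) with modest amplitudes — SIRT2's amplitude 2.0 reproduces its
single-cycle day-23 contrast (1.517 vs 0.506) when the dose responds.
LTF, MFGE8 and CTNNAL1 are noisy non-responders; IGFBP3, IGFBP5, COL3A1
and ESR2 are never detected; IGF1 is detected per animal (probability 1/6,
treated animals only, mirroring the observed single responding cow); UXT,
RPS9 and GPAM are stable references whose geometric-mean abundance is ~1.

The between-animal sd (0.08 in log10) is deliberately below the day-to-day
residual sd (0.2–0.35). With only 9 animals, a larger animal effect lets a
null gene's chance alignment of animal effects with the group assignment
mimic a persistent treatment shift — which would contradict the reported
dominance of the four markers. This is an assumption about real MSC data,
not a measured quantity; it is the main caveat when reading the end-to-end
recovery results.

**Milk yield.** Wood's lactation curve
$y(t) = a\,t^{b}e^{-ct}$ (defaults $a=13.7$, $b=0.30$, $c=0.004$: peak
≈37 kg/day at 60–90 days in milk) with a per-animal log-normal scale
(sd 0.12), daily noise (sd 2.5 kg), and for treated animals a multiplicative
boost $1 + 0.45\,r(t)$ where $r$ ramps up over 28 days from the first dose
and decays (time constant 20 days) whenever more than one dose interval has
elapsed since the last dose. The decay term produces the production-
difference trough during the mid-study gap and the post-treatment decline;
the 0.45 boost reproduces the ≈43% cycle-12 difference. Both groups share
the same days-in-milk distribution (70 ± 4 at first dose) so that a zero
boost makes the groups exchangeable.

**Raw curves.** Per replicate,
$X(c) = X_0 E^{c} / (1 + X_0 (E^{c}-1)/K)$ and
$F(c) = s\,(B + X(c)) + N(0, \sigma)$ with per-gene efficiencies drawn
uniformly on [1.7, 2.0], plateau $K = 3000$, baseline $B = 50$, noise sd 1,
multiplicative session factors (log-sd 0.25, geometric mean 1) over
sessions of 56 samples, $X_0$ proportional to true abundance
(`x0Scale` $10^{-4}$) with a 5% replicate effect. Undetected gene-samples
give flat baseline-only curves.

**What the generator does not emulate:** mastitis or other confounders
(hooks exist as covariates but are unimplemented), pharmacokinetics,
dose-to-dose carry-over, probe chemistry, inhibitors or melt behaviour,
and the irregular per-day sample availability of a real farm (every animal
is sampled on every sampling day). Passing tests therefore demonstrate that
the pipeline recovers the structure this generator encodes — not that real
MSC data will be as clean.

# Curve quantification

The baseline is a constant. It is first estimated as the mean of the
pre-amplification cycles (cycles before the fluorescence leaves the
early-cycle noise band) and then refined on a 201-point grid within ±2
standard errors of that estimate, maximising the log-linear r² of the best
window. The anchoring matters: an unconstrained baseline search can always
straighten some 4–6 cycle window (oversubtraction bends the low end up,
the plateau bends the top down), which systematically biases the
efficiency; anchored, the refinement only sharpens the fit.

The window of linearity is 4–6 consecutive cycles, above the noise floor
(3 × sd of the first five corrected cycles) and below 5% of the observed
plateau — the early exponential phase, where the logistic's per-cycle ratio
still equals the true efficiency (at fluorescence $F$, the apparent
per-cycle ratio is $E/(1 + F(E-1)/K)$, so windows near the plateau read
low). Among windows whose r² is within 0.002 of the maximum the steepest is
chosen (plateau bending only ever flattens the log-slope); exact ties go to
the later, then the longer window. Under the generator's conditions this
recovers mean amplicon efficiencies within ±0.02 of truth across
E ∈ [1.7, 2.0].

Per amplicon, wells with $|E - \mathrm{median}(E)| > 0.05$ are excluded
from the mean efficiency but keep their own log-linear fit and are still
quantified — dropping them entirely would discard ~20% of wells and no gene
could survive a zero-missing filter. The quantification threshold $N_q$ is
one per amplicon: the geometric mean of the window-midpoint fitted
fluorescences over that amplicon's good wells. $C_q$ is the fractional
cycle where the well's fitted segment crosses $N_q$ (flagged if more than 3
cycles outside the window) and $N_0 = N_q / \bar E^{C_q}$, which makes
$N_0\,\bar E^{C_q} = N_q$ an identity.

# Session correction, reference validation, relative expression

Between-session ratios are geometric means, over shared conditions
(default key: gene × group), of condition-mean ratios. The default factor
estimator takes the geometric mean of each session's row and renormalises
to geometric mean 1 (corrected data keep their scale on average); the
maximum-likelihood option alternates condition/session effects on log
means until the change is below 1e−10. With complete condition overlap the
ratio matrix is exactly consistent and both estimators annihilate it
exactly; the noisy-round-trip tolerance (2%) binds only under partial
overlap. A disconnected session graph is an error naming the unbridgeable
groups.

Reference validation follows the BestKeeper conventions: the dispersion
statistic is the mean absolute deviation of Cq from the gene's geometric
mean (inconsistent above 1 cycle), the index is the per-sample geometric
mean over candidates, and candidates need Pearson r ≥ 0.7 with the index.
Correlation p-values are descriptive (no multiplicity correction).

Relative expression is target $N_0$ over the geometric mean of the three
reference $N_0$s — the only dimensionally coherent reading of
reference-geometric-mean normalisation. Replicates are aggregated by
arithmetic mean of usable wells (geometric optional). The inclusion filter
is deterministic and ordered: genes with any missing detection are dropped
first (plus CTNNAL1, excluded a priori as detected-but-uninformative), then
samples missing any retained gene; it is idempotent.

# Univariate statistics

The two-group gate: both groups pass the Lilliefors-corrected KS test at
α = 0.05 → t-test (pooled if Levene's p ≥ 0.05, Welch otherwise);
otherwise Mann–Whitney U, exact when min(n) ≤ 8 without ties, tie-corrected
normal approximation otherwise. Groups too small to test for normality
(n < 4; the control group has n = 3) are treated as passing — the design's
per-day comparisons would otherwise never use the t-test the reference
analysis reports. All tests are two-sided; stars are a pure step function
at 0.05/0.01/0.001. The gate's realised type-I rate is ≈4.9% (measured at
10,000 null simulations).

The cycle-wise yield table computes the percentage production difference
per day — $100(\bar y_\text{rbst} - \bar y_\text{ctl})/\bar y_\text{ctl}$
— then averages over the cycle's days (the only reading that yields an sd
for the difference), and compares animal-day values between groups.

# Multivariate screen

Preprocessing is $\log_{10}$ followed by Pareto scaling
(centre, divide by $\sqrt{\mathrm{sd}}$); zero-variance columns are dropped
with a warning and the centre/scale are stored for projecting unknowns.

PCA is NIPALS (convergence when the relative score change is below 1e−12,
up to 5000 iterations — close eigenvalues slow the power iteration; a
non-converged component is an error), deflating after each component;
per-component R²X is the removed sum of squares over the total. On
complete data it agrees with the SVD to 1e−6, which the tests assert.

Hotelling's $T^2_i = \sum_a t_{ia}^2/\mathrm{var}(t_a)$ with the
$(N^2-1)$ chemometrics limit
$\frac{A(N-1)(N+1)}{N(N-A)}F_{1-\alpha}(A, N-A)$ (the $(N-1)$ variant is a
flag). DModX is the row residual sd normalised by the pooled residual sd,
with the critical limit $\sqrt{F_{1-\alpha}(K-A,(N-A-1)(K-A))}$. Outlier
exclusion is the union of the two 95% criteria, applied once (no
iterative refitting).

OPLS-DA: predictive weight $w \propto X^\top y$, orthogonal components
extracted from the loading's part orthogonal to $w$ and deflated; the
number of orthogonal components grows while the 7-fold cross-validated Q²
improves by more than 0.01 (max 3). Folds are deterministic: samples
sorted by id, assigned round-robin — reruns are byte-identical. The
predictive score is oriented so the treated-class mean is positive, making
the S-plot's upper-right corner reproducibly mean up-regulated under
treatment. S-plot coordinates are $p_1 = t^\top x_g/(N-1)$ and
$p(corr)_1 = p_1/(s_t s_{x_g})$; biomarkers are ranked by $|p(corr)_1|$
(ties by $|p_1|$) with a default panel threshold of 0.4.

CV-ANOVA compares the cross-validated predictive residuals against those
of the training-fold-mean-only model under the same folds:
$F = \frac{(\mathrm{PRESS}_0 - \mathrm{PRESS})/A}{\mathrm{PRESS}/(N-1-A)}$
with $A$ the number of fitted components, truncated at 0 (p = 1) when the
model does no better than the mean. The F reference is accurate at
moderate sample size (≈5% null rejection at N = 30) and grows conservative
for large N (2–3% at N ≥ 60) — a known property of the approximation; the
package's calibration checks use N = 30.

Screening unknowns projects new samples through the stored preprocessing
and model (orthogonal components removed first) and flags predictive
scores above the control population's 95th percentile. Because the
training controls' scores reflect a fitted model, the realised flag rate
on fresh control samples runs somewhat below 5% — conservative in the
direction that matters for an accusation-adjacent screen. Samples missing
a panel gene are rejected with a reason, never projected.

# Problem sizes and determinism

The test suite and the acceptance script simulate at the design's own
scale: 324 samples × 9 genes for multivariate stages, 500 wells for curve
recovery, 100 replicate studies for end-to-end marker recovery, 6000 null
comparisons for the type-I rate and 500 datasets for CV-ANOVA calibration.
All generator randomness is governed by a single integer seed; every stage
restores the caller's RNG state.

# Known limitations

* The animal-confounding caveat above: with 9 animals, marker recovery
  depends on between-animal variability being smaller than residual noise.
* The baseline model is a constant; drifting baselines are not modelled.
* CV-ANOVA is conservative at large N; its p-values are best read as
  ranks, not calibrated tail probabilities, for studies of hundreds of
  samples.
* The screening decision rule is a single percentile threshold on one
  score; it does not model per-farm baselines or repeated sampling of the
  same animal.
* Session labels are input metadata; the package does not infer runs.
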