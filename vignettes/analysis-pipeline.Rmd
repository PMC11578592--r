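---
title: "Saccadic vigour, preparatory EEG, and mediation: the analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saccadic vigour, preparatory EEG, and mediation: the analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigoureeg)
```

## The scientific problem

Incentives make people respond sooner and move faster. In an
incentivised-saccade design, a participant fixates one of three circles
11° apart, hears an incentive cue (50p or 0p maximum reward), sees a
preparation cue, and 1500 ms later makes a speeded saccade to a dimmed
target while a salient distractor sometimes lights up. Run once under
placebo and once under a muscarinic M1 antagonist (trihexyphenidyl,
"THP"), the design asks three questions:

1. Does muscarinic blockade blunt the invigoration of saccades by
   incentives (drug × incentive interactions on velocity and RT)?
2. Is preparatory cortical activity — the contingent negative variation
   (CNV), a slow negativity building between the preparation cue and the
   target — modulated the same way?
3. Does the CNV *explain* (mediate) the incentive effects on behaviour,
   and the drug's moderation of them?

This package implements the full measurement and inference chain for
that design, plus a synthetic-data generator that emulates the study's
trial, eye-trace, and EEG structure, so every stage runs and is testable
without any external recording.

## Behavioural measures

**Residual peak velocity (vigour).** Peak velocity grows with amplitude
(the main sequence), so raw velocity confounds motivation with movement
size. Within each participant × drug session we regress peak velocity on
amplitude (OLS, intercept included, pooling incentive and distractor
levels) and keep the per-trial residual. Fitting within session removes
any overall drug effect on velocity, amplitude, or their relation —
which is why the drug *main effect* on residual velocity is ~0 by
construction, while within-session incentive and interaction effects
survive. Within every group the residuals have exactly zero mean and are
orthogonal to amplitude; both identities are asserted to 1e-8 in the
tests.

**Saccadic RT.** Time from target onset to saccade onset; analysed on
the log scale. The parser estimates per-sample speed with a centred
4 ms sliding window (central differences, then a moving average), masks
segments faster than 3000°/s or with tracking loss, marks saccades where
speed exceeds 30°/s or acceleration 8000°/s² (the OR combiner is the
default; AND is available), and takes the first saccade over 1° in
amplitude with onset between 100 and 900 ms. Trials whose peak velocity
falls outside 50–1600°/s are excluded. Because a threshold crossing
necessarily lags the true movement onset, the onset is back-extrapolated
by `2·v/v̇` (exact for the quadratic rise of a minimum-jerk profile);
this keeps parsed RTs within ±2 ms of the generator's ground truth.

**Distractor pull.** The signed angle between the fixation→gaze vector,
taken when gaze first leaves a 1.5° fixation circle, and the
fixation→target line; positive is toward the distractor, and the sign
flips if the distractor is mirrored across the target line (a tested
invariant). The circle radius is not part of the original description;
1.5° is a configurable default. Angles live in (−180°, 180°], ties at
−180° map to +180°.

## ERP measures

Epochs are trials × channels × samples at 256 Hz, windows are always
half-open `[start, end)` on sample times (so the 1200–1500 ms window at
256 Hz anchored at −200 ms holds exactly 77 samples). The three
window-mean measures at Cz are: P3a (200–280 ms after the preparation
cue), CNV (1200–1500 ms after the preparation cue), and a
pre-preparation measure (900–1100 ms after the incentive cue, baselined
100 ms before that cue — the mirrored rule, since the original wording
is ambiguous). Baselining subtracts the mean of the 100 ms before the
epoching event and is idempotent. Artifact rejection drops a trial iff
any channel sample exceeds ±200 μV or a blink/saccade was flagged during
the epoch.

A `preprocess()` step (mastoid-average reference, 0.1–80 Hz Butterworth
band-pass applied forward–backward, Butterworth band-stop notch at
50 Hz, integer-factor downsampling) is provided and verified against
spectral oracles. The filter orders are configurable defaults (2nd-order
high-pass, 4th-order low-pass, 2nd-order stop-band): the original report
names the filter families but not the orders. Synthetic epochs are
generated directly at 256 Hz, so this stage is exercised on constructed
signals rather than sitting in the main synthetic path.

## Single-trial mixed models

Every inference runs through one model family:

```
outcome ~ 1 + incentive * distractor * THP + (1 | participant)
```

with all factors and the outcome z-scored over the analysed trials
(population-SD convention; interaction columns are products of the
z-scored parents and are not re-standardized), so coefficients are
standardized. RT is log-transformed before standardization. Estimation
is by maximum likelihood — not REML — so coefficients remain comparable
across the nested model sequences used in mediation. Degrees of freedom
are reported as n − k and p-values come from the t distribution on them;
no Satterthwaite correction is attempted.

Two engines fit the same model: `lme4::lmer(REML = FALSE)` and a
profiled-ML solver written here. With a single random intercept the
fixed effects and residual variance profile out analytically, leaving a
one-dimensional optimisation over the variance ratio λ = τ²/σ²; each
objective evaluation costs O(G·p²) after one O(N·p) pass. The two
engines agree to 1e-5 in the tests; the profiled solver is the default
because mediation and cluster nulls refit it thousands of times.

The ERP ~ behaviour matrix (`fit_erp_behaviour_models()`) regresses each
of the three window measures on each behavioural variable with the
factorial terms as covariates, and compares the behaviour term to a
Bonferroni threshold of 0.05/9.

## Cluster-mass permutation inference

The window-free analysis regresses behaviour on voltage at every
electrode × time node. Nodes whose |t| exceeds a cluster-forming
threshold (default: the two-tailed 5% critical value at the engine's
df — unreported in the original, so configurable) are clustered by
connectivity (spatial neighbours at the same sample, same electrode at
consecutive samples; spatial neighbours are electrodes within a layout
distance chosen to give a median degree of ~6) with same-sign
membership; the cluster statistic is the mass Σt. The null is the
maximum |mass| over permutations that shuffle voltages across trials
*within each participant × condition cell*, leaving behaviour untouched;
p = (1 + #{null ≥ observed}) / (n_perm + 1) (add-one smoothing, so p is
never 0), two-tailed through the absolute mass, FWER 0.05.

Whether the original per-node regressions refit the full mixed model on
every permutation is not stated; both paths exist here. The `"lmm"`
engine fits the random-intercept model per node and is the reference;
the default `"ols2"` engine residualizes behaviour and voltage against
the factorial design within participant, takes per-participant slopes,
and tests them across participants (df = P − 1). The two agree on
planted signals in the tests, and FWER calibration (500 null datasets,
8 electrodes × 50 samples, 200 permutations) is run with the same
engine that builds the null, as it must be. On toys small enough to
enumerate every within-cell permutation, the Monte-Carlo p matches the
exact p. Permutations are seeded counter-style (`seed + i`), so runs are
reproducible and order-independent.

The same machinery runs in one dimension over angle bins for the
distractor-pull density curves (participant-level sign-flip null), and
in "difference" mode for condition difference waves.

## Mediation and mediated moderation

Four-step mediation, all models ML random-intercept fits on the
identical trial subset (trials with a valid mediator, even for the
models that do not include it):

1. `Y ~ 1 + X` — total effect β_total;
2. `M ~ 1 + X` — the a-path;
3. `Y ~ 1 + X + M + X:M` — the b-path and the direct effect β_direct
   (the interaction term follows the fuller of the two formulas in the
   source report; it is switchable).

The statistic is Δ|β| = |β_direct| − |β_total|; negative means
mediation. Its null shuffles the mediator across trials within each
participant (a within-cell option also exists) and refits model 3;
the one-tailed p is the proportion of the null with an equal or more
negative change, add-one smoothed. The p is withheld unless steps 1–3
are individually significant at 0.05. Mediated moderation repeats the
scheme on the interaction: models 5–7 add the moderator W, and the
statistic is the change in the |X:W| coefficient between models 7
(which adds M and M:W) and 5. The gates are the two moderation steps
(X:W on outcome and on mediator); the reduction itself is the measured
quantity, so model 7's M:W term is reported but does not gate.

Degenerate cases are explicit: a constant mediator returns Δ|β| = 0
with the p withheld, and a single-participant fit reproduces the
ordinary-regression Baron–Kenny computation to 1e-6.

## The synthetic-data generator

Defaults are the study conditions: 20 participants × 2 counterbalanced
sessions (placebo, THP) × 20 blocks × 24 trials (6 per condition per
block — 480 per session, 120 per condition); planted standardized
effects equal to the published single-trial regression tables; lognormal
RTs (median ≈ 280 ms, log-SD 0.2); main-sequence velocities (slope
30 (°/s)/°, intercept 150 °/s, per-participant jitter); an equilateral
triangle geometry with 11° sides (the original states only the 11°
separation, so the layout is a modelling choice exposed in the config);
EEG artifacts at rate 0.134 and unusable saccades at rate 0.032, chosen
to reproduce the reported trial counts (≈16,627 EEG-clean and ≈18,585
behaviourally valid of 19,200).

Every outcome is constructed as a unit-variance standardized latent —
planted βs on the ±1 factor codes, a participant intercept where the
analysis does not remove it, and Gaussian residual whose variance is
solved so the total is exactly 1 — then mapped to physical units. The
pipeline's z-score-then-fit step therefore recovers the planted
standardized βs without attenuation, which is what the recovery and
coverage tests check. Velocity carries no planted participant intercept
and a ≈0 drug main effect, because within-session residualization
removes both identically.

The mediation pathway is planted in the same currency: the CNV latent
M* carries the published table's factorial effects, and log RT adds
`b·M* + b_THP·M*·z_THP` with b = 0.1264 and b_THP = 0.0139 (the reported
per-μV coefficients times the implied ≈9.95 μV CNV SD); velocity adds
b = 0.0149. The direct coefficients subtract the indirect contributions
(exact, because products of ±1 factor codes are closed under
multiplication), so the behavioural totals stay at the table values and
the mediation Δ|β| values (≈ −0.0116 for RT, ≈ +0.0014 for velocity, ≈
−0.0008 for the moderation) are emergent, not hard-coded.

Eye traces are straight minimum-jerk saccades (peak velocity =
1.875·A/D, so the duration is solved from the planted velocity) after a
fixation period equal to the planted RT, with 0.01° position noise —
realistic velocity envelopes are all the parser needs. EEG epochs are a
P3a Gaussian bump (240 ms latency, 30 ms width) plus a linear ramp from
500 ms, attenuated over a 16-channel layout by a Gaussian spatial
falloff, plus white channel noise; the ramp slope and bump amplitude are
solved per trial *after* the noise draw so the baselined window means at
Cz equal the planted values exactly. Distractor-pull angles come from a
two-component mixture — a repulsion-shifted target component and a
capture component centred on the distractor direction whose weight rises
with distractor salience and is modulated by the drug; the planted
standardized pull effects are honoured to first order only (the
calibration of mixture weights to standardized βs is approximate by a
few percent, documented rather than iterated away).

What the generator does **not** emulate: volume conduction or
oscillatory EEG, blinks as physiological waveforms, saccade curvature,
amplitude effects of reward, a distinct frontal (non-Cz) pathway for
velocity, or pupil data. Passing tests therefore show that the
*inference machinery* is correct and calibrated under the planted
structure, not that the biological claims hold in real data.

## Numerical choices and problem sizes

- z-scoring divides by the population SD (n); βs are invariant to the
  n vs n−1 choice because outcome and predictors share it.
- The λ profile is optimised on the log scale over e^±14 with an
  explicit λ = 0 boundary check; ties prefer the boundary (OLS).
- Angle wrap-around: (−180°, 180°], −180° ties to +180°.
- Time is in ms with t = 0 at the epoching/target event; intervals are
  half-open; sample indices are 0-based in the sidecar metadata.
- The test suite runs the full study scale (20 × 960) for the recovery
  and coverage studies (100 seeds), 500 null datasets at 8 × 50 nodes
  for FWER calibration, 150 null datasets for mediation type-I, and
  exhaustive enumeration on 6–8-trial toys; the whole suite completes in
  roughly ten minutes on one core.
- The analysis scripts run mediation at 2500 permutations (the study's
  count) in under a minute thanks to the profiled solver; the
  cluster-regression demonstration uses 10 participants, a 16-channel
  montage at 32 Hz effective resolution, and 200 permutations.

## Known limitations

- The profiled solver covers exactly one random intercept; random
  slopes or crossed effects are out of scope (as in the source design).
- The two-stage cluster engine is an approximation to the mixed model;
  it is the default for permutation tractability and is validated
  against the `"lmm"` engine on small grids, but the two can diverge
  when participants contribute very unequal trial counts.
- The pull mixture's standardized effects are first-order calibrated;
  recovered pull βs can deviate from the plants by a few percent.
- EEG and behavioural validity are drawn independently, so the
  mediation subset (≈16,100 trials) is slightly smaller than the
  EEG-clean count; the reported study's subsets overlapped differently.
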