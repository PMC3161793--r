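---
title: "Modeling audiovisual localization: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling audiovisual localization: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avlocnet)
```

## The generative model

Six random variables describe one localization trial: the task `s` (0
acoustic, 1 visual), the mode of presentation `m` (0 unisensory, 1
bisensory), the primary stimulus position `xp` (degrees of azimuth), the
secondary position `xs` (degrees, with a sentinel category for unimodal
trials), the percept `xhat` (the subject's pointer response after
normalization), and the decision time `t` (seconds from stimulus onset to
movement onset). The package's target object is the factorization

$$P(s)\,P(m)\,P(x_p)\,P(x_s \mid m)\,P(\hat x \mid s, x_p, x_s)\,
  P(t \mid s, x_s),$$

with multinomial distributions for the discrete factors, a Gaussian
conditional for the percept per parent configuration, and a log-normal
conditional for the decision time (log decision times are close to normal).
The structure itself is not assumed: it is elicited from data by
information-theoretic independence tests, and the factorization above is
what those tests recover from the default simulator (`canonical_factorization()`
provides it directly).

Key modeling assumptions: the percept integrates the audiovisual
information in the acoustic task (a fusion weight `w` pulls the response
toward the visual distractor) and segregates it in the visual task; the
decision time depends on the sensory nature of the target and on the mode
of presentation, but not on the primary position; subject identity enters
only through a sensorimotor response offset (removed by normalization) and
mild dispersion differences.

## The synthetic-subject simulator

No public dataset accompanies the behavioral protocol, so the package ships
a seeded generator (`simulate_dataset()`) whose *defaults are the study
conditions*; all tests and the acceptance script run against them.

Per subject and task the design enumerates 450 trials: 75 unimodal (15 per
primary position), 75 spatially coincident, 300 non-coincident (offsets
±5/±10 deg; secondaries span −20…20 deg). Ten subjects and both tasks give
9000 trials.

Calibration of `sim_params()` defaults, fixed before the evaluation suite
was built:

* **Localization noise SDs** (deg): acoustic unisensory 7.5, visual
  unisensory 2.8, acoustic bisensory 5.8, visual bisensory 3.1 — the
  protocol's printed dispersion statistics (3.1 splits the difference
  between the printed coincident and non-coincident visual values). Each
  subject's SDs are jittered by 10% between subjects.
* **Fusion weight**: population mean 0.972 with between-subject SD 0.15,
  clipped to [0, 1]. The mean solves the variance identity
  $E[w^2]\cdot 62.5 + E[\sigma_{a,bi}^2] + \kappa^2/2 + v_{norm} = 9.5^2$,
  where 62.5 is the variance of the equiprobable non-coincident offsets,
  $\kappa$ the task-offset SD below and $v_{norm}$ the residual variance of
  the normalization estimate — so the pooled non-coincident acoustic SD
  reproduces 9.5 deg.
* **Sensorimotor offsets** (deg): a shared bias (between-subject SD 3)
  plus small task-specific offsets ($\kappa$ = 2 per task). Real subjects'
  auditory and visual spatial maps are calibrated slightly differently;
  the shared component is what normalization removes, and half of the
  differential component survives it. A mean task difference of zero keeps
  this consistent with the observation that the bias does not differ
  significantly between tasks.
* **Decision times**: log-normal with locations ln 0.95 / ln 0.80 /
  ln 0.75 / ln 0.62 s for acoustic-uni / acoustic-bi / visual-uni /
  visual-bi (the published analysis prints only F statistics, so the
  levels are free calibration constants respecting both orderings), a
  log-scale bump of 0.10 for maximally eccentric secondaries (|xs| = 20) in
  the acoustic task, within-subject log-SD 0.41 and a between-subject
  log-offset SD of 0.02. The dispersion pair (0.41, 0.02) was derived from
  the closed-form expectation `r2_expected()` — the unexplained variance of
  a held-out subject's cell mean is the within-cell variance over 15
  trials plus the offset variance — so that the cross-validated
  decision-time R² lands near the published cell-level and collapsed-mode
  values. An optional primary-eccentricity effect exists
  (`delta_ecc_primary`) and defaults to zero, keeping the decision time
  independent of `xp` as the published model requires.
* **Kinematics**: minimum-jerk pointer trajectories from the 40-deg
  neutral stop, movement duration log-normal around 1.0 s independent of
  condition (movement time showed no condition effects). Trajectories are
  generated on demand for testing the feature extractors; the trial table
  carries the generator's decision and movement times directly.

What the generator deliberately does **not** emulate: position-dependent
response nonlinearities, sequential (trial-order) effects, attention
lapses, eye movements, and any subject-by-stimulus interaction beyond the
fusion-weight and task-offset heterogeneity. Passing tests therefore show
that the pipeline recovers the statistical structure it assumes, at
realistic noise levels — not that real data contain no further structure.

## Preprocessing

Movement onset (end) is the first sample at which the pointer speed rises
above (falls below, and stays below) 1.5 deg/s; velocity is estimated by
centered differences after a 3-sample moving average, since only the cutoff
is prescribed. Decision time = onset − stimulus onset; movement time =
end − onset; the endpoint is the median hold-phase position. Onset
detection necessarily lags true movement start by the threshold-crossing
time of the minimum-jerk speed profile (≈35 ms for a 40-deg movement); the
tests verify detection against a brute-force scan of the closed-form speed
at the sampled grid, to within one sample period.

Normalization subtracts each subject's mean raw response over unisensory
trials pooled across both tasks (the design positions average to zero, so
this removes the bias estimate); it is idempotent, and every subject must
have unisensory trials.

## Discretization

Fixed histogram binnings (`binning_for()`): 5 width-5 bins for `xp`; 9
width-5 bins plus a sentinel bin for `xs`; 15 bins for `xhat` (13 width-5
bins centered −30…30 plus two boundary bins covering the pointer stops);
two bins for `s` and `m`; width-0.2 s bins for `t` on a grid from 0 to the
empirical 99th percentile, plus one overflow bin. Intervals are half-open
`[a, b)` with the last regular bin closed; values exactly at ±32.5 deg
belong to the inner width-5 bins. Densities are maximum-likelihood plug-in
histograms; entropies are in bits (normalized MI is base-invariant, so the
base is presentational).

## Structure elicitation

Pairwise dependence is scored by MI normalized by the joint entropy so that
values are comparable across pairs, and compared against *null-calibrated
thresholds*: the 0.95 quantile of the normalized MI over 100 artificial
datasets of the same size in which every variable is an independent
discrete uniform over its bins. The quantile policy (rather than a mean or
maximum over the null replicates) is a documented choice; it makes the
per-pair false-positive rate 5% by construction. Thresholds are recomputed
for the tested subset's size, and conditional thresholds draw the
conditioning variable uniform as well.

Design choices the elicitation rests on, each of which proved necessary:

* **Design-coupled pair exclusion.** The protocol places the secondary at
  offsets from the primary, so `xp` and `xs` are strongly dependent *by
  construction* (normalized MI ≈ 0.11 from the design alone; the package
  detects it when asked, `exclude = NULL`). That dependence describes the
  stimulus-delivery protocol, not perception, and no conditioning set can
  remove a direct coupling — so the pair is excluded from the candidate
  edge set by default and recorded as a non-adjacency with an empty
  separator. This is exactly what licenses the collider
  `xp -> xhat <- xs` during orientation.
* **Input-tier conditioning.** Conditioning sets (sizes 1–2, from each
  endpoint's adjacency) are drawn from the input variables
  `{s, m, xp, xs}` only. Conditioning an edge test on an *output* (`xhat`,
  `t`) invites selection bias — the outputs are common effects of the
  inputs — and the 14–15-level output binnings inflate the plug-in bias of
  the null until weak true dependences (the decision-time links) drown in
  it. Two-variable sets are required because `t` and `xhat` share two
  common causes (`s` and `xs`); no single conditioner separates them.
* **Redundancy veto and removal order.** The sentinel bin makes the mode
  deterministic given the secondary position, `m = f(xs)`. Consequently
  `I(t; m | xs) = 0` exactly *and* `I(t; xs | m)` is small: tested naively,
  each edge removes the other and the decision-time node disconnects.
  Removals are therefore greedy in ascending order of the normalized CMI
  statistic (the exactly-zero redundant test goes first), and a variable
  `z` is vetoed as a separator for edge `x–y` when the `z`-edge to one
  endpoint was itself removed with the other endpoint as its separator.
  This retains `t – xs` over `t – m`, matching the published model's
  reading that the secondary position carries both the mode and the
  location of the accessory information.
* **Orientation.** Colliders `x -> z <- y` are declared for unshielded
  triples with `z` outside the recorded separator of `(x, y)`, processed
  in decreasing order of the separation margin (how decisively the pair
  tested independent) so that unambiguous independences orient first; a
  candidate that would reverse an existing arrow is skipped and *reported*
  in the `conflicts` field, never silently resolved. Meek propagation
  rules then run to exhaustion. The `m – xs` edge remains undirected in
  the PDAG and is resolved as `m -> xs` only at factorization time, where
  the conditional `P(xs | m)` needs a direction.

Context-specific independence is explored with multinets
(`csi_local_networks()`): fixing `s` (or `m`) to each value, dropping the
column, and re-running the elicitation on the remaining five variables. On
default data the local networks reproduce the fusion/segregation
asymmetry: `xhat` is adjacent to `xs` in the acoustic context only, while
the decision-time links persist in both.

Known limitations of the elicitation: in the bisensory (`m = 1`) context
the only remaining decision-time signal is the small eccentricity bump, so
the slight `t – xs` dependence is usually below threshold at this sample
size; and because `xs` is yoked to `xp`, that bump can surface as a weak
`t – xp` edge instead — an artifact of the design coupling, not of the
generator's causal structure.

## Fitting and MAP inference

`fit_model()` is pure maximum likelihood: empirical frequencies for the
multinomials, per-configuration sample mean/SD for the Gaussian percept
factor, mean/SD of log seconds for the log-normal time factor. No
smoothing or priors; parent configurations with fewer than two
observations are flagged and inference on them is refused rather than
backed off. The full factorial design guarantees 15 observations per
condition cell, so flags never fire on default data.

The MAP percept is the mode of the Gaussian conditional — its mean, which
also equals the training-cell sample mean. For the decision time,
`map_decision_time()` exposes three point summaries of the log-normal
conditional with location $\mu$ and scale $\sigma$: the density mode
$e^{\mu-\sigma^2}$, the median $e^{\mu}$, and the conditional expectation
$e^{\mu+\sigma^2/2}$. The cross-validation compares point predictions to
held-out *arithmetic* cell means, and the only summary that is unbiased
for an arithmetic mean is the conditional expectation: at the calibrated
dispersion the mode under-predicts every cell by
$e^{-1.5\sigma^2} \approx 0.78$, a common multiplicative deficit that no
dispersion setting can reconcile with the published collapsed-mode
accuracy. `crossvalidate()` therefore defaults to the mean
(`dt_type = "mean"`); the mode and median remain available, and for the
percept the distinction vanishes (a Gaussian's mode, median and mean
coincide).

A note on normalization: because the design couples `xp` and `xs`, the
product $P(x_p)P(x_s|m)$ assigns mass to stimulus pairs the protocol never
delivers, where the conditionals are undefined. The discretized
factorization integrates to 1 over its domain whenever the input
distribution actually factorizes this way (verified in the tests on
independently sampled positions); on the yoked design it is a conditional
model of the outputs given the delivered stimuli.

## Evaluation

Folds are exact leave-one-subject-out: with 10 subjects, the exhaustive
deterministic partition is the canonical form of a 10-fold scheme in which
nine subjects train and one tests. Per fold the model is refitted and
queried for every condition cell; observations are the held-out subject's
cell means. Reported quantities, each the mean of per-fold R² values
(negative values reported as-is):

* percept R² over the 60 `(task, xp, xs)` cells, both tasks pooled;
* decision-time R² over the same 60 cells (predictions vary only with
  `(task, xs)`, observations are per-couple means of 15 trials — the
  within-cell variability is what keeps this value moderate);
* collapsed-mode decision-time R² over 2 tasks × 3 modes of presentation
  (unisensory / bisensory coincident / bisensory non-coincident), with the
  time factor refitted on the grouped variable.

On the default calibration the acceptance sweep (20 replicate datasets)
yields approximately 0.94 / 0.60 / 0.87 for these three quantities, with
the percept clearly better predicted than the per-couple decision times
and the collapsed grouping recovering most of the lost accuracy — the same
ordering and close to the published magnitudes. The collapsed value runs
two to four points below its closed-form expectation because a per-fold R²
over six group cells pays a small-sample (Jensen) penalty that the
expectation oracle ignores; this is a property of the metric, shared by
any analysis that averages per-fold R² over few cells.

Problem sizes throughout: 9000-trial datasets, 10 subjects, 20 replicate
seeds for stochastic summaries, 100 null replicates per threshold. A full
pipeline run (simulate, normalize, elicit, fit, cross-validate) takes a
few seconds on one CPU; the 20-replicate sweeps take a few minutes.

## Degenerate inputs and numerical conventions

Zero-entropy joints define normalized MI as 0; a constant variable is
therefore independent of everything (this is how the secondary position
drops out of the unisensory-context local network). Probabilities are
plug-in counts over n with no pseudo-counts; entropy uses
$0\log 0 := 0$. Responses are clipped to the physical pointer range
[−40, 40] deg rather than resampled. Histogram normalization is checked to
1e−12, MI/CMI oracle equalities to 1e−10. All randomness flows from
explicit integer seeds; the command-line pipeline fans a single global
seed into fixed per-stage substreams so stages can be rerun independently.
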