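---
title: "Hybrid reinforcement learning and single-trial EEG regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid reinforcement learning and single-trial EEG regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepEEG)
```

## The task and the generative model

The two-step task dissociates model-free (MF) from model-based (MB)
control. On each of 500 trials a first-stage choice between two stimuli
leads probabilistically (80% common / 20% rare) to one of two
second-stage states, where a second choice pays an integer number of
points. Payoffs drift across trials as independent random walks with
reflective bounds at +5 and −4 points. `task_config()` holds these
environment parameters; `simulate_subject()` lets an artificial agent
play the task.

Agents learn state–action values Q by SARSA(λ). Writing stage-1/stage-2
states and actions as $(s_1, a_1)$, $(s_2, a_2)$ and the (scaled) outcome
as $r$, the prediction errors on a trial are

$$\delta_1 = Q(s_2, a_2) - Q(s_1, a_1), \qquad
  \delta_2 = r - Q(s_2, a_2),$$

both computed with pre-update values, and the updates applied at the
second stage are

$$Q(s_1, a_1) \mathrel{+}= \alpha\,\delta_1 + \alpha\lambda\,\delta_2,
  \qquad
  Q(s_2, a_2) \mathrel{+}= \alpha\,\delta_2 .$$

With $\lambda = 0$ only the current stage learns from the outcome. An MB
planner values stage-1 actions through the instructed transition matrix,
$Q_{MB}(s_A, a) = P(s_B\mid a)\max_{a'}Q(s_B,a') + P(s_C\mid
a)\max_{a'}Q(s_C,a')$; at the second stage MF and MB values coincide. The
hybrid agent mixes the two with weight $w$, $Q_{net} = w\,Q_{MB} +
(1-w)\,Q_{MF}$, and chooses by a softmax with inverse temperature
$\beta$, choice stickiness $\pi$ (bonus for repeating the previous
stage-1 stimulus) and response stickiness $\rho$ (bonus for repeating the
previous key):

$$P(a) \propto \exp\{\beta\,(Q_{net}(a) + \pi\,\mathrm{rep}(a) +
  \rho\,\mathrm{resp}(a))\}.$$

Stimulus positions are held fixed on screen, so with the default
configuration rep and resp coincide; the response-stickiness variant is
then penalized by BIC for its redundant parameter, which is the intended
behavior of the model comparison.

**Reward scaling.** Points are divided by the upper walk bound (+5)
before entering the value update, placing outcomes in [−0.8, 1]. The
scale is absorbed by $\beta$ and leaves the fitted $w$ essentially
unchanged (tested to ±0.05); it keeps prediction errors on the unit scale
on which their across-trial terciles are naturally reported.

**Update sequencing.** Both stage updates are applied at the second
stage, with the eligibility-weighted $\lambda\delta_2$ credit to the
stage-1 value — the standard two-step SARSA(λ) convention. Q values start
at 0 and are never reset between blocks. Trials without a response
contribute no likelihood; they reset the stickiness indicators while Q
values carry forward.

## Parameter estimation and model selection

`fit_subject()` maximizes the sequence log-likelihood by BFGS in a
transformed space (logit for unit-interval parameters, log for $\beta$
with an upper bound of 20, identity for $\pi, \rho$), from 20 random
starts by default, with the compiled likelihood evaluated inside the
optimizer and the R reference implementation cross-checked against it to
1e−12 in the tests. Estimation is pure maximum likelihood — no priors —
and fully reproducible given a seed. Nine variants are compared:
{MF, MB, hybrid} × {pure, +choice stickiness, +choice+response
stickiness}, with BIC $= k\ln n_{obs} - 2\,\mathcal{L}$ counting two
choice observations per complete trial; `compare_models()` sums BIC over
subjects and breaks ties toward fewer parameters. For pure-MB variants
$\lambda$ is unidentifiable (stage-1 MF values never reach the choice)
and is fixed at 0 rather than counted.

## Behavioral statistics

`screen_random_responder()` excludes subjects whose stay probability is
not positively associated (one-sided p < .05) with the previous trial's
reward or the reward×transition interaction in a per-subject logistic
regression. Complete separation — a perfectly reward-driven chooser —
makes the Wald test uninformative; such subjects are kept when the
diverging coefficient is positive, and flagged. `build_stay_design()`
codes previous reward (+1 points > 0, −1 otherwise — zero-point "nothing"
outcomes count as non-reward) and previous transition (+1 common),
z-scores the BIS-11 and OCI-R sum scores across the included sample, and
`fit_stay_glmm()` delegates the logistic mixed model (full four-way fixed
design, by-subject transition×reward random slopes) to lme4, reporting
exponentiated fixed effects. Gender, when supplied, is coded ±0.5 and
enters only this behavioral model.

A caveat discovered while validating the MF signature: with graded point
outcomes, a *pure* TD learner shows a genuine positive reward×transition
interaction (odds ratio ≈ 1.3–1.4 in our simulations), because the
obtained reward magnitude is systematically higher after common
transitions — the agent exploits the frequently visited second-stage
state better — and the ±1 dichotomization folds that magnitude into the
interaction term. With binary-magnitude outcomes (bounds −1..+1) the
canonical "interaction ≈ 1" MF signature holds (OR ≈ 0.87, n.s.). The
signature tests therefore check the canonical pattern on the
binary-outcome configuration and the reward-effect/MB-interaction
contrasts on the graded task.

The RT marker of MB control, `rt_delta()`, is the median stage-2 RT on
rare minus common trials (stage-1 available via an argument): the
synthetic RT model is log-normal with a +30 ms additive shift on rare
trials, and the marker recovers that shift at the cohort level.
`rt_delta_regression()` relates the deltas to traits by robust
regression.

## Synthetic EEG with planted, trait-linked modulation

`generate_cohort()` draws BIS/OCI sum scores from a bivariate normal
(defaults 65 ± 10 and 12 ± 8, r = .3 — typical community-sample values),
sets $w = \mathrm{logistic}(-0.5\,\mathrm{OCI}_z + \mathcal N(0,0.8))$
(compulsivity lowers model-basedness), and draws the remaining agent
parameters uniformly within plausible ranges (α 0.2–0.8, λ 0.3–0.9, β
2–8, π 0–0.4).

`generate_eeg_epochs()` builds feedback-locked epochs (−200 to 1000 ms,
500 Hz, channels FCz, Cz, Pz, F3, F4) as band-limited Gaussian noise (SD
12 µV, 8 ms temporal smoothing) plus two Gaussian-windowed components:

* an FRN at FCz (peak 294 ms, FWHM 60 ms, base −4 µV) carrying a
  transition main effect (−0.62 µV for common = +1; common trials more
  negative) and an RPE modulation that mixes a signed-linear term (70%)
  with a feedback-valence step (30%), scaled by a subject gain with
  population mean 1.6 µV per RPE-SD;
* a P3 at Cz (peak 370 ms, FWHM 120 ms, base +6 µV) carrying a rarity
  main effect (−1.25 µV under common = +1 coding) and a U-shaped RPE
  response (|RPE| weight 0.8 plus signed admixture 0.55) scaled by a
  subject gain with population mean 1.0 µV.

RPE effects are multiplied by (1 ± 0.3) on common/rare trials, planting
the stronger common-trial RPE coupling. Subject gains are linear in
z-scored traits and $w$: the FRN gain grows with $w$ (slope 0.31 µV/z)
and the rare-trial P3 gain falls with compulsivity (slope −0.45 µV/z) —
magnitudes chosen to equal the second-level coefficients they should
reproduce, with 1 µV of subject-level gain noise so that, together with
first-level estimation noise, second-level standard errors land near 0.1
µV/z at n ≈ 200.

Two deliberate infidelities matter for interpretation. First, the P3's
U-shaped RPE response means the *linear* first-level RPE regressor
recovers only the signed admixture — the recovered slope is attenuated
relative to the planted gain, and the quantitative recovery test
therefore uses a configuration with the U-shape switched off, while sign
recovery is tested under the full default. Second, the subset first-level
regressions z-score the RPE within each transition type, so their b
values are in µV per subset-SD; rare trials carry larger prediction
errors (their states are visited and learned less), inflating rare-cell
slopes by ~1.4 relative to an all-trials standardization. The
`rpe_standardization` option plants modulation on either scale. What the
generator does *not* emulate: 1/f spectra, artifacts, volume conduction
across a realistic 61-channel montage — so passing tests certify the
statistical machinery, not robustness to real recording conditions.

## First-level analysis

The per-subject pipeline is fixed and order-logged: fast-response filter
(RT < 100 ms at either stage) → adaptive artifact rejection → baseline
correction (−200–0 ms) → single-trial robust regression. Artifact
rejection scores each trial by its maximum absolute pointwise z across
channel × time and rejects above a threshold that starts at 4 SD and
adapts in 0.1 steps to remove at least one and at most 5% of trials. A
note on attainable scores: with a contamination fraction f, a pointwise
z-statistic cannot exceed about $\sqrt{(1-f)/f}$, so at 10% contamination
the threshold adapts *downward* from 4 while still removing only
contaminated trials — the cap, not the start value, is the binding
constraint.

`robust_regress_trials()` fits EEG ~ transition + RPE + transition:RPE
(common = +1, RPE z-scored within subject) at every channel × time point
by iteratively reweighted least squares with Huber weights (tuning
constant 1.345 for 95% Gaussian efficiency, at most 50 iterations,
coefficient tolerance 1e−8); an infinite tuning constant reproduces OLS
exactly, and the implementation is cross-checked against MASS::rlm.
`group_tmap()` runs pointwise two-tailed one-sample t-tests across
subjects and Benjamini–Hochberg adjusts over the default family of all
time points at FCz and Cz (whole-scalp family via an argument).
`find_component_windows()` takes the FRN as the most negative
grand-average sample at FCz in 250–350 ms and the P3 as the most positive
at Cz in 330–430 ms (ties to the earlier latency; boundary peaks warn)
and returns ±25 ms windows; `mean_b_in_window()` averages a regressor's
b values inside a window.

## Second level

`second_level_regression()` regresses the windowed RPE b values, per
component and transition type, on z-scored BIS, OCI and $w$ with all
interactions (8 terms; interaction columns are products of z-scored mains
and are not re-standardized). Fits use the same Huber M-estimator with
standard errors from the M-estimation sandwich (a bare "robust
regression" specification leaves the SE estimator open; the sandwich is
the standard asymptotic choice) and t-distribution p-values on n − p
degrees of freedom. No multiple-testing correction is applied across the 8-term
table — the windowed-value strategy exists precisely to avoid that — and
`median_split_followup()` (ties to the low group) plus
`compare_coefficients_z()` implement the interaction follow-ups.

## Validation harness sizes

The test suite exercises the full pipeline at sizes chosen to keep a
complete run near ten minutes of CPU: equation oracles at 3 trials to
1e−12; behavioral signatures at 30 subjects × 500 trials; parameter
recovery at 100 subjects × 500 trials × 20 restarts (r(w, ŵ) ≥ 0.8);
model recovery at 30 subjects over all nine variants; FDR null
calibration over 200 replicates of 12 subjects × 60 trials at 125 Hz with
white noise (the rejection rate equals q only under independent
pointwise statistics); end-to-end trait-link recovery over five
replicates of 200 subjects × 500 trials at 125 Hz on FCz/Cz. The reduced
sampling rate and two-channel montage in the large simulation studies
thin the time axis and scalp coverage without touching any analysis code
path.

## Known limitations

Hierarchical (group-level) model fitting, learned transition matrices,
and stimulus-locked analyses are out of scope. The likelihood surface of
the stickiness-augmented variants is mildly multimodal; 20 restarts make
the MLE reproducible in practice, but pathological subjects (near-random
responders) are flagged rather than refined. λ recovers poorly from
single-subject data — a known property of this model family — which is
why model selection and w recovery, not λ recovery, are the certified
quantities.
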