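---
title: "Models and methods: simulating and analysing saccadic orienting under amygdala disruption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experiment this package models

`amygaze` implements the analysis pipeline for a two-alternative saccadic
orienting experiment in which a fearful and a neutral face appear
simultaneously at opposite horizontal eccentricities (5.3 degrees) after a
jittered central fixation (1750 +/- 250 ms), while the amygdala on one side
is transiently disrupted by brief electrical stimulation in a blocked
design. Participants either look at the face that first captures their
attention ("Yield") or look away from it ("Oppose"). The behavioural
readouts are the orientation choice (fearful vs neutral face) and the
saccadic latency, acquired with 1 kHz eye tracking; a bipolar intracranial
channel provides local field potentials; the face stimuli themselves enter
a pixelwise analysis of which facial features drive fast orienting.

Because the corresponding patient data cannot be redistributed, the package
is built around a synthetic-experiment generator with known ground truth.
Every analysis stage is exercised end to end against that truth: the
generator is first-class, tested code, not a fixture.

# The synthetic-experiment generator

`design_spec()` + `make_design()` reproduce the design constants: blocks of
50 trials, one block per Instruction-by-Disruption-presence condition per
participant (6 participants by default, ~200 trials each), fearful-face
hemifield randomized per trial, fixation jitter uniform in +/-250 ms. The
disruption laterality label (ipsi/contralateral to the fearful face) arises
per trial from the fixed electrode side and the randomized hemifield, as in
the real task. All randomization is counter-hashed per trial
(splitmix-style), so a subset of trials always reproduces exactly the same
draws as the full design.

`ground_truth()` holds the generating parameters. Default effect sizes are
the study's headline point estimates: a start-point shift of -0.104
(native scale) between disruption lateralities under Yield, +19 ms of
non-decision time under disruption, +0.194 boundary separation under
Oppose, a +17 ms laterality-by-emotion latency interaction under Yield
(+32 ms disruption main effect, -17 ms emotion main effect, -22 ms
three-way pattern), fear-preference rates of 48% (Yield) and 42% (Oppose)
with a +0.11 Early-Late rate difference and a -0.15 laterality-by-latency
interaction. Effects are injected on each parameter's link scale
(logit for the start point and preference rate, log for boundary,
non-decision time, latency location and shift) with offsets solved
numerically so the named response-scale contrast equals its target exactly;
`truth$contrasts` stores the implied true value of every planned contrast.

Base values are the package's own choices where no published value exists,
picked once for realism: boundary 0.65, non-decision time 150 ms, and a
per-instruction drift solved so the absorption probability reproduces the
stated preference rates (about -0.12 evidence/s under Yield, -0.38 under
Oppose; near-ambiguous choice) --
together giving latencies with mean ~290 ms and SD ~120 ms -- and a
shifted-lognormal truth of shift 100 ms, log-median log(150), log-SD 0.3
(mean ~260 ms, SD ~55 ms). Subject intercept deviations are Normal(0, 0.1)
on each link scale. Behaviour can be generated from three models, one per
fitted family: the drift-diffusion race (default; latency = t0 +
first-passage time drawn by inverting the numerically integrated
first-passage distribution), the shifted-lognormal latency cells (chosen
emotion a fair coin), or the Bernoulli preference cells (null latencies,
choice drawn given the within-cell median-split label). Fitting each family
to data generated by its own family is the standard parameter-recovery
design; the drift-diffusion cohort doubles as the end-to-end input for the
gaze, LFP and face stages.

What the generator deliberately does not emulate: sequential/order effects,
practice or fatigue, blinks and vertical eye movements, stimulation
artefacts, non-stationary LFP background, photographic face content, or
inter-trial dependencies. Passing tests therefore demonstrate correctness
of the machinery under the stated generating assumptions, not robustness to
every property of real recordings.

# Saccade detection and trial QC

Velocity is estimated by Savitzky-Golay differentiation (order 2). The
window is 15 samples: at the generator's 0.1 degree sensor noise a
narrower window leaves the smoothed velocity noise floor above the printed
5 deg/s onset threshold (an 11-sample window gives ~9.9 deg/s noise and
~1.4 spurious supra-threshold runs per trace, which break the
preceding-fixation rule on ~2% of genuine saccades); 15 samples bring the
floor to ~4 deg/s while shifting detected onsets by under 2 ms. Candidates
are runs of supra-threshold speed; onset is the last sub-threshold sample
before the run, offset the first after it. The four printed criteria are
applied to candidates: duration >= 20 ms, amplitude >= 0.5 degrees, onset
threshold 5 deg/s, preceding fixation >= 50 ms. "Preceding fixation" is
operationalized as the absence of any other supra-threshold movement
(a candidate passing the duration and amplitude criteria) ending within
50 ms before onset -- a reading that reproduces the two-movements-30 ms-apart
rejection and is robust to sensor noise, unlike requiring a raw quiet
velocity window.

Scoring applies the printed rules in the original order: inadequate
fixation in the 100 ms before stimulus onset (automated surrogate for the
manual check: SD > 0.5 degrees or any sample > 1 degree from the fixation
position) discards the trial unscored; otherwise the first saccade with
onset after the stimulus defines latency and direction; latency < 100 ms is
implausibly fast; no onset by 1000 ms is an absent response (the only case
coded `choice = "none"`).

# The three behavioural models

All three are hierarchical Bayesian models with participant random
intercepts on every modelled parameter (partial pooling) and
weakly-informative priors: standard-Normal fixed effects on each link
scale, half-Normal(0,1) random-intercept SDs, Normal(log 250 ms, 1) /
Normal(log 0.3, 1) / Normal(log 100 ms, 1) intercept priors for the latency
location, log-SD and shift, and Normal(log 0.2 s, 1) for the non-decision
intercept. Factors are sum-to-zero coded throughout, so the hemifield
confound is marginalized by equal-weight averaging and main effects remain
interpretable under imbalance.

**Latency** is shifted-lognormal: `latency = delta + exp(mu + sigma * z)`,
with `mu` fully factorial in Instruction x Disruption(None/Ipsi/Contra) x
Emotion of the chosen face, plus the fearful-face hemifield as a confound
column; `sigma` and `delta` carry intercepts (log link) and participant
intercepts only -- the data carry little information about
condition-dependent spread or shift, and the shift is bounded above by 95%
of each participant's fastest valid latency.

**Choice** is Bernoulli on the fearful-face preference rate `theta`
(logit link), factorial in Instruction x Disruption x binarized Latency.
The latency bin is a median split computed independently within each
Instruction x Disruption x Hemifield cell (ties, including the median value
itself, go Late), which makes the label orthogonal to the design factors.

**The drift-diffusion model** treats choice and latency jointly as first
passage of a Wiener process with unit diffusion between boundaries 0 and
`a`: drift `v` (positive toward the fearful face -- the upper boundary codes
orientation to fear), relative start point `z` (logit link), boundary
separation `a` and non-decision time `t0` (log links). `v` and `z` vary
with Instruction x Disruption(3) x Hemifield; `a` and `t0` with
Instruction x Disruption presence only, because caution and motor delay are
set before the stimulus reveals the fearful side. There are no
inter-trial variability parameters. The defective first-passage density is
evaluated by the small-time/large-time series decomposition with the
standard accuracy-based switching rule (tolerance 1e-8 in the likelihood,
1e-10 where densities are reported); the two expansions agree to 1e-8
across the supported parameter range, and the density is validated against
an Euler-Maruyama simulation oracle. `t0` may approach, but not reach, the
participant's fastest response among the trials its cell governs; no extra
safety margin is imposed because the first-passage density vanishes
smoothly there.

## Posterior sampling

The study's original analysis was fitted with Hamiltonian Monte Carlo.
This package
samples with differential-evolution MCMC with a historical archive
(DE-MCz; ter Braak & Vrugt 2008), a gradient-free scheme whose
difference-vector proposals self-adapt to the posterior's correlation
structure, augmented with moves that target the specific geometry of these
models:

* a Laplace pre-step (BFGS mode, finite-difference Hessian with
  eigenvalues clipped to an absolute sane band) seeds the proposal archive
  with the right scales and correlations;
* block-conditional refresh proposals draw the fixed-effect blocks from
  their conditional under the mode's Gaussian approximation (re-estimated
  once from the sampled archive late in burn-in, mildly inflated), giving
  near-independent refreshes of exactly the reported parameters;
* the random-intercept SDs are redrawn by griddy Gibbs from their exact
  conditionals, which are data-free in the centered parameterization;
* recentering moves shift an intercept against its subject deviations
  along the likelihood-invariant ridge the centered parameterization
  creates;
* the latency model additionally gets an exact conjugate Gibbs draw of its
  jointly-Gaussian block (cell means, hemifield slope, subject
  intercepts), a likelihood-matched inverse-gamma refresh of each
  subject's sigma, and a shift-versus-median trade-off move along the
  shifted-lognormal's known ridge.

Chains are centred rather than non-centred because each participant
contributes ~200 trials, which makes subject intercepts data-dominated.
Convergence is gated at split R-hat <= 1.01 and bulk ESS >= 400 for all
reported parameters -- the fixed effects, plus the latency model's sigma
and delta intercepts, i.e. everything that enters a reported contrast. The
random-intercept SD hyperparameters are excluded from the gate: with six
participants and weak per-subject information for `v`, `z` and `theta`,
their posteriors occupy the heavy-tailed zero-variance corner of the
hierarchical funnel, mix slowly there, and appear in no reported output.
A fit failing the gate raises a classed convergence error. Defaults are
6 chains x 12000 iterations (latency), 6 x 8000 (choice) and 8 x 32000
(drift-diffusion, several minutes). The latency and choice defaults pass
the gate with margin (R-hat ~1.005, ESS 700-900). The drift-diffusion
posterior is the hardest target for a gradient-free sampler: at the default
length a handful of fixed effects typically land at split R-hat 1.01-1.02
with ESS 600-900, in which case the gate raises and the remedy is a longer
chain (the error object carries the fit for inspection). Recovery studies
in the test suite run reduced ungated chains, as their claims are about
coverage across replicates rather than any single fit; their credible
intervals match long-run references.

## Contrasts

Planned contrasts are linear combinations of the per-draw factorial cell
values on the reporting scale: expected latency in ms (`delta +
exp(mu + sigma^2/2)` at the typical subject, i.e. random intercepts at
zero), preference rates, and native-scale `z`, `v`, `a` (`t0` in ms).
Summaries are the posterior mean, the 2.5/97.5 percentile credible
interval, and `P(effect)`, the posterior mass on the side of zero of the
estimated direction. The suite mirrors the pre-registered set: Disruption
presence; laterality within Yield; laterality x Emotion (or x Latency bin)
within Yield; the Instruction x laterality x third-factor pattern
difference (defined here as Oppose-pattern minus Yield-pattern); and the
third factor's main effect; for the drift-diffusion model, laterality
contrasts for `z` and `v`, and Instruction/presence effects for `a` and
`t0`. Equal-weight averaging over hemifield implements "marginalized out";
whether the original analysis used equal or frequency weights is not
stated, and equal weights follow from the sum-to-zero coding.

# Face-feature inference

Difference images (attended minus neglected face, pre-aligned by
construction) are modelled pixelwise by ordinary least squares with
Disruption x binarized-Latency cells and orientation side as a confound;
the reported maps are the three per-disruption Early-minus-Late t maps and
their joint three-contrast omnibus F. Family-wise error over the
upper-face mask is controlled by a max-statistic permutation null that
re-draws the Early/Late labels within Disruption x side blocks -- trials
are treated as the exchangeable unit, the natural reading for a pooled
fixed-effects model. Permutation replaces random-field theory deliberately:
it is exact under exchangeability and needs no smoothness estimation. The
synthetic images are a smoothed Gaussian noise field plus a scleral-region
signal on Early trials whose weight depends on the disruption condition
(strongest ipsilateral to the fearful face, absent contralateral),
emulating scleral exposure driving fast orienting.

# Induced time-frequency analysis

Epochs are -2 to +4 s around stimulus onset at 1024 Hz, from a bipolar
montage of the two most distal contacts, high-passed at 0.1 Hz with a
zero-phase fifth-order Butterworth applied as cascaded biquad sections
(the single transfer-function form is numerically unstable at so low a
cutoff). The low band (2-48 Hz) uses a single Hanning taper with a 400 ms
window (~5 Hz resolution); the high band (52-148 Hz, 4 Hz grid) uses three
discrete-prolate-spheroidal multitapers on a 200 ms window
(time-bandwidth 2, i.e. +/-10 Hz smoothing); both step in 25 ms. Trials
are combined by bisquare robust averaging (tuning constant 4.685, at most
20 iterations), rescaled per frequency to percent change over the -600 to
-200 ms baseline of the condition average, and smoothed with a Gaussian
kernel of 4 x 2 (high) or 3 x 2 (low) frequency x time pixels FWHM
truncated at 4 SD.

Inference is a within-subject 2 x 2 factorial on Recording side
(ipsi/contralateral to the fearful face) x Emotion of the oriented target,
restricted to 0-400 ms: the per-participant interaction contrast is tested
with a one-sample F (squared t, df 1 and participants minus 1) and a
max-statistic sign-flip permutation null -- within-participant exchange of
the side labels flips the contrast's sign, so the null is exact under the
no-interaction hypothesis. Only Yield undisrupted trials are analysed
(disrupted blocks carry stimulation artefact). The generator injects a
Gaussian-windowed ~99 Hz burst (centre 80 ms, SD 25 ms, spanning roughly
30-130 ms) with random carrier phase per trial -- induced, not
phase-locked -- on trials where gaze oriented contralateral to the
recording side, which is exactly the side-by-emotion interaction pattern.
Its amplitude is specified in percent of baseline band power and converted
to a carrier amplitude by measuring, with the package's own estimator, the
pink-noise baseline power and the estimator's response to a unit burst, so
injected and recovered percent-change scales agree by construction.
Structural inference is reproduced at the study's six participants, but
recovery and calibration studies default to 12 synthetic participants for
statistical stability of the tests themselves.

# Problem sizes and open choices

Recovery studies use 20 cohorts of 6 participants x ~200 trials with
reduced sampler settings; family-wise error calibration uses 200 null
replicates at 1000 permutations on reduced image sizes (24 x 20 pixel face
frames; 25 x 33 pixel time-frequency images); the end-to-end gamma
recovery uses 12 participants (~600 epochs). These sizes are the package's
choices, balancing the stability of the checks against routine run times.

Choices the source analysis left open, decided here: the drift-diffusion
boundaries code fearful/neutral orientation (contrasts are phrased in
emotion terms); sigma and delta carry no condition effects; marginalization
uses equal weights; latency contrasts are differences of posterior
expected latencies on the response scale at the typical subject;
median-split ties go Late; the robust-averaging weight function is
bisquare with the standard tuning constant; the three-way planned contrast
is the Oppose-minus-Yield pattern difference. Known limitations: no
inter-trial variability parameters in the diffusion model (by design); the
sampler trades gradient information for bespoke moves and needs long
chains for the drift-diffusion posterior; the LFP background is stationary
pink noise, so robust averaging is exercised by injected artefact tests
rather than realistic non-stationarity.
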