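---
title: "Simulating and analysing autonomous home-cage training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing autonomous home-cage training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The system being simulated

`homecage` is a closed-loop simulator of an autonomous home-cage apparatus in
which mice train themselves, without experimenter supervision, in voluntary
head-fixation and a delayed-response tactile decision task, together with the
statistical toolkit used to analyse the resulting behavior.  The package has
two halves that talk to each other:

* **Protocol state machines** — deterministic controllers for a single trial
  (`run_trial()`), head-fixation training (`step_headport_entry()`,
  `step_fixation_training()`, `update_release_thresholds()`,
  `resolve_release()`), staged task training with auto-assist programs
  (`advance_stage()`, `select_trial_type()`, `evaluate_autoassist()`),
  contingency reversal (`check_contingency_reversal()`) and optogenetic
  trial scheduling (`assign_photostim()`).
* **A generative mouse agent** (`agent_params()`, `sample_trial_behavior()`,
  `sample_engagement()`, `update_learning_state()`) that closes the loop:
  it decides when to engage, when to struggle, and how to lick, with a
  choice policy whose strategy shifts over training.

`simulate_homecage()` couples the two and emits trial and fixation logs;
the analysis stack (`build_design()`, `fit_logistic()`,
`crossval_predict()`, `partial_model_pvalue()`, `sliding_window_analysis()`,
`nested_bootstrap_effect()`, `classify_unit_and_modulation()`) then operates
on those logs exactly as it would on logs from a real apparatus.

## The task

A trial has a sample epoch of 1.3 s (0.2 s pole travel, 1 s presentation,
and 0.1 s into retraction), a delay epoch (0.3–1.3 s during training,
1.3 s when trained), a 0.1 s auditory go cue that opens a 1.5 s response
window, and a 2.5 s inter-trial interval.  The pole appears at an anterior
or posterior position; under the standard contingency anterior instructs
lick-left and posterior lick-right.  The first lick strictly after the go
cue is the choice; no lick within 1.5 s is an ignore, which is excluded
from every performance criterion.  Errors append a timeout (2 s in the
directional stage, 4 s afterwards) before the inter-trial interval; the
relative order of timeout and inter-trial interval is a package choice, as
is treating a lick exactly at the go time as pre-go (the half-open window
`(go, go + 1.5]` avoids double-counting the boundary).  In delay-enforcing
stages a pre-go lick pauses the trial for 0.1 s and restarts the epoch —
sample or delay — in which it occurred.  Event times are kept on a 0.1 ms
grid, the resolution of the task controller being emulated.

Photostimulation, when scheduled, is a 40 Hz sinusoid lasting 1.3 s with a
100 ms linear offset ramp, starting at the beginning of the sample, delay,
or response epoch on a random ~10% of trials, with intensity drawn from a
configured set; a 10 Hz masking flash covers every trial from sample onset
to response end.  The stimulus duration is fixed at 1.3 s even when
assigned to a shorter delay (it then overruns into the response epoch):
in the emulated experiments stimulation only runs after training, when the
delay is 1.3 s, so the overlap arises only in simulated edge cases and is
logged rather than truncated.

## Head-fixation training

The headport-entry subprotocol lures the mouse in: every 20 rewarded licks
retract the lickport 3 mm (to ~14 mm, where licking requires triggering the
headport switches), 12 h without licks re-extend it, the rewarded spout
alternates every three rewards, and 30 switch triggers advance to fixation
training.  Fixation durations ramp from 3 s by 2 s per 20 time-up releases
(escapes and self-releases do not count) to 30 s — 280 time-up releases in
all — switching from soft (1.78 bar) to hard clamp (2.78 bar after the
first 2 s) once the duration reaches 10 s, and extending from 30 to 60 s
after task training completes.

Self-release thresholds start at (−1, 30) g and adapt on the last 20
head-fixations: above 90% self-releases the band widens by 2 g per side,
below 5% it narrows, stopping at a minimum width of 10 g (the controller
needs a floor to avoid a degenerate band; none is prescribed by the
emulated system).  Escapes count as non-self releases in this 20-event
buffer.  "Reaching 30 s" is interpreted as ≥ 30 s, since the schedule
3, 5, …, 29, 31 never hits 30 exactly.  Escape detection requires the
switches to disengage within the first 0.2 s of clamping, before the
pistons hold.

Body weight is estimated as the mode of a 0.1 g histogram of on-platform
load readings (readings above a 5 g floor), mirroring how a load-sensing
platform under the home cage doubles as a scale.

## The agent

The agent's choice policy is a logistic rule on ±1-coded inputs:

$$P(\text{left}) = \sigma\!\big(v\,\mathrm{pole} + w_{\mathrm{hist}} A_1 +
w_{\mathrm{wsls}} A_1 R_1 + b\big),$$

mixed with a lapse (probability 0.05 of a uniform choice) and an ignore
probability (0.03).  Over training the stimulus weight $v$ rises along a
sigmoid schedule (midpoint 8000 trials, scale 1500) to an asymptote of 2.5,
while the perseveration weight decays 0.5 → 0.1 and the win-stay-lose-switch
weight 0.9 → 0.  Two of these choices deserve comment:

* **Why a WSLS term?**  A pure previous-choice (perseveration) policy has
  stationary accuracy exactly 50% in the blocked directional-licking stage
  (staying is correct after a correct trial and wrong after an error, in
  equal measure), so an agent with only stimulus, perseveration and bias
  terms can never pass the 70% directional criterion before the stimulus
  weight grows.  A win-stay-lose-switch policy, by contrast, solves the
  blocked stage (switching after an error is exactly what the block
  demands) — and an early WSLS strategy giving way to stimulus-driven
  responding is precisely the strategy progression the analysis stack is
  designed to detect.  The WSLS weight of 0.9 is deliberately moderate:
  the auto-assist programs induce trial-type autocorrelation that a strong
  WSLS policy could exploit to pass the discrimination criterion without
  any stimulus sensitivity.
* **Why these schedule constants?**  The defaults were calibrated once so
  that the simulated trials-to-criterion (≈ 6,500–7,500 trials to sustained
  70%) sits at the scale reported for real mice learning this task
  (≈ 8,600 ± 3,400 trials), and were not revisited afterwards.

Engagement is a two-component renewal process: with probability 0.8 the next
head-fixation continues the current bout (exponential gap, 1 s scale),
otherwise a between-bout interval (exponential, 2400 s mean) intervenes,
deferred to the dark cycle with probability 0.67 (days are 86,400 s, dark
first).  Both components are multiplied by 1.5 when the previous fixation's
last scored trial was an error — a post-error disengagement effect.  Note
that circadian deferral adds hours to between-bout intervals, so the raw
error/correct IFI ratio in closed-loop data understates the multiplier;
the acceptance script therefore measures it on within-bout gaps (< 10 s),
where it is identified.

Struggling is a Poisson process (0.08 events/s) of load excursions with
exponential amplitude (mean 15 g) and random sign around a 5 g resting
load.  Inside the closed-loop simulator the first threshold crossing is
drawn analytically from this model (`sample_release()`); the literal 20 Hz
trace (`simulate_load_trace()`) feeds `resolve_release()` in the test
suite, and the two routes are cross-checked against each other.

In contingency-reversal mode the stimulus weight is instead updated by a
reward-driven delta rule, `v ← v + α (w_{max}\, r\, a\, \mathrm{pole} − v)`
with α = 0.05, because a feed-forward schedule cannot re-learn a flipped
stimulus–response mapping.  In a two-choice task with deterministic reward
the product $r\,a\,\mathrm{pole}$ equals the contingency sign on every
trial, so $v$ relaxes geometrically toward the correct mapping after each
flip.

The agent is a study design, not an estimate: no generative behavioral
model is specified by the emulated system, and none of the agent's
parameters should be read as measurements of real mice.  What passing tests
show is that the protocol logic, the estimators and the inference machinery
behave correctly on data with this structure — learning curves, history
strategies, engagement bouts, struggle statistics.  Real data add
non-stationarities the agent does not model: satiation within a day,
whisker-dependent psychophysics, sensor noise, and drift in motivation.

## Task protocol details

Stage criteria (70% directional, 75% discrimination, 70% per 0.2 s delay
increment) are assessed on consecutive *non-overlapping* blocks of 30
scored trials counted from the last stage or delay change, and the reversal
criterion (> 80%, strictly) on non-overlapping blocks of 100.  With
every-trial sliding evaluation a criterion is eventually passed by a lucky
streak at chance-level competence (in simulation the whole schedule can
ratchet through at 56% true accuracy), which contradicts the intent that
stage completion track competence; block-wise assessment is the package's
reading of "assessed over 30 trials".  Criterion windows are never
evaluated before they fill.

The four auto-assist programs follow the printed rules: lickport moves
toward the non-preferred spout when the per-type performance difference
exceeds 30 points over the last 50 trials or 80 points over the last 20;
a free reward on the next trial of a type after five consecutive errors in
it; presentation probabilities reweighted by the last 30 trials,
`p(worse) = 0.5 + 0.5 min(0.3, Δaccuracy)` capped at 0.8 (the mapping from
"more frequently" to numbers is a package choice); and forced repetition of
a type after three consecutive errors until two correct.  Ignore trials
break consecutive-error runs.  Lickport assist moves in 1 mm steps
(±3 mm cap) and walks back to center when the bias clears; the free reward
is delivered at trial start on the correct spout.  Auto-assists are active
during discrimination and delay training, and off during optogenetic
testing, as is the agent's learning schedule (frozen).

## The choice model

For each scored trial with at least 20 predecessors the design matrix holds
the current stimulus $S_0$ (+1 = lick-left-instructing), stimulus history
$S_1..S_5$, choice history $A_1..A_5$ (+1 = licked left), reward history
$R_1..R_5$, the 20-trial stimulus average $S_{avg}$, the win-stay-lose-
switch regressor $WSLS = A_1 R_1$, and a constant bias.  Ignore trials are
dropped before coding, so history regressors automatically carry the last
scored values across them.  $P(\text{left})$ is a logistic function of the
weighted sum; $P > 0.5$ predicts a left lick.

Fitting is maximum likelihood by iteratively reweighted least squares with
a ridge of $10^{-4}$ on non-bias weights, which stabilises separable
windows while perturbing identified fits by far less than their standard
errors; an all-one-class response returns a bias-saturated fit with a
warning.  Tests verify the optimizer against a dense grid-search maximizer
of the unpenalised likelihood on small instances.

Cross-validation must respect the fact that each row carries 20 trials of
history: a test block of 60 consecutive trials is held out together with
guard zones of 20 trials on both sides, and the model trains on up to 400
remaining trials of the 500-trial window.  Nine blocks are placed with
starts evenly spaced over the usable positions (trial 21 to 441); blocks
may overlap.  The description this emulates is internally ambiguous
("5-fold", nine repetitions, 60-trial test sets in a 500-trial window
cannot all be literal), so even spacing is a design decision, and the guard
property — no training trial within 20 of any test trial — is asserted
exhaustively in the test suite.

Partial models zero the *fitted* weight of a regressor without refitting.
Significance is by bootstrap: the pooled test-set trials are resampled 1000
times and the p-value is the fraction of resamples in which the partial
model predicts strictly better than the full model.  Exact ties are common
(zeroing a small weight often flips no prediction), so the strict p-value
and a mid-p variant (ties counted one half) are reported side by side; the
degenerate case of a zero-variance regressor yields strict p = 0 with tie
fraction 1, which is flagged rather than hidden.  Calibration simulations
use the mid-p.  A regressor is "relied upon" when p < 0.05 in at least five
consecutive 500-trial windows (100-trial steps, so 1000 trials).  The
shuffle control permutes choices while leaving every history-derived
regressor column untouched.

## Resampling inference

Photostimulation effects are within-mouse performance changes
(stimulation − control, in percentage points) averaged unweighted across
mice.  The nested bootstrap resamples mice with replacement, then sessions
within each resampled mouse (one simulated day, dark + light, is one
session), then trials within each resampled session; the one-tailed p is
the fraction of resampled effects with sign opposite the observed one.
Trial resampling within a session is drawn as a multinomial over the four
(condition × outcome) cells, which is distributionally identical to
resampling trial indices and considerably faster.  A mouse lacking either
condition is dropped with a warning; with one mouse and one session the
procedure degenerates gracefully to a plain trial bootstrap.

At desk scale the calibration studies use 5 mice × 3 sessions × 200 trials
with 1000 resamples: the null rejection rate stays below 8% and a 20-point
injected deficit is detected with essentially full power.  The partial-model
mid-p rejects a truly unused regressor at close to the nominal 5%; the
calibration uses the exogenous stimulus-history regressor $S_3$, because
with deterministic rewards $R_k = A_k S_k$ exactly, making reward history
collinear with the other regressors and not a clean null.

## Electrophysiology metrics

Units are typed by the trough-to-peak width of the mean spike waveform:
strictly below 0.55 ms is putative fast-spiking, otherwise putative
pyramidal.  Per intensity, spike rates during the 1.3 s photostimulus are
compared with the 500 ms pre-stimulus baseline by a paired two-tailed
t-test across sweeps (pairing is a package choice; the emulated analysis
does not state it), and the relative firing rate is the mean stimulation
rate divided by the mean baseline rate — undefined, and flagged, when the
baseline rate is zero.

## Numerical and scale choices

Problem sizes were chosen so the full test suite and the acceptance script
each run in minutes on one core: closed-loop runs cap at 20,000 trials
(training completes in well under that), parameter recovery uses 50
replicates of 5,000 trials, calibration studies 200 replicates with 1,000
bootstrap resamples, and the dose-response simulation 60 sweeps per
intensity.  All randomness flows from a single seed; runs are reproducible
bit for bit, and the logs round-trip through JSON Lines with resume-safe
reads.

## Known limitations

* The agent's learning is an imposed schedule (except in reversal mode);
  it does not learn from reward in standard mode, so manipulations that
  would change a real mouse's learning rate have no effect on it.
* Satiation, body-weight dynamics and their correlation with engagement are
  not modeled beyond the circadian preference and post-error multiplier.
* The strict partial-model bootstrap is conservative by construction for
  regressors whose removal changes few predictions; the mid-p variant
  mitigates but does not remove this.
* Hardware, pneumatic physics, audio, video, spike sorting and image
  registration are out of scope; spike inputs are per-sweep counts.
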