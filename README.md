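# homecage

Closed-loop simulation and analysis of autonomous home-cage behavioral
training.

## What this package is for

Autonomous home-cage systems let mice train themselves, without an
experimenter, in voluntary head-fixation and a delayed-response tactile
decision task: the animal enters a headport, is clamped by pneumatic
pistons, runs a bout of trials, and releases itself by struggling against a
load-sensing platform.  Such systems are controllers all the way down —
adaptive release thresholds, staged shaping criteria, anti-bias assist
programs, optogenetic trial scheduling — and their behavioral output is
analysed with a matching statistical stack: choice-history logistic
regression with history-excluding cross-validation and bootstrap model
selection, and nested (mouse/session/trial) bootstrap inference for
photostimulation effects.

`homecage` makes every one of those algorithms executable and testable
without hardware or animals.  It provides:

* **Protocol state machines** — a single-trial engine (epoch timing,
  first-lick-after-go choice registration, early-lick restart policy,
  outcome/timeout assignment), headport-entry and head-fixation training
  with the adaptive self-release threshold controller, staged task
  training (directional licking → discrimination → delay) with the four
  auto-assist programs, contingency reversal, and the ~10% photostimulation
  scheduler.
* **A generative mouse agent** that closes the loop and doubles as the
  synthetic-data generator: a logistic choice policy
  `P(left) = σ(v·pole + w_hist·A1 + w_wsls·A1R1 + bias)` whose stimulus
  weight rises along a learning schedule while choice-history and
  win-stay-lose-switch weights decay; engagement bouts with circadian
  preference and post-error disengagement; Poisson struggle excursions that
  drive self-releases.
* **The analysis stack** — design-matrix construction
  (S0, S1–S5, A1–A5, R1–R5, S_avg, WSLS, bias), ridge-stabilised logistic
  maximum likelihood, 9-block cross-validation with 20-trial guard zones,
  partial-model bootstrap p-values (strict and mid-p), sliding-window
  reliance classification, shuffle controls, percent-correct performance,
  the nested bootstrap, Pearson 2×2 proportion tests, inter-fixation
  interval analyses, and spike-width/relative-firing-rate ephys metrics.

Everything is reproducible bit-for-bit from a seed, and logs round-trip
through JSON Lines with resume-safe reads.

## Worked example

Train a simulated mouse from naive to criterion and watch its strategy
shift from choice history to the stimulus:

```r
library(homecage)

run <- simulate_homecage(seed = 1, max_trials = 20000,
                         n_trials_after_complete = 4000)
print(run)
#> homecage_run: 11011 trials, 2850 fixations
#>   stage reached: complete
#>   70% criterion (200-trial window) at trial 6921

sc <- run$trials[run$trials$outcome != "ignore", ]
performance(utils::tail(sc, 500))
#> [1] 87.8

fits <- sliding_window_analysis(run$trials[run$trials$stage != "directional", ],
                                window = 500, step = 1500)
t(vapply(fits, function(f) coef(f$fit)[c("S0", "A1", "WSLS")], numeric(3)))
#>  window_start   S0   A1 WSLS cv_accuracy
#>             1 0.06 0.47 0.49       0.683
#>          1501 0.05 0.42 0.39       0.639
#>          3001 0.05 0.39 0.47       0.689
#>          4501 0.46 0.37 0.50       0.724
#>          6001 0.60 0.27 0.35       0.665
#>          7501 1.02 0.23 0.24       0.681
#>          9001 1.79 0.19 0.09       0.841
```

Early windows are dominated by the previous-choice (`A1`) and
win-stay-lose-switch (`WSLS`) regressors; as learning proceeds the current
stimulus (`S0`) takes over and cross-validated choice prediction rises —
the signature the sliding-window analysis is built to detect.  The mouse
completes head-fixation training (3 → 30 s ramp), passes the directional,
discrimination and delay stages, and sustains 70% correct around trial
7,000, the scale real mice need for this task.

A command-line wrapper covers the same ground from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/homecage.R", package="homecage"))') \
    simulate --seed 1 --out runs/m1
```

with `fit-choice`, `opto-test`, `ephys` and `report` subcommands operating
on the emitted logs.

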