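---
title: "Models and methods: simulating and analysing pupillometry of processing speed training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pstpupil)
```

# The problem this package addresses

Task-evoked pupil dilation under constant luminance indexes how many
attentional resources a task consumes. In a processing-speed-training (PST)
study built on a modified useful-field-of-view (UFOV) paradigm, the question
is whether adaptive training makes resource allocation more *efficient*: if
it does, the pupil dilation gap between a hard task (central identification
plus peripheral localisation among target-like distractors; "Task 4") and an
easy one with identical response demands ("Task 2") should shrink after
training in the trained group only.

`pstpupil` implements the full computational apparatus of such a study so
that every stage is testable without human data: the trial paradigm, the
adaptive staircase, a synthetic observer and eye-tracker, the pupil
measurement pipeline, and the repeated-measures statistics. The synthetic
generator is first-class, tested code: its defaults *are* the study
conditions (20 subjects randomized 10/10; 500-trial test phases; six
training days of two 375-trial blocks; 1000 Hz eye sampling), and the
analysis half of the package never sees anything the generator does not
write through the same file formats a real tracker pipeline would use.

# The paradigm

Each trial is a 506 ms fixation cue, the stimulus (car or truck centrally;
at levels 2--4 also a peripheral target at one of 8 locations on a 5.7
degree ring), a 1000 ms full-screen white-noise mask, and an unspeeded
response probe. Test phases fix the stimulus duration at 200 ms and cycle
the task level every 25 trials (5 cycles, 500 trials). Level 3 surrounds
the peripheral target with easily rejected triangle distractors; level 4
with target-like distractors.

Decisions the published paradigm leaves open, fixed here by configuration:

* **Angular offset of the ring.** Location 0 at 12 o'clock, clockwise.
  Arbitrary; nothing downstream consumes absolute angles.
* **Car/truck balance.** "Fifty percent of trials" is realised as an exact
  per-25-trial-set balance via a seeded shuffle (the Bernoulli-per-trial
  alternative is available with `balance_identity = FALSE`).
* **Geometry units.** Degrees of visual angle are kept as abstract
  geometry; no pixel conversion, since rendering is out of scope.
* **Probe duration.** The response period is unspeeded; the simulator
  closes it at the observer's drawn response time.

# The staircase

Training starts every block at Task 1, 200 ms. Every fourth trial a
performance check counts the central and peripheral responses of the
preceding four trials independently (8 possible responses at levels 2--4,
4 at level 1):

* accuracy **> 75%**: one step harder -- the next shorter duration on the
  ladder 306, 259, 200, 153, 106, 82, 59, 35, 24 ms, or the next task level
  once the ladder floor is reached (Task 4 saturates and keeps running at
  24 ms);
* accuracy **< 37.5%**: one step easier, mirrored (Task 1 at 306 ms is the
  floor);
* otherwise unchanged. Both thresholds are strict, so exactly 6/8 (75%) and
  exactly 3/8 (37.5%) leave the state alone.

Further choices where the verbal description underdetermines the
algorithm:

* **Duration across level transitions** is preserved: a level-up happens
  only at the shortest duration and stays there; a level-down only at the
  longest. This is the only reading consistent with both transition rules
  and with Task 4 "continuing at the shortest duration".
* **Window counters reset after every check**, including "same", so checks
  always use disjoint 4-trial windows.
* **Level-1 windows** have 4 responses, where 37.5% is unattainable; the
  strict thresholds are applied as stated (1/4 = 25% steps easier,
  2/4 = 50% holds).
* **Block granularity.** Each training block restarts at Task 1 / 200 ms;
  `reset_each_block = FALSE` carries state across a day instead.

# The synthetic observer

Per-response accuracy is a logistic in log duration between a guessing
floor (0.5 central, 1/8 peripheral) and a lapse-limited ceiling
$1-\lambda$:

$$p(d) = \gamma + (1 - \gamma - \lambda)\,
  \mathrm{logistic}\!\big(\beta(\log d - \log \theta_\ell s)\big),$$

with level-specific midpoints $\theta_\ell$, common slope $\beta$, and a
multiplicative threshold shift $s \in (0,1]$ for trained observers.
Response time is a truncated normal (mean 0.95 s, SD 0.25 s, floor 0.2 s),
matching the ~0.9--1.0 s unspeeded responses such paradigms yield; only
mean RT is analysed, so nothing finer is modelled.

The defaults ($\theta = (0.2, 0.7, 2, 10)$ ms, $\beta = 0.55$,
$\lambda = 0.05$, $s = 0.25$) were chosen once to satisfy, simultaneously,
the two behavioural facts the paradigm exhibits in young adults:

1. at the 200 ms test duration, per-response accuracy lands at roughly
   92% / 90% / 85% for levels 2/3/4 -- high, near ceiling, Task 4 clearly
   hardest;
2. during training the staircase *progresses*: young adults' duration
   thresholds on the easy levels lie below the 24 ms ladder floor, so >75%
   windows occur at 24 ms and level transitions fire. A block typically
   spends a handful of checks in Tasks 1--3 and then hovers inside Task 4
   -- which is why adaptive training yields few Task 2 trials relative to
   Task 4, a property the training-trend analysis must tolerate.

These two constraints force a shallow slope: a steep psychometric function
that is at 85% at 200 ms is far below 75% at 24 ms and the staircase would
never leave Task 1. A consequence of the shallow slope is that the nominal
midpoints sit below the physically presentable range; they are curve
parameters, not claims about measurable thresholds. The post-training
shift $s = 0.25$ reproduces a ~5-point accuracy gain at 200 ms, the
magnitude reported for trained young adults.

# The synthetic eye-tracker

`simulate_trial_eye()` emits one sample per millisecond from cue onset to
probe onset: gaze (fixation-plus-jitter with Poisson-rate saccades and
blinks) and pupil in arbitrary units (au),

$$\text{pupil}(t) = g \cdot B \cdot \big(1 + \tfrac{A_\ell}{100} k(t)\big)
  + \varepsilon_t,$$

where $B$ is the session baseline (default 1000 au), $g$ a lognormal
session gain (default 5% spread) standing for the camera/eye geometry that
makes raw au incomparable across sessions, $A_\ell$ the level-specific
evoked amplitude in percent, and $\varepsilon_t$ white noise with SD 2 au
-- an order-of-magnitude emulation of a research tracker's relative
resolution (about 0.01 mm on a 5 mm pupil), not a calibration.

The kernel $k(t)$ is a raised-cosine rise starting 100 ms after stimulus
onset and reaching an exact plateau of 1 after 400 ms, i.e. by 1006 ms into
the trial -- before the window of interest opens even for the shortest
(24 ms) trials, whose window starts at 1030 ms. Because the analysis only
ever reads the plateau, the rise shape is immaterial to every measured
quantity; what matters is that the injected amplitude is *exact* inside the
window, which is what makes machine-precision recovery tests possible.
Blinks mark samples invalid with pupil 0, as trackers report them.
Luminance is constant by construction (the mask fills the screen), so no
light reflex or luminance model is needed.

Population structure is layered on top by `amplitude_model()`: group-level
mean amplitudes per level and phase, a between-subject offset (SD 2
percentage points) constant across phases, and a per-phase disturbance
(SD 1.5 points). Task 2 is pinned at 0 -- it defines the reference. The
pre-phase default puts Task 4 at +2.2% and Task 3 at 0 (between the two
groups' observed baseline values); the trained group's post-phase means are
flattened to 0, controls keep their baseline values, and during training a
trained subject's amplitudes interpolate linearly from pre to post across
days. With these dispersions the follow-up two-sample t on the
difference-of-differences has expectation near the reported effect size
(|t| just above 2 at n = 10 + 10), so power for the Group x Time
interaction is a realistic ~60--70%, not an artificially easy 100%. No
per-subject variance is published for these effects; the dispersions are
chosen for testability and are configuration, not physiology.

# The measurement pipeline

1. **Fixation detection** is dispersion-based (I-DT): maximal runs of valid
   samples whose summed x/y range stays within 1.0 gaze units (degrees as
   abstract geometry) for at least 100 ms. The published analysis delegated
   this to vendor software; I-DT is the standard re-implementable choice
   and is validated against the generator's programmed saccade/blink ground
   truth (boundaries within 10 ms). Invalid samples always split runs, so
   no fixation contains a blink.
2. **Window of interest**: the 500 ms before probe onset, equal to the
   final 500 ms of the mask, where luminance is identical across
   conditions. All intervals are half-open `[start, end)`.
3. **Per-trial measure**: the mean over samples lying inside both the
   window and any fixation. A fixation straddling the window edge
   contributes only its in-window samples (sample-level intersection);
   whether the published analysis averaged per fixation instead is not
   stated, so `method = "fixation"` provides the alternative. A trial with
   no qualifying sample is missing, with the reason logged, never
   imputed.
4. **Per-condition means**: unweighted across non-missing trials -- the
   trial is the experimental unit, so unequal fixation coverage must not
   reweight trials.
5. **Normalization**: percent change from the Task 2 mean, which is
   defined to be zero. Ratios of within-session means cancel the session
   gain exactly; the package asserts this invariance to machine precision.
   Task 1 engages focused rather than divided attention and is excluded
   from analysis summaries (measured, but not normalized).

A session whose Task 2 mean is missing or non-positive fails normalization
loudly; adaptive-training blocks, where a task level can lack trials
entirely, are analysed with `normalize = FALSE` and handled by the
training-trend logic, which flags days with missing tasks
(`missing_task`) or fewer than 4 trials in Task 2 or 4 (`low_n`).

# The statistics

* **Within-subject error bars** (`cousineau_morey()`): per-subject centring
  plus the $\sqrt{M/(M-1)}$ bias correction for $M$ conditions. Exactly
  invariant to per-subject additive offsets.
* **Split-plot repeated-measures ANOVA** (`mixed_rm_anova()`): classical
  sums-of-squares decomposition via `aov()` with `Error()` strata, exact
  for the balanced designs this study produces; unbalanced or incomplete
  input is an explicit error, never approximated. The test suite verifies
  the full F/df/p tables against an independent brute-force cell-means
  oracle to 1e-9, together with the classical identity that a
  two-level within-factor F equals the squared paired t. No sphericity
  correction is applied by default (the reported dfs are uncorrected);
  all-constant input returns F = 0, p = 1 by definition rather than 0/0.
* **Post-hoc t tests**: closed-form paired and pooled two-sample t,
  two-sided, *without* multiple-testing correction -- matching how such
  designs are conventionally reported, and worth remembering near
  p = 0.05. Zero-variance differences with nonzero mean report infinite t
  with p = 0 and a warning.
* **Difference scores**: per subject and phase, Task 4 minus Task 2
  percent change. Task 2 is 0 by construction; the code asserts rather
  than assumes it. The follow-up to the Group x Time interaction is a
  pooled two-sample t on per-subject (post - pre) difference-of-difference
  scores, the construction consistent with 18 degrees of freedom at
  10 + 10 subjects.
* Baseline-only ANOVAs use one value per subject and task (subject-level
  observations), consistent with the 2 and 36 degrees of freedom the
  design prints.

# Problem sizes, runtime, and the condition-mean marginal

Full-scale sessions (500 test trials, twelve 375-trial training blocks per
trained subject, all with millisecond eye streams) are what
`generate_study()` writes by default. The test suite and the acceptance
script exercise the identical code paths at reduced trial counts -- e.g.
80-trial test phases and three training days of one 150-trial block -- a
choice of problem size, not of model: every rule, format, and invariant is
unchanged, and the percent-change estimator's precision at these counts
(measurement SE well below 0.01 percentage points per condition) is far
finer than any tolerance tested.

Large simulation studies of the *statistics* (e.g. 1000-replicate null
calibration of the Task F test) use `simulate_condition_means()`, the
generator's condition-level marginal: because the evoked kernel is exactly
1 throughout the window, a session's per-task windowed mean is exactly
$gB(1 + A/100)$ plus the averaged measurement noise, so the marginal draws
that quantity directly and pushes it through the real
`pct_change_from_task2()` and the real ANOVA. Crucially this preserves the
shared Task 2 denominator, which induces the equal-variance contrast
structure that makes the uncorrected F test calibrated; simulating the
normalized values naively as independent noise (with Task 2 frozen at 0)
would violate sphericity and inflate the type-I rate. Under a null
configuration the measured rejection rate is ~0.05, as it should be.

# Known limitations

* The observer is static within a phase; it does not learn trial by trial.
  Training-induced change enters only through the threshold shift at
  posttest and the day-wise amplitude interpolation.
* The pupil model has no light reflex, hippus, foreshortening, or
  gaze-position artifact -- the paradigm's window is equiluminant by
  construction, and those artifacts are out of scope.
* Saccade kinematics are schematic (linear relocation over 30 ms); they
  exist to exercise the fixation detector, not to model oculomotor
  dynamics.
* Passing tests on this synthetic data shows the *pipeline and statistics*
  are correct; it cannot show that real pupils behave like the generator.
  Group-level human F and t statistics are sampling realisations and are
  not reproducible from any simulation.
* Eye-stream files at full scale are large (~1.7 M samples per 500-trial
  session); `run_study()` therefore analyses in memory and writes summary
  intermediates, with full raw streams only via `generate_study()`.
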