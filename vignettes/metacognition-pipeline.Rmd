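---
title: "Estimating metacognitive efficiency from confidence-rating tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating metacognitive efficiency from confidence-rating tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacogsdt)
```

## The problem

Metacognition is the ability to monitor one's own performance: a good
self-monitor is confident when right and doubtful when wrong. Comparing
raw confidence between people is misleading, because confidence mixes
true self-knowledge with response bias, confidence bias, and first-order
task difficulty. Type-2 signal detection theory separates these.
`metacogsdt` implements the full analysis pipeline for a two-group study
design in which each subject performs a confidence-rated 2-AFC visual
task (contrast-oddball detection, difficulty controlled by an adaptive
staircase) and a confidence-rated old/new word-recognition task, and the
question is whether the groups differ in metacognitive efficiency in
either domain.

Because the package also has to be testable without access to human
data, it includes a first-class synthetic-observer module that generates
complete trial-level datasets with known ground truth.

## Type-1 model

Each trial presents one of two stimulus classes S1/S2 (interval 1 vs 2;
new vs old). The observer is modelled with Gaussian evidence:
$x \sim N(\mp d'/2, 1)$ and responds "S2" when $x$ exceeds a criterion
$c$. From the hit rate $H = P(\text{S2 resp} \mid \text{S2})$ and false
alarm rate $F = P(\text{S2 resp} \mid \text{S1})$,

$$ d' = z(H) - z(F), \qquad c = -\tfrac{1}{2}\,[z(H) + z(F)]. $$

The perceptual task is scored yes/no-style over the two intervals,
without the $\sqrt{2}$ 2-AFC correction: at staircase-controlled 71%
accuracy this gives $d' \approx 1.1$, the operating range the design
targets.

Old/new recognition data violate the equal-variance assumption: old
items carry extra mnemonic variability. The unequal-variance model lets
the two classes have different evidence SDs; their ratio $s$
(S1-to-S2, i.e. new-to-old, typically below 1) is estimated as the
slope of the zROC — ordinary least squares of $z(H_k)$ on $z(F_k)$
across the $2K - 1$ cumulative rating criteria, excluding endpoints at
0/1. Sensitivity is then reported on the $d_a$ scale,

$$ d_a = \sqrt{\tfrac{2}{1+s^2}}\,\bigl[z(H) - s\,z(F)\bigr], \qquad
   c_a = -\tfrac{1}{2}\sqrt{\tfrac{2}{1+s^2}}\,\bigl[z(H) + s\,z(F)\bigr], $$

which reduce to $d'$ and $c$ at $s = 1$. Note the S1/S2 coding: the
old-item distribution is the *signal* (S2) so that the conventional
memory zROC slope below 1 corresponds to old items being noisier; the
trial schema documents this mapping.

Zero cells make the z-transforms diverge, so tables are padded before
fitting: whenever any cumulative rating cell is empty or full, $1/(2K)$
is added to every cell (the convention of the widely used meta-d' code
family). The scheme is configurable (`"if-needed"`, `"always"`,
`"none"`) and recorded on the table. Confidence levels a subject never
used are retained as structural zeros rather than collapsed, so $K$
stays comparable across subjects.

## Type-2 model: meta-d' and M-ratio

The meta-d' idea: ask what type-1 sensitivity an SDT-ideal observer
would need in order to produce the *observed confidence behavior*. The
meta-level model has the same structure as the type-1 model — evidence
distributions separated by $\mathrm{meta}\text{-}d'$ (on the $d_a$
scale for the unequal-variance variant, with $s$ carried over from the
type-1 fit), the type-1 criterion carried at the same relative position
$c' = c/d'$ ($c_a/d_a$), and $K - 1$ free monotone confidence criteria
on each response side. Only the response-conditional rating
probabilities enter the multinomial likelihood; the observed type-1
choice behavior is taken as given, never re-fit. Metacognitive
efficiency is

$$ \text{M-ratio} = \mathrm{meta}\text{-}d' / d'
   \quad (\text{or } \mathrm{meta}\text{-}d_a / d_a), $$

which is 1 for an ideal metacognitive observer, below 1 when confidence
carries less information than the choice, and may be negative when
confidence is anti-informative; negative values are preserved
throughout.

A caveat inherited from the method: in the unequal-variance variant the
slope $s$ is estimated from confidence data and then held fixed in both
the type-1 and type-2 models, which strains the assumption that the two
models are independent. The pipeline surfaces this as documentation and
additionally reports the equal-variance variant for memory, as the
original analysis did.

### Numerical choices

* Criteria are parameterised as the carried criterion plus cumulative
  softplus increments, making monotonicity structural inside an
  unconstrained optimiser.
* The likelihood is maximised with `nlminb` and analytic gradients
  (unit-tested against finite differences), from three deterministic
  starts (scaled sensitivity, perturbed spacing) to dodge local optima;
  the best converged solution wins and the convergence flag is honest.
* `meta_d` is box-bounded in $[-5, 5]$; the objective tolerance is
  below $10^{-8}$.
* All-constant confidence is refused as degenerate rather than fitted.
* The fit is validated against an independent brute-force oracle (dense
  grid over meta-d with criteria profiled by Nelder-Mead under a
  different parameterisation); the two agree to 0.01 on random tables.

## The synthetic observer

One generative trial: a decision variable $x \sim N(\pm\,sep/2,\sigma)$
($\sigma = 1$ for S1, $1/s$ for S2); the choice compares
$x + \varepsilon_c$, $\varepsilon_c \sim N(0, \sigma_c^2)$, to the
criterion; the confidence variable is $y = x + \varepsilon_m$,
$\varepsilon_m \sim N(0, \sigma_m^2)$, binned by fixed criteria on the
chosen response's side.

* **Metacognitive noise** $\sigma_m$ degrades confidence only, driving
  M-ratio continuously below 1 (exactly 1 at $\sigma_m = 0$).
* **Choice noise** $\sigma_c$ degrades the decision only, leaving
  confidence better informed than the choice and producing M-ratios
  above 1, as seen empirically in control groups. It is supported only
  for $s = 1$, where the evidence-axis scaling is exact; memory-task
  target M-ratios are therefore capped at 1 (the default control
  memory target, 0.93, yields a censored normal with a small point
  mass at 1).

The mapping from a target M-ratio to a noise SD has no exact closed
form — conditioning on the response attenuates fitted meta-d' faster
than the naive $1/\sqrt{1+\sigma_m^2}$ evidence rescaling — so it is
calibrated once by simulation (400k-trial sessions, two fixed seeds per
grid point, sensitivity 1.1) and stored as a monotone lookup curve;
`calibrate_noise_map()` reproduces the procedure and a unit test checks
the stored curve against a fresh rebuild.

Confidence criteria default to offsets
`r paste(default_confidence_offsets(), collapse = ", ")` (evidence-SD
units around the decision criterion), calibrated once so a typical
observer reports mean confidence near 4.7 on the 6-point scale — the
overconfident band these tasks reliably produce (criteria partly below
the decision criterion express that overconfidence).

### Perceptual task and staircase

The oddball contrast starts 20 percentage points above the 20%
distractor baseline and moves by absolute 0.03 steps: up after any
error, down after two consecutive correct responses — the 1-up/2-down
rule, which converges near 70.7% correct. ("Step 3%" is read as
absolute contrast; the alternative relative reading is configurable.)
The synthetic observer's psychometric function is a cumulative Gaussian
in the contrast difference with a 2% lapse rate, parameterised by its
70.7%-correct threshold with the slope tied to the threshold
(a Weber-like one-parameter family). On each trial the detection
probability $p$ at the current contrast is realised through an SDT
decision variable with effective sensitivity $2\,z(p)$, so choice
accuracy is exactly $p$ while confidence flows from the same evidence.
Per-observer thresholds are drawn from truncated normals matched to the
group threshold summaries (0.19/0.09 and 0.16/0.05, bounded to
[0.04, 0.50]).

The threshold estimate is the mean contrast difference at reversals
after discarding the first four (reversal averaging; the accuracy
statistic uses all 180 trials, with no burn-in, matching how the study
summarises accuracy).

Subjects whose perceptual accuracy falls below the sample mean minus 8
SDs are excluded before group analysis. Mean and SD are computed
leaving the candidate out: with the candidate included the criterion is
vacuous at this sample size (the largest possible sample z-score is
$(n-1)/\sqrt{n} \approx 6.9$ at $n = 48$), so the leave-one-out form is
the only reading under which the rule can ever fire.

### Memory task

100 words are studied; the test presents all 200 (100 old, 100 new),
with the high/low imageability label crossed evenly so each
old/new-by-imageability cell holds 50 trials. Old items are drawn with
evidence-SD ratio $s = 0.8$. Imageability has no generative effect by
default (the study found none); `imageability_da_shift` exists as a
power-exploration knob. Memory sensitivity varies across subjects
(truncated normal, SD 0.3, bounds [0.1, 2.5]), reproducing the wide
accuracy range (roughly 50–85%) that an uncontrolled task produces.

### Cohort defaults

Group sizes 23/24; perceptual M-ratio means 0.67 vs 1.01 and memory
(unequal-variance) M-ratio means 0.82 vs 0.93; memory $d_a$ means 0.92
vs 1.19; response/confidence-time means per task and group from the
published timing table, drawn lognormal per trial around per-subject
means. The between-subject SDs of *true* M-ratio (0.2) and memory
$d_a$ (0.3) are generative choices: observed between-subject SDs also
contain estimation noise from 180/200-trial fits, and with these
values the observed SDs land in the published 0.3–0.45 band. Timing is
decoration for pipeline completeness — lognormal with CV 0.35, no
diffusion-style coupling to accuracy.

Cohort generation is exactly reproducible: one integer seed determines
every draw, and the manifest records each subject's true parameters
for recovery testing.

## Group-level statistics

Per subject and task the pipeline extracts sensitivity, mean
confidence, M-ratio (both variance models for memory, plus separate
unequal-variance fits for high- and low-imageable words — 100 trials
each), mean RT and confidence time, and for the perceptual task the
contrast threshold and accuracy. Group comparisons use a classic
Levene test (absolute deviations from group means — the study names
only "Levene's test", and the mean-centered classic form is the
default reading) to pick pooled versus Welch two-tailed t-tests at
$\alpha = 0.05$; Welch df are fractional. The mixed Group x Task ANOVA
(between x within) reports F, p and partial $\eta^2$; metacognition is
analysed both in the study's mixed-units form (equal-variance
perceptual with unequal-variance memory M-ratio) and all-equal-variance
form, labelled explicitly. Pearson correlations cover M-ratio versus
sensitivity within task, cross-task metacognition (pooled and per
group), and high- versus low-imageability metamemory per group.
Negative-M-ratio subjects are retained by default
(`retain_negative_m_ratio` switches the sensitivity analysis). No
multiple-testing correction is applied, matching the original analysis;
interpret nominal p-values accordingly.

## What the simulations do and do not show

The generator reproduces the design-level statistics (staircase-held
accuracy near 71% with about a point of spread; wide memory accuracy
range; overconfident mean ratings near 4.7) and the group-level means
it is pointed at. It does not model learning or fatigue across the
session, sequential dependencies, word-level effects beyond the
imageability label, or any RT-accuracy coupling; passing tests
therefore validate the estimation and statistics pipeline and the
design's power properties, not those aspects of real behavior.

Problem sizes used by the test suite were chosen to keep the full run
in the tens of minutes on one core: recovery checks use $10^4$-trial
sessions over 6–20 seeds; the dissociation check uses 100 full cohorts
at the published group parameters; null calibration uses 120
identical-group cohorts of 16 subjects per group at full trial counts.

## Known limitations

* The shared-$s$ caveat of the unequal-variance meta-d' approach is
  documented, not resolved.
* The carried type-1 criterion uses the fixed-$c'$ convention; the
  alternative of re-fitting the criterion inside the type-2 likelihood
  is not implemented.
* Choice noise (M-ratio above 1) is only generative for equal-variance
  observers.
* Unequal-variance M-ratio estimates from 200-trial sessions are heavy
  tailed (small fitted $d_a$ inflates the ratio); the pipeline keeps
  them, as the original analysis did, so group SDs can be large.
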