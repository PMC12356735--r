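---
title: "Modelling single-trial reward prediction errors and feedback-locked ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling single-trial reward prediction errors and feedback-locked ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`rlerp` implements a complete analysis chain for probabilistic feedback
learning with EEG: a task simulator, Rescorla–Wagner model fitting with
single-trial prediction-error export, feedback-locked ERP scoring, behavioral
metrics, and the associated linear mixed models. Every stage runs on
synthetic data with known ground truth, so the chain can be validated end to
end before it ever touches a recording. This vignette explains the models,
the tunable parameters, and the design decisions taken where the design was
genuinely open.

## The task

Each session has eight blocks of 40 trials (320 trials). Four abstract
stimuli appear ten times per block in randomized order: two *learnable*
stimuli for which one response side yields positive feedback ("+20ct") with
probability 0.90 and negative feedback ("−10ct") otherwise, and two
*distractors* with 50/50 feedback independent of the response. Feedback
follows the response after 500 ms (immediate session) or 6500 ms (delayed
session); every participant completes both sessions, order counterbalanced.
Two criterion rules shape the session: accuracy on valid learnable trials
strictly above 65% within the first two blocks triggers a fresh stimulus set
(to lengthen the pre-learning phase), and never exceeding 65% through block
eight appends a ninth block (to provide post-learning trials). Trials with
responses before 100 ms, after 3000 ms, with multiple presses, or without a
response are invalid and leave every analysis denominator.

Open points we fixed: the task description states only the correct-choice
contingency, so incorrect choices on learnable stimuli receive positive
feedback with probability 0.10 (the mirror of 90/10); "exceeded" is read
strictly (> 0.65); within-block presentation counts are equal (ten per
stimulus) because nothing suggests otherwise; and distractor feedback is
Bernoulli per trial rather than balanced per block — a per-block balance
would make late-block distractor feedback predictable from earlier trials,
which the task's logic gives no reason to allow.

## The learning model

Action values update by the delta rule, with the prediction error defined as

$$\delta_t = R_{a,t} - Q_{a,t}, \qquad Q_{a,t+1} = Q_{a,t} + \alpha\,\delta_t,$$

and choices follow a softmax over the two response sides,

$$p_{a_1,t} = \frac{e^{\beta Q_{a_1,t}}}{e^{\beta Q_{a_1,t}} + e^{\beta Q_{a_2,t}}}.$$

Learning rates are specific to each stimulus and feedback valence (eight
per standard session), all in $[0,1]$; one inverse temperature
$\beta \in [0,50]$ is shared. Fitting minimizes the negative log-likelihood
of the observed choices minus the log density of a gamma(shape 2, scale 3)
prior on $\beta$ — maximum a posteriori estimation that discourages
implausibly deterministic fits. Distractor trials stay in the likelihood:
the model is agnostic about learnability, and their learning rates simply
absorb whatever structure the random feedback induces.

Decisions the equations leave open:

* **Reward coding** is $R \in \{0, 1\}$ (negative/positive). This keeps
  $Q \in [0,1]$, $|\delta| \le 1$, and makes the centered unsigned PE span
  exactly $[-0.5, 0.5]$. The monetary magnitudes (+20/−10 ct) are display
  labels, not model quantities.
* **Initial values** are $Q = 0.5$: the first choice is unbiased and the
  first prediction error of every stimulus has magnitude 0.5, hence a
  centered unsigned PE of zero.
* **Unsigned PE centering** is $\mathrm{uPE} = |\delta| - 0.5$, increasing
  with surprise. The alternative direction $0.5 - |\delta|$ is exposed as
  `upe_center = "half_minus_abs"` in `fit_config()` /
  `compute_trial_pes()`; the default is the direction under which positive
  uPE slopes mean larger amplitudes for more surprising feedback, which is
  how such slopes are interpreted throughout.
* **Optimization** is bounded L-BFGS-B from 20 uniform multi-start points
  drawn under a fixed seed; the best objective wins and ties go to the
  earliest start. The lower bound for $\beta$ is $10^{-6}$ rather than 0
  because the gamma log-density diverges at zero; the reported bounds
  remain $[0, 50]$. The sequential likelihood replay is implemented in
  C++ (Rcpp) — fitting 50 agents takes on the order of two minutes.

A caution established by the package's own parameter-recovery analysis: at
session length (320 trials), the eight stimulus-by-valence learning rates
are only weakly identified from choices alone. The fitted objective
reliably beats the generating parameters' objective, and recovery error
shrinks as trials grow (mean absolute error roughly 0.32 at 320 trials vs
0.17 at 3200 in our runs), so this is an information limit, not an
optimizer failure: once a high-$\beta$ agent responds deterministically,
wide ranges of learning rates produce identical choice sequences. The
inverse temperature, by contrast, recovers well in rank order
(Spearman $\rho \gtrsim 0.7$). Trial-level regressors for the planted-truth
analyses are therefore built from the generative parameters, and fitted
learning rates should be interpreted with restraint on real data too.

## ERP scoring

Epochs span −200 to 600 ms around feedback onset; the mean of the 200 ms
baseline is subtracted per epoch and channel. Artifact rejection flags a
trial when any scored channel shows a sample-to-sample step above 50 µV/ms,
any absolute value above 100 µV, a within-epoch range above 100 µV, or a
range below 0.1 µV inside any sliding 100-ms window. "Difference between
values" is read as the epoch's max-minus-min per channel, the step as a
per-sample gradient scaled to µV/ms, and the low-activity window slides
with a one-sample stride; thresholds apply to the scored channels
(configurable).

The FRN is scored at the frontocentral site: the peak is the most negative
*strict* local minimum between 200 and 350 ms in the participant's
condition-average waveform (endpoints excluded, ties to the earliest
latency), and the single-trial amplitude is the mean over ±20 ms around
that latency. Condition averages cross feedback timing × valence ×
learnability — the within-subject factors of the ERP models; the
appropriate crossing is an argument (`condition_by`) because other designs
may warrant a different one. When an average has no local minimum, all its
trials get missing FRN amplitudes and an outlier flag. P3a (frontocentral)
and P3b (centroparietal) are plain 300–500 ms window means and never
depend on peak detection. The FRN and P3a windows overlap on 300–350 ms by
construction; both are computed from the same epoch and reported
separately. Optional continuous preprocessing (0.1–30 Hz band-pass, 50 Hz
notch, mastoid re-reference) is provided for completeness but sits off the
default synthetic path, which generates artifact-light signals.

## Behavioral metrics

Block accuracy is the percentage of correct responses among *valid
learnable* trials; invalid trials leave the denominator and distractors
never enter. Choice switching asks, for each valid trial, whether the
response at the next valid presentation of the same stimulus (same session
and stimulus set) differs. Invalid trials are skipped in the forward search
because they carry no comparable response; the last presentation of a
stimulus has no successor and is missing. Response type (correct/false) is
undefined on distractor trials, and such rows drop out of models that use
it.

## Mixed models

All categorical predictors are simple coded at ±0.5 (patient, delayed,
positive, learnable, correct = +0.5), block is standardized over the
modeled rows, and the unsigned PE enters as a continuous predictor in
$[-0.5, 0.5]$. Five templates mirror the study design: accuracy
(group × timing × block), switching (group × timing × valence × response
type × block), and FRN/P3a/P3b (group × timing × uPE × valence ×
learnability), each with its maximal by-participant random structure.

Model fitting attempts the maximal random structure first, retries a
failed or singular fit with the bobyqa optimizer, and then deletes random
terms one at a time — interactions before main effects, higher order
first, last-listed first within an order — until a stable fit is reached.
The fixed-effects formula is never touched. Singular fits count as
failures and trigger the same reduction; the intercept-only structure is
the terminal fallback and is accepted (flagged) even when singular,
because a mixed model of repeated measures should not silently drop the
participant intercept. Fixed-effect inference uses Satterthwaite
approximate degrees of freedom; p < .05 two-sided throughout, with no
multiplicity correction. Switching models treat the 0/1 flag as Gaussian —
the convention under which such coefficients are reported as mean
differences — and a logistic variant is deliberately out of the default
path.

Simple slopes of a focal predictor are linear combinations of the fixed
coefficients: differentiate the fixed part with respect to the focal
variable and evaluate the moderators at their ±0.5 codes, everything else
at its centered zero. Standard errors, Satterthwaite degrees of freedom
and p-values come from the fitted coefficient covariance via
`lmerTest::contest1D()`. Influence screening reports Cook's distances —
by default leave-one-participant-out, since influential units in a
repeated-measures design are whole subjects — with a 4/n flagging cutoff
(the method names no threshold; 4/n is the common rule of thumb).
Observation-level distances are available as an option. Flags are
reported, never acted on.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline is validated. Cohorts default to 21 patients and 25
controls, matching the study scale. Agents draw learning rates from
Beta(2, 4) (mean 0.33 — moderate learning) and inverse temperatures from
the gamma(2, 3) distribution that also serves as the fitting prior,
truncated at 50; 3% of trials are made invalid to exercise the exclusion
rules. Patients and controls behave identically by default — mirroring the
absence of a behavioral group difference — and differ only through the
planted ERP coefficients.

Single-trial amplitudes follow a linear model in the coded design:
by default a valence effect of 0.65 µV and group effect of −1.61 µV on the
FRN, a timing effect confined to controls (timing −1.1, timing × group
2.06), and unsigned-PE coding confined to positive feedback in controls
(conditional slope 0.98 µV on the FRN, 1.95 on the P3a; the P3b plants
timing-dependent uPE coding in controls: 1.18/2.36/−0.97/0 for
positive-immediate/positive-delayed/negative-delayed/negative-immediate).
`upe_slope_terms()` converts such conditional-slope specifications into
interaction coefficients exactly. On top of the fixed part sit a
by-participant random intercept (SD 6 µV) and residual noise (SD 5 µV),
giving a marginal single-trial SD near 8 µV — the scale observed for these
components. All coefficients and SDs are configurable.

Continuous EEG embeds each trial's amplitudes into two channels using
compact-support components: a smooth (raised-cosine) FRN dip on ±20 ms
around 250 ms whose scoring-window mean equals the planted amplitude,
riding on a zero-window-mean trough anchor that guarantees a detectable
negative peak at the planted center regardless of the amplitude's sign,
and a P3 bump on 300–500 ms normalized the same way. Compact support is
what makes the zero-noise round trip *exact* — a Gaussian bump's tails
would leak across the scoring windows — and is the deliberate departure
from a more physiological waveform. What the generator does **not**
emulate: 1/f background spectra, ocular and muscle artifacts, volume
conduction across a full montage, or any ERP structure beyond the planted
linear model. Passing round-trip tests therefore shows the *scoring
arithmetic* is right, not that the pipeline is robust to real-world noise.

## Problem sizes and numerical choices

The validation suite runs at deliberately chosen scales: feedback
contingencies at 10,000 draws (binomial SE ≈ 0.3–0.5%), likelihood
equivalence exhaustively over all 4,680 toy sequences of up to four
trials, parameter recovery over 50 agents at 320 trials, type-I
calibration over 500 null replicates of a 20-participant design, and
planted-effect recovery pooled over eight replicate studies at full cohort
size. Pooling deserves a note: a true-null conditional slope tested at
α = .05 is significant in 5% of seeds by construction, so the recovery
check asserts pooled *estimates* against the planted values (within
±0.3 µV, about 2.6 pooled standard errors) rather than demanding a
particular per-seed significance pattern; the planted 0.98 slope must
additionally be significant. All randomness flows through explicit seeds,
and equal seeds reproduce events tables bitwise.

## Known limitations

Learning-rate identifiability at session length is the main one (above).
Peak detection on noisy condition averages inherits the sensitivity of the
most-negative-local-minimum rule: when a participant's average FRN rides
high (a large positive intercept), the planted trough's absolute value can
sit above small noise dips elsewhere in the search window, and the
detected latency scatters — visible in the noisy round trip of
`analysis/03_score_erp.R` as sub-µV scoring error. Deepening the embedded
trough anchor would fix the latency at the cost of pushing extreme trials
across the ±100 µV artifact threshold; the default keeps planted
artifact flags exact and accepts the latency jitter, which is also what
noisy real averages produce.
The FRN/P3a window overlap is inherited from the scoring definitions.
Continuous-EEG generation is memory-proportional to the inter-trial
interval, so delayed sessions at 1 kHz are large; the analysis scripts use
250–500 Hz and trial subsets where the full rate adds nothing. The
stepwise reduction order is one reasonable, fully deterministic choice
among several used by stepwise tools; the realized structure is always
reported so a reader can see what was actually fitted.
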