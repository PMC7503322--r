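---
title: "Simulating stressor-controllability experiments with shuttlebox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating stressor-controllability experiments with shuttlebox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(shuttlebox)
```

## The paradigm

Learned-helplessness research rests on the triadic design: one group can
terminate an aversive stimulus by its own action (escapable condition,
EC), a second group receives exactly the same stimulation but without any
action–outcome contingency (yoked inescapable condition, YC), and a third
receives no stimulation at all (control, CC). Because yoking equates
stress exposure, any EC–YC difference isolates the effect of
*controllability* rather than of stress per se. After induction, subjects
are tested in a new environment where escape is objectively possible; the
classic animal apparatus is the shuttle box.

`shuttlebox` implements a human translation of this design end to end,
with simulated participants in place of humans:

* **Study 1** (three groups): 40 stress-induction trials. Each trial
  delivers 6 s of pre-cue stimulation; a cue then opens a 1-s response
  window. For EC, any press inside the window stops the stimulation
  (total duration = 6 s + reaction time); a late press or miss extends it
  to the 15-s cap. Ratings of aversiveness, perceived control,
  exhaustion, frustration and helplessness are collected on a 1–7 Likert
  scale after every 10th trial; inter-trial intervals are 1 s ± 250 ms.
* **Study 2** (EC and YC only): 60 trials over three cues (circle,
  triangle, square), each shown equally often. EC participants must
  discover, by trial and error, which of three buttons matches each cue;
  only a *correct* in-window press terminates the stimulation. The
  duration cap starts at 10 s and drops by 0.5 s after every 15th trial
  (10 / 9.5 / 9 / 8.5 s). Ratings follow every 15th trial (frustration
  omitted).
* **Yoking.** In study 1 each YC participant inherits, trial by trial,
  the exact stress durations of one EC partner; the cue onset is shifted
  so stimulation continues 1–4 s (uniformly) past the cue no matter how
  fast the YC participant responds. In study 2, YC durations are the
  per-trial *means* over the whole EC pool, randomly shuffled
  (pseudo-yoking).
* **Escape behaviour test.** A 15×15 grid with 4 hidden safe cells; the
  participant starts at the centre, explores stress-free, then endures a
  stress phase that ends on reaching a safe cell or at a cap. Study 1:
  one block of five trials, 10-s exploration, 20-s stress cap, position
  carried from exploration into stress. Study 2: two blocks of five
  trials, 5-s phases, position reset to the centre at every phase start,
  and — the critical manipulation — safe cells silently relocated for
  block 2.

## Design decisions in the simulator

* **Time is continuous seconds** (millisecond precision), event-driven;
  durations, not frame ticks, are what the procedure specifies.
* **Study-2 pre-cue duration and ITI** are not separately specified for
  the improved variant and are inherited from study 1; both are ordinary
  config fields and can be overridden.
* **Cue order** is a balanced random permutation (each cue exactly
  `n_trials / n_cues` times) without run-length constraints.
* **Pseudo-yoking and the decrement cap.** A plain shuffle of the EC
  mean vector can push an early-trial mean (≈9 s) into a late slot whose
  cap is 8.5 s. Clamping it would break the exposure-conservation
  guarantee that is the entire point of yoking, so the shuffle is
  cap-constrained: positions are filled in increasing order of their
  cap, drawing uniformly among the remaining means that fit. Feasibility
  is guaranteed because every mean is bounded by the cap of its trial of
  origin (Hall's condition). The output is an exact permutation of the
  mean vector *and* respects every cap.
* **Grid conventions.** The centre of the 15×15 grid is cell (7, 7)
  (0-based); the start cell counts as visited and is excluded from the
  safe-cell draw so no trial begins solved. Moves are single orthogonal
  steps; a move off the edge leaves the position unchanged but still
  counts as a key press (activity is key presses, not displacement).
  Safe cells light up when entered in either phase and become learnable.
  Block-2 relocation redraws all four cells independently of block 1.
* **Learner feedback** is applied only for in-window presses: a late or
  missing press says nothing about the cue–button mapping, and treating
  it as disconfirming would purge correct candidates.
* **CC trials** mirror EC timing with zero stimulation; a press ends the
  trial early, which keeps reaction times comparable across groups.

## The simulated participants

The paradigm provides no participant model, so the package defines one —
the agent — and ships three documented presets (`ec_like`, `yc_like`,
`cc_like`) that encode the behavioural phenotypes the design is meant to
detect. Four sub-models per agent:

* **Reaction times**: shifted lognormal (median = shift + exp(meanlog))
  with a miss probability. Presets: `cc_like` fastest (median ≈ 0.34 s),
  `ec_like` fast (≈ 0.40 s), `yc_like` slow (≈ 0.58 s, miss 8%) —
  uncontrollable stress slows cue-locked responding.
* **Learner**: EC-like agents eliminate disconfirmed buttons per cue
  (at most two errors per cue without lapses, so long-run accuracy is 1);
  YC-like agents press at random (their feedback carries no signal).
* **Ratings / affect**: linear-Gaussian with rounding and clipping to
  1–7 — the simplest family able to express monotone drifts such as a
  slight decline in perceived control over probes. Preset baselines
  order the groups as the paradigm predicts (YC most helpless, CC most
  in control). Affect scores (STADI total, PANAS positive/negative) are
  Gaussian pre-scores plus a pre-to-post shift, negative-valence shifts
  being largest for YC and absent for CC.
* **Navigation** is where the two stress histories diverge, and every
  mechanism is a standard stress/learning phenomenon expressed at grid
  scale:
  * *ec_like — memory-guided systematic search.* Searching skill
    develops with experience: early trials wander, and from the sixth
    trial the agent follows a boustrophedon sweep whose progress pointer
    persists across phases. In a stress phase with a remembered safe
    cell it takes a shortest Manhattan path to the nearest one. Stale
    memories (after relocation) are abandoned after `stale_persistence
    = 3` moves and purged on sight — rapid, flexible updating.
  * *yc_like — frantic, habit-bound search.* A momentum walk (repeat
    heading with probability 0.85, bounce off walls) that presses much
    faster (`move_interval = 0.12 s` vs 0.20 s, i.e. 500 vs 300 key
    presses per minute — the high-activity signature). Its memory is
    rigid where it should be flexible and fragile where it should be
    stable: locations rehearsed over two or more trials are retained
    essentially for ever, but locations first encoded *under acute
    stress* survive a trial transition with probability only 0.05
    (stress-impaired encoding), and the survival of all once-seen
    locations erodes to that level as time on task accumulates. In the
    stress phase the walk is captured by the *most-rehearsed* remembered
    location — habit-ordered, not distance-ordered recall — even when it
    is stale, with imprecise pursuit (`nav_noise = 0.1`), and stale
    locations are kept in memory after being found empty
    (perseveration). With accumulating time under uncontrollable stress
    the stress-free phases are increasingly spent clinging to remembered
    spots or the familiar start region instead of exploring
    (`safety_bias = 0.6`, ramping in over the first six trials) —
    safety behaviour / passivity.
  * Every phase starts with a rotated initial heading so that undirected
    search fans into a different grid sector each phase rather than
    retracing one corridor.

  Together these produce the paradigm's signature on the study-2 grid:
  both phenotypes learn block 1, but after the silent relocation the
  EC-like searcher re-sweeps and recovers (improving its escape rate)
  while the YC-like searcher squanders its much higher activity on old
  locations and fails to re-learn — less efficient behaviour exactly
  where the efficiency score (activity per minute per escape) is
  designed to look.
* **Population heterogeneity.** A preset is a population mean;
  `sample_participant()` draws individuals by jittering the RT scale
  (meanlog ± N(0, 0.3)) and rating baselines (± N(0, 0.8), clipped).
  Navigation is not jittered — between-participant variability on the
  grid already arises from random layouts and stochastic policies.

The preset parameter values were fixed once, by pilot simulation at the
package's design stage, to make these qualitative contrasts reliable at
realistic group sizes; they are not fitted to any human data set and no
claim of cognitive-process realism is attached to them.

## Behavioural metrics

Per participant and block: exploration (distinct cells visited per
minute of stress-free time, start cell included), escapes (stress phases
ended by reaching a safe cell), and efficiency — activity per minute of
stress-phase time divided by the number of escapes, so *higher = less
efficient*. Efficiency is undefined for a zero-escape block and is
propagated as a missing value, which later costs the participant
listwise in repeated-measures analyses (visible as reduced error df).
Mean reaction time uses in-window presses only; a participant with none
is flagged rather than averaged. The study-2 EC correct-response rate
counts correct in-window presses over all trials.

## The statistical pipeline

* **Outlier rule**: values outside `[Q1 − 3·IQR, Q3 + 3·IQR]` are
  excluded ("extreme" box-plot outliers only). Quartiles use linear
  interpolation (type 7) — the most common convention, documented here
  because the rule's source names none.
* **Chi-square**: Yates continuity correction for 2×2 tables, none for
  larger ones — the only combination consistent with both published sex
  comparisons (0.03 uncorrected 2×3; 0.06 corrected 2×2).
* **t-tests** are Student (pooled variance), with Cohen's d from the
  pooled SD — required to reproduce the published d = −0.36 from the
  printed age summaries and consistent with df = n1 + n2 − 2 reporting.
  Both the t-test and the one-way ANOVA (partial eta squared) can run
  from printed `(n, mean, SD)` summaries, and the raw-data path reduces
  to the summary path so the two agree exactly.
* **Kruskal–Wallis** adds the eta-squared-H effect size
  `(H − k + 1)/(N − k)`, reported as-is even when slightly negative.
* **Mixed rmANOVA** (one between factor, one within factor, unequal
  group sizes supported): between effect from a one-way ANOVA on subject
  means; within and interaction effects as univariate tests on
  orthonormally contrast-transformed data with type-III
  (unweighted-marginal) sums of squares against the subject×within error
  stratum. Greenhouse–Geisser epsilon is estimated from the pooled
  within-group covariance of the transformed data and applied whenever
  there are more than two within levels (with two levels sphericity is
  trivial and epsilon is exactly 1). Exactly constant within-subject
  profiles are reported as F = 0 rather than as the 0/0 rounding residue
  they would otherwise produce. Subjects missing any within level are
  dropped listwise and counted.
* **Multiplicity**: Holm step-down for post-hoc families; Bonferroni
  with an explicit family size for the dependent-variable families. The
  published analyses state the rule but not the family memberships; this
  package groups each phase's dependent variables into one family (acute
  ratings + RT; the three affect scores; the three escape metrics) and
  records the correction next to every row of `analysis_report()`.
* **Outlier screening and the pattern-recovery check.** The
  paper-layout `analysis_report()` applies the extreme-outlier fence
  before its tests, including (as missing values) the repeated-measures
  variables — faithful to the published procedure, whose box-plot
  screening targets artifacts of human data collection.
  `replicate_efficiency_interaction()`, by contrast, tests the raw
  efficiency scores with listwise deletion only: in a generative
  simulation an extreme efficiency score *is* the behaviour of interest,
  not an artifact, and screening it would discard exactly the signal the
  check is about.

## What the generator does and does not emulate

The synthetic cohorts reproduce the paradigm's structure (timing,
yoking, probes, grid mechanics) and the qualitative group contrasts its
read-outs are designed to detect. They do not emulate: inter-individual
trait moderators (locus of control, self-efficacy), habituation or
sensitisation dynamics in ratings beyond a linear drift, physiological
stress responses, item-level questionnaire content (only total scores
are generated), or any quantitative match to published human effect
sizes. A passing simulation therefore validates the machinery and the
direction of the designed contrasts, not numerical claims about human
behaviour.

## Numerical choices and problem sizes

Seeds flow through a single deterministic hash (`derive_seed()`), giving
every component (timeline, yoking, layouts, behaviour, population draw)
an independent, individually reproducible stream; identical inputs give
byte-identical sessions, records and CSV logs. Durations are compared
with a 1e-9 s slack where caps are enforced. The package's own test
suite exercises the pipeline at the study's scale: 100 yoked pairs for
exposure conservation, 10,000 draws for the cue-onset law, over 1,000
grid trajectories against brute-force metric oracles, and 100 replicate
experiments of 50 + 50 participants for the efficiency-interaction
pattern; these sizes keep the default test run in the minutes range on a
single CPU while leaving the checks statistically meaningful.

## Known limitations

* The agent population is a design instrument, not a fitted model; its
  parameters should not be interpreted as measurements of human
  cognition. The published mean correct rate of study-2 EC participants
  (0.60) is substantially below the presets' (≈ 0.9 with rare lapses):
  matching it would require modelling unmeasured human factors, which is
  out of scope.
* The efficiency score inherits the published definition's instability
  at low escape counts (it is a ratio with a small integer denominator);
  its undefined-at-zero behaviour is propagated, not smoothed.
* Robust (trimmed-means) repeated-measures ANOVA and rank-based effect
  sizes for two-sample comparisons are not implemented; the pipeline
  covers the primary analyses only.
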