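---
title: "Simulating tablet-based vision screening: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating tablet-based vision screening: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivalscreen)
```

rivalscreen re-creates, as deterministic and seedable code, a three-part
tablet screening protocol for childhood amblyopia: an interocular
brightness-disparity staircase played under binocular rivalry, a tumbling-E
visual-acuity state machine with a pinhole retest, and a digital
AO-HRR-style colour-vision test. Simulated observers stand in for child
subjects so that the protocol's screening performance can be studied as a
property of the model rather than estimated from scarce clinical data. This
vignette documents the models, every tunable that matters, the design
choices made where the protocol description left the mechanics open, and
what the simulations can and cannot say about real screening.

## The brightness-disparity staircase

Two rivalrous stimuli (one per eye, separated by polarizers in the physical
test) differ in physical brightness by a signed disparity on a fixed grid:
multiples of `step = 0.3` log units up to `max_disparity = 1.8` (positive =
right-eye stimulus brighter). The subject taps the brighter-looking
stimulus; each tap moves the disparity one step *against* the chosen eye.
A **crossing** is a response reversal — two consecutive taps choosing
opposite eyes — and brackets the perceived-equality point between the two
disparities at which those taps occurred. A game ends after
`required_crossings = 2` crossings ("crossed and re-crossed").

The **endpoint** is scored as the mean of the crossing midpoints, snapped
to the step grid with ties toward zero, and reported with the
left-eye-deficit sign convention: a positive endpoint of 0.3 means the
right-eye stimulus had to be 0.3 log units brighter for perceived equality,
i.e. a 0.3 log-unit left-eye (OS) deficit. Averaging reversal midpoints is
the standard way of scoring up-down staircases, and here it carries an
exactness guarantee proved by the test suite: a noiseless observer whose
interocular attenuation difference lies on the grid recovers it *exactly*,
from every start level.

```{r staircase}
run_brightness_game(observer_amblyope(delta = 0.3))$endpoint
```

Two mechanics were genuinely open and are package design choices:

* **Tie behaviour.** A noiseless observer at exact perceived equality
  repeats its previous choice (perceptual hysteresis; right eye with no
  history). This makes the two crossings bracket the equality point
  symmetrically from both sides, which is what makes reversal averaging
  exact. A trial-parity alternation rule was rejected because it breaks
  that symmetry for half the deficit values.
* **Start levels.** Games start at the grid extreme (first crossing is then
  always informative) and the three games of a session alternate sides
  (+1.8, −1.8, +1.8) to cancel starting-side bias.

A trial budget of `2 * (2 * max/step + 1) * required_crossings` trials (52
at defaults) guarantees termination under arbitrary response sequences; a
game stopped at the budget reports the clamped disparity as its endpoint
and flags `ceiling = TRUE`.

**Classification.** A session is `"balanced"` (normal) when at least two of
the three endpoints are zero *or* when the nonzero endpoints disagree in
sign. The sign-discordance clause is deliberate: a treated amblyope with
alternating ocular preference (endpoints 0.3 OS / 0.3 OD / 0.0) scores
normal, which is the only reading under which such a subject is not a false
positive. A stricter reading — signed endpoints must sum to zero — is
available as `staircase_config(balance_rule = "net-sum")`.

## The tumbling-E acuity protocol

Pairs of equally sized tumbling Es are judged same/different (match drawn
50/50 from the seeded generator). The chart ladder is
400, 200, 100, 80, 60, 50, 40, 30, 25, 20 (Snellen denominators, i.e.
20/400 … 20/20); the protocol names only the endpoints, the 20/60 start and
the 20/30 cutoff, so the intermediate lines follow common clinical charts
and are configurable. Three correct responses advance one line. The first
error at a line opens a *second chance* of up to three fresh pairs at that
size; any further error ends the run there. A run from the 20/60 start that
completes no line restarts once from 20/400, and results pool: the recorded
acuity is the smallest line with three correct responses anywhere in the
session. Failing the 20/400 line is recorded as *below floor* ("less than
20/400") — an explicit flag, not a sentinel number, so numeric summaries
must consciously exclude or cap such records.

An eye measuring 20/30 or worse (or below floor) is retested through the
pinhole; better eyes are not retested and carry no pinhole field.

```{r acuity}
run_eye_protocol(observer_refractive(0.3), "OD", seed = 1)
run_eye_protocol(observer_amblyope(neural = 0.3), "OS", seed = 1)
```

## The colour test

The packaged plate set (`hrr_plates()`) is a synthetic stand-in for the
AO-HRR book: 4 demonstration plates and 20 test plates (14 red-green, 6
tritan), counts configurable via `make_plate_set()` since the real plate
inventory is proprietary artwork. Demonstration plates gate qualification;
test plates follow in a seeded shuffle. The scoring rule — at least
`defect_threshold = 2` errors on one axis marks a defect — is a package
assumption, as no scoring rule is published for the digital presentation.
Two defective eyes with identical labels classify as hereditary
(`bilateral-identical`); a single defective eye as acquired (`monocular`),
the pattern of the amblyopic eye's blue-yellow defect.

## Simulated observers

`observer_profile()` is the generative model; each archetype mirrors a
subject type the screening distinguishes.

| parameter | units | default | meaning |
|---|---|---|---|
| `brightness_attenuation` | log units/eye | 0 | additive dimming of that eye's percept |
| `neural_logmar` | logMAR/eye | 0 | acuity floor the pinhole cannot fix (amblyopic loss) |
| `refractive_logmar` | logMAR/eye | 0 | optical blur, removed by the pinhole |
| `color_axis` | —/eye | `"none"` | axis of missed shape plates |
| `decision_noise` | log units | 0 | logistic scale of brightness choices |
| `acuity_guess_rate` | probability | 0 | P(correct) on sub-threshold E pairs |
| `color_miss_prob` | probability | 1 | P(miss) on defect-axis plates |
| `preference_cycle` | log units/game | `NULL` | alternating ocular preference |

Three modelling choices deserve emphasis:

* **Additive log-luminance attenuation** is the minimal perceptual model
  consistent with grid-valued equality endpoints; no claim is made about
  the physiology behind amblyopic brightness imbalance.
* **Sub-threshold acuity responses are reliably wrong by default**
  (`acuity_guess_rate = 0`) rather than 50/50 guesses. This keeps the
  noiseless protocol exactly equal to its closed form — the smallest ladder
  line at or above the effective threshold — for every seed, which is what
  makes the worked endpoints reproducible. Chance-level guessing
  (`acuity_guess_rate = 0.5`, true two-alternative chance) is used in the
  stochastic simulations; it can only flatter the record, never worsen it.
* **No psychometric slope** between lines, and no lapses: responses switch
  abruptly from correct to incorrect at threshold. Real children show
  gradual transitions and attention lapses; the simulations therefore
  bound, rather than estimate, field performance.

## Cohorts, referral and the headline result

`simulate_cohort()` expands archetype counts into profiles; the default
mixture is the study's composition — 202 normal subjects and 2 unilateral
amblyopes whose brightness attenuations cycle through 0.3 and 0.6 log
units (the two reported endpoint magnitudes) with a 0.3 logMAR neural
loss. Referral reasons, each independently sufficient: brightness
imbalance; best measured acuity worse than 20/30 in either eye; monocular
colour defect. Treated amblyopes carry a non-target truth label for
amblyopia detection, matching how an alternating-preference subject was
counted in the study cohort.

With noiseless observers and every amblyope at least one step (0.3 log
units) of attenuation, brightness-only screening separates the two groups
*perfectly for every seed* — 100% sensitivity and specificity is a theorem
of the model (exact staircase recovery plus the 2-of-3 rule), not an
empirical estimate. The simulations reproduce the study's headline number
but cannot, by construction, validate it against field variability.

```{r cohort}
profiles <- simulate_cohort(list(normal = 202, "unilateral-amblyope" = 2),
                            seed = 42)
records <- run_cohort(profiles, screening_config(tests = "brightness"),
                      seed = 42)
evaluate_screening(records, rule = "brightness")
```

## Decision noise: the power-analysis surface and its edge

With `decision_noise > 0`, brightness choices become logistic in the
perceived difference and specificity degrades as noise grows. The
degradation is monotone over the instrument's operating range — noise up to
roughly the 0.3 log-unit step (the acceptance sweep uses
0.025–0.4 log units, 200 common random seeds per point, with common random
numbers across noise levels for variance reduction).

Beyond that range the curve *turns back up*, and this is a finding worth
stating plainly: when responses are near-random, first crossings cluster
near each game's start disparity, and because the three games alternate
start sides the endpoints come out sign-discordant — which the 2-of-3 rule
scores as balanced. Measured with 3000 seeds, specificity falls from 89% at
noise 0.2 to 81% at 0.4, then recovers to 88% at 0.8. In field terms: a
child tapping at random tends to score *normal*, not abnormal. Screening
programmes relying on this protocol need an independent attentiveness check
(the study's demonstration-plate gate plays that role for the colour test).
A related snapping artefact caps the other monotonicity property: the mean
recovered |endpoint| orders correctly with the true deficit only while
noise stays below the step, because the ties-toward-zero grid snap absorbs
one-step deficits under heavier noise.

## Agreement statistics

`bland_altman()` follows the 2·SD convention (not 1.96·SD) with the sample
(n−1) standard deviation; eyes, not subjects, are the pairing unit, and
intra-subject correlation is deliberately ignored — both conventions match
how acuity-chart agreement is customarily reported, and both are
configurable or documented where they matter. Printed-summary arithmetic
(d ± 2·SD from rounded d and SD) can disagree with limits computed from
unrounded data in the second decimal; the package validates the former,
since raw per-child data are not published. One caveat the simulations
surface: chart-line differences are discrete and leptokurtic (a spike at
zero plus line-jump tails), so 2·SD limits cover slightly less than the
nominal ~95% — the packaged two-variant cohort simulation measures 118/126
≈ 94%.

## Problem sizes and numerical conventions

The shipped simulations use a 204-subject cohort for the headline metric,
169 deficit-by-start combinations for exact staircase recovery, 1,000
random paired sets for the Bland–Altman oracle comparison (agreement to
1e−12), and 200–500 seeds per point for the stochastic sweeps — sizes at
which every reported quantity is stable to well under its printed
precision. All percentages round half-away-from-zero (`round_percent()`),
the single convention consistent with the study's printed rates. All
staircase arithmetic is done on an integer step grid internally, so no
floating-point drift can move an endpoint off-grid. Every stochastic
routine takes a seed and scopes it (`withr::with_seed`), leaving the
caller's RNG state untouched; session JSON files are written canonically
(fixed key order, 10 significant digits) so identical runs are
byte-identical.

## Known limitations

* Observers have no attention lapses, no learning, no response-time
  structure; testing-time and enjoyment outcomes of the original study are
  out of scope.
* Display physics (luminance calibration, gamma, polarizer crosstalk) is
  abstracted into the log-unit disparity grid.
* The plate set is synthetic; severity grading (mild/medium/strong) and
  real plate artwork are not modelled.
* Perfect separation in the noiseless cohort is a model property;
  real-world sensitivity for deficits smaller than one 0.3 log-unit step
  is unknown, and sub-step deficits are invisible to the staircase by
  construction.
* Extreme decision noise masquerades as a normal result (see above).
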