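---
title: "Deriving digital biomarkers from Klondike Solitaire gameplay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving digital biomarkers from Klondike Solitaire gameplay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solitairebm)
```

## The problem

Mild cognitive impairment (MCI) is underdiagnosed, and conventional
neuropsychological screening is laborious, episodic and stressful for the
patient. Commercial card games that older adults already play offer a
complementary measurement channel: every tap and drag in a game of Klondike
Solitaire is a behavioral trace, and traces aggregated into per-game
summaries — *digital biomarkers* — can be compared between clinical groups.
`solitairebm` implements that measurement chain end to end:

1. a deterministic **rules engine** for Klondike Solitaire,
2. a **telemetry** layer (JSON Lines event logs and a replay that classifies
   every gesture against the rules),
3. **extraction** of 23 named biomarkers in six categories,
4. two **synthetic-data generators** (an agent-based player and a
   model-based table generator),
5. an expert-rating **consensus** analysis (two-way consistency ICC), and
6. the **group-difference analysis**: per-biomarker generalized linear mixed
   models with crossed random effects, a likelihood-ratio test for the MCI
   effect, and marginal/conditional R².

The raw gameplay data of the motivating study are not public. The package
therefore treats the published result tables as *inputs*
(`reference_results()`, `cohort_reference()`) and validates the analysis
machinery by parameter recovery on synthetic cohorts.

## The game model

A position holds seven build stacks (face-up runs descend by rank with
alternating colors), four suit stacks (each a strictly ascending single-suit
run from the ace), a face-down stock and a face-up talon. `klondike_deal()`
deals 28 cards onto the board (stack *i* gets *i* cards, top card face-up)
and 24 into the stock. The permutation is a pure function of the seed
(shuffle scheme `mt-sample-v1`), so any logged game can be replayed exactly.

Choices the rules leave open, and what the package does:

* **Draw mode.** Draw-1 by default (`draw3` available). With one card per
  flip every pile tap is informative, which suits flip-rate biomarkers.
* **Scoring.** The classic scheme: +5 talon→build, +10 any→suit stack, +5
  for turning a face-down card, −15 for a worried move (suit→build), floored
  at 0. The deployed app's true scheme is unknown, so score-based
  conclusions are treated as app-specific; the scheme lives behind
  `apply_move()` and is deliberately simple.
* **Worried moves** off a suit stack are legal; they are required for the
  −15 rule and occur in real play.
* **Recycling** the talon into the stock is the same gesture as a pile flip
  and counts as one pile move.
* **Undo** restores the previous position exactly, score included, which
  makes the undo path property-testable (apply-then-undo is the identity).

## Telemetry and replay

A log is one participant-game: a header (participant, game index, seed,
draw mode, per-card touch rectangles in normalized `[0,1]²` coordinates)
plus a time-ordered gesture stream of pickups, drops, pile taps, undo taps,
hint taps and stray taps. `replay()` reconstructs the state sequence from
the seed and classifies each gesture:

* pickup+drop implying a legal relocation → `successful_board`;
* a drop violating the rank/color/suit rules → `erroneous_board` (the app
  rejects the drop, so the position is unchanged and the attempt is not
  undoable);
* a drop back at its origin → `neutral_board`;
* the taps map to `pile`, `undo`, `hint`, `stray`.

Timing semantics: think time runs from the end of the previous gesture to
the pickup (or tap); move time from pickup to drop (taps have move time 0).
The first gesture's think time starts at *t* = 0. With these boundaries the
per-gesture total is exactly think + move, which the extraction relies on.

Tap accuracy is `100·(1 − d/d_max)` clamped to `[0,100]`, with `d` the
distance from the tap to the touched card's center and `d_max` its
center-to-corner distance — a dead-center tap scores 100, a corner tap 0.
Center-to-corner normalization was chosen so the score is a true 0–100
percentage regardless of the card's aspect ratio.

## The 23 biomarkers

`biomarker_registry()` lists the catalog: six time statistics (think/move/
total × mean/SD over successful board gestures), five performance measures
(the final-β-error flag and the β, ace-β, king-β and pile-move
percentages), two error percentages (successful/erroneous share of board
moves), three execution measures (accuracy mean/SD, stray-tap count), two
auxiliary percentages (undo, hint) and five result measures (game time,
score, solved, cards-moved mean/SD). A *β error* is a missed opportunity:
flipping the pile, or moving, while a productive board move (generally, or
specifically an ace or king placement) was available.

Denominator conventions (the published definitions leave them open):

* board moves `B` = successful + erroneous attempts (aborted drags are
  excluded by default; `include_neutral = TRUE` adds them — the published
  group constants for the two error percentages do not sum to 100, so a
  third attempt class must at least be representable);
* pile moves `P` include recycles; game moves `G = B + P`;
* β error = share of pile moves made while any relocation existed; ace/king
  β errors count gestures taken while the placement was available but not
  played, over `G`, i.e. per gesture, not per opportunity episode;
* the pile-move share is `P/G` (a true percentage; with draw-1 play flips
  routinely outnumber board moves, so `P/B` would exceed 100);
* undo/hint percentages use `G + undo + hint` so they are bounded by 100;
* a zero denominator yields `NA` ("undefined"), never 0 — a game without
  pile flips carries no β-error information — and undefined values are
  dropped per biomarker (with a count) by the model stage.

`playable_opportunities()` reports `any_board_move` as "any legal
relocation exists", which includes worried moves, keeping it exactly
equivalent to the legal-move enumeration minus pile flips; the
king-to-empty opportunity excludes whole-stack king runs, which could only
shuttle between empty columns.

## The agent-based generator

`simulate_game()` plays a deal with a greedy priority policy — aces and
twos to the suit stacks first (always safe), then full-run moves that turn
a face-down card, then talon→build placements, then whole-run relocations
that vacate a column while a king is waiting, and other suit-stack
placements *last*: delaying them keeps tableau runs growing (the standard
keep-your-options-open strategy), so deeper games relocate progressively
longer runs. Impairment is expressed through a `cognitive_profile()`:

* lognormal think and move times (medians `exp(think_mu)`, `exp(move_mu)`);
* `p_overlook`: the per-card probability of missing an available move.
  Spotting a movable run means checking every card in it against the
  destination, so the miss probability compounds with run length
  (`1 − (1 − p)^n`): impaired players specifically under-use multi-card
  moves, which is what depresses their cards-moved statistics. Overlooking
  is also *sticky*: a candidate missed once stays unperceived until a
  successful move redraws attention to the board. Stickiness is what makes
  the parameter genuinely lossy — a stalled player keeps missing the same
  pairing, accumulates fruitless passes through the pile, and quits, where
  an independent per-decision miss would be retried at every flip and
  almost always recovered;
* `p_error`: illegal drop attempts (rejected, state unchanged);
* `tap_sd`: Gaussian pickup jitter around card centers (drives accuracy);
* `p_undo`, `p_hint`, `stray_rate` for the auxiliary gestures;
* `persistence`: consecutive fruitless passes through the pile before
  quitting. A full-overlook scan with an empty stock and talon also counts
  as a fruitless pass.

There is deliberately no look-ahead search: the agent emulates study
participants, not optimal play. The group presets (`healthy_profile()`,
`mci_profile()`) differ in the directions the expert-rated player actions
predict — slower thinking, more overlooking, more illegal attempts, noisier
taps, more fidget taps, less persistence — with magnitudes chosen once as
plausible defaults (median think 1.8 s vs 3.2 s; overlook 6% vs 22%; error
2% vs 8%). Under these defaults the impaired group's mean contrasts match
the signs of all twelve published significant effects, which is verified as
an acceptance property.

`generate_cohort()` draws ages (healthy: mean 70, SD 5.4; MCI: mean 80, SD
5.2) and tablet/game proficiency ordinals (0 = never .. 4 = daily) from the
published cohort frequency tables, jitters the group profile per
participant, and has every participant play the same three deals in order.
The three default seeds (2, 8, 9) are synthetic stand-ins for the study's
unpublished deals: the first three seeds a deterministic non-overlooking
agent can solve.

What the agent does *not* emulate: fatigue and learning across the three
games, strategic (deliberate) β errors, device-specific touch artifacts,
and within-session attention fluctuation. Passing tests therefore show that
the measurement chain is correct and directionally sensitive, not that the
simulated effect sizes match human ones.

## The model-based generator and parameter recovery

`generate_from_glmm()` draws biomarker tables directly from the analysis
model: `η = constant + β_mci·MCI + β_age·age + β_tablet·tablet +
β_game·game + u_participant + u_seed + u_slope·MCI`, identity link adding
Gaussian residual noise, logit link drawing Bernoulli outcomes. Covariates
come from the same cohort reference as the agent. Because the published
table reports only the intercept and the MCI coefficient, the other fixed
effects default to 0.

Variance components are not published. For identity-link rows
`spec_from_reference()` calibrates them from the row's own printed
marginal/conditional R² under the package's variance decomposition
(fixed-effect variance `β²/4` for a balanced two-group design; random
share split participant : seed : slope = 70 : 20 : 10), so that a planted
row reproduces its printed R² pattern by construction. The two logit rows
print R²c < R²m — inconsistent with the decomposition — so logit rows use
fixed defaults (participant SD 1, seed SD 0.5, slope SD 0.5 on the
log-odds scale), keeping participant variance dominant and the Laplace
approximation accurate.

## The group-difference analysis

`fit_biomarker_glmm()` fits, by maximum likelihood (never REML), the model
with fixed effects for MCI, age and the two proficiency ordinals (entered
as numeric 0–4; dummy coding is a generator/model coding choice that must
simply match on both sides) and crossed random intercepts for participant
and game seed. `lrt_mci()` removes only the fixed MCI term — the random
structure, including the by-participant MCI slope when present, is kept in
the reduced model — and refers `2·Δ log L` to χ²₁. `r2_nakagawa()` computes
the variance-decomposition R² with `π²/3` as the distribution variance for
the logit link. `results_table()` assembles one row per biomarker in
registry order, recording per-biomarker failures in-row;
`significance_filter()` is a strict raw-p cutoff with no multiplicity
correction, matching the exploratory single-test design.

**The by-participant MCI slope.** MCI does not vary within a participant,
so the slope is equivalent to letting the participant variance differ by
group, and it is only weakly identified. For continuous biomarkers the
package keeps it ON by default (with a documented fallback that drops it
when the fit is singular). For binary biomarkers it is OFF by default: with
three games per participant and the solve rates implied by the published
solved row (≈7% vs ≈1%), the slope's likelihood is maximized at degenerate
values — the slope variance inflates without bound and drags the MCI
coefficient far past its true value, while the fit is *not* singular, so
the singularity fallback never triggers. The slope-free mixed logistic
model recovers planted coefficients well. `random_slope = TRUE` restores
the literal model for either link.

## Numerical and testing choices

* All randomness is derived from explicit integer seeds through an
  RNG-preserving wrapper; simulating never perturbs the caller's RNG
  stream, and the pipeline derives stage seeds from one master seed.
* The ICC is computed from explicit two-way ANOVA mean squares (targets as
  rows, raters as columns), single and average measures, with the standard
  F-based confidence interval; its tests compare against an `aov()`-based
  oracle and a permutation null. Reliability bands use the conventional
  0.5/0.75/0.9 cutoffs with inclusive lower bounds. The average-measures
  unit is the default report: the panel consensus, not a single expert, is
  the measurand of the rating design.
* Zero between-target variance, degenerate card rectangles, empty logs and
  zero denominators raise typed errors or `NA` flags rather than
  propagating NaN.
* Problem sizes used by the test-suite simulations: the legal-move oracle
  runs on 1,000 random mid-game positions; the overlook-monotonicity check
  uses 200 games per setting; parameter recovery uses 500 participants per
  group with 3 games each; the type-I study uses 500 likelihood-ratio
  replicates at 20 participants per group. These sizes give Monte-Carlo
  error comfortably inside the asserted bounds.

## Known limitations

* The engine validates and enumerates but does not prove solvability; the
  default deals are certified only by the deterministic agent's play.
* The score scheme and draw mode of the original app are unknown; score
  comparisons across apps are not meaningful without re-calibration.
* Agent-based effect magnitudes are package defaults, not estimates; only
  effect *directions* are claimed.
* The mixed logistic path uses the Laplace approximation (crossed random
  effects preclude adaptive quadrature in lme4); with very rare outcomes a
  few percent of attenuation in coefficients is expected.
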