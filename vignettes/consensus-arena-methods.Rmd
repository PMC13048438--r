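---
title: "Movement-based best-of-n consensus: models and measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-based best-of-n consensus: models and measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(consensusarena)
```

## The problem

A group of 7–10 embodied agents must converge, within 100 s and without any
explicit communication channel, on the largest of four circular sites placed
at the corners of a 150 m × 150 m arena (centers at (±40, ±40) m). Three
sites have a 12 m radius; the correct site is larger by 25% (easy, 15 m),
16.7% (medium, 14 m) or 8.3% (hard, 13 m). Avatars move forward at a fixed
8 m/s and rotate at up to π rad/s. A trial succeeds when every avatar stands
on the same, correct site; success earns `100 − time` gold points. Three
information regimes are studied: *global* (site sizes visible from
anywhere), *local* (a site's size only visible within a 25 m visibility
radius), and *informed minority* (global visibility, plus two agents told
the correct site outright).

Everything observable is a trajectory: one `(x, y, heading)` record per
avatar per timestep. The entire analysis chain — who supports which option,
how much social disagreement an individual faces, when opinions switch, and
which spatial factors modulate switching — has to be reconstructed from
those trajectories. This package implements both that measurement chain and
an agent-based simulator that generates trajectory data with the
statistical structure the chain assumes, so that every fitted coefficient
has a known, recoverable ground truth.

## The simulator

Each agent holds a perceived radius per site, a current target, and an
occupancy clock. Once per second (the *decision tick*) it:

1. **Perceives.** In global/informed-minority trials every perceived radius
   is `true radius + ε`, with `ε ~ N(0, sigma_percept)` drawn once per
   agent, site and trial. In local trials a site is revealed, with the same
   noise model, only once the agent has come within
   `local_visibility_radius` (default 25 m) of its center; revelation is
   permanent. Informed agents additionally know the correct *label*.
2. **Selects a target** if it has none: the argmax over sites of
   `perceived radius + w_social × (supporters among the others)`. Unknown
   radii are imputed at an optimistic prior (`prior_radius`, default 14 m —
   the midpoint of the correct-site radii — so unexplored options remain
   worth visiting); if nothing is known the agent explores its nearest (or
   a random) unexplored site. In the local condition the selection is
   re-run at the tick a new radius is revealed, which produces sequential
   scouting: an agent that discovers a small site moves on, one that
   discovers a large site stays. Informed agents target the correct site.
3. **Re-evaluates through a logistic switch hazard.** With `ds` the
   disagreeing social information (largest supporter count among the other
   options minus the supporters of the current choice, focal excluded),
   `d` the distance to the current target's center and `τ` the occupancy
   clock,
   `P(switch) = plogis(alpha + beta_ds·ds + beta_dist·d + beta_time·τ)`.
   On a switch, the destination is the option maximising the same
   selection score among the alternatives. Informed agents have their
   social terms multiplied by `informed_social_discount`; at the default
   of 0 they never abandon the correct site.
4. **Moves.** Kinematics are integrated at `sample_rate` (default 10 Hz)
   Euler sub-steps: rotate toward the goal at up to π rad/s, advance at
   8 m/s only while the heading error is below 15°, and halt at a goal
   point drawn uniformly inside the target disc. Per-substep displacement
   and turn are therefore hard-capped, and agents cannot leave the arena.

A trial starts from uniform positions in the 20 m start disc with uniform
headings and ends at the first second at which all agents stand strictly
inside one site disc (correct or not), or at the 100 s limit. All
randomness flows from a single per-trial seed; batch seeds are derived
reproducibly from a master seed.

### Default calibration

| parameter | default | units | rationale |
|---|---|---|---|
| `sigma_percept` | 1 | m | comparable to the 1–3 m radius differences, so difficulty genuinely modulates discriminability |
| `w_social` | 0.5 | m/supporter | one supporter is worth half the hard-difficulty size gap |
| `beta_ds` | 0.3 | logit per unit | a 7-vs-0 disagreement raises the hazard by ~2.1 logits |
| `beta_dist` | 0.02 | logit per m | commitment: switching is rarer close to the chosen site |
| `beta_time` | −0.05 | logit per s | sunk cost: leaving gets harder the longer a site is held |
| `alpha` | −3 | logit | a ~5%/s baseline switch rate at the neutral point |
| `informed_social_discount` | 0 | — | informed agents are fully independent |
| `prior_radius` | 14 | m | optimistic imputation for unseen sites; drives scouting in the local condition |

These values are the package's own design, fixed once: the study that the
simulator emulates reports fitted effects (positive social, positive
distance, negative occupancy-time) but no generative parameters for its
human participants. `beta_time = −0.05` matches the magnitude that study
reports for its fitted occupancy-time effect; the others were chosen so
that every covariate of the downstream models has a non-degenerate, signed,
recoverable counterpart.

### The chance baseline

The chance level of the task is 25%: four options, one correct. The
baseline policy (`policy = "random_consensus"`) implements an uninformed
group that herds onto one uniformly drawn option and travels there with the
full kinematics. The draw is at the group level deliberately: with
independent per-agent uniform choices, consensus itself would almost never
occur (probability `4^(1-N)` per option), and the estimated success rate
would measure consensus failure, not option-level chance.

## Opinion extraction

A participant supports a site if **moving toward** it (speed > 0.1 m/s and
the angle between the velocity vector and the bearing to the site center
below 30°; the smallest angle wins, the nearer site breaks exact ties) or
**occupying** it (speed ≤ 0.1 m/s and position strictly inside exactly one
site disc); otherwise its opinion is *none*. Opinions are evaluated at the
start of each one-second bin (`[t, t+1)`, bin-start sampling throughout).
Velocities are estimated by central finite differences *at the native
sampling rate* before the grid is thinned to bin starts: differencing the
1 Hz positions instead would span 2 s windows and smear the sub-second
stop-and-turn that accompanies every switch into spurious *none* bins,
silently deleting switch events. The 0.1 m/s threshold replaces an exact
zero-speed test, which is fragile under finite differencing.

## Social and spatial metrics

* **DeltaSocial** `= max_i≠cur N_i − N_cur`, with `N_i` the number of
  *other* individuals supporting option `i`. The focal is excluded from
  all counts, so the range for group size N is `[−(N−1), N−1]`.
* **Inter-player distance**: mean of all `N(N−1)/2` pairwise distances.
* **COM**: the unweighted mean position of all N participants, focal
  included.
* **Approach speed** `= ‖v_i‖ · (−d/dt) dist(p_i, COM)` in m²/s²:
  the negative radial speed toward the COM, multiplied by the focal's own
  speed so that drift of the COM past a stationary participant does not
  register. Positive = active approach. Derivatives use a symmetric finite
  difference spanning one second (snapped to the sampling grid).

## Switch events

Per participant and second, on the 1 Hz opinion series:

* A **moving** second (moving toward site s, with a successor bin) emits a
  sample. `switch = 1` iff the next bin supports a *different* site while
  moving and that support holds for at least two consecutive bins (the
  "sustained for ≥ 1 s" rule); otherwise `switch = 0`.
* A **still** (occupying) second emits a sample with
  `time_passed = seconds since this occupation began`. The first second of
  an occupation initializes the clock and emits nothing; the clock resets
  after any interruption. A departure is a switch only if it is a sustained
  move toward an alternative.
* Terminal seconds (no successor bin) and seconds with opinion *none* emit
  nothing. Covariates (DeltaSocial, distance to the current target's
  center, OnCorrect) are evaluated at the bin start.

## Outcomes and summaries

Consensus is detected on the 1 Hz grid (first second with all avatars
strictly inside one disc; the ≤ 1 s discretization relative to a
continuous-time check is accepted and documented). Success = consensus on
the correct site; gold = `100 − consensus time` for successes, else 0.
Cell summaries report the success proportion with a 95% Wilson interval
(chosen over Wald for its behaviour at proportions near 0 and 1), the mean
± SD consensus time over successful trials, and the mean time of
incorrect-consensus trials separately.

## Inference layer

`fit_model()` fits LMMs/GLMMs with independent random intercepts via lme4
(Laplace approximation for the binomial family; `nAGQ = 0` available for
large recovery studies). Event tables can be separable or have degenerate
groupings, so a documented fallback exists: if the mixed fit errors or
fails to converge, a fixed-effects-only fit is used with cluster-robust
covariance (sandwich) by the first grouping column, and the result is
flagged. `anova_type2()` produces per-term Type II Wald χ² tests
(car::Anova); `emm_pairwise()` produces estimated-marginal-mean pairwise
contrasts (emmeans) with Benjamini–Hochberg adjustment within the contrast
family (all pairs of one factor in one model); `predicted_switch_curve()`
gives fixed-effects probabilities over a DeltaSocial grid with random
effects at zero. Reported coefficients use treatment coding (reference:
condition *global*, difficulty *easy*); Type II tests are
coding-invariant. One caveat worth stating: step-up BH adjustment is *not*
idempotent in general (re-adjusting an adjusted vector inflates it again),
so the package asserts monotonicity and dominance rather than idempotence.

## Validation design and problem sizes

The package validates itself with (sizes chosen to keep the full suite in
the tens of minutes on one core):

* brute-force oracle equivalence for DeltaSocial, inter-player distance,
  site distance and COM distance on > 1,000 random configurations;
* a 10,000-trial chance baseline whose Wilson interval must cover 25%;
* hazard recovery: 500 global trials for the DeltaSocial coefficient
  (±30% band) and 50 replicates of 200 trials (150 global + 50 local) for
  the signs of all three hazard coefficients — the still model is fitted
  on local trials because global trials reach consensus too quickly to
  accumulate occupancy time;
* qualitative orderings at 200 trials per design cell under a fixed,
  documented master seed: pooled success easy ≥ medium ≥ hard, local
  slower than global (successful trials), informed minority at least as
  successful as global, and 100% success for noise-free asocial groups;
* a 1,000-replicate null simulation in which the Type II Wald test must
  hold its 5% size.

## What the generator does and does not emulate

It reproduces the *statistical structure* the measurement chain assumes:
noisy size perception, social copying that grows with disagreement, spatial
commitment, sunk costs, independent informed individuals, and the
geometry/kinematics of the task. It does not attempt cognitive realism:
no learning within or across trials, no heterogeneity between agents, no
collision avoidance (discs may hold everyone), no anticipation or
signalling, and the social signal read by agents is the others' current
targets rather than an inferred opinion. Consequently, passing tests show
that the pipeline measures what it claims to measure on data with known
structure — not that human groups behave like these agents, and the
human study's specific success rates are deliberately out of scope.

## Numerical conventions

Arena-centered coordinates, x right / y up, meters; time in seconds from
trial start; half-open bins `[t, t+1)` with bin-start sampling. Ties in
target selection break by larger perceived radius then label order, ties
in frame classification by smaller angle then nearer site — all total, for
determinism. Speed/turn caps are asserted to `1e-6` tolerance. Trajectory
CSVs are written with shortest round-trip decimal formatting and re-parsed
with correctly-rounded conversion, so write → load → write is bit-identical.
Every stochastic stage takes an explicit integer seed; per-trial seeds are
drawn reproducibly from the master seed.
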