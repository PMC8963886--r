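---
title: "Compositional strategy analysis of Pac-Man-style foraging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional strategy analysis of Pac-Man-style foraging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacstrat)
```

## The model

`pacstrat` analyzes joystick play in a monkey-adapted Pac-Man task under a
hierarchical hypothesis: at any moment the player entertains a small set of
simple *basis strategies*, each of which scores the four joystick directions
from a restricted view of the game, and the observed choice arises from a
weighted blend of those scores.  The six basis strategies are

* **local** — graze: summed item units (pellet 1, energizer 2, fruit in
  drop-equivalents) on the depth-10 forward paths of each direction;
* **global** — forage toward mass: the count of pellets in the strict
  half-plane of each direction (the player's own row/column counts for
  neither side);
* **evade Blinky / evade Clyde** — a negative penalty when the respective
  ghost is in normal mode and sits on a forward path;
* **approach** — a ghost bonus regardless of ghost mode (the hunting and
  the suicidal readings share this score);
* **energizer** — like local but counting energizers only.

Paths are non-reversing walks: a walk may loop but never undoes its last
move, mirroring the movement rule imposed on the game's characters.  Paths
that hit a dead end early are kept at their truncated length — discarding
them would make dead-end directions artificially score-less.  A
configuration switch (`utility_params(simple_paths = TRUE)`) restricts to
simple paths instead.

Per direction $d$ and strategy $a$ the utility is the mean over the
direction's path set, $U_{a,d} = \frac{1}{|T_d|}\sum_{\tau \in T_d}
U_a(\tau)$, with $-\infty$ on unavailable directions.  Two preprocessing
steps make strategies commensurable within a *trial* (one round of play,
from start or reset to death or clearance): the nonpositive evade utilities
are shifted by their within-trial minimum, and every strategy is divided by
its within-trial finite maximum.  A strategy whose maximum is not positive
in a trial carries no information there and is set identically to zero
rather than divided.

Choices follow a softmax over the blended utility
$Q_d(t) = \sum_a w_a U_{a,d}(t)$, and the weights $w \ge 0$ of a time
window are estimated by maximum likelihood.  Reported weights are
normalized to sum one; the softmax absorbs the overall scale, so the raw
magnitude doubles as an inverse temperature.

## The two-pass dynamic fit

Weights are assumed piecewise-constant.  Each round is first cut into
event-bounded *fine windows* (boundaries at every change of chosen
direction and at every ghost or energizer consumption — the consuming step
starts a new window).  Pass one fits each fine window by MLE, yielding a
weight time series.  An exact dynamic program then partitions that series
into $K$ contiguous segments minimizing the within-segment quadratic loss,
and pass two refits each coarse segment by MLE, giving the segment
log-likelihood sum $L(K)$.

**Selecting $K$.**  In-sample $L(K)$ is (essentially) non-decreasing in
$K$: refitting two halves of a window separately can never lose likelihood.
A bare $\arg\max_K L(K)$ therefore pins $K$ at the top of its range and
defeats the purpose of segmentation.  The package's default selection
criterion is AIC, $L(K) - 6K$ (six weights per segment); BIC
($L(K) - 3K\log n$) and the bare rule remain available via
`fit_dynamic(criterion =)`.  In recovery experiments BIC proved too
conservative — most of the six weights per segment are pinned at zero, so
the effective dimension is far below six and genuine regime switches worth
10–12 log-likelihood units were rejected — while AIC recovers the true
segment count reliably.

**Numerical choices.**  The window log-likelihood is concave in $w$; it is
maximized by L-BFGS-B from five fixed starting points under $0 \le w \le
50$ (the box keeps perfectly separable windows from diverging).  A tiny
ridge term ($10^{-3}\,\lVert w\rVert^2$) acts as a minimum-norm tie-break:
after per-trial normalization an evade utility is close to constant across
the available directions on most steps (the ghost is rarely on a forward
path), and a constant score is invisible to a softmax by shift invariance —
without the tie-break the optimizer can park arbitrary weight on such
likelihood-flat strategies.  The reported log-likelihood is the pure
(unpenalized) value at the optimum.  Argmax ties anywhere in the package
resolve by the fixed priority up > left > down > right.

Strategies whose per-step utility-argmax action sequences coincide on a
window are merged into one hybrid column (the members' mean utility) before
fitting, and the hybrid's weight is split equally afterwards; because the
mean-column construction makes the split exactly reproduce the hybrid's
blended utility, merged and unmerged fits attain the same likelihood.

## The simulator

One engine step is one tile traversal (0.417 s of game clock); actions are
per-tile decisions.  The bundled 21x24 maze has four quadrants, two tunnel
pairs that teleport to the opposite side preserving direction, and a
central single-exit ghost home.  A new game places 88 pellets and 4
energizers (73/3 in the alternative configuration) uniformly over three
randomly chosen quadrants, one quadrant left empty, plus one random fruit.
Blinky always chases; Clyde chases beyond eight tiles and otherwise heads
for the lower-left corner; normal-mode ghosts never reverse unless forced.
An energizer scares both ghosts for 14 s with a 2 s warning flash; scared
ghosts move at half speed and, under the default rule, in uniformly random
non-reversing directions (the alternative `scared_rule = "homeward"`
implements a half-speed retreat to the pen, since the task description
supports both readings).  Eating a scared ghost pays 8 drops and sends it
home to respawn; contact with a normal ghost (including swapping tiles)
resets the round with pellets unchanged.  Clearing the maze pays 20, 10, or
5 drops depending on the round count.  Ghost randomness flows through a
small in-state generator, so a recorded episode replays exactly from its
initial state without touching R's RNG.

## What the synthetic agents emulate — and what they do not

The compositional agent plays the simulator through the same softmax
mixture the fitter assumes, with a known piecewise-constant weight schedule
and an explicit inverse temperature.  One structural mismatch is
unavoidable: the generator normalizes utilities per step, because the
trial-wide extrema of a trial still being played cannot be known, while the
fitter normalizes per trial.  Per-strategy argmax directions are invariant
to this positive rescaling, so dominant-strategy ground truth is preserved,
but fitted weight *values* are pulled slightly off the schedule's — which
is why recovery is scored on dominant-label agreement and segment count
rather than exact weight error.

The recovery benchmark runs under `ghost_contact = "none",
ghost_policy = "wander"`: ghosts walk randomly at full speed and never
interact.  Two distinct artifacts motivate this condition.  Deaths would
cut the ground-truth schedule into rounds at arbitrary points, conflating
segmentation errors with forced resets.  More subtly, a pursuing ghost
settles one tile behind Pac-Man, and from there the shifted evade utility
is high in whatever direction Pac-Man is moving — collinear with every
other strategy's preferred direction — which destroys weight
identifiability (fits then load on evade regardless of the truth).  The
default benchmark schedule is three 60-step segments with dominants
local / global / local at weight 0.85 and inverse temperature 12,
calibrated once so that about 90% of generated actions are greedy.  The
two ghost-dependent strategies have sparse utility support under wandering
ghosts, so the thresholded benchmark concentrates on strategies that are
informative at every step; `recovery_schedules()` covers all six dominants
for non-thresholded checks.  Passing recovery therefore shows that the
two-pass machinery inverts its own generative model under realistic play
statistics — it does not show that real monkeys use these strategies, nor
that the weights of weakly informative strategies are well determined in
any particular window.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `local_depth` | 10 | steps | forward-path depth of the path strategies |
| pellet / energizer units | 1 / 2 | utility units | the unit weights of the local-reward analyses |
| fruit units | drops / 2 | utility units | keeps fruit commensurate (1 pellet = 2 drops = 1 unit); switchable to unit weight |
| ghost bonus / evade penalty | +4 / −4 | utility units | 8 drops / 2, sign-mirrored |
| `step_seconds` | 0.417 | s | one tile traversal |
| scared duration / flash | 14 / 2 | s | energizer effect |
| `k_range` | 2–20 | segments | candidate segment counts per round |
| optimizer box / ridge | 50 / 1e−3 | — | divergence guard and flatness tie-break |

The per-trial normalization makes fits insensitive to each strategy's
overall scale, which is why the utility-unit defaults are safe choices:
rescaling any one strategy's parameters rescales its utilities and is
divided out again.

## The LARL baseline

The flat comparator is a linear utility over seven hand-crafted features
(direction-local pellet count within five steps, distances to nearest
pellet, energizer, each ghost and nearest scared ghost, and an
inverse-distance-weighted far-pellet mass), updated by a temporal
difference rule whose target uses the *logged* next action rather than the
max — with greedy logs the two coincide exactly, which the tests exploit as
an oracle.  Features whose referent is absent are null: they contribute
nothing to the utility and receive no gradient.  Features are z-scored
within the log before fitting; the linear ranking is invariant to affine
feature rescaling, while the raw distance scales made the TD iteration
diverge.  Learning rate and discount are chosen by three-fold
cross-validated action-prediction accuracy over the default grids, which
bracket the values the task's published fits selected.

## Problem sizes

The shipped checks run at desk scale, chosen to exercise every code path
while keeping a full suite run in minutes: recovery uses ten 180-step
episodes; the model-comparison check pools three episodes; oracle
equivalences use 100 random mazes (distances), series of length ≤ 12
(segmentation), and 60–80-step logs (TD equivalence).  All stochastic
checks fix their seeds.

## Known limitations

* The fitted weights of strategies with sparse utility support (evade and
  approach far from any ghost, energizer with no energizer in range) are
  only weakly identified within short windows; the ridge tie-break sets
  them to zero rather than leaving them arbitrary.
* Context classification uses a documented precedence (scared > early/late
  > other); the task's own criteria table is not public, so the precedence
  is a package choice.
* The static model fits one window across the whole log, including across
  deaths; the dynamic model never lets windows span a reset.
* Sub-tile motion, rendering, and eye-movement analyses are out of scope.
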