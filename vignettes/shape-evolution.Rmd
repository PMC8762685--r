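---
title: "Evolving shape distractors for visual search: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving shape distractors for visual search: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfevolve)
```

## The problem

Which properties of a closed shape let it be found quickly in a crowded
display, and which let other shapes hide it? `rfevolve` approaches the
question generatively: instead of hand-picking distractor shapes, a genetic
algorithm (GA) evolves them, using search reaction time (RT) as the fitness
signal. Distractors that make search for a fixed target fast (Evolve-Easy)
or slow (Evolve-Hard) are selected, recombined and mutated over generations.
The package implements the full loop — shape synthesis, the GA, a
synthetic observer that supplies RTs, and three shape-similarity
parameterizations used to interpret what evolved.

## Radial-frequency shapes and the genome

A radial-frequency (RF) pattern perturbs a base circle of radius $r_0$
(default 30 px) with sinusoids at integer angular frequencies:

$$ r(\theta) = r_0 + s \sum_{f=1}^{10} g_f\, A_f \sin(f\theta + \phi_f), $$

where $A_f \ge 0$ is the amplitude (internal units), $\phi_f \in (0, 360]$
degrees the phase, and $g_f \in \{0,1\}$ a gate that can switch a frequency
off. The 30-element vector $(A, \phi, g)$ is the *genome*. The contour is
sampled at 360 angles; where $r(\theta) < 0$ the point reflects through the
origin, producing the internal loops characteristic of strongly modulated RF
shapes.

Choices worth stating explicitly:

* **Sine basis.** Sine versus cosine is a 90° phase convention with no
  observable consequence; the package uses sine and converts degree phases
  to radians only inside synthesis.
* **Amplitude-to-pixel scale.** `amp_scale` defaults to `base_radius/100`,
  so amplitude 100 modulates the radius by one full base radius. This keeps
  genome amplitudes in the 50–150 bookkeeping range of the initializer while
  mapping them onto a sensible "proportion of radius" scale. It is the one
  declared free parameter of synthesis.
* **Initialization.** Amplitudes are drawn uniformly from 50–150 and divided
  by the frequency, approximating the 1/f amplitude fall-off of natural
  images; phases are uniform over 1–360°. How gates are set at generation 1
  must be decided by the implementation: the package uses independent
  Bernoulli(0.5) draws (configurable), which maximizes initial diversity in
  the on/off pattern and matches the target genomes' sparse spectra in
  expectation.
* **Rasterization.** Shapes are filled on a 128×128 canvas under the
  *nonzero-winding* rule, so internal loops render as filled lobes rather
  than holes. This is an interpretation — an even-odd rule would make loop
  interiors background — chosen so that skeleton and area analyses operate
  on one connected filled region, matching the visual appearance of the
  outline stimuli. Contours that do not fit the canvas are shrunk (never
  enlarged) with a logged warning; for self-intersecting contours the area
  measurement falls back to the foreground count of this mask, counting
  loop interiors once.

## The evolutionary loop

Each generation holds 12 distractor genomes. Every distractor is tested once
at each of two set sizes (16 and 24), blocked by set size with the order
randomized within blocks — 24 trials per generation. After scoring:

* **Selection.** Evolve-Easy keeps the 3 distractors with the lowest mean
  RT; Evolve-Hard keeps the 3 with the highest weighted score
  $\mathrm{slope} - w \cdot \overline{RT}$ with $w = 0.15$ by default, where
  the slope is the two-point RT-by-set-size slope in ms/item. Ties break
  stably toward the earlier distractor.
* **Reproduction.** The 3 parents survive verbatim (elitism); 9 offspring
  are produced, each by uniform crossover of two distinct parents drawn
  uniformly at random — every element inherited from either parent with
  probability 1/2 — followed by mutation.
* **Mutation.** Each of the 30 elements mutates independently with
  probability 0.02: a gate flips, an amplitude is doubled or halved with
  equal probability, a phase is redrawn uniformly from 1–360°.
* **Constraints.** For constrained runs, a per-frequency mask clamps the
  target's active frequencies on (with the target's amplitudes, phases
  free) or forces them off; masked amplitude/gate elements never mutate, and
  the mask is re-asserted on every offspring, so it holds exactly in every
  generation.

### The sign of the hard-direction score

The hard score $\mathrm{slope} - 0.15 \cdot \overline{RT}$, *maximized*,
rewards steep slopes but penalizes long mean RTs. At millisecond scale the
mean-RT term dominates the slope term (hundreds vs tens of ms), so under the
package's observer model maximizing this score selects the *least*
target-like distractors and evolution runs in the easy direction. Because
the intended behavior of hard evolution is to lengthen search, the weight
`hard_weight` is a configuration field, sign included. The package default
keeps the conventional value $+0.15$; the direction-recovery tests in the
suite run the RT-promoting alternative `hard_weight = -0.15` (i.e.
$\mathrm{slope} + 0.15 \cdot \overline{RT}$, maximized), which reliably
reproduces the easy/hard divergence. Both conventions are first-class; no
intent is guessed beyond making the sign explicit.

## Three shape-similarity parameterizations

1. **Skeleton distance.** The filled mask is thinned to its medial-axis
   skeleton by iterated Zhang–Suen morphological thinning run to
   convergence (one pixel is retained if a final symmetric cluster would
   otherwise vanish, so a skeleton is never empty). The distance between two
   skeletons is the mean, over distractor skeleton points, of the Euclidean
   distance to the nearest target skeleton point, minimized over rigid
   alignments: both sets centered on their centroids, the distractor rotated
   exhaustively in 1° steps (reflection optional, off by default). The
   measure is *directed* (distractor toward target); a symmetric variant is
   available but not default. No size normalization is applied by default
   since all evolved stimuli share one base radius; a `normalize_scale` flag
   exists for size-jittered displays.
2. **Total curvature.** The isoperimetric ratio $P^2/A$ — $4\pi$ for a
   circle, larger for anything else, invariant to rigid motion and scale.
   The similarity measure is the absolute difference of the two ratios.
3. **Radial Fourier spectrum.** The contour is read as a radius sequence
   about its centroid (well-defined for any contour traversed by arc
   length, star-shaped or not), Fourier transformed, and the amplitude at
   frequency $f$ taken as $2|c_f|/n$ — a scaling under which a synthesized
   genome recovers `amp_scale` × amplitude at its active frequencies.
   Distance is the L2 norm of the difference, spectra zero-padded to a
   common length. Amplitudes only; phase is discarded.

## The synthetic observer

The observer is declared plumbing: a monotone link from target–distractor
similarity to search cost, invented so the loop can run and be tested
without human data. It is *not* fitted to any human RT measurements.
A metric distance $d$ is normalized to $s = 1/(1 + d/\sigma)$ (scale
$\sigma$ per metric: 30 for spectrum, 5 for skeleton, 10 for curvature,
chosen so typical distances between evolved stimuli spread over the
responsive range). The probability that a distractor must be inspected is a
Hill function $q = s^k / (s^k + h^k)$ with half-saturation $h = 0.5$ and
exponent $k = 4$. Simulated RT is

$$ RT = t_0 + t_\mathrm{item} \cdot E[\text{items inspected}] + \epsilon, $$

with $t_0 = 500$ ms, $t_\mathrm{item} = 50$ ms/item; on target-present
trials $1 + (n-1)q/2$ items are inspected in expectation (the target is
found midway through the inspected subset), on absent trials
$nq \cdot 1.5 + 1$. Noise is Gaussian (SD 60 ms) clipped below at $-t_0/2$ —
clipping rather than resampling keeps the number of RNG draws per trial
fixed, so seeded streams stay aligned across parameterizations — and RTs
are therefore always positive.

Consequently, what a passing end-to-end test shows is that the *mechanism*
(selection, recombination, constraint handling) moves the pool in the
intended direction under a monotone similarity–RT link. It does not show
that human observers weight shape similarity this way, that the particular
metric drives human search, or anything about absolute RT magnitudes.

## Experiment harness

Displays place items evenly on a circle of radius five base radii (150 px)
around fixation with a random global rotation — a spacing that keeps items
from overlapping up to set size 24; the array geometry is otherwise
unconstrained and this default is the package's own. In standard mode
distractors take arbitrary orientations and the target stays upright. In the
present/absent mode the set sizes are 8/12/16, target presence is *exactly*
counterbalanced (not Bernoulli) within each set size so the 50% rate is
testable as exact, all items' orientations are jittered within ±25° (so an
upright target remains upright-looking), and sizes within ±10% — the size
jitter magnitude is a documented guess, configurable. RTs above 10,000 ms
are excluded from analysis (strictly greater; boundary records are kept),
and search slopes are ordinary least-squares fits through the per-set-size
mean RTs, separately for present and absent trials.

## Determinism and numerical choices

* Every stochastic entry point takes a seed and consumes one global RNG
  stream in a documented order (initialization: amplitudes, phases, gates,
  id; evolution: pairing, crossover, mutation per offspring), so equal seeds
  give bitwise-identical runs, including genome ids, which are drawn from
  the same stream.
* Genome JSON is written with 17 significant digits, making write/read an
  exact round trip for doubles.
* Degenerate inputs error early and by name: an identically zero radius is a
  "null contour", an empty mask cannot be skeletonized, scoring names the
  distractor missing a set size.
* Selection ties break by pool position; sorting is stable by construction.

## Problem sizes used by the test suite

The suite checks rates at the sizes at which their tolerances are sharp:
mutation frequency over $10^6$ element draws (±0.1 pp), crossover
inheritance over $10^5$ offspring (±0.5 pp), initialization bounds over
$10^5$ genomes, the isoperimetric inequality over $10^3$ random simple
contours, skeleton alignment against a brute-force oracle on ≤32×32 point
sets, and the direction signature over 20 paired seeded runs of the full
8-generation loop (with the elitism/monotonicity property over 50 runs of a
deterministic surrogate fitness). These sizes are the package's choices,
balancing the sharpness of each check against the cost of a routine test
run.

## Known limitations

* The observer is a caricature: no accuracy errors, no eye movements, no
  learning, a single similarity scalar per distractor. Replacing it with
  recorded trial logs is supported by design (`score_distractors` accepts
  any trial data frame).
* The skeleton metric uses mean nearest-point distance after rigid
  alignment, not hierarchical axis-graph matching; parts correspondence is
  therefore implicit.
* Whether a published analysis would count loop interiors once or twice in
  the area term is unknowable from the ratio alone; the mask-count fallback
  (counting once) is the package's documented convention.
* The shipped rabbit-like silhouette is synthetic (an ellipse with two
  Gaussian ear lobes) and stands in for a natural-shape target; it
  reproduces no published stimulus.
```{r}
sessionInfo()
```
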