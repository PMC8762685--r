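# rfevolve

Genetic-algorithm evolution of radial-frequency shape distractors for
visual search.

## What this is for

In visual search, some distractor shapes let a target pop out and others
hide it, and it is far from obvious which shape properties are responsible.
`rfevolve` is for researchers in visual psychophysics who want to explore
that question generatively: rather than hand-picking distractors, a genetic
algorithm evolves them, using search reaction time (RT) as the fitness
signal — toward faster search (Evolve-Easy) or slower search (Evolve-Hard).
The package provides the complete loop: parametric shape synthesis, the
evolutionary engine, a pluggable synthetic observer that supplies simulated
RTs (so the loop runs and is testable without human data), and three
shape-similarity parameterizations for analyzing what evolved.

## The model

Stimuli are radial-frequency (RF) patterns: a base circle of radius
$r_0 = 30$ px whose radius is modulated by sinusoids at integer angular
frequencies,

$$ r(\theta) = r_0 + s \sum_{f=1}^{10} g_f A_f \sin(f\theta + \phi_f), $$

with per-frequency amplitude $A_f$, phase $\phi_f$ (degrees), and a binary
gate $g_f$ — a 30-element "genome". Initial amplitudes are uniform on
50–150 divided by $f$ (an approximate 1/f spectrum); phases uniform on
1–360°.

Each generation, 12 distractors are each tested at set sizes 16 and 24 (24
trials). The 3 fittest survive unchanged — lowest mean RT for easy
evolution, highest $\mathrm{slope} - 0.15\cdot\overline{RT}$ for hard
evolution (the weight, sign included, is configurable; see the methods
vignette) — and 9 offspring are bred by uniform crossover (each element from
either parent with probability 1/2) plus per-element mutation at rate 0.02
(gate flip, amplitude ×2 or ÷2, phase redrawn). Constrained runs clamp the
target's frequencies on (with the target's amplitudes) or off.

Target–distractor similarity is measured three ways:

* **skeleton** — mean nearest-point distance between morphologically
  thinned medial-axis skeletons after best rigid (centroid + exhaustive
  rotation) alignment;
* **curvature** — difference of the isoperimetric ratio $P^2/A$ ($4\pi$ for
  a circle);
* **spectrum** — L2 distance between radial Fourier amplitude spectra.

## Worked example

```r
library(rfevolve)

target <- example_targets()$BB   # "bumpy brick": active at frequencies 2 and 6
easy <- rf_evolve(target, "easy", seed = 11)
hard <- rf_evolve(target, "hard", ga = ga_config(hard_weight = -0.15), seed = 11)
print(easy)
#> RF distractor evolution: direction easy, 8 generations, metric spectrum
#>   mean RT: 907 ms (gen 1) -> 838 ms (gen 8)
#>   pool-mean spectrum distance to target: 15.82 -> 24.02
print(hard)
#> RF distractor evolution: direction hard, 8 generations, metric spectrum
#>   mean RT: 907 ms (gen 1) -> 943 ms (gen 8)
#>   pool-mean spectrum distance to target: 15.82 -> 10.67
```

Both runs start from the same random pool (mean simulated RT 907 ms). Under
easy evolution the pool's spectra drift *away* from the target (distance
15.8 → 24.0) and search gets faster; under hard evolution (with the
RT-promoting weight) the spectra converge on the target (15.8 → 10.7) and
search slows — the qualitative signature of similarity-guided search. All
three similarity metrics are available for any evolved distractor:

```r
compare_shapes(hard$populations[[8]]$genomes[[1]], target)
#> skeleton curvature  spectrum
#>    8.386     8.751    23.510
```

`plot(easy)` draws the RT and distance trajectories;
`metrics_over_generations(easy)` tabulates all three metrics per
generation; `write_run(easy, "rundir")` exports per-generation population
JSON plus trial and summary CSVs. `load_silhouette()` brings in arbitrary
closed contours (e.g. the synthetic rabbit fixture in `inst/extdata/`), and
`run_exp4_block()` runs counterbalanced present/absent search blocks over
jittered displays with RT filtering (`filter_rts()`) and slope analysis
(`rt_setsize_slopes()`).

A thin command-line front end over these functions is in
`inst/cli/rfevolve.R` (subcommands `compare`, `evolve`, `simulate-exp4`).

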