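---
title: "Model and methods of the humoral immune simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods of the humoral immune simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(humoralsim)
```

## The model in one page

`humoralsim` simulates the humoral arm of the adaptive immune response as a
continuous-time stochastic agent system. Because the humoral phase (blood or
lymph) is spatially well mixed, no positions or motion are modelled; instead
agents carry *shapes* — points on two discrete lattices that stand for the
binding profile of a receptor or ligand. A point `(x, y)` has `x` in
`0..N` and `y` in `-N/2..N/2` (`N = 1000` by default); positive `y` encodes
convexity, negative `y` concavity. A receptor binds best the *mirror image*
`(x, -y)` of a ligand, and binding quality decays with the Chebyshev
(l-infinity) distance `d` between the receptor and that mirror image. All
radii in the model (binding radii, selection radii, mutation steps) are
measured with this single metric.

Two agent classes exist:

* **Individually tracked cells** — B cells (BCR on the antigen lattice,
  presented peptide, activation state, regulatory-contact timer) and T
  helper cells (TCR on the peptide lattice, activation state, regulatory
  flag).
* **Counted populations** — self-antigen populations, foreign (pathogen)
  populations, bone marrow cells, antibody pools keyed by shape, and the
  shapeless danger-signal and interleukin pools.

Events — births, deaths, selection, actions, divisions, soluble-signal
emission and action — carry mean waiting times and race as independent
exponential clocks: the next event fires with probability proportional to
its rate and the clock advances by an exponential draw with mean one over
the total rate. Groups of identical events are treated as single channels
(the superposition property of exponential clocks makes this exact). All
birth rates are throttled by the logistic factor `max(0, 1 - n/K)`; death
rates never are. One time step is 0.1 day and a default run spans 5000
steps.

## The two model presets

The **self-centered preset** (default, `sim_params()`) implements three
interaction regimes:

1. *Weak* — B cells capture soluble self antigens, present the self peptide
   in MHCII, and are visited by positively selected regulatory T helper
   (Threg) cells whose TCR lies in a characteristic annulus
   (`ring_inner`–`ring_outer`, defaults 50–80) around a self-peptide mirror
   image. The contact refreshes a survival timer on the B side and supports
   rare homeostatic (weak) divisions on both sides. This maintains a
   standing immune image of self.
2. *Intermediate* — a B cell presenting a *foreign* peptide cannot be
   reached by Thregs; once its contact timer exceeds `tcrit_stress`
   (2 steps) it activates and emits danger signals. Each danger signal
   recruits one random T helper cell, which in turn releases interleukins;
   each interleukin lets one random *activated* B cell divide. The result
   is a fast, polyclonal first line of defense.
3. *Strong* — a T helper cell whose TCR matches the foreign peptide in a
   B cell's MHCII (within `thrad`, default 80) forms a two-signal pair:
   both cells become strongly activated and expand clonally with mutation;
   after `s_plasma` consecutive strong divisions a B cell differentiates
   into a plasma cell whose antibodies carry its BCR shape and kill
   matching antigens. Strong offspring become memory cells with
   probability `pmem`.

Two demographic rules close the response. **Clonal contraction**: once a
cell's antigen is gone, effector B cells die with probability
`p_contraction` (0.9) at their next control event; survivors persist as
memory, and strongly activated T helper clones go quiescent. Without
contraction the first response leaves half the repertoire as standing
effectors and trivialises the second infection. **Memory recall**: memory
cells divide strong-kind on antigen contact without the stress period,
and — being uncontrolled presenters — they also respond to interleukins
with strong-kind divisions during an emergency. Recall therefore
reignites quickly but still needs fresh antigen capture, which is what
makes the second elimination two to three times faster than the first
rather than instantaneous.

The **conventional preset** (`sim_params(model = "crs")`) differs by exactly
four switches: weak and intermediate divisions are disabled
(`weakrepr = 0`, `medrepr = 0`), thymic selection becomes negative-only
(`comptype = 1`: everything within `ring_outer` of a self mirror is
deleted and nobody is regulatory), and the marrow's T-helper output slows
(`tauthm = 30` instead of 5). Danger signals, interleukins and the
activation-control process are inert in this preset; a unit test verifies
that the trajectory is then bit-identical to the self-centered
configuration with those switches applied.

## Selection geometry

B-cell negative selection deletes marrow candidates with
`d < b_negsel_radius` (50) to any self-antigen mirror, leaving empty
exclusion balls in the surviving repertoire. Thymic selection under the
self-centered preset deletes candidates with `d* < ring_inner`, marks
those with `ring_inner <= d* <= ring_outer` as regulatory, and passes the
rest; under the conventional preset everything with `d* <= ring_outer`
dies. The annulus/ball survivor fractions are verified in the tests
against exact lattice enumeration on a reduced 100 x 100 lattice.

**Peripheral tolerance.** Division offspring are screened against the same
exclusion balls as marrow candidates. Without this, mutation plus
affinity-dependent homeostatic division lets B clones hill-climb into the
forbidden zone and the intact model drifts into autoimmunity; with it, the
default model is stable and the negative-selection knockout
(`b_negsel = 0`), which removes both screens, reproduces the rapid
self-cell collapse expected of that pathology.

## Affinity weighting and mutation

Within the action radius, capture succeeds with probability
`a(d) = (1 - d/(r+1))^aff_exp` (default exponent 2), so closer receptors
engulf more often. Weak divisions carry an additional factor `a(d)^2`:
homeostatic proliferation requires a stronger tonic signal than capture.
This separation makes the intact repertoire (which cannot come closer than
`b_negsel_radius = 50`) demographically stable while unscreened clones at
`d ~ 0` out-divide their death rate roughly tenfold — the engine of the
knockout experiment. Mutated offspring (probability `pmut`) are displaced
by a uniform point on the Chebyshev sphere whose integer radius is uniform
in `[rminnew, rminnew/crnew]` (weak divisions use `rminsprd`/`crspread`),
clamped to the lattice.

## Free constants and their rationale

The printed parameter set pins the action radii, action waiting times, the
mutation and memory probabilities, the stress period and the default
infection (350 cells, division wait 60). The remaining constants are
package defaults, chosen once to make the simulated organism behave like a
healthy one and then frozen:

* `taubm = 10`, `tauthm = 5`, lifespans `b_life = th_life = 1000` steps and
  capacities `kb = kth = 2000` give a few hundred circulating cells of each
  lineage with headroom for clonal expansion.
* Self populations (150 cells each, capacity 1000, division wait 50) grow
  logistic-fashion to saturation within the first weeks.
* `k_treg = 100` caps each regulatory ring: rings fill within the first
  ~100 days and persist, fluctuating with peptide presentation.
* Danger/interleukin bursts of 10 with decay waits of 10/5 steps make the
  polyclonal first line ignite within a few steps of the first foreign
  presentation; plasma cells live 40 steps and antibodies decay with mean
  20 steps, so humoral protection wanes between well-separated infections
  instead of trivialising the second response.
* `act_speedup = 24`: activated and strongly activated cells act an order
  of magnitude faster than naive ones, reflecting blast physiology; this
  constant sets the overall tempo of clonal expansion and thus the
  elimination-time scale.
* `p_contraction = 0.9`: the post-clearance effector cull; the surviving
  tenth, plus `pmem` offspring, is the memory pool.

With these defaults a default-sized infection is eliminated in roughly 60
steps (6 days) on average, a small percentage of runs lose the race and
the host dies, and a second identical infection 15 days later is cleared
about three times faster — the regime reported for this class of models.

## What the simulator does and does not emulate

The synthetic world is the study condition itself: three clonal self
populations, uniformly random naive repertoires, and pathogens that differ
only in shape, initial count and division speed. Real repertoires are not
uniform, antigen presentation involves dedicated cells (macrophages,
dendritic cells) that are absent here, innate immunity is missing, and
pathogen diversity is far richer than a lattice point. Passing tests
therefore show internal consistency of the model and reproduction of the
reference statistics under the stated conditions — not quantitative
predictions for real infections.

## Numerical choices

* The event race advances by the race minimum (exponential with the total
  rate); per-event waiting times are never stored, which is equivalent by
  memorylessness.
* Injections and snapshot times are hard boundaries: pending exponential
  draws that overshoot a boundary are discarded and redrawn, which is
  exact for memoryless clocks.
* The time series records the state at multiples of `record_every`;
  outcome classification, however, uses event-granular crossing times
  recorded inside the core, so it is independent of the stride.
* Fisher tail probabilities are accumulated in log space with `lchoose`
  and log-sum-exp; values around 1e-45 are reproduced to printed
  precision.
* A run is a deterministic function of `(parameters, seed)`; all
  randomness flows through R's global RNG, so `set.seed` reproduces runs
  bit for bit, including inside the compiled core.
* Host death (a pathogen reaching `death_threshold = 4000`) stops the run
  at the event time; the time series is truncated at that point.

## Problem sizes used by the tests and the acceptance script

The reference statistics were computed from 500 replicates per arm; the
packaged experiments default to 100 replicates per arm (memory and model
comparison) and 200 sensitivity samples, with acceptance bands widened to
three standard errors of the reduced sample sizes. A single default run
simulates roughly 2-5 million events.

## Known limitations

* Only one antigen-presenting cell type (the B cell itself) exists.
* Th memory is represented only as persisting expanded clones; there is no
  distinct fast path on the T side.
* The interpretation of the four mutation-range constants
  (`rminnew`/`crnew`, `rminsprd`/`crspread`) as sphere-radius bounds is a
  package choice; only the constants' names and defaults are pinned by the
  parameter table they come from.
* Regulatory cells are excluded from danger-signal recruitment and from
  strong activation; their job is homeostatic surveillance only.
* Whether the x-boundary of the lattice wraps is unspecified in the source
  material; the lattice here has hard boundaries and mutation offsets are
  clamped, which slightly enriches boundary shapes.
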