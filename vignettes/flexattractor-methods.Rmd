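---
title: "Self-organizing grid cells and the topology of their population activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organizing grid cells and the topology of their population activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flexattractor)
```

## The scientific question

Grid cells fire on a hexagonal lattice of locations, and cells of one
module share spacing and orientation, differing only in spatial phase.
The textbook account attributes this alignment to a two-dimensional
continuous attractor whose recurrent architecture mirrors the torus that
the population activity is known to trace.  This package implements a
self-organizing model in which that assumption can be probed: grid maps
emerge from Hebbian learning on place-cell-like inputs, while a *fixed*
recurrent collateral network of configurable architecture — a 2D torus,
a 1D ring, a 1D open stripe, a fragmented collection of short stripes,
or nothing at all — couples the cells.  The package's analysis stack
then measures, with tools from topological data analysis, whether the
population activity forms a torus even when the architecture is
one-dimensional, and which features of the architecture remain visible
in the ensemble of maps.

## The network model

The model has an input layer of `n_input = 225` cells with Gaussian
spatial tuning (s.d. 5.4 cm, peak rate 20) whose centres tile a 1 m
square arena, projecting through plastic weights `W_in` onto
`n_grid = 100` grid cells.  A virtual animal moves 0.6 cm per step, its
heading a random walk with 17 degree s.d. increments; steps that would
leave the arena redraw the turn (the boundary rule is not prescribed by
the model; redrawing keeps the speed constant, at the price of a
moderate over-representation of the walls in occupancy).

Each step the total field of cell *i* is

    h_i = sum_j W_in[i,j] r_in[j]  +  (W_rec r)_i / mean(r)

where `W_rec` holds the fixed recurrent collaterals, row-normalized to
unit L1 norm and multiplied by the recurrent gain 2.  Dividing the
recurrent drive by the instantaneous mean grid rate makes the two terms
comparable in magnitude — the stated goal for the gain — independently
of the overall activity scale; the division is skipped (no recurrent
drive) on silent steps.

Adaptation uses two internal variables,

    h_act(t+1)   = h(t) - h_inact(t)
    h_inact(t+1) = h_inact(t) + beta * h_act(t),        beta = 0.04

so `h_inact` is a leaky integral of the field and `h_act` the field
minus its own recent history: cells fatigue under sustained drive, which
together with global inhibition forces the population to take turns and
is the engine of the hexagonal pattern.  Inhibition is implemented as an
exact threshold: the `(1 - active_fraction)` quantile of `h_act` (ties
broken by cell index) silences all but the top 60% of cells, and rates
are `r = G (h_act - T)_+ / mean((h_act - T)_+)` with the mean over all
cells, pinning the population mean rate at `G = 0.1`.

The Hebbian rule is
`dW[i,j] = eps (r_in[j] r[i] - rbar_in[j] rbar[i])` with running
averages updated as `rbar(t+1) = rbar(t)(1 - delta) + r(t) delta`,
`delta = 0.5`.  Negative weights are clipped at zero and **each row is
then divided by its Euclidean norm**, so rows live on the unit sphere
and the synapses of a cell compete for a fixed total strength, as in
Oja-type rules.  (A variant that only projects rows back when their
norm exceeds one behaves very similarly in our runs, because rows reach
the sphere quickly and stay there; the unconditional division is the
form implemented.)

The learning rate is not part of the reference parameter set; the
default `eps = 0.005` was chosen so that scaled runs of 10^6 steps reach
the qualitative end-state regime (stable periodic weight patterns),
while the full 2x10^7-step protocol continues to refine hexagonality and
alignment.  Rate maps use a 41 x 41 grid of 2.4 cm pixels centred in the
arena — so the central 60 cm crop used by all topological analyses is
exactly 25 x 25 pixels — and are exponential accumulators,
`m <- m (1 - tau) + r tau` with `tau = 0.03`, touching only the
traversed pixel.  Checkpoints of the transient maps are stored every 5%
of the run.

The compiled stepper truncates the input tuning curves at 4.5 sigma
(relative contributions below 5e-5) and tracks the row-norm projection
through a lazy per-row scalar with an exactly maintained sum of squares,
refreshed every 8192 steps; dense reference implementations of every
operation exist in R and the test suite checks the stepper against them,
and the elementary operations against naive double-loop evaluation.

```{r}
cfg <- sim_config(architecture = "ring1d", n_steps = 1e6, seed = 1)
sim <- run_grid_sim(cfg)
summary(sim)
```

## Grid scores

Autocorrelograms correlate two copies of a map under all integer-pixel
displacements (Pearson correlation over the overlap, computed via FFT
cross-correlations) and are tapered by a circular Hamming window whose
radius equals the arena side, damping the poorly-sampled extreme lags.

Three estimator choices deserve a note, because naive versions fail on
realistic maps:

* **Spacing** is the radius with maximal 6-period angular Fourier
  modulation of the polar-interpolated correlogram (bilinear
  interpolation, 1-pixel radial and 1-degree angular steps, radii from 2
  pixels outward).  Comparing raw magnitudes across radii lets the
  high-variance outer lags win, while comparing tapered magnitudes drags
  the winner inward (the taper rescales genuine rings too).  The profile
  is therefore weighted by the square root of the mean pixel overlap at
  each radius, which equalizes the sampling variance of a correlation
  without distorting well-sampled structure.  A parabolic sub-bin
  refinement interpolates between radial bins.
* **Noise gating.**  An estimate is flagged when the winning ring's peak
  correlation stays below 0.25 or when the 6-fold phase is not stable
  across neighbouring radii (circular coherence below 0.97).  On 100
  white-noise maps this flags essentially everything, while trained maps
  from long runs pass with a wide margin (peaks above 0.38, coherence
  above 0.995 in our calibration runs).
* **Gridness** is the mean correlation at the six 60-degree-spaced
  maxima minus the mean at the six interleaved minima, read off the
  *untapered* polar profile at the spacing radius; the angular phase of
  the maxima comes from the argument of the 6-fold coefficient (for a
  profile `cos(6(theta - phi0))` that argument is `-6 phi0`).

Population alignment is quantified by pooling the six first-order
autocorrelogram maxima of every cell, clustering them with k-means
(k = 6, 10 restarts) and averaging the absolute within-cluster pairwise
angle differences.

## The topological pipeline

The analyses run on the central 60 cm crop of the maps (25 x 25 = 625
pixels), avoiding boundary irregularities.  Two point clouds are built
from the population matrix `M` (cells x pixels): the *population cloud*
(columns of `M`, one point per pixel, in R^100) with the kNN-geodesic
metric (k = 10 symmetrized nearest-neighbour graph, shortest paths), and
the *neuron cloud* (rows, one point per cell, in R^625) with the Pearson
correlation distance.

Vietoris-Rips persistent homology in degrees 0-2 with Z/2 or Z/3
coefficients is computed by a persistent-cohomology engine written for
this package (union-find for degree 0; coboundary reduction with the
clearing and apparent-pair optimisations for degrees 1-2; simplices in
the combinatorial number system; filtration order (diameter, index)).
By default the filtration is truncated at the enclosing radius of the
metric space — the scale at which the complex becomes a cone — so every
class of degree >= 1 dies within the filtration and diagrams are
complete.  The single essential degree-0 class receives a finite display
lifetime of 1.2 times the largest finite lifetime, placing it above the
noise on a comparable scale so that it can take part in the cutoff
histogram below.  The engine is validated in the tests against a
brute-force boundary-matrix reduction on random clouds and tie-rich
shortest-path metrics in both coefficient fields.

**Automated Betti numbers.**  Lifetimes are pooled, a 100-bin histogram
between 0 and the maximum is smoothed with a Gaussian kernel of 3-bin
s.d., and the cutoff is the local minimum with the greatest fall from
the immediately preceding local maximum (plateau bins at the start of a
flat valley count as minima).  Per-degree counts of generators above the
cutoff are the Betti numbers.  Pools are per homology degree; a degree
with fewer than 50 generators falls back to the pool of all cycles of
the diagram (a neuron cloud has one long H1 bar and a handful of H2
specks — a per-degree histogram of one value is meaningless, while
noise lifetimes share a scale within one metric space).  For the
local-homology analysis the pool is the annulus diagrams of all points,
mirroring the pooled-condition procedure.

**Local structure.**  The local dimension of each point is the drop-off
of the explained-variance curve of a PCA over its k = 70 nearest
Euclidean neighbours (k = 20 for the no-attractor condition): the first
multiplicative spectral gap reaching at least half the largest gap, i.e.
the first sharp corner of the log-scree curve.  Taking the *first*
qualifying corner rather than the global maximum keeps the weak
curvature shelf of an embedded torus (a few percent of variance in
components 3-5) from inflating the estimate, and the global-gap and
chord-distance variants both misread exactly that shelf on our
fixtures.  Local homology forms, for each point, the annulus of
neighbours ranked k1 = 50 to k2 = 100 (10/30 for the no-attractor
condition), computes its H1 persistence, and thresholds against the
pooled cutoff: interior points of a closed surface give beta1 = 1,
boundary points 0, cone singularities more than 1.  A per-point cutoff
variant exists for annuli that are atypical by construction (the glue
point of two planes splits its annulus over two sparse rings, which a
pooled threshold calibrated on one-ring annuli rejects).

**Orientability and classification.**  Persistence is computed in Z/2
and Z/3; preservation of the salient H2 class under the change of field
means an orientable surface, while its collapse (accompanied, for a
surface, by the loss of one H1 class) betrays the 2-torsion of a
non-orientable surface.  The verdict compares the *top H2 lifetimes*
across the fields rather than thresholded counts: once the salient
generator disappears, the remaining H2 diagram is pure noise and a
histogram cutoff over it carries no information (the cutoff machinery
assumes a signal-plus-noise mixture).  With local dimension 2 (at 90% of
points), no boundary or singularities (beta1 = 1 at 90% of points) and
orientability established, the classification of closed surfaces applies
and Betti numbers (1, 2, 1) identify the torus.

```{r}
pop <- ideal_grid_population(100, noise_sd = 0.06, seed = 1)
cloud <- build_population_cloud(pop, k = 10)
classify_surface(cloud)
```

## Configurations of one-dimensional attractors

For ring architectures the package colours each crop pixel by the
attractor coordinate best describing the population activity there (the
activity-weighted circular mean of the neuron ring angles; pixels with
balanced antipodal activity are flagged as degenerate).  The
*configuration order* describes how one cycle of the ring is laid out in
space.  We classify it by following the cycle itself: starting from the
first neuron's firing field nearest the arena centre, the trace steps to
the nearest field of each successive neuron (lattice translates allowed,
so the path may run beyond the mapped window), and the accumulated
displacement of one full cycle is expressed in the hexagonal lattice
basis and ranked by neighbour shell — order 0 closes on itself, order 1
ends one field over, order 2 at a sqrt(3)-spacing neighbour, and so on.
An earlier design based on the winding of the pixel-phase field around a
hexagonal tile perimeter was abandoned: for a lattice-periodic phase
field without singularities on the path the contributions of opposite
tile edges cancel exactly, so that winding is identically zero and
carries no information, while the path-tracing construction measures
precisely the displacement that defines the order.  Frontier pixels
(circular phase gradient above pi/4 per pixel) are reported as a mask
for visualization.  Stripe attractors are classified the same way along
the open path from the first to the last neuron, which distinguishes a
stretched stripe from one folding back onto its start even when the two
extremes land on lattice-equivalent positions.

The decoded phase of a winding-(1,0) configuration is not exactly linear
in the first lattice coordinate: the circular mean acquires a half-cycle
transverse tilt (a `pi * v` term in the wrapped second coordinate)
because two of the three cosine wave vectors contribute with a
v-dependent phase.  The round-trip test accounts for this analytically.

## Synthetic fixtures

`ideal_grid_population()` builds aligned populations directly from the
three-cosine kernel `f(x) = 1 + (2/3) sum_i cos(k_i . x)` (wave vectors
120 degrees apart; `f` ranges over [0, 3] so maps are valid nonnegative
rates; the translation lattice of `f` is rotated 30 degrees from the
wave vectors, a fact the phase layouts must and do respect).  Phases
uniform over the unit cell emulate the end state of 2D-attractor
training (population cloud a torus); phases winding around the unit cell
emulate ring-attractor configurations (neuron cloud a circle).  Additive
Gaussian noise is clipped at zero.  With the default 2% of the kernel
peak the pipeline's verdicts are stable; the fixtures emulate end-state
structure only — learning transients, trajectory sampling noise and
boundary effects of real runs are *not* represented, so passing fixtures
demonstrates the analysis stack, not the simulator.

`manifold_sample()` provides seeded ground-truth spaces: a flat torus
and a half-twisted Klein tube in R^4 (sampled on a stratified grid with
jitter, which keeps their Rips homology detectable at a few hundred
points; independent uniform sampling needs substantially more points for
the same margins), a circle, a bounded sheet, a sphere-cap of chosen
dimension, and two planes glued at a point.

## Problem sizes and numerical choices

The test-suite and acceptance workloads use the sizes at which the
analyses are routinely run here: 625-point population clouds (the full
25 x 25 crop), 100-point neuron clouds, 625-720-point manifold samples,
and scaled training runs of 10^6 steps for the learning-trend checks
(five seeds per condition; the reference protocol of 2x10^7 steps
sharpens every contrast and was used to calibrate the defaults).  The
Rips filtration runs to the enclosing radius (complete diagrams); on
the rare point clouds whose final filtration stretch produces
pathologically heavy reduction chains, the computation falls back
automatically to a ceiling of 0.85 and then 0.75 of that radius, which
caps the affected deaths without losing generators.  Degenerate inputs are handled explicitly:
constant maps are flagged rather than scored, silent transfer steps
produce zero rates (normalisation guard at 1e-12), disconnected kNN
graphs raise an error naming the component sizes, and all-equal lifetime
pools return a flagged cutoff at the maximum (treating everything as
noise).

## Known limitations

* The simulator reproduces the attractor signatures of alignment and
  compression robustly: at 10^6 steps (and more strongly at 2x10^7) all
  three collateral architectures show smaller angular spread and smaller
  final spacing than the no-attractor condition (at 2x10^7: spreads
  10.4/9.1/12.1 degrees for ring/stripe/torus against 18.8 without
  collaterals; spacings 38-43 cm against 48 cm).  The *gridness*
  ordering is weaker than reported: at full scale the one-dimensional
  attractors do exceed the no-attractor condition (0.67 and 0.77 against
  0.63) but the torus condition does not (0.61), and at the scaled 10^6
  steps of the trend checks none of the attractor conditions does.
  Within-run spacing is essentially flat after the maps form rather than
  contracting throughout learning (only the torus condition shows a mild
  decrease).  The trend assertions are retained as stated and the
  gridness-ordering and spacing-contraction expectations fail honestly
  at the scaled size; plausible causes are the unknown learning rate
  (our scaled choice shortens the transient during which contraction and
  differential hexagonalization would accumulate) and residual ambiguity
  in the adaptation update order.
* The boundary rule over-samples the arena walls; analyses crop to the
  central 60 cm partly for this reason.
* Rips persistence on 625-point clouds at the enclosing radius costs
  tens of seconds to a few minutes per field; the engine supports
  explicit thresholds when speed matters more than completeness.
* The fragmented architecture is exercised by the simulator but its
  spatial-phase organisation is, by design, not summarised by a single
  configuration order.
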