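---
title: "Modelling intercellular calcium waves on chain and branched cell networks"
author: "CICRwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intercellular calcium waves on chain and branched cell networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CICRwave)
```

## The model

CICRwave simulates the propagation of cytosolic calcium waves through
networks of endothelial cells patterned into single-file chains and
branched ("T") structures. Two processes compete:

* **Intracellular CICR dynamics.** Each cell's cytosolic calcium
  concentration $C$ (dimensionless) evolves under a single-variable
  reaction $f(C) = -k(C)\,C$, where the rate constant $k$ switches among
  three values at two concentration thresholds. Below $UC_1$ the
  endoplasmic reticulum absorbs calcium ($k_1 > 0$, so $f < 0$). Between
  $UC_1$ and $UC_2$ calcium-induced calcium release dominates and the
  concentration grows ($k_2 < 0$, $f > 0$): this is the regenerative step
  that lets a wave travel without attenuation. Once $C$ strictly exceeds
  $UC_2$ the cell switches to the post-pulse intake rate $k_3 > 0$ **and
  keeps it forever** — a permanent refractory lock that stands in for the
  ~30 s refractory period of a real cell, which is long compared with
  every simulated horizon. Concentrations exactly at a threshold are
  assigned to the release regime; this measure-zero tie-break is fixed
  for bit-reproducibility.

* **Intercellular gap-junction diffusion.** Cells are unit squares on an
  integer lattice. Cells sharing a side exchange calcium through an
  *edge* coupling with coefficient $\bar D$; cells sharing only a corner
  (which happens only in the junction cluster of the T structure)
  exchange through a *vertex* coupling with coefficient $\bar D_v <
  \bar D$, reflecting the longer diagonal path and the sparser
  gap-junction contact area at a corner.

The update is a synchronous explicit finite-difference scheme. With
per-step coupling weights $w_{ij}$ and per-step reaction increment
$f_i$, every step computes, from the previous step's values only,

$$C_i \leftarrow \max\!\Big(0,\; C_i + \sum_j w_{ij}\,(C_j - C_i) + f_i\Big).$$

Rate regimes are evaluated from the pre-step concentration vector, the
update is fully synchronous, and the result is clamped at zero (the
physical floor; clamping events are counted in the result metadata).
A mechano-stimulation is modelled purely as an initial condition: the
stimulated cell starts at $C_0$, everything else at zero.

## Default parameters

| symbol | meaning | default |
|---|---|---|
| $C_0$ | stimulus concentration | 2.0 |
| $UC_1$ | CICR trigger threshold | 0.3 |
| $UC_2$ | refractory-entry threshold | 3.0 |
| $k_1$ | intake rate, $C < UC_1$ (per step) | 0.03 |
| $k_2$ | release rate, $UC_1 \le C \le UC_2$ (per step) | $-0.025$ |
| $k_3$ | refractory intake rate (per step) | 0.0045 |
| $\Delta t$ | integration step (dimensionless time) | 0.01 |
| $\bar D$ | edge diffusion coefficient (per unit time) | 0.6 |

All quantities are dimensionless; the physical calibration below maps
them to seconds and micrometres.

### The scaling convention

The scheme needs a convention for how the tabulated coefficients enter a
single step. The package parameterises three
(`simulationSettings(convention = ...)`):

* `per_step`: $w_{ij} = \bar D$, $f_i = -k\,C_i$. Unusable at the
  defaults: an explicit scheme with neighbour weight 0.6 violates the
  stability bound (checkerboard amplification $|1 - 4\bar D| > 1$) and
  overflows; the integrator detects this and aborts with the step index.
* `per_time`: $w_{ij} = \bar D\,\Delta t$, $f_i = -k\,C_i\,\Delta t$.
  Stable but inert: the release rate $|k_2|\Delta t$ is then four orders
  of magnitude below the diffusive drain, the stimulated cell never
  reaches $UC_2$, and no wave forms.
* `calibrated` (default): $w_{ij} = \bar D\,\Delta t$ with the reaction
  applied per step, $f_i = -k\,C_i$, i.e. the diffusion coefficient is a
  rate per unit dimensionless time while the tabulated $k$ values are
  already per-step rates.

The calibrated convention is the only one of the three that produces a
travelling CICR wave at the default parameters, and it simultaneously
reproduces four independent observables computed by the test suite: the
cell-to-cell propagation time (0.861 dimensionless units), the
single-pulse spatial extent (9 cells), a pulse temporal width near 11 s
after calibration (measured widths are 10–15 s), and a physical
diffusion coefficient of $2.8\times10^{-10}\,\mathrm{m^2/s}$, the order
of magnitude measured for free cytosolic calcium. The alternative
constant-rate reaction $f = -k$ was also considered and rejected: its
per-step intake $k_1 = 0.03$ exceeds the maximum possible edge inflow
$\bar D\,\Delta t\,\cdot C_{max} \approx 0.018$, so no cell could ever be
pulled over threshold and no wave could propagate.

## Network architectures

`buildChain(n, d_edge)` builds a single-file chain; terminal cells simply
have one coupling (zero-flux boundary, no ghost cells — the protocols use
chains long enough that the boundary is never reached by an active
front).

`buildTStructure(d_edge, dv)` builds the branched test architecture: a
61-cell backbone on row 0; a 30-cell side branch ("1s" ... "30s") rising
from the column of backbone cell 31; and two cluster cells 1′ (above
cell 30) and 2′ (above cell 32) flanking the branch entrance, mimicking
the multi-cell cluster that forms where three single-file branches meet.
Every orthogonally adjacent pair is edge-coupled with $\bar D$.

### Which diagonal pairs are vertex-coupled

The lattice generates eight diagonally adjacent pairs around the
junction. Applying vertex couplings to **all** of them
(`vertex_pairs = "all"`) turns out to change the physics qualitatively:
backbone cell 29 then carries a vertex drain into 1′, the incoming wave
stalls one cell *before* the junction, and — because cells 29 and 33
block symmetrically — dual stimulation gains nothing over single
stimulation. Both blocking at the junction entrance itself (cell 30) and
a genuine dual-stimulation advantage require confining vertex couplings
to the four pairs that couple the branch entrance and cluster to the
junction cells: 1s–30, 1s–32, 1′–31, 2′–31. This
(`vertex_pairs = "junction"`) is the shipped default. The choice is a
reconstruction: it is the smallest symmetric pair set consistent with
the junction geometry, and the only one of the candidates we tried that
preserves the dual-over-single ordering of blocking thresholds.

## Protocols and classification

Four in-silico experiments are provided: `runChainSingle()` (middle cell
31 stimulated), `runChainDual()` (cells 28 and 35, six cells apart,
mirroring the experimental labels 1...8), `runTSingle()` (backbone cell
28) and `runTDual()` (cells 28 and 34, flanking the junction).

`classifyPropagation()` operationalizes "the wave propagated": a cell is
*activated* when its rate regime reached the refractory lock;
side-branch propagation means the mid-branch sentinel "15s" activated
(far from both the junction and the branch tip, so neither junction
leakage nor tip effects can masquerade as propagation); full-structure
propagation means every cell except the degree-one terminals activated.
A run in which any cell activated during the last 5% of the requested
horizon is flagged inconclusive rather than silently classified.
`sweepDv()` classifies a grid of $\bar D_v$ values (resolution 0.01,
matching the two significant figures the thresholds are quoted to) and
reports the largest propagating and smallest blocked values, checking —
not assuming — that propagation occupies a contiguous prefix of the
grid.

With the defaults, single stimulation of the T structure propagates into
the branch for $\bar D_v \le 0.36$ and blocks at the junction entrance
(cell 30) from 0.37; dual stimulation propagates up to 0.48. The
qualitative structure — a finite single-stimulus blocking threshold
strictly below the dual-stimulus one, with blocking localised at the
junction entrance — is robust across every junction pair set we
examined, while the absolute threshold values are specific to this
junction reconstruction and shift with it. They should be read as
properties of this package's junction model, not as universal constants.

## Wave metrics and physical calibration

A cell's *response time* is the time its signal attains its maximum
positive rate of change — the same estimator used on experimental
fluorescence, applied to simulated concentrations, so that simulation
and experiment are compared like for like (a threshold-crossing variant
is available; at the defaults both give the same cell-to-cell time to
within one recording interval). Rates are forward differences
timestamped at the interval end; ties break to the earliest time.

`spatialExtent()` measures the maximum number of contiguous cells above
$UC_1$ **within one propagation direction**. A middle-cell stimulus
launches two mirror pulses that share their tail region around the
stimulated cell for the first few seconds; the whole-chain count
(`scope = "chain"`) therefore briefly spans both pulses (17 cells at the
defaults) and is not the width of *a* pulse (9 cells).

`calibrate()` matches the simulated cell-to-cell time (0.861
dimensionless) to the measured 1.8 s, giving 2.07 s per dimensionless
unit, an effective integration step of 0.0207 s, a wave speed of
17.3 µm/s at the measured 31.2 µm cell spacing, and a physical
diffusion coefficient $\bar D\,\Delta x^2 / \tau = 2.8\times10^{-10}\,
\mathrm{m^2/s}$.

`detectCrossing()` tests the refractory-annihilation prediction: in a
dual-stimulation chain the two waves merge and die, so no cell beyond a
stimulated cell may show a second activation episode. The stimulated
cells themselves show a small secondary hump in their pulse tail — both
neighbours fire simultaneously about one cell-time later and their
combined backflow briefly reverses the decay. This is a known artifact
of the discrete-lattice diffusion (about a quarter of the primary rise
rate at the defaults) and is excluded by construction, because crossing
is only sought outside the stimulated segment; there, second episodes
are detected as post-peak local rate maxima above 10% of the cell's
first-pulse peak rate.

## The experimental trace pipeline and the synthetic generator

`trace_analysis` reimplements the fluorescence workflow: background
correction and normalization by the initial corrected intensity
(`normalizeTraces()`; traces whose initial corrected intensity is not
positive are flagged unusable), response calling (`callResponse()`), a
trailing four-interval running average of the rate for weak signals
(`runningAverageRate()`; trailing rather than centred, so a response
time never precedes the data that produced it), and chain statistics
(`propagationStats()`).

"Responded" is only qualitatively defined for real data — a fast rise
followed by a slower decline, irrespective of magnitude. The
operationalization here: the peak (located on a lightly smoothed copy of
the trace for weak signals) must rise above the pre-rise baseline — the
lower quartile of pre-peak samples, robust to the rise sitting inside
the leading window — by more than `noise_mult` (default 3) times the
per-sample noise, estimated as the MAD of the first differences
divided by $\sqrt 2$; and the quarter-prominence rise time must be
shorter than the quarter-prominence return time, both measured on raw
samples with a two-sample debounce so that a single noisy sample cannot
open or close a pulse. Raw-rate response times carry a 0.6 s
uncertainty (half the 1.2 s sampling interval); running-average times
carry 1.2 s.

`generateTraces()` provides ground-truthed synthetic recordings:
pulses with a 3 s linear rise and an exponential decay reaching 10% of
the peak after 12 s (so the full width matches the observed 10–15 s),
onsets shifted by per-pair lags $1.8\,\mathrm{s} \times U$ with $U$
uniform on $[1/2, 2]$ (lags vary by up to a factor of two), a
propagation range of 4.7 cells, 1.2 s sampling, and additive Gaussian
noise on the normalized scale. All randomness flows through one seeded
generator; a fixed seed gives bit-identical output. What the generator
deliberately does **not** emulate: amplitude attenuation with distance,
spontaneous single-cell firing, photobleaching, and heavy-tailed noise.
Passing the recovery tests therefore demonstrates that the pipeline
recovers lags under the stated noise model, not that it is robust to
every pathology of real recordings.

For lag recovery the pipeline estimates the central cell-to-cell lag as
the **median** of adjacent-responder pair lags (`median_lag`): at
signal-to-noise 5 an occasional spurious responder call adjacent to a
true responder creates one pair with an arbitrary lag, which a mean
over the typical seven pairs cannot absorb. The test suite verifies
recovery to within one sampling interval in at least 95% of 200 seeded
replicates at signal-to-noise 5, and `tracesFromSimulation()` closes
the loop: noiseless simulated trajectories, calibrated, resampled at
1.2 s and pushed through the trace pipeline, reproduce the responder
set and response-time ordering of the dimensionless wave metrics. Four
pre-stimulus baseline samples are prepended there, mirroring the
baseline images collected before the probe touches the cell; without
them the stimulated cell's rise would predate the recording and its
pulse shape would be unclassifiable.

## Numerical choices and problem sizes

* Horizon 15 000 steps (150 dimensionless units): ≥ 1.5× the time for a
  wave at 0.87 per cell to cross the backbone plus branch. Sweeps stop a
  run early once every cell has locked, or once the global maximum falls
  below $UC_1$ — below the lower threshold every term is contractive, so
  the maximum can never rise again and the activation pattern is final.
* Integration instability (non-finite concentration) aborts with the
  step index rather than propagating NaNs.
* The full suite simulates chains of 61 cells and T structures of 93
  cells; sweeps use a 0.01 grid over $[0, 0.3]$ (tests) or $[0, 0.6]$
  (the acceptance script, so both transitions are bracketed).

## Known limitations

* The junction coupling scheme is a reconstruction; absolute blocking
  thresholds depend on it (see above).
* The refractory lock is permanent, so re-firing phenomena on horizons
  longer than a real cell's refractory period are out of scope.
* The model produces no amplitude attenuation along the chain and no
  cell-to-cell variability; experimental variability (lags differing by
  factors of two) enters only through the synthetic-trace generator.
* Two-cell-wide branches, "Y" junctions, sheets and disordered networks
  are not modelled.

## A minimal session

```{r example, eval = FALSE}
p <- reactionParameters()
s <- simulationSettings()

sim <- runChainSingle(p, s)
rt <- responseTimes(sim)
cellToCellTime(rt, as.character(31:40))$mean   # 0.861
spatialExtent(sim)                             # 9 cells

cal <- calibrate(0.861)
effectiveStep(cal)                             # ~0.0209 s
waveSpeed(cal)                                 # ~17.3 um/s

sweep <- sweepDv(p, s, dv_grid = seq(0, 0.6, 0.01), mode = "single")
attr(sweep, "largest_propagating")             # 0.36
```
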