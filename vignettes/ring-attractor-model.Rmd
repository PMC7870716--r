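---
title: "A spiking ring-attractor model of the fly head-direction circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking ring-attractor model of the fly head-direction circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxring)
```

## The circuit and its reduction

The fruit fly maintains an internal estimate of its heading as a localized
peak of activity — a "bump" — distributed over neurons of the central
complex. Four neuron classes innervating the protocerebral bridge (PB, nine
glomeruli per hemisphere) and the ellipsoid body (EB, eight tiles) carry
this representation: E-PG neurons (EB wedges to PB glomeruli, excitatory),
P-EG neurons (PB to the matching EB tile, excitatory), P-EN neurons (PB to
the EB tile one octant to the left or right, excitatory), and the
PB-intrinsic inhibitory Delta7 neurons, whose output terminals recur every
eighth glomerulus along the bridge.

`cx_arbors()` encodes these projection patterns as a terminal table;
`infer_synapses()` applies the standard light-microscopy assumption that
overlapping input and output terminals in the same volume form synapses;
`reduce_circuit()` collapses the mirrored hemispheres into effective
functional units. The reduction merges neurons that carry the same signal —
same class, same input-volume signal classes — and write into
signal-equivalent volumes. Two points deserve emphasis:

* **Hemisphere identification is a functional assumption, not a graph
  fact.** The two hemispheric copies of, say, E-PG_1 reach complementary
  subsets of the Delta7 population, so no purely structural
  neighborhood-equality rule merges them. What licenses the merge is the
  observation that the two PB activity bumps sit over equally numbered
  glomeruli, i.e. left and right glomeruli of equal number carry the same
  signal. The reduction therefore identifies PB glomeruli across
  hemispheres at the signal level and refines volume signal classes
  iteratively; equality of *written* signals is what eventually identifies
  glomeruli G1 and G9 and closes the ring (eight octants from nine
  glomeruli).
* P-EN units are deliberately **not** merged across hemispheres: the left
  and right members of each octant pair are the anatomical hook for angular
  velocity input (not modelled here), so the effective circuit keeps 16
  P-EN units as 8 overlapped pairs.

The result is a 40-unit circuit (8 E-PG, 8 P-EG, 8+8 P-EN, 8 Delta7) with
200 signed edges and exact eight-fold rotational symmetry
(`check_radial_symmetry()` returns 8). Delta7 units inhibit each other
all-to-all (56 edges) and every E-PG unit excites all eight Delta7 units
(64 edges); each Delta7 unit inhibits the P-EG/P-EN units of its own and
the preceding octant, so the inhibitory projection is uniform around the
ring.

## Neurons and synapses

Units are leaky integrate-and-fire neurons advanced by forward Euler at
`dt = 1e-4` s:

V' = ((V0 - V)/Rm + I_ext + I_syn) / Cm

with Cm = 2 nF, Rm = 10 MOhm (time constant 20 ms), rest -52 mV, threshold
-45 mV. A threshold crossing inserts a stereotyped 2 ms action-potential
template (Gaussian rise to +20 mV, half-sinusoid fall to -72 mV; each
segment affinely rescaled to span exactly [0, 1] over its own support — the
only reading of the published normalization constants that pins the
endpoints) and enforces an absolute refractory period of the template
duration. Each spike injects into its targets a postsynaptic current
kernel: half-sinusoid rise to 5 nA over 2 ms, then 2^(-t/5 ms) decay,
truncated at 7 half-lives (37 ms total). The decay segment is *not*
affinely rescaled: rescaling would break the exact half-life landmark
I(2 ms + t_psc) = I_psc/2. Synaptic weights scale this unit kernel and are
expressed as I_psc-equivalents per action potential; inhibition is exact
negation. Heading input reaches E-PG units as Poisson spike trains passed
through the same unit kernel (direct current injection is also available).

## Stimulus encoding

A cue at azimuth `h` produces a von Mises rate profile over the eight
octants, scaled so the minimum equals the 5 imp/s background, the maximum
the peak stimulus rate, and the full width at half maximum of the
above-background rate equals 90 degrees; kappa is solved numerically from
the FWHM condition. Azimuth 0 maps to the center of octant 1; octants
advance clockwise in 45-degree steps. The peak rate nominally equals the
peak E-PG population rate, which is circular at build time; the package
default (380 imp/s) is the E-PG peak measured from the reference circuit,
and the self-consistency loop closes after one iteration (driving the
circuit at 380 yields an E-PG peak of roughly 340-400 depending on the
window).

## Weight optimization

The five free weights (w1: E-PG out; w2: P-EN to E-PG; w3: P-EG to E-PG;
w4: Delta7 to P-EN/P-EG; w5: Delta7 to Delta7; excitatory in [0, 100],
inhibitory in [-100, 0]) are fitted by minimizing

4 (eH1 + eH2) + eW1 + eW2 + N p0

over the two-step protocol (stimulus at 0 deg for 0.5 s, 1 s darkness,
stimulus at 180 deg, 1 s darkness), where eH are the circular heading
errors of the decoded bump at the two darkness ends, eW the deviations of
its FWHM from 90 degrees (both scaled by 360), and p0 = mean(exp(-2|w|))
penalizes vanishing weights. Bump heading and width are measured on the
time-averaged E-PG rate profile over the final 250 ms before each
checkpoint; an absent bump scores the worst case (eH = 0.5, eW = 0.75).

Numerical choices that mattered:

* **Common random numbers and repetition.** Within one fit every
  evaluation shares a single stimulus-encoding seed, so the optimizer sees
  a deterministic function. With a single encoding per evaluation the
  search reliably exploits the particular Poisson draw — weight sets
  scoring ~0.1 under their own seed scored ~3 under fresh seeds and were
  non-functional. `n_rep` averages the objective over a few independent
  encodings and removes this failure mode.
* **Log-magnitude initialization.** Weights act multiplicatively over
  orders of magnitude; a swarm initialized uniformly over the box almost
  always converges to a saturated large-weight regime with a 200-degree
  bump. Particles are therefore initialized log-uniformly (one particle at
  the prescribed 0.01 starting point); optional restarts and a short
  bounded Nelder-Mead polish refine the best point.
* Both particle swarm (constriction form, chi = 0.7298, c1 = c2 = 1.49618)
  and bounded Metropolis annealing are provided; PSO is the default.

## The reference weights and a three-way trade-off

`cx_reference_weights()` = (2.5, 1.0, 4.0, -1.5, -1.5) was selected by
screening near-optimal solutions of the objective with the sensitivity
battery. The screening exposed a structural trade-off the objective alone
cannot see:

* With strong Delta7-Delta7 inhibition (|w5| around 4 and above) the
  darkness bump is cleanest — in darkness the Delta7 pool falls silent,
  leaving a deep, saturated attractor state. But under quenched
  heterogeneity (membrane conductance noise at 25 percent of nominal) the
  mutually inhibiting pool freezes into an asymmetric winner-take-all
  state: a fixed subset of Delta7 units fires, the octants they disinhibit
  capture the bump permanently, and tracking collapses.
* With weak |w5| (around 1) the pool stays in an averaging regime and
  tracking survives 50 percent conductance noise, but the darkness bump
  widens and drifts.
* |w5| around 1.5 with moderate w4 achieves both: an 88-degree bump stable
  through seconds of darkness, 180-degree relocation on an azimuth step,
  and tracking that still meets the 10-degree criterion in the majority of
  trials at 50 percent conductance heterogeneity, while capacitance
  heterogeneity (which corrupts the integration time constant rather than
  the operating point) collapses tracking by 20 percent — the observed
  membrane-property asymmetry.

One published qualitative claim does **not** reproduce in this
implementation: tolerance to noise on the *input* synapses of Delta7
neurons. Per-edge noise on E-PG-to-Delta7 weights is here the most harmful
weight-class perturbation (failures from ~15 percent noise): mutual
inhibition among Delta7 units amplifies rather than averages small drive
differences unless the pool is saturated, and the saturated regime is
incompatible with darkness stability anywhere we searched the weight box.
The other per-class asymmetries do reproduce: E-PG-to-P-EN noise degrades
tracking more than P-EN-to-E-PG noise, P-EG-to-E-PG noise is nearly
harmless (and complete P-EG silencing leaves stimulus-driven tracking
intact — the P-EG loop matters for darkness stability, not for driven
tracking), and Delta7-to-P-EN/P-EG noise is disruptive, as expected when
inhibition of the excitatory ring is essential for a single bump.

## Decoding and tracking metrics

Bump azimuth is the population vector (circular mean of octant centers
weighted by E-PG rates from a causal 50 ms boxcar); width is the FWHM of
the profile by circular linear interpolation; both are flagged undefined
on flat profiles. Tracking error is the absolute wrapped difference to the
true heading; a trial succeeds when the error is below 10 degrees for more
than half of the stimulated duration. The global lag is the argmax of the
cross-correlation of the *detrended* unwrapped heading series (the net
rotation trend carries no timing information and biases the estimate
toward zero; sub-sample refinement by parabolic interpolation), and
per-frequency lags are cross-spectral phases power-averaged within
log-spaced bands, since single Fourier bins of a stochastic trajectory are
far too noisy. With the reference circuit the global lag is about 50 ms
(membrane constant 20 ms, PSC decay 5 ms, decoder window, and bump inertia
during saccade recovery), and band lags rise with frequency: fast heading
components trail more.

## The synthetic trajectory

The tracking experiments drive the circuit with a synthetic stand-in for a
digitized arena flight: quasi-regularly timed 120-degree saccades
(gamma-renewal intervals, shape 16; shape 1 recovers Poisson timing) over
a slow continuous drift carrying 10 percent of the net rotation, completing
one revolution per 1/0.916 s so the heading power spectrum peaks at
0.916 Hz (verified by both periodogram and autocovariance estimators).
Saccade-dominated rotation with near-straight inter-saccade segments is
what arena flight looks like, and it is also the only regime in which the
10-degree criterion is meaningful for an eight-state attractor: under fast
*smooth* rotation the bump advances in 45-degree steps, so the tracking
error sawtooths through the criterion regardless of lag. The generator
reproduces the published spectral signature and the qualitative velocity
structure, not the microstructure of any individual fly's flight; tests
passing on it say nothing about, e.g., translational optic flow or
closed-loop visual control.

## Problem sizes and reproducibility

Default experiment sizes: 3.5 s two-step protocols, 10-20 s trajectories,
simulation step 1e-4 s, 20 trials per sweep condition, optimizer budgets
of order 1000-2000 evaluations — sizes at which every experiment in the
test suite and the acceptance script reruns from scratch in minutes on one
core. Every stochastic step (encoding, trajectory, perturbation, search)
takes an explicit seed, and per-trial seeds are derived deterministically
from a base seed, so all results are exactly reproducible.

## Known limitations

* Wedge-level EB resolution is collapsed to tiles; stray terminals,
  electron-microscopy synapse counts, and per-synapse (untied) weights are
  out of scope.
* Angular-velocity input to P-EN units is not modelled; the L/R pairs are
  kept distinct only as the hook for it.
* The Delta7 output-domain table follows the published seven-glomerulus
  spacing rule; the light-microscopy data give the pattern, not a
  definitive per-neuron domain list.
* The Delta7-input noise tolerance discussed above is a known divergence.
* The success criterion is sensitive to decoder quantization near octant
  boundaries; with only eight readout channels a few degrees of the error
  budget are structural.
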