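---
title: "Modelling electrical coupling between unmyelinated axons of brainstem neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling electrical coupling between unmyelinated axons of brainstem neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(axonet)
```

## The system and the question

Hatchling *Xenopus* tadpoles swim because a small population of brainstem
reticulospinal interneurons (descending interneurons, dINs — about 30 per
side, somata spaced roughly 10 µm apart in a rostrocaudal column) drives the
spinal motor circuits. Paired recordings show these neurons are electrically
coupled over somatic separations up to ~200 µm, far beyond the reach of
their short dendrites, so the coupling is almost certainly through gap
junctions between their thin (~0.4 µm), unmyelinated descending axons.

`axonet` implements a biophysical model of this population to ask where
along the axons such junctions can lie, and what axo-axonic coupling does to
input resistance, firing phenotype, action-potential propagation, population
pacemaker rhythm and sensory recruitment.

## Model components

### Morphology and discretisation

Each neuron has four sections: an isopotential soma+dendrite cylinder whose
lateral area equals the estimated 1000 µm² (diameter = length =
`sqrt(1000/pi)` ≈ 17.84 µm), two short (5 µm) tapered hillock sections
interpolating linearly from 2 µm down to the axon diameter, and a uniform
0.4 µm axon. Compartment lengths are 5 µm in the hillock and proximal axon
(out to 400 µm) and 100 µm beyond; with the passive parameters below the
axonal space constant is ~224 µm, so even the coarse bins stay well under a
space constant. The soma+dendrite lumping follows the observation that the
real dendrites are electrotonically compact; only the area matters, not the
shape.

The axon length is not constrained by the anatomy used here (biological
values span roughly 280–2050 µm); the default is 1500 µm, long enough that
propagation can be probed over the full distance reported for the real
cells, and configurable per morphology. Hillock dimensions are likewise not
constrained by data; the defaults are small enough that the hillock
contributes negligibly to load, and both are exposed in the configuration.

### Membrane currents

Membrane potential obeys

$$C\,\frac{dV}{dt} = i_{lk} + i_{na} + i_{kf} + i_{ks} + i_{ca} + i_{ext},$$

with every current written in the depolarising-positive convention
$i = g\,(e - V)$: a leak ($e_{lk} = -52$ mV, base 0.25 mS/cm²), a
Hodgkin–Huxley sodium current $g_{na} m^3 h (e_{na} - V)$
($e_{na} = +50$ mV, base 10 mS/cm²), fast and slow potassium currents
$g_{kf} n^4$ and $g_{ks} n^2$ ($e_k = -81.5$ mV, bases 2.5 and
2.0 mS/cm²), and a Goldman–Hodgkin–Katz (constant-field) calcium current
gated by $m^2$ (permeability 0.016 cm/s). Every gate follows first-order
kinetics with rates of the shared form

$$r(V) = \frac{A + BV}{C + \exp((D+V)/E)},$$

parameterised per gate by the packaged registry
(`inst/extdata/rate_params.csv`), with the calcium closing rate switching
parameter sets at −25 mV (the split voltage itself uses the upper branch;
the two branches agree there to ~2 %).

Two bookkeeping choices deserve emphasis:

* **Sign consistency of the sodium activation rate.** The registry stores
  $E = -12.56$ mV for the sodium opening rate $\alpha_m$. The sign is fixed
  by the physics: activation must increase with depolarisation (a positive
  $E$ makes $m_\infty$ *decrease* with voltage and puts
  $m_\infty(-52\,\mathrm{mV}) \approx 0.7$, which no resting neuron
  survives), and every other activating rate in the set carries a negative
  $E$. A property test asserts the monotonicity.
* **GHK magnitude convention.** The GHK flux is evaluated with
  concentrations in mol/L (defaults 100 nmol/L internal, 10 mmol/L
  external calcium — conventional for this preparation, configurable) and
  the result is read in µA/cm². Under strict mol/cm³ bookkeeping the
  calibrated permeability constant of 0.016 cm/s would produce maximal
  calcium currents two orders of magnitude above the sodium maximum and a
  voltage-steep standing current that destabilises the resting state
  entirely; under the mol/L convention the calcium current is of the same
  order as (but smaller than) the other currents, the rest state is stable,
  and all of the cell's reported firing behaviours emerge. The removable
  singularity at $V = 0$ is evaluated by series expansion, so the current
  is continuous there; raising the calcium scale tenfold was checked to
  destroy the single-spike phenotype, which independently supports the
  small-calcium reading.

Rates that come out marginally negative at strongly hyperpolarised
potentials (the slow-potassium opening rate below ≈ −75 mV) are clamped to
zero, keeping them valid transition rates; gates therefore remain in
\[0, 1\] without clipping.

### Channel densities

Realised densities are $g_x = \hat g_x \times M_X \times N(1, 0.05)$, one
normal draw per neuron, channel and realisation, clamped at zero. The
chosen multipliers are $M_{na} = 3$ and 1.0 for the others. The final model
is non-uniform along the axon: over the initial segment 20–70 µm from the
soma, sodium density is multiplied by 5 and both potassium densities by
0.5. The potassium factor is not pinned by any reported number (only the
direction, "decreased", is); 0.5 is the package default and configurable.
In coupled mode the leak is halved to 0.125 mS/cm², the value that
compensates the junctional shunt when the cell sits in the network.

### Gap-junction layout

Junctions are generated on the proximal axon of each (caudal) neuron: its
first 50 µm are divided into 1 µm bins; per bin, up to six more rostral
neurons whose axons pass that rostrocaudal coordinate are sampled uniformly
without replacement, and each sampled partner receives a 600 MΩ junction at
the bin centre with probability 0.015 (density 0.015 µm⁻¹ × 1 µm). The cap
of six reflects the packing of equal cylinders in a bundle; it is enforced
per bin, with duplicates between the same pair in different bins allowed
(bins are independent). Restricting partners to *rostral* neurons follows
from the definition of the junction position along the caudal member's
axon: it keeps every junction inside the stated region of the caudal axon,
which a bidirectional reading violates whenever the region starts away from
the soma. A fixed-point variant (single candidate position, Bernoulli per
pair) is included for comparison; it clusters junctions and was not chosen.

Under the defaults the expected total is 119.25 junctions per 30-neuron
network (the first six neurons have fewer than six rostral partners), i.e.
~8 junction contacts per axon and ~23 % of the 435 unordered pairs directly
coupled; most other pairs are coupled indirectly through one intermediate
axon.

### Electrical system and integration

Compartments couple axially with conductances from $R_i = 80$ Ω·cm and the
two half-compartment cylinders; each junction contributes $1/R_{GJ}$
between the two axonal compartments straddling its coordinate; membranes
carry 1 µF/cm². Passive questions (coupling coefficients, input
resistance) use the exact sparse steady-state solve $G\,\Delta V = I$
(Matrix); the conductance matrix is symmetric with non-positive
off-diagonals and leak-only row sums, which the suite asserts, along with
transfer-resistance reciprocity against a dense oracle and the analytic
space constant $\lambda = \sqrt{R_m d / 4 R_i}$ to 2 %.

Dynamics use a compiled implicit first-order (backward-Euler) step:
staggered exponential gate updates at the pre-step voltage, all linear
terms (leak, open ohmic conductances, axial coupling, synaptic conductance
and the self side of each junction) implicit, the junction partner voltage
and the GHK flux explicit. Each neuron is an unbranched chain, so the
implicit system is tridiagonal (Thomas algorithm); the explicit junction
side is harmless because junctional conductances (1.7 nS) are far below
axial ones (31 nS) and the splitting is a convergent Jacobi iteration at
steady state. Gate and GHK voltage dependences are tabulated on a 0.025 mV
grid with linear interpolation. Defaults: dt = 0.01 ms active (self-
convergence: halving dt moves spike times by < 0.05 ms), 0.1 ms passive;
20 ms settling from $V = e_{lk}$ with gates at steady state before any
protocol. Sealed ends terminate every axon. A non-finite state aborts with
the failure time.

## Measurement protocols

* **Coupling coefficients**: 50 runs per network; a random soma receives a
  constant hyperpolarising current (−100 pA by default — the passive model
  is linear, and the suite asserts amplitude- and sign-invariance) and
  every other soma's steady deflection is expressed as a percentage of the
  source's. Summaries are distance-binned medians with quartile and 5–95 %
  bands.
* **Input resistance**: steady somatic deflection over injected current;
  hyperpolarising steps close the active channels, so the passive solve is
  exact for this measurement.
* **Firing classification**: 200 ms steps at 50–300 pA; `single` means
  exactly one spike at every suprathreshold level; persistence beyond the
  step or firing before it marks instability.
* **Rebound**: a −200 pA, 20 ms pulse during a +100 pA background must
  trigger a spike within 20 ms of pulse offset, while the same pulse from
  rest must not. (The pulse amplitudes are package defaults; only the
  qualitative protocol is constrained.)
* **Propagation and velocity**: a brief suprathreshold somatic pulse
  (500 pA, 5 ms) with probes along the axon (every 20 µm proximally, every
  100 µm beyond 400 µm); success requires a spike at the most distal probe
  within 50 ms; velocity is the slope of a distance–time fit. The
  junction-region velocity is fitted over arcs ≤ 70 µm, the region that
  actually holds junctions.
* **Density sweep**: the full tested multiplier grid (4 × 6 × 3 × 3 × 3 =
  648 combinations; a printed figure of 288 for this grid does not match
  its own factor counts, so the grid is configurable and the full product
  is the default) with firing/propagation/rebound fractions per point;
  interactive use and the tests run reduced grids.
* **Population step**: a common step into every soma; frequency from
  inter-spike intervals within the step (neurons with < 2 spikes contribute
  none); synchrony is the voltage-based index
  $\chi = \sqrt{\mathrm{Var}_t \langle V \rangle / \overline{\mathrm{Var}_t V_i}}$
  — the population-mean trace retains its temporal variance only if the
  neurons fire together. Any monotone synchrony measure would serve; this
  one avoids phase bookkeeping for rasters.

## Sensory drive

The trigeminal interneuron (tIN) population (20 cells) converts a
normalised skin-stimulus strength *s* (100 % = swimming threshold) into
spike trains: the spike count is drawn from $p(N = n \mid S = s)$ anchored
at $p(1\,|\,95) = 0.5$, $p(1\,|\,100) = 1$, and $p(1\,|\,s > 120) = 0.3$,
with piecewise-linear interpolation; below 100 % the remainder is silence,
above it the remainder is multi-spike with configurable weights over 2–5
spikes (the true high-stimulus count distribution is not published; the
weights are placeholders, and nothing quantitative rests on them). Spike
times are per-index normals $t_k \sim N(\mu_k, \sigma_k)$, sorted; the
defaults $\mu_k = 5 + 10(k-1)$ ms, $\sigma_k = 2$ ms are likewise
structural placeholders. Each spike drives a difference-of-exponentials
glutamatergic conductance (rise 1 ms, decay 4 ms, reversal 0 mV) on the
dIN somata, with identical synapse parameters everywhere; in the
recruitment experiment each dIN receives its *own* stochastic realisation
of the 20-tIN train set, modelling the heterogeneity of synaptic input
across cells — with a single waveform shared by all dINs the uncoupled
population is nearly homogeneous and recruits almost as sharply as the
coupled one, erasing the graded-versus-step distinction the experiment
probes. The peak conductance (default 0.4 nS per contact) is calibrated — `calibrate_synapse_peak()` — so the
threshold stimulus recruits the coupled population, and recorded in
configuration rather than hard-coded. What this generator emulates is the
*statistics* of sensory drive; it does not model trigeminal neurons, skin
biophysics or NMDA voltage dependence, so passing recruitment tests speak
to the effect of electrical coupling on recruitment, not to sensory coding.

## What the model reproduces, and where it deviates

With the printed parameters the package reproduces, without tuning: the
layout statistics (≈119 junctions, ~8 contacts per axon, ~23 % direct
pairs); the ~600 MΩ junction-free input resistance and the ~50 % passive
shunting drop; the single-spike-when-coupled / repetitive-when-uncoupled
phenotype flip with rheobase ≈ 75–100 pA; rebound firing only from a
depolarised background; whole-population synchronous pacemaker firing that
accelerates with current (≈19 Hz at its threshold, ≈33 Hz just above,
~60–75 Hz maximum) before repetitive firing fails; desynchronisation as
junctions are subsampled; junction-free conduction velocity ≈0.32 m/s over
the proximal region; near-certain propagation with 2000 MΩ junctions; and
the all-or-none versus graded recruitment switch.

Quantitative deviations remain, all in one direction and with a common
root: the stochastic layout scheme, taken literally, yields ~119 junctions
(the top of the quoted 80–120 range), so the junctional shunt is somewhat
stronger than in the reported model. Consequently the coupled input
resistance is ~220 MΩ rather than ~300, network coupling-coefficient
*medians* are ~4 % (0–50 µm) and ~1 % (150–200 µm) at uniform leak —
the experimentally measured 10–15 %/5 % values are reached only by the
upper band of the model distribution — the coupled junction-region
velocity is ~0.11 m/s rather than ~0.16, and single-neuron propagation
with the ×5 initial segment succeeds in ~45 % of instantiations rather
than just over half. The passive electrical core was cross-checked against
an independent dense-grid oracle (input resistance and a two-cell coupling
coefficient to < 1 %, space constant to 0.1 %), so these gaps are
properties of the stated parameter set, not of the implementation; the
shipped checks assert the reported values as stated and flag these gaps
rather than masking them with loosened tolerances.

## Problem sizes

The shipped checks use desk-scale sizes chosen as a deliberate
reproducibility budget: 50–100 generated networks for passive and layout
statistics, 10 seeds for input-resistance, rheobase and velocity averages,
5 and 3 seeds for the population frequency measurements, 20 instantiations
for propagation fractions, 10 seeds × 5 stimulus levels for recruitment,
and two-value-per-channel grids for sweep smoke tests. Each is a parameter
of the corresponding function, so any of them can be scaled up.

## Known limitations

One-sided column only: no reciprocal inhibition, no post-inhibitory-rebound
rhythm network, no NMDA pharmacology, no A-type potassium channel, no
calcium accumulation, no stochastic channel gating, no ascending axons or
dendritic arbors. Velocities in the distal 100 µm compartments are
discretisation-limited; velocity fits therefore use the finely
compartmentalised proximal axon.
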