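# axonet

Biophysical simulation of a column of brainstem reticulospinal neurons
(dINs) whose thin, unmyelinated axons are electrically coupled by
axo-axonic gap junctions — the population that drives swimming in hatchling
*Xenopus* tadpoles. The package is for computational neuroscientists who
want to explore how the number, position and resistance of axonal gap
junctions shape measurable quantities: soma-to-soma coupling coefficients,
input resistance, single-versus-repetitive firing, action-potential
propagation along fine axons, population pacemaker rhythm, and all-or-none
sensory recruitment.

## The model

Thirty multicompartment neurons (isopotential 1000 µm² soma, two tapered
hillock sections, a 0.4 µm × 1500 µm axon; compartments of 5 µm proximally
and 100 µm distally) form a rostrocaudal column with somata 10 µm apart.
Membrane potential follows

    C dV/dt = g_lk (e_lk − V) + g_na m³h (e_na − V)
            + g_kf n⁴ (e_k − V) + g_ks n² (e_k − V) + i_ca(GHK) + i_ext

with Hodgkin–Huxley-type gate kinetics, rates of the form
`(A + BV)/(C + exp((D+V)/E))`, and a Goldman–Hodgkin–Katz calcium current.
Channel densities carry per-neuron noise (`N(1, 0.05)`), chosen multipliers
(Na ×3), and an excitable initial segment (Na ×5, K ×0.5 over 20–70 µm of
axon). Gap junctions (600 MΩ) are placed stochastically at density
0.015 µm⁻¹ over the first 50 µm of each axon, at most six partner axons per
1 µm bin. Passive questions are answered by exact sparse steady-state
solves; dynamics run in a compiled implicit (backward-Euler) integrator
with staggered gate updates. See the methods vignette
(`vignettes/coupled-axon-networks.Rmd`) for every assumption and numerical
choice.

## Worked example

```r
library(axonet)
set.seed(1)
net <- final_din_network()          # 30 dINs, density layout, coupled leak
st  <- layout_statistics(net)
dens <- realise_densities(net$pop$compartments, net$density,
                          g_lk_base = net$g_lk)
classify_firing(net, 14, densities = dens)
population_step(net, 40, densities = dens)
```

prints (seed 1):

```
din_network: 30 neurons, 121 gap junctions, g_lk = 0.125 mS/cm2
junctions: 121  (8.1 per axon, 23% of pairs direct)
input resistance: 218 MOhm coupled, 558 MOhm without junctions
firing, coupled: single (spikes at 50/100/200/300 pA: 0/1/1/1)
firing, junctions deleted: repetitive (7/10/5/1)
population step at 40 pA: 33.5 Hz, synchrony 0.80
```

Read: this layout draw produced 121 junctions (~8 contacts per axon; 23 %
of the 435 neuron pairs share a direct junction, the rest couple through
intermediate axons). Junctional shunting roughly halves the somatic input
resistance. The same neuron that fires exactly one spike at every
suprathreshold step while coupled fires repetitively once its junctions are
deleted — the single-spike phenotype is a network property, not a cellular
one. When all 30 somata are driven together the population fires as a
synchronous ~33 Hz pacemaker.

Other entry points: `measure_coupling()` / `bin_coupling()` for
coupling-coefficient profiles, `propagation_test()` /
`conduction_velocity()` for axonal reliability, `density_sweep()` for
multiplier grids, `recruitment_experiment()` for the sensory switch, and
`run_experiment()` (or `inst/cli/axonet.R`) for config-driven runs with
reproducibility manifests.

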