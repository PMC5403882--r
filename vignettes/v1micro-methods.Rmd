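---
title: "Modeling contextual processing in mouse V1 with three inhibitory cell types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling contextual processing in mouse V1 with three inhibitory cell types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(v1micro)
```

# The scientific problem

Visual neurons respond not only to what is inside their receptive field but
to the surrounding context: responses to homogeneous surfaces are weak,
object boundaries are enhanced, and top-down signals can selectively boost
responses to a preferred stimulus. The three major genetically defined
inhibitory interneuron classes of cortex — parvalbumin- (PV),
somatostatin- (SST) and vasoactive-intestinal-peptide-expressing (VIP)
cells — have distinctive connectivity: PV cells inhibit pyramidal (Pyr)
cells and themselves over short ranges; SST cells inhibit every other class
(but not themselves) and collect long-range horizontal excitation; VIP
cells mainly inhibit SST cells, creating a disinhibitory pathway.

`v1micro` implements a two-level model of how this division of labor shapes
contextual processing in mouse primary visual cortex:

1. a **four-population firing-rate model** of the layer 2/3 microcircuit
   (Pyr, PV, SST, VIP) for qualitative analysis — fixed points, stability,
   and input scans; and
2. a **multi-column spiking network** of leaky integrate-and-fire (LIF)
   neurons: thirteen layered columns (layers 2/3, 4, 5, 6) in a
   one-dimensional periodic arrangement, with cell-type-specific
   superficial-layer connectivity and four intercolumnar connection
   families, driven by Poisson background fibers and thalamic relay cells.

# The rate model

Each population's rate $f_x$ relaxes toward a rectified square-root
transfer of its net synaptic drive:

$$\tau_m \dot f_x = -f_x + c_x\,\sqrt{u_x - \theta}\; H(u_x - \theta),$$

with $\tau_m = 10$ ms, threshold $\theta = 360$ pA and gain coefficient
$c_x = 5.33\ \mathrm{Hz}/\sqrt{\mathrm{pA}}$ for all four populations (the
square-root law is the F-I curve of the underlying LIF neuron near
rheobase; the coefficient can be varied per population). The net drives
encode the circuit's structure — SST receives no self- or PV inhibition,
VIP inhibits SST, and so on:

$$
\begin{aligned}
u_e &= I_e + S_{ee} f_e - S_{ep} f_p - S_{es} f_s - S_{ev} f_v\\
u_p &= I_p + S_{pe} f_e - S_{pp} f_p - S_{ps} f_s\\
u_s &= I_s + S_{se} f_e - S_{sv} f_v\\
u_v &= I_v + S_{ve} f_e - S_{vp} f_p - S_{vs} f_s
\end{aligned}
$$

Defaults (in `rate_model_params()`) are the fitted superficial-layer
coefficients, e.g. $S_{ee}=1.98$, $S_{ep}=5.68$, $S_{es}=3.05$,
$S_{sv}=0.36$, $S_{vs}=1.48$, with applied currents
$I_e=366, I_p=362, I_s=361, I_v=370$ pA.

## Numerical analysis choices

**Fixed points.** The rectification partitions state space into $2^4$
"active sets". `enumerate_steady_states()` solves the restricted smooth
system $f_A = g(u_A)$ for each subset $A$ by damped Newton iteration with
backtracking on the residual norm, from deterministic low-discrepancy
starts placed log-uniformly in $[0.1, 200]$ Hz, plus endpoints of
trajectories integrated from a coarse lattice (so attractors whose basins
miss the lattice are still found). A candidate is kept only when inactive
populations sit at or below threshold. Completeness is relative to the
multi-start design; roots far outside the start range could be missed.

**Stability.** The Jacobian uses the right-hand derivative of the
square-root gain for active populations and the locked zero branch below
threshold; a population sitting exactly at threshold makes the fixed point
one-sided and the state is labelled `marginal` when the leading eigenvalue
is within tolerance of zero, rather than guessed. Unstable foci are probed
for a surrounding limit cycle by integration (2000 ms horizon, 1000 ms
discarded; a cycle requires peak-to-peak pyramidal variation above 0.5 Hz
with a stable period, successive peak intervals within 5%).

**Scans.** `scan_input()` and `sst_silencing_threshold()` carry each grid
point's solutions to the next point as additional Newton starts
(poor-man's continuation), because branches near folds have basins smaller
than the branch's movement per grid step. The silencing threshold is the
midpoint between the last grid value with a stable pyramidal-active
attractor (steady or periodic) and the first without, on a 0.5 pA grid by
default.

With the default parameters the model reproduces the qualitative regimes:
a stable pyramidal-active state coexists with a Pyr-silent PV/VIP state at
the default SST drive; pyramidal activity disappears for SST drives above
$\approx 365$ pA; VIP input first disinhibits Pyr (by suppressing SST) and
then becomes purely inhibitory once SST is silent; without the VIP→SST
coupling, VIP input never disinhibits. One deviation from a naive reading
of the qualitative analysis is worth recording: *halving the SST gain
coefficient* makes the pyramidal decline shallower (higher $f_e$ at
matched drive, and half the SST rate at matched drive), but it does not
extend the stable branch — the branch instead loses stability via a
subcritical Hopf slightly earlier. The package therefore treats "slower
decline" (a slope statement) as the tested property of reduced SST gain.

# The spiking network

## Populations and wiring

A column holds 19,294 LIF neurons: L2/3 5171 E + 1459 I, L4 5479 E +
1370 I, L5 1213 E + 266 I, L6 3599 E + 737 I. The superficial inhibitory
pool is split 24% VIP and 30% SST (round-half-even), the remainder PV:
671 PV / 438 SST / 350 VIP.

All neurons share one LIF parameter set ($\tau_m$ 10 ms, $V_{th}$ −50 mV,
$V_{reset}$ −65 mV, $\tau_{ref}$ 3 ms, $C$ 250 pF; resting potential taken
equal to reset). Synapses are instantaneous-rise exponential-decay current
pulses; each neuron carries one receptor channel per incoming kinetic
class. Superficial cell-type-specific peaks and decay constants (e.g.
PV→Pyr −466.7 pA / 6.0 ms, SST→Pyr −200.0 / 7.5, VIP→SST −66.7 / 10.4,
SST→VIP −525.8 / 3.4) follow the estimates derived from paired-recording
charge measurements; elsewhere the defaults are 175.6 pA excitatory,
−702.4 pA inhibitory, 0.5 ms decay, with L4E→L2/3 Pyr at 245.84 pA.
Because the cell-type-specific inhibition carries much more charge than
the 0.5-ms default, every excitatory synapse onto a superficial pyramidal
cell uses a lengthened 2 ms decay (peaks unchanged); the within-L2/3
excitatory synapses onto interneurons likewise use their tabulated 2 ms.

Within layer 2/3, excitatory wiring is Bernoulli with merged-class
probabilities; inhibitory wiring is budgeted: the total I→E (and per-target
I→I) synapse counts implied by the merged-class probabilities are split
across source types by the reported connection-probability weighting
factors (PV:SST:VIP = 1:1:0.125 onto Pyr; 1:0.857 onto PV; 1:1 onto VIP
from SST and PV) multiplied by source population size, with
largest-remainder rounding so budgets are conserved exactly. VIP is the
sole inhibitory source of SST cells; its 0.625 weighting factor scales the
→SST budget directly, since proportional allocation over a single source
would make the factor inert. Budgeted synapses are drawn uniformly with
replacement (multapses allowed); Bernoulli rules are realized exactly
(binomial count, then distinct pairs; no autapses).

Interlaminar wiring, thalamic targeting (layers 4 and 6) and the
external-input protocol follow the published layered-microcircuit map of
the lineage this model descends from; those tables are config-overridable
defaults, not quantities this package estimates. The four merged-class
layer 2/3 probabilities are not printed anywhere in that lineage for this
variant; the package ships `p_ee = 0.1009`, `p_ie = 0.1689`,
`p_ii = 0.1371` from the base map and a calibrated `p_ei = 0.115`, chosen
once so that the spontaneous state reproduces the described regime — all
cell types able to fire, inhibitory cells more active than excitatory
ones, and the VIP/SST mutual-inhibition exclusivity with VIP dominant at
the default background rates. All four are `superficial_p` arguments to
the builders.

Thirteen columns are arranged on a ring (periodic boundary). Exactly four
connection families cross columns, all among superficial cells: Pyr→Pyr
(6.6%, nearest neighbours), PV→Pyr (4.6%, nearest neighbours), Pyr→PV
(0.9%, nearest neighbours) and Pyr→SST (0.2%, up to four columns each
way — the long-range pathway behind surround competition). Intercolumnar
synapses use intracolumnar parameters with 5× longer conduction delays
(7.5 ± 3.75 ms excitatory, 3.75 ± 1.88 ms inhibitory). Weights jitter as
sign-truncated Gaussians with SD equal to the tabulated ±; delays as
Gaussians floored at one time step.

## Inputs

Background: each population receives an aggregate Poisson barrage equal to
(number of external fibers) × (per-fiber rate), e.g. L2/3 Pyr
1600 × 8 Hz = 12,800 Hz, SST 1500 × 2 Hz = 3,000 Hz, with fiber peak
current 87.9 ± 8.8 pA. Thalamus: 902 relay cells per column project to
layers 4 and 6; during a stimulus window each relay cell fires Poisson at
its column's rate. The figure-ground, two-object and top-down protocols
use 400 ms onset and 100 ms duration; the single-column pulse protocol
uses a 10 ms wave. The pulse rate is not printed in the source material;
the package default is 100 Hz, i.e. about one spike per relay cell per
wave, a standard single-volley convention.

## Engine

The simulator is clock-driven (default `dt` 0.1 ms) with exact exponential
propagators for the membrane and every current channel, so subthreshold
integration is exact for piecewise-constant inputs and results are robust
to the step size. Spikes are detected at step boundaries, reset the
membrane, and clamp it for the refractory period while channels keep
integrating; deliveries go through a ring buffer with per-synapse integer
delays (floored at one step) and are applied at the arrival step, so a
PSC probe peaks at exactly the synaptic weight. Event payloads travel in
single precision. Ties are processed in ascending neuron index. All
randomness (background counts with amplitude jitter, thalamic volleys,
initial membrane potentials) is drawn from R's RNG, so a seed fixes the
realization bit-exactly. Initial potentials default to a truncated normal
spread between reset and threshold, which decorrelates the startup
transient; `v_init = "rest"` gives the deterministic cold start used by
the engine-verification tests.

## Downscaling

`scale` shrinks every population by a common linear factor while keeping
connection probabilities, background fiber counts and the 902 thalamic
cells per column unchanged, so synapse counts fall roughly with the square
of the scale. `compensate_weights = TRUE` multiplies weights by
1/scale, preserving each neuron's expected in-degree × weight product; the
default is FALSE because weight compensation inflates synaptic
fluctuations (each PSP is 1/scale too large), which destabilizes the
delicately balanced superficial regime well before quarter scale. The
reference analyses in the test suite run the 13-column network at scale
0.25 and the single column at 0.25–1.0; the methods' problem sizes are the
package's choices for desk-scale reproduction, and the full-size network
remains the reference configuration.

What downscaled runs do and do not show: the feedforward pathway
(thalamus → L4 → L2/3), the VIP/SST competition, the pulse-response
ordering (VIP earliest, then Pyr and PV, SST last) and the long-range
Pyr→SST surround effects (surface dominance and background suppression
under strengthened Pyr→SST) all survive quarter-scale. The short-range
PV-mediated boundary enhancement that makes *edge* columns dominate under
default connectivity is a small effect carried by a pathway that
downscaled networks barely recruit; its direction at quarter scale depends
on the particular wiring realization, and the full ≈2× surface-to-edge
ratio of the strengthened-Pyr→SST condition is correspondingly compressed
(≈1.2× at quarter scale). The trial-to-trial VIP/SST bistability seen in
small networks is a finite-size effect of the same competition that is
winner-stable at full size.

# Protocols and analysis

`make_pulse_experiment()`, `make_figure_ground()`, `make_two_object()` and
`make_topdown()` package the four stimulus designs with their timing,
per-column thalamic rates, sweep grids (e.g. Pyr→SST 0.2%→4%, a factor of
20) and named background variants (the pulse variants raise SST to 6 Hz or
move VIP to 2/14 Hz per fiber — package choices, since the source values
are figure-borne). `run_experiment()` builds once, precompiles the network
(`prepare_simulation()`), and runs trials whose seeds derive from the
master seed by a fixed counter scheme.

Analysis: `population_rate()` (spike count / neurons / window),
`column_rates()`, trial-averaged `psth()` (5 ms bins by default),
`edge_normalized_profile()` (per-trial division by that trial's mean edge
response — edge mean 1 by construction, zero-edge trials excluded and
counted — or pooled division by a supplied reference), `onset_latencies()`
(first bin above baseline mean + 3 SD sustained for 2 bins; the source
reports only an ordering, so the rule is the package's), and
`oscillation_frequency()` (smoothed periodogram peak, reported only when
it exceeds 3× the median smoothed power — white Poisson firing stays
below this).

# Known limitations

* Desk-scale networks compress contextual effect sizes and make the
  default-connectivity edge-versus-surface direction
  realization-dependent (above).
* Quarter-scale VIP cells run hot (≈110 Hz oscillatory baseline versus
  ≈78 Hz at full size), which makes their pulse-onset detection by the
  baseline + 3 SD rule marginal: the VIP response is plainly visible in
  the PSTH but may cross the threshold in only one bin, failing the
  two-bin persistence requirement at some seeds.
* Steady-state enumeration is complete only relative to its multi-start
  design; the branch scans mitigate this with carried seeds.
* The rate model's limit-cycle detector uses a finite horizon; extremely
  slow oscillations would be missed.
* No synaptic plasticity, adaptation, conductance-based synapses or
  generalized-LIF variants; orientation tuning is outside scope — columns
  are abstract receptive fields driven by per-column rates.
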