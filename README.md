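# v1micro

Multi-column spiking and rate models of mouse primary visual cortex (V1)
with the three major inhibitory interneuron classes — parvalbumin (PV),
somatostatin (SST) and vasoactive-intestinal-peptide (VIP) cells.

The package is for computational neuroscientists studying contextual
visual processing: surround suppression, boundary (edge) enhancement,
figure-ground competition, and selective top-down gain control through
disinhibition. It provides two connected levels of description:

1. **A four-population firing-rate model** of the layer 2/3 microcircuit.
   Each population's rate follows
   `tau_m df_x/dt = -f_x + c sqrt(u_x - theta) H(u_x - theta)`, where the
   net drives `u_x` encode the cell-type-specific circuit (PV inhibits Pyr
   and itself; SST inhibits all others but receives none from PV or
   itself; VIP mainly inhibits SST). The package enumerates steady states
   over all active sets, classifies stability from the one-sided Jacobian,
   detects limit cycles, scans applied currents, and computes the
   SST-silencing and VIP-activation thresholds.
2. **A 13-column spiking network** of 19,294-neuron layered columns
   (layers 2/3, 4, 5, 6) of identical leaky integrate-and-fire neurons
   with multiple exponential postsynaptic-current channels, wired with
   cell-type-specific superficial connectivity (inhibitory synapse budgets
   split by connection-probability weighting factors), four intercolumnar
   connection families among superficial cells only (short-range Pyr→Pyr,
   PV→Pyr, Pyr→PV; long-range Pyr→SST), periodic boundary conditions, 5×
   intercolumnar conduction delays, Poisson background fibers and 902
   thalamic relay cells per column.

Stimulus protocols reproduce the standard experiment designs: a 10 ms
thalamic pulse (response-onset ordering across cell types), an 80/40 Hz
figure-ground layout with per-trial edge-normalized column profiles, a
two-object competition design, and a top-down modulation design with
factorial VIP/SST background grids.

## Worked example

```r
library(v1micro)

## rate model: all fixed points of the layer 2/3 microcircuit at defaults
p <- rate_model_params()
sts <- enumerate_steady_states(p)
for (s in sts) cat(sprintf("f = (%5.2f, %4.2f, %4.2f, %5.2f) Hz  active = {%s}  %s\n",
    s$rates[1], s$rates[2], s$rates[3], s$rates[4],
    paste(s$active_set, collapse = ","), s$stability))
cat("SST silencing threshold:", sst_silencing_threshold(p, step = 0.5), "pA\n")
cat("VIP activation threshold:", vip_activation_threshold(p), "pA\n")

## spiking network: structural census of one column
g <- build_column(seed = 1, realize = FALSE)
cat("single column neurons:", sum(g$pops$count), "\n")
```

prints

```
f = ( 0.00, 0.87, 0.00, 16.49) Hz  active = {p,v}  stable
f = ( 1.62, 1.24, 0.00, 17.08) Hz  active = {e,p,v}  unstable
f = (10.63, 3.01, 1.22, 18.87) Hz  active = {e,p,s,v}  stable
SST silencing threshold: 364.75 pA
VIP activation threshold: 360 pA
single column neurons: 19294
```

Two attractors coexist at the default drives: a pyramidal-silent PV/VIP
state and the fully active state with Pyr at ~10.6 Hz. Driving SST above
~365 pA removes every pyramidal-active attractor (SST silences the
circuit); VIP cells start firing once their drive exceeds the 360 pA gain
threshold, which is what makes VIP-mediated disinhibition switch-like.

A scaled-down spiking run (quarter-scale column, thalamic pulse):

```r
spec <- make_pulse_experiment()          # 10 ms wave at 400 ms
res  <- run_experiment(spec, seed = 21, scale = 0.25, trials = 12)
ps   <- lapply(c(VIP = "L23_VIP", Pyr = "L23_Pyr", PV = "L23_PV",
                 SST = "L23_SST"), function(x) psth(res$records, x))
onset_latencies(ps, baseline_window = c(100, 390), onset = 400)$latency
#> VIP Pyr  PV SST
#> 405 405 405 410
```

VIP cells respond first and SST cells last, the signature of the
disinhibitory circuit. A command-line front end is installed at
`inst/cli/v1micro` (`build-check`, `rate-scan`, `run`, `analyze`).

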