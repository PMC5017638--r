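# netstim

Simulation-based analysis of how focal stimulation controls brain network
dynamics. `netstim` couples Wilson-Cowan neural-mass oscillators through a
weighted structural connectome (with conduction delays and additive noise),
stimulates single regions with a constant current, and quantifies the
functional and structural consequences — then asks whether cheap *linear*
network-control diagnostics computed from the wiring alone predict those
nonlinear consequences. It is aimed at computational neuroscientists
studying stimulation targeting, structure-function coupling, and network
control theory.

## The model in brief

Each of N regions carries an excitatory/inhibitory pair

    tau dE_j/dt = -E_j + (S_e_max - E_j) S_e(c1 E_j - c2 I_j
                    + c5 sum_k A_jk E_k(t - tau_d_jk) + P_j(t)) + sigma w_j
    tau dI_j/dt = -I_j + (S_i_max - I_j) S_i(c3 E_j - c4 I_j) + sigma v_j

with sigmoid `S(x) = 1/(1+exp(-a(x-theta))) - 1/(1+exp(a*theta))` and the
classic limit-cycle constants (tau = 8 ms, c1..c4 = 16, 12, 15, 3). An
isolated unit rests at a low fixed point, oscillates (~20-25 Hz) under a
moderate constant current P = 1.25, and saturates at a high fixed point for
strong currents. On a network, the global coupling c5 is swept to find the
collective oscillatory transition; all stimulation experiments run at the
grid point just below it. Functional states are matrices of maximum lagged
cross-correlation (1 s window, ±250 ms lags) between excitatory traces.
Per-region stimulation is summarized by three statistics — functional
effect (mean |Δfc|), structural effect (change in corr(A, fc)), fractional
activation (fraction of pairs with |Δfc| above 0.6) — and compared against
average controllability Trace(W_i) (discrete Lyapunov Gramian of the
normalized adjacency) and modal controllability
`phi_i = sum_j (1 - lambda_j^2) v_ij^2`.

A synthetic-connectome generator (modular block structure with a dense
subcortical core, log-normal volume-normalized weights, spatially clustered
coordinates for delays) makes the full pipeline runnable and testable
without diffusion-imaging data.

## Worked example

```r
library(netstim)

## a synthetic 40-region connectome and its conduction delays
g <- generate_connectome(40, seed = 2)
delays <- compute_delays(as.matrix(g$regions[, c("x_mm", "y_mm", "z_mm")]))

## where does the network start to oscillate?
scan <- find_transition_point(g$network, delays, wc_params(), seed = 100)
scan$c5_transition
#> [1] 1.25
scan$c5_operating
#> [1] 1.2

## stimulate every region in turn at the operating point
camp <- stimulation_campaign(g$network, delays, wc_params(),
                             scan$c5_operating, seed = 200)
round(camp$correlations["functional_effect", "fractional_activation"], 3)
#> [1] 0.939
round(camp$correlations["avg_ctrl", "functional_effect"], 3)
#> [1] 0.309
round(camp$correlations["modal_ctrl", "functional_effect"], 3)
#> [1] -0.358
```

Reading these numbers: the coupled network jumps from its low fixed point
into collective oscillation at c5 = 1.25, so the campaign runs at 1.2,
where every region fluctuates near rest. Across the 40 stimulation
experiments, regions whose stimulation changes functional connectivity the
most are almost exactly the regions whose impact is global rather than
focal (Spearman rho = 0.94 between functional effect and fractional
activation), and the size of the functional effect rises with average
controllability (+0.31) and falls with modal controllability (-0.36) — the
linear predictions hold in the nonlinear model. `system_aggregate()`
further summarizes effects per cognitive system together with the
system-by-system connection density table.

A command-line wrapper with subcommands (`generate`, `simulate`,
`controllability`, `effects`, `sweep`, `campaign`, `icc`) is installed at
`inst/cli/netstim`; every run writes a YAML manifest (config hash, seeds,
version) for provenance. See the vignette
(`vignettes/network-stimulation.Rmd`) for the model assumptions, parameter
meanings, and numerical choices.

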