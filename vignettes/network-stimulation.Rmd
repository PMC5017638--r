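---
title: "Stimulation and control of Wilson-Cowan brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulation and control of Wilson-Cowan brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netstim)
```

## The question

Focal brain stimulation (TMS, tDCS, DBS) perturbs one region of a network
whose wiring is known only at the level of white-matter tracts. Which regions,
when stimulated, reconfigure activity across the whole brain, and which only
locally? Linear network control theory offers cheap predictions from the
structural matrix alone — average and modal controllability — but the brain is
nonlinear. `netstim` implements a complete in-silico test of those
predictions: it simulates networks of delay-coupled, noisy Wilson-Cowan
neural-mass oscillators on a weighted structural connectome, stimulates one
region at a time with a constant current, and measures how far and how broadly
the simulated functional state moves.

## The model

Each region j carries an excitatory/inhibitory firing-rate pair governed by

$$\tau \dot E_j = -E_j + (S^{max}_e - E_j)\,
  S_e\!\big(c_1 E_j - c_2 I_j + c_5 \textstyle\sum_k A_{jk} E_k(t - \tau^d_{jk})
  + P_j(t)\big) + \sigma w_j(t)$$
$$\tau \dot I_j = -I_j + (S^{max}_i - I_j)\, S_i\!\big(c_3 E_j - c_4 I_j\big)
  + \sigma v_j(t)$$

with the sigmoid $S(x) = 1/(1+e^{-a(x-\theta)}) - 1/(1+e^{a\theta})$, whose
offset makes $S(0)=0$ so the origin is a genuine rest state. Defaults
(`wc_params()`): $\tau = 8$ ms, $c_1\ldots c_4 = 16, 12, 15, 3$,
$a_e = 1.3$, $a_i = 2$, $\theta_e = 4$, $\theta_i = 3.7$, $\sigma = 10^{-5}$.
With these constants the isolated unit has three regimes as the constant
drive $P$ grows: a low fixed point ($P = 0$), a limit cycle (moderate $P$,
e.g. the stimulation amplitude 1.25 used throughout), and a high fixed point
(strong $P$, e.g. 2.5). `find_fixed_points()` locates and classifies the
equilibria by nullcline root-finding and the local Jacobian.

Regions couple through their excitatory populations via the weighted
adjacency matrix $A$ scaled by the global coupling $c_5$, with conduction
delays $\tau^d_{jk} = d_{jk} / v$ at $v = 10$ mm/ms. The external current
$P_j(t)$ is zero except for the stimulated region, which receives a constant
1.25 during the stimulation window — enough to push an isolated unit onto
its limit cycle.

Choices the equations above leave open, and what this package does:

* **Sigmoid ceilings.** $S^{max}$ is set to $\sup S = 1 - 1/(1+e^{a\theta})$,
  the refractory convention of the original mean-field derivation, keeping
  rates in $[0, S^{max})$. Both ceilings are arguments of `wc_params()`.
* **Integrator.** Fixed-step explicit Euler (default `dt_ms = 0.1`, enforced
  $\le \tau/10$ and $\le$ the smallest positive delay) with the stored
  trajectory doubling as the delay buffer; delays are quantized to integer
  steps with round-half-to-even; history before $t=0$ is the initial
  condition ($E = I = 0.1$ everywhere). A fixed step is deliberate: delays
  plus per-step noise rule out adaptive solvers, and it buys bit-for-bit
  reproducibility — the same seed gives the same trajectory, exactly. The
  unit suite verifies that halving `dt` moves fixed-point endpoints by less
  than $10^{-3}$. One consequence worth knowing: on the limit cycle the
  Euler discretization at 0.1 ms runs about 6% slower than the continuous
  system (23.5 Hz vs 25.0 Hz from an adaptive reference solver at
  tolerance $10^{-10}$).
* **Noise.** $w_j, v_j$ are standard-normal draws per region and per step,
  entering the right-hand side multiplied by $\sigma$ exactly as written
  above — i.e. *not* scaled by $\sqrt{dt}$. Read literally the equations
  describe per-step additive noise rather than an Itô SDE; we follow the
  literal reading by default and expose `noise = "sqrt_dt"` for the
  Euler-Maruyama interpretation. At $\sigma = 10^{-5}$ the distinction is
  immaterial for every statistic in this package (Pearson correlations are
  scale-free), but it matters if you raise $\sigma$.

## Synthetic connectomes

Empirical inputs would be volume-normalized streamline-count matrices from
deterministic tractography on an 83-region whole-brain parcellation.
`generate_connectome()` emulates them so the entire pipeline is testable
without imaging data:

* **Block structure.** Regions belong to four coarse cognitive systems —
  sensory/association (34 of 83), higher-order cognitive (22), medial
  default mode (12), subcortical (15). Edges appear independently per pair
  with probability given by the system-pair density profile; the default
  profile uses the empirical block densities of human connectomes grouped
  this way (subcortical within-density 0.412, default mode 0.257, all other
  blocks 0.025-0.137), so the subcortical core is densest, the default mode
  next.
* **Weights.** Nonzero streamline counts are log-normal (meanlog 0, sdlog
  0.75), divided by the summed endpoint volumes (volumes themselves
  log-normal), exactly as `volume_normalize()` does for empirical counts.
  The sdlog default is a deliberate middle ground mapped out during design:
  at sdlog 1 the strongest hubs receive so much recurrent drive during
  stimulation that they saturate at the high fixed point instead of
  oscillating, while at sdlog 0.5 the network is so homogeneous that its
  near-critical baseline fluctuations become globally correlated and the
  activation statistics lose their dynamic range. Both extremes break
  phenomena the generator exists to emulate.
* **Overall scale.** The matrix is rescaled so its mean weighted degree
  equals `weight_scale` (default 6). This pins the operating regime of the
  coupled model: with the default, the oscillatory transition of 83-region
  networks falls inside the standard coupling sweep window
  $c_5 \in [1.0, 1.5]$ across seeds (we verified seeds 1-8), mirroring the
  between-subject spread reported for empirical connectomes. Spectral-radius
  pinning was tried first and rejected: the leading eigenvector of
  heavy-tailed networks localizes on hubs, so equal spectral radius does not
  give equal collective behaviour.
* **Geometry.** Each system is a Gaussian spatial cluster (SD 16 mm) inside
  a 140 mm box, clipped to its central 80% with a 6 mm minimum inter-region
  distance, so pairwise conduction delays at 10 mm/ms stay within the
  physiological 0.5-20 ms band.

What the generator does **not** emulate: spatial distance-dependence of
connection probability, hemispheric symmetry, the exact empirical degree
sequence, or any subject-specific features. Tests passing on these networks
show the *machinery* behaves as the theory predicts on data with realistic
block structure and heavy tails; they are not evidence about any particular
empirical connectome.

## The experiments

**Transition sweep** (`find_transition_point()`). For each $c_5$ on the grid
1.0 to 1.5 (step 0.05), a 2 s unstimulated simulation is run (first 1 s
discarded) and each region's mean excitatory rate is recorded. Visually the
transition is obvious — a sudden network-wide jump in firing — but to be
testable it needs a rule: we flag the first grid point whose across-region
median mean rate exceeds 3 times the previous point's *and* where more than
half the regions sit above a 0.05 rate floor. The conjunction matters: near
the fixed point the median is at noise scale ($\sim 10^{-5}$), so ratios
alone misfire, and hub subnetworks can ignite alone without carrying the
majority. Both knobs (`jump_factor`, `rate_floor`) are exposed. The
operating point for all stimulation work is the grid value immediately
before the transition — the network rests near its low fixed point but is
maximally responsive.

**Stimulation campaign** (`stimulation_campaign()`). Per target region: 1 s
stabilization (discarded), 1 s pre-stimulation window, 1 s stimulation
window with $P_{target} = 1.25$. Functional states are matrices of the
maximum lagged cross-correlation (1 s window, $\pm 250$ ms lag) between
excitatory traces; each lag's value is an exact Pearson correlation over the
overlapping samples (FFT cross-products plus cumulative-sum normalization).
The maximum is over *signed* correlations — excitatorily coupled oscillators
synchronize positively, and taking magnitudes would fold genuine
anticorrelation into apparent coupling; `use_abs = TRUE` is available. Three
statistics summarize each stimulation:

* functional effect — mean $|\Delta fc|$ over unordered region pairs;
* structural effect — $\mathrm{corr2}(A, fc_{during}) -
  \mathrm{corr2}(A, fc_{before})$, where `corr2()` correlates
  upper-triangle off-diagonal entries (the diagonal is structurally 0 in
  $A$ and 1 in $fc$, so including it — the full-matrix convention of some
  toolboxes — only injects a constant contrast; a flag restores it);
* fractional activation — fraction of pairs with $|\Delta fc| > 0.6$
  (thresholds 0.2/0.4 give qualitatively comparable results; the statistic
  is provably non-increasing in the threshold, and mean $|\Delta fc|$ is
  bounded below by threshold × fraction).

Traces frozen at a fixed point (possible only at $\sigma = 0$) would make
correlations undefined; such rows are flagged and their fc entries set to 0
rather than letting NaN poison the averages. A lag maximum attained on the
boundary of the lag range is flagged as a possible window artifact.

**Reproducibility** (`icc()`). For subjects-by-scans tables of the
transition point, a balanced two-way ANOVA yields mean squares between
subjects (RMS), between scans (SMS), and error (EMS), combined into
between- and within-subject intraclass correlations
$ICC_B = J(SMS-EMS)/D$ and $ICC_W = I(RMS-EMS)/D$ with
$D = J\,SMS + I\,RMS + (IJ-I-J)\,EMS$. High $ICC_W$ means scans of one
subject agree while subjects differ; on synthetic tables with known variance
components the $ICC_W$ estimator recovers the generating intraclass
correlation $\sigma_b^2/(\sigma_b^2+\sigma_e^2)$ (verified by Monte Carlo in
the test suite). Identical values everywhere make the ratio 0/0; the report
is then flagged `degenerate` rather than guessed.

**Controllability** (`controllability_profile()`). The linear surrogate is
$x(t+1) = A_{norm}\, x(t) + B u(t)$ with $A_{norm} = A / (1 + \lambda_{max})$
— the divisor guarantees Schur stability and hence a convergent Gramian; the
offset is configurable. Average controllability of region i is
$\mathrm{Trace}(W_i)$, with $W_i$ the infinite-horizon Gramian for a single
input at i, obtained from the exact discrete Lyapunov solve (for symmetric
$A_{norm}$ via its eigendecomposition; the truncated series survives as a
test oracle). Modal controllability is
$\phi_i = \sum_j (1-\lambda_j^2)\, v_{ij}^2$ over the eigenpairs of
$A_{norm}$; non-symmetric input is rejected rather than silently handled
with a Schur form, since undirected connectomes are always symmetric. The
steady-state response to constant input at one region is
$(I - A_{norm})^{-1} e_i u$. All eigenvalues in the modal formula are taken
from the *stabilized* matrix, consistent with the dynamics the Gramian uses.

## A worked run, scaled down

The problem sizes below are the package's reference configuration for a
single-machine run: an 83-region network for the sweep, a 40-region network
for the full per-region campaign.

```{r sweep, eval = FALSE}
g <- generate_connectome(83, seed = 1)
delays <- compute_delays(as.matrix(g$regions[, c("x_mm", "y_mm", "z_mm")]))
scan <- find_transition_point(g$network, delays, wc_params(), seed = 11)
scan$c5_transition   # 1.15 for this seed: inside [1.0, 1.5]
scan$c5_operating    # 1.10, the grid point just before

g40 <- generate_connectome(40, seed = 2)
d40 <- compute_delays(as.matrix(g40$regions[, c("x_mm", "y_mm", "z_mm")]))
scan40 <- find_transition_point(g40$network, d40, wc_params(), seed = 100)
camp <- stimulation_campaign(g40$network, d40, wc_params(),
                             scan40$c5_operating, seed = 200)
camp$correlations
```

On this configuration the campaign reproduces the sign structure the linear
theory predicts: functional effect correlates positively with average
controllability and negatively with modal controllability, and functional
effect and fractional activation are almost perfectly rank-coupled
(Spearman $\rho > 0.9$) — large state changes are global, small ones focal.
The numeric values are computed, not quoted; run the chunk (about eight
minutes) or `tests/testthat/test-acceptance.R` to regenerate them.

## Numerical notes and limitations

* Determinism is end-to-end: generator, integrator and campaign consume
  explicit seeds, route all randomness through R's RNG, and restore the
  caller's RNG state. Sweep grid point k uses seed `seed + k - 1`; campaign
  target r uses seed `seed + r`.
* The Euler frequency bias mentioned above means spectral quantities carry
  an O(dt) distortion; halve `dt_ms` if a few percent matters and spend the
  2x compute.
* Near the operating point the network is by construction close to
  criticality, so 1 s functional-connectivity windows have few effective
  degrees of freedom and a nonzero window-to-window noise floor; the
  zero-amplitude control campaign in the test suite quantifies it.
* Stimulating the very strongest hubs can saturate them at the high fixed
  point (their recurrent input exceeds the limit-cycle window). This is a
  property of the model, not a bug; it caps the functional effect of
  extreme hubs and is visible in campaign outcomes as a bend at the top of
  the controllability-effect curve.
* Runtime scales as $N^2 \times$ steps for simulation and
  $N^2 T \log T$ for functional connectivity; an 83-region campaign over
  all regions takes roughly 10-12 minutes on one core.
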