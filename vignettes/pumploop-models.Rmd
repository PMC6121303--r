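---
title: "Models of Na/K-ATPase pumping and signaling in pumploop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of Na/K-ATPase pumping and signaling in pumploop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pumploop)
```

The Na/K-ATPase is both an ion pump and a signaling scaffold. Its transport
function cycles through the Post-Albers conformations
E1 &rarr; E1P &rarr; E2P &rarr; E2 &rarr; E1, while its signaling function
rests on a scaffold interaction in which the E1 conformation tonically
inhibits an associated Src kinase and the E2 conformation does not. Shifting
pumps toward E2 — by cardiotonic steroids such as ouabain, or by oxidants —
releases Src, transactivates the EGFR cascade, generates reactive oxygen
species (ROS), and ROS in turn push more pumps toward E2 and stimulate pump
endocytosis: a feed-forward oxidant amplification loop. `pumploop`
implements this picture at three levels of description, each usable on its
own and all sharing the same state vocabulary.

## 1. The conformational cycle as a Markov chain

A single pump is modelled as a discrete-time Markov chain over the
Post-Albers states: conformational switches over a short interval
$\Delta t$ depend only on the current conformation, giving a one-step
row-stochastic matrix $P = (p_{ij})$ with
$p_{ij} = \Pr(X_{n+1} = j \mid X_n = i)$. The long-run behaviour is the
stationary distribution $\pi$ solving $\pi P = \pi$, $\sum_j \pi_j = 1$ —
the "superposition of conformations" a pump represents at equilibrium.

`stationary_distribution()` solves this by power iteration, mirroring the
repeated one-step evolution whose limit defines $\pi$. Numerical choices:

* Iteration runs on the damped matrix $(P + I)/2$, which has the same
  stationary set as $P$ but is always aperiodic, so strictly periodic
  chains (e.g. the deterministic Post-Albers rotation) converge as well.
  The convergence criterion $\lVert \pi P - \pi\rVert_\infty <$ `tol`
  (default $10^{-10}$, `max_iter` $10^6$) is always evaluated on the
  undamped $P$.
* Uniqueness is checked structurally first: the positive-entry graph must
  have exactly one closed communicating class (strong components via
  igraph); otherwise the chain has no unique stationary law and the solver
  refuses rather than silently returning one of many.
* The test suite cross-checks power iteration against an independent exact
  linear solve of the augmented system $(\pi(P - I) = 0,\ \sum\pi = 1)$ to
  $10^{-10}$ on batches of random strictly positive matrices.

No published per-step probabilities exist for an arbitrary $\Delta t$, so
`default_post_albers_matrix()` is an explicitly illustrative strongly
cyclic matrix (0.75–0.80 forward probability per step, small dwell and
reverse probabilities); $\Delta t$ is carried as metadata in arbitrary
units and never mapped to seconds.

Hidden sub-states (for instance conformations bound to different numbers
of Na or K ions) are supported structurally by `expand_hidden_states()`:
an edge $i \to j$ with probability $p$ is rerouted through a new hidden
state with an optional geometric dwell, conserving the total path
probability $p$. Because the visible-state process watched at its own
visits is unchanged by such an insertion, the renormalised visible
stationary occupancy equals the original $\pi$ — a property the tests
verify exactly. No biological parameterisation of hidden states is
asserted.

## 2. The kinetic cycle as a master equation

Replacing step probabilities with transition rates $k_i^+$ ($i \to i+1$)
and $k_i^-$ ($i+1 \to i$) on the closed unicycle gives the master equation
$$\frac{dp_i}{dt} = \sum_{j \ne i}\left[k_{j\to i}\,p_j - k_{i \to j}\,p_i\right].$$
`integrate_master()` evolves it with `deSolve` (lsoda, rtol $10^{-10}$);
rate schedules may be functions of time.

Because the pump is driven (ATP hydrolysis), its steady state is a
*nonequilibrium* steady state with a nonzero cycle flux. `ness_flux()`
computes $J^{\mathrm{NESS}}$ as the net probability current
$\pi_i k_i^+ - \pi_{i+1} k_i^-$ at the exact stationary density of the
generator (null-space solve via QR). On a unicycle this current is the
same on every edge at stationarity; the implementation computes it on all
edges and verifies their agreement to $10^{-10}$ rather than trusting a
single edge. We deliberately compute the flux from the stationary density
instead of a closed-form spanning-diagram ratio: the closed form is easy
to mistranscribe for general $n$, whereas the current at the exact
$\pi$ *is* the defining quantity. The tests pin the implementation to the
unambiguous closed form on the symmetric driven 3-cycle,
$k^+ = (2,2,2)$, $k^- = (1,1,1)$: uniform $\pi$, $J = (2-1)/3 = 1/3$.

The dissipation of the cycling pump is
$$e_p = J^{\mathrm{NESS}} \,\ln\!\frac{\prod_i k_i^+}{\prod_i k_i^-},$$
implemented dimensionless (natural-log affinity times flux; no $k_BT$
factor is applied because no physical unit system is defined for the
rates). $e_p \ge 0$ always, with equality exactly at detailed balance
($\prod k^+ = \prod k^-$) — property-tested over a thousand random rate
sets. A subtlety the suite documents: swapping $k^+$ and $k^-$ always
flips the sign of $J$, but preserves its magnitude exactly only on
2-cycles; for longer cycles the spanning-diagram denominator is not
swap-invariant. $e_p$ itself is swap-invariant whenever the flux magnitude
is. Only the forward map rates $\to e_p$ is provided; estimating rate
constants from a measured $e_p$ is out of scope.

## 3. Signaling vs. pumping pools as superposed plane waves

A deliberately simple complex-plane picture: the pump population is split
into a caveolar "signaling" pool (slow conformational cycling, complexed
with caveolin-1 and Src) and a "pumping" pool, separated both spatially
and in frequency. Each pool is a plane wave
$A\,e^{i(2\pi f t + \phi)}$ on its own spatial domain, the domains laid
end-to-end; the real part stands for the E1&harr;E2 transition coordinate
and the imaginary part for phosphorylation. Defaults: signaling pool over
250 arb units at 150&nbsp;Hz, pumping pool over 500 arb units at
500&nbsp;Hz.

The readout is the Fourier power spectrum along time
(`power_spectrum()`), with per-position periodograms
$|F_k|^2/N^2$ averaged over space. Numerical choices, made once:

* Time grid: 1 s sampled at 4096 Hz. This is Nyquist-safe for the 500 Hz
  pool and gives a 1 Hz bin width, so the configured pool frequencies fall
  exactly on bins. `build_field()` refuses sub-Nyquist sampling and names
  the required rate.
* No window function (rectangular): the fields are deterministic tones,
  and leakage control would only blur the peaks the model is about.
* Averaging periodograms over space (rather than averaging fields first)
  keeps the spectrum linear in disjoint-domain pool contributions and
  preserves Parseval's identity — summed spectral power equals the
  spatially averaged time-domain mean square — which the tests assert to
  $10^{-8}$ relative on every generated field.
* Spatial resolution defaults to 1 arb unit; positions within one pool are
  identical copies of its tone, so tests often use coarser `dx` with no
  loss.

Ouabain binding stabilises E2 and removes part of the E1 (Src-inhibiting)
contribution of the signaling pool. A shift of the E2:E1 balance by a
fraction $s$ is realised as amplitude scaling of the signaling pool by
$(1-s)$ — with the consequence that its spectral peak height falls
monotonically in $s$ while the pumping peak is untouched, which is exactly
the observable the model is meant to produce. Alternative realisations
(frequency or phase shifts) were rejected because the phenomenon being
modelled is a diminished signaling peak at an unchanged pumping peak.
One documentation note: descriptions of the shifted spectrum sometimes
place the smaller peak near 180 Hz rather than the 150 Hz used for the
unshifted configuration; the package keeps the signaling pool at 150 Hz
in both scenarios and does not guess at an intent behind the discrepancy.
The wave picture is a visualisation device, not a physical quantum claim.

## 4. The oxidant amplification loop

The ODE module couples six states: plasma pumps in E1 ($N_{E1}$) and E2
($N_{E2}$), endocytosed pumps ($N_{endo}$), phosphorylated Src
($Src_p$), ROS, and a cumulative aging signal. The built-in assumptions:

1. pumps are synthesised at a basal rate (`synth_rate`, into E1);
2. ROS shift pumps toward E2, as do cardiotonic steroids
   (`g_ros_shift`, `g_cts_shift`);
3. there is a basal ROS source (`rho_basal`);
4. phosphorylated Src drives ROS production (`g_src_ros`, lumping the
   Src&rarr;EGFR&rarr;ROS cascade into one gain);
5. ROS detoxification is first order (`delta_ros`);
6. ROS stimulate pump endocytosis (`g_endo`, per plasma pump);
7. phosphorylated Src decays first order (`delta_srcp`).

Ouabain enters through instantaneous-equilibrium hyperbolic receptor
occupancy $c/(c + \mathrm{IC}_{50})$ (Hill 1, `IC50_ouabain` = 1000 µM, so
the standard 100 µM challenge is 1/11 occupancy &asymp; 10% of the IC50),
feeding an additive E1&rarr;E2 rate term; no slow-binding kinetics are
modelled. Design choices where the formulation was genuinely open:

* **Src sensing.** The activatable fraction of the controlled Src pool is
  $1 - N_{E1}/(N_{E1}+N_{E2}+N_{endo})$: only E1 pumps inhibit, and
  endocytosed pumps count as fully dis-inhibiting. The plasma-only
  denominator $N_{E1}/(N_{E1}+N_{E2})$ is available as
  `src_sensing = "plasma"`, but it cannot express dis-inhibition by
  endocytosis (proportional internalisation leaves the plasma E1 fraction
  unchanged), so the total-pool form is the default.
* **ROS action on the conformational balance** is additive in the rate
  (`ros_shift_mode = "additive"`); a multiplicative variant is exposed as
  a switch without any claim about which is mechanistically right.
* **Endocytosis** draws proportionally from E1 and E2 plasma pools by
  default (`endo_from = "E2_only"` available for sensitivity analysis);
  endocytosed pumps degrade first order and do not recycle.
* **Aging** is a pure accumulator
  $dAge/dt = a_{ros}(ROS + 1000 \cdot \text{endocytic flux})$, the
  endocytic flux weighted `endo_aging_factor` = 1000 relative to free ROS,
  with no feedback from Age onto the other states.
* About half of cellular Src is under pump control
  (`frac_src_controlled` = 0.5) and the nominal surface density is
  $2\times10^6$ pumps per cell, in line with cultured renal epithelial
  cells. ROS and Src units are arbitrary; time is in arbitrary simulation
  "ticks" with the perturbation conventionally at $t = 2500$.

### Calibration

Quantitative rate constants for this loop are not available; the model is
anchored instead to two requirements — roughly half of plasma pumps in E1
at rest, and a basal state that is stationary well before the perturbation
time. `calibrate_basal()` therefore frees one parameter (by default
$k_{21}$, the E2&rarr;E1 rate) and root-finds it against the *exact*
algebraic fixed point of the loop: given ROS the pump subsystem is linear
and solved in closed form, and a damped iteration on the scalar ROS
balance converges to the joint fixed point (`basal_fixed_point()`,
tolerance $10^{-12}$). The result is then verified by direct simulation to
$t = 2500$: the relative residual of the derivatives must be below
$10^{-6}$ and the achieved E1 fraction within 0.01 of target. The whole
procedure is deterministic and takes well under a second. All shipped
defaults should be read as calibrated illustrative values, not measured
constants.

### Integration and diagnostics

`simulate_loop()` integrates with lsoda at rtol $10^{-8}$, splitting the
time axis at perturbation onsets so step inputs are handled without
solver-discontinuity artefacts; an auxiliary cumulative-degradation state
makes the pump mass balance
$N_{E1}+N_{E2}+N_{endo}+\text{degraded} - \text{synthesised}$ checkable at
every output sample (the tests do, at $10^{-5}$ relative). Runaway ROS
(supercritical gain) is flagged on the result rather than raised, since a
diverging loop is a legitimate model outcome. The loop's stability
boundary is made concrete by `leading_eigenvalue()`: scaling the two
feed-forward gains $g_{src\to ros}$ and $g_{ros\to shift}$ by a common
factor moves the leading eigenvalue of the Jacobian at the basal state
from negative to positive; with the calibrated defaults the sign change
lies inside the documented bracket [1, 50], and the default operating
point sits below it.

```{r fig6, fig.width = 7, fig.height = 4}
params <- calibrate_basal(loop_params())
traj <- simulate_loop(params, perturbation("ouabain", 2500, 100), t_max = 5000)
glance(traj)
autoplot(traj)
```

The ouabain challenge reproduces the qualitative panel of responses the
loop was built to express: the E1 fraction drops from 0.5, ROS and
phosphorylated Src rise, plasma pumps are lost to endocytosis, and the
aging slope increases. Identifiability at desk scale is smoke-tested by
refitting $(g_{src\to ros}, \delta_{ros})$ to a synthetic trajectory with
`fit_loop_params()` (Nelder–Mead on the log scale), which recovers the
generating values to well under 5%.

## What the simulations do and do not show

Every input here is generated by the package itself — transition
matrices, rate sets, pool geometries and loop parameters are model
specifications, not data. Passing tests therefore demonstrate internal
consistency (conservation laws, oracle agreement, directional responses,
identifiability) under the stated study conditions; they do not validate
the biological assumptions. In particular: conformational independence
between neighbouring pumps is an idealisation; the Src&rarr;ROS cascade is
lumped into a single gain; Na/K gradient dynamics are deliberately
excluded; ROS, Src and aging axes are in arbitrary units, so only
directions and fold-changes — not absolute magnitudes — are meaningful;
and the wave-pool picture is an illustrative superposition, not a physical
wave function.

## Problem sizes

The shipped scenarios and tests run at the scales the models were designed
around: 2–8 state chains ($10^5$-step sample paths for occupancy checks),
1 s × 4096 Hz × 750-position wave fields, loop trajectories of 5000 ticks
at unit output resolution, 100-matrix and 1000-rate-set property batches.
The full suite completes in well under a minute on a single CPU.
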