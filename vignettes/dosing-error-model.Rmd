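---
title: "Predicting dosing-error boluses in multi-infusion set-ups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting dosing-error boluses in multi-infusion set-ups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multinfusion)
```

## The problem

In critical care, several syringe pumps commonly feed one lumen of a thin
catheter. Three physical mechanisms then make the dose actually entering the
blood stream deviate, transiently, from the set rates:

1. **Dead-volume (push-out) memory.** The catheter lumen between the mixing
   point M and the tip P holds the *old* mixture. When one pump's rate
   changes, that old mixture is expelled at the *new* total rate, so the
   delivery of a drug whose own pump was never touched changes temporarily.
2. **Syringe compliance.** The rubber plunger makes each syringe an elastic
   reservoir (compliance $C$, ml/Pa). A rate change alters the pressure in
   the whole network, and every syringe charges or discharges stored volume
   through the lines — the "capacitor" of the electric analog.
3. **Poiseuille mixing.** Flow in the catheter is laminar; the centerline
   moves at twice the average speed, so an entering slab of fluid is
   stretched into paraboloid sheets. The dosing error arrives *earlier*
   (at half the plug-flow delay) and is smeared out in time.

`multinfusion` implements all three in one analytic chain — RC-network
transients, a voxel (plug-flow FIFO) model of the catheter contents, and a
discrete convolution for the laminar smearing — and verifies the chain
against an independent brute-force streamline simulator.

## The RC network

Each channel is a flow source in parallel with its syringe compliance
$C_i$, feeding through line resistance $R_i$ into the mixing point, from
which the catheter resistance $R_{cath}$ leads to the (zero-reference)
venous pressure. For two pumps, with the "green" pump stepped down by
$u_{down}$ at $t = 0$ and the "red" pump untouched, the excess red flow
into the catheter is the two-exponential

$$u^{diff}(t) = \frac{u_{down}\,R_{cath}C_2}{\sqrt{b^2-4ac}}
  \left(e^{-t/\vartheta_{2}} - e^{-t/\vartheta_{1}}\right),\qquad
  \vartheta_{1,2} = \tfrac{1}{2}\left(b \mp \sqrt{b^2-4ac}\right)$$

with $a = R_{cath}R_1 + R_{cath}R_2 + R_1R_2$,
$b = C_1(R_{cath}+R_1) + C_2(R_{cath}+R_2)$, $c = C_1C_2$. Its integral —
the excess volume delivered — is simply $Q = C_2 R_{cath} u_{down}$,
independent of the line resistances. Sign convention: `downstep` is stored
as the positive magnitude of a rate *decrease*, and a decrease produces a
*positive* red excess (the red syringe discharges as the network pressure
falls); the state-space simulator fixes this orientation.

```{r}
setup <- standard_setup()
ud <- to_internal(6, "ml/h")
uf <- to_internal(6.5, "ml/h")
tf <- transient_flow(setup, ud)
c(theta_first = tf$theta_first, theta_second = tf$theta_second)
dosing_error_volume(setup, ud)
```

For arbitrary channel counts, schedules and clamps,
`state_space_simulate()` integrates the same network as a linear ODE with
one pressure state per compliance (`deSolve::lsoda`, restarted at every
breakpoint), plus one exactly-integrated state for the cumulative excess
volume. The two-pump closed form and the ODE agree to better than $10^{-6}$
relative; this dual route is a test invariant, not an implementation detail.

## Catheter memory and the entry sequence

The lumen is divided into $N$ voxels of length $\gamma = L/N$; contents are
advected toward the tip by the cumulative displacement
$\lambda(t) = (L/V_{cath})\int_0^t u_{cath}$. The delay time solves
$\int_0^{t_{delay}} u_{cath} = V_{cath}$ — slightly *less* than
$V_{cath}/u_{final}$ after a downstep, because the compliance discharge
transiently raises the total flow. The deviation fraction entering at M,
$a^{diff}(t) = u^{diff}(t)/u_{cath}(t)$, is resampled onto the entry-voxel
index $j$ via $\lambda(t_j) = j\gamma$; its zeroth sum times
$\gamma V_{cath}/L$ recovers $Q$ (this anchors the normalisation of all
discrete moments).

### Two displacement conventions

The closed-form moment expressions for the central time and width of the
bolus are derived under a *stabilized* displacement: $\lambda$ built from
$u_{final}$ plus the monitored channel's own deviation only. The physically
transported displacement also contains the *other* syringe's discharge,
which shifts the true bolus later by tens of seconds under the reference
parameters. `entry_sequence()` exposes both:
`lambda_convention = "stabilized"` reproduces the closed forms (they agree
within 1% at the reference parameters and exactly as $R \to 0$), while
`"actual"` (the default, used by `assemble_trace()`) is what the
independent streamline oracle validates. This distinction is a genuine
approximation of the closed forms, not a numerical artefact, and users
comparing against bedside measurements should prefer the `"actual"` chain.

## Poiseuille mixing

An entering slab is stretched two-fold (centerline speed $2\times$ mean),
so the entry sequence is stretched to $b_{2j} = a^{diff}_j$, and the tip
voxel mixes contributions of earlier slabs with geometric weights

$$w_i = \frac{\gamma L}{(\gamma i + L)^2},$$

whose cumulative sum $x/(L+x)$ is exactly the volume-averaged tip
concentration of the parabolic profile. The tip composition is the discrete
convolution $\psi_k = \sum_j b_{k-j} w_j$ plus a *remnant* term
$\propto L/(L+\gamma k)$ for old-mixture fluid retained near the wall.

Index bookkeeping, fixed here once: the convolution index $k$ lives on a
grid with **half** the entry spacing ($\Delta\tau/2 =
\gamma V_{cath}/(2 L u_{final})$ per index), counted from the first-arrival
time. This is the unique choice under which (i) the cumulative kernel
matches the parabolic-profile kinematics, (ii) the zero-order-hold stretch
(odd indices copy the even neighbour) conserves bolus volume exactly
($\sum\psi \cdot \gamma V_{cath}/2L = Q\sum w$), and (iii) the time-domain
trace agrees with the streamline simulator. In the assembled trace the exit
index advances with the actual displacement, $\gamma k = 2\lambda(t) - L$;
the first arrival is the $\lambda = L/2$ crossing, which equals
$t_{delay}/2$ exactly only for constant flow.

Moments of $\psi$ are computed two ways — brute-force index sums over the
convolution, and the Z-domain product rule for
$\Psi(z) = A^{diff}(z^2)W(z)$ evaluated as derivative limits at
$z \to 1$ — which agree to rounding error; another dual-route invariant.

### Truncation

The kernel tail decays only as $1/i^2$ and its first moment grows
logarithmically, so all semi-infinite sums are truncated at the horizon
$T_{max} = \max(10\,\vartheta_2,\; 3 V_{cath}/u_{final})$, chosen so the
two-exponential transient has decayed below $e^{-10}$ and the dead volume
has turned over three times; the corresponding kernel index and covered
kernel mass are reported in the metrics metadata. A consequence worth
knowing: at the horizon the composed trace still carries a few percent of
its peak (the algebraic remnant and kernel tails); only the plug-flow bolus
decays exponentially. Width estimates of the Poiseuille bolus are therefore
*truncation-qualified* quantities; the closed-form `sigma_closed(...,
with_poiseuille = TRUE)` is a compact expression whose dead-volume
term is exact only in the documented limits (its limiting values
$2CR_{cath}$, $4CR_{cath}$ and $V_{cath}/u_{final}$ are all reproduced to
$10^{-3}$ by `limit_checks()`).

## Bolus metrics

A bolus is summarized by volume $Q$, central time $t_{central}$ and width
parameter $\sigma$ (first and second moments; the clinically reported
duration is $2\sigma$), with times in the $\tau$ frame measured from the
delay reference. Closed forms for the symmetric case
($C_1 = C_2$, $R_1 = R_2$, $R \ll R_{cath}$):

```{r}
c(Q = dosing_error_volume(setup, ud),
  t_central = t_central_closed(setup, ud, uf),
  sigma = sigma_closed(setup, ud, uf),
  sigma_pois = sigma_closed(setup, ud, uf, with_poiseuille = TRUE))
```

The general asymmetric width is served by `discrete_moments()` only — the
general closed expression is unwieldy and adds nothing over the discrete
route, which is exact up to resampling.

## The streamline oracle

`oracle_simulate()` shares nothing with the analytic chain beyond the ODE
flow: it divides the cross-section into equal-volume annular shells (shell
midpoints in $r^2$, so the velocity factors $2(1-(r/R)^2)$ average to one
exactly), advects each shell as a plug flow at its own speed, and assembles
the tip outflow per shell. It reports both the *flow-weighted* outflow
concentration (the transported quantity, used for the per-fluid
conservation check, which holds to $<10^{-6}$ ml) and the *volume-averaged*
tip concentration (what the analytic tip model predicts). The advected
deviation fraction (`beta_dev`) is the direct counterpart of the
convolution term: comparison on the reference scenario agrees to about
$10^{-4}$ on $Q$, $t_{central}$ and $\sigma$; a flux-minus-set-rate
comparison would instead differ by $u_R E_\infty/u_{final}$ (the elastic
excess volume $E_\infty \approx 0.21$ ml here), an inherent feature of the
stabilized-flow branch split of the composed trace, not a defect of either
side.

```{r}
trace <- assemble_trace(setup)
oracle <- oracle_simulate(setup)
compare_with_oracle(trace, oracle)
```

## Scenario composition and its limits

`assemble_trace()` composes: zero before the event; the constant push-out
deviation $u_R (u^G_{final}-u^G_{old})/(u^G_{old}+u_R)$ until the first
arrival; then the tip bolus $\psi \cdot (u^G_{final}+u_R)$. Only
single-step events are composed analytically — the closed chain assumes the
flow has stabilized by the first arrival, so overlapping events within one
delay time are refused and routed to the simulators, whose superposition
needs no such assumption.

The syringe-exchange model (`syringe_exchange_error()`) treats the clamped
green line as an open circuit; the red error is the pump term
$u_R T_{exchange}$ (if left running) plus the compliance discharge, which
saturates at $C_2 R_{cath} u^G_{old}$.

## Reference parameters and defaults

| parameter | default | unit | role |
|---|---|---|---|
| $R_{cath}$ | 1145 | Pa/(ml/h) | catheter resistance |
| $R_1, R_2$ | 23 | Pa/(ml/h) | feeding-line resistances |
| $C_1, C_2$ | $1.5\times10^{-5}$ | ml/Pa | syringe compliances |
| $u^R_{pump}$ | 0.5 | ml/h | monitored (red) rate |
| $u^G_{old} \to u^G_{final}$ | 12 → 6 | ml/h | green step |
| $V_{cath}$ | 1.0 | ml | dead volume (scenario-dependent) |
| $L$ | 1.0 | — | catheter length (only ratios enter) |
| $N$ | $10^4$ | — | voxels |
| `n_shells` | 200 | — | oracle shells (equal volume) |

$V_{cath}$ and $L$ are not part of the standard parameter table; the
defaults above are packaged fixture values and freely overridable. Internal
units are s/ml/Pa; configuration files use the clinical units shown.
Problem sizes in the shipped tests ($N = 10^4$ voxels, $\sim 10^4$-point
flow grids, 200 shells, 100-draw property sweeps) were chosen so the full
verification chain resolves the fast time constant
($\vartheta_1 \approx 1.2$ s) by two orders of magnitude while a complete
run stays interactive.

## What the synthetic scenarios do and do not emulate

The fixture generator spans the documented parameter sweeps (catheter
resistance $\times\{1,2,3\}$, red compliance $\times\{0.52, 0.36\}$, the
two syringe-exchange variants) plus log-uniform draws over a factor ten
around the reference values. They emulate ideal piecewise-constant pump
schedules in a linear network. They do **not** emulate: non-return valves
or filters (nonlinear elements), viscosity contrasts, pump-height changes,
the entrance length over which the parabolic profile develops, radial
diffusion (true Taylor–Aris dispersion), multi-lumen catheters, or pump
mechanics (stick-slip, stepper ripple). Passing tests therefore demonstrate
the internal consistency and numerical fidelity of the model chain, not its
clinical accuracy for any particular hardware.

## Numerical choices

* ODE: `lsoda`, rtol $10^{-11}$, atol $10^{-13}$, restarted at every
  schedule breakpoint and clamp edge (the system is mildly stiff,
  $\vartheta_1/\vartheta_2 \approx 10^{-2}$).
* Delay and arrival times: exact piecewise-quadratic inversion of the
  trapezoidal cumulative volume (reduces to $V/u$ with no quadrature for
  constant flow).
* Voxel advection: conservative donor-cell shift (integer part plus
  fractional linear carry); per-fluid volume conservation is exact to
  rounding, at the price of some numerical smearing of sharp fronts.
* Convolutions: FFT, real part, zero-padded to the next power of two.
* Degenerate inputs: zero compliance or zero catheter resistance give an
  identically zero transfer; $R_1 = R_2 = 0$ collapses to a single
  exponential with $\vartheta_2 = 2CR_{cath}$; zero bolus mass makes the
  moment metrics refuse rather than return NaN.

## Known limitations

* The closed-form moments carry the stabilized-displacement approximation
  discussed above; expect $O(R/R_{cath})$ plus
  $O(E_\infty/V_{cath})$-scale deviations from the `"actual"` chain.
* The Poiseuille width depends on the truncation horizon through the
  kernel's slowly decaying tail; report it together with its truncation
  metadata.
* Analytic composition covers one setting change at a time; event
  sequences run through the simulators.
* The remnant term uses the monitored pump's set rate throughout (the two
  printed variants of its numerator coincide while that rate is constant,
  which is the only regime the composition covers).
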