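---
title: "Gauge-theoretic neural fields on the cortical sheet: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gauge-theoretic neural fields on the cortical sheet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexgauge)
```

## The model

`cortexgauge` simulates mesoscopic cortical activity as a complex neural
field $\phi(\mathbf{r}, t)$ on a two-dimensional sheet.  Each point of the
sheet carries one excitatory–inhibitory bi-layer; balanced excitation and
inhibition makes the local dynamics oscillatory, which is why a single
*complex* amplitude per point suffices.  Local connections act over a disc
of radius $R$ with gain $U$, and a long-wavelength expansion of the
connectivity integral turns the integro-differential field equation into a
Klein–Gordon (massive wave) equation

$$\partial_t^2\phi \;=\; -\,m^2c^4\,\phi + c^2\,\nabla^2\phi,
\qquad m^2c^4 = 1 - Ua - b\,\nabla^2 U,\quad c^2 = Ub,$$

where $a = \pi R^2$ and $b = \pi R^4/4$ are the zeroth and (half the)
second moment of the connection disc.  The "mass" sets the local
oscillation frequency of a disconnected column, the "speed of light" the
lateral propagation speed of activity waves — both inherited directly from
anatomy ($U$, $R$) rather than free parameters.

Three extensions of this core are implemented, each the subject of one
module:

* **U(1) gauge sector** (`gauge_potential`, `evolve_coupled`,
  `gauss_solve`, `hebbian_rate`): a spatio-temporal modulation
  $e^{i\theta}$ of the intrinsic connection is absorbed into a
  connectivity potential $A_\mu$ with coupling $\varepsilon$
  ($-\varepsilon A_\mu = \partial_\mu\theta$), giving gauge-covariant
  dynamics $g^{\mu\nu}D_\mu D_\nu \phi + m^2c^4\phi = 0$ with
  $D_\mu = \partial_\mu - i\varepsilon A_\mu$.  The conserved phase
  (Noether) current has temporal component $J_t = -|\phi|^2$ for a
  unit-frequency phasor, and the Gauss-law constraint
  $\nabla^2 A_t = -|\phi|^2$ identifies the rate of connection change with
  a (non-linear) Hebbian rule: activity sources connectivity the way
  charge sources an electrostatic potential.
* **Metric learning** (`stress_energy`, `evolve_expansion`,
  `learning_rate`, `delta_response_experiment`): slow change of
  *extrinsic* (lateral) connections is modelled as dynamics of the sheet
  metric in Robertson–Walker form with expansion factor $a(t)$, driven by
  the field's stress–energy through Friedmann-like equations
  $\dot a^2 = A a^2 - k$, $\ddot a = -B a$.  In the high-mass limit the
  expansion rate reduces to $\dot a \approx \pm m|\phi|$ — Hebbian growth
  proportional to activity amplitude.
* **SU(2) multilayer sector** (`su2_generators`, `gain_rates`,
  `generalized_oscillation`, `evolve_su2_approx`): with two bi-layers the
  field is a 2-spinor and connection modulations become unitary rotations
  generated by the (unnormalized) Pauli matrices.  The slow rotation of
  amplitude and phase between layers — a *generalized oscillation*
  $e^{-i\alpha T^a t} = \cos(\alpha t)I - i\sin(\alpha t)T^a$ — rides on
  the fast carrier $e^{imt}$.

The **LFP toolkit** turns the multilayer picture into a laminar forward
model: a Dirac stimulus on one layer produces the decaying carrier
$g(t) = H(t)\,m^{-1}e^{imt}e^{-Ct/2}$, rotated between layers at rate
$\alpha$ (two layers) or by three pairwise rotation rates (three layers).
`fit_lfp` inverts noisy laminar traces for $(m, C, \alpha, \dots)$ by
damped Gauss–Newton least squares.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `U` | intrinsic connection gain (dimensionless) | 0.1 | weak-connectivity regime, subcritical mass ($Ua < 1$) |
| `R` | connection disc radius (model length) | 1 | sets $a$, $b$; the grid `dx = 0.1` resolves it by 10 nodes |
| `epsilon` | U(1) coupling | 0.01 | connection modulation is a weak perturbation of the oscillation |
| `m`, `C` | LFP carrier frequency and damping | 1, 0.1 | one model time unit per carrier radian; decay over ~20 carrier cycles, as in evoked responses |
| `alpha` | inter-layer rotation rate | 0.05 | slow relative to the carrier ($\alpha \ll m$), the regime where the factorized solution is valid |
| `noise_sd` | observation noise (absolute) | 5% of the peak $1/m$ | the noise level at which inversion quality is quoted |

All quantities are in model units; the unit of the field coefficient is
fixed by normalizing the linear term of the field equation to 1, and no
physical unit conversion is attempted.

## Numerical choices

**Integrator.** The wave equations are stepped with velocity-Verlet
leapfrog — second order, symplectic, time reversible.  For linear fields
the energy error is a *bounded oscillation* of relative size
$(\omega\,\Delta t)^2/8$, not a drift; the conservation tests therefore
run resolved configurations (smooth low-wavenumber fields with
$\omega\,\Delta t \lesssim 3\times10^{-3}$, e.g. `dt = 0.001` on a
32×32 sheet), where the bound is below $10^{-6}$ over $10^4$ steps.  A
CFL guard enforces $\Delta t \le 0.5\,\Delta x/c_\mathrm{eff}$ and runaway
norms abort with a diagnostic.

**Lattice gauge structure.** The spatial components of the connectivity
potential live on *forward links* of the grid (`A_x[j]` on the link
$j \to j{+}\hat x$), and the covariant Laplacian uses hop factors
$e^{-i\varepsilon\,\Delta x\,A}$ (Peierls substitution).  Two properties
follow *exactly* on the lattice, not merely to discretization order:
gauge transformations are an exact symmetry of the coupled evolution and
of the link-based Lagrangian density, and the leapfrog update conserves a
discrete Noether charge $Q^{n+1/2} = \sum_j \mathrm{Im}
(\phi^*_{n+1}\phi_n)/\Delta t$ with an exact local lattice continuity
equation — because the link Laplacian is Hermitian at every step, even
while $A$ evolves.  The node-centered `covariant_derivative` keeps the
familiar centered-difference definition and is covariant to $O(\Delta
x^2)$.  The temporal gauge $A_t = 0$ is used for evolution (the simplest
choice with this exact structure); `gauss_solve` reconstructs the
Gauss-law $A_t$ diagnostically at snapshots.

**Sign conventions.** The pseudo-metric is written with $g^{tt} = +1$ and
negative spatial entries; the Laplace–Beltrami operator is exposed with
the sign that reduces to the *positive* flat Laplacian, so the evolution
reads $\partial_t^2\phi = -m^2c^4\phi + c^2\Delta_g\phi$.  The gauge
shift uses $A \to A + \partial\theta/\varepsilon$, the sign fixed by
covariance of $D = \partial - i\varepsilon A$; the opposite sign printed
in the defining relation is absorbed into the sign of $\theta$.  The
Noether current is normalized as $J_\mu = \mathrm{Im}(\phi^* D_\mu\phi)$
so that a unit-frequency phasor gives exactly $J_t = -|\phi|^2$
(a factor-2 variant appears in parts of the literature; conservation is
unaffected).

**Gauss law.** `gauss_solve` embeds the grid in a padded domain
(factor 2) with zero boundary and solves the 5-point Poisson system with
a sparse direct factorization, so the discrete identity
$\nabla^2 A_t = -|\phi|^2$ holds to solver precision; the free-space
$-\log(r)/2\pi$ point-source profile is recovered up to the $O((r/L)^2)$
image correction.  The $2\pi$ of the two-dimensional Green's function is
kept so the Poisson equation is satisfied exactly;
`normalization = "bare"` rescales to the bare $-\log(r)\,q$ convention.

**Curvature.** `christoffel` and `ricci_scalar` take any diagonal metric
as a `function(point) -> matrix`, differentiate it by central differences
(default step $10^{-3}$), and assemble $\partial\Gamma$ analytically from
first and second metric derivatives, so only a single differencing level
enters and the result is second-order accurate (the 2-sphere value
$2/\rho^2$ is reproduced to $10^{-6}$).  Robertson–Walker Einstein
components are closed forms.

**Expansion dynamics.** `evolve_expansion` integrates the first-order
Friedmann form $\dot a = \pm\sqrt{A a^2 - k}$ with `deSolve` and then
checks the companion acceleration equation and the conservation law using
the *analytic* time derivative of the first-order form (numerically
differentiating only the user-supplied $A(a,t)$), so the reported
residuals measure model consistency rather than finite-difference
truncation.  Note that the two printed equations are mutually consistent
only for matched families ($B = 0$ with $A = \rho_0/a^2$; $B = -A$ with
constant $A$); the package checks exactly those.  Parameter recovery
(`fit_expansion`) uses the constant-$A$ family because in the
conserved-density family only $\rho_0 - k$ enters $a(t)$ and a joint fit
is degenerate.

**Impulse convention for the LFP Green's function.** The printed closed
form $H(t)\,m^{-1}e^{imt}e^{-Ct/2}$ is the *single-pole, rotating-wave*
response: of the two roots of $s^2 + m^2 + iC$, the $+iC$ damping term
damps the co-rotating root and *amplifies* the counter-rotating one, so a
two-sided $\delta$ realization ($\phi(0)=0,\ \dot\phi(0)=1$) of the
second-order equation contains a growing branch that the closed form (and
the underlying first-order bi-layer dynamics) excludes.  The ODE oracle
test therefore initializes on the decaying pole and runs at weak damping
($m = 1$, $C = 0.01$), where the closed form is accurate to
$\sim\!6\times10^{-4}$ over ten carrier periods; at $m \ne 1$ the printed
decay $C/2$ differs from the exact $C/2m$, so the oracle regime is pinned
to $m = 1$.

**SU(2) factorization.** The printed final approximate multilayer ODE and
its printed solution differ by a stray factor $i$ (the printed ODE has
non-unitary solutions); the package implements the unitary closed form,
which exactly solves $\ddot{\vec\phi} = (-m^2 I + 2m\,\alpha\!\cdot\!T)
\vec\phi$ up to the dropped $\alpha^2$ term.  The oracle test integrates
that self-consistent equation and compares layer *amplitude envelopes*
(≤1% over one slow rotation at $\alpha = m/50$); the complex traces
additionally carry the expected second-order carrier-phase drift of order
$\pi\alpha/m$, which the factorization does not claim to capture.
Likewise, the structure constants are *computed* from the printed
generators (giving $f^{123} = 2$, twice the half-normalized convention
the commutation relation suggests) rather than assumed.

**Three-layer forward model.** The three-layer response is built from the
three real antisymmetric rotation generators (pairwise amplitude
transfer) scaled by independent rates and exponentiated in closed form
(Rodrigues).  Complex phase-type generators are deliberately excluded
from the default model: with a single stimulated layer and real
observations they are weakly identifiable, and the amplitude-transfer
rotations are the component highlighted in laminar recordings.

**Delta-response experiment.** The "delta" stimulus is a Gaussian
velocity impulse of width $2\,\Delta x$ at the grid center — the
narrowest grid-representable approximation whose response converges to
the delta response.  Learning is represented by a larger constant
expansion factor $a$, which divides the effective lateral speed by $a$;
with the packaged defaults (64×64, `dx = 0.1`, $U = 0.1$, $R = 1$,
$a: 1 \to 1.5$) slower dispersal concentrates the evoked energy at the
stimulated site, so both the peak amplitude and the integrated response
at the probe grow (ratios ≈ 1.35 and ≈ 1.9), monotonically over the
packaged sweep $a \in \{1.3, 1.6, 2.0\}$.  The direction of this effect
is asserted only for these packaged conditions; it is not claimed for
all parameter regimes.

## What the synthetic data emulate — and what they do not

`make_synthetic_lfp` produces laminar evoked responses: closed-form
rotating decaying waves plus independent Gaussian observation noise on
each sample (optionally real-part-only observations, matching real LFP
channels), fully reproducible from a seed.  This captures the structure
the inversion must exploit — a shared carrier, layer-coupled envelopes, a
known stimulated layer — but deliberately omits features of real laminar
data: 1/f background activity, trial-to-trial latency jitter, volume
conduction across contacts, electrode drift and non-Gaussian artifacts.
Passing the recovery tests therefore demonstrates the estimator is
correct and well-conditioned in its model class, not that the model fits
arbitrary recordings.

Problem sizes were chosen so the full suite and the acceptance script
each run in well under a minute of CPU: 128×128 dispersion runs, 32×32
gauge runs over $10^4$ steps, 20-seed inversion batches of 601-sample
two-layer records.

## Inversion details

`fit_lfp` minimizes the stacked real/imaginary residual with
Levenberg–Marquardt (`minpack.lm`), with five restarts from initial
values jittered by ±30% under a fixed per-fit RNG stream, which handles
the carrier-phase local minima that trap single-start fits.  Standard
errors come from the Gauss–Newton curvature $J^\top J$ at the optimum
scaled by the residual variance; optional Gaussian priors enter as ridge
residuals.  Uncertainty is therefore a Laplace-style approximation —
full posterior sampling is out of scope.

## Known limitations

* The integro-differential field equation with retarded time is never
  stepped directly; the PDE reduction is assumed exact at the simulated
  wavelengths (the long-wavelength regime).
* Only diagonal metrics are supported, and grid evolution of the
  Robertson–Walker metric requires the spatially flat form
  (`k_curv = 0`); curved `k_curv` enters through the closed-form Einstein
  tensor only.
* The full non-abelian Yang–Mills self-interaction is not evolved as a
  PDE; the SU(2) sector provides generators, currents, gain rates and the
  factorized slow-rotation solution.
* Directional (first-derivative) connectivity terms and torsion are
  excluded.
* Stability (as opposed to stationarity) of the nontrivial strong-coupling
  states is not analysed; `stable_states` verifies stationarity.
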