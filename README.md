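# cortexgauge

Field-theoretic simulation of cortical activity for computational
neuroscientists: neural fields on the cortical sheet as Klein–Gordon
waves whose mass and speed derive from local connectivity, gauge-coupled
connectivity fields whose conservation laws yield Hebbian learning rules,
curved-surface (Robertson–Walker) metric learning, and a laminar
local-field-potential (LFP) forward model with parameter inversion.

## The model in brief

Cortical activity is a complex field $\phi(\mathbf r,t)$ — one
excitatory–inhibitory bi-layer per point, whose balanced interaction makes
the local dynamics oscillatory.  Connections act over a disc of radius
$R$ with gain $U$; a long-wavelength expansion gives the massive wave
equation

$$\partial_t^2 \phi = -(1 - Ua - b\nabla^2 U)\,\phi + Ub\,\nabla^2\phi,
\qquad a = \pi R^2,\; b = \tfrac{\pi R^4}{4}.$$

On top of this core:

* **U(1) sector** — a phase modulation of the connection gain becomes a
  gauge potential $A_\mu$ with covariant derivative
  $D_\mu = \partial_\mu - i\varepsilon A_\mu$; the Noether current of the
  phase symmetry is conserved, and its Gauss law
  $\nabla^2 A_t = -|\phi|^2$ makes connection change follow a
  (non-linear) Hebbian rule with a $-\log(r)$ spatial profile.
* **Metric learning** — lateral connection change is carried by an
  expanding surface metric $a(t)$ obeying Friedmann-like equations
  sourced by the field's stress–energy; in the high-mass limit
  $\dot a \approx \pm m|\phi|$.
* **SU(2) multilayer sector** — two bi-layers form a 2-spinor whose
  inter-layer dynamics are unitary "generalized oscillations"
  $e^{-i\alpha T^a t}$ generated by Pauli matrices, riding on the fast
  carrier $e^{imt}$.
* **LFP toolkit** — laminar impulse responses
  $g(t) = H(t)\,m^{-1}e^{imt}e^{-Ct/2}$ rotated between 2 or 3 layers,
  synthetic noisy records, and Levenberg–Marquardt inversion for
  $(m, C, \alpha, \dots)$ with Gauss–Newton standard errors.

## Worked example: simulate and invert a laminar LFP

```r
library(cortexgauge)

t <- seq(0, 60, by = 0.1)
rec <- make_synthetic_lfp(
  "two_layer", list(m = 1, C = 0.1, alpha = 0.05), t,
  noise_sd = 0.05, seed = 7, stim_layer = 2
)
fit <- fit_lfp(rec, "two_layer")
fit
#> <inversion_result> converged = TRUE, iterations = 11, RSS = 6.03255
#>         estimate    std_error
#> m     0.99965559 0.0003571623
#> C     0.09834408 0.0007161774
#> alpha 0.04995578 0.0003576124
```

All three generating parameters are recovered to a fraction of a percent
from traces carrying 5%-of-peak Gaussian noise; the standard errors are
the Gauss–Newton uncertainties at the optimum.

The wave core works the same way:

```r
par <- kg_params(connectivity_kernel(U = 0.1, R = 1))
par
#> <kg_params> mass2c4 = 0.685841, c2 = 0.0785398
f0 <- scalar_field(matrix(0.1 + 0i, 64, 64), dx = 0.1)
traj <- evolve_kg(f0, par, dt = 0.01, n_steps = 2000, probe = c(32, 32))
measure_frequency(Re(traj$probe_series), 0.01)
#> [1] 0.8281574   # = sqrt(mass2c4) = 0.828155, the column's bare frequency
```

Command-line wrappers live in `inst/cli/`
(`simulate-kg.R`, `simulate-lfp.R`, `invert-lfp.R`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/simulate-lfp.R", package="cortexgauge"))')" \
  --model two_layer --m 1 --C 0.1 --alpha 0.05 --noise-sd 0.02 --seed 7 --out lfp.csv
```

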