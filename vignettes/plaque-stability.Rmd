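---
title: "Methods: stability analysis of the plaque inflammation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability analysis of the plaque inflammation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquestab)
```

## The model and its assumptions

The package analyses a minimal inflammation model of early
atherosclerosis with three species in the arterial intima: oxidised LDL
$L$, macrophages $M$ and necrotic lipids $N$,

$$
\begin{aligned}
L_t &= D_L \nabla^2 L - k_L L M + L_0,\\
M_t &= D_M \nabla^2 M - \nabla\!\cdot(\mu M \nabla L) - k_M L M + f(L),\\
N_t &= k_M L M - k_N N,
\end{aligned}
$$

with homogeneous no-flux (Neumann) boundary conditions.  The structural
assumptions are: all LDL entering the wall is immediately oxidised;
monocytes mature instantly into macrophages; the phagocytosis reaction
$L + M \to N$ is first order in each reactant, and foam-cell necrosis is
fast, so macrophage loss feeds necrotic mass directly; necrotic lipids
are dense and immobile ($D_N = 0$, no chemotaxis); only macrophages are
chemotactic, moving up the ox-LDL gradient with Keller–Segel flux
$\mu M \nabla L$; immune clearance removes necrotic material at rate
$k_N$.  Influx is modelled through source terms rather than boundary
fluxes: a constant ox-LDL supply $L_0$ and a macrophage recruitment
response $f(L)$, sigmoidal because recruitment saturates at high ox-LDL
levels.  Coefficients are spatially constant (intimal homogeneity); the
domain has fixed volume (early disease, small fibrous atheromas).

### Parameters and units

| parameter | meaning | units | default |
|---|---|---|---|
| `D_L`, `D_M` | diffusion of ox-LDL / macrophages | length²/time | 1 |
| `mu` | chemotactic sensitivity | length²/(time·conc.) | 0 |
| `k_L`, `k_M` | reaction rates of $L+M\to N$ | 1/(time·conc.) | 1 |
| `k_N` | necrotic clearance rate | 1/time | 1 |
| `L0` | ox-LDL influx | conc./time | 1 |

All quantities are nondimensional O(1) values; nothing in the package is
calibrated to clinical data (see *Limitations*).

### Response families

`f` is never pinned down by the biology beyond "sigmoidal", so three
families ship:

* `response_identity()` — $f(L) = L$, for exact-arithmetic tests only;
* `response_logistic(a, b, s, c)` — $a + b/(1+e^{-s(L-c)})$, the
  physiological default;
* `response_pinned(L_star, value, slope)` — a logistic re-parameterised
  to take a prescribed value and slope (either sign) at a prescribed
  point.  The steepness $s = \max(1, 4|f'|/f)$ guarantees
  $f \ge f(L^*)/2 > 0$ everywhere, so non-negativity never constrains
  the admissible pins.  Negative slopes model a *pathological* immune
  response and are how the unstable regime is produced in experiments.

Equilibrium requires solving $f(L_e) = k_M L_0 / k_L$.  This is done by
an expanding-bracket scan (geometric grid from machine epsilon upward)
followed by bisection to an interval width of $10^{-12}$ — deliberately
derivative-free, because the pinned family need not be monotone; the
first bracketed root is taken.  For a pinned response whose pinned value
equals the required influx the pin point is returned exactly.

## Stability theory implemented

Writing $L = L_e + a$, $M = M_e + b$, $N = N_e + c$ and linearising gives
constants $k_1 = k_L M_e$, $k_2 = k_L L_e$, $k_3 = k_M M_e - f'(L_e)$,
$k_4 = k_M L_e$, $k_5 = k_N$, $k_6 = k_M M_e$, $\chi_a = \mu M_e$,
$D_a = D_L$, $D_b = D_M$, with the identity
$k_1 k_4 - k_2 k_3 = k_L L_e f'(L_e)$.

**Spectral criterion.**  The well-mixed (space-integrated) system has
Jacobian eigenvalues $\lambda_1 = -k_5$ and
$\lambda_{2,3} = \tfrac12\!\left(-(k_1{+}k_4) \mp
\sqrt{(k_1{-}k_4)^2 + 4k_2k_3}\right)$; stability holds iff
$k_1 k_4 > k_2 k_3$, i.e. iff $f'(L_e) > 0$.  With $k_3 > 0$ the
discriminant is positive and all eigenvalues are real; a steep response
($f' > k_M M_e$, so $k_3 < 0$) can make $\lambda_{2,3}$ a complex pair,
in which case real parts are reported and used for the flag.

**Energy certificate.**  Multiplying each linearised equation by its
perturbation, integrating by parts under no-flux conditions, and
splitting every cross term $\int uv$ with the Cauchy inequality
$\epsilon u^2 + v^2/(4\epsilon) \ge uv$ yields, for positive weights
$x, y, z$ and $\epsilon_1..\epsilon_5$,

$$
\tfrac12 \tfrac{d}{dt}\!\int\! x a^2 + y b^2 + z c^2 \le
 C_a\!\int\! a^2 + C_b\!\int\! b^2 + C_c\!\int\! c^2
 + C_{\nabla a}\!\int\!|\nabla a|^2 + C_{\nabla b}\!\int\!|\nabla b|^2
$$

with the five bracketed coefficients implemented verbatim in
`certificate_coefficients()`.  When $f'(L_e) > 0$ **and**
$\chi_a^2 < 4 D_b D_a k_3/k_2$, weights making all five coefficients
strictly negative exist, and `construct_certificate()` builds them
explicitly: $\epsilon_1 = k_6/k_5$, $\epsilon_2 = k_4/k_5$ (these make
$C_c = -k_5 z/2 < 0$ identically), $\epsilon_4 = \epsilon_5 = k_1/(2k_2)$,
and then

* $y/x$ must lie in the open interval
  $\bigl(k_2/(4\epsilon_5(k_4 - k_3/(4\epsilon_4))),\;
  (k_1-k_2\epsilon_5)/(k_3\epsilon_4)\bigr)$, which with these
  $\epsilon$'s simplifies to $(k_2^2/(2k_1k_4-k_2k_3),\, k_2/k_3)$ and is
  non-empty exactly when $k_1k_4 > k_2k_3$;
* $z$ must be below two explicit positive upper bounds;
* when $\chi_a > 0$, $\epsilon_3$ must lie in
  $(\chi_a/(4D_b),\; D_a k_3/(\chi_a k_2))$, non-empty exactly under
  criterion 2.

### Free choices, ties, and degeneracies

The existence proof leaves the position inside each open interval free.
The package fixes them once, scale-invariantly: **geometric mean** for
the ratio intervals ($y/x$ and $\epsilon_3$), **half the minimum** upper
bound for $z$, and the normalisation $x = 1$ (only weight ratios enter
the functional).  Geometric means keep a multiplicative safety margin to
both endpoints, which matters because the certificate must evaluate
strictly negative in floating point across wide parameter sweeps.

Equality ties ($k_1k_4 = k_2k_3$, or $\chi_a^2 = 4D_bD_ak_3/k_2$) are
classified **not** stable: the criteria are strict inequalities, and the
boundary cases genuinely lose exponential decay.  $k_3 \le 0$ (very steep
healthy response) is allowed in the coefficient container — the spectral
report is still valid — but certification rejects it, since criterion 2's
right-hand side would be non-positive.

**Decay rate.**  From the coefficient inequalities,
$d\phi/dt \le -M\phi$ with the *weight-normalised* rate
$M = 2\min(|C_a|/x, |C_b|/y, |C_c|/z)$.  A plain "absolute value of the
maximum coefficient" is not dimensionally coherent against the weighted
functional $\phi = \tfrac12\int xa^2+yb^2+zc^2$; the normalised form is
the one the simulations are checked against
($\phi(t) \le 1.05\,\phi(0)e^{-Mt}$, the 5% slack covering quadrature
and time-integration error, not model error).

## Geometry and discretisation

The intima is an off-centre annulus, parameterised in bipolar
coordinates $x = d\sinh\tau/(\cosh\tau-\cos\sigma)$,
$y = d\sin\sigma/(\cosh\tau-\cos\sigma)$: constant-$\tau$ curves are
nested non-concentric circles (radius $d/\sinh\tau$, centre
$d\coth\tau$), so $\tau_{ext} < \tau < \tau_{int}$ with
$\sigma \in [-\pi,\pi)$ periodic is exactly a thin eccentric annulus.
The metric scale factor is taken as the standard bipolar
$h = d/(\cosh\tau - \cos\sigma)$ — the unique choice for which
$(1/h^2)(\partial_\tau^2 + \partial_\sigma^2)$ is the Laplacian, and
hence the only one consistent with the interior stencil below.

* **Grid** (`bipolar_grid`): $\Delta\tau = (\tau_{int}-\tau_{ext})/(m-1)$
  with the walls on grid rows, $\Delta\sigma = 2\pi/n$ with index
  arithmetic modulo $n$ everywhere.  Default fixture
  `tau_ext = 1, tau_int = 2, m = n = 32, d = 1`: a thin annulus whose
  inner circle is offset — chosen as a plausible thickened intima, not
  fitted to anatomy.
* **Interior** rows use the centred 5-point Laplacian scaled by $1/h^2$;
  the chemotaxis term uses the expanded product
  $\mu\nabla M\cdot\nabla L + \mu M \nabla^2 L$ with centred first
  differences.
* **Boundary** rows use a one-sided 3-point divergence of the flux
  components $F$ ($\tau$) and $G$ ($\sigma$),
  $(1/h)\,[(-3F_1+4F_2-F_3)/(2\Delta\tau) + \partial_\sigma G]$, mirrored
  at the last row, with $F \equiv 0$ **on** the wall row — that zero *is*
  the no-flux condition.  $F$ and $G$ are full physical flux components:
  diffusion coefficient included and, for macrophages, the chemotactic
  part subtracted, so "no flux" means no *total* flux (the chemotactic
  wall flux is an interpretation the model leaves open; total-flux zero
  is the physically conservative reading and is what the package
  implements).  The discrete $L$ equation carries the $+L_0$ source on
  all rows — without it the homogeneous equilibrium would not be a
  stationary point of the scheme.
* The prefactor $1/h$ above is kept as the default (`div_mode =
  "faithful"`).  The full curvilinear divergence
  $(1/h^2)(\partial_\tau(hF) + \partial_\sigma(hG))$ is available as
  `div_mode = "consistent"`; it is exactly mass-conservative for
  $\tau$-symmetric fields, while the faithful form is conservative only
  to first order at the walls (measured drift for a $\tau$-symmetric
  diffusion pulse at $m=n=64$: $\sim 3\times10^{-7}$ of total mass per
  unit time, shrinking under refinement).  All shipped validation runs
  use the faithful mode.
* **Quadrature** (`area_weights`): metric cell areas
  $h^2\Delta\tau\Delta\sigma$ with trapezoid half-weights at the wall
  rows; the sum converges to the analytic annulus area
  $\pi d^2(\sinh^{-2}\tau_{ext} - \sinh^{-2}\tau_{int})$ (relative error
  $<10^{-3}$ at $m=n=200$).  A bare $\Delta\tau\Delta\sigma$ Riemann sum
  is exposed via `metric = FALSE` for comparison, since an energy
  diagnostic could be defined either way; the metric-weighted form is
  the default because it approximates the actual area integral.

## Time integration

No ODE-solver package is assumed; the integrator is part of the package.
The semi-discrete system is stiff (the diffusion spectrum scales as
$(h\Delta\tau)^{-2}$, about $5\times10^4$ on the default grid), so
`mol_integrate()` uses **TR-BDF2** — trapezoidal half-step then BDF2,
one-step, L-stable, second order — with the classical embedded error
estimate filtered through $(I - \gamma\Delta t J/2)^{-1}$, an RMS error
norm against `atol + rtol·|u|` (defaults $10^{-10}$, $10^{-8}$), and a
step controller whose size changes are quantised so that the sparse LU
factorisation of the stage matrix is reused across steps.  In linearized
mode the whole right-hand side is assembled once as a sparse matrix (the
two spatial blocks are multiples of a single scalar operator, itself
built by applying the field-level stencils to basis vectors — so the
matrix is identical to the field code by construction) and each stage is
one cached sparse solve.  In nonlinear mode a simplified Newton iteration
uses a finite-difference Jacobian with a conservative structural
colouring (the one-sided wall stencil widens the sparsity to four rows).

The independent cross-check is `reference_rk45()`, a self-contained
explicit Dormand–Prince 5(4) integrator sharing no code with the implicit
path; uniform-initial-data PDE runs are required to match the 3-variable
homogeneous solve to $10^{-6}$.

## The perturbation generator

`perturbation_fourier`, `perturbation_bump` and `perturbation_random`
produce initial perturbations that are exactly compatible with the
no-flux walls: cosine $\tau$-profiles have zero normal slope for any
integer mode; the Gaussian bump's $\tau$ argument passes through a
smoothstep reparameterisation with vanishing derivative at the walls;
the random pattern is a seeded combination of compatible Fourier modes
(including the spatial-mean mode, the one that grows in the unstable
regime) with $1/(1+k_\tau+k_\sigma)$ spectral damping, drawn from a
private RNG stream so user code's RNG state is untouched.  Amplitudes
above 10% of the smallest equilibrium concentration trigger a warning in
nonlinear mode — beyond that the linear theory being tested is not the
dominant behaviour.

What the generator does **not** emulate: measurement noise, spatially
varying coefficients, anatomically realistic intima shapes, HDL
buffering, or flow coupling.  A green validation run therefore
establishes that the *discretised model* behaves as the *theory for this
model* predicts — not that the model describes any particular artery.

## Experiment classification

`run_experiment` integrates a perturbation and records
$I(t) = \int (a^2+b^2+c^2)\,dA$.  Classification thresholds are artifact
choices (the underlying analysis only exhibits qualitative
convergence/divergence): **stable** when $I$ falls below $10^{-3} I(0)$,
or plateaus (relative change $<10^{-4}$ over the final 10% of the run
while bounded by $2I(0)$ — nonlinear runs whose perturbation shifts total
mass converge to a nonzero constant, and the plateau branch captures
that); **unstable** when $I$ exceeds $10\,I(0)$; otherwise
**inconclusive**.  Zero-amplitude runs are stable by convention
($I \equiv 0$).

## Numerical-choice summary

* bisection tolerance $10^{-12}$; equilibrium residuals validated to
  $10^{-10}$;
* strict inequalities everywhere a criterion is evaluated; no epsilon
  fudge on the stability boundary;
* solver defaults rtol $10^{-8}$/atol $10^{-10}$; the bulk validation
  sweeps in the test suite run at rtol $10^{-5}$ with capped horizons to
  fit their time budget — legitimate because every check they feed has
  slack (5% on the decay envelope, $10^3\times$ on classification)
  orders of magnitude above integration error at that tolerance;
* experiment horizons are scaled by the known slowest spectral rate
  ($t_{end} \sim 7/|\lambda_{max}|$ for decay runs), so classification
  outcomes are determined by the dynamics, not by an arbitrary fixed
  horizon.

## Known limitations

* Criterion 2 is sufficient, not necessary: models violating it with
  $f'(L_e) > 0$ still simulate stable (for $\chi_a \ge 0$ the
  linearised dispersion relation has no sign change at any wavenumber —
  the acceptance suite probes this), so the certificate's absence proves
  nothing about instability.
* The faithful boundary divergence is first-order accurate and not
  exactly conservative; the consistent mode fixes conservation but is
  not what the validated scheme specifies.
* The decay bound $M$ is conservative, often far below the true decay
  rate; it certifies stability, not sharp dynamics.
* No parameter estimation, no HDL species, no moving boundary, no
  fluid–structure coupling.
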