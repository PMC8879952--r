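---
title: "Methods: the CIN2D indicator, PMF estimation and the Langevin surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CIN2D indicator, PMF estimation and the Langevin surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cin2d)
set.seed(1)
```

## 1. The indicator

A two-dimensional nanomaterial meeting a phospholipid bilayer interacts
through its affinity for the two lipid moieties: the polar head group and
the hydrophobic tail. Both affinities are summarized by adsorption free
energies obtained from potentials of mean force (PMFs) along the
face-normal coordinate $\xi$:

$$g_h = \min_\xi \Delta G_{\text{head}}(\xi), \qquad
  g_t = \min_\xi \Delta G_{\text{tail}}(\xi),$$

with the convention $\Delta G(\xi \to \infty) = 0$, so both are $\le 0$.
The **computational indicator of nanotoxicity** is

$$\mathrm{CIN}_{2D} = g_h - g_t \quad [\text{kJ/mol}],$$

interpreted against the membrane's **extraction resistance**

$$g_0 = \min_N \frac{G_N}{N},$$

where $G_N$ is the barrier to extracting $N$ lipids cooperatively. The
per-lipid barrier falls with $N$ (neighbours share the cost of the created
defect), so the minimum over small $N$ is the relevant resistance. For a
POPC bilayer at 310 K the shipped series ($G_1 = 93.3$, $G_2 = 152.0$,
$G_3 = 224.4$ kJ/mol) gives $g_0 = 74.8 \approx 75$ kJ/mol
(`g0_from_series(popc_extraction_series())`).

Classification (`classify_regime()`):

* $|g_h| + |g_t| < k_B T$ — **no_interaction**: both affinities are within
  thermal noise ($k_B T \approx 2.58$ kJ/mol at 310 K;
  $k_B = 0.0083144621$ kJ/(mol·K)).
* $\mathrm{CIN}_{2D} < 0$ — **adsorption**: the face prefers heads, so it
  decorates the membrane surface.
* $0 \le \mathrm{CIN}_{2D} < g_0$ — **insertion**: tails are preferred, but
  not strongly enough to pay the extraction cost; the sheet wedges into the
  hydrophobic core.
* $\mathrm{CIN}_{2D} \ge g_0$ — **lipid_extraction**: the tail preference
  exceeds the membrane's resistance; lipids climb onto the sheet.

Boundary conventions are closed upward: $\mathrm{CIN}_{2D} = 0$ is
insertion, $\mathrm{CIN}_{2D} = g_0$ is lipid_extraction, and a note column
records boundary hits.

**Uncertainty.** Each face energy carries an error $u_h$, $u_t$ (typically
the replicate dispersion of the PMF minimum). The indicator's uncertainty is
the conservative sum $u = |u_h| + |u_t|$ (errors of a difference of two
independently estimated quantities; the sum, rather than quadrature, guards
against correlated systematic error between the two one-sided estimates). A
classification is **not confident** when $[\mathrm{CIN} - u,\,
\mathrm{CIN} + u]$ straddles a regime boundary (0 or $g_0$) or when
$u \ge |\mathrm{CIN}|$.

**Open choices made here.** The two faces enter with equal weight — no
attempt is made to weight by contact area or coverage. $g_0$ is exposed as a
parameter (default 75) because it belongs to the membrane and temperature,
not the nanosheet; any lipid composition can be screened by supplying its
own extraction series.

## 2. Estimating PMFs from steered pulling

All estimators consume `work_curve` objects: monotone trap positions
$\xi_i$ with accumulated external work $W_i$ (kJ/mol), $W_1 = 0$, tagged
with a direction (`adsorption`: decreasing $\xi$, toward the surface;
`desorption`: increasing $\xi$). Force-mode files are converted to work by
trapezoidal quadrature on read.

In the stiff-spring regime (spring constant $k = 1000$ kJ/(mol·Å²), trap
fluctuation $\sqrt{k_B T / k} \approx 0.05$ Å, far below any landscape
feature), the work along a slow pull approximates the free-energy change
directly:

* **Forward** (`pmf_forward`): $\Delta G(\xi) = W(\xi)$, reordered onto
  increasing $\xi$.
* **Reverse** (`pmf_reverse`): $\Delta G(\xi) = -(W_{\text{end}} - W(\xi))$.
* **Bidirectional** (`pmf_bidirectional`): each curve is converted per its
  direction, interpolated onto the intersection grid at the coarsest native
  spacing (never inventing resolution), then averaged pointwise; the
  dispersion column is the pointwise sample standard deviation across
  replicates. Averaging forward and reverse branches cancels the
  leading-order dissipation, which has opposite sign in the two directions.
* **Jarzynski** (`pmf_jarzynski`): the nonequilibrium work identity
  $\Delta G(\xi) = -k_B T \ln \langle e^{-W(\xi)/k_B T} \rangle$ over
  replicate pulls of a single direction. The average is computed with a
  log-sum-exp guard (subtracting $\min W$ before exponentiating) so that
  strongly dissipative work values cannot overflow. Uncertainty comes from
  a seeded bootstrap over curves (default 200 resamples), each replicate
  re-zeroed before dispersion is taken. The estimator is exact in
  principle but biased from finite samples: the exponential average is
  dominated by rare low-work trajectories.
* **Mean work** (`pmf_mean_work`): the naive baseline
  $\Delta G \approx \langle W \rangle$. By Jensen's inequality it bounds the
  Jarzynski estimate from above pointwise ($\langle W \rangle \ge
  -k_B T \ln \langle e^{-W/k_B T}\rangle \ge \Delta G$, the second law);
  the test suite asserts both inequalities on simulated data.

Every profile is re-zeroed at its largest $\xi$ (bulk reference), an
idempotent operation. Temperatures must agree across curves entering one
estimate; mixing is an error, as is estimating from curves with no grid
overlap.

## 3. The Langevin surrogate

`simulate_pull()` generates synthetic pulling data with known ground truth.
A single coordinate $x$ (the lipid moiety's distance from the face) evolves
by overdamped Langevin dynamics in a model landscape $U(x)$ while a
harmonic trap of stiffness $k$ moves at constant velocity $v$ from
$\xi_{\text{start}}$ to $\xi_{\text{end}}$:

$$dx = \frac{-U'(x) - k\,(x - \lambda(t))}{\gamma}\,dt
  + \sqrt{\frac{2 k_B T\,dt}{\gamma}}\,\eta, \qquad
  dW = k\,(\lambda - x)\,d\lambda,$$

integrated by Euler–Maruyama in compiled code using R's RNG, so `set.seed()`
makes every trajectory reproducible.

**Parameters, units and defaults.**

| parameter | default | unit | rationale |
|---|---|---|---|
| `spring_k` | 1000 | kJ/(mol·Å²) | stiff-spring pulling; trap sd 0.05 Å |
| `velocity` | 1e-4 | Å/ps | slow protocol: dissipation $\ll k_B T$ |
| `temperature` | 310 | K | physiological |
| `friction` $\gamma$ | 50 | kJ·ps/(mol·Å²) | sets the surrogate's time scale; diffusion $k_BT/\gamma \approx 0.05$ Å²/ps, in the range of lipid-scale transverse diffusion, while keeping slow pulls to seconds of CPU |
| `dt` | $0.05\,\gamma/k$ | ps | resolves the trap relaxation time $\gamma/k$; `pull_protocol()` errors if $dt > 0.1\,\gamma/k$ (`cin2d_stability_error`) rather than integrating an unstable scheme |
| `burn_in` | 0 (forward), $10^4$ steps (reverse sets) | steps | reverse pulls start trapped at the surface and must equilibrate first |

Model landscapes (`model_potential()`): `flat` (exact answers: zero free
energy, drag work $\gamma v L$), `adsorption_well` (Gaussian well plus
exponential repulsive wall — the generic adsorption PMF shape),
`hydration_oscillatory` (adds a damped cosine emulating hydration-layer
ripples), `extraction_plateau` (smoothstep ramp to a plateau — the shape of
an $N$-lipid extraction PMF). `potential_minimum()` provides the analytic
ground truth for recovery tests.

**Recorded force.** The instantaneous spring force fluctuates with standard
deviation $\sqrt{k_B T\, k} \approx 50$ kJ/(mol·Å) at the defaults; point
samples of it cannot reconstruct the work by quadrature. The simulator
therefore records the block-averaged spring force between save points,
making force-mode files integrate back to the work curve exactly (up to
quadrature error).

**What the surrogate does and does not emulate.** It reproduces the
statistical structure that work-based estimators care about:
Boltzmann-distributed trap fluctuations at rest (verified by a
Kolmogorov–Smirnov test against the Gaussian stationary law), dissipated
work growing with pulling speed, near-Gaussian work at slow pulling, and
exact known free-energy differences. It does **not** emulate atomistic
steered MD: there is no explicit membrane or solvent, no
position-dependent friction, no membrane deformation or lipid cooperativity,
and the single reaction coordinate hides all orthogonal relaxation. Its
role is validation of the estimation pipeline, not prediction.

**Problem sizes used.** The validation suite runs bidirectional sets of
2+2 pulls at the default protocol ($4 \times 10^5$ steps each, seconds per
pull) recovering a $-50$ kJ/mol well within its own replicate error, and
Jarzynski over 50 fast pulls (velocity 0.02–0.05 Å/ps) where it measurably
beats the mean-work baseline. Fixture profiles use 121–201 grid points.

## 4. Numerical choices

* $k_B = 0.0083144621$ kJ/(mol·K) throughout; exported as `kB`.
* Intersection grids at the coarsest native spacing: averaging never
  interpolates beyond the resolution either input actually has.
* Profile minima are located by `which.min` (ties to the smallest $\xi$);
  adsorption energies are clamped at $\le 0$ by construction of the
  re-zeroed profile.
* Numbers cross file boundaries at full precision (`%.17g` in delimited
  files, `digits = NA` in JSON), so write–read round trips are exact.
* Bootstrap and simulation RNG are seed-controlled and restore the caller's
  RNG state.

## 5. Worked pipeline

```{r pipeline, eval = FALSE}
pot    <- model_potential("adsorption_well", well_depth = -50)
proto  <- pull_protocol(xi_start = 12, xi_end = 2)
curves <- make_bidirectional_set(pot, proto, 2, 2, seed = 2024)
prof   <- pmf_bidirectional(curves)
g      <- adsorption_energy(prof, "head")     # -49.5 +/- 0.3 vs truth -49.94

r <- classify_regime(nanosheet_energies(), g0 = 75)
tidy(r)
plot_diagram(phase_diagram(r))
```

## 6. Limitations

The indicator compares two one-dimensional free-energy minima; it cannot
see kinetic barriers to reorientation, edge effects of finite sheets,
coverage dependence, or membrane curvature. Reported energies shipped in
`nanosheet_energies()` are literature values with their published error
bars; recomputing them requires atomistic steered MD outside this package's
scope. $g_0$ for membranes other than POPC at 310 K must be supplied by the
user. The confidence flag is a coarse interval check, not a posterior
probability.
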