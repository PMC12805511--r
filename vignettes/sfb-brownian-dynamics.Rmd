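---
title: "Semiflexible-body Brownian dynamics and NMR relaxation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiflexible-body Brownian dynamics and NMR relaxation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfbdyn)
```

## The model

`sfbdyn` treats a molecule in solution as a *semiflexible body*: a freely
tumbling rigid frame hydrodynamically coupled to the $N_s = 3N - 6$
internal Z-matrix coordinates $\mathbf q$ (bond lengths, bond angles,
dihedrals), all evolving diffusively (Smoluchowski regime, no inertia).
The conformational potential is harmonic around a single reference
minimum $\mathbf q_0$,

$$U(\mathbf q) = \tfrac12 (\mathbf q-\mathbf q_0)^T
\mathbf K (\mathbf q-\mathbf q_0),$$

with $\mathbf K$ the curvature (internal Hessian) matrix.  The shifted
coordinates

$$\mathbf z = (k_BT)^{-1/2}\, \mathbf T^T \mathbf K^{1/2}
(\mathbf q-\mathbf q_0)$$

are dimensionless "normal modes" with a standard-Gaussian equilibrium
density; $\mathbf T$ is the orthogonal matrix that diagonalizes the
scaled internal diffusion block.  In the coordinates
$(\boldsymbol\Omega, \mathbf z)$ the whole model is described by a single
$(3+N_s)\times(3+N_s)$ diffusion tensor $\mathbf D$, whose eigenvalues
are the effective frequencies of the motions: their extremes fix the
integration time step and the required trajectory length *before* any
simulation is run.

Two inputs parametrize $\mathbf D$:

* a **hydrodynamic generalized diffusion tensor**, from a bead model
  (one bead per atom, equal effective radius $R_\mathrm{eff}$) with
  Stokes-Einstein friction $\xi = C\pi R\eta$ per bead ($C = 6$ stick,
  $4$ slip) and Rotne-Prager-Yamakawa coupling between beads, projected
  from bead velocities onto (translation, rotation, $\dot{\mathbf q}$)
  via a geometry matrix, with translation then removed by a Schur
  complement;
* the **curvature matrix** $\mathbf K = \mathbf B^T \mathbf H \mathbf B$,
  from a user-supplied Cartesian Hessian $\mathbf H$ at the minimum and
  the Jacobian $\mathbf B = \partial \mathbf x / \partial \mathbf q$
  (valid at a stationary point, where the gradient term vanishes).

### A note on the curvature scaling

The scaling $\mathbf K^{1/2} (k_BT)^{-1/2}$ is applied symmetrically to
the *internal* rows and columns only.  A global $(k_BT)^{-1}$ prefactor
over the whole tensor would be dimensionally inconsistent for the
rotational block; the adopted placement leaves every block in s$^{-1}$
and reproduces the analytic sandbox tensor (below) exactly, which we
treat as the authoritative structural check.

## Brownian dynamics in (quaternion, z)

Orientation is propagated as a unit quaternion to avoid gimbal lock.
One Euler step is

$$\begin{pmatrix}\tilde{\mathbf Q}\\ \Delta\mathbf z\end{pmatrix}
 = -\Delta t\, \mathbf W(\mathbf Q)\, \mathbf D
   \begin{pmatrix}\mathbf 0_3\\ \mathbf z\end{pmatrix}
 + \sqrt{2\Delta t}\, \mathbf W(\mathbf Q)\, \mathbf D^{1/2}\mathbf n,$$

where $\mathbf W$ carries the $4\times3$ quaternion kinematic matrix
$b(\mathbf Q)$ on the rotational rows and an identity on the internal
rows, $\mathbf n$ is standard white noise, and $\mathbf D^{1/2}$ is a
Cholesky factor computed once (the tensor is configuration-independent).
The new quaternion is $\tilde{\mathbf Q} + \lambda \mathbf Q$ with the
Lagrange multiplier $\lambda$ solving
$\lambda^2 + 2\lambda\,\mathbf Q\cdot\tilde{\mathbf Q} +
|\tilde{\mathbf Q}|^2 = 1$, so the norm is unit *exactly* after every
step; the root nearer $+1$ is taken for continuity.  The internal rows
update $\mathbf z \mathrel{+}= \Delta\mathbf z$, which makes the scheme a
discretized Ornstein-Uhlenbeck process whose stationary density is the
standard Gaussian — the property every equilibrium test relies on.

The Runge-Kutta (Heun) variant performs a virtual Euler jump with the
*same* noise vector, renormalizes the virtual quaternion (a choice; the
alternative is untested in the literature we follow), and averages drift
and noise-projection matrices between the start and virtual points.  It
tolerates a five-fold larger step: $\Delta t = 1/(2\omega_{\max})$
against $1/(10\,\omega_{\max})$ for Euler.

Two numerical caveats worth knowing:

* at the limiting step $\Delta t = 1/(2\omega_{\max})$ the fastest mode
  has $\omega\Delta t = 0.5$ and the Heun scheme's stationary variance is
  biased low by $\approx 8\%$ for that mode (the bias falls quadratically
  with $\Delta t$; at $\Delta t = 0.1/\omega_{\max}$, used by the
  reference convergence experiment, it is 0.25%).  Observables dominated
  by slow modes are unaffected, but strict distributional tests on the
  fastest $z$ should use the smaller step;
* a step large enough that the quaternion quadratic has no real root, or
  that any $|z_i|$ exceeds 10, aborts with a step-size diagnosis rather
  than returning garbage.

### Scheduling

`make_schedule()` derives everything from the mode spectrum: step
$\Delta t$ as above, per-trajectory length $1000\tau$ with
$\tau = 1/(6\,\omega_{\min})$ (the rank-2 correlation-time convention;
the bare $1/\omega_{\min}$ is exposed via `tau_factor = 1`), an ensemble
of 20 trajectories, and a dump stride targeting $10^4$ snapshots per
trajectory.  Every number can be overridden; a user step above the
stability bound warns rather than errors.

### Reproducibility

The compiled inner loop draws its Gaussian increments from R's own RNG,
so a trajectory is bit-identical to one stepped through the R-level
reference functions under the same seed (a unit test asserts this), and
ensembles derive trajectory seeds as `master_seed + i - 1`.

## The sandbox system

For experimentation the package ships the four-coordinate analytic
system: isotropic unit rotational block, one internal coordinate with
hydrodynamic coefficient 10, coupling $c \in [0,1]$ to the $D_{ZZ}$
rotational entry only, and scalar force constant $k$ (in $k_BT$ units),
all frequencies scaled by the isotropic rotational rate:

```{r}
sandbox_model(1, 10)$D
sandbox_eigenvalues(1, 10)
```

The closed-form eigenvalues
$\omega_{1,4} = [(1+10k) \mp \sqrt{(1-10k)^2 + 4kc^2}]/2$,
$\omega_2=\omega_3=1$ are verified against dense eigendecomposition over
a $(c,k)$ grid to $10^{-12}$.  The coupling index
$\mathrm{CI}_j \propto \sum_{i=1}^{3} |D_{i,j+3}| /
\sqrt{D_{ii} D_{j+3,j+3}}$ (normalized over internal coordinates)
quantifies how much each $z_j$ mixes with rotation; the printed form of
this definition in our source material is typographically garbled, and
the dimensionless normalized-coupling reading above is our
interpretation — it is 0 exactly for a decoupled coordinate and 1 when a
single coordinate carries all the coupling.

## Convergence diagnostics

At equilibrium the Euler angles (ZYZ) satisfy: $\alpha$, $\gamma$
uniform on $(-\pi,\pi]$, $\cos\beta$ uniform on $[-1,1]$; each $z_i$ is
standard normal.  `convergence_report()` compares Kolmogorov-Smirnov
statistics of the dumped series against 1%-level critical values for an
*effective* sample size

$$n_\mathrm{eff} = \min\!\left(n_\mathrm{snapshots},\;
\frac{T_\mathrm{total}}{2\,t_\mathrm{corr}}\right),
\qquad t_\mathrm{corr} = \frac{1}{2 D_\mathrm{iso}} \text{ (angles)},\;
\frac{1}{\omega_i} \text{ (}z_i\text{)},$$

because the raw snapshot count grossly overstates the information in a
serially correlated series.  The decorrelation times come from the
rank-1 rotational diffusion law and the OU autocorrelation respectively.
A coordinate with $n_\mathrm{eff} < 50$ cannot be assessed and is
reported as not converged — which is exactly the verdict a
$\tau$-length trajectory deserves.  This reproduces the expected
ordering: internal coordinates equilibrate within $\sim 10\tau$ while
the free rotation needs $\sim 1000\tau$.

## NMR observables

Probes (C-H or N-H, with CH$_2$ pairs flagged) are detected from the
bond topology; the dipolar frame has $Z$ along the bond and $Y$ normal
to the H-C-X plane.  The rank-2 correlation function

$$C(t) = 5\,\overline{D^2_{00}(\Omega(t+s))\,D^2_{00}(\Omega(s))}$$

is estimated over all time origins (FFT, unbiased per-lag counts), capped
at half the trajectory length, and averaged over the ensemble; the
factor 5 makes $C(0)=1$ at equilibrium.  It is then fitted with
$\sum_k a_k e^{-t/\tau_k}$ (default 4, at most 5 terms), $a_k \ge 0$,
by separable least squares: a Nelder-Mead search over $\log\tau_k$ with
weights solved by nonnegative least squares at each iterate, followed by
a Levenberg-Marquardt polish; near-duplicate and zero-weight components
are pruned.  The initial guess is log-spaced between the dump resolution
and the window; a failed fit raises an error asking for a user-supplied
guess rather than returning a bad model.

Two conditioning choices matter:

* **Time-constant cap.**  A component slower than the observation window
  is not identifiable, yet nonnegative fitting will happily park a
  near-flat exponential on the positive excursions of correlated tail
  noise — and $J(0) = 2\sum_k a_k\tau_k$ amplifies it linearly in
  $\tau$.  Since no rank-2 relaxation time of this model can exceed
  $1/(6\,\omega_{\min})$, the pipeline caps $\tau_k$ at five times that
  value (standalone fits default to $10\times$ the longest lag).
* **Convergence test on the signal window.**  Fit quality is judged on
  lags where $|C| > 0.1\,C(0)$; the tail's contribution to the residual
  depends only on how many noise-dominated lags happen to be recorded.

The spectral density is the Lorentzian sum
$J(\omega) = \sum_k a_k\, 2\tau_k/(1+\omega^2\tau_k^2)$ (cosine-transform
convention, interaction strength carried entirely by the prefactors) and
relaxation follows the standard dipolar expressions with
$d = (\mu_0/4\pi)\gamma_H\gamma_X\hbar/r^3$, optional axially symmetric
CSA $c^2 = \tfrac{2}{15}\omega_X^2\delta^2$ (inactive at the default
$\delta_\mathrm{CSA}=0$), and
$\mathrm{NOE} = 1 + (\gamma_H/\gamma_X)(d^2/4)\,[6J(\omega_H{+}\omega_X)
- J(\omega_H{-}\omega_X)]\,T_1$.  The convention set is validated by the
extreme-narrowing limit $\mathrm{NOE} \to 1 + \gamma_H/(2\gamma_C)
\approx 2.988$ and by $T_1 = T_2$ there.  No constant offset is added to
the fit: free tumbling forces $C(\infty)=0$.

## Synthetic data generator

`make_fixture()` stands in for the external
minimization/Hessian tool chain.  It builds a chain (or the branched
4-atom demonstration) molecule and assembles the Cartesian Hessian as
$\mathbf H = \mathbf B_w^T\,\mathrm{diag}(k)\,\mathbf B_w$ from the
Wilson gradient rows of the internal coordinates, so that

* the true curvature matrix is $\mathrm{diag}(k)$ *exactly* (the
  recovery test closes the loop to $10^{-8}$), and
* the six rigid-body modes are null by construction.

Default force constants are typical molecular-mechanics magnitudes —
350 kcal mol$^{-1}$ Å$^{-2}$ stretches, 60 and
8 kcal mol$^{-1}$ rad$^{-2}$ bends and torsions — chosen once to give
the realistic two-decade separation between "tumbling" and internal
frequencies.  What the generator does *not* emulate: anharmonicity,
multiple minima and dihedral flips, geometry-dependent hydrodynamics,
and solvent structure; passing tests therefore validate the machinery
and its statistics, not the force-field realism of any specific
molecule.

## Numerical choices

* **Placement convention**: atom 1 at the origin, atom 2 on $+z$, atom 3
  in the $xz$-plane with $x > 0$; only internal motion and the
  separately tracked rotation are physical, so any fixed convention
  works.  Dihedral sign is IUPAC (right-handed looking along the
  2→3 axis).
* **Jacobians** by Richardson-extrapolated central differences (base
  step $10^{-3}$ Å/rad, ~$10^{-10}$ relative accuracy); a Hessian in the
  input frame is paired with the Kabsch-aligned Jacobian so the
  curvature matrix is invariant under rigid motion of the input.
* **Curvature regularization**: eigenvalues below $10^{-8}$ of the
  largest are floored (with a warning); genuinely negative curvature is
  an error, since the model requires a minimum.
* **Friction conditioning**: the generalized friction mixes translation
  (O(1)) with rotation/internal (O($10^{-10}$ m)) columns, so it is
  Jacobi-scaled to unit diagonal before inversion.
* **RPY overlap branch** for bead separations below $2R$ — routine at
  atomic bead radii — keeps the mobility positive definite.
* **Eigenvector conventions**: ascending eigenvalues; largest-magnitude
  component positive; an already-diagonal block keeps its natural axes
  (a degenerate rotational block would otherwise acquire an arbitrary
  basis); the rotational eigenbasis is forced to a proper rotation.
* **Serialization** uses plain-text formats throughout (Tinker-dialect
  XYZ, whitespace matrix files, TSV tables).

## Problem sizes used by the test suite

The stochastic checks run at deliberately modest sizes chosen to leave
comfortable statistical margins: the sandbox equilibrium experiment uses
one $1000\tau$ trajectory at $\Delta t = 0.1/\omega_4$ ($\approx 10^6$
steps); the free-rotor law uses 20 trajectories of $1000\tau/6$; OU
autocorrelations use $10^5$–$10^6$ steps.  All are seeded and complete
in seconds thanks to the compiled inner loop.

## Known limitations

Single harmonic minimum (no Boltzmann-weighted multi-minimum averaging,
no activated jumps); geometry-independent diffusion tensor; equal bead
radii with scalar slip/stick coefficient; no CSA-dipolar tilt beyond a
pass-through parameter; no quadrupolar nuclei, cross-correlated or
exchange contributions.  The Smoluchowski operator is never represented
on a basis — for the system sizes of interest that route is
computationally hopeless, which is precisely why the trajectory solution
exists.
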