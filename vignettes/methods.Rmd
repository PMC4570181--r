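---
title: "Sparse source reconstruction for diffuse optical tomography: models, solvers and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse source reconstruction for diffuse optical tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otrecon)
```

## The problem

Bioluminescence, fluorescence and Cerenkov luminescence tomography all try
to recover an internal light-source density from light measured on the
surface of a small animal or phantom. Photon transport in tissue is highly
scattering, so the map from an internal source to boundary flux is smooth
and strongly contractive: after finite-element discretization the forward
model collapses to a single severely ill-conditioned linear system

$$A S = \Phi,$$

with $A \in \mathbb{R}^{m\times n}$ the sensitivity matrix, $S \ge 0$ the
nodal source density and $\Phi$ the boundary measurements. Measurements
are few, unknowns are many, and tiny data perturbations produce large
solution changes — some prior is indispensable. Because realistic sources
(tumors, tracer accumulations) occupy a tiny fraction of the volume,
sparsity is the natural prior, giving the $\ell_1$-regularized problem

$$\min_S\; \mu\lVert S\rVert_1 + \tfrac12\lVert AS - \Phi\rVert_2^2 .$$

## Forward model

The diffusion approximation to the radiative transfer equation is used, as
is standard for the strongly scattering regime:

$$-\nabla\!\cdot\!\big(D\,\nabla\phi\big) + \mu_a\,\phi = q
\quad\text{in }\Omega, \qquad
\phi + 2 A_n D\,\frac{\partial\phi}{\partial\nu} = 0
\quad\text{on }\partial\Omega,$$

with $D = 1/(3(\mu_a+\mu_s'))$, absorption $\mu_a$ and reduced scattering
$\mu_s'$ in mm$^{-1}$, and the Robin factor $A_n$ computed from the
tissue refractive index (default $n = 1.37$) through the usual polynomial
fit of the effective Fresnel reflectance. `assemble_diffusion_system()`
discretizes this with linear (P1) tetrahedral elements, producing a sparse
symmetric positive-definite stiffness-plus-mass operator `K` and the
consistent mass matrix `M`; a nodal source density $q$ enters as the load
$Mq$.

`build_sensitivity_matrix()` offers two row semantics:

* **emission-only** (bioluminescence/Cerenkov-like): row $(e,d)$ of $A$ is
  the fluence at detector node $d$ per unit source density at node $j$,
  i.e. $(K^{-1}M)_{dj}$, identical for all excitations;
* **excitation-weighted** (fluorescence, Born approximation): the same
  kernel weighted by the excitation fluence
  $\phi_x^{(e)}(j)$ solved from the excitation-wavelength optics with a
  point source at the excitation node.

Rows are assembled by one adjoint solve per unique detector node; `K` is
symmetric, so adjoint and forward constructions coincide (tested to
$10^{-10}$ relative).

Measured quantity: nodal fluence at the detector nodes. Converting to a
Fick-law exitance would rescale each row by a positive constant and does
not change the recovery geometry, so the simpler quantity is used.

## Phantom generator

`generate_cylinder_mesh()` builds a deterministic structured
tetrahedralization of a cylinder: concentric hexagonal rings form a
triangulated disk (ring $k$ carries $6k$ nodes), disks are stacked into
prisms, and each prism is split into three tetrahedra with quad-face
diagonals keyed to global column order so adjacent prisms conform. The
construction has no randomness at all — identical arguments give
byte-identical meshes — and its total volume matches $\pi r^2 h$ to well
under 2% at the resolutions used here.

The packaged `cylinder_4tissue` phantom reproduces a standard
heterogeneous benchmark: a cylinder 20 mm in diameter and height with
muscle background and lung/bone/heart inclusions, optical properties for
both excitation and emission wavelengths taken from the published tissue
table, and two spherical sources of radius 1 mm and unit density centered
at (6, 5, 0) and (6, −5, 0) mm. The published benchmark does not tabulate
the inclusion geometry, only a cross-sectional figure; the default layout
(`default_cylinder_layout()`) is therefore a documented qualitative
approximation — two lung cylinders, a bone column, a heart ellipsoid —
and is fully configurable. Localization accuracy is judged against the
source positions, which are exact.

**Ground truth of a discretized source.** A radius-1 mm sphere requested
at (6, 5, 0) is realized on a ~1.1 mm mesh by the set of nodes inside the
sphere (here: two nodes). The recorded ground-truth center of each source
is the density-weighted centroid of the nodes actually assigned, which
reduces to the nearest node for point (radius-0) sources. Judging against
the off-mesh request, or against the single nearest node, would penalize
even a perfect reconstruction by a fixed discretization offset (0.58 mm
at this resolution) that says nothing about the solver.

Default study conditions (all overridable): mesh edge 1.1 mm (5149 nodes,
comparable to the published 5657-node discretization), 4 excitation point
sources equally spaced on the $z=0$ boundary circle, each detected over
the opposite 160° arc of lateral boundary nodes, noiseless measurements.
The excitation count and noise level are not stated in the published
benchmark; 4 excitations is a deliberately lean choice and noiseless data
matches a reproduction of printed exact-localization results. A Gaussian
noise model (`noise_sigma_rel`) is available for robustness studies.

## Inverse solvers

### Linearized Bregman with sparse regularization

The core solver is the two-line iteration

$$v^{k+1} = v^k + A^\top(\Phi - A S^k), \qquad
  S^{k+1}_i = \delta\,\mathrm{shrink}(v^{k+1}_i, \mu),$$

with $\mathrm{shrink}(x,\gamma)=\mathrm{sign}(x)\max(|x|-\gamma,0)$, from
$v^0 = S^0 = 0$, stopping at the first
$\lVert S^{k+1}-S^k\rVert/\lVert S^k\rVert \le \varepsilon = 10^{-3}$
(the ratio is skipped while $\lVert S^k\rVert = 0$; an iteration cap
always applies). Each step needs only two matrix products and scalar
shrinkage. The shrinkage step is exactly the proximal operator of the
$\ell_1$ norm: $S^{k+1}$ minimizes
$\mu\lVert S\rVert_1 + \tfrac{1}{2\delta}\lVert S-\delta v^{k+1}\rVert^2$,
an identity the test suite checks against per-coordinate numerical
minimization on random instances.

### Parameter defaults

Neither $\mu$ nor $\delta$ has a universal value; `default_parameters()`
derives both from the data:

* $\delta = 1/\sigma_{\max}(A)^2$, with $\sigma_{\max}$ estimated by a
  fixed 100-step power iteration from a deterministic start vector. This
  is the classical non-expansiveness bound for the iteration.
* $\mu$: for consistent data the linearized Bregman iteration converges to
  the solution of the *constrained* problem
  $\min \mu\lVert S\rVert_1 + \tfrac{1}{2\delta}\lVert S\rVert_2^2$
  s.t. $AS=\Phi$, so the threshold $\mu$ must dominate the scale of
  $S/\delta$ — a threshold proportional to $\lvert A^\top\Phi\rvert$
  alone is dwarfed by the dual variable $v$ after the thousands of
  accumulation steps an ill-conditioned system needs, and the "sparse"
  solution degenerates into a dense minimum-norm one. The default is
  $\mu = 5\max_j|\tilde S_j|/\delta$, where $\tilde S$ is a cheap scale
  probe of the least-squares solution (20 plain CG steps on the normal
  equations). The rule is invariant to rescaling $\Phi$ and $A$. The
  constant 5 was calibrated once on the package's synthetic cylinder
  benchmark (values in 2–8 behave similarly; far smaller values
  under-sparsify, roughly 20 and above collapse the two sources into one
  merged atom) and is not adjusted per run.
* For the Split Bregman solver, whose $\mu$ is the weight of the
  *penalized* objective itself, the default is instead
  $\mu = 0.01\max|A^\top\Phi|$; values beyond $\max|A^\top\Phi|$ would
  annihilate the solution.
* $\varepsilon = 10^{-3}$ (the published stopping value),
  `max_iter = 5000`.

A known property of the relative-change stopping rule is that it can fire
during stagnation phases of the Bregman iteration (the dual accumulates
below threshold while the primal barely moves); the rule is kept as
published, and the iteration cap plus the residual history let users
detect such stops.

### Baselines

* `l2cg_solve()`: Tikhonov regularization
  $(A^\top A + \lambda I)S = A^\top\Phi$ by conjugate gradients. The
  default cap of 20000 iterations is deliberately generous: on the FEM
  system the tiny-$\lambda$ problem needs roughly 13000 CG iterations,
  and *semiconverged* iterates are qualitatively different (early
  iterates resemble back-projection and localize poorly).
* `l1sb_solve()`: Split Bregman with auxiliary variable $d\approx S$,
  alternating a CG solve in $S$, $d=\mathrm{shrink}(S+b,\mu\delta)$ and
  the Bregman update $b \leftarrow b + S - d$, with the same stopping
  rule.

### Column equilibration

`reconstruct()` — the fitting front end — equilibrates the columns of $A$
to unit Euclidean norm before solving and rescales the solution
afterwards (`precondition = TRUE` by default). Deep nodes have small
column norms, so without equilibration every penalized solver prefers
shallow nodes that explain boundary data with less amplitude; on the
cylinder benchmark all three solvers drift about 1 mm outward without it.
This is the standard sensitivity normalization of diffuse optical
tomography. The module-level solver functions apply no normalization, so
their published-algorithm semantics (and the closed-form test oracles)
are untouched.

### Nonnegativity

Source density is physically nonnegative, but the published iteration does
not project onto the nonnegative orthant; `solver_config(nonneg = TRUE)`
enables projection as an opt-in, default off for fidelity.

## Evaluation metrics

* **Location error**: Euclidean distance between a reconstructed source
  center and the true (snapped) center, in mm.
* **Center extraction**: nodes at or above 50% of the image maximum are
  grouped into connected components over the mesh edge graph; each
  component's center is its $S$-weighted centroid, components are ranked
  by energy (sum of $S$ times lumped nodal volume). The 50%-of-max
  threshold-centroid definition is stable under refinement and reduces to
  the peak node for single-node reconstructions.
* **CNR**:
  $\lvert \bar S_{\mathrm{ROI}}-\bar S_{\mathrm{BG}}\rvert /
  \sqrt{w_{\mathrm{ROI}}\sigma^2_{\mathrm{ROI}} +
        w_{\mathrm{BG}}\sigma^2_{\mathrm{BG}}}$,
  with volume-fraction weights and volume-weighted means/variances
  (lumped nodal volumes). The published benchmark reports CNR values but
  not the formula; this standard definition is therefore used for
  *ordering* comparisons only, never as a numeric target.
* **Matching**: true sources are paired to extracted centers greedily by
  distance without replacement — unambiguous for the two-source phantom
  and permutation-invariant.

## What the reproduction run shows — and what it cannot

`reproduce_table2()` regenerates the full two-source experiment and runs
all three solvers. On this noiseless, same-operator (inverse-crime)
benchmark the package's defaults localize both sources to well under half
a mesh edge: worst-source location error ≈ 0.14 mm for the linearized
Bregman solver and ≈ 0.01 mm for ℓ2-CG, against a nominal edge of
1.1 mm, with the contrast ordering CNR(LBSR) > CNR(ℓ1-SB) > CNR(ℓ2-CG)
(≈ 14.2 > 11.0 > 5.6 at these settings). The residual 0.14 mm offset of
the Bregman solution is sub-resolution cluster-centroid quantization, not
a systematic bias.

Two caveats delimit what passing these checks means. First, simulated
measurements come from the same discretized operator used for
reconstruction, with no model error and (by default) no noise — real data
adds both, and the fully converged tiny-$\lambda$ ℓ2 solution in
particular would degrade sharply under noise where the sparse solver
degrades gracefully. Second, one qualitative published claim inverts at
this scale: counted as "nodes above 10% of the maximum", the fully
converged equilibrated ℓ2-CG solution is *more* compact than the
Bregman solution stopped by the $10^{-3}$ rule (a dominant peak versus a
low-level halo), even though its background scatter is plainly visible in
the threefold-lower CNR. The oversmooth/scattering character of ℓ2
solutions is thus captured here by the CNR ordering, not by that
particular count.

The in-vivo murine benchmark (micro-CT segmentation, Cerenkov data) is
not redistributable; the package ships the corresponding tissue optics as
the `mouse_tissues` preset and exercises the permissible-source-region
mechanism (`restrict_psr()`, the published box
$[10,25]\times[15,35]\times[2,10]$ mm) on synthetic data only.
Reconstruction wall times are hardware-bound and are reported per run
rather than compared to published figures.

## Numerical choices and degenerate inputs

* Spatial units are mm throughout; the cylinder axis is $z$ with the
  origin at the phantom center.
* Mesh sizes used by the shipped tests: 1.1 mm edge (5149 nodes) for the
  reproduction run, 0.8 mm (14222 nodes) for the Green's-function check,
  1.6–2.0 mm for unit fixtures.
* Ties when snapping a source to a node go to the lowest node index;
  overlapping region shapes resolve to the later layout entry; sources
  overlapping on a node resolve to the later source.
* `shrink(0, γ) = 0` (the removable singularity of $x/|x|$).
* Divergent iterations (non-finite iterates, $\delta$ too large) abort
  with a diagnostic naming the iteration rather than returning garbage;
  degenerate data ($\Phi = 0$, all-zero $A$, empty PSR boxes, empty
  reconstructions) raise explicit errors or warnings.
* All randomness (measurement noise, none by default) sits behind
  explicit integer seeds; mesh generation and the power iteration are
  deterministic by construction.

## Known limitations

* The diffusion approximation is inaccurate within roughly one transport
  mean free path of sources and boundaries and in low-scattering regions;
  no radiative-transfer or Monte Carlo forward model is provided.
* Continuous-wave only: no time- or frequency-domain data, no
  multispectral stacking.
* The structured mesher handles cylinders only; arbitrary geometries must
  be imported (VTK legacy or TetGen .node/.ele).
* The default $\mu$ rule targets consistent (low-noise) data; strongly
  noisy data warrant a smaller $\mu$ or the discrepancy principle, chosen
  by the user.
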