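# otrecon — sparse source reconstruction for diffuse optical tomography

Optical molecular imaging modalities — bioluminescence tomography (BLT),
fluorescence molecular tomography (FMT) and Cerenkov luminescence
tomography (CLT) — reconstruct an internal light-source distribution from
light measured on the boundary of a phantom or small animal. Photon
transport in tissue is diffusive, so the discretized forward model

    A S = Φ

(`A` the FEM sensitivity matrix, `S` the nodal source density, `Φ` the
boundary flux) is severely ill-conditioned, and the inverse problem needs
a prior to be solvable at all. Because realistic sources are spatially
compact, this package regularizes with sparsity and solves

    min_S  μ‖S‖₁ + ½‖A S − Φ‖₂²

with its core solver, the **linearized Bregman iteration with sparse
regularization**: the two-line scheme

    v⁰ = S⁰ = 0
    vᵏ⁺¹ = vᵏ + Aᵀ(Φ − A Sᵏ)
    Sᵏ⁺¹ = δ · shrink(vᵏ⁺¹, μ),    shrink(x, γ) = sign(x)·max(|x| − γ, 0)

stopped at the first ‖Sᵏ⁺¹ − Sᵏ‖/‖Sᵏ‖ ≤ ε = 10⁻³ — only matrix products
and scalar shrinkage per step. Two classical baselines are included for
comparison: Tikhonov (ℓ2) regularization by conjugate gradients and the
Split Bregman ℓ1 solver.

The package is aimed at researchers prototyping or benchmarking
reconstruction algorithms for BLT/FMT/CLT: it provides the full loop of
phantom generation (a deterministic structured tetrahedral cylinder
mesher with tissue optical-property presets at excitation and emission
wavelengths), a P1 finite-element diffusion forward model with Robin
boundary conditions, boundary excitation/detector modeling, the three
inverse solvers, localization and contrast-to-noise evaluation, a
permissible-source-region mechanism, and file-based
simulate/reconstruct/evaluate pipelines (legacy VTK, TetGen .node/.ele,
CSV, JSON).

## Worked example

Reconstruct the two-source heterogeneous cylinder phantom (20 mm diameter
and height; muscle, lungs, bone and heart tissue optics; spherical
sources of radius 1 mm at (6, 5, 0) and (6, −5, 0) mm) from noiseless
fluorescence measurements taken with 4 boundary excitation sources and
160° opposite-side detector arcs:

```r
library(otrecon)

ph   <- make_phantom("cylinder_4tissue", resolution = 1.1)
det  <- place_detectors(ph$mesh, n_excitations = 4, fov_degrees = 160)
sens <- build_sensitivity_matrix(ph, det, channel = "excitation-weighted")
meas <- simulate_measurements(sens, ph$true_source_vector)

fit <- reconstruct(sens, meas, method = "lbsr")   # linearized Bregman
print(fit)
#> otrecon fit (lbsr): 1096 iterations, converged
#>   nonzero coefficients: 107 of 3689; max |S| = 0.1329
#>   final residual ||AS - Phi|| = 0.0001489

evaluate_run(ph, fit)
#> reconstruction evaluation
#>   source 1: true (6.06, 4.84, 0.00) -> recon (6.09, 4.86, 0.00), LE = 0.03 mm
#>   source 2: true (6.06, -4.84, 0.00) -> recon (6.10, -4.97, -0.00), LE = 0.14 mm
#>   CNR = 14.2; max reconstructed value = 0.1329; iterations = 1096; runtime = 86.96 s
```

The solver concentrates the reconstruction on 107 of 3689 candidate
nodes; both recovered source centers lie within 0.14 mm of the true
(mesh-snapped) centers — an order of magnitude below the 1.1 mm mesh
resolution — and the contrast-to-noise ratio of 14.2 reflects a clean
separation from the background. `reconstruct(..., method = "l2cg")` and
`method = "l1sb"` run the baselines; `reproduce_table2()` runs all three
and writes a comparison table (reconstructed centers, location error,
CNR, runtime, peak reconstructed energy per method).

The solver defaults (step size δ = 1/σ_max(A)², automatic threshold μ,
column equilibration of `A`) are derived from the data by
`default_parameters()`; every knob is overridable via `solver_config()`.
See the methods vignette (`vignettes/methods.Rmd`) for the model,
parameter rules and validation details.

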