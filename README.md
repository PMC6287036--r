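# ecgpose

Beat-by-beat tracking of the heart's position and orientation inside the
torso from simultaneous heart-surface and body-surface potential recordings.

## The problem

Electrocardiographic forward models — and the ECGI inverse solutions built on
them — assume the heart's location inside the torso is known. It is not: the
heart translates vertically and rotates about its atrial tether with every
breath, and experimental preparations carry registration error of their own.
`ecgpose` estimates, for every heartbeat *b*, the six-parameter rigid pose
`p_b = (tx, ty, tz, θ, φ, ρ)` (translation in mm; pitch, yaw, roll in
radians, defined on an anatomical anchor point and septal axis) by solving
the bound-constrained nonlinear least-squares problem

    p̂_b = argmin_{p ∈ Ξ}  Σ_t ‖ y_b(t) − A(p) x_b(t) ‖²

where `x_b(t)` are heart-surface potentials, `y_b(t)` body-surface
potentials, `A(p)` the boundary-element (BEM) transfer matrix of the heart
moved to pose `p`, and `Ξ` a feasibility box that keeps the heart from
intersecting the torso surface. The corrected forward matrix `A(p̂_b)`
improves both forward-computed body-surface potentials and Tikhonov inverse
reconstructions of heart potentials.

The package contains everything needed end to end: mesh I/O and geometry
predicates (OFF / ASCII VTK, watertightness, intersection tests), the
linear-collocation BEM solver with analytic solid-angle integrals, the pose
kinematics and feasible-box certification, the per-beat optimizer, a
zero-order Tikhonov inverse with per-beat L-curve selection of λ, evaluation
metrics (relative error, node RMSD), and a synthetic respiratory-motion
generator used for validation.

## A worked example

Simulate a respiratory trajectory (10 poses, half-cosine vertical translation
up to 20 mm plus 10° pitch), synthesize body-surface potentials through the
BEM forward model, add Gaussian noise at SNR 30 dB, and recover each beat's
pose starting from the nominal (static) geometry:

```r
library(ecgpose)

res <- run_synthetic_experiment(n_beats = 10, n_reps = 3, snr_db = 30,
                                seed = 1, evaluate = FALSE)
rmsd <- res$rmsd
round(c(nominal_mean = mean(rmsd$rmsd_nominal),
        nominal_max  = max(rmsd$rmsd_nominal),
        corrected_mean = mean(rmsd$rmsd_corrected),
        corrected_max  = max(rmsd$rmsd_corrected)), 3)
#>   nominal_mean    nominal_max corrected_mean  corrected_max
#>          9.905         18.131          0.106          0.252
```

The static geometry is wrong by up to ~18 mm at maximal inhale; after
per-beat correction the heart mesh lands within a fraction of a millimetre
of the truth (node RMSD, combining translation and rotation error over all
heart nodes). Individual fits are standard model objects:

```r
fit <- res$fits[[1]]
coef(fit)          # the six estimated pose parameters
summary(fit)       # objective decrease, BSP relative error, pose error
predict(fit)       # torso potentials synthesized at the corrected pose
plot(res$fits)     # estimated vertical translation across the beats
```

Lower-level entry points mirror the pipeline stages:
`read_mesh()` / `write_mesh()`, `anatomical_frame()`, `compute_bounds()`,
`assemble_transfer_matrix()` / `transfer_at_pose()`, `correct_pose()` /
`correct_all_beats()`, `tikhonov_inverse()` / `lcurve_select()`,
`moving_average()` / `extract_qrs()` / `relative_error()`,
`evaluate_experiment()`, and `write_dataset()` / `read_dataset()` for
on-disk bundles (OFF meshes, delimited-text potentials, YAML manifest). A
thin command-line front end over the same functions ships in
`inst/cli/ecgpose.R` with `simulate`, `correct` and `evaluate` subcommands.

See the vignette (`vignettes/geometry-correction.Rmd`) for the model, the
numerical design of the BEM solver, and the exact synthetic study
conditions.

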