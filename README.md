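# spfdeeg

EEG source localization with a finite-difference volume conductor and
matching pursuit, in R.

`spfdeeg` is for researchers who want a self-contained, inspectable
implementation of the full EEG source-localization chain on voxelized head
models:

1. **Forward problem** — the quasi-static Poisson equation
   ∇·(σ∇φ) = −∇·**J** discretized with the scalar-potential
   finite-difference (SPFD) scheme: potentials on voxel-corner nodes,
   Kirchhoff's current law per node, edge conductances S = σ̄·h from the
   arithmetic mean of the four flanking voxel conductivities. Solved by SOR
   or geometric multigrid (V-cycles with SOR smoothing, optionally as a CG
   preconditioner) to a relative residual below 10⁻⁶.
2. **Lead field by reciprocity** — the M × 3N matrix L mapping gray-matter
   dipole moments to ground-referenced electrode potentials, built with one
   forward solve per non-ground electrode (74 solves for the 75-electrode
   10-10 system) instead of 3N dipole solves.
3. **Inverse problem** — greedy matching pursuit: score every lead-field
   column by corrcoef(i) = φ·Lᵢ/(‖φ‖‖Lᵢ‖), take the argmax as the source
   location/orientation, optionally iterate on residuals for multiple
   sources, and reconstruct the full current-density distribution by
   re-solving the forward problem at the estimate.
4. **Phantoms and evaluation** — layered-sphere head phantoms in four
   conductivity variants (segmented, homogeneous, CSF-insert, and a
   smoothed "segmentation-free" model), 10-20/10-10 electrode montages
   placed by the proportional scheme, and a Monte-Carlo harness measuring
   localization error under Gaussian noise at chosen SNRs, with summary
   statistics and pairwise t-tests.

Everything runs at desk scale (2 mm voxels by default, 0.5 mm supported)
with no external data: the phantom module generates all inputs.

## Worked example

A five-shell sphere (skin / skull / CSF / gray / white), a 10-20 montage,
a reciprocity lead field, and one localized dipole:

```r
library(spfdeeg)

labels  <- make_layered_sphere(spacing = 2, radii_mm = c(30, 26, 22, 20, 12))
sigma   <- assign_conductivity(labels)       # tabulated tissue values, S/m
gm      <- gray_matter_index(labels)
montage <- place_montage(labels, "10-20")
#> <tissue_volume> 33 x 33 x 33 voxels @ 2 mm; 13997 head voxels, 5 tissues
#> <gm_index> N = 3244 gray-matter voxels
#> <electrode_montage> 10-20 system, 21 electrodes, ground Fp1

L <- build_lfm(sigma, montage, gm)           # 20 reciprocal forward solves
#> <leadfield> 21 electrodes x 9732 columns (N = 3244 gray voxels), 20 reciprocal solves

# a test dipole in gray matter, solved forward:
src <- voxel_dipole_term(sigma$grid, gm$voxel_list[1500, ], axis = "+y", gm = gm)
sol <- solve_multigrid(sigma, src)
#> <spfd_solution> multigrid(cg): 8 iterations, relative residual 9.88e-07
phi <- reference_potentials(sol, montage)

mp_localize(L, phi)                          # noise-free: exact recovery
#> <mp_fit> column 4499 -> voxel 1500, axis +y at (-2.0, 14.0, 6.0) mm, corr 1.0000
```

The estimate names the lead-field column, the gray-matter voxel, the dipole
axis with polarity, the location in head coordinates (here exactly the true
voxel center, correlation 1 — with matched models and no noise the scalp
pattern *is* a lead-field column), and the winning correlation. Under noise
the same call degrades gracefully; a small Monte-Carlo run quantifies it:

```r
rep <- run_experiment(sigma, list(anatomical = L), n_trials = 20,
                      snr_db = c(Inf, 10, 0), seed = 1)
summarize_report(rep)
#> Localization error by model / montage / SNR:
#>       model montage snr_db  n        mean_sd max_error_mm frac_below_10mm depth_error_corr
#>  anatomical   10-20    Inf 20  0.00 +/- 0.00          0.0            1.00               NA
#>  anatomical   10-20     10 20  5.47 +/- 5.12         18.5            0.75           -0.135
#>  anatomical   10-20      0 20 16.04 +/- 9.86         34.9            0.30           -0.369
```

Mean error is 0 mm at infinite SNR and grows as the noise floor rises;
`compare_models()` turns two such reports into a pooled two-sample t-test.

A thin command-line front end over the same functions lives in
`inst/cli/spfdeeg.R` (subcommands `phantom`, `montage`, `forward`,
`leadfield`, `localize`, `evaluate`; NIfTI volumes, CSV electrode tables,
YAML experiment configs, JSON results with per-run manifests).

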