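# emdense

Automated real-space refinement and validation of atomic models in cryo-EM
density maps, for structural biologists refining models at 3–4.5 Å
resolution and for methods developers who need the surrounding machinery —
error detection, voxel-size calibration, masked FSC bookkeeping — as
composable R functions.

At near-atomic resolution, model errors are local, systematic and easy to
overfit away. The package implements a workflow built around three ideas:

1. **Error detection from density *and* strain.** Each residue gets a
   combined score

   *Z*<sub>error</sub>(i) = 0.45 *Z*<sub>dens</sub>(i) + 0.05 *Z*<sub>lcldens</sub>(i) + 0.15 *Z*<sub>bonded</sub>(i) + 0.35 *Z*<sub>rama</sub>(i),

   standardising the absolute per-residue real-space correlation, the
   locally-normalised correlation (residues within 10 Å), the harmonic
   bond/angle/planarity strain and the Ramachandran energy (pre-proline
   conditioned, 40 kernel-density tables). Incorrectly built regions either
   drift off the density or hold the density under strain; the combined
   score sees both. Residues below the cutoffs −0.5, −0.3, −0.1, 0 are
   selected for rebuilding in successive rounds, plus a final
   Ramachandran-only pass.

2. **Voxel-size refinement.** The magnification, hence voxel size, of a
   reconstruction is uncertain at the percent level. Holding the model's
   calculated density fixed, the map's voxel size *v* and origin *o* are
   refined to maximise the real-space correlation CC(*v*, *o*), with
   tricubic-spline interpolation and analytic derivatives under L-BFGS;
   alternating with coordinate refinement converges voxel size and model
   together.

3. **Half-map overfitting control.** Refinement runs against one half-map;
   integrated FSC (mean shell correlation from 10 Å to the map resolution,
   under a 12 Å model mask) against the independent half-map ranks models,
   and the fit-to-density weight is chosen to maximise
   U = iFSC<sub>free</sub> − 0.004·E per-residue-energy. Candidates go
   through a top-50 (validation iFSC) → top-10 (geometry) → final (full-map
   iFSC) selection, with per-residue uncertainty from the ensemble spread.

Everything needed to exercise the workflow is generated in code: ideal-
geometry toy structures, seeded torsion-walk decoys with controlled RMSD,
simulated half-maps with independent noise, and injected-error models with
ground-truth labels (including register-shift errors that are invisible to
density fit but glaring to strain).

## Worked example

Simulate a misfit model and a map, detect the error, refine, and check the
voxel size:

```r
library(emdense)

native <- make_structure(60, "bundle")                 # ideal 60-residue bundle
maps <- simulate_halfmaps(native, resolution = 3, voxel = 1, noise_sigma = 0.3)

# inject a 5-residue error with ground-truth labels
bad <- inject_errors(native, list(c(28, 32)), seed = 4)

# score every residue: the worst scores sit in the displaced span (the
# 28-32 error tapers over two flanking residues, so 26 is part of it)
diag <- residue_error_score(bad$model, maps$train, resolution = 3)
diag[which.min(diag$z_error), c("chain", "resno", "z_error")]
#> # A tibble: 1 × 3
#>   chain resno z_error
#>   <chr> <int>   <dbl>
#> 1 A        26   -2.05

# a map whose header voxel is mis-set by +3% is recovered exactly
sim <- simulate_density(native, 3, voxel = 1)
bad_map <- density_map(sim$data, voxel = sim$voxel * 1.03,
                       origin = sim$origin, resolution = 3)
refine_voxel(bad_map, sim)
#> <voxel_refine_result> isotropic: voxel 1.03/1.03/1.03 -> 1.0003/1.0003/1.0003 A,
#>   CC 0.9235 -> 1.0000 (16 evals)
```

The full pipeline — per-trajectory rebuild/relax rounds against the training
half-map, validation-map selection, weight choice and full-map polishing —
runs through one call:

```r
cfg <- refinement_config(n_trajectories = 2L, mc_steps = 50L,
                         minimize_maxit = 25L, relax_cycles = 1L,
                         resolution = 3, seed = 7L)
res <- run_protocol(bad$model, maps$train, maps$validation, maps$full, cfg)
res
#> <protocol_result> 2 trajectories; chosen density weight 15; best full-map iFSC 0.947
#>   mean per-residue CC: 0.883 (start) -> 0.990 (final)
```

The printed numbers say: the chosen fit-to-density weight (15) is the one
maximising free-map agreement after energy regularisation, and the mean
per-residue correlation of the worst model rose from 0.883 to 0.990 while
the work−free iFSC gap stayed below 0.01 — improvement without overfitting.

Result objects carry `tidy()`/`glance()` methods and `autoplot()` figures
(FSC curves, per-residue error tracks, precision-recall curves, voxel-
refinement trajectories). A thin command-line wrapper for the common map
operations lives at `inst/cli/emdense.R`.

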