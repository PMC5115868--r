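---
title: "Models and methods behind emdense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind emdense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(emdense)
```

emdense implements the computational core of an automated real-space
refinement and validation workflow for atomic models in cryo-EM density:
per-residue error detection from density fit and geometric strain, voxel-size
calibration against model density, masked FSC evaluation with half-map
overfitting control, LocalRelax-style region scheduling, pre-proline
Ramachandran statistics, and half-map-driven model selection. This vignette
records the models, the tunable parameters, and the design decisions —
including where the package deliberately simplifies.

## Density model

Model density is a sum of per-atom isotropic Gaussians. An atom with element
electron count $Z$, occupancy $q$ and isotropic displacement $B$ (Å$^2$)
contributes a Gaussian of integral $Z\,q\,s_{\mathrm{aa}}$ and variance

$$\sigma^2 = \left(\frac{d}{\pi}\right)^2 + \frac{B}{8\pi^2},$$

where $d$ is the target resolution in Å and $s_{\mathrm{aa}}$ is the
sidechain scale factor (1 for backbone atoms). The resolution term is chosen
so that a $B=0$ atom's Fourier amplitude falls to $e^{-2}$ at spatial
frequency $1/d$; at the 3–4.5 Å resolutions this package targets, a single
Gaussian per atom is an adequate, fully differentiable stand-in for tabulated
scattering factors (a documented approximation — no electron scattering
tables, no anisotropic $B$).

Sidechain atoms scatter systematically less than backbone in real
reconstructions (flexibility and radiation damage); the default scale table
groups amino acids into three classes with factors 0.66 (ARG, LYS, GLU, MET,
ASP), 0.71 (CYS, GLN, HIS, ASN, THR, SER) and 0.78 (TYR, TRP, ALA, PHE, PRO,
ILE, LEU, VAL). The conversion from fitted B-factors to scales follows the
peak-height argument for a 3-D Gaussian, $s \propto B^{-3/2}$, normalised so
backbone equals 1 (`b_to_scale()`).

## Map handling

Maps are MRC2014, mode-2 float. Axis permutations are normalised to x-fastest
order on read; the origin is taken from the header origin record, falling
back to start indices × voxel. Sharpening multiplies Fourier amplitudes by
$\exp(-B s^2/4)$ (the crystallographic convention); the optional low-pass is
a half-cosine falloff over roughly one Fourier sample rather than a hard
cutoff, to avoid ringing. The $s = 0$ term is untouched, so the mean density
is preserved.

Off-grid density values and gradients use tricubic Catmull–Rom convolution:
exact at grid nodes, $C^1$, reproduces linear fields, analytic spatial
gradients. Points outside the padded support return value 0 and gradient 0,
so correlation contributions vanish outside the measured volume. (A
prefiltered interpolating B-spline would be marginally smoother; the
convolution spline satisfies every property the algorithms need at a fraction
of the complexity.)

## Per-residue error score

For each residue $i$ four standardised quantities combine into

$$Z_{\mathrm{error}}(i) = 0.45\,Z_{\mathrm{dens}}(i) + 0.05\,Z_{\mathrm{lcldens}}(i)
 + 0.15\,Z_{\mathrm{bonded}}(i) + 0.35\,Z_{\mathrm{rama}}(i),$$

with more negative meaning worse. $Z_{\mathrm{dens}}$ standardises the
absolute per-residue real-space correlation (voxels within 3 Å of the
residue's atoms, all atoms by default; backbone-only by flag);
$Z_{\mathrm{lcldens}}$ standardises the correlation after subtracting the
mean over residues within 10 Å (any-atom distance, difference normalisation
by default, ratio by flag) — robust against local-resolution variation.
$Z_{\mathrm{bonded}}$ and $Z_{\mathrm{rama}}$ standardise the negated
harmonic bond/angle/planarity strain and the Ramachandran energy. Chain
termini have no defined $(\phi,\psi)$; they contribute neutrally (zero
z-component) rather than the table mean, which would spuriously flag every
terminus as strained. Residues without density (outside the map) are excluded
from the statistics and carry a missing combined score.

Rebuild selection proceeds through cutoffs $Z < -0.5, -0.3, -0.1, 0$ —
increasing coverage, decreasing precision — with a final pass on
$Z_{\mathrm{rama}}$ alone. Selection sets nest by construction. Predictor
quality is evaluated against the RMS > 1 Å truth labelling with a
precision-recall curve; AUPRC integrates by trapezoid over recall (stated
because AUPRC values depend on the rule).

## Ramachandran potentials

Forty tables — 20 amino acids × {pre-proline, pre-non-proline} — are
estimated by periodic adaptive kernel density on a 10° grid: a
fixed-bandwidth (15°) wrapped-Gaussian pilot on the grid sets local
bandwidths $h_i = h_0 \sqrt{g / \hat p(x_i)}$ ($g$ the geometric mean pilot
density, $\lambda$ clamped to [0.3, 4]), and the final density sums
per-sample wrapped Gaussians. Energies are $-\log \max(P, P_{\mathrm{floor}})$
with $P_{\mathrm{floor}} = 10^{-7}$ per square degree. Buckets with fewer
than 100 samples fall back to the pooled same-flag table, so there are always
40 tables. The default tables are trained from the package's own synthetic
torsion sampler (mixtures of wrapped-Gaussian basins at the canonical helix,
sheet, polyproline-II and left-handed-helix positions, with glycine mirrored
and broadened and proline's $\phi$ constrained); users with real
high-resolution torsion statistics should supply them in the same TSV format.
The sampler's basin centres deliberately coincide with the structure
builder's canonical torsions so that generated structures are stationary
points of the potential — fixtures and forcefield describe the same
idealised world.

## Coordinate refinement

`minimize_into_density()` is restrained Cartesian minimisation (L-BFGS-B,
analytic gradients) of

$$E = E_{\mathrm{bonded}} + w_{\mathrm{rama}} E_{\mathrm{rama}}
 + E_{\mathrm{rep}} + w_{\mathrm{dens}}\, n_{\mathrm{res}} (1 - \mathrm{CC}_{\mathrm{local}}),$$

over the movable atoms only; everything else is bit-identical on output.
Bonded ideals are Engh–Huber-style (N–CA 1.458, CA–C 1.525, C–O 1.231,
CA–CB 1.530, C–N 1.329 Å; spring constants 300 Å$^{-2}$ for bonds, 80 rad$^{-2}$
for angles, 40 for the ω planarity torsion). Repulsion is a soft-sphere
penalty between non-bonded atoms (van der Waals radii minus a 0.4 Å
tolerance), computed with a cell list. The density term is the Pearson CC
between simulated and experimental density over voxels within 4 Å of the
movable residues, made *extensive* by the movable-residue count: a global
correlation's per-atom derivative scales as one over the model size, so
without this scaling the density force on a 200-residue model would sit two
orders of magnitude below the bonded noise floor and refinement would stall.
Per-residue density energies are extensive in exactly this sense.

`local_relax()` schedules overlapping regions: pick the unmarked residue
with the most neighbors (Cβ–Cβ < 8 Å; glycine uses Cα), let its neighbors
move backbone and sidechain and its neighbors-of-neighbors sidechain only,
minimise, mark the pick and its neighbors, repeat until all residues are
marked; four sweeps with the repulsion weight ramped 0.1/0.3/0.6/1.0 of
full. Regions above 100 residues are trimmed by distance to the pick; chains
under 20 residues are taken whole. "Sidechain-only" is realised by freezing
backbone atoms during minimisation — a documented proxy for discrete rotamer
optimisation, which this package does not implement.

`rebuild_region()` replaces fragment insertion with Metropolis Monte Carlo
over the backbone torsions of each contiguous selected span: proposals are
drawn from the residues' Ramachandran tables (70%) or local Gaussian moves
(30%), the span is rebuilt at ideal geometry from its fixed N-terminal
anchor, and states are scored by standardised local density at the rebuilt
atoms, Ramachandran energy, and a harmonic closure restraint tying the
predicted downstream backbone to its fixed position. The best state visited
is returned (so the score never worsens), runs are bit-reproducible given the
seed, and spans whose best state cannot close are left unchanged. The
proposal bias carries no Hastings correction: the sampler is used as a
stochastic optimiser, not as an equilibrium sampler. The interface is
pluggable so a true fragment engine could replace it.

## Voxel-size refinement

The experimental map's voxel size $v$ and origin $o$ are refined to maximise
the Pearson correlation between the map and the fixed calculated density
sampled at each voxel's trial world position (tricubic values and analytic
derivatives; quasi-Newton with gradient tolerance $10^{-6}$, 200-iteration
cap). Isotropic mode (1 scale + 3 origin parameters) is the default;
anisotropic (3 + 3) by option. Only the header geometry changes — map values
are never resampled on write.

`iterate_voxel_coord()` alternates coordinate refinement with voxel
refinement until the voxel estimate moves less than $10^{-4}$ Å between
cycles. Two design choices here deserve explanation:

* **Frame of the coordinate step.** By default coordinates are refined
  against the map in its *deposited* frame and the voxel estimate is a pure
  measurement against the progressively better model. If instead the
  coordinates chase the rescaled map (`refine_frame = "refined"`), a model
  with a rigid-body dilation mode — e.g. a multi-chain assembly, whose
  chains can drift apart without bonded cost — can track an erroneous scale
  estimate self-consistently, and the alternation never converges to the
  true voxel. Covalent single-domain proteins largely lack this mode, which
  is why the feedback variant works in the single-chain setting; the
  deposited-frame default is also consistent with reporting model-to-map
  metrics at deposited voxel sizes. The feedback variant remains available
  for genuinely mis-calibrated headers.
* **Non-convergence.** If the cycle cap is hit, the *last* cycle is
  returned (flagged): per-cycle CCs are scored against different models and
  are not comparable, so "best CC" would systematically re-select the first,
  most model-error-biased cycle.

`fit_rigid_chains()` provides a maximally restrained coordinate refiner —
one rotation + translation per chain, analytic torque/force gradients from
the density CC — whose chemistry (and hence absolute scale) cannot deform at
all; it is the refiner of choice when the voxel estimate itself is the
quantity of interest.

## FSC, iFSC and overfitting control

FSC uses `n_bins = 50` equal-width frequency shells to Nyquist, after
real-space multiplication by a model mask (12 Å radius, low-pass filtered to
12 Å, clipped to [0, 1]). No phase-randomisation correction of mask-induced
correlation is applied (documented limitation; the same mask is used for all
models being compared, so rankings are unaffected). iFSC is the unweighted
mean of shell correlations between 10 Å and the map's stated resolution
(coefficient-count weighting by flag). Work/free bookkeeping simulates the
model's density once and correlates it against the training and validation
half-maps under the same mask; `gap = work - free` is the overfitting
indicator. The fit-to-density weight for full-map refinement maximises
$U = \mathrm{iFSC}_{\mathrm{free}} - 0.004\,E_i$ over a candidate grid, with
$E_i$ the mean per-residue energy; ties break toward the smaller weight. The
0.004 constant normalises the two terms' dynamic ranges (one source prints
0.04; 0.004 is used, and the constant is configurable).

## Model selection

Candidates are ranked by masked validation-map iFSC (top 50), re-ranked by a
geometry composite (top 10), and the final model is the stage-2 survivor
with the best full-map iFSC; per-residue uncertainty is the Cα RMSF of the
stage-2 ensemble after iterative least-squares superposition (plain Kabsch
iteration to the mean — not a maximum-likelihood covariance model). The
geometry composite standardises, across candidates, the steric clash count
(sphere overlap > 0.4 Å), the negated fraction of residues inside the
top-98% mass region of their Ramachandran table, and mean bonded strain,
averaged with equal weights — a documented proxy for external validators; a
`geometry_scorer` hook accepts real scores. Selection is a pure function of
the score table: permuting candidates permutes only identities, ties break
by candidate id.

## The synthetic world

Every test input is generated in code, seeded:

* **Structures** are built at ideal bonded geometry from torsions (helix
  −57/−47, sheet −119/113). The "bundle" used for larger maps is an
  antiparallel arrangement of separate ~30-residue helix chains on an
  11.2 Å packing grid with continuous residue numbering. It is deliberately
  multi-chain: connecting loops built at rigid ideal geometry unavoidably
  carry 2.6–2.8 Å intra-turn contacts, and relieving those under the
  repulsion term inflates the model and aliases into every density-scale
  measurement.
* **Decoys** (`perturb_model()`) add Gaussian noise to φ/ψ per 12-residue
  window, rebuild at ideal geometry, rigidly refit each window, and bisect
  the noise scale until the all-atom RMSD lands within ±5% of target. The
  windowed walk distributes deviation along the chain the way dynamics does;
  a whole-chain walk concentrates RMSD in lever-arm end swings whose global
  character no local refinement can undo. A finishing geometry-only
  minimisation leaves decoys at the forcefield's local optimum, as
  dynamics-perturbed models are after all-atom minimisation. For experiments
  that probe rigid element displacement (the voxel-spread benchmark),
  `chain_offset` adds seeded perpendicular offsets per chain.
* **Half-maps** add independent white noise streams to the simulated signal
  (the full map carries the averaged noise, σ/√2). White noise is a
  simplification: real half-maps have frequency-dependent noise, solvent
  background and CTF residuals, so passing tests demonstrate algorithmic
  correctness, not performance on real reconstructions.
* **Injected errors** displace residue spans with a 2-residue taper (real
  misplacement decays smoothly; a sharp junction would concentrate strain on
  correctly-placed neighbors and make the labels adversarial). The
  strain-compensated mode is a register shift — a screw of one helical
  repeat (1.5 Å rise, 99.6° twist, handedness chosen so screwed Cα stay on
  the original Cα track) plus 0.25 Å in-span jitter: atoms move 2–4 Å while
  the density envelope barely changes, so the error is essentially invisible
  to density fit but glaring to the strain terms — the register-error
  phenomenology that motivates the combined score.

## Problem sizes and numerical choices

The package's own evaluation runs at sizes a single CPU handles comfortably:
the voxel-recovery benchmark uses a 200-residue bundle on a ~45×45×60 grid
at 1 Å voxel with 50 decoys and three alternation cycles; predictor
evaluation uses 60-residue fixtures over 20 seeds; the end-to-end protocol
contract runs 30–60-residue fixtures with 2–4 trajectories, 50–200 MC steps
and a 15/35/60 weight grid. Convergence tolerances: L-BFGS gradient norm
$10^{-6}$ (voxel), $10^{-4}$ Å voxel change between alternation cycles,
B-factors bounded to [0, 600] Å$^2$. Ties everywhere break toward the
smaller index or smaller parameter, so every pipeline stage is deterministic
given its seed.

## Known limitations

No rotamer library or sidechain torsion scoring (sidechains beyond Cβ are
scaled, not modelled); no symmetry-coupled minimisation (operators are
applied for scoring only); no CTF, solvent or local-resolution modelling in
the simulators; no phase-randomised mask correction; MolProbity/EMRinger are
replaced by the documented composite proxy. Quality metrics that depend on a
full all-atom force field with rotamer optimisation, or on those external
validators, are covered by directional property tests only.
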