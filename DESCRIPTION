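Package: emdense
Title: Automated Real-Space Refinement and Validation of Atomic Models in Cryo-EM Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for refining and validating atomic models against cryo-EM
    density maps. Implements per-residue error detection combining density fit
    and geometric strain Z-scores, voxel-size and origin refinement against
    model-derived density, sidechain-aware model density simulation, masked
    Fourier shell correlation (FSC) and integrated-FSC evaluation with
    half-map overfitting control, pre-proline-conditioned Ramachandran
    potentials estimated by periodic adaptive kernel density, LocalRelax
    overlapping-region coordinate optimization, Monte Carlo region rebuilding,
    and half-map-driven model selection. Includes seeded synthetic-fixture
    generators (toy structures, torsion-walk decoys, simulated half-maps with
    independent noise, injected-error models with ground-truth labels) so the
    whole protocol can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
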