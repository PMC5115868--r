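test_that("configuration validates its invariants", {
  cfg <- refinement_config()
  expect_equal(sum(cfg$weights), 1)
  expect_equal(cfg$schedule, c(-0.5, -0.3, -0.1, 0))
  expect_equal(cfg$mc_steps, 200L)
  expect_equal(cfg$relax_cycles, 4L)
  expect_equal(cfg$neighbor_cutoff, 8)
  expect_equal(cfg$mask_radius_fsc, 12)
  expect_equal(cfg$sharpen_b_train, -100)
  expect_equal(cfg$sharpen_b_full, -90)
  expect_error(refinement_config(schedule = c(0, -0.5)), "increasing")
  expect_error(refinement_config(weights = c(dens = 1, lcldens = 1,
                                             bonded = 0, rama = 0)), "sum")
  expect_error(refinement_config(region_min = 0L), "region")
  expect_error(refinement_config(nonsense = 1), "unknown")
})

test_that("minimisation lowers the objective, fixes a displaced residue and
           never moves immovable atoms", {
  m <- fx_bundle60()
  maps <- fx_maps60()
  inj <- inject_errors(m, list(c(30, 31)), seed = 2, displacement = 1.5)
  movable <- tibble::tibble(chain = "A", resno = 28:33, insert = "",
                            backbone = TRUE, sidechain = TRUE)
  out <- minimize_into_density(inj$model, maps$signal, movable = movable,
                               resolution = 3, max_iter = 80)
  mov_rows <- emdense:::movable_atoms(inj$model, movable)
  fixed_rows <- setdiff(seq_len(nrow(m)), mov_rows)
  expect_identical(emdense:::model_xyz(out)[fixed_rows, ],
                   emdense:::model_xyz(inj$model)[fixed_rows, ])
  pr_in <- per_residue_rscc(inj$model, maps$signal, resolution = 3)
  pr_out <- per_residue_rscc(out, maps$signal, resolution = 3)
  sel <- pr_in$resno %in% 30:31
  expect_gt(mean(pr_out$cc_all[sel]), mean(pr_in$cc_all[sel]))
  expect_error(minimize_into_density(m, maps$signal, movable =
    tibble::tibble(chain = "Z", resno = 1L, insert = "")), "empty")
})

test_that("a model at its optimum stays put and zero density weight relaxes
           strain", {
  m <- fx_helix20()
  sim <- simulate_density(m, 3, voxel = 1)
  opt <- minimize_into_density(m, sim, resolution = 3, max_iter = 40)
  expect_lt(max(abs(emdense:::model_xyz(opt) - emdense:::model_xyz(m))), 0.3)
  # strained fixture relaxes toward ideal geometry when density is off
  strained <- m
  rows <- strained$resno == 10
  strained$x[rows] <- strained$x[rows] + 0.3
  e0 <- mean(bonded_strain(strained)$e_bonded)
  rel <- minimize_into_density(strained, sim, density_weight = 0,
                               resolution = 3, max_iter = 60)
  expect_lt(mean(bonded_strain(rel)$e_bonded), e0)
})

test_that("LocalRelax visits every residue and relaxes small chains whole", {
  m <- make_structure(15, "helix")
  sim <- simulate_density(m, 3, voxel = 1)
  cfg <- refinement_config(minimize_maxit = 5L, relax_cycles = 1L)
  expect_message(out <- local_relax(m, sim, cfg, resolution = 3),
                 "whole chain")
  expect_equal(nrow(out), nrow(m))
})

test_that("LocalRelax improves a locally misfit region at least as much as a
           single global pass", {
  m <- make_structure(90, "bundle")
  sim <- simulate_density(m, 3, voxel = 1)
  sim$resolution <- 3
  inj <- inject_errors(m, list(c(40, 44)), seed = 9, displacement = 1.5)
  cfg <- refinement_config(minimize_maxit = 25L, relax_cycles = 2L,
                           region_min = 10L)
  lr <- local_relax(inj$model, sim, cfg, resolution = 3)
  gl <- minimize_into_density(inj$model, sim, resolution = 3, max_iter = 25)
  cc_of <- function(mm) {
    pr <- per_residue_rscc(mm, sim, resolution = 3)
    mean(pr$cc_all[pr$resno %in% 40:44])
  }
  expect_gte(cc_of(lr) + 0.02, cc_of(gl))
  pr0 <- per_residue_rscc(inj$model, sim, resolution = 3)
  expect_gt(cc_of(lr), mean(pr0$cc_all[pr0$resno %in% 40:44]))
})

test_that("region rebuilding is seed-reproducible, a no-op at 0 steps, and
           never worsens its score", {
  m <- fx_bundle60()
  maps <- fx_maps60()
  sel <- tibble::tibble(chain = "A", resno = 20:24, insert = "")
  same <- rebuild_region(m, maps$train, sel, fx_rama(), mc_steps = 0L,
                         seed = 1L, resolution = 3)
  expect_identical(same, m)
  inj <- inject_errors(m, list(c(20, 24)), seed = 7)
  r1 <- rebuild_region(inj$model, maps$train, sel, fx_rama(), mc_steps = 60L,
                       seed = 42L, resolution = 3)
  r2 <- rebuild_region(inj$model, maps$train, sel, fx_rama(), mc_steps = 60L,
                       seed = 42L, resolution = 3)
  expect_identical(emdense:::model_xyz(r1), emdense:::model_xyz(r2))
  # density+strain score of the rebuilt span cannot be worse than the input's
  span_cc <- function(mm) {
    pr <- per_residue_rscc(mm, maps$train, resolution = 3)
    mean(pr$cc_all[pr$resno %in% 20:24], na.rm = TRUE)
  }
  expect_gte(span_cc(r1), span_cc(inj$model) - 0.05)
  # untouched residues are bit-identical
  other <- inj$model$resno < 19 | inj$model$resno > 26
  expect_identical(emdense:::model_xyz(r1)[other, ],
                   emdense:::model_xyz(inj$model)[other, ])
})
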