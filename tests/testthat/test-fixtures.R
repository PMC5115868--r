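test_that("structure builder is deterministic and hits its torsion targets", {
  a <- make_structure(20, "helix")
  b <- make_structure(20, "helix")
  expect_identical(a, b)
  tor <- backbone_torsions(a)
  expect_equal(tor$phi[3:18], rep(-57, 16), tolerance = 1e-6)
  expect_equal(tor$psi[3:18], rep(-47, 16), tolerance = 1e-6)
  expect_error(make_structure(2), "at least 3")
  # mixed motif produces both helix- and strand-region torsions
  mx <- backbone_torsions(make_structure(30, "mixed"))
  expect_true(any(abs(mx$phi - (-57)) < 1, na.rm = TRUE))
  expect_true(any(abs(mx$phi - (-119)) < 1, na.rm = TRUE))
  expect_true(any(mx$psi > 90, na.rm = TRUE))
})

test_that("the bundle is compact and clash-free at ideal strain", {
  m <- make_structure(120, "bundle")
  expect_lt(max(bonded_strain(m)$e_bonded), 0.1)
  expect_equal(geometry_report(m)$n_clash, 0L)
  xyz <- emdense:::model_xyz(m)
  expect_lt(max(apply(xyz, 2, function(v) diff(range(v)))), 90)
})

test_that("torsion-walk decoys land within 5% of the target RMSD", {
  m <- make_structure(60, "bundle")
  d1 <- perturb_model(m, 3.0, seed = 1)
  r1 <- attr(d1, "achieved_rmsd")
  expect_gte(r1, 2.85)
  expect_lte(r1, 3.15)
  expect_equal(emdense:::model_rmsd(d1, m), r1)
  d2 <- perturb_model(m, 3.0, seed = 2)
  expect_gt(emdense:::model_rmsd(d1, d2), 0.5) # different seeds differ
  expect_identical(perturb_model(m, 3.0, seed = 1), d1) # bit-reproducible
  expect_error(perturb_model(m, 0, seed = 1), "positive")
})

test_that("half-map noise streams are independent and vanish at zero sigma", {
  m <- fx_helix20()
  clean <- simulate_halfmaps(m, resolution = 4, voxel = 2, noise_sigma = 0)
  expect_equal(clean$train$data, clean$validation$data)
  expect_equal(clean$train$data, clean$full$data)
  noisy <- simulate_halfmaps(m, resolution = 4, voxel = 2, noise_sigma = 0.5)
  n1 <- noisy$train$data - noisy$signal$data
  n2 <- noisy$validation$data - noisy$signal$data
  expect_lt(abs(cor(as.numeric(n1), as.numeric(n2))), 0.02)
  # full map noise = average of the two streams
  expect_equal(noisy$full$data - noisy$signal$data, (n1 + n2) / 2,
               tolerance = 1e-12)
  expect_error(simulate_halfmaps(m, seeds = c(7L, 7L)), "distinct")
})

test_that("FSC between half-maps decays with frequency and rises as noise
           drops", {
  m <- fx_bundle60()
  lo <- simulate_halfmaps(m, resolution = 3, noise_sigma = 0.1)
  hi <- simulate_halfmaps(m, resolution = 3, noise_sigma = 0.8)
  cv_lo <- fsc_curve(lo$train, lo$validation, n_bins = 12)
  cv_hi <- fsc_curve(hi$train, hi$validation, n_bins = 12)
  # decay with frequency at fixed noise
  expect_gt(mean(cv_hi$fsc[1:4]), mean(cv_hi$fsc[9:12]))
  # less noise, higher correlation
  expect_gt(integrate_fsc(cv_lo, 10, 3), integrate_fsc(cv_hi, 10, 3))
})

test_that("injected errors label exactly the displaced residues", {
  m <- fx_bundle60()
  none <- inject_errors(m, list())
  expect_false(any(none$labels$is_error))
  expect_equal(none$model, m)
  inj <- inject_errors(m, list(c(20, 24)), seed = 5)
  # the span moves by the full displacement; the 2-residue taper flanks move
  # by 0.75x and 0.4x of it, so labels (RMS > 1) cover the span plus flanks
  expect_setequal(inj$labels$resno[inj$labels$is_error], 18:26)
  rms <- per_residue_rms(inj$model, m)
  expect_true(all(rms$rms[rms$resno %in% 20:24] >= 1.5))
  expect_true(all(rms$rms[rms$resno %in% c(17, 27)] == 0))
  expect_message(inject_errors(m, list(c(5, 10), c(8, 14)), seed = 1),
                 "merged")
})

test_that("strain-compensated errors keep density fit while raising strain", {
  m <- fx_bundle60()
  maps <- fx_maps60()
  inj <- inject_errors(m, list(c(8, 14)), compensate_strain = TRUE, seed = 6)
  pr <- per_residue_rscc(inj$model, maps$signal, resolution = 3)
  err_rows <- pr$resno %in% 8:14
  cc_err <- mean(pr$cc_all[err_rows], na.rm = TRUE)
  cc_ok <- mean(pr$cc_all[!err_rows], na.rm = TRUE)
  expect_lt(cc_ok - cc_err, 0.1)
  st <- bonded_strain(inj$model)
  st0 <- bonded_strain(m)
  expect_gt(mean(st$e_bonded[st$resno %in% 7:15]),
            2 * mean(st0$e_bonded[st0$resno %in% 7:15]))
  expect_true(any(inj$labels$is_error))
})
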