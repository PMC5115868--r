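test_that("B-to-scale conversion follows the -3/2 power law", {
  expect_equal(b_to_scale(50, 50), 1.0)
  expect_equal(b_to_scale(200, 50), 4^(-3 / 2)) # ratio 4 -> 0.125
  expect_equal(b_to_scale(200, 50), 0.125)
  expect_lt(b_to_scale(80, 50), b_to_scale(60, 50)) # monotone decreasing
  expect_error(b_to_scale(-1, 50), "positive")
})

test_that("the sidechain scale table has the three canonical groups", {
  tab <- sidechain_scale_table()
  expect_setequal(unique(tab$scale), c(0.66, 0.71, 0.78))
  expect_true(all(tab$scale > 0 & tab$scale <= 1))
  expect_equal(sidechain_scale("ARG"), 0.66)
  expect_equal(sidechain_scale("VAL"), 0.78)
  expect_equal(sidechain_scale("SER"), 0.71)
  expect_setequal(tab$resid[tab$scale == 0.66],
                  c("ARG", "LYS", "GLU", "MET", "ASP"))
  expect_warning(u <- sidechain_scale("XYZ"), "XYZ")
  expect_equal(u, 1.0)
})

test_that("backbone atoms are never rescaled", {
  m <- make_structure(6, "helix", sequence = "ARG")
  g <- emdense:::atom_gaussians(m, 3)
  bb <- m$elety %in% c("N", "CA", "C", "O")
  # carbon backbone atoms keep full electron weight, CB gets 0.66
  expect_equal(unique(g$weight[m$elety == "CA"]), 6)
  expect_equal(unique(g$weight[m$elety == "CB"]), 6 * 0.66)
})

test_that("simulated density is linear in occupancy and peaks at the atom", {
  a <- atomic_model(tibble::tibble(
    chain = "A", resno = 1L, insert = "", resid = "ALA", elety = "CA",
    element = "C", x = 5, y = 5, z = 5, b = 0, o = 1))
  tmpl <- density_map(array(0, c(11, 11, 11)), voxel = 1)
  d1 <- simulate_density(a, 3, template = tmpl, scales = NULL)
  peak <- which(d1$data == max(d1$data), arr.ind = TRUE)
  expect_equal(as.integer(peak[1, ]), c(6L, 6L, 6L))
  a2 <- a; a2$o <- 2
  d2 <- simulate_density(a2, 3, template = tmpl, scales = NULL)
  expect_equal(sum(d2$data), 2 * sum(d1$data), tolerance = 1e-10)
  expect_error(simulate_density(a, 1.5, template = tmpl), "Nyquist|finer")
})

test_that("an ARG sidechain atom contributes 0.66x its backbone density", {
  base <- tibble::tibble(chain = "A", resno = 1L, insert = "", resid = "ARG",
                         element = "C", x = 5, y = 5, z = 5, b = 0, o = 1)
  tmpl <- density_map(array(0, c(11, 11, 11)), voxel = 1)
  side <- simulate_density(atomic_model(cbind(base, elety = "CB")), 3,
                           template = tmpl)
  bb <- simulate_density(atomic_model(cbind(base, elety = "CA")), 3,
                         template = tmpl)
  expect_equal(side$data, 0.66 * bb$data, tolerance = 1e-12)
})

test_that("global RSCC matches the sum-formula oracle on toy grids", {
  set.seed(9)
  a <- density_map(array(sample(0:9, 64, TRUE) + 0, c(4, 4, 4)))
  b <- density_map(array(sample(0:9, 64, TRUE) + 0, c(4, 4, 4)))
  av <- as.numeric(a$data); bv <- as.numeric(b$data)
  n <- length(av)
  oracle <- (sum(av * bv) - sum(av) * sum(bv) / n) /
    sqrt((sum(av^2) - sum(av)^2 / n) * (sum(bv^2) - sum(bv)^2 / n))
  expect_equal(global_rscc(a, b), oracle, tolerance = 1e-12)
  expect_equal(global_rscc(a, a), 1.0)
  neg <- density_map(-a$data)
  expect_equal(global_rscc(a, neg), -1.0)
  flat <- density_map(array(1, c(4, 4, 4)))
  expect_error(global_rscc(a, flat), "variance")
})

test_that("global RSCC is invariant to affine intensity transforms", {
  a <- fx_noise_map(8, seed = 10)
  b <- fx_noise_map(8, seed = 11)
  r0 <- global_rscc(a, b)
  b2 <- density_map(3.7 * b$data + 12)
  expect_equal(global_rscc(a, b2), r0, tolerance = 1e-10)
})

test_that("per-residue RSCC is ~1 on self-simulated density and flags the
           displaced residue as worst", {
  m <- fx_bundle60()
  sim <- simulate_density(m, 3, voxel = 1)
  pr <- per_residue_rscc(m, sim, resolution = 3)
  expect_true(all(pr$cc_all > 0.99, na.rm = TRUE))
  bad <- m
  rows <- bad$resno == 30
  bad$x[rows] <- bad$x[rows] + 3
  pr2 <- per_residue_rscc(bad, sim, resolution = 3)
  expect_equal(pr2$resno[which.min(pr2$cc_all)], 30L)
})

test_that("B-factor fitting recovers a uniform B and responds to blurring", {
  m <- make_structure(8, "helix")
  m$b <- 50
  target <- simulate_density(m, 3, voxel = 1, padding = 6)
  start <- m
  start$b <- rep(25, nrow(m))
  fit <- suppressWarnings(fit_bfactors(start, target, resolution = 3))
  expect_lt(abs(median(fit$b) - 50), 10)
  # blurring the map raises the fitted B
  blurred <- sharpen_map(target, 60)
  blurred$resolution <- 3
  fit2 <- suppressWarnings(fit_bfactors(start, blurred, resolution = 3))
  expect_gt(median(fit2$b), median(fit$b))
  # fitted B survives a PDB round trip in the B column
  f <- withr::local_tempfile(fileext = ".pdb")
  write_model(fit, f)
  expect_equal(read_model(f)$b, round(fit$b, 2), tolerance = 0.01)
})
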