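test_that("Ramachandran tables recover a single wrapped-Gaussian basin", {
  set.seed(30)
  n <- 400
  samples <- tibble::tibble(
    aa = "ALA",
    phi = rnorm(n, -60, 8), psi = rnorm(n, -40, 8),
    next_is_pro = FALSE)
  pot <- suppressMessages(build_rama_potential(samples))
  tab <- pot$tables[["ALA|npre"]]
  peak <- which(tab$p == max(tab$p), arr.ind = TRUE)
  expect_lt(abs(pot$centers[peak[1]] - (-60)), 10.01) # within one grid cell
  expect_lt(abs(pot$centers[peak[2]] - (-40)), 10.01)
})

test_that("tables are normalised probabilities over the torus", {
  pot <- fx_rama()
  expect_length(pot$tables, 40L)
  cell <- pot$spacing^2
  sums <- vapply(pot$tables, function(t) sum(t$p) * cell, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(vapply(pot$tables, function(t) all(t$p >= 0), logical(1))))
  # energies bounded above via the probability floor
  emax <- -log(pot$p_floor)
  expect_true(all(vapply(pot$tables, function(t) all(t$e <= emax + 1e-9),
                         logical(1))))
})

test_that("uniform samples give a near-uniform table", {
  set.seed(31)
  n <- 2000
  samples <- tibble::tibble(aa = "GLY", phi = runif(n, -180, 180),
                            psi = runif(n, -180, 180), next_is_pro = FALSE)
  pot <- suppressMessages(build_rama_potential(samples))
  p <- pot$tables[["GLY|npre"]]$p
  u <- 1 / 360^2
  # adaptive-bandwidth KDE speckles a flat density; bound the worst cell and
  # the average deviation
  expect_lt(max(abs(p - u)) / u, 0.8)
  expect_lt(mean(abs(p - u)) / u, 0.2)
  expect_error(build_rama_potential(samples[0, ]), "no torsion samples")
})

test_that("KDE tables converge with sample size (KL decreases)", {
  draw <- function(n, seed) {
    set.seed(seed)
    comp <- sample(2, n, TRUE)
    tibble::tibble(aa = "LEU",
                   phi = rnorm(n, c(-60, -120)[comp], 10),
                   psi = rnorm(n, c(-45, 120)[comp], 10),
                   next_is_pro = FALSE)
  }
  big <- suppressMessages(build_rama_potential(draw(6000, 1)))$tables[["LEU|npre"]]$p
  kl <- function(n, seed) {
    p <- suppressMessages(build_rama_potential(draw(n, seed)))$tables[["LEU|npre"]]$p
    sum(big * log(pmax(big, 1e-12) / pmax(p, 1e-12)))
  }
  expect_lt(mean(c(kl(800, 11), kl(800, 12))),
            mean(c(kl(200, 11), kl(200, 12))))
})

test_that("pre-proline residues use their own conditioned table", {
  pot <- fx_rama()
  # construct a potential whose pre/npre ALA tables differ in one known cell
  pot2 <- pot
  tab <- pot2$tables[["ALA|pre"]]
  # raise the 4 cells around (-57, -47) so bilinear interpolation sees them
  iphi <- order(abs(pot2$centers - (-57)))[1:2]
  ipsi <- order(abs(pot2$centers - (-47)))[1:2]
  tab$e[iphi, ipsi] <- 500
  pot2$tables[["ALA|pre"]] <- tab
  m <- make_structure(5, "helix", sequence = c("ALA", "ALA", "PRO", "ALA", "ALA"))
  e <- rama_energy(m, pot2)
  e_ref <- rama_energy(m, pot)
  # residue 2 precedes PRO -> hits the modified pre-proline table; residue 4
  # (same torsions, not pre-PRO) is untouched
  expect_gt(e$e_rama[2], e_ref$e_rama[2] + 100)
  expect_equal(e$e_rama[4], e_ref$e_rama[4])
})

test_that("termini are flagged and residues at the table maximum score the
           minimum energy", {
  pot <- fx_rama()
  m <- make_structure(6, "helix")
  e <- rama_energy(m, pot)
  expect_false(e$defined[1])
  expect_false(e$defined[6])
  expect_true(all(e$defined[2:5]))
  tab <- pot$tables[["ALA|npre"]]
  peak <- which(tab$p == max(tab$p), arr.ind = TRUE)
  m2 <- make_structure(5, "helix", sequence = "ALA")
  tor_target <- c(pot$centers[peak[1]], pot$centers[peak[2]])
  m3 <- emdense:::build_backbone(rep(tor_target[1], 5), rep(tor_target[2], 5),
                                 rep(180, 5), rep("ALA", 5))
  e3 <- rama_energy(m3, pot)
  expect_equal(e3$e_rama[3], min(tab$e), tolerance = 1e-8)
})

test_that("glycine and non-glycine tables differ at identical angles", {
  pot <- fx_rama()
  ga <- rama_energy(make_structure(5, "helix", sequence = "GLY"), pot)
  aa <- rama_energy(make_structure(5, "helix", sequence = "ALA"), pot)
  expect_false(isTRUE(all.equal(ga$e_rama[3], aa$e_rama[3])))
})

test_that("bonded strain is zero at ideal geometry and exact for a stretch", {
  m <- fx_helix20()
  s <- bonded_strain(m)
  expect_true(all(s$e_bonded < 0.1)) # built at ideals
  # stretch one N-CA bond (intra-residue term) by 0.1 A
  m2 <- m
  row <- which(m2$resno == 10 & m2$elety == "N")
  ca <- which(m2$resno == 10 & m2$elety == "CA")
  dir <- c(m2$x[row] - m2$x[ca], m2$y[row] - m2$y[ca], m2$z[row] - m2$z[ca])
  dir <- dir / sqrt(sum(dir^2))
  m2$x[row] <- m2$x[row] + 0.1 * dir[1]
  m2$y[row] <- m2$y[row] + 0.1 * dir[2]
  m2$z[row] <- m2$z[row] + 0.1 * dir[3]
  s2 <- bonded_strain(m2)
  gained <- s2$e_bonded - s$e_bonded
  # bond term alone adds 300 * 0.1^2 / 2 = 1.5 on residue 10 (angles at N
  # and CA shift a little too, so compare the bond part with slack)
  expect_gt(gained[s2$resno == 10], 1.4)
  # locality: only residues 9-11 can change (shared terms)
  expect_true(all(abs(gained[!s2$resno %in% 9:11]) < 1e-9))
  expect_true(all(s2$e_bonded >= 0))
})

test_that("geometry report counts sphere overlaps and scores an ideal helix
           clash-free", {
  m <- fx_helix20()
  rep1 <- geometry_report(m)
  expect_equal(rep1$n_clash, 0L)
  expect_gt(rep1$frac_rama_favored, 0.9)
  expect_lt(rep1$mean_strain, 0.1)
  # two carbons 1.0 A apart on distant residues -> one clash
  clashy <- atomic_model(tibble::tibble(
    chain = "A", resno = c(1L, 5L), insert = "", resid = "ALA",
    elety = "CA", element = "C", x = c(0, 1), y = 0, z = 0, b = 0, o = 1))
  rep2 <- geometry_report(clashy)
  expect_equal(rep2$n_clash, 1L)
})

test_that("rama tables survive text serialisation", {
  pot <- fx_rama()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rama_potential(pot, f)
  pot2 <- read_rama_potential(f)
  expect_length(pot2$tables, 40L)
  expect_equal(pot2$tables[["ALA|npre"]]$p, pot$tables[["ALA|npre"]]$p,
               tolerance = 1e-6)
  expect_equal(pot2$centers, pot$centers)
})
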