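test_that("PDB write/read round-trips coordinates to format precision", {
  m <- make_structure(3, "helix")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(nrow(m2), nrow(m))
  expect_equal(emdense:::model_xyz(m2), emdense:::model_xyz(m),
               tolerance = 1e-3)
  expect_equal(m2$resid, m$resid)
})

test_that("UNK residues are flagged for exclusion", {
  m <- make_structure(4, "helix")
  m$resid[m$resno == 2] <- "UNK"
  f <- withr::local_tempfile(fileext = ".pdb")
  write_model(m, f)
  expect_message(m2 <- read_model(f), "UNK")
  expect_true(all(m2$unknown[m2$resno == 2]))
  expect_false(any(m2$unknown[m2$resno != 2]))
})

test_that("BIOMT records parse into symmetry operators", {
  m <- make_structure(3, "helix")
  rot <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  attr(m, "symmetry_ops") <- list(list(R = diag(3), t = c(0, 0, 0)),
                                  list(R = rot, t = c(1, 2, 3)))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_model(m, f)
  ops <- attr(read_model(f), "symmetry_ops")
  expect_length(ops, 2L)
  expect_equal(ops[[1]]$R, diag(3))
  expect_equal(ops[[2]]$R, rot, tolerance = 1e-6)
  expect_equal(ops[[2]]$t, c(1, 2, 3), tolerance = 1e-4)
})

test_that("symmetry expansion applies operators and remaps chains", {
  one <- atomic_model(tibble::tibble(
    chain = "A", resno = 1L, insert = "", resid = "ALA", elety = "CA",
    element = "C", x = 10, y = 0, z = 0, b = 0, o = 1))
  rotz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                             3, byrow = TRUE)
  c4 <- lapply(0:3, function(k) list(R = rotz(k * pi / 2), t = c(0, 0, 0)))
  out <- expand_symmetry(one, ops = c4)
  expect_equal(nrow(out), 4L)
  expect_equal(cbind(out$x, out$y, out$z),
               rbind(c(10, 0, 0), c(0, 10, 0), c(-10, 0, 0), c(0, -10, 0)),
               tolerance = 1e-8)
  expect_equal(length(unique(out$chain)), 4L)
  # identity-only set reproduces the input
  id <- expand_symmetry(one, ops = list(list(R = diag(3), t = c(0, 0, 0))))
  expect_equal(emdense:::model_xyz(id), emdense:::model_xyz(one))
  # non-orthonormal rotation rejected
  expect_error(expand_symmetry(one, ops = list(list(R = diag(3) * 2,
                                                    t = c(0, 0, 0)))),
               "orthonormal")
})

test_that("neighbor graph follows the CB distance cutoff exactly", {
  two <- function(d) atomic_model(tibble::tibble(
    chain = "A", resno = 1:2, insert = "", resid = "ALA",
    elety = "CB", element = "C", x = c(0, d), y = 0, z = 0, b = 0, o = 1))
  expect_equal(nrow(neighbor_graph(two(7.9), cutoff = 8)$edges), 1L)
  expect_equal(nrow(neighbor_graph(two(8.1), cutoff = 8)$edges), 0L)
  single <- neighbor_graph(two(5)[1, ], cutoff = 8)
  expect_equal(nrow(single$nodes), 1L)
  expect_equal(nrow(single$edges), 0L)
})

test_that("neighbor graph matches a brute-force distance check and is monotone", {
  m <- make_structure(24, "bundle")
  g <- neighbor_graph(m, cutoff = 8)
  # brute force over representative atoms
  reps <- g$rep_xyz
  d <- as.matrix(dist(reps))
  want_deg <- rowSums(d < 8) - 1L
  expect_equal(g$nodes$degree, as.integer(want_deg))
  g2 <- neighbor_graph(m, cutoff = 10)
  expect_true(all(g2$nodes$degree >= g$nodes$degree))
})

test_that("per-residue RMS is exact arithmetic in the map frame", {
  m <- make_structure(4, "helix")
  expect_true(all(per_residue_rms(m, m)$rms == 0))
  shifted <- m
  shifted$x[shifted$resno == 2] <- shifted$x[shifted$resno == 2] + 1
  r <- per_residue_rms(shifted, m)
  expect_equal(r$rms[r$resno == 2], 1.0)
  expect_true(all(r$rms[r$resno != 2] == 0))
  # 3 atoms displaced by 0, 0, 3 -> sqrt(mean(c(0,0,9))) = sqrt(3)
  a <- atomic_model(tibble::tibble(
    chain = "A", resno = 1L, insert = "", resid = "GLY",
    elety = c("N", "CA", "C"), element = c("N", "C", "C"),
    x = c(0, 2, 4), y = 0, z = 0, b = 0, o = 1))
  b <- a; b$x[3] <- b$x[3] + 3
  expect_equal(per_residue_rms(b, a)$rms, sqrt(3))
  expect_error(per_residue_rms(a, make_structure(3, "helix")[10, ]),
               "no matched")
})

test_that("ensemble deviation is invariant to rigid transforms", {
  m <- make_structure(10, "helix")
  expect_error(ensemble_deviation(list(m)), "at least 2")
  same <- ensemble_deviation(list(m, m))
  expect_lt(max(same$per_residue$rmsf), 1e-8)
  expect_lt(max(same$pairwise_rmsd), 1e-8)
  rot <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  m2 <- emdense:::set_model_xyz(m, sweep(emdense:::model_xyz(m) %*% rot, 2,
                                         c(5, -3, 2), `+`))
  dev <- ensemble_deviation(list(m, m2))
  expect_lt(max(dev$per_residue$rmsf), 1e-6)
  expect_lt(max(dev$pairwise_rmsd), 1e-6)
})

test_that("symmetry expansion scales atom count by operator count", {
  m <- make_structure(5, "helix")
  rotz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                             3, byrow = TRUE)
  ops <- lapply(c(0, 2 * pi / 3, 4 * pi / 3),
                function(a) list(R = rotz(a), t = c(0, 0, 0)))
  expect_equal(nrow(expand_symmetry(m, ops = ops)), 3L * nrow(m))
})
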