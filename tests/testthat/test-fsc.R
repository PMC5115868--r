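test_that("FSC of a map with itself is 1 in every shell", {
  m <- fx_noise_map(16, seed = 20)
  cv <- fsc_curve(m, m, n_bins = 10)
  expect_true(all(abs(cv$fsc - 1) < 1e-10))
  expect_true(all(diff(cv$freq) > 0))
})

test_that("FSC against independent noise fluctuates about zero", {
  a <- fx_noise_map(64, seed = 21)
  b <- fx_noise_map(64, seed = 22)
  cv <- fsc_curve(a, b, n_bins = 20)
  expect_lt(abs(mean(cv$fsc)), 0.05)
})

test_that("FFT-shell FSC equals a brute-force DFT oracle on 16^3 grids", {
  set.seed(23)
  n <- 16L
  a <- array(rnorm(n^3), c(n, n, n))
  b <- array(rnorm(n^3), c(n, n, n)) + 0.5 * a
  # brute-force DFT via explicit DFT matrix per axis
  wmat <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  dft3 <- function(x) {
    y <- apply(x, c(2, 3), function(v) wmat %*% v)
    dim(y) <- c(n, n, n)
    y <- aperm(apply(y, c(1, 3), function(v) wmat %*% v), c(2, 1, 3))
    y <- aperm(apply(y, c(1, 2), function(v) wmat %*% v), c(2, 3, 1))
    y
  }
  fa <- dft3(a); fb <- dft3(b)
  freq <- emdense:::fft_freqs(n, 1)
  s <- sqrt(outer(outer(freq^2, freq^2, `+`), freq^2, `+`))
  ds <- 0.5 / 8
  bin <- pmin(pmax(ceiling(as.numeric(s) / ds), 1L), 9L)
  keep <- bin <= 8 & as.numeric(s) > 0
  oracle <- vapply(1:8, function(k) {
    sel <- keep & bin == k
    Re(sum(fa[sel] * Conj(fb[sel]))) /
      sqrt(sum(Mod(fa[sel])^2) * sum(Mod(fb[sel])^2))
  }, numeric(1))
  got <- fsc_curve(density_map(a), density_map(b), n_bins = 8)
  expect_equal(got$fsc, oracle, tolerance = 1e-8)
})

test_that("FSC is symmetric and scale-invariant", {
  a <- fx_noise_map(12, seed = 24)
  b <- density_map(a$data + array(rnorm(12^3), c(12, 12, 12)))
  expect_equal(fsc_curve(a, b, 6)$fsc, fsc_curve(b, a, 6)$fsc)
  b3 <- density_map(4.2 * b$data)
  expect_equal(fsc_curve(a, b3, 6)$fsc, fsc_curve(a, b, 6)$fsc,
               tolerance = 1e-12)
})

test_that("integrated FSC averages the in-range shells", {
  cv <- tibble::tibble(freq = c(0.05, 0.12, 0.16, 0.2, 0.24),
                       fsc = c(1.0, 0.8, 0.6, 0.4, 0.2),
                       n_coef = rep(10L, 5))
  # range 10 A -> 4 A covers shells at 0.12..0.24
  expect_equal(integrate_fsc(cv, low_res = 10, high_res = 4), 0.5)
  # all five shells: (1+0.8+0.6+0.4+0.2)/5 = 0.6
  expect_equal(integrate_fsc(cv, low_res = 25, high_res = 4), 0.6)
  cv1 <- tibble::tibble(freq = seq(0.1, 0.3, length.out = 5),
                        fsc = rep(1, 5), n_coef = rep(1L, 5))
  expect_equal(integrate_fsc(cv1, 10, 3.4), 1.0)
  cv05 <- cv1; cv05$fsc <- rep(0.5, 5)
  expect_equal(integrate_fsc(cv05, 10, 3.4), 0.5)
  expect_error(integrate_fsc(cv1, 3.4, 10), "coarser")
  expect_error(integrate_fsc(cv1, 100, 50), "no FSC shells")
})

test_that("integrated FSC is monotone in shell values", {
  cv <- tibble::tibble(freq = seq(0.11, 0.28, length.out = 6),
                       fsc = runif(6), n_coef = rep(1L, 6))
  base <- integrate_fsc(cv, 10, 3.4)
  cv$fsc[3] <- cv$fsc[3] + 0.1
  expect_gt(integrate_fsc(cv, 10, 3.4), base)
})

test_that("work and free iFSC agree on identical half-maps and split with
           independent noise", {
  m <- fx_bundle60()
  maps <- fx_maps60()
  same <- fsc_work_free(m, maps$train, maps$train, resolution = 3)
  expect_equal(same$gap, 0)
  wf <- fsc_work_free(m, maps$train, maps$validation, resolution = 3)
  # model refined against neither map: no overfitting signal
  expect_lt(abs(wf$gap), 0.02)
})

test_that("a model fit to the training map's noise shows a positive gap", {
  m <- fx_bundle60()
  maps <- fx_maps60()
  overfit <- minimize_into_density(m, maps$train, resolution = 3,
                                   density_weight = 250, max_iter = 40)
  wf <- fsc_work_free(overfit, maps$train, maps$validation, resolution = 3)
  expect_gt(wf$gap, 0)
})

test_that("density-weight choice maximises U with ties to the smaller weight", {
  cand <- tibble::tibble(weight = c(10, 20), ifsc_free = c(0.60, 0.62),
                         energy = c(10, 20))
  expect_equal(choose_density_weight(cand), 10) # U = 0.56 vs 0.54
  expect_equal(choose_density_weight(cand[2, ]), 20)
  expect_equal(choose_density_weight(cand, c_energy = 0), 20) # pure argmax
  tie <- tibble::tibble(weight = c(30, 15), ifsc_free = c(0.5, 0.5),
                        energy = c(0, 0))
  expect_equal(choose_density_weight(tie), 15)
  expect_error(choose_density_weight(cand[0, ]), "no candidate")
})
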