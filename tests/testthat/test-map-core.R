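test_that("MRC write/read round-trips grid values and geometry", {
  set.seed(1)
  m <- density_map(array(rnorm(8^3), c(8, 8, 8)), voxel = 1.5,
                   origin = c(-3, 2, 7.5))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, f)
  m2 <- read_map(f)
  expect_equal(m2$data, m$data, tolerance = 1e-6)
  expect_equal(m2$voxel, c(1.5, 1.5, 1.5))
  expect_equal(m2$origin, c(-3, 2, 7.5), tolerance = 1e-6)
  # second round trip is bit-exact (values already float32)
  f2 <- withr::local_tempfile(fileext = ".mrc")
  write_map(m2, f2)
  expect_identical(read_map(f2)$data, m2$data)
})

test_that("origin falls back to start indices times voxel", {
  # hand-written header: nstart (-4,-4,-4), voxel 2, zero origin record
  f <- withr::local_tempfile(fileext = ".mrc")
  con <- file(f, "wb")
  writeBin(as.integer(c(4, 4, 4, 2, -4, -4, -4, 4, 4, 4)), con, size = 4L,
           endian = "little")
  writeBin(as.numeric(c(8, 8, 8, 90, 90, 90)), con, size = 4L, endian = "little")
  writeBin(1:3, con, size = 4L, endian = "little")
  writeBin(numeric(3), con, size = 4L, endian = "little")
  writeBin(c(1L, 0L), con, size = 4L, endian = "little")
  writeBin(integer(25), con, size = 4L, endian = "little")
  writeBin(numeric(3), con, size = 4L, endian = "little") # zero origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  writeBin(0, con, size = 4L, endian = "little")
  writeBin(0L, con, size = 4L, endian = "little")
  writeBin(raw(800), con)
  writeBin(as.numeric(1:64), con, size = 4L, endian = "little")
  close(con)
  m <- read_map(f)
  expect_equal(m$origin, c(-8, -8, -8))
  expect_equal(m$voxel, c(2, 2, 2))
})

test_that("malformed and truncated map files raise format errors", {
  f <- withr::local_tempfile(fileext = ".mrc")
  writeBin(as.raw(1:100), f)
  expect_error(read_map(f), "header|truncated")
  expect_error(read_map(tempfile()), "not found")
})

test_that("axis-permuted maps are normalised to canonical order", {
  # file stored with mapc/mapr/maps = 2,1,3 (column index runs along y)
  arr <- array(as.numeric(1:24), c(2, 3, 4)) # file axes: (y=2, x=3, z=4)
  f <- withr::local_tempfile(fileext = ".mrc")
  con <- file(f, "wb")
  writeBin(as.integer(c(2, 3, 4, 2, 0, 0, 0, 3, 2, 4)), con, size = 4L,
           endian = "little") # mx,my,mz follow crystal x,y,z
  writeBin(as.numeric(c(3, 2, 4, 90, 90, 90)), con, size = 4L, endian = "little")
  writeBin(c(2L, 1L, 3L), con, size = 4L, endian = "little")
  writeBin(numeric(3), con, size = 4L, endian = "little")
  writeBin(c(1L, 0L), con, size = 4L, endian = "little")
  writeBin(integer(25), con, size = 4L, endian = "little")
  writeBin(numeric(3), con, size = 4L, endian = "little")
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  writeBin(0, con, size = 4L, endian = "little")
  writeBin(0L, con, size = 4L, endian = "little")
  writeBin(raw(800), con)
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  close(con)
  m <- read_map(f)
  expect_equal(dim(m$data), c(3L, 2L, 4L))
  expect_equal(m$data[, , 1], t(arr[, , 1])) # x fastest after normalisation
  expect_equal(m$voxel, c(1, 1, 1))
})

test_that("B-factor scaling is exact on an analytic sinusoid", {
  n <- 40L
  x <- (0:(n - 1)) # voxel 1 A
  per <- 5
  arr <- array(rep(sin(2 * pi * x / per), n * n), c(n, n, n))
  m <- density_map(arr, voxel = 1)
  sh <- sharpen_map(m, b_factor = -100)
  # amplitude factor exp(100 * (1/5)^2 / 4) = e
  expect_equal(max(abs(sh$data)) / max(abs(m$data)), exp(1), tolerance = 1e-6)
  # b = 0, no low-pass: identity
  id <- sharpen_map(m, 0)
  expect_lt(max(abs(id$data - m$data)), 1e-10)
})

test_that("sharpening inverts and preserves the mean", {
  m <- fx_noise_map(12, seed = 3)
  sh <- sharpen_map(m, -80)
  back <- sharpen_map(sh, 80)
  expect_lt(max(abs(back$data - m$data)) / max(abs(m$data)), 1e-6)
  expect_equal(mean(sh$data), mean(m$data), tolerance = 1e-10)
})

test_that("low-pass filtering validates against Nyquist and attenuates", {
  m <- fx_noise_map(16, seed = 4)
  expect_error(sharpen_map(m, 0, lowpass_resolution = 1.5), "Nyquist")
  lp <- sharpen_map(m, 0, lowpass_resolution = 6)
  f_hi <- abs(fft(lp$data))
  f_in <- abs(fft(m$data))
  s <- sqrt(emdense:::freq_sq_grid(m))
  hi <- s > 1 / 4
  expect_lt(mean(f_hi[hi]), 0.05 * mean(f_in[hi]))
})

test_that("model masks are binary geometry, clipped and idempotent", {
  mdl <- tibble::tibble(chain = "A", resno = 1L, insert = "", resid = "ALA",
                        elety = "CA", element = "C", x = 5, y = 5, z = 5,
                        b = 0, o = 1)
  tmpl <- density_map(array(0, c(11, 11, 11)), voxel = 1)
  msk <- make_mask(mdl, tmpl, mask_radius = 2)
  expect_equal(msk$data[6, 6, 6], 1) # at the atom
  expect_equal(msk$data[6, 6, 8], 1) # 2 A away
  expect_equal(msk$data[6, 6, 9], 0) # 3 A away
  expect_true(all(msk$data %in% c(0, 1)))
  filt <- make_mask(mdl, tmpl, mask_radius = 2, filter_resolution = 4)
  expect_true(all(filt$data >= 0 & filt$data <= 1))
  expect_error(make_mask(mdl[0, ], tmpl, 2), "empty")
})

test_that("FSC mask at the default radius stays high at atom centres", {
  mdl <- fx_helix20()
  tmpl <- simulate_density(mdl, 4, voxel = 2, padding = 14)
  # before filtering the mask is exactly 1 at the voxel under every atom
  hard <- make_mask(mdl, tmpl, mask_radius = 12)
  idx <- round(sweep(sweep(emdense:::model_xyz(mdl), 2, tmpl$origin),
                     2, tmpl$voxel, `/`)) + 1
  expect_true(all(hard$data[idx] == 1))
  # the 12 A cosine-edge filter erodes a small object's edges but atoms stay
  # well inside the soft mask
  msk <- make_mask(mdl, tmpl, mask_radius = 12, filter_resolution = 12)
  at_atoms <- interpolate_map(msk, emdense:::model_xyz(mdl))$value
  expect_true(all(at_atoms > 0.6))
  expect_gt(mean(at_atoms), 0.8)
  expect_true(all(msk$data >= 0 & msk$data <= 1))
})

test_that("interpolation is exact at nodes and on linear ramps", {
  set.seed(5)
  arr <- array(rnorm(10^3), c(10, 10, 10))
  m <- density_map(arr, voxel = 2, origin = c(1, 1, 1))
  # node (4,5,6) in array indexing -> world origin + (idx-1)*voxel
  p <- c(1, 1, 1) + (c(4, 5, 6) - 1) * 2
  expect_equal(interpolate_map(m, p)$value, arr[4, 5, 6])
  ramp <- array(0, c(10, 10, 10))
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    ramp[i, j, k] <- 0.3 * i - 1.2 * j + 2 * k
  }
  mr <- density_map(ramp, voxel = 1)
  set.seed(6)
  pts <- matrix(runif(30, 2, 7), 10)
  got <- interpolate_map(mr, pts)$value
  want <- 0.3 * (pts[, 1] + 1) - 1.2 * (pts[, 2] + 1) + 2 * (pts[, 3] + 1)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("interpolation gradients pass finite-difference checks", {
  n <- 20
  g <- array(0, c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    g[i, j, k] <- exp(-((i - 10)^2 + (j - 9)^2 + (k - 11)^2) / 30)
  }
  m <- density_map(g, voxel = 1.3, origin = c(-2, 0, 1))
  set.seed(7)
  pts <- matrix(runif(15, 5, 15), 5) * 1.3
  r <- interpolate_map(m, pts)
  h <- 1e-5
  for (ax in 1:3) {
    pp <- pts; pp[, ax] <- pp[, ax] + h
    pm <- pts; pm[, ax] <- pm[, ax] - h
    fd <- (interpolate_map(m, pp)$value - interpolate_map(m, pm)$value) / (2 * h)
    expect_equal(r$gradient[, ax], fd, tolerance = 1e-5)
  }
})

test_that("points outside the support return zero value and gradient", {
  m <- fx_noise_map(8)
  r <- interpolate_map(m, c(100, 100, 100))
  expect_equal(r$value, 0)
  expect_equal(as.numeric(r$gradient), c(0, 0, 0))
})
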