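#' Density map objects
#'
#' A `density_map` wraps a 3-D array of real density values together with the
#' physical geometry of the grid: per-axis voxel spacing and the position of
#' the first voxel centre (the origin), both in Angstrom. Internally the array
#' is kept in canonical order with the x index fastest, matching the MRC2014
#' column/row/section convention after axis normalisation.
#'
#' @param data 3-D numeric array of density values.
#' @param voxel Per-axis voxel spacing in Angstrom (length 1 or 3, all > 0).
#' @param origin Position of voxel `[1,1,1]` in Angstrom (length 3).
#' @param resolution Optional stated resolution annotation in Angstrom.
#' @return An object of class `density_map`.
#' @export
density_map <- function(data, voxel = 1, origin = c(0, 0, 0),
                        resolution = NA_real_) {
  if (length(dim(data)) != 3L) abort("`data` must be a 3-D array")
  if (any(dim(data) < 2L)) abort("density grid needs >= 2 samples per axis")
  voxel <- rep_len(as.numeric(voxel), 3L)
  if (any(!is.finite(voxel)) || any(voxel <= 0)) {
    abort("voxel spacings must be finite and > 0")
  }
  if (!all(is.finite(data))) abort("density values must all be finite")
  structure(
    list(data = data, voxel = voxel, origin = rep_len(as.numeric(origin), 3L),
         resolution = as.numeric(resolution)),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "<density_map> %s grid, voxel %s A, origin (%s) A%s\n",
    paste(dim(x$data), collapse = "x"),
    paste(signif(x$voxel, 6), collapse = "/"),
    paste(signif(x$origin, 6), collapse = ", "),
    if (is.na(x$resolution)) "" else sprintf(", stated resolution %g A", x$resolution)
  ))
  cat(sprintf("  density range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' @export
dim.density_map <- function(x) dim(x$data)

is_density_map <- function(x) inherits(x, "density_map")

stop_if_not_map <- function(x, arg = "map") {
  if (!is_density_map(x)) abort(sprintf("`%s` must be a density_map", arg))
  invisible(x)
}

# world-coordinate extent of the voxel centres
map_extent <- function(map) {
  cbind(map$origin, map$origin + (dim(map$data) - 1L) * map$voxel)
}

#' Read an MRC/CCP4 density map
#'
#' Parses the 1024-byte MRC2014 header and the mode-2 (32-bit float) data
#' block. Axis permutations declared through the `mapc`/`mapr`/`maps` header
#' words are normalised to canonical x-fastest order. Voxel spacing is cell
#' length divided by grid sampling; the origin is taken from the header
#' origin record, falling back to start indices times the voxel size when the
#' origin record is all-zero.
#'
#' @param path Path to an MRC/CCP4 map file.
#' @return A [density_map].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("map file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nxyz <- ints[1:3]; mode <- ints[4]; nstart <- ints[5:7]; mxyz <- ints[8:10]
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  readBin(con, "numeric", n = 3L, size = 4L, endian = "little") # cell angles
  mapcrs <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  readBin(con, "numeric", n = 3L, size = 4L, endian = "little") # dmin/dmax/dmean
  readBin(con, "integer", n = 1L, size = 4L, endian = "little") # ispg
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  readBin(con, "integer", n = 25L, size = 4L, endian = "little") # extra
  orig <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  maptag <- rawToChar(readBin(con, "raw", n = 4L))
  readBin(con, "raw", n = 1024L - 212L) # machst, rms, labels
  if (any(nxyz < 1L) || any(nxyz > 4096L)) {
    abort(sprintf("malformed MRC header: bad grid dimensions nx/ny/nz = %s",
                  paste(nxyz, collapse = ",")))
  }
  if (mode != 2L) {
    abort(sprintf("malformed MRC header: unsupported mode %d (only mode 2 float)", mode))
  }
  if (!all(sort(mapcrs) == 1:3)) {
    abort(sprintf("malformed MRC header: mapc/mapr/maps = %s is not a permutation of 1:3",
                  paste(mapcrs, collapse = ",")))
  }
  if (any(mxyz < 1L) || any(cella <= 0)) {
    abort("malformed MRC header: non-positive cell length or sampling (cella/mx)")
  }
  if (nsymbt > 0L) readBin(con, "raw", n = nsymbt)
  nvox <- prod(nxyz)
  vals <- readBin(con, "numeric", n = nvox, size = 4L, endian = "little")
  if (length(vals) < nvox) abort("truncated map file: fewer data values than header declares")
  arr <- array(vals, dim = nxyz)
  # normalise axis order: column index c of the file runs along axis mapc etc.
  voxel_cell <- cella / mxyz            # spacing per crystallographic axis
  perm <- order(mapcrs)                 # file axis holding x, y, z
  if (!identical(perm, 1:3)) arr <- aperm(arr, perm)
  voxel <- voxel_cell                   # now indexed x,y,z
  nstart_xyz <- nstart[perm]
  origin <- if (all(orig == 0)) nstart_xyz * voxel else orig
  density_map(arr, voxel = voxel, origin = origin)
}

#' Write a density map in MRC2014 format
#'
#' Writes canonical axis order (mapc/mapr/maps = 1/2/3), mode 2 float data,
#' zero start indices and the origin stored in the header origin record, so
#' that read/write round trips preserve the grid geometry exactly.
#'
#' @param map A [density_map].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stop_if_not_map(map)
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(map$data)
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(d * map$voxel, 90, 90, 90)), con, size = 4L, endian = "little")
  writeBin(1:3, con, size = 4L, endian = "little")
  writeBin(as.numeric(c(min(map$data), max(map$data), mean(map$data))),
           con, size = 4L, endian = "little")
  writeBin(c(1L, 0L), con, size = 4L, endian = "little")   # ispg, nsymbt
  writeBin(integer(25L), con, size = 4L, endian = "little")
  writeBin(as.numeric(map$origin), con, size = 4L, endian = "little")
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)          # little-endian stamp
  writeBin(as.numeric(sd(map$data)), con, size = 4L, endian = "little")
  writeBin(0L, con, size = 4L, endian = "little")           # nlabl
  writeBin(raw(800L), con)
  writeBin(as.numeric(map$data), con, size = 4L, endian = "little")
  invisible(path)
}

# per-axis spatial-frequency grids (1/A) in FFT layout
fft_freqs <- function(n, voxel) {
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq_len(floor(n / 2)) - floor(n / 2) - 1L)
  k / (n * voxel)
}

# |s|^2 array matching fft(map$data)
freq_sq_grid <- function(map) {
  d <- dim(map$data)
  sx <- fft_freqs(d[1], map$voxel[1])
  sy <- fft_freqs(d[2], map$voxel[2])
  sz <- fft_freqs(d[3], map$voxel[3])
  outer(outer(sx^2, sy^2, `+`), sz^2, `+`)
}

nyquist_resolution <- function(map) 2 * max(map$voxel)

#' Sharpen (or blur) a map by B-factor scaling, with optional low-pass filter
#'
#' Fourier amplitudes are scaled by `exp(-b_factor * s^2 / 4)` with
#' `s = 1/d` the spatial frequency in 1/Angstrom; negative B amplifies
#' high-resolution features. The optional low-pass filter applies a
#' cosine-edge falloff centred at the requested resolution (soft over one
#' Fourier-sample shell to avoid ringing). The mean density (s = 0 term) is
#' preserved.
#'
#' @param map A [density_map].
#' @param b_factor Sharpening B in Angstrom^2 (negative sharpens).
#' @param lowpass_resolution Optional low-pass resolution in Angstrom; must be
#'   coarser than the Nyquist limit `2 * max(voxel)`.
#' @return A [density_map] with filtered values on the same grid.
#' @export
sharpen_map <- function(map, b_factor, lowpass_resolution = NULL) {
  stop_if_not_map(map)
  s2 <- freq_sq_grid(map)
  scale <- exp(-b_factor * s2 / 4)
  if (!is.null(lowpass_resolution)) {
    nyq <- nyquist_resolution(map)
    if (lowpass_resolution <= nyq) {
      abort(sprintf(
        "lowpass resolution %.3g A is beyond the Nyquist limit %.3g A for this grid",
        lowpass_resolution, nyq))
    }
    scale <- scale * lowpass_taper(sqrt(s2), 1 / lowpass_resolution,
                                   edge = 2 / max(dim(map$data) * map$voxel))
  }
  f <- fft(map$data) * scale
  out <- Re(fft(f, inverse = TRUE)) / length(f)
  density_map(out, voxel = map$voxel, origin = map$origin,
              resolution = if (is.null(lowpass_resolution)) map$resolution
                           else lowpass_resolution)
}

# half-cosine taper from 1 to 0 across [s_cut - edge/2, s_cut + edge/2]
lowpass_taper <- function(s, s_cut, edge) {
  t <- (s - (s_cut - edge / 2)) / edge
  t <- pmin(pmax(t, 0), 1)
  0.5 * (1 + cos(pi * t))
}

#' Model-derived mask
#'
#' Binary occupancy (1 within `mask_radius` of any atom, 0 elsewhere) on the
#' grid of `map`, optionally low-pass filtered to `filter_resolution` and
#' clipped back to `[0, 1]`. This is the mask used both for segmentation
#' (small radius) and for masked FSC evaluation (12 A radius filtered to
#' 12 A).
#'
#' @param model Atomic model (tibble with `x`, `y`, `z`; see [read_model]).
#' @param map Template [density_map] supplying the grid geometry.
#' @param mask_radius Mask radius around atoms in Angstrom.
#' @param filter_resolution Optional low-pass resolution in Angstrom.
#' @return A [density_map] with values in `[0, 1]`.
#' @export
make_mask <- function(model, map, mask_radius, filter_resolution = NULL) {
  stop_if_not_map(map)
  xyz <- model_xyz(model)
  if (nrow(xyz) == 0L) abort("cannot build a mask from an empty model")
  d <- dim(map$data)
  occ <- array(FALSE, d)
  for (a in seq_len(nrow(xyz))) {
    p <- xyz[a, ]
    lo <- pmax(ceiling((p - mask_radius - map$origin) / map$voxel) + 1, 1)
    hi <- pmin(floor((p + mask_radius - map$origin) / map$voxel) + 1, d)
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    dx2 <- (map$origin[1] + (ii - 1) * map$voxel[1] - p[1])^2
    dy2 <- (map$origin[2] + (jj - 1) * map$voxel[2] - p[2])^2
    dz2 <- (map$origin[3] + (kk - 1) * map$voxel[3] - p[3])^2
    r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    occ[ii, jj, kk] <- occ[ii, jj, kk] | (r2 <= mask_radius^2)
  }
  m <- density_map(occ + 0, voxel = map$voxel, origin = map$origin)
  if (!is.null(filter_resolution)) {
    m <- sharpen_map(m, b_factor = 0, lowpass_resolution = filter_resolution)
    m$data <- pmin(pmax(m$data, 0), 1)
  }
  m
}

#' Interpolate a map off-grid
#'
#' Tricubic (Catmull-Rom) spline interpolation: exact at grid nodes,
#' continuous first derivatives, analytic spatial gradient. Points outside
#' the padded grid support return value 0 and gradient 0 (so correlation
#' contributions vanish outside the measured volume).
#'
#' @param map A [density_map].
#' @param points Numeric matrix (n x 3) of query positions in Angstrom (a
#'   single point may be given as a length-3 vector).
#' @return A list with `value` (length n) and `gradient` (n x 3 matrix,
#'   density units per Angstrom).
#' @export
interpolate_map <- function(map, points) {
  stop_if_not_map(map)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  qidx <- sweep(sweep(points, 2L, map$origin, `-`), 2L, map$voxel, `/`)
  r <- cpp_interp(as.numeric(map$data), dim(map$data), qidx, gradient = TRUE)
  r$gradient <- sweep(r$gradient, 2L, map$voxel, `/`)
  r
}

# resampled copy of a map onto a template grid (tricubic; zero outside)
resample_map <- function(map, template) {
  d <- dim(template$data)
  idx <- as.matrix(expand.grid(x = seq_len(d[1]) - 1L, y = seq_len(d[2]) - 1L,
                               z = seq_len(d[3]) - 1L))
  pts <- sweep(sweep(idx, 2L, template$voxel, `*`), 2L, template$origin, `+`)
  v <- interpolate_map(map, pts)$value
  density_map(array(v, d), voxel = template$voxel, origin = template$origin,
              resolution = map$resolution)
}
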