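#' Fourier shell correlation between two maps
#'
#' Both maps are (optionally) multiplied by a real-space mask, Fourier
#' transformed, and correlated within `n_bins` equal-width spatial-frequency
#' shells up to the grid Nyquist:
#' `FSC(s) = Re<F_a F_b*> / sqrt(<|F_a|^2><|F_b|^2>)`.
#'
#' @param map_a,map_b [density_map]s on identical grids.
#' @param n_bins Number of resolution shells (default 50).
#' @param mask Optional mask [density_map] applied in real space (no
#'   phase-randomisation correction of mask-induced correlation is applied).
#' @return A tibble of class `fsc_curve` with `shell`, `freq` (1/Angstrom,
#'   shell centre), `resolution` (Angstrom), `fsc`, `n_coef`.
#' @export
fsc_curve <- function(map_a, map_b, n_bins = 50L, mask = NULL) {
  check_same_grid(map_a, map_b)
  a <- map_a$data; b <- map_b$data
  if (!is.null(mask)) {
    check_same_grid(map_a, mask)
    a <- a * mask$data
    b <- b * mask$data
  }
  fa <- as.vector(fft(a)); fb <- as.vector(fft(b))
  s <- as.numeric(sqrt(freq_sq_grid(map_a)))
  nyq <- 1 / (2 * max(map_a$voxel))
  ds <- nyq / n_bins
  bin <- pmin(pmax(ceiling(s / ds), 1L), n_bins + 1L)
  keep <- bin <= n_bins & s > 0
  bin <- bin[keep]
  num <- Re(fa[keep] * Conj(fb[keep]))
  pa <- Mod(fa[keep])^2
  pb <- Mod(fb[keep])^2
  s_num <- tapply(num, bin, sum)
  s_pa <- tapply(pa, bin, sum)
  s_pb <- tapply(pb, bin, sum)
  shells <- as.integer(names(s_num))
  fsc <- as.numeric(s_num) / sqrt(as.numeric(s_pa) * as.numeric(s_pb))
  fsc[!is.finite(fsc)] <- 0
  out <- tibble(
    shell = shells,
    freq = (shells - 0.5) * ds,
    resolution = 1 / ((shells - 0.5) * ds),
    fsc = fsc,
    n_coef = as.integer(table(bin))
  )
  structure(out, n_bins = as.integer(n_bins), nyquist = nyq,
            class = c("fsc_curve", class(out)))
}

#' Integrated FSC over a resolution range
#'
#' Unweighted mean of per-shell correlations over shells whose centre
#' frequency lies in `[1/low_res, 1/high_res]` (optionally weighted by shell
#' coefficient counts).
#'
#' @param curve An [fsc_curve] tibble (or any tibble with `freq` and `fsc`).
#' @param low_res Low-resolution bound in Angstrom (default 10).
#' @param high_res High-resolution bound in Angstrom (e.g. the map's stated
#'   resolution).
#' @param weighted Weight shells by coefficient count instead of the default
#'   unweighted mean.
#' @return iFSC in `[-1, 1]`.
#' @export
integrate_fsc <- function(curve, low_res = 10, high_res, weighted = FALSE) {
  if (low_res <= high_res) abort("`low_res` must be coarser than `high_res`")
  sel <- curve$freq >= 1 / low_res & curve$freq <= 1 / high_res
  if (!any(sel)) abort("no FSC shells inside the requested resolution range")
  if (weighted) {
    sum(curve$fsc[sel] * curve$n_coef[sel]) / sum(curve$n_coef[sel])
  } else {
    mean(curve$fsc[sel])
  }
}

#' Work/free integrated FSC of a model against two half-maps
#'
#' Simulates the model density on the half-map grid and computes the masked
#' iFSC against the training half-map ("work") and the independent
#' validation half-map ("free"); `gap = work - free` is the overfitting
#' indicator (about zero for a model not fit to either map's noise).
#'
#' @param model Atomic model tibble.
#' @param training_map,validation_map Half-map [density_map]s (same grid).
#' @param resolution High-resolution bound in Angstrom (defaults to the
#'   training map's annotation).
#' @param mask_radius Model mask radius, filtered to `mask_filter` (default
#'   12 A / 12 A).
#' @param mask_filter,low_res,n_bins See [make_mask()] / [integrate_fsc()].
#' @return Tibble with `ifsc_work`, `ifsc_free`, `gap`, plus curves in the
#'   `curves` attribute.
#' @export
fsc_work_free <- function(model, training_map, validation_map,
                          resolution = NULL, mask_radius = 12,
                          mask_filter = 12, low_res = 10, n_bins = 50L) {
  check_same_grid(training_map, validation_map)
  resolution <- resolution %||% training_map$resolution
  if (is.na(resolution)) abort("supply `resolution`")
  sim <- simulate_density(model, resolution, template = training_map)
  mask <- make_mask(model, training_map, mask_radius, mask_filter)
  cw <- fsc_curve(sim, training_map, n_bins = n_bins, mask = mask)
  cf <- fsc_curve(sim, validation_map, n_bins = n_bins, mask = mask)
  work <- integrate_fsc(cw, low_res, resolution)
  free <- integrate_fsc(cf, low_res, resolution)
  out <- tibble(ifsc_work = work, ifsc_free = free, gap = work - free)
  attr(out, "curves") <- list(work = cw, free = cf)
  out
}

#' Choose the fit-to-density weight from half-map candidates
#'
#' Among candidate weights, pick the one maximising
#' `U = iFSC_free - c * per_residue_energy` with `c = 0.004` by default; the
#' energy term regularises against overfitting (geometry degrades sharply
#' past the optimal weight). Ties break toward the smaller weight.
#'
#' @param candidates Tibble (or data frame) with columns `weight`,
#'   `ifsc_free` and `energy` (mean per-residue energy).
#' @param c_energy Energy regularisation constant (default 0.004).
#' @return The selected weight (scalar).
#' @export
choose_density_weight <- function(candidates, c_energy = 0.004) {
  if (is.null(nrow(candidates)) || nrow(candidates) == 0L) {
    abort("no candidate weights supplied")
  }
  u <- candidates$ifsc_free - c_energy * candidates$energy
  ord <- order(-u, candidates$weight)
  candidates$weight[ord[1]]
}
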