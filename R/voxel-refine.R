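#' Refine map voxel size and origin against fixed model density
#'
#' The model's calculated density is held fixed while the experimental map's
#' voxel size and origin are refined to maximise the real-space Pearson
#' correlation: each experimental voxel is placed at its trial world
#' position and the calculated map is sampled there with tricubic splines
#' (analytic derivatives). Quasi-Newton (L-BFGS-B) optimisation; isotropic
#' mode scales all three axes together (1 scale + 3 origin parameters),
#' anisotropic refines per-axis scales (6 parameters).
#'
#' @param map Experimental [density_map] (values untouched; only the header
#'   geometry is refined).
#' @param model_density Calculated [density_map] (fixed geometry).
#' @param mode `"isotropic"` (default, as in practice) or `"anisotropic"`.
#' @param refine_origin Jointly refine the origin (default TRUE).
#' @param mask Optional weight [density_map] on the experimental grid.
#' @param max_iter L-BFGS iteration cap (default 200).
#' @param gtol Projected-gradient convergence tolerance (default 1e-6).
#' @return List of class `voxel_refine_result`: `voxel`, `origin`,
#'   `cc_initial`, `cc_final`, `iterations`, `converged`, `map` (the input
#'   map with refined header geometry), `trajectory`.
#' @export
refine_voxel <- function(map, model_density, mode = c("isotropic", "anisotropic"),
                         refine_origin = TRUE, mask = NULL, max_iter = 200L,
                         gtol = 1e-6) {
  mode <- match.arg(mode)
  stop_if_not_map(map); stop_if_not_map(model_density, "model_density")
  v0 <- map$voxel; o0 <- map$origin
  mvec <- if (is.null(mask)) numeric(0) else as.numeric(mask$data)
  eval_cc <- function(vox, orig) {
    cpp_resample_cc(as.numeric(map$data), dim(map$data),
                    as.numeric(model_density$data), dim(model_density$data),
                    model_density$voxel, model_density$origin,
                    vox, orig, mvec)
  }
  r0 <- eval_cc(v0, o0)
  if (is.na(r0$cc)) abort("correlation undefined (flat map?)")
  traj <- list()
  unpack <- function(p) {
    if (mode == "isotropic") {
      list(vox = p[1] * v0, orig = if (refine_origin) p[2:4] else o0)
    } else {
      list(vox = p[1:3] * v0, orig = if (refine_origin) p[4:6] else o0)
    }
  }
  cache <- list(p = NULL, r = NULL) # fn and gr are called at the same point
  eval_at <- function(p) {
    if (!identical(p, cache$p)) {
      u <- unpack(p)
      cache <<- list(p = p, r = c(eval_cc(u$vox, u$orig), u))
    }
    cache$r
  }
  fn <- function(p) {
    r <- eval_at(p)
    if (is.na(r$cc)) return(1e6)
    traj[[length(traj) + 1L]] <<- c(r$vox, r$cc)
    -r$cc
  }
  gr <- function(p) {
    r <- eval_at(p)
    gv <- -r$grad_voxel * v0 # d/d(scale) per axis
    go <- -r$grad_origin
    if (mode == "isotropic") {
      c(sum(gv), if (refine_origin) go)
    } else {
      c(gv, if (refine_origin) go)
    }
  }
  p0 <- c(if (mode == "isotropic") 1 else c(1, 1, 1),
          if (refine_origin) o0)
  ns <- if (mode == "isotropic") 1L else 3L
  lower <- c(rep(0.8, ns), if (refine_origin) o0 - 10)
  upper <- c(rep(1.2, ns), if (refine_origin) o0 + 10)
  fit <- optim(p0, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = max_iter, pgtol = gtol, factr = 1e7))
  u <- unpack(fit$par)
  cc_final <- -fit$value
  converged <- fit$convergence == 0L
  if (cc_final < r0$cc) { # guard: never return a worse point than the start
    u <- list(vox = v0, orig = o0)
    cc_final <- r0$cc
  }
  out_map <- map
  out_map$voxel <- u$vox
  out_map$origin <- u$orig
  structure(list(
    voxel = u$vox, origin = u$orig,
    cc_initial = r0$cc, cc_final = cc_final,
    iterations = fit$counts[["function"]], converged = converged,
    mode = mode, initial_voxel = v0, map = out_map,
    trajectory = if (length(traj)) do.call(rbind, traj) else NULL),
    class = "voxel_refine_result")
}

#' @export
print.voxel_refine_result <- function(x, ...) {
  cat(sprintf(
    "<voxel_refine_result> %s: voxel %s -> %s A, CC %.4f -> %.4f (%d evals%s)\n",
    x$mode, paste(signif(x$initial_voxel, 5), collapse = "/"),
    paste(signif(x$voxel, 5), collapse = "/"),
    x$cc_initial, x$cc_final, x$iterations,
    if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Rigid-body fit of each chain into density
#'
#' Refines a rotation (about the chain centroid) and translation per chain
#' to maximise the real-space correlation between simulated and experimental
#' density. Because bonded geometry is untouched, the model's absolute
#' dimensions stay anchored by chemistry -- the property that lets
#' alternating voxel/coordinate refinement converge to the true voxel size
#' instead of tracking a mis-scaled map header.
#'
#' @param model Atomic model tibble.
#' @param map Experimental [density_map].
#' @param resolution Simulation resolution (defaults to map annotation).
#' @param max_iter L-BFGS iteration cap.
#' @return The rigidly refitted model.
#' @export
fit_rigid_chains <- function(model, map, resolution = NULL, max_iter = 60L) {
  stop_if_not_map(map)
  resolution <- resolution %||% map$resolution
  if (is.na(resolution)) abort("supply `resolution`")
  xyz0 <- model_xyz(model)
  chains <- unique(model$chain)
  rows_of <- lapply(chains, function(ch) which(model$chain == ch))
  cents <- lapply(rows_of, function(r) colMeans(xyz0[r, , drop = FALSE]))
  g0 <- atom_gaussians(model, resolution)
  mapvec <- as.numeric(map$data)
  rotmat <- function(w) { # Rodrigues from rotation vector
    th <- sqrt(sum(w^2))
    if (th < 1e-12) return(diag(3))
    k <- w / th
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3,
                byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  place <- function(p) {
    xyz <- xyz0
    for (i in seq_along(chains)) {
      q <- p[(6 * i - 5):(6 * i)]
      r <- rows_of[[i]]
      xyz[r, ] <- sweep(sweep(xyz0[r, , drop = FALSE], 2, cents[[i]]) %*%
                          t(rotmat(q[1:3])), 2, cents[[i]] + q[4:6], `+`)
    }
    xyz
  }
  cache <- list(p = NULL, r = NULL)
  eval_all <- function(p) {
    if (identical(p, cache$p)) return(cache$r)
    xyz <- place(p)
    dc <- cpp_density_cc(xyz, g0$weight, g0$sigma2, mapvec, dim(map$data),
                         map$voxel, map$origin, numeric(0))
    G <- numeric(length(p))
    for (i in seq_along(chains)) {
      r <- rows_of[[i]]
      ga <- dc$grad_xyz[r, , drop = FALSE]
      arm <- sweep(xyz[r, , drop = FALSE], 2, cents[[i]])
      # torque: sum over atoms of (x - c) x grad
      G[6 * i - 5] <- sum(arm[, 2] * ga[, 3] - arm[, 3] * ga[, 2])
      G[6 * i - 4] <- sum(arm[, 3] * ga[, 1] - arm[, 1] * ga[, 3])
      G[6 * i - 3] <- sum(arm[, 1] * ga[, 2] - arm[, 2] * ga[, 1])
      G[(6 * i - 2):(6 * i)] <- colSums(ga)
    }
    r <- list(E = -dc$cc, G = -G)
    cache <<- list(p = p, r = r)
    r
  }
  p0 <- numeric(6 * length(chains))
  fit <- optim(p0, fn = function(p) eval_all(p)$E,
               gr = function(p) eval_all(p)$G, method = "L-BFGS-B",
               control = list(maxit = max_iter))
  set_model_xyz(model, place(fit$par))
}

#' Alternate voxel-size refinement with coordinate refinement
#'
#' Model errors bias single-pass voxel refinement; alternating coordinate
#' refinement with voxel refinement against the improved model converges
#' both. By default coordinate refinement runs in the deposited frame (the
#' map with its original header), matching the convention of reporting
#' model-to-map metrics at deposited voxel sizes: the voxel estimate is then
#' a pure measurement against a progressively better model and cannot be
#' dragged by its own feedback. `refine_frame = "refined"` refines
#' coordinates against the rescaled map instead (the estimate feeds back;
#' appropriate when the header really is mis-calibrated). Cycles stop when
#' the voxel size changes by less than `tol` between cycles or `max_cycles`
#' is reached (then the last cycle is returned, flagged non-converged).
#'
#' @param map Experimental [density_map].
#' @param model Atomic model tibble.
#' @param coordinate_refiner Function `(model, map) -> model` (e.g. a wrapper
#'   over [minimize_into_density()] or [fit_rigid_chains()]).
#' @param max_cycles Cycle cap (default 5).
#' @param tol Voxel convergence tolerance in Angstrom (default 1e-4).
#' @param resolution Simulation resolution (defaults to map annotation).
#' @param mode,refine_origin Passed to [refine_voxel()].
#' @param refine_frame `"deposited"` (default) or `"refined"`; see above.
#' @return List: `map` (refined geometry), `model`, `result` (final
#'   [refine_voxel] result), `cycles` tibble.
#' @export
iterate_voxel_coord <- function(map, model, coordinate_refiner,
                                max_cycles = 5L, tol = 1e-4,
                                resolution = NULL,
                                mode = "isotropic", refine_origin = TRUE,
                                refine_frame = c("deposited", "refined")) {
  refine_frame <- match.arg(refine_frame)
  resolution <- resolution %||% map$resolution
  if (is.na(resolution)) abort("supply `resolution`")
  cur_map <- map
  cur_model <- model
  cycles <- list()
  last <- NULL
  prev_voxel <- map$voxel
  converged <- FALSE
  for (cy in seq_len(max_cycles)) {
    sim <- simulate_density(cur_model, resolution)
    res <- refine_voxel(if (refine_frame == "deposited") map else cur_map,
                        sim, mode = mode, refine_origin = refine_origin)
    cur_map <- res$map
    cycles[[cy]] <- tibble(cycle = cy, voxel = mean(res$voxel),
                           cc = res$cc_final)
    last <- list(res = res, map = cur_map, model = cur_model)
    if (max(abs(res$voxel - prev_voxel)) < tol) {
      converged <- TRUE
      break
    }
    prev_voxel <- res$voxel
    if (cy < max_cycles) {
      cur_model <- coordinate_refiner(
        cur_model, if (refine_frame == "deposited") map else cur_map)
    }
  }
  if (!converged) {
    # CC values from different cycles are scored against different models and
    # are not comparable; the last cycle (most-refined model) is returned
    inform("voxel/coordinate iteration hit max_cycles; returning last cycle")
  }
  list(map = last$map, model = last$model, result = last$res,
       converged = converged, cycles = dplyr::bind_rows(cycles))
}
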