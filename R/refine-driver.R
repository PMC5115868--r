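#' Protocol configuration
#'
#' All protocol constants in one validated list: error-score weights, the
#' rebuild cutoff schedule, Monte Carlo steps per rebuild stage, LocalRelax
#' cycles with the van der Waals repulsion ramp, fit-to-density weight and
#' its candidate grid, sharpening Bs (training -100, full reconstruction
#' -90), mask radii (FSC 12 A, segmentation 2 A), FSC integration limits
#' (10 A to the map resolution), trajectory count, region size bounds
#' (20-100 residues), the 8 A C-beta neighbor cutoff, and seeds.
#'
#' @param ... Overrides for any default field.
#' @return List of class `refinement_config`.
#' @export
refinement_config <- function(...) {
  cfg <- list(
    weights = error_weights(),
    schedule = cutoff_schedule(),
    mc_steps = 200L,
    relax_cycles = 4L,
    rep_ramp = c(0.1, 0.3, 0.6, 1.0),
    density_weight = 35,
    weight_grid = c(15, 35, 60),
    c_energy = 0.004,
    sharpen_b_train = -100,
    sharpen_b_full = -90,
    mask_radius_fsc = 12,
    mask_radius_segment = 2,
    fsc_low = 10,
    n_bins = 50L,
    n_trajectories = 4L,
    region_min = 20L,
    region_max = 100L,
    neighbor_cutoff = 8,
    w_rep = 10,
    w_rama = 1,
    cc_mask_radius = 4,
    minimize_maxit = 60L,
    stage1_keep = 50L,
    stage2_keep = 10L,
    resolution = NA_real_,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(paste("unknown config fields:", paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  if (abs(sum(cfg$weights) - 1) > 1e-8) abort("error weights must sum to 1")
  if (any(diff(cfg$schedule) <= 0)) abort("cutoff schedule must be strictly increasing")
  if (cfg$region_min <= 0 || cfg$region_min > cfg$region_max) {
    abort("region bounds must satisfy 0 < min <= max")
  }
  structure(cfg, class = "refinement_config")
}

# geometry-only relaxation (bonded + repulsion + rama; no map needed) --
# used to leave generated decoys at the forcefield's local optimum, as
# MD-perturbed models are after all-atom minimisation
relax_geometry <- function(model, max_iter = 60L, w_rep = 10, w_rama = 1,
                           rama = default_rama_potential()) {
  xyz0 <- model_xyz(model)
  topo <- backbone_topology(model)
  quads <- rama_quads(model, rama)
  radii <- vdw_radii[toupper(model$element)]
  radii[is.na(radii)] <- 1.7
  chain_id <- as.integer(factor(model$chain))
  cache <- list(p = NULL, r = NULL)
  eval_all <- function(p) {
    if (identical(p, cache$p)) return(cache$r)
    xyz <- matrix(p, ncol = 3L)
    bd <- cpp_bonded(xyz, topo$bonds$idx, topo$bonds$v0, topo$bonds$k,
                     topo$angles$idx, topo$angles$v0, topo$angles$k,
                     topo$torsions$idx, topo$torsions$v0, topo$torsions$k)
    cl <- cpp_clash(xyz, radii, model$resno, chain_id, w = w_rep, tol = 0.4)
    rm_ <- rama_term(xyz, quads, rama)
    r <- list(E = sum(bd$bond_e) + sum(bd$angle_e) + sum(bd$torsion_e) +
                cl$energy + w_rama * rm_$energy,
              G = as.numeric(bd$gradient + cl$gradient + w_rama * rm_$gradient))
    cache <<- list(p = p, r = r)
    r
  }
  fit <- optim(as.numeric(xyz0), fn = function(p) eval_all(p)$E,
               gr = function(p) eval_all(p)$G, method = "L-BFGS-B",
               control = list(maxit = max_iter))
  set_model_xyz(model, matrix(fit$par, ncol = 3L))
}

# movable atom-row indices from a residue selection with backbone/sidechain
# flags; NULL selection = everything movable
movable_atoms <- function(model, movable = NULL) {
  if (is.null(movable)) return(seq_len(nrow(model)))
  if (is.null(movable[["backbone"]])) movable$backbone <- TRUE
  if (is.null(movable[["sidechain"]])) movable$sidechain <- TRUE
  key <- residue_key(model)
  mkey <- paste(movable$chain, movable$resno, movable$insert, sep = "|")
  m <- match(key, mkey)
  hit <- !is.na(m)
  bb <- model$elety %in% backbone_atoms
  sel <- hit & ((bb & movable$backbone[m]) | (!bb & movable$sidechain[m]))
  which(sel)
}

# interior-residue (phi, psi) quads with each residue's energy grid gathered
# up front, so the per-evaluation rama term is fully vectorised
rama_quads <- function(model, potential) {
  tor <- backbone_torsions(model)
  rk <- residue_key(model)
  at <- function(keyv, name) match(paste(keyv, name), paste(rk, model$elety))
  keys <- paste(tor$chain, tor$resno, tor$insert, sep = "|")
  prev <- match(paste(tor$chain, tor$resno - 1L, "", sep = "|"), keys)
  nxt <- match(paste(tor$chain, tor$resno + 1L, "", sep = "|"), keys)
  phi_q <- cbind(at(keys[prev], "C"), at(keys, "N"), at(keys, "CA"), at(keys, "C"))
  psi_q <- cbind(at(keys, "N"), at(keys, "CA"), at(keys, "C"), at(keys[nxt], "N"))
  ok <- stats::complete.cases(phi_q) & stats::complete.cases(psi_q)
  resid <- tor$resid[ok]
  pre <- tor$next_is_pro[ok]
  nc <- length(potential$centers)
  egrid <- array(0, c(nc, nc, sum(ok)))
  for (i in seq_len(sum(ok))) {
    egrid[, , i] <- rama_table_of(potential, resid[i], pre[i])[[1]]$e
  }
  list(phi = phi_q[ok, , drop = FALSE], psi = psi_q[ok, , drop = FALSE],
       resid = resid, pre = pre, egrid = egrid,
       centers = potential$centers, spacing = potential$spacing)
}

# total rama energy + atom-coordinate gradient via table bilinear
# interpolation chained through analytic dihedral gradients
rama_term <- function(xyz, quads, potential, gradient = TRUE) {
  n <- nrow(quads$phi)
  if (n == 0L) {
    return(list(energy = 0, gradient = if (gradient) xyz * 0 else NULL))
  }
  rphi <- cpp_dihedral_grad(xyz, quads$phi)
  rpsi <- cpp_dihedral_grad(xyz, quads$psi)
  r2d <- 180 / pi
  nc <- length(quads$centers)
  locate <- function(ang) {
    u <- (ang - quads$centers[1]) / quads$spacing
    u <- u - floor(u / nc) * nc
    i0 <- floor(u)
    list(i0 = (as.integer(i0) %% nc) + 1L, i1 = (as.integer(i0 + 1) %% nc) + 1L,
         t = u - i0)
  }
  a <- locate(rphi$angle * r2d)
  b <- locate(rpsi$angle * r2d)
  sq <- seq_len(n)
  v00 <- quads$egrid[cbind(a$i0, b$i0, sq)]
  v10 <- quads$egrid[cbind(a$i1, b$i0, sq)]
  v01 <- quads$egrid[cbind(a$i0, b$i1, sq)]
  v11 <- quads$egrid[cbind(a$i1, b$i1, sq)]
  val <- (1 - a$t) * (1 - b$t) * v00 + a$t * (1 - b$t) * v10 +
    (1 - a$t) * b$t * v01 + a$t * b$t * v11
  E <- sum(val)
  grad <- NULL
  if (gradient) {
    gphi <- ((1 - b$t) * (v10 - v00) + b$t * (v11 - v01)) / quads$spacing * r2d
    gpsi <- ((1 - a$t) * (v01 - v00) + a$t * (v11 - v10)) / quads$spacing * r2d
    grad <- xyz * 0
    scatter <- function(grad, vals, idx) {
      s <- rowsum(vals, idx)
      rows <- as.integer(rownames(s))
      grad[rows, ] <- grad[rows, ] + s
      grad
    }
    for (atm in 1:4) {
      cols <- (3 * atm - 2):(3 * atm)
      grad <- scatter(grad, gphi * rphi$gradient[, cols, drop = FALSE],
                      quads$phi[, atm])
      grad <- scatter(grad, gpsi * rpsi$gradient[, cols, drop = FALSE],
                      quads$psi[, atm])
    }
  }
  list(energy = E, gradient = grad)
}

#' Restrained Cartesian minimisation into density
#'
#' Gradient-based (L-BFGS-B) minimisation of
#' `E = bonded strain + rama energy + clash repulsion +
#' density_weight * (1 - masked local CC)` over the coordinates of movable
#' atoms; all other atoms are left bit-identical. The CC is computed between
#' simulated and experimental density over voxels near the movable residues.
#'
#' @param model Atomic model tibble.
#' @param map Experimental [density_map].
#' @param movable `NULL` for all atoms, or a tibble with `chain`, `resno`,
#'   `insert` and optional logical `backbone` / `sidechain` columns.
#' @param density_weight Weight on the fit-to-density term.
#' @param config A [refinement_config()].
#' @param resolution Simulation resolution (defaults to map annotation).
#' @param w_rep Repulsion weight override (LocalRelax ramps this).
#' @param max_iter Iteration cap override.
#' @param rama Ramachandran potential.
#' @return The model with refined movable coordinates; the achieved objective
#'   is in the `objective` attribute (never above the starting value).
#' @export
minimize_into_density <- function(model, map, movable = NULL,
                                  density_weight = NULL,
                                  config = refinement_config(),
                                  resolution = NULL, w_rep = NULL,
                                  max_iter = NULL,
                                  rama = default_rama_potential()) {
  stop_if_not_map(map)
  resolution <- resolution %||% map$resolution %||% config$resolution
  if (is.na(resolution)) abort("supply `resolution`")
  density_weight <- density_weight %||% config$density_weight
  w_rep <- w_rep %||% config$w_rep
  max_iter <- max_iter %||% config$minimize_maxit
  mov <- movable_atoms(model, movable)
  if (!length(mov)) abort("movable set is empty")
  xyz0 <- model_xyz(model)
  topo <- backbone_topology(model)
  quads <- rama_quads(model, rama)
  g0 <- atom_gaussians(model, resolution)
  radii <- vdw_radii[toupper(model$element)]
  radii[is.na(radii)] <- 1.7
  chain_id <- as.integer(factor(model$chain))
  # mask: voxels near residues owning movable atoms
  mov_res <- unique(residue_key(model)[mov])
  res_atoms <- which(residue_key(model) %in% mov_res)
  wts <- numeric(length(map$data))
  wts[voxels_near(map, xyz0[res_atoms, , drop = FALSE],
                  config$cc_mask_radius)] <- 1
  mapvec <- as.numeric(map$data)
  # the density term is made extensive (scaled by the number of movable
  # residues) so the per-atom density force does not vanish as the model
  # grows -- a global CC's per-atom derivative scales as 1/model-size
  dens_scale <- density_weight * length(mov_res)
  eval_core <- function(p, gradient) {
    xyz <- xyz0
    xyz[mov, ] <- matrix(p, ncol = 3L)
    bd <- cpp_bonded(xyz, topo$bonds$idx, topo$bonds$v0, topo$bonds$k,
                     topo$angles$idx, topo$angles$v0, topo$angles$k,
                     topo$torsions$idx, topo$torsions$v0, topo$torsions$k,
                     gradient = gradient)
    cl <- cpp_clash(xyz, radii, model$resno, chain_id, w = w_rep, tol = 0.4,
                    gradient = gradient)
    rm_ <- rama_term(xyz, quads, rama, gradient = gradient)
    dc <- cpp_density_cc(xyz, g0$weight, g0$sigma2, mapvec, dim(map$data),
                         map$voxel, map$origin, wts, nsigma = 3,
                         grad_xyz = gradient)
    cc <- if (is.na(dc$cc)) 0 else dc$cc
    E <- sum(bd$bond_e) + sum(bd$angle_e) + sum(bd$torsion_e) + cl$energy +
      config$w_rama * rm_$energy + dens_scale * (1 - cc)
    if (!is.finite(E)) abort("non-finite refinement objective")
    if (!gradient) return(list(E = E))
    G <- bd$gradient + cl$gradient + config$w_rama * rm_$gradient
    if (!is.na(dc$cc)) G <- G - dens_scale * dc$grad_xyz
    if (!all(is.finite(G))) abort("non-finite refinement gradient")
    list(E = E, G = as.numeric(G[mov, ]))
  }
  cache <- list(p = NULL, r = NULL) # optim calls fn and gr at the same point
  eval_all <- function(p) {
    if (!identical(p, cache$p)) cache <<- list(p = p, r = eval_core(p, TRUE))
    cache$r
  }
  p0 <- as.numeric(xyz0[mov, ])
  fit <- optim(p0, fn = function(p) eval_all(p)$E,
               gr = function(p) eval_all(p)$G,
               method = "L-BFGS-B", control = list(maxit = max_iter))
  e0 <- eval_core(p0, FALSE)$E
  if (fit$value <= e0) {
    xyz <- xyz0
    xyz[mov, ] <- matrix(fit$par, ncol = 3L)
    out <- set_model_xyz(model, xyz)
    attr(out, "objective") <- fit$value
  } else {
    out <- model
    attr(out, "objective") <- e0
  }
  out
}

#' LocalRelax: overlapping-region coordinate optimisation
#'
#' Repeatedly picks the unmarked residue with the most neighbors (C-beta
#' distance < 8 A; ties break toward the lowest chain/residue number), makes
#' its neighbors movable in backbone and sidechain and its
#' neighbors-of-neighbors sidechain-only, minimises that region into
#' density, then marks the pick and its neighbors -- until every residue is
#' marked. The whole sweep runs `relax_cycles` times with the repulsion
#' weight ramped up each cycle. Regions exceeding the upper size bound are
#' trimmed by distance to the pick; chains smaller than the lower bound are
#' taken whole.
#'
#' @param model Atomic model tibble.
#' @param map Experimental [density_map].
#' @param config A [refinement_config()].
#' @param resolution Simulation resolution.
#' @param density_weight Fit-to-density weight (default from config).
#' @param cycles Override of `config$relax_cycles`.
#' @return The relaxed model.
#' @export
local_relax <- function(model, map, config = refinement_config(),
                        resolution = NULL, density_weight = NULL,
                        cycles = NULL) {
  resolution <- resolution %||% map$resolution %||% config$resolution
  density_weight <- density_weight %||% config$density_weight
  cycles <- cycles %||% config$relax_cycles
  ramp <- rep_len(config$rep_ramp, cycles)
  cur <- model
  for (cy in seq_len(cycles)) {
    g <- neighbor_graph(cur, cutoff = config$neighbor_cutoff)
    n <- nrow(g$nodes)
    adj <- vector("list", n)
    for (e in seq_len(nrow(g$edges))) {
      i <- g$edges$i[e]; j <- g$edges$j[e]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    marked <- rep(FALSE, n)
    if (n < config$region_min) {
      inform(sprintf("chain of %d residues below region bound %d; relaxing whole chain",
                     n, config$region_min))
    }
    while (!all(marked)) {
      cand <- which(!marked)
      ri <- cand[which.max(g$nodes$degree[cand])]
      nb <- unique(c(ri, adj[[ri]]))
      nnb <- setdiff(unique(unlist(adj[nb])), nb)
      if (n < config$region_min) {
        nb <- seq_len(n); nnb <- integer(0)
      } else if (length(nb) + length(nnb) > config$region_max) {
        d2 <- rowSums(sweep(g$rep_xyz, 2, g$rep_xyz[ri, ])^2)
        room <- config$region_max - length(nb)
        nnb <- nnb[order(d2[nnb])][seq_len(max(room, 0))]
        if (length(nb) > config$region_max) {
          nb <- c(ri, setdiff(nb[order(d2[nb])], ri))[seq_len(config$region_max)]
        }
      }
      movable <- dplyr::bind_rows(
        tibble(chain = g$nodes$chain[nb], resno = g$nodes$resno[nb],
               insert = g$nodes$insert[nb], backbone = TRUE, sidechain = TRUE),
        if (length(nnb)) tibble(chain = g$nodes$chain[nnb],
                                resno = g$nodes$resno[nnb],
                                insert = g$nodes$insert[nnb],
                                backbone = FALSE, sidechain = TRUE))
      has_atoms <- length(movable_atoms(cur, movable)) > 0L
      if (has_atoms) {
        cur <- minimize_into_density(cur, map, movable = movable,
                                     density_weight = density_weight,
                                     config = config, resolution = resolution,
                                     w_rep = ramp[cy] * config$w_rep)
      }
      marked[nb] <- TRUE
    }
  }
  cur
}

# contiguous spans (by resno, per chain) of a residue selection
selection_spans <- function(selection) {
  if (!nrow(selection)) return(list())
  out <- list()
  for (ch in unique(selection$chain)) {
    rs <- sort(unique(selection$resno[selection$chain == ch]))
    brk <- c(0, which(diff(rs) > 1L), length(rs))
    for (k in seq_len(length(brk) - 1L)) {
      out[[length(out) + 1L]] <- list(chain = ch,
                                      resno = rs[(brk[k] + 1L):brk[k + 1L]])
    }
  }
  out
}

# rebuild span backbone from the fixed (N, CA, C) of its first residue,
# given per-residue (phi, psi); returns coordinates for span atoms
rebuild_span_xyz <- function(anchor, phi, psi, seqs) {
  n <- length(phi)
  res <- vector("list", n)
  Np <- anchor$N; CAp <- anchor$CA; Cp <- anchor$C
  for (i in seq_len(n)) {
    O <- nerf_place(Np, CAp, Cp, 1.231, deg(120.8), deg(psi[i] + 180))
    r <- list(N = Np, CA = CAp, C = Cp, O = O)
    if (seqs[i] != "GLY") r$CB <- place_cb(Np, CAp, Cp)
    res[[i]] <- r
    Nn <- nerf_place(Np, CAp, Cp, 1.329, deg(116.2), deg(psi[i]))
    CAn <- nerf_place(CAp, Cp, Nn, 1.458, deg(121.7), deg(180))
    if (i < n) {
      Cn <- nerf_place(Cp, Nn, CAn, 1.525, deg(111.2), deg(phi[i + 1]))
      Np <- Nn; CAp <- CAn; Cp <- Cn
    } else {
      res[[i]]$N_next <- Nn
      res[[i]]$CA_next <- CAn
    }
  }
  res
}

#' Monte Carlo rebuilding of error regions
#'
#' A simplified stand-in for fragment-based rebuilding: Metropolis Monte
#' Carlo over the backbone torsions of each contiguous selected span,
#' proposals biased by the residues' Ramachandran tables, scored by local
#' density correlation plus Ramachandran energy plus a harmonic closure
#' restraint tying the rebuilt span end to the fixed downstream backbone.
#' The best-scoring state visited is returned, so the combined score never
#' worsens; results are bit-reproducible given the seed. Spans whose best
#' state fails to close are returned unchanged (flagged via message).
#'
#' @param model Atomic model tibble.
#' @param map Experimental [density_map].
#' @param residues Selection tibble (`chain`, `resno`) e.g. from
#'   [select_rebuild_set()].
#' @param rama Ramachandran potential (proposal bias and scoring).
#' @param mc_steps Monte Carlo steps per span (default 200; 0 returns the
#'   input unchanged).
#' @param seed Integer seed (required for reproducibility).
#' @param config A [refinement_config()].
#' @param resolution Simulation resolution.
#' @param kT Metropolis temperature (default 1).
#' @param w_closure Closure restraint weight per A^2 (default 10).
#' @return The model with rebuilt spans.
#' @export
rebuild_region <- function(model, map, residues, rama = default_rama_potential(),
                           mc_steps = 200L, seed = 1L,
                           config = refinement_config(), resolution = NULL,
                           kT = 1, w_closure = 10) {
  if (mc_steps == 0L || !nrow(residues)) return(model)
  resolution <- resolution %||% map$resolution %||% config$resolution
  spans <- selection_spans(residues)
  zmap <- (as.numeric(map$data) - mean(map$data)) / sd(map$data)
  zmap_map <- density_map(array(zmap, dim(map$data)), voxel = map$voxel,
                          origin = map$origin, resolution = resolution)
  with_seed_(seed, {
    for (sp in spans) {
      model <- rebuild_one_span(model, zmap_map, sp, rama, mc_steps,
                                kT, w_closure, config)
    }
  })
  model
}

rebuild_one_span <- function(model, zmap, sp, rama, mc_steps, kT, w_closure,
                             config) {
  rk <- residue_key(model)
  keys <- paste(sp$chain, sp$resno, "", sep = "|")
  tor <- backbone_torsions(model)
  tkey <- paste(tor$chain, tor$resno, tor$insert, sep = "|")
  ti <- match(keys, tkey)
  seqs <- tor$resid[ti]
  pre <- tor$next_is_pro[ti]
  first <- model[rk == keys[1], ]
  anchor <- list(N = unlist(first[first$elety == "N", c("x", "y", "z")]),
                 CA = unlist(first[first$elety == "CA", c("x", "y", "z")]),
                 C = unlist(first[first$elety == "C", c("x", "y", "z")]))
  if (length(anchor$N) != 3L || length(anchor$CA) != 3L || length(anchor$C) != 3L) {
    return(model)
  }
  nxt_key <- paste(sp$chain, max(sp$resno) + 1L, "", sep = "|")
  nxt <- model[rk == nxt_key, ]
  target_next <- if (nrow(nxt)) {
    list(N = unlist(nxt[nxt$elety == "N", c("x", "y", "z")]),
         CA = unlist(nxt[nxt$elety == "CA", c("x", "y", "z")]))
  } else NULL
  phi <- tor$phi[ti]; psi <- tor$psi[ti]
  phi[is.na(phi)] <- -57; psi[is.na(psi)] <- -47
  score <- function(ph, ps) {
    pieces <- rebuild_span_xyz(anchor, ph, ps, seqs)
    xyz <- do.call(rbind, lapply(pieces, function(r) {
      do.call(rbind, r[intersect(names(r), c("N", "CA", "C", "O", "CB"))])
    }))
    dens <- mean(interpolate_map(zmap, xyz)$value)
    er <- 0
    for (i in seq_along(ph)) {
      tab <- rama_table_of(rama, seqs[i], pre[i])[[1]]
      er <- er + rama_interp(tab, rama$centers, rama$spacing,
                             ph[i], ps[i])$value
    }
    clo <- 0
    if (!is.null(target_next)) {
      last <- pieces[[length(pieces)]]
      clo <- sum((last$N_next - target_next$N)^2)
      if (length(target_next$CA) == 3L) {
        clo <- clo + sum((last$CA_next - target_next$CA)^2)
      }
    }
    list(E = -config$density_weight * dens / 10 + er + w_closure * clo,
         pieces = pieces, closure = clo)
  }
  cur <- score(phi, psi)
  E0 <- cur$E
  best <- list(E = cur$E, phi = phi, psi = psi)
  for (step in seq_len(mc_steps)) {
    i <- sample.int(length(phi), 1L)
    ph2 <- phi; ps2 <- psi
    if (runif(1) < 0.7) {
      draw <- rama_draw(rama, seqs[i], pre[i])
      ph2[i] <- draw[1]; ps2[i] <- draw[2]
    } else {
      ph2[i] <- ph2[i] + rnorm(1, 0, 10)
      ps2[i] <- ps2[i] + rnorm(1, 0, 10)
    }
    prop <- score(ph2, ps2)
    if (prop$E < cur$E || runif(1) < exp((cur$E - prop$E) / kT)) {
      phi <- ph2; psi <- ps2; cur <- prop
      if (cur$E < best$E) best <- list(E = cur$E, phi = phi, psi = psi)
    }
  }
  if (best$E >= E0) return(model) # nothing better found; keep input span
  final <- score(best$phi, best$psi)
  if (!is.null(target_next) && final$closure > 4) {
    inform(sprintf("span %s %d-%d: best state fails closure; span unchanged",
                   sp$chain, min(sp$resno), max(sp$resno)))
    return(model)
  }
  pieces <- final$pieces
  for (i in seq_along(keys)) {
    rows <- which(rk == keys[i])
    for (a in seq_along(rows)) {
      nm <- model$elety[rows[a]]
      if (!is.null(pieces[[i]][[nm]])) {
        model$x[rows[a]] <- pieces[[i]][[nm]][1]
        model$y[rows[a]] <- pieces[[i]][[nm]][2]
        model$z[rows[a]] <- pieces[[i]][[nm]][3]
      }
    }
  }
  model
}

# one (phi, psi) draw biased by a residue's rama table
rama_draw <- function(potential, aa, pre) {
  tab <- rama_table_of(potential, aa, pre)[[1]]
  p <- as.numeric(tab$p)
  cell <- sample.int(length(p), 1L, prob = p)
  n <- length(potential$centers)
  i <- ((cell - 1L) %% n) + 1L
  j <- ((cell - 1L) %/% n) + 1L
  sp <- potential$spacing
  c(potential$centers[i] + runif(1, -sp / 2, sp / 2),
    potential$centers[j] + runif(1, -sp / 2, sp / 2))
}

#' Run the full rebuild-refine-select protocol
#'
#' Stage 1 (per trajectory, against the training half-map): pre-relax, then
#' one rebuild/relax round per cutoff of the schedule -- the error score is
#' recomputed at the start of each round so fixed errors are not re-refined
#' -- plus a final Ramachandran-only round. Stage 2: rank the trajectory
#' ensemble by masked validation-map iFSC and geometry ([select_models]).
#' Stage 3 (against the full reconstruction): choose the fit-to-density
#' weight on the half-maps (`U = iFSC_free - c * E`), then two cycles of
#' LocalRelax and B-factor refinement with voxel-size refinement interleaved
#' -- no rebuilding, so the full map cannot be overfit through large moves.
#'
#' @param model Starting atomic model.
#' @param train_map,val_map,full_map [density_map]s on a shared grid.
#' @param config A [refinement_config()]; `resolution` must be set there or
#'   carried by the maps.
#' @return List of class `protocol_result`: `ensemble` (stage-1 models),
#'   `selection` ([select_models] result), `final` model, `weight` (chosen
#'   density weight), `diagnostics` (initial and final error scores),
#'   `voxel` (final voxel-refinement result).
#' @export
run_protocol <- function(model, train_map, val_map, full_map,
                         config = refinement_config()) {
  check_same_grid(train_map, val_map); check_same_grid(train_map, full_map)
  resolution <- config$resolution %||% train_map$resolution
  if (is.na(resolution)) resolution <- train_map$resolution
  if (is.na(resolution)) abort("set `resolution` in the config or map")
  rama <- default_rama_potential()
  diag0 <- residue_error_score(model, train_map, rama,
                               weights = config$weights,
                               resolution = resolution)
  ensemble <- list()
  failures <- list()
  for (t in seq_len(config$n_trajectories)) {
    seed_t <- config$seed + 1009L * t
    traj <- tryCatch({
    m <- minimize_into_density(model, train_map, density_weight =
                                 config$density_weight, config = config,
                               resolution = resolution)
    stage <- 0L
    for (ct in config$schedule) {
      stage <- stage + 1L
      diag <- residue_error_score(m, train_map, rama,
                                  weights = config$weights,
                                  resolution = resolution)
      sel <- select_rebuild_set(diag, ct)
      if (nrow(sel)) {
        m <- rebuild_region(m, train_map, sel, rama,
                            mc_steps = config$mc_steps,
                            seed = seed_t + stage, config = config,
                            resolution = resolution)
      }
      m <- minimize_into_density(m, train_map, density_weight =
                                   config$density_weight, config = config,
                                 resolution = resolution)
    }
    diag <- residue_error_score(m, train_map, rama, weights = config$weights,
                                resolution = resolution)
    sel <- select_rebuild_set(diag, 0, component = "rama")
    if (nrow(sel)) {
      m <- rebuild_region(m, train_map, sel, rama, mc_steps = config$mc_steps,
                          seed = seed_t + 99L, config = config,
                          resolution = resolution)
      m <- minimize_into_density(m, train_map, density_weight =
                                   config$density_weight, config = config,
                                 resolution = resolution)
    }
    m
    }, error = function(e) e)
    if (inherits(traj, "error")) {
      # a failed trajectory is recorded; the protocol continues with the rest
      failures[[length(failures) + 1L]] <- tibble(
        trajectory = t, message = conditionMessage(traj))
      warn(sprintf("trajectory %d failed: %s", t, conditionMessage(traj)))
    } else {
      ensemble[[length(ensemble) + 1L]] <- traj
    }
  }
  if (!length(ensemble)) abort("all trajectories failed")
  selection <- select_models(ensemble, val_map, full_map,
                             resolution = resolution, config = config)
  # stage 3: density-weight choice from half-maps, then LocalRelax +
  # B-factor refinement against the full reconstruction
  top <- selection$stage2_models
  cand <- lapply(config$weight_grid, function(w) {
    mm <- minimize_into_density(top[[1]], full_map, density_weight = w,
                                config = config, resolution = resolution)
    wf <- fsc_work_free(mm, train_map, val_map, resolution = resolution,
                        mask_radius = config$mask_radius_fsc,
                        low_res = config$fsc_low, n_bins = config$n_bins)
    energy <- mean(bonded_strain(mm)$e_bonded) +
      mean(rama_energy(mm, rama)$e_rama)
    tibble(weight = w, ifsc_free = wf$ifsc_free, energy = energy)
  })
  weight <- choose_density_weight(dplyr::bind_rows(cand),
                                  c_energy = config$c_energy)
  refined <- lapply(top, function(m) {
    for (cy in 1:2) {
      m <- local_relax(m, full_map, config = config, resolution = resolution,
                       density_weight = weight, cycles = 1L)
      m <- fit_bfactors(m, full_map, resolution = resolution)
    }
    m
  })
  vox <- iterate_voxel_coord(full_map, refined[[1]], max_cycles = 3L,
                             resolution = resolution,
                             coordinate_refiner = function(mm, mp) {
                               minimize_into_density(mm, mp, density_weight =
                                                       weight, config = config,
                                                     resolution = resolution)
                             })
  refined[[1]] <- vox$model
  ifsc_full <- vapply(refined, function(m) {
    mask <- make_mask(m, full_map, config$mask_radius_fsc, config$mask_radius_fsc)
    cv <- fsc_curve(simulate_density(m, resolution, template = full_map),
                    full_map, n_bins = config$n_bins, mask = mask)
    integrate_fsc(cv, config$fsc_low, resolution)
  }, numeric(1))
  final <- refined[[order(-ifsc_full)[1]]]
  diag_final <- residue_error_score(final, train_map, rama,
                                    weights = config$weights,
                                    resolution = resolution)
  structure(list(
    ensemble = ensemble, selection = selection, final = final,
    refined = refined, weight = weight, ifsc_full = ifsc_full,
    diagnostics = list(initial = diag0, final = diag_final),
    failures = if (length(failures)) dplyr::bind_rows(failures) else NULL,
    voxel = vox$result, config = config), class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf(
    "<protocol_result> %d trajectories; chosen density weight %g; best full-map iFSC %.3f\n",
    length(x$ensemble), x$weight, max(x$ifsc_full)))
  cat(sprintf("  mean per-residue CC: %.3f (start) -> %.3f (final)\n",
              mean(x$diagnostics$initial$cc, na.rm = TRUE),
              mean(x$diagnostics$final$cc, na.rm = TRUE)))
  invisible(x)
}
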