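# Seeded synthetic inputs: toy structures built at ideal geometry,
# torsion-walk decoys with controlled RMSD, simulated half-maps with
# independent noise, and injected-error models with ground-truth labels.

# run `code` under a fixed seed without disturbing the caller's RNG stream
with_seed_ <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# NeRF atom placement: D given A,B,C with |CD| = r, angle BCD = theta,
# torsion ABCD = phi (radians)
nerf_place <- function(A, B, C, r, theta, phi) {
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + r * (-cos(theta) * bc + sin(theta) * cos(phi) * m +
             sin(theta) * sin(phi) * n)
}

# C-beta from N, CA, C (L-amino-acid construction along the NA/CA bisector)
place_cb <- function(N, CA, C) {
  u1 <- N - CA; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- C - CA; u2 <- u2 / sqrt(sum(u2^2))
  bis <- -(u1 + u2); bis <- bis / sqrt(sum(bis^2))
  perp <- c(u1[2] * u2[3] - u1[3] * u2[2],
            u1[3] * u2[1] - u1[1] * u2[3],
            u1[1] * u2[2] - u1[2] * u2[1])
  perp <- perp / sqrt(sum(perp^2))
  half <- 54.75 * pi / 180
  CA + 1.530 * (cos(half) * bis - sin(half) * perp)
}

deg <- function(x) x * pi / 180

# backbone (+O, +CB) from per-residue torsions at ideal bonded geometry
build_backbone <- function(phi, psi, omega, sequence, chain = "A", b = 30,
                           resno_start = 1L) {
  n <- length(phi)
  atoms <- list()
  Np <- c(0, 0, 0)
  CAp <- c(1.458, 0, 0)
  Cp <- nerf_place(c(0, -1, 0), Np, CAp, 1.525, deg(111.2), deg(phi[1]))
  for (i in seq_len(n)) {
    O <- nerf_place(Np, CAp, Cp, 1.231, deg(120.8), deg(psi[i] + 180))
    res <- list(N = Np, CA = CAp, C = Cp, O = O)
    if (sequence[i] != "GLY") res$CB <- place_cb(Np, CAp, Cp)
    atoms[[i]] <- res
    if (i < n) {
      Nn <- nerf_place(Np, CAp, Cp, 1.329, deg(116.2), deg(psi[i]))
      CAn <- nerf_place(CAp, Cp, Nn, 1.458, deg(121.7), deg(omega[i]))
      Cn <- nerf_place(Cp, Nn, CAn, 1.525, deg(111.2), deg(phi[i + 1]))
      Np <- Nn; CAp <- CAn; Cp <- Cn
    }
  }
  nm <- unlist(lapply(atoms, names))
  xyz <- do.call(rbind, lapply(atoms, function(r) do.call(rbind, r)))
  nat <- vapply(atoms, length, integer(1))
  atomic_model(tibble(
    chain = chain,
    resno = rep(resno_start + seq_len(n) - 1L, nat),
    insert = "",
    resid = rep(sequence[seq_len(n)], nat),
    elety = nm, element = substr(nm, 1L, 1L),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b = b, o = 1))
}

default_sequence <- function(n) {
  pool <- c("ALA", "LEU", "GLU", "VAL", "LYS", "PHE", "ASP", "ILE", "ARG",
            "THR", "SER", "TYR", "MET", "ASN", "GLN", "TRP", "HIS", "GLY")
  rep_len(pool, n)
}

#' Build a deterministic toy structure at ideal geometry
#'
#' Poly-peptide backbones (N, CA, C, O, C-beta) built by natural-extension
#' placement with ideal bond lengths and angles, so bonded strain is ~0 by
#' construction. Motifs: `"helix"` (phi/psi -57/-47), `"sheet"` (-119/113),
#' `"mixed"` (helix then strand), and `"bundle"` -- an antiparallel bundle of
#' separate ~30-residue helix chains packed on a 10.5 A grid with continuous
#' residue numbering across chains: a compact, clash-free fold suitable for
#' simulating maps of larger proteins (connecting loops built at rigid ideal
#' geometry would unavoidably clash, so the bundle is multi-chain).
#'
#' @param n_residues Number of residues (>= 3).
#' @param motif Secondary-structure recipe.
#' @param sequence Optional vector of three-letter codes (recycled).
#' @param b Uniform isotropic B-factor (Angstrom^2).
#' @return An [atomic_model] tibble.
#' @export
make_structure <- function(n_residues,
                           motif = c("helix", "sheet", "mixed", "bundle"),
                           sequence = NULL, b = 30) {
  motif <- match.arg(motif)
  if (n_residues < 3L) abort("need at least 3 residues")
  sequence <- rep_len(sequence %||% default_sequence(n_residues), n_residues)
  if (motif == "bundle") {
    return(build_bundle(n_residues, sequence, b = b))
  }
  tor <- switch(motif,
    helix = list(phi = rep(-57, n_residues), psi = rep(-47, n_residues)),
    sheet = list(phi = rep(-119, n_residues), psi = rep(113, n_residues)),
    mixed = {
      nh <- ceiling(n_residues / 2)
      list(phi = c(rep(-57, nh), rep(-119, n_residues - nh)),
           psi = c(rep(-47, nh), rep(113, n_residues - nh)))
    })
  build_backbone(tor$phi, tor$psi, rep(180, n_residues), sequence, b = b)
}

# antiparallel multi-chain helix bundle on a square packing grid
build_bundle <- function(n, sequence, b = 30, spacing = 11.2,
                         helix_len = 30L) {
  nh <- max(2L, ceiling(n / helix_len))
  len <- diff(round(seq(0, n, length.out = nh + 1)))
  ncol_ <- ceiling(sqrt(nh))
  rot_x180 <- diag(c(1, -1, -1))
  out <- list()
  start <- 1L
  for (h in seq_len(nh)) {
    L <- len[h]
    ch <- build_backbone(rep(-57, L), rep(-47, L), rep(180, L),
                         sequence[start:(start + L - 1L)],
                         chain = LETTERS[h], b = b, resno_start = start)
    xyz <- model_xyz(ch)
    ca <- xyz[ch$elety == "CA", , drop = FALSE]
    axis <- ca[nrow(ca), ] - ca[1, ]
    axis <- axis / sqrt(sum(axis^2))
    # rotate the helix axis onto +z (Rodrigues), then alternate direction
    t <- c(0, 0, 1)
    v <- c(axis[2] * t[3] - axis[3] * t[2],
           axis[3] * t[1] - axis[1] * t[3],
           axis[1] * t[2] - axis[2] * t[1])
    cth <- sum(axis * t)
    R <- if (sum(v^2) < 1e-12) diag(3) else {
      vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3,
                   byrow = TRUE)
      diag(3) + vx + vx %*% vx / (1 + cth)
    }
    xyz <- sweep(xyz, 2, colMeans(ca)) %*% t(R)
    if (h %% 2L == 0L) xyz <- xyz %*% t(rot_x180)
    ix <- (h - 1L) %% ncol_
    iy <- (h - 1L) %/% ncol_
    xyz <- sweep(xyz, 2, c(ix * spacing, iy * spacing, 0), `+`)
    out[[h]] <- set_model_xyz(ch, xyz)
    start <- start + L
  }
  atomic_model(dplyr::bind_rows(out))
}

# rebuild a model's backbone from (possibly modified) torsions, rigidly
# superposing the rebuilt copy back onto the original atoms -- as a whole, or
# per segment when seg_id (one id per residue) is given
rebuild_from_torsions <- function(model, phi, psi, seg_id = NULL) {
  tor <- backbone_torsions(model)
  seqs <- tor$resid
  chains <- unique(tor$chain)
  m2 <- dplyr::bind_rows(lapply(chains, function(ch) {
    rows <- which(tor$chain == ch)
    build_backbone(phi[rows], psi[rows], rep(180, length(rows)), seqs[rows],
                   chain = ch, b = median(model$b),
                   resno_start = min(tor$resno[rows]))
  }))
  m2 <- atomic_model(m2)
  rigid_fit <- function(xyz_new, i1, i2, apply_rows) {
    cm <- colMeans(xyz_new[i2, , drop = FALSE])
    cf <- colMeans(model_xyz(model)[i1, , drop = FALSE])
    A <- sweep(xyz_new[i2, , drop = FALSE], 2, cm)
    s <- svd(crossprod(A, sweep(model_xyz(model)[i1, , drop = FALSE], 2, cf)))
    R <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
    xyz_new[apply_rows, ] <- sweep(sweep(xyz_new[apply_rows, , drop = FALSE],
                                         2, cm) %*% R, 2, cf, `+`)
    xyz_new
  }
  key1 <- paste(residue_key(model), model$elety)
  key2 <- paste(residue_key(m2), m2$elety)
  full <- model_xyz(m2)
  groups <- if (is.null(seg_id)) list(seq_along(phi)) else
    split(seq_along(phi), seg_id)
  res_of2 <- match(residue_key(m2), unique(residue_key(m2)))
  res_of1 <- match(residue_key(model), unique(residue_key(model)))
  for (g in groups) {
    rows2 <- which(res_of2 %in% g)
    rows1 <- which(res_of1 %in% g)
    common <- intersect(key1[rows1], key2[rows2])
    i1 <- match(common, key1)
    i2 <- match(common, key2)
    full <- rigid_fit(full, i1, i2, rows2)
  }
  set_model_xyz(m2, full)
}

model_rmsd <- function(a, b) {
  ka <- paste(residue_key(a), a$elety); kb <- paste(residue_key(b), b$elety)
  m <- match(ka, kb)
  ok <- !is.na(m)
  sqrt(mean(rowSums((model_xyz(a)[ok, , drop = FALSE] -
                       model_xyz(b)[m[ok], , drop = FALSE])^2)))
}

#' Perturb a model by a seeded random torsion walk
#'
#' Gaussian noise is added to the phi/psi angles and the backbone is rebuilt
#' at ideal geometry; the noise scale is bisected until the all-atom RMSD to
#' the input lands within +-5% of `target_rmsd`. By default the walk is
#' applied per `segment`-residue window, each rebuilt window rigidly refit
#' onto its original position, so the deviation is distributed along the
#' chain (as molecular-dynamics perturbation would) instead of accumulating
#' as a lever-arm swing of the chain ends; `segment = Inf` gives the plain
#' whole-chain walk.
#'
#' @param model Atomic model built at ideal geometry (e.g. from
#'   [make_structure()]).
#' @param target_rmsd Target all-atom RMSD in Angstrom (> 0).
#' @param seed Integer seed; different seeds give distinct decoys.
#' @param segment Window length in residues for the local walk (default 12).
#' @param relax Finish with a short geometry-only minimisation (default
#'   TRUE), leaving the decoy at the forcefield's local optimum -- as
#'   dynamics-perturbed models are after all-atom minimisation. The RMSD
#'   target is re-checked afterwards.
#' @param chain_offset Optional rigid offset (Angstrom) applied to each chain
#'   perpendicular to its long axis before rescaling the walk, emulating the
#'   rigid displacement of whole secondary-structure elements that dynamics
#'   perturbation produces. Default 0 (pure torsion walk).
#' @return Perturbed [atomic_model] with an `achieved_rmsd` attribute.
#' @export
perturb_model <- function(model, target_rmsd, seed, segment = 12L,
                          relax = TRUE, chain_offset = 0) {
  if (target_rmsd <= 0) abort("`target_rmsd` must be positive")
  tor <- backbone_torsions(model)
  n <- nrow(tor)
  draws <- with_seed_(seed, {
    list(eps = matrix(rnorm(2 * n), n, 2),
         chain_dir = matrix(rnorm(3 * 26), ncol = 3),
         chain_mag = abs(rnorm(26, 1, 0.25)))
  })
  eps <- draws$eps
  phi0 <- tor$phi; psi0 <- tor$psi
  phi0[is.na(phi0)] <- -57; psi0[is.na(psi0)] <- -47
  within <- stats::ave(seq_len(n), tor$chain, FUN = seq_along)
  seg_id <- paste(tor$chain, ceiling(within / min(segment, n))) # per chain
  offset_chains <- function(m) {
    if (chain_offset == 0) return(m)
    xyz <- model_xyz(m)
    for (ci in seq_along(unique(m$chain))) {
      ch <- unique(m$chain)[ci]
      rows <- which(m$chain == ch)
      ca <- xyz[rows, , drop = FALSE][m$elety[rows] == "CA", , drop = FALSE]
      ax <- svd(sweep(ca, 2, colMeans(ca)))$v[, 1]
      u <- draws$chain_dir[ci, ]
      u <- u - sum(u * ax) * ax
      u <- u / sqrt(sum(u^2))
      xyz[rows, ] <- sweep(xyz[rows, , drop = FALSE], 2,
                           chain_offset * draws$chain_mag[ci] * u, `+`)
    }
    set_model_xyz(m, xyz)
  }
  try_scale <- function(s) {
    m <- rebuild_from_torsions(model, phi0 + s * eps[, 1], psi0 + s * eps[, 2],
                               seg_id = seg_id)
    m <- offset_chains(m)
    list(model = m, rmsd = model_rmsd(m, model))
  }
  bisect <- function(goal) {
    hi <- 2
    r_hi <- try_scale(hi)
    while (r_hi$rmsd < goal && hi < 90) {
      hi <- hi * 2
      r_hi <- try_scale(hi)
    }
    if (r_hi$rmsd < goal) {
      abort(sprintf("target RMSD %.2f A unreachable for this structure", goal))
    }
    lo <- 0
    best <- r_hi
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      r <- try_scale(mid)
      best <- r
      if (abs(r$rmsd - goal) <= 0.03 * goal) break
      if (r$rmsd < goal) lo <- mid else hi <- mid
    }
    best
  }
  goal <- target_rmsd
  best <- bisect(goal)
  if (relax) {
    for (round in 1:3) { # relaxation shifts the RMSD; re-target if needed
      relaxed <- relax_geometry(best$model, max_iter = 50L)
      rmsd <- model_rmsd(relaxed, model)
      if (abs(rmsd - target_rmsd) <= 0.05 * target_rmsd) {
        best <- list(model = relaxed, rmsd = rmsd)
        break
      }
      goal <- goal * target_rmsd / rmsd
      best <- bisect(goal)
      if (round == 3L) {
        relaxed <- relax_geometry(best$model, max_iter = 50L)
        best <- list(model = relaxed, rmsd = model_rmsd(relaxed, model))
      }
    }
  }
  out <- best$model
  attr(out, "achieved_rmsd") <- best$rmsd
  out
}

#' Simulate training/validation/full maps from a model
#'
#' Signal is the model's simulated density; the two half-maps add
#' independent white Gaussian noise streams, and the full map carries the
#' averaged noise (sigma / sqrt(2)), as for a reconstruction from the
#' combined particle set. All three share geometry.
#'
#' @param model Atomic model tibble.
#' @param resolution Simulation resolution in Angstrom (default 3).
#' @param voxel Grid spacing in Angstrom (default 1).
#' @param noise_sigma Noise standard deviation in units of the signal's
#'   standard deviation over the map.
#' @param seeds Two distinct integer seeds for the half-map noise streams.
#' @param padding Grid padding around the model (Angstrom).
#' @return List with `train`, `validation`, `full`, `signal` ([density_map]s).
#' @export
simulate_halfmaps <- function(model, resolution = 3, voxel = 1,
                              noise_sigma = 0.3, seeds = c(101L, 202L),
                              padding = 8) {
  if (seeds[1] == seeds[2]) abort("half-map noise seeds must be distinct")
  signal <- simulate_density(model, resolution, voxel = voxel, padding = padding)
  s0 <- sd(signal$data)
  d <- dim(signal$data)
  n1 <- with_seed_(seeds[1], array(rnorm(prod(d)), d))
  n2 <- with_seed_(seeds[2], array(rnorm(prod(d)), d))
  mk <- function(noise) {
    density_map(signal$data + noise_sigma * s0 * noise, voxel = signal$voxel,
                origin = signal$origin, resolution = resolution)
  }
  list(train = mk(n1), validation = mk(n2), full = mk((n1 + n2) / 2),
       signal = signal)
}

#' Inject localised errors into a model, with ground-truth labels
#'
#' Displaces the backbone of the given residue spans. Plain mode shifts each
#' span rigidly by >= 1.5 A in a random direction (density fit collapses);
#' with `compensate_strain` the span is register-shifted instead: a screw
#' operation of one helical repeat (1.5 A rise + ~100 degree twist about the
#' local helix axis) moves every atom by 2-3 A while leaving the density
#' envelope almost unchanged -- the fit stays high while bonded strain at
#' the span junctions rises, the signature of a register error. Truth
#' labels mark residues whose heavy-atom RMS to the input exceeds
#' `label_threshold`.
#'
#' @param model Atomic model tibble.
#' @param spans List of `c(first_resno, last_resno)` spans (overlaps merged).
#' @param compensate_strain Use the strain-compensated register-slide mode.
#' @param seed Integer seed for displacement directions.
#' @param displacement Rigid displacement magnitude in Angstrom (>= 1.5).
#' @param slide Register-slide magnitude in Angstrom (compensated mode).
#' @param label_threshold RMS threshold for the truth label (default 1 A).
#' @return List with `model` and `labels` (tibble: chain, resno, insert,
#'   rms, is_error).
#' @export
inject_errors <- function(model, spans, compensate_strain = FALSE, seed = 1L,
                          displacement = 3, slide = 2, label_threshold = 1) {
  if (!length(spans)) {
    labels <- per_residue_rms(model, model)
    labels$is_error <- FALSE
    return(list(model = model, labels = labels[, c("chain", "resno", "insert",
                                                   "rms", "is_error")]))
  }
  if (displacement < 1.5) abort("`displacement` must be >= 1.5 A")
  spans <- merge_spans(spans)
  out <- model
  out <- with_seed_(seed, {
  dirs <- matrix(rnorm(3 * length(spans)), ncol = 3)
  for (k in seq_along(spans)) {
    sp <- spans[[k]]
    rows <- which(out$resno >= sp[1] - 2L & out$resno <= sp[2] + 2L)
    if (!any(out$resno >= sp[1] & out$resno <= sp[2])) {
      abort(sprintf("span %d-%d matches no residues", sp[1], sp[2]))
    }
    # displacement tapers over 2 flanking residues on each side, as real
    # misplacement fields decay smoothly rather than breaking one bond
    wt_of <- function(resno) {
      dist_out <- pmax(pmax(sp[1] - resno, resno - sp[2]), 0)
      c(1, 0.75, 0.4)[pmin(dist_out, 2L) + 1L]
    }
    for (ch in unique(out$chain[rows])) { # spans may touch several chains
      crows <- rows[out$chain[rows] == ch]
      w <- wt_of(out$resno[crows])
      if (compensate_strain) {
        # screw by one helical repeat about the chain's helix axis
        ca_all <- model_xyz(out[out$chain == ch & out$elety == "CA", ])
        if (nrow(ca_all) < 4L) next
        cen <- colMeans(ca_all)
        axis <- svd(sweep(ca_all, 2, cen))$v[, 1]
        sgn <- sign(dirs[k, 1])
        K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                      -axis[2], axis[1], 0), 3, byrow = TRUE)
        screw <- function(p, wgt, s_rot) {
          th <- wgt * s_rot * 99.6 * pi / 180
          R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
          (p - cen) %*% R + cen + wgt * sgn * slide * 0.75 * axis
        }
        # the handedness coupling between twist and rise depends on the
        # arbitrary sign of the fitted axis: pick the rotation sign that
        # keeps the screwed CA positions on the original CA track
        ca_rows <- crows[out$elety[crows] == "CA"]
        track_err <- vapply(c(1, -1), function(s_rot) {
          moved <- t(vapply(ca_rows, function(r) {
            as.numeric(screw(c(out$x[r], out$y[r], out$z[r]), 1, s_rot))
          }, numeric(3)))
          mean(apply(moved, 1L, function(p) {
            min(sqrt(rowSums(sweep(ca_all, 2, p)^2)))
          }))
        }, numeric(1))
        s_rot <- c(1, -1)[which.min(track_err)]
        xyz <- model_xyz(out[crows, ])
        for (i in seq_along(crows)) { # per-residue partial screw
          xyz[i, ] <- screw(xyz[i, ], w[i], s_rot)
        }
        # small in-span jitter distributes bonded/rama strain over the span
        # while each atom stays well inside the density envelope
        xyz <- xyz + w * matrix(rnorm(length(xyz), 0, 0.25), ncol = 3L)
        out$x[crows] <- xyz[, 1]; out$y[crows] <- xyz[, 2]
        out$z[crows] <- xyz[, 3]
        next
      }
      u <- dirs[k, ] / sqrt(sum(dirs[k, ]^2))
      shift <- outer(w, displacement * u)
      out$x[crows] <- out$x[crows] + shift[, 1]
      out$y[crows] <- out$y[crows] + shift[, 2]
      out$z[crows] <- out$z[crows] + shift[, 3]
    }
  }
  out
  })
  labels <- per_residue_rms(out, model)
  labels$is_error <- labels$rms > label_threshold
  list(model = out, labels = labels[, c("chain", "resno", "insert", "rms",
                                        "is_error")])
}

merge_spans <- function(spans) {
  m <- do.call(rbind, spans)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- list(m[1, ])
  for (i in seq_len(nrow(m))[-1]) {
    last <- out[[length(out)]]
    if (m[i, 1] <= last[2] + 1L) {
      out[[length(out)]] <- c(last[1], max(last[2], m[i, 2]))
      inform("overlapping error spans merged")
    } else {
      out[[length(out) + 1L]] <- m[i, ]
    }
  }
  out
}

#' Generate synthetic backbone-torsion samples
#'
#' Draws (phi, psi) samples per (amino acid, pre-proline flag) bucket from
#' mixtures of wrapped Gaussian basins (alpha, beta, polyproline-II and
#' left-handed alpha; glycine gets a mirrored basin and broader spread,
#' proline a constrained phi). Pre-proline buckets shift weight toward the
#' beta/PPII basins. Used to train the default Ramachandran tables; real
#' torsion statistics can be supplied in the same format.
#'
#' @param n_per_bucket Samples per (aa, flag) bucket (default 220).
#' @param seed Integer seed.
#' @return Tibble: `aa`, `phi`, `psi`, `next_is_pro`.
#' @export
make_torsion_samples <- function(n_per_bucket = 220L, seed = 1L) {
  basins <- function(aa, pre) {
    if (aa == "GLY") {
      return(tibble(w = c(0.3, 0.3, 0.2, 0.2),
                    mphi = c(-70, 80, -150, 100), mpsi = c(-30, 20, 160, -170),
                    s = c(18, 18, 22, 22)))
    }
    if (aa == "PRO") {
      return(tibble(w = c(0.5, 0.5), mphi = c(-63, -63), mpsi = c(-35, 148),
                    s = c(8, 10)))
    }
    if (pre) {
      tibble(w = c(0.30, 0.40, 0.25, 0.05),
             mphi = c(-57, -119, -75, 58), mpsi = c(-47, 113, 150, 42),
             s = c(10, 14, 12, 8))
    } else {
      tibble(w = c(0.45, 0.35, 0.15, 0.05),
             mphi = c(-57, -119, -75, 58), mpsi = c(-47, 113, 150, 42),
             s = c(9, 13, 12, 8))
    }
  }
  wrap180 <- function(x) ((x + 180) %% 360) - 180
  with_seed_(seed, {
    out <- list()
    for (aa in amino_acids) {
      for (pre in c(TRUE, FALSE)) {
        b <- basins(aa, pre)
        comp <- sample(nrow(b), n_per_bucket, replace = TRUE, prob = b$w)
        out[[length(out) + 1L]] <- tibble(
          aa = aa,
          phi = wrap180(rnorm(n_per_bucket, b$mphi[comp], b$s[comp])),
          psi = wrap180(rnorm(n_per_bucket, b$mpsi[comp], b$s[comp])),
          next_is_pro = pre)
      }
    }
    dplyr::bind_rows(out)
  })
}
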