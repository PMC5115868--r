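#' Ideal bonded-geometry parameters
#'
#' Engh-Huber-style ideal backbone bond lengths, bond angles and the peptide
#' planarity (omega) restraint, with harmonic spring constants. Energies are
#' `0.5 k dev^2` with lengths in Angstrom and angles in radians.
#'
#' @param k_bond,k_angle,k_torsion Spring constants (per A^2 / per rad^2).
#' @return List of class `bonded_params` with `bonds`, `angles`, `torsions`
#'   tibbles (atom-name patterns; `+` suffix marks the next residue).
#' @export
bonded_params <- function(k_bond = 300, k_angle = 80, k_torsion = 40) {
  structure(list(
    bonds = tibble(
      a = c("N", "CA", "C", "CA", "C"),
      b = c("CA", "C", "O", "CB", "N+"),
      d0 = c(1.458, 1.525, 1.231, 1.530, 1.329),
      k = k_bond),
    angles = tibble(
      a = c("N", "N", "C", "CA", "CA", "O", "C"),
      b = c("CA", "CA", "CA", "C", "C", "C", "N+"),
      c = c("C", "CB", "CB", "O", "N+", "N+", "CA+"),
      t0 = c(111.2, 110.5, 110.1, 120.8, 116.2, 123.0, 121.7) * pi / 180,
      k = k_angle),
    torsions = tibble(
      a = "CA", b = "C", c = "N+", d = "CA+", t0 = pi, k = k_torsion)
  ), class = "bonded_params")
}

# Resolve a parameter table's atom-name patterns against the model, returning
# index matrices plus, per term, the residues sharing it. Residues connect to
# the next residue by numbering (same chain, resno + 1, empty insert path).
backbone_topology <- function(model, params = bonded_params()) {
  ord <- order(model$chain, model$resno, model$insert)
  rk <- residue_key(model)
  keys <- unique(rk[ord])
  atom_at <- function(keyv, name) {
    match(paste(keyv, name), paste(rk, model$elety))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  ch <- vapply(parts, `[`, "", 1L)
  no <- as.integer(vapply(parts, `[`, "", 2L))
  nxt <- match(paste(ch, no + 1L, "", sep = "|"), keys)
  resolve <- function(names_list) {
    cols <- lapply(names_list, function(nm) {
      plus <- endsWith(nm, "+")
      base <- sub("\\+$", "", nm)
      kv <- if (plus) keys[nxt] else keys
      idx <- rep(NA_integer_, length(keys))
      ok <- !is.na(kv)
      idx[ok] <- atom_at(kv[ok], base)
      idx
    })
    do.call(cbind, cols)
  }
  build <- function(tab, cols) {
    out_idx <- NULL; out_v1 <- numeric(0); out_k <- numeric(0)
    out_res <- list()
    for (r in seq_len(nrow(tab))) {
      idx <- resolve(as.list(tab[r, cols, drop = TRUE]))
      ok <- stats::complete.cases(idx)
      if (!any(ok)) next
      out_idx <- rbind(out_idx, idx[ok, , drop = FALSE])
      v0col <- intersect(c("d0", "t0"), names(tab))
      out_v1 <- c(out_v1, rep(tab[[v0col]][r], sum(ok)))
      out_k <- c(out_k, rep(tab$k[r], sum(ok)))
      out_res <- c(out_res, lapply(which(ok), function(i) {
        unique(rk[stats::na.omit(idx[i, ])])
      }))
    }
    if (is.null(out_idx)) {
      out_idx <- matrix(integer(0), 0, length(cols))
    }
    list(idx = out_idx, v0 = out_v1, k = out_k, res = out_res)
  }
  list(
    keys = keys,
    bonds = build(params$bonds, c("a", "b")),
    angles = build(params$angles, c("a", "b", "c")),
    torsions = build(params$torsions, c("a", "b", "c", "d"))
  )
}

#' Per-residue bonded-geometry strain
#'
#' Harmonic deviations of backbone bond lengths, bond angles and peptide
#' planarity from their ideals, attributed to residues (terms shared between
#' two residues are split evenly).
#'
#' @param model Atomic model tibble.
#' @param params A [bonded_params()] set.
#' @param topology Optional precomputed [backbone_topology] (perf).
#' @return Tibble with `chain`, `resno`, `insert`, `e_bonded` (>= 0, zero at
#'   ideal geometry). Missing atoms simply drop their terms.
#' @export
bonded_strain <- function(model, params = bonded_params(), topology = NULL) {
  topo <- topology %||% backbone_topology(model, params)
  xyz <- model_xyz(model)
  r <- cpp_bonded(xyz,
                  topo$bonds$idx, topo$bonds$v0, topo$bonds$k,
                  topo$angles$idx, topo$angles$v0, topo$angles$k,
                  topo$torsions$idx, topo$torsions$v0, topo$torsions$k,
                  gradient = FALSE)
  e <- setNames(numeric(length(topo$keys)), topo$keys)
  add <- function(term_e, term_res) {
    for (i in seq_along(term_e)) {
      rs <- term_res[[i]]
      e[rs] <<- e[rs] + term_e[i] / length(rs)
    }
  }
  add(r$bond_e, topo$bonds$res)
  add(r$angle_e, topo$angles$res)
  add(r$torsion_e, topo$torsions$res)
  parts <- strsplit(topo$keys, "|", fixed = TRUE)
  tibble(chain = vapply(parts, `[`, "", 1L),
         resno = as.integer(vapply(parts, `[`, "", 2L)),
         insert = vapply(parts, function(p) if (length(p) > 2L) p[3] else "", ""),
         e_bonded = as.numeric(e))
}

amino_acids <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' Backbone torsion angles
#'
#' Computes phi/psi/omega per residue (degrees) together with the identity of
#' the following residue (`next_is_pro`), the conditioning variable of the
#' pre-proline Ramachandran potential. Chain termini get `NA` torsions.
#'
#' @param model Atomic model tibble.
#' @return Tibble: `chain`, `resno`, `insert`, `resid`, `phi`, `psi`,
#'   `omega`, `next_is_pro`.
#' @export
backbone_torsions <- function(model) {
  rk <- residue_key(model)
  keys <- unique(rk[order(model$chain, model$resno, model$insert)])
  at <- function(keyv, name) match(paste(keyv, name), paste(rk, model$elety))
  parts <- strsplit(keys, "|", fixed = TRUE)
  ch <- vapply(parts, `[`, "", 1L)
  no <- as.integer(vapply(parts, `[`, "", 2L))
  prev <- match(paste(ch, no - 1L, "", sep = "|"), keys)
  nxt <- match(paste(ch, no + 1L, "", sep = "|"), keys)
  idx <- list(
    phi = cbind(at(keys[prev], "C"), at(keys, "N"), at(keys, "CA"), at(keys, "C")),
    psi = cbind(at(keys, "N"), at(keys, "CA"), at(keys, "C"), at(keys[nxt], "N")),
    omega = cbind(at(keys, "CA"), at(keys, "C"), at(keys[nxt], "N"),
                  at(keys[nxt], "CA")))
  xyz <- model_xyz(model)
  ang <- lapply(idx, function(qq) {
    ok <- stats::complete.cases(qq)
    out <- rep(NA_real_, nrow(qq))
    if (any(ok)) {
      out[ok] <- cpp_dihedrals(xyz, qq[ok, , drop = FALSE]) * 180 / pi
    }
    out
  })
  resid <- model$resid[match(keys, rk)]
  tibble(chain = ch, resno = no,
         insert = vapply(parts, function(p) if (length(p) > 2L) p[3] else "", ""),
         resid = resid,
         phi = ang$phi, psi = ang$psi, omega = ang$omega,
         next_is_pro = !is.na(nxt) & resid[nxt] == "PRO")
}

#' Build pre-proline-conditioned Ramachandran potentials
#'
#' Estimates, for every (amino acid, pre-proline flag) pair, a periodic 2-D
#' probability density over (phi, psi) by adaptive kernel density: a
#' fixed-bandwidth wrapped-Gaussian pilot sets local bandwidths
#' `h_i = h0 * (g / p_pilot(x_i))^(1/2)` (g the geometric mean pilot
#' density), and the final density sums per-sample wrapped Gaussians on a
#' regular grid. Densities convert to energies as `-log(max(P, floor))`.
#' Buckets with fewer than `min_bucket` samples fall back to the pooled
#' (all-amino-acid, same flag) table; the result always holds 40 tables.
#'
#' @param torsion_samples Tibble with `aa` (three-letter code), `phi`, `psi`
#'   (degrees in `[-180, 180)`), `next_is_pro` (logical).
#' @param grid_spacing Grid spacing in degrees (default 10).
#' @param h0 Pilot/base bandwidth in degrees (default 15).
#' @param min_bucket Minimum samples per (aa, flag) bucket (default 100).
#' @param p_floor Probability floor per square degree (default 1e-7).
#' @return Object of class `rama_potential`: tables (named
#'   `AA|pre` / `AA|npre`), grid centres, metadata tibble.
#' @export
build_rama_potential <- function(torsion_samples, grid_spacing = 10, h0 = 15,
                                 min_bucket = 100L, p_floor = 1e-7) {
  if (is.null(nrow(torsion_samples)) || nrow(torsion_samples) == 0L) {
    abort("no torsion samples supplied")
  }
  centers <- seq(-180 + grid_spacing / 2, 180 - grid_spacing / 2,
                 by = grid_spacing)
  cell <- grid_spacing^2
  kde <- function(phi, psi) {
    n <- length(phi)
    pw <- function(d, h) { # wrapped Gaussian kernel over +-1 period images
      dnorm(d, 0, h) + dnorm(d + 360, 0, h) + dnorm(d - 360, 0, h)
    }
    accum <- function(h) {
      p <- matrix(0, length(centers), length(centers))
      for (i in seq_len(n)) {
        p <- p + outer(pw(centers - phi[i], h[i]), pw(centers - psi[i], h[i]))
      }
      p / n
    }
    # pilot density on the grid (fixed bandwidth), read back at the samples
    pilot_grid <- accum(rep(h0, n))
    pilot <- rama_interp(list(p = pilot_grid), centers, grid_spacing,
                         phi, psi, field = "p")$value
    g <- exp(mean(log(pmax(pilot, 1e-12))))
    lambda <- pmin(pmax(sqrt(g / pmax(pilot, 1e-12)), 0.3), 4)
    p <- accum(h0 * lambda)
    p / (sum(p) * cell)
  }
  finalize <- function(p) {
    e <- -log(pmax(p, p_floor))
    srt <- sort(as.numeric(p), decreasing = TRUE)
    cum <- cumsum(srt * cell)
    t98 <- srt[which(cum >= 0.98)[1]]
    list(p = p, e = e, t98 = t98)
  }
  flags <- c(pre = TRUE, npre = FALSE)
  pooled_cache <- list()
  pooled <- function(f) { # computed lazily: only when some bucket is short
    if (is.null(pooled_cache[[f]])) {
      sel <- torsion_samples$next_is_pro == flags[[f]]
      pooled_cache[[f]] <<- if (any(sel)) {
        kde(torsion_samples$phi[sel], torsion_samples$psi[sel])
      } else {
        matrix(1 / (360^2), length(centers), length(centers))
      }
    }
    pooled_cache[[f]]
  }
  tables <- list()
  meta <- list()
  for (aa in amino_acids) {
    for (f in names(flags)) {
      sel <- torsion_samples$aa == aa & torsion_samples$next_is_pro == flags[[f]]
      n <- sum(sel)
      use_pooled <- n < min_bucket
      p <- if (use_pooled) pooled(f) else
        kde(torsion_samples$phi[sel], torsion_samples$psi[sel])
      tables[[paste(aa, f, sep = "|")]] <- finalize(p)
      meta[[length(meta) + 1L]] <- tibble(aa = aa, flag = f, n_samples = n,
                                          pooled = use_pooled)
    }
  }
  n_pooled <- sum(vapply(meta, function(m) m$pooled, logical(1)))
  if (n_pooled > 0L) {
    inform(sprintf("%d of 40 Ramachandran buckets below %d samples; using pooled tables",
                   n_pooled, min_bucket))
  }
  structure(list(tables = tables, centers = centers, spacing = grid_spacing,
                 h0 = h0, p_floor = p_floor, meta = dplyr::bind_rows(meta)),
            class = "rama_potential")
}

#' @export
print.rama_potential <- function(x, ...) {
  cat(sprintf("<rama_potential> %d tables, %g deg grid, %d pooled buckets\n",
              length(x$tables), x$spacing, sum(x$meta$pooled)))
  invisible(x)
}

rama_table_of <- function(potential, aa, pre) {
  key <- paste(ifelse(aa %in% amino_acids, aa, "ALA"),
               ifelse(pre, "pre", "npre"), sep = "|")
  potential$tables[key]
}

# periodic bilinear interpolation on one table's grid; field = "e" or "p"
rama_interp <- function(table, centers, spacing, phi, psi, field = "e",
                        gradient = FALSE) {
  m <- table[[field]]
  n <- length(centers)
  locate <- function(ang) {
    u <- (ang - centers[1]) / spacing
    u <- u - floor(u / n) * n # periodic
    i0 <- floor(u)
    list(i0 = (as.integer(i0) %% n) + 1L, i1 = (as.integer(i0 + 1) %% n) + 1L,
         t = u - i0)
  }
  a <- locate(phi); b <- locate(psi)
  v00 <- m[cbind(a$i0, b$i0)]; v10 <- m[cbind(a$i1, b$i0)]
  v01 <- m[cbind(a$i0, b$i1)]; v11 <- m[cbind(a$i1, b$i1)]
  val <- (1 - a$t) * (1 - b$t) * v00 + a$t * (1 - b$t) * v10 +
    (1 - a$t) * b$t * v01 + a$t * b$t * v11
  if (!gradient) return(list(value = val))
  list(value = val,
       dphi = ((1 - b$t) * (v10 - v00) + b$t * (v11 - v01)) / spacing,
       dpsi = ((1 - a$t) * (v01 - v00) + a$t * (v11 - v10)) / spacing)
}

#' Per-residue Ramachandran energy
#'
#' `E(i) = -log P(phi_i, psi_i | AA_i, is_pro_{i+1})` from a
#' [build_rama_potential()] object. Chain termini (undefined phi or psi) get
#' `NA` and are flagged `defined = FALSE`; error scoring treats them as
#' neutral (a terminus is not evidence of strain).
#'
#' @param model Atomic model tibble.
#' @param potential A `rama_potential`.
#' @param torsions Optional precomputed [backbone_torsions()] tibble.
#' @return Tibble: `chain`, `resno`, `insert`, `e_rama`, `defined`.
#' @export
rama_energy <- function(model, potential = default_rama_potential(),
                        torsions = NULL) {
  tor <- torsions %||% backbone_torsions(model)
  e <- numeric(nrow(tor))
  defined <- !is.na(tor$phi) & !is.na(tor$psi)
  for (i in seq_len(nrow(tor))) {
    tab <- rama_table_of(potential, tor$resid[i], tor$next_is_pro[i])[[1]]
    e[i] <- if (defined[i]) {
      rama_interp(tab, potential$centers, potential$spacing,
                  tor$phi[i], tor$psi[i])$value
    } else {
      NA_real_
    }
  }
  tibble(chain = tor$chain, resno = tor$resno, insert = tor$insert,
         e_rama = e, defined = defined)
}

vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

#' Geometry-quality report
#'
#' A deterministic composite proxy for external geometry validators: steric
#' clash count (van der Waals spheres overlapping by more than 0.4 A,
#' excluding bonded neighbours), the fraction of residues inside the top-98%
#' probability region of their Ramachandran table, and mean per-residue
#' bonded strain.
#'
#' @param model Atomic model tibble.
#' @param potential Ramachandran potential (default bundled synthetic-trained
#'   tables).
#' @param params Bonded ideals, see [bonded_params()].
#' @return One-row tibble: `n_clash`, `clash_per_1000`, `frac_rama_favored`,
#'   `mean_strain`.
#' @export
geometry_report <- function(model, potential = default_rama_potential(),
                            params = bonded_params()) {
  radii <- vdw_radii[toupper(model$element)]
  radii[is.na(radii)] <- 1.7
  chain_id <- as.integer(factor(model$chain))
  cl <- cpp_clash(model_xyz(model), radii, model$resno, chain_id,
                  w = 1, tol = 0.4, gradient = FALSE, count_overlap = 0.4)
  tor <- backbone_torsions(model)
  fav <- rep(NA, nrow(tor))
  for (i in seq_len(nrow(tor))) {
    if (is.na(tor$phi[i]) || is.na(tor$psi[i])) next
    tab <- rama_table_of(potential, tor$resid[i], tor$next_is_pro[i])[[1]]
    p <- rama_interp(tab, potential$centers, potential$spacing,
                     tor$phi[i], tor$psi[i], field = "p")$value
    fav[i] <- p >= tab$t98
  }
  strain <- bonded_strain(model, params)
  tibble(
    n_clash = cl$n_clash,
    clash_per_1000 = 1000 * cl$n_clash / nrow(model),
    frac_rama_favored = mean(fav, na.rm = TRUE),
    mean_strain = mean(strain$e_bonded)
  )
}

#' Default Ramachandran potential
#'
#' Tables trained once per session from the package's synthetic torsion
#' sampler ([make_torsion_samples()], fixed seed) and cached. Users with real
#' torsion statistics (e.g. a high-resolution-structure-derived table) should
#' build their own via [build_rama_potential()].
#'
#' @return A `rama_potential`.
#' @export
default_rama_potential <- function() {
  if (is.null(.emdense_env$default_rama)) {
    samples <- make_torsion_samples(n_per_bucket = 220L, seed = 1234L)
    .emdense_env$default_rama <- suppressMessages(
      build_rama_potential(samples))
  }
  .emdense_env$default_rama
}

#' Write / read Ramachandran tables as portable text
#'
#' Serialises every table of a `rama_potential` into a single TSV (long
#' format: table key, phi, psi, probability) that [read_rama_potential()]
#' restores.
#'
#' @param potential A `rama_potential`.
#' @param path File path.
#' @return `path` invisibly, or the restored `rama_potential`.
#' @export
write_rama_potential <- function(potential, path) {
  rows <- lapply(names(potential$tables), function(key) {
    p <- potential$tables[[key]]$p
    g <- expand.grid(phi = potential$centers, psi = potential$centers)
    tibble(table = key, phi = g$phi, psi = g$psi,
           p = as.numeric(p))
  })
  write.table(dplyr::bind_rows(rows), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_rama_potential
#' @export
read_rama_potential <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  centers <- sort(unique(d$phi))
  spacing <- centers[2] - centers[1]
  cell <- spacing^2
  tables <- lapply(split(d, d$table), function(dd) {
    dd <- dd[order(dd$psi, dd$phi), ]
    p <- matrix(dd$p, length(centers), length(centers))
    e <- -log(pmax(p, 1e-7))
    srt <- sort(as.numeric(p), decreasing = TRUE)
    t98 <- srt[which(cumsum(srt * cell) >= 0.98)[1]]
    list(p = p, e = e, t98 = t98)
  })
  structure(list(tables = tables, centers = centers, spacing = spacing,
                 h0 = NA_real_, p_floor = 1e-7,
                 meta = tibble(aa = sub("\\|.*", "", names(tables)),
                               flag = sub(".*\\|", "", names(tables)),
                               n_samples = NA_integer_, pooled = NA)),
            class = "rama_potential")
}
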