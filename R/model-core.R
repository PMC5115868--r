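#' Atomic models as tibbles
#'
#' An atomic model is a tibble with one row per atom and columns `chain`,
#' `resno` (integer residue number), `insert` (insertion code, `""` when
#' absent), `resid` (three-letter residue name), `elety` (atom name),
#' `element`, `x`, `y`, `z` (Angstrom), `b` (isotropic B, Angstrom^2) and
#' `o` (occupancy). Symmetry operators parsed from BIOMT records are kept in
#' the `symmetry_ops` attribute as a list of `list(R = 3x3, t = length-3)`
#' entries. All package functions accept any tibble/data.frame with these
#' columns.
#'
#' @param atoms Data frame with the columns above (missing `insert`, `b`,
#'   `o`, `element` are filled with defaults).
#' @param symmetry_ops Optional list of symmetry operators.
#' @return A tibble of class `atomic_model`.
#' @export
atomic_model <- function(atoms, symmetry_ops = list()) {
  atoms <- as_tibble(atoms)
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) abort(paste("model is missing columns:", paste(miss, collapse = ", ")))
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$b)) atoms$b <- 30
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$elety)
  if (!all(is.finite(atoms$x + atoms$y + atoms$z))) abort("non-finite coordinates")
  if (any(atoms$b < 0)) abort("negative B-factors")
  atoms$resno <- as.integer(atoms$resno)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key)) abort("duplicate (chain, resno, insert, atom name) entries")
  for (op in symmetry_ops) check_rotation(op$R)
  structure(atoms, symmetry_ops = symmetry_ops,
            class = c("atomic_model", class(atoms)))
}

guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", elety)
  substr(e, 1L, 1L)
}

check_rotation <- function(R, tol = 1e-4) {
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    abort("symmetry operator rotation is not orthonormal")
  }
  invisible(R)
}

model_xyz <- function(model) {
  matrix(c(model$x, model$y, model$z), ncol = 3L)
}

set_model_xyz <- function(model, xyz) {
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

# stable per-residue key in chain order
residue_key <- function(model) paste(model$chain, model$resno, model$insert, sep = "|")

#' Read an atomic model from a PDB file
#'
#' ATOM/HETATM records are parsed with \pkg{bio3d}; BIOMT symmetry operators
#' are read from the raw REMARK 350 lines. Residues named `UNK` are flagged
#' in the logical `unknown` column (conventionally excluded from refinement
#' and scoring).
#'
#' @param path Path to a PDB file.
#' @return An [atomic_model] tibble.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file not found: %s", path))
  reader <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif
  } else {
    function(p, ...) bio3d::read.pdb(p, verbose = FALSE, ...)
  }
  pdb <- tryCatch(reader(path),
                  error = function(e) abort(sprintf("cannot parse model %s: %s",
                                                    path, conditionMessage(e))))
  a <- pdb$atom
  m <- atomic_model(tibble(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid,
    elety = a$elety,
    element = ifelse(is.na(a$elesy) | a$elesy == "", guess_element(a$elety), a$elesy),
    x = a$x, y = a$y, z = a$z,
    b = ifelse(is.na(a$b), 0, a$b),
    o = ifelse(is.na(a$o), 1, a$o)
  ), symmetry_ops = read_biomt(path))
  m$unknown <- m$resid == "UNK"
  if (any(m$unknown)) {
    inform(sprintf("%d atoms in UNK residues flagged for exclusion",
                   sum(m$unknown)))
  }
  m
}

# BIOMT records: REMARK 350   BIOMT<row>  <opno>  r1 r2 r3 t
read_biomt <- function(path) {
  ln <- grep("^REMARK 350\\s+BIOMT", readLines(path, warn = FALSE), value = TRUE)
  if (!length(ln)) return(list())
  row <- as.integer(substr(ln, 19L, 19L))
  rest <- lapply(strsplit(trimws(substr(ln, 20L, 80L)), "\\s+"), as.numeric)
  opno <- vapply(rest, `[`, numeric(1), 1L)
  vals <- t(vapply(rest, function(v) v[2:5], numeric(4)))
  ops <- list()
  for (k in sort(unique(opno))) {
    sel <- which(opno == k)
    sel <- sel[order(row[sel])]
    if (length(sel) != 3L) abort(sprintf("incomplete BIOMT operator %d", k))
    R <- vals[sel, 1:3, drop = FALSE]
    check_rotation(R)
    ops[[length(ops) + 1L]] <- list(R = R, t = vals[sel, 4])
  }
  ops
}

#' Write an atomic model to a PDB file
#'
#' @param model Atomic model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  n <- nrow(model)
  if (any(nchar(model$chain) > 1L)) {
    # PDB chain column is one character; remap (e.g. symmetry-expanded ids)
    pool <- c(LETTERS, letters, 0:9)
    ids <- unique(model$chain)
    model$chain <- pool[match(model$chain, ids)]
    inform("multi-character chain ids remapped to single characters for PDB")
  }
  rec <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n) %% 100000L,
    ifelse(nchar(model$elety) < 4L, paste0(" ", model$elety), model$elety),
    " ", model$resid, model$chain, model$resno %% 10000L,
    ifelse(model$insert == "", " ", model$insert),
    model$x, model$y, model$z, model$o, model$b, model$element)
  ops <- attr(model, "symmetry_ops")
  hdr <- character(0)
  if (length(ops)) {
    hdr <- unlist(lapply(seq_along(ops), function(k) {
      op <- ops[[k]]
      sprintf("REMARK 350   BIOMT%d %3d%10.6f%10.6f%10.6f%15.5f",
              1:3, k, op$R[, 1], op$R[, 2], op$R[, 3], op$t)
    }))
  }
  writeLines(c(hdr, rec, "END"), path)
  invisible(path)
}

#' Expand symmetry operators into a full assembly
#'
#' Applies every operator to the asymmetric unit; chain identifiers of the
#' non-identity copies get numeric suffixes so atom keys stay unique.
#'
#' @param model Atomic model with a `symmetry_ops` attribute (or pass `ops`).
#' @param ops Optional list of operators overriding the attribute.
#' @return Expanded [atomic_model]; atom count = input x number of operators.
#' @export
expand_symmetry <- function(model, ops = NULL) {
  ops <- ops %||% attr(model, "symmetry_ops")
  if (is.null(ops) || !length(ops)) abort("model carries no symmetry operators")
  xyz <- model_xyz(model)
  out <- lapply(seq_along(ops), function(k) {
    op <- ops[[k]]
    check_rotation(op$R)
    m <- set_model_xyz(model, sweep(xyz %*% t(op$R), 2L, op$t, `+`))
    if (k > 1L) m$chain <- paste0(m$chain, k)
    m
  })
  res <- dplyr::bind_rows(out)
  atomic_model(res, symmetry_ops = list())
}

#' Residue neighbor graph
#'
#' Residues i, j are neighbors when their representative atoms are closer
#' than `cutoff` Angstrom. The representative is C-beta, or C-alpha for
#' glycine (and for any residue lacking a C-beta); residues with neither are
#' isolated nodes.
#'
#' @param model Atomic model tibble.
#' @param cutoff Neighbor distance cutoff in Angstrom (default 8).
#' @return A list of class `neighbor_graph` with `nodes` (tibble: chain,
#'   resno, insert, degree), `edges` (tibble: i, j as node row indices) and
#'   the representative coordinates.
#' @export
neighbor_graph <- function(model, cutoff = 8) {
  rep_atoms <- model |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert) |>
    dplyr::summarise(
      x = select_rep(.data$elety, .data$x),
      y = select_rep(.data$elety, .data$y),
      z = select_rep(.data$elety, .data$z),
      .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert)
  xyz <- as.matrix(rep_atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  has_rep <- is.finite(xyz[, 1])
  if (any(!has_rep)) {
    inform(sprintf("%d residues lack both CB and CA; left isolated", sum(!has_rep)))
  }
  edges <- NULL
  if (n > 1L) {
    d <- as.matrix(stats::dist(xyz))
    d[!has_rep, ] <- Inf; d[, !has_rep] <- Inf
    hit <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
    edges <- tibble(i = hit[, 1], j = hit[, 2])
  } else {
    edges <- tibble(i = integer(0), j = integer(0))
  }
  deg <- tabulate(c(edges$i, edges$j), nbins = n)
  structure(list(
    nodes = tibble(chain = rep_atoms$chain, resno = rep_atoms$resno,
                   insert = rep_atoms$insert, degree = deg),
    edges = edges, rep_xyz = xyz, cutoff = cutoff), class = "neighbor_graph")
}

select_rep <- function(elety, coord) {
  i <- match("CB", elety)
  if (is.na(i)) i <- match("CA", elety)
  if (is.na(i)) return(NA_real_)
  coord[i]
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d residues, %d edges (cutoff %g A)\n",
              nrow(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Per-residue RMS deviation against a reference model
#'
#' Residues are matched by chain + residue number + insertion code and atoms
#' by name; the RMS is taken over shared heavy atoms with no superposition
#' (both models are assumed to sit in the same map frame, as when labelling
#' misplaced residues against a reference structure).
#'
#' @param model,reference Atomic model tibbles.
#' @param atoms `"heavy"` (default, all non-hydrogen shared atoms) or `"CA"`.
#' @return Tibble with `chain`, `resno`, `insert`, `n_atoms`, `rms` (Angstrom).
#' @export
per_residue_rms <- function(model, reference, atoms = c("heavy", "CA")) {
  atoms <- match.arg(atoms)
  sel_a <- model[model$element != "H", ]
  sel_b <- reference[reference$element != "H", ]
  if (atoms == "CA") {
    sel_a <- sel_a[sel_a$elety == "CA", ]
    sel_b <- sel_b[sel_b$elety == "CA", ]
  }
  key_a <- paste(residue_key(sel_a), sel_a$elety)
  key_b <- paste(residue_key(sel_b), sel_b$elety)
  m <- match(key_a, key_b)
  ok <- !is.na(m)
  if (!any(ok)) abort("no matched residues between model and reference")
  d2 <- (sel_a$x[ok] - sel_b$x[m[ok]])^2 + (sel_a$y[ok] - sel_b$y[m[ok]])^2 +
    (sel_a$z[ok] - sel_b$z[m[ok]])^2
  tibble(chain = sel_a$chain[ok], resno = sel_a$resno[ok],
         insert = sel_a$insert[ok], d2 = d2) |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert) |>
    dplyr::summarise(n_atoms = dplyr::n(), rms = sqrt(mean(.data$d2)),
                     .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert)
}

# Kabsch rotation of mobile (n x 3) onto fixed (n x 3); returns fitted coords
kabsch_fit <- function(mobile, fixed) {
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  A <- sweep(mobile, 2L, cm)
  B <- sweep(fixed, 2L, cf)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(A %*% R, 2L, cf, `+`)
}

#' Ensemble per-residue deviation and pairwise RMSD
#'
#' All models are iteratively least-squares superposed (on shared C-alpha
#' atoms) onto the evolving mean structure; per-residue spread is the RMSF of
#' the C-alpha position over the superposed ensemble, and the pairwise
#' C-alpha RMSD matrix is computed in the common frame.
#'
#' @param models List of >= 2 atomic model tibbles sharing a residue set.
#' @param max_iter Superposition refinement iterations (default 5).
#' @return List of class `ensemble_deviation` with `per_residue` (tibble:
#'   chain, resno, insert, rmsf) and `pairwise_rmsd` (matrix, Angstrom).
#' @export
ensemble_deviation <- function(models, max_iter = 5L) {
  if (length(models) < 2L) abort("need at least 2 models")
  cas <- lapply(models, function(m) {
    ca <- m[m$elety == "CA", ]
    ca[order(ca$chain, ca$resno, ca$insert), ]
  })
  key <- Reduce(intersect, lapply(cas, residue_key))
  if (!length(key)) abort("models share no residues")
  coords <- lapply(cas, function(ca) model_xyz(ca[match(key, residue_key(ca)), ]))
  ref <- coords[[1]]
  for (it in seq_len(max_iter)) {
    coords <- lapply(coords, kabsch_fit, fixed = ref)
    ref <- Reduce(`+`, coords) / length(coords)
  }
  dev2 <- Reduce(`+`, lapply(coords, function(xy) rowSums((xy - ref)^2)))
  rmsf <- sqrt(dev2 / length(coords))
  nm <- length(coords)
  pw <- matrix(0, nm, nm)
  for (i in seq_len(nm - 1L)) for (j in (i + 1L):nm) {
    fit <- kabsch_fit(coords[[j]], coords[[i]])
    pw[i, j] <- pw[j, i] <- sqrt(mean(rowSums((fit - coords[[i]])^2)))
  }
  parts <- strsplit(key, "|", fixed = TRUE)
  structure(list(
    per_residue = tibble(
      chain = vapply(parts, `[`, "", 1L),
      resno = as.integer(vapply(parts, `[`, "", 2L)),
      insert = vapply(parts, function(p) if (length(p) > 2L) p[3] else "", ""),
      rmsf = rmsf),
    pairwise_rmsd = pw), class = "ensemble_deviation")
}

#' @export
print.ensemble_deviation <- function(x, ...) {
  pw <- x$pairwise_rmsd[upper.tri(x$pairwise_rmsd)]
  cat(sprintf(
    "<ensemble_deviation> %d residues, %d models; CA RMSD range %.2f-%.2f A, mean RMSF %.2f A\n",
    nrow(x$per_residue), nrow(x$pairwise_rmsd),
    if (length(pw)) min(pw) else 0, if (length(pw)) max(pw) else 0,
    mean(x$per_residue$rmsf)))
  invisible(x)
}
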