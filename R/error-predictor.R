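#' Standardise a vector to zero mean and unit variance
#'
#' Missing values are excluded from the statistics and returned as missing;
#' a zero-variance input returns all zeros with a warning.
#'
#' @param values Numeric vector (>= 2 finite values).
#' @return Standardised vector of the same length.
#' @export
zscore <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 2L) abort("need at least 2 finite values to standardise")
  s <- sd(values[ok])
  out <- rep(NA_real_, length(values))
  if (s == 0) {
    warn("zero variance; Z-scores set to 0")
    out[ok] <- 0
    return(out)
  }
  out[ok] <- (values[ok] - mean(values[ok])) / s
  out
}

#' Default error-score weights
#'
#' The combined per-residue error score weights its four standardised
#' components (absolute density CC, locally normalised CC, bonded strain,
#' Ramachandran strain) as 0.45 / 0.05 / 0.15 / 0.35; the weights sum to 1.
#'
#' @return Named numeric vector.
#' @export
error_weights <- function() {
  c(dens = 0.45, lcldens = 0.05, bonded = 0.15, rama = 0.35)
}

#' Per-residue error score from density fit and strain
#'
#' Combines four per-residue Z-scores into
#' `z_error = w_dens z_dens + w_lcldens z_lcldens + w_bonded z_bonded +
#' w_rama z_rama`. `z_dens` standardises the absolute per-residue density
#' correlation; `z_lcldens` standardises the correlation after subtracting
#' the mean over residues within `local_radius` (robust to local-resolution
#' variation); the strain terms standardise the negated bonded and
#' Ramachandran energies, so for every component more negative means worse.
#' Residues without density (outside the map) are excluded from the Z
#' statistics.
#'
#' @param model Atomic model tibble placed in the map frame.
#' @param map Experimental [density_map].
#' @param rama Ramachandran potential (default bundled tables).
#' @param weights Component weights, see [error_weights()].
#' @param window_radius Per-residue CC window in Angstrom (default 3).
#' @param local_radius Neighborhood radius for local CC normalisation
#'   (default 10 A, any-atom distance).
#' @param resolution Simulation resolution (defaults to map annotation).
#' @param dens_atoms `"all"` (default) or `"backbone"` CC for the density
#'   terms.
#' @param local_mode `"difference"` (default) or `"ratio"` normalisation.
#' @return A tibble of class `residue_diagnostics`: per residue cc,
#'   cc_local_norm, the four z components, and `z_error`.
#' @export
residue_error_score <- function(model, map, rama = default_rama_potential(),
                                weights = error_weights(), window_radius = 3,
                                local_radius = 10, resolution = NULL,
                                dens_atoms = c("all", "backbone"),
                                local_mode = c("difference", "ratio")) {
  dens_atoms <- match.arg(dens_atoms)
  local_mode <- match.arg(local_mode)
  if (abs(sum(weights) - 1) > 1e-8) {
    warn("error-score weights do not sum to 1")
  }
  cc_tab <- per_residue_rscc(model, map, window_radius = window_radius,
                             resolution = resolution)
  cc <- if (dens_atoms == "all") cc_tab$cc_all else cc_tab$cc_backbone
  # local normalisation: residues within local_radius by any-atom distance
  keys <- paste(cc_tab$chain, cc_tab$resno, cc_tab$insert, sep = "|")
  rk <- residue_key(model)
  xyz <- model_xyz(model)
  res_rows <- split(seq_len(nrow(model)), match(rk, keys))
  cc_local <- rep(NA_real_, length(keys))
  centers <- t(vapply(res_rows, function(rr) colMeans(xyz[rr, , drop = FALSE]),
                      numeric(3)))
  span <- vapply(res_rows, function(rr) {
    max(sqrt(rowSums(sweep(xyz[rr, , drop = FALSE], 2,
                           colMeans(xyz[rr, , drop = FALSE]))^2)))
  }, numeric(1))
  for (i in seq_along(keys)) {
    # centre-distance prefilter, exact any-atom check on candidates
    cand <- which(sqrt(rowSums(sweep(centers, 2, centers[i, ])^2)) <
                    local_radius + span[i] + span)
    near <- cand[vapply(cand, function(j) {
      min_atom_dist(xyz[res_rows[[i]], , drop = FALSE],
                    xyz[res_rows[[j]], , drop = FALSE]) < local_radius
    }, logical(1))]
    vals <- cc[near]
    vals <- vals[is.finite(vals)]
    if (!length(vals) || !is.finite(cc[i])) next
    cc_local[i] <- if (local_mode == "difference") cc[i] - mean(vals)
                   else cc[i] / mean(vals)
  }
  strain <- bonded_strain(model)
  er <- rama_energy(model, rama)
  stopifnot(nrow(strain) == length(keys), nrow(er) == length(keys))
  z_dens <- zscore(cc)
  z_lcldens <- zscore(cc_local)
  z_bonded <- zscore(-strain$e_bonded[match(keys, paste(strain$chain,
    strain$resno, strain$insert, sep = "|"))])
  z_rama <- zscore(-er$e_rama[match(keys, paste(er$chain, er$resno, er$insert,
    sep = "|"))])
  # components without a defined value (chain termini, isolated residues)
  # contribute neutrally; z_error stays NA only where density is missing
  zval <- function(z) ifelse(is.na(z), 0, z)
  z_error <- ifelse(is.na(z_dens), NA_real_,
    weights[["dens"]] * z_dens + weights[["lcldens"]] * zval(z_lcldens) +
      weights[["bonded"]] * zval(z_bonded) + weights[["rama"]] * zval(z_rama))
  out <- tibble(
    chain = cc_tab$chain, resno = cc_tab$resno, insert = cc_tab$insert,
    cc = cc, cc_local_norm = cc_local,
    z_dens = z_dens, z_lcldens = z_lcldens, z_bonded = z_bonded,
    z_rama = z_rama, z_error = z_error)
  structure(out, weights = weights,
            class = c("residue_diagnostics", class(out)))
}

min_atom_dist <- function(a, b) {
  sqrt(max(min(outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)), 0))
}

#' Default rebuild cutoff schedule
#'
#' Residue selection proceeds through increasingly permissive error-score
#' cutoffs -0.5, -0.3, -0.1, 0 (each stage's set contains the previous), and
#' a final pass selects on the Ramachandran component alone.
#'
#' @return Numeric vector of cutoffs.
#' @export
cutoff_schedule <- function() c(-0.5, -0.3, -0.1, 0)

#' Select residues for rebuilding
#'
#' @param diag A [residue_error_score()] tibble.
#' @param cutoff Z cutoff; residues with score below it are selected.
#' @param component `"error"` (combined, default) or `"rama"` (the final
#'   rama-only pass).
#' @return Tibble of selected residues (possibly empty).
#' @export
select_rebuild_set <- function(diag, cutoff, component = c("error", "rama")) {
  component <- match.arg(component)
  z <- if (component == "error") diag$z_error else diag$z_rama
  diag[!is.na(z) & z < cutoff, c("chain", "resno", "insert")]
}

#' Evaluate the error predictor against ground truth
#'
#' Truth labels are residues whose RMS to the reference exceeds
#' `rms_threshold`; the predictor score is `-z_error` (higher = more likely
#' wrong). Builds the precision-recall curve over all score thresholds and
#' integrates AUPRC by trapezoid over recall; also reports the four schedule
#' operating points.
#'
#' @param diag A [residue_error_score()] tibble.
#' @param reference_model Reference atomic model (or pass `truth`).
#' @param model The scored model (needed to compute RMS when `truth` is not
#'   given).
#' @param truth Optional logical vector/tibble overriding the RMS labels.
#' @param rms_threshold Truth threshold in Angstrom (default 1).
#' @return List of class `predictor_evaluation`: `auprc`, `pr_curve` tibble,
#'   `operating_points`, `prevalence`, `degenerate` flag.
#' @export
evaluate_predictor <- function(diag, reference_model = NULL, model = NULL,
                               truth = NULL, rms_threshold = 1) {
  if (is.null(truth)) {
    if (is.null(reference_model) || is.null(model)) {
      abort("supply either `truth` or both `model` and `reference_model`")
    }
    rms <- per_residue_rms(model, reference_model)
    m <- match(paste(diag$chain, diag$resno, diag$insert),
               paste(rms$chain, rms$resno, rms$insert))
    truth <- rms$rms[m] > rms_threshold
  }
  ok <- !is.na(truth) & !is.na(diag$z_error)
  lab <- truth[ok]
  score <- -diag$z_error[ok]
  degenerate <- length(unique(lab)) < 2L
  if (degenerate) {
    warn("all-positive or all-negative truth labels: AUPRC degenerate")
  }
  ord <- order(score, decreasing = TRUE)
  lab <- lab[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  npos <- sum(lab)
  precision <- tp / (tp + fp)
  recall <- if (npos > 0) tp / npos else rep(0, length(tp))
  pr <- tibble(threshold = score[ord], recall = recall, precision = precision)
  auprc <- if (degenerate) NA_real_ else {
    r <- c(0, recall); p <- c(1, precision)
    sum(diff(r) * (head(p, -1) + p[-1]) / 2)
  }
  ops <- lapply(cutoff_schedule(), function(ct) {
    sel <- diag$z_error[ok] < ct
    tibble(cutoff = ct, n_selected = sum(sel, na.rm = TRUE),
           precision = if (any(sel, na.rm = TRUE))
             mean(truth[ok][sel], na.rm = TRUE) else NA_real_,
           recall = if (npos > 0)
             sum(truth[ok] & sel, na.rm = TRUE) / npos else NA_real_)
  })
  structure(list(auprc = auprc, pr_curve = pr,
                 operating_points = dplyr::bind_rows(ops),
                 prevalence = mean(lab), degenerate = degenerate),
            class = "predictor_evaluation")
}

#' @export
print.predictor_evaluation <- function(x, ...) {
  cat(sprintf("<predictor_evaluation> AUPRC %.3f (prevalence %.3f%s)\n",
              x$auprc, x$prevalence,
              if (x$degenerate) ", DEGENERATE" else ""))
  print(x$operating_points)
  invisible(x)
}
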