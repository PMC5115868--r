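#' Select refined models by validation iFSC, geometry, and full-map iFSC
#'
#' Three nested ranking stages: all candidates are ranked by masked
#' integrated FSC against the independent validation map and the top
#' `stage1_keep` (50) survive; those are ranked by the geometry composite
#' (lower = better) and the top `stage2_keep` (10) survive; the final model
#' is the stage-2 survivor with the best integrated FSC against the full
#' reconstruction. Per-residue ensemble deviation is computed over the
#' stage-2 survivors. Candidate order never affects the chosen set: ties
#' break by candidate id.
#'
#' The geometry composite standardises the clash count, the negated
#' Ramachandran-favored fraction and the mean bonded strain across
#' candidates and averages them (a documented proxy for external geometry
#' validators; pass `geometry_scorer` to plug in real scores).
#'
#' @param models List of atomic model tibbles.
#' @param validation_map,full_map [density_map]s on a shared grid.
#' @param resolution High-resolution FSC bound in Angstrom.
#' @param config A [refinement_config()] (mask radius, shell count, caps).
#' @param geometry_scorer Function `model -> numeric` (lower = better);
#'   default derives the composite from [geometry_report()].
#' @return List of class `selection_result`: `scores` tibble (per candidate:
#'   id, ifsc_validation, geometry, ifsc_full, stage flags), `stage1_ids`,
#'   `stage2_ids`, `final_id`, `final_model`, `stage2_models`,
#'   `ensemble_deviation`.
#' @export
select_models <- function(models, validation_map, full_map, resolution = NULL,
                          config = refinement_config(),
                          geometry_scorer = NULL) {
  if (!length(models)) abort("no candidate models")
  check_same_grid(validation_map, full_map)
  resolution <- resolution %||% validation_map$resolution
  if (is.na(resolution)) abort("supply `resolution`")
  n <- length(models)
  if (n < config$stage1_keep || n < config$stage2_keep) {
    inform(sprintf("only %d candidates; selection stages keep all available", n))
  }
  ifsc_val <- numeric(n)
  for (i in seq_len(n)) {
    mask <- make_mask(models[[i]], validation_map, config$mask_radius_fsc,
                      config$mask_radius_fsc)
    sim <- simulate_density(models[[i]], resolution, template = validation_map)
    cv <- fsc_curve(sim, validation_map, n_bins = config$n_bins, mask = mask)
    ifsc_val[i] <- integrate_fsc(cv, config$fsc_low, resolution)
  }
  geom <- if (is.null(geometry_scorer)) {
    reports <- dplyr::bind_rows(lapply(models, geometry_report))
    zsafe <- function(v) if (sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / sd(v)
    (zsafe(reports$n_clash) + zsafe(-reports$frac_rama_favored) +
        zsafe(reports$mean_strain)) / 3
  } else {
    vapply(models, geometry_scorer, numeric(1))
  }
  stage1 <- order(-ifsc_val, seq_len(n))[seq_len(min(config$stage1_keep, n))]
  stage2 <- stage1[order(geom[stage1], stage1)][seq_len(min(config$stage2_keep,
                                                            length(stage1)))]
  ifsc_full <- rep(NA_real_, n)
  for (i in stage2) {
    mask <- make_mask(models[[i]], full_map, config$mask_radius_fsc,
                      config$mask_radius_fsc)
    sim <- simulate_density(models[[i]], resolution, template = full_map)
    cv <- fsc_curve(sim, full_map, n_bins = config$n_bins, mask = mask)
    ifsc_full[i] <- integrate_fsc(cv, config$fsc_low, resolution)
  }
  final_id <- stage2[order(-ifsc_full[stage2], stage2)][1]
  dev <- if (length(stage2) >= 2L) {
    ensemble_deviation(models[stage2])
  } else NULL
  scores <- tibble(
    id = seq_len(n), ifsc_validation = ifsc_val, geometry = geom,
    ifsc_full = ifsc_full,
    stage1 = seq_len(n) %in% stage1, stage2 = seq_len(n) %in% stage2,
    final = seq_len(n) == final_id)
  structure(list(scores = scores, stage1_ids = sort(stage1),
                 stage2_ids = sort(stage2), final_id = final_id,
                 final_model = models[[final_id]],
                 stage2_models = models[stage2],
                 ensemble_deviation = dev),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d candidates -> %d (validation iFSC) -> %d (geometry) -> final #%d\n",
    nrow(x$scores), length(x$stage1_ids), length(x$stage2_ids), x$final_id))
  cat(sprintf("  final validation iFSC %.3f, full-map iFSC %.3f\n",
              x$scores$ifsc_validation[x$final_id],
              x$scores$ifsc_full[x$final_id]))
  invisible(x)
}
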