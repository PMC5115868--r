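# broom-style tidiers and ggplot2 autoplot methods for the result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a voxel-refinement result
#'
#' @param x A `voxel_refine_result`.
#' @param ... Unused.
#' @return One row per axis: axis, initial and refined voxel (Angstrom).
#' @export
tidy.voxel_refine_result <- function(x, ...) {
  tibble(axis = c("x", "y", "z"),
         voxel_initial = x$initial_voxel,
         voxel_refined = x$voxel,
         origin_refined = x$origin)
}

#' @rdname tidy.voxel_refine_result
#' @export
glance.voxel_refine_result <- function(x, ...) {
  tibble(cc_initial = x$cc_initial, cc_final = x$cc_final,
         scale = mean(x$voxel / x$initial_voxel),
         iterations = x$iterations, converged = x$converged, mode = x$mode)
}

#' Tidy a model-selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return The per-candidate score table.
#' @export
tidy.selection_result <- function(x, ...) x$scores

#' @rdname tidy.selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble(n_candidates = nrow(x$scores),
         n_stage1 = length(x$stage1_ids),
         n_stage2 = length(x$stage2_ids),
         final_id = x$final_id,
         ifsc_validation = x$scores$ifsc_validation[x$final_id],
         ifsc_full = x$scores$ifsc_full[x$final_id])
}

#' Tidy a predictor evaluation
#'
#' @param x A `predictor_evaluation`.
#' @param ... Unused.
#' @return The precision-recall curve tibble.
#' @export
tidy.predictor_evaluation <- function(x, ...) x$pr_curve

#' @rdname tidy.predictor_evaluation
#' @export
glance.predictor_evaluation <- function(x, ...) {
  tibble(auprc = x$auprc, prevalence = x$prevalence,
         degenerate = x$degenerate)
}

#' Plot an FSC curve
#'
#' @param object An [fsc_curve] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fsc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq, y = .data$fsc)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "spatial frequency (1/Å)",
                  y = "Fourier shell correlation") +
    ggplot2::theme_minimal()
}

#' Plot per-residue error diagnostics
#'
#' Combined error score along the chain with the rebuild-selection cutoffs.
#'
#' @param object A `residue_diagnostics` tibble.
#' @param cutoffs Cutoff schedule to draw (default [cutoff_schedule()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.residue_diagnostics <- function(object, cutoffs = cutoff_schedule(),
                                         ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$resno, y = .data$z_error)) +
    ggplot2::geom_hline(yintercept = cutoffs, linetype = 2, colour = "grey70") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$z_error < min(cutoffs)),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::facet_wrap(~chain, scales = "free_x") +
    ggplot2::labs(x = "residue", y = expression(Z[error])) +
    ggplot2::theme_minimal()
}

#' Plot a predictor evaluation (precision-recall curve)
#'
#' @param object A `predictor_evaluation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.predictor_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$pr_curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$prevalence, linetype = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision",
                  subtitle = sprintf("AUPRC = %.3f", object$auprc)) +
    ggplot2::theme_minimal()
}

#' Plot a voxel-refinement trajectory
#'
#' @param object A `voxel_refine_result`.
#' @param ... Unused.
#' @return A ggplot of CC against mean voxel size over the optimizer path.
#' @export
autoplot.voxel_refine_result <- function(object, ...) {
  tr <- object$trajectory
  if (is.null(tr)) abort("result carries no trajectory")
  d <- tibble(voxel = rowMeans(tr[, 1:3, drop = FALSE]), cc = tr[, 4])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$voxel, y = .data$cc)) +
    ggplot2::geom_path(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "voxel size (Å)", y = "real-space CC") +
    ggplot2::theme_minimal()
}
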