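#' Plot a 10 x 10 ROI map
#'
#' Tile plot of a regional map in the paper-style orientation: dorsoventral
#' position on the x axis (ventral left), apicobasal position on the y axis
#' (apical top); missing ROIs are blank.
#'
#' @param x an `roi_map` from [aggregate_to_roi()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.roi_map <- function(x, ...) {
  td <- tidy(x)
  td$mean[td$n_voxels == 0] <- NA
  ggplot2::ggplot(td, ggplot2::aes(x = .data$roi_dv, y = .data$roi_ab,
                                   fill = .data$mean)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_y_reverse(breaks = c(1, 5, 10)) +
    ggplot2::scale_x_continuous(breaks = c(1, 5, 10)) +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "dorsoventral ROI (ventral → dorsal)",
                  y = "apicobasal ROI (apex → base)",
                  fill = x$quantity,
                  title = paste0(x$quantity,
                                 if (!is.null(x$condition))
                                   paste0(" (", x$condition, ")"))) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.roi_map
#' @param map an `roi_map`.
#' @export
plot_roi_map <- function(map, ...) autoplot.roi_map(map, ...)

#' Plot a volumetric capnogram with its phase segmentation
#'
#' @param breath a [capno_breath()].
#' @param phases optional [segment_phases()] result (computed if absent).
#' @return A ggplot object: pCO2 vs expired volume with phase boundaries
#'   and the phase III fit.
#' @export
plot_capnogram <- function(breath, phases = NULL) {
  stopifnot(inherits(breath, "capno_breath"))
  phases <- phases %||% segment_phases(breath)
  fitline <- tibble::tibble(
    volume_ml = seq(phases$phase3[1], phases$phase3[2], length.out = 50))
  fitline$pco2_mmhg <- phases$fit[1] + phases$fit[2] * fitline$volume_ml
  ggplot2::ggplot(breath, ggplot2::aes(.data$volume_ml, .data$pco2_mmhg)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(phases$phase2[1], phases$phase3[1]),
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_line(data = fitline, color = "red", linewidth = 0.4) +
    ggplot2::annotate("point", x = mean(phases$phase3),
                      y = alveolar_pco2(breath, phases), color = "red") +
    ggplot2::labs(x = "expired volume (ml)", y = "pCO2 (mmHg)") +
    ggplot2::theme_minimal()
}

#' Plot global strain components per subject
#'
#' @param report a `study_report` from [run_study()].
#' @return A ggplot object comparing dynamic strain at ZEEP with the
#'   static/dynamic decomposition at PEEP per subject.
#' @export
plot_global_strains <- function(report) {
  stopifnot(inherits(report, "study_report"))
  g <- report$global[report$global$complete, ]
  long <- tidyr::pivot_longer(
    g[c("subject", "ls_dynamic_zeep", "ls_dynamic", "ls_static", "ls_total")],
    cols = -"subject", names_to = "component", values_to = "strain")
  ggplot2::ggplot(long, ggplot2::aes(.data$component, .data$strain)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "volumetric strain (%)") +
    ggplot2::theme_minimal()
}
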