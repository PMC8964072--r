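#' Aeration compartment thresholds
#'
#' The conventional CT aeration compartments, as closed intervals on the
#' printed bounds: hyperaerated \[-1000, -901\], normoaerated \[-900, -501\],
#' poorly aerated \[-500, -101\], non-aerated \[-100, +100\] HU. Lung voxels
#' outside \[-1000, 100\] are clamped into the nearest class.
#'
#' @param hyper_upper,normo_upper,poor_upper upper HU bound of the
#'   hyperaerated, normoaerated and poorly aerated classes.
#' @return A numeric vector of class-break HU values used by
#'   [classify_aeration()].
#' @export
aeration_thresholds <- function(hyper_upper = -901, normo_upper = -501,
                                poor_upper = -101) {
  stopifnot(hyper_upper < normo_upper, normo_upper < poor_upper)
  c(hyper_upper = hyper_upper, normo_upper = normo_upper,
    poor_upper = poor_upper)
}

.aeration_classes <- c("hyper", "normo", "poor", "non")

#' Gas fraction map from HU
#'
#' The standard linear relation between CT attenuation and gas content:
#' `gf = -HU / 1000`, clamped to \[0, 1\] (air = 1, water/tissue = 0).
#'
#' @param vol a [ct_volume()].
#' @param mask a `lung_mask` (or logical array); gas fraction is `NA`
#'   outside.
#' @return An object of class `aeration_map` with element `gas_fraction`
#'   filled (3D array in \[0, 1\], `NA` outside the lung).
#' @export
gas_fraction <- function(vol, mask) {
  stopifnot(is_ct_volume(vol))
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  stopifnot(identical(dim(m), dim(vol$hu)))
  gf <- array(NA_real_, dim(vol$hu))
  gf[m] <- pmin(pmax(-vol$hu[m] / 1000, 0), 1)
  structure(list(gas_fraction = gf, class_field = NULL,
                 spacing = vol$spacing, state = vol$state),
            class = "aeration_map")
}

#' Classify lung voxels into aeration compartments
#'
#' @param vol a [ct_volume()].
#' @param mask a `lung_mask` or logical array.
#' @param thresholds class breaks from [aeration_thresholds()].
#' @return An `aeration_map` with both `gas_fraction` and `class_field`
#'   filled; `class_field` is an integer array (1 = hyper, 2 = normo,
#'   3 = poor, 4 = non; `NA` outside the lung).
#' @examples
#' vol <- ct_volume(array(c(-950, -700, -300, -50), c(8, 8, 8))[1:8, 1:8, 1:8],
#'                  spacing = c(2, 2, 2))
#' @export
classify_aeration <- function(vol, mask, thresholds = aeration_thresholds()) {
  am <- gas_fraction(vol, mask)
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  hu <- vol$hu[m]
  # closed on the printed bounds: breaks halfway between adjacent integers
  breaks <- c(-Inf, thresholds[["hyper_upper"]] + 0.5,
              thresholds[["normo_upper"]] + 0.5,
              thresholds[["poor_upper"]] + 0.5, Inf)
  cls <- findInterval(hu, breaks, left.open = FALSE)
  cls <- pmin(pmax(cls, 1L), 4L)
  cf <- array(NA_integer_, dim(vol$hu))
  cf[m] <- cls
  am$class_field <- cf
  am
}

#' @export
print.aeration_map <- function(x, ...) {
  n <- sum(!is.na(x$gas_fraction))
  cat("<aeration_map> ", n, " lung voxels", sep = "")
  if (!is.null(x$class_field)) {
    fr <- tabulate(x$class_field[!is.na(x$class_field)], 4L) / n
    cat("; ", paste(sprintf("%s %.1f%%", .aeration_classes, 100 * fr),
                    collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Per-ROI aeration class fractions
#'
#' Voxel-count fraction of each aeration compartment within every ROI of a
#' 10 x 10 grid. Fractions sum to one per ROI by construction.
#'
#' @param map an `aeration_map` with `class_field` filled (see
#'   [classify_aeration()]); must be built on the same state's mask as the
#'   grid.
#' @param grid an `roi_grid` from [partition_rois()].
#' @return A tibble with columns `roi_ab`, `roi_dv`, `hyper`, `normo`,
#'   `poor`, `non` (fractions; `NA` rows for missing ROIs).
#' @export
aeration_fractions <- function(map, grid) {
  stopifnot(inherits(map, "aeration_map"), inherits(grid, "roi_grid"))
  if (is.null(map$class_field))
    stop("`map` has no class field: run classify_aeration() first", call. = FALSE)
  if (!identical(dim(map$class_field), dim(grid$labels_ab)))
    stop("aeration map and ROI grid have different shapes", call. = FALSE)
  idx <- which(!is.na(grid$labels_ab))
  if (anyNA(map$class_field[idx]))
    stop("ROI grid covers voxels outside the aeration map ",
         "(grid built on a different state's mask?)", call. = FALSE)
  ab <- grid$labels_ab[idx]; dv <- grid$labels_dv[idx]
  cls <- map$class_field[idx]
  n <- grid$n_ab
  counts <- array(0, c(grid$n_ab, grid$n_dv, 4L))
  tab <- table(factor(ab, levels = seq_len(grid$n_ab)),
               factor(dv, levels = seq_len(grid$n_dv)),
               factor(cls, levels = 1:4))
  counts[] <- as.numeric(tab)
  tot <- counts[, , 1] + counts[, , 2] + counts[, , 3] + counts[, , 4]
  out <- tidyr::expand_grid(roi_ab = seq_len(grid$n_ab),
                            roi_dv = seq_len(grid$n_dv))
  for (k in 1:4) {
    fr <- counts[, , k] / ifelse(tot > 0, tot, NA_real_)
    out[[.aeration_classes[k]]] <-
      fr[cbind(out$roi_ab, out$roi_dv)]
  }
  out
}

#' PEEP-minus-ZEEP change in aeration fractions per ROI
#'
#' @param zeep,peep per-ROI fraction tibbles from [aeration_fractions()],
#'   computed on grids with the same ROI topology (ROIs are matched by their
#'   `(roi_ab, roi_dv)` index across states).
#' @return A tibble with columns `roi_ab`, `roi_dv`, `d_hyper`, `d_normo`,
#'   `d_poor`, `d_non` (fraction units, PEEP - ZEEP). ROIs missing in either
#'   state are `NA`. The four deltas sum to zero per ROI.
#' @export
aeration_delta <- function(zeep, peep) {
  stopifnot(is.data.frame(zeep), is.data.frame(peep))
  j <- dplyr::inner_join(zeep, peep, by = c("roi_ab", "roi_dv"),
                         suffix = c("_z", "_p"))
  if (nrow(j) != nrow(zeep))
    stop("ROI grids have different topology", call. = FALSE)
  dplyr::transmute(j,
    roi_ab = .data$roi_ab, roi_dv = .data$roi_dv,
    d_hyper = .data$hyper_p - .data$hyper_z,
    d_normo = .data$normo_p - .data$normo_z,
    d_poor = .data$poor_p - .data$poor_z,
    d_non = .data$non_p - .data$non_z)
}
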