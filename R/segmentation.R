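#' Segmentation configuration
#'
#' Parameters of the Hounsfield-threshold lung segmentation.
#'
#' @param hu_min,hu_max HU thresholds; voxels with HU in the closed interval
#'   \[`hu_min`, `hu_max`\] are lung candidates. Defaults -1000 and -50 HU,
#'   the standard bounds that capture aerated lung while excluding soft
#'   tissue and bone.
#' @param closing_radius morphological closing radius (voxels) applied per
#'   lung to fill vessel-sized holes; 0 disables closing.
#' @param min_component_voxels components smaller than this are discarded as
#'   noise.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(hu_min = -1000, hu_max = -50,
                                closing_radius = 1L,
                                min_component_voxels = 50L) {
  stopifnot(hu_min < hu_max, closing_radius >= 0, min_component_voxels >= 1)
  structure(list(hu_min = hu_min, hu_max = hu_max,
                 closing_radius = as.integer(closing_radius),
                 min_component_voxels = as.integer(min_component_voxels)),
            class = "segmentation_config")
}

new_lung_mask <- function(mask, spacing, side = NULL, state = NULL) {
  structure(list(mask = mask, side = side, spacing = spacing, state = state),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  cat("<lung_mask> ", paste(dim(x$mask), collapse = " x "), " voxels, ",
      sum(x$mask), " in mask (", format(round(lung_volume(x), 1)), " ml)\n",
      sep = "")
  invisible(x)
}

#' Segment the lungs of a CT volume by HU thresholding
#'
#' Retains voxels with HU inside the configured threshold interval, removes
#' air connected to the volume boundary (air outside the body), keeps the two
#' largest remaining connected components as the left and right lung, and
#' optionally applies a morphological closing to fill vessel-sized holes.
#' Lungs merged at the midline are split by a single
#' erosion--relabel--dilation pass.
#'
#' @param vol a [ct_volume()].
#' @param cfg a [segmentation_config()].
#' @return A `lung_mask`: list with logical array `mask`, integer array
#'   `side` (0 = background, 1 = left, 2 = right, assigned by component
#'   centroid along the left-right axis), `spacing` and `state`.
#' @examples
#' ph <- make_phantom(phantom_config(shape = c(32, 32, 32), spacing = c(4, 4, 4)))
#' m <- segment_lungs(ph$volume)
#' lung_volume(m)
#' @export
segment_lungs <- function(vol, cfg = segmentation_config()) {
  stopifnot(is_ct_volume(vol))
  thr <- vol$hu >= cfg$hu_min & vol$hu <= cfg$hu_max
  lc <- label_components(thr)
  if (length(lc$sizes) > 0L) {
    touch <- components_touching_boundary(lc$labels, length(lc$sizes))
    keep <- which(!touch & lc$sizes >= cfg$min_component_voxels)
  } else keep <- integer(0)
  if (length(keep) == 0L) stop("no lung found", call. = FALSE)
  keep <- keep[order(lc$sizes[keep], decreasing = TRUE)]
  keep <- head(keep, 2L)

  if (length(keep) == 1L) {
    # possibly merged lungs: erode, relabel, keep two largest, dilate back
    comp <- lc$labels == keep
    er <- binary_erode(comp, 1L)
    lc2 <- label_components(er)
    if (length(lc2$sizes) >= 2L) {
      top2 <- order(lc2$sizes, decreasing = TRUE)[1:2]
      parts <- lapply(top2, function(l) binary_dilate(lc2$labels == l, 1L) & comp)
      comp_list <- parts
    } else comp_list <- list(comp)
  } else {
    comp_list <- lapply(keep, function(l) lc$labels == l)
  }

  if (cfg$closing_radius > 0L)
    comp_list <- lapply(comp_list, binary_close, radius = cfg$closing_radius)

  # left/right by centroid along axis 3 (low index = left)
  cz <- vapply(comp_list, function(m) component_centroid(array(as.integer(m), dim(m)), 1L)[3],
               numeric(1))
  side <- array(0L, dim(vol$hu))
  if (length(comp_list) == 2L) {
    left <- which.min(cz); right <- which.max(cz)
    side[comp_list[[left]]] <- 1L
    side[comp_list[[right]]] <- 2L
  } else {
    side[comp_list[[1L]]] <- if (cz[1] <= dim(vol$hu)[3] / 2) 1L else 2L
  }
  mask <- side > 0L
  new_lung_mask(mask, vol$spacing, side = side, state = vol$state)
}

#' Extract one lung from a two-lung mask
#'
#' @param mask a `lung_mask` with side labels (from [segment_lungs()] or
#'   [make_phantom()]).
#' @param side `"left"` / 1 or `"right"` / 2.
#' @return A single-lung `lung_mask`, e.g. for [partition_rois()].
#' @export
lung_side_mask <- function(mask, side) {
  stopifnot(inherits(mask, "lung_mask"))
  if (is.null(mask$side)) stop("mask carries no side labels", call. = FALSE)
  if (is.character(side)) side <- match(match.arg(side, c("left", "right")),
                                        c("left", "right"))
  new_lung_mask(mask$side == side, mask$spacing, state = mask$state)
}

#' Lung volume from a segmentation mask
#'
#' The voxel count of the mask multiplied by the voxel volume, in ml.
#'
#' @param mask a `lung_mask` or a logical 3D array.
#' @param spacing voxel spacing (mm); taken from the mask when present.
#' @param side optional: 1 or 2 to restrict to the left or right lung.
#' @return Volume in ml.
#' @examples
#' m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10] <- TRUE
#' lung_volume(m, spacing = c(1, 1, 1))  # 1 ml
#' @export
lung_volume <- function(mask, spacing = NULL, side = NULL) {
  if (inherits(mask, "lung_mask")) {
    spacing <- spacing %||% mask$spacing
    m <- if (!is.null(side)) mask$side == side else mask$mask
  } else m <- mask
  if (is.null(spacing)) stop("`spacing` required", call. = FALSE)
  n <- sum(m)
  if (n == 0L) stop("empty mask", call. = FALSE)
  n * voxel_volume_mm3(spacing) / 1000
}

#' Bundle the four state lung volumes
#'
#' @param eelv_zeep,eilv_zeep,eelv_peep,eilv_peep lung volumes in ml at
#'   end-expiration (EELV) and end-inspiration (EILV) under ZEEP and PEEP.
#' @return A one-row tibble of class `lung_volumes`.
#' @export
lung_volumes <- function(eelv_zeep, eilv_zeep, eelv_peep, eilv_peep) {
  v <- c(eelv_zeep, eilv_zeep, eelv_peep, eilv_peep)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all lung volumes must be positive", call. = FALSE)
  if (eilv_zeep < eelv_zeep || eilv_peep < eelv_peep)
    warning("EILV below EELV within a condition: check segmentations")
  out <- tibble::tibble(eelv_zeep = eelv_zeep, eilv_zeep = eilv_zeep,
                        eelv_peep = eelv_peep, eilv_peep = eilv_peep)
  class(out) <- c("lung_volumes", class(out))
  out
}
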