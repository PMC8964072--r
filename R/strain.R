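#' Strain map container
#'
#' A scalar volumetric-strain field in percent on the reference lung:
#' `100 * (det F - 1)` with `F = I + grad(u)` the deformation gradient. Values
#' are `NA` outside the lung.
#'
#' @param values 3D numeric array (%) with `NA` outside the lung.
#' @param spacing voxel spacing (mm).
#' @param component `"STATIC"`, `"DYNAMIC"` or `"TOTAL"`.
#' @param condition `"ZEEP"` or `"PEEP"`.
#' @param reference ventilation-state label of the frame the map lives in.
#' @return An object of class `strain_map`.
#' @export
strain_map <- function(values, spacing, component = c("DYNAMIC", "STATIC", "TOTAL"),
                       condition = c("ZEEP", "PEEP"), reference = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  component <- match.arg(component)
  condition <- match.arg(condition)
  inl <- values[!is.na(values)]
  if (any(!is.finite(inl)))
    stop("strain values must be finite inside the lung", call. = FALSE)
  structure(list(values = values, spacing = as.numeric(spacing),
                 component = component, condition = condition,
                 reference = reference),
            class = "strain_map")
}

#' @export
print.strain_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat("<strain_map> TS_", x$component, " (", x$condition, "), ",
      length(v), " lung voxels, mean ", format(round(mean(v), 1)),
      "%, range ", paste(format(round(range(v), 1)), collapse = " .. "),
      "%\n", sep = "")
  invisible(x)
}

#' Recover a volumetric strain map from a displacement field
#'
#' Computes the deformation gradient `F = I + grad(u)` by central differences
#' of the displacement scaled by the physical spacing, evaluates the
#' volumetric strain `(det F - 1) * 100` at every lung voxel (the quadrature
#' points), and projects it onto a regular hexahedral finite-element mesh
#' with trilinear shape functions spanning the lung bounding box: nodal
#' values are the mass-weighted (lumped L2 projection) averages of the
#' quadrature values of in-mask elements, and the voxel map is the trilinear
#' interpolation of the nodal values. The projection acts as a
#' mesh-scale-consistent smoother of the raw voxelwise Jacobian.
#'
#' @param field a [displacement_field()] on the reference grid.
#' @param mask the reference-state `lung_mask` (or logical array).
#' @param node_spacing_mm finite-element node spacing in mm (>= voxel
#'   spacing).
#' @param component,condition labels for the resulting [strain_map()].
#' @return A [strain_map()] on the reference lung.
#' @details If `det F <= 0` on more than 1% of lung voxels a warning reports
#'   the count (orientation-reversing folds indicate a failed registration).
#' @export
recover_strain <- function(field, mask, node_spacing_mm = 4,
                           component = "DYNAMIC", condition = "ZEEP") {
  stopifnot(inherits(field, "displacement_field"))
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  d <- dim(m)
  stopifnot(identical(dim(field$u)[1:3], d))
  spacing <- field$spacing
  if (any(node_spacing_mm < spacing))
    stop("`node_spacing_mm` must be >= voxel spacing", call. = FALSE)
  if (any(!is.finite(field$u))) stop("non-finite displacement field", call. = FALSE)

  jac <- dense_jacobian(field$u[, , , 1], field$u[, , , 2], field$u[, , , 3],
                        spacing)$det
  idx <- which(m)
  n_bad <- sum(jac[idx] <= 0)
  if (n_bad > 0.01 * length(idx))
    warning(sprintf("det(F) <= 0 on %d of %d lung voxels", n_bad, length(idx)))

  # node grid over the lung bounding box
  g <- coord_grids(d)
  ix <- g$x[idx]; iy <- g$y[idx]; iz <- g$z[idx]
  ns_vox <- node_spacing_mm / spacing
  lo <- c(min(ix), min(iy), min(iz)); hi <- c(max(ix), max(iy), max(iz))
  nnod <- pmax(2L, as.integer(ceiling((hi - lo) / ns_vox)) + 1L)
  step <- (hi - lo) / (nnod - 1L)
  step[hi == lo] <- 1
  # local element coordinates of each quadrature (voxel) point
  ex <- (ix - lo[1]) / step[1]; ey <- (iy - lo[2]) / step[2]
  ez <- (iz - lo[3]) / step[3]
  e0x <- pmin(floor(ex), nnod[1] - 2L); fx <- ex - e0x
  e0y <- pmin(floor(ey), nnod[2] - 2L); fy <- ey - e0y
  e0z <- pmin(floor(ez), nnod[3] - 2L); fz <- ez - e0z
  node_lin <- function(ax, ay, az) (e0x + ax + 1L) +
    (e0y + ay) * nnod[1] + (e0z + az) * nnod[1] * nnod[2]
  wsum <- numeric(prod(nnod)); vsum <- numeric(prod(nnod))
  jv <- jac[idx]
  for (az in 0:1) for (ay in 0:1) for (ax in 0:1) {
    w <- (if (ax) fx else 1 - fx) * (if (ay) fy else 1 - fy) *
         (if (az) fz else 1 - fz)
    ln <- node_lin(ax, ay, az)
    wsum <- wsum + .accumulate(ln, w, prod(nnod))
    vsum <- vsum + .accumulate(ln, w * jv, prod(nnod))
  }
  nodal <- ifelse(wsum > 1e-9, vsum / wsum, NA_real_)
  nodal <- array(nodal, nnod)

  # interpolate nodal Jacobians back to lung voxels
  nx <- (ix - lo[1]) / step[1] + 1; ny <- (iy - lo[2]) / step[2] + 1
  nz <- (iz - lo[3]) / step[3] + 1
  js <- trilinear_sample_na(nodal, nx, ny, nz)
  miss <- is.na(js)
  js[miss] <- jv[miss]  # isolated voxels with no supported nodes keep raw J
  values <- array(NA_real_, d)
  values[idx] <- (js - 1) * 100
  strain_map(values, spacing, component = component, condition = condition,
             reference = field$reference)
}

.accumulate <- function(index, weights, n) {
  out <- numeric(n)
  s <- rowsum(weights, group = index)
  out[as.integer(rownames(s))] <- s
  out
}

#' Pull a PEEP-referenced dynamic strain map back to the ZEEP frame
#'
#' The dynamic strain at PEEP lives on the end-expiratory PEEP lung; before
#' it can be summed with the static map (which lives on the end-expiratory
#' ZEEP lung) it is resampled into the ZEEP frame by evaluating it at
#' `x + u_static(x)`, where `u_static` maps EE_ZEEP to EE_PEEP.
#'
#' @param dynamic_peep a [strain_map()] referenced to `EE_PEEP`.
#' @param static_field the [displacement_field()] mapping `EE_ZEEP` to
#'   `EE_PEEP`.
#' @return A [strain_map()] in the `EE_ZEEP` frame.
#' @export
pullback_dynamic <- function(dynamic_peep, static_field) {
  stopifnot(inherits(dynamic_peep, "strain_map"),
            inherits(static_field, "displacement_field"))
  if (!is.null(dynamic_peep$reference) && !is.null(static_field$target) &&
      dynamic_peep$reference != static_field$target)
    stop("frame mismatch: dynamic map is referenced to ",
         dynamic_peep$reference, " but the static field targets ",
         static_field$target, call. = FALSE)
  d <- dim(dynamic_peep$values)
  stopifnot(identical(dim(static_field$u)[1:3], d))
  g <- coord_grids(d)
  sp <- static_field$spacing
  xs <- g$x + as.vector(static_field$u[, , , 1]) / sp[1]
  ys <- g$y + as.vector(static_field$u[, , , 2]) / sp[2]
  zs <- g$z + as.vector(static_field$u[, , , 3]) / sp[3]
  vals <- array(trilinear_sample_na(dynamic_peep$values, xs, ys, zs), d)
  strain_map(vals, sp, component = dynamic_peep$component,
             condition = dynamic_peep$condition,
             reference = static_field$reference)
}

#' Compose the total strain map
#'
#' Voxelwise sum of the static and (pulled-back) dynamic strain maps, both in
#' the `EE_ZEEP` frame; the additive total mirrors the global definition
#' `LS_TOTAL = LS_STATIC + LS_DYNAMIC`.
#'
#' @param static,dynamic_in_zeep_frame [strain_map()]s on the same grid and
#'   frame.
#' @return A [strain_map()] with component `"TOTAL"`.
#' @export
compose_total <- function(static, dynamic_in_zeep_frame) {
  stopifnot(inherits(static, "strain_map"),
            inherits(dynamic_in_zeep_frame, "strain_map"))
  if (!is.null(static$reference) && !is.null(dynamic_in_zeep_frame$reference) &&
      static$reference != dynamic_in_zeep_frame$reference)
    stop("frame mismatch: maps are referenced to different states", call. = FALSE)
  if (!identical(dim(static$values), dim(dynamic_in_zeep_frame$values)))
    stop("strain maps have different shapes", call. = FALSE)
  strain_map(static$values + dynamic_in_zeep_frame$values, static$spacing,
             component = "TOTAL", condition = "PEEP",
             reference = static$reference)
}

#' Global lung strains from the four state volumes
#'
#' Computes the global strain scalars from segmented lung volumes:
#' \deqn{LS_{STATIC} = (EELV_{PEEP} - EELV_{ZEEP}) / EELV_{ZEEP} \times 100}
#' \deqn{LS_{DYNAMIC} = (EILV_{PEEP} - EELV_{PEEP}) / EELV_{PEEP} \times 100}
#' \deqn{LS_{TOTAL} = LS_{STATIC} + LS_{DYNAMIC}}
#' \deqn{LS_{DYNAMIC,ZEEP} = (EILV_{ZEEP} - EELV_{ZEEP}) / EELV_{ZEEP} \times 100}
#' Static strain at ZEEP is taken as zero (the end-expiratory ZEEP lung is
#' the reference configuration), so the total at ZEEP equals the dynamic
#' strain at ZEEP.
#'
#' @param volumes a [lung_volumes()] (or data frame with columns
#'   `eelv_zeep`, `eilv_zeep`, `eelv_peep`, `eilv_peep`; one row per subject).
#' @return A tibble with columns `ls_static`, `ls_dynamic`, `ls_total`,
#'   `ls_dynamic_zeep` (%), one row per input row.
#' @examples
#' global_strains(lung_volumes(1000, 1300, 1200, 1500))
#' @export
global_strains <- function(volumes) {
  stopifnot(is.data.frame(volumes))
  need <- c("eelv_zeep", "eilv_zeep", "eelv_peep", "eilv_peep")
  if (!all(need %in% names(volumes)))
    stop("`volumes` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  v <- volumes[need]
  if (any(!is.finite(as.matrix(v))) || any(as.matrix(v) <= 0))
    stop("all lung volumes must be positive", call. = FALSE)
  dplyr::transmute(
    tibble::as_tibble(volumes),
    ls_static = (.data$eelv_peep - .data$eelv_zeep) / .data$eelv_zeep * 100,
    ls_dynamic = (.data$eilv_peep - .data$eelv_peep) / .data$eelv_peep * 100,
    ls_total = .data$ls_static + .data$ls_dynamic,
    ls_dynamic_zeep = (.data$eilv_zeep - .data$eelv_zeep) / .data$eelv_zeep * 100
  )
}
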