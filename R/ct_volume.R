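#' CT volume container
#'
#' A `ct_volume` wraps a 3D array of Hounsfield units together with its
#' physical voxel spacing and a ventilation-state label. The package uses a
#' fixed anatomical axis convention:
#'
#' * axis 1: apicobasal, index increases apex to base;
#' * axis 2: dorsoventral, index increases ventral to dorsal (supine subject);
#' * axis 3: left-right.
#'
#' All regional direction names (apical/basal quadrants, dorsoventral aeration
#' gradients) are defined on these array axes, so volumes read from files with
#' a different on-disk axis order must be permuted into this convention (see
#' the `axis_perm` argument of [read_ct_volume()]).
#'
#' @param hu 3D numeric array of Hounsfield units, each dimension >= 8,
#'   values within \[-1100, 3100\].
#' @param spacing numeric length-3, voxel spacing in mm along the three axes;
#'   all components must be > 0. Anisotropic spacing is supported.
#' @param state optional ventilation-state label, one of `"EE_ZEEP"`,
#'   `"EI_ZEEP"`, `"EE_PEEP"`, `"EI_PEEP"` (end-expiration/-inspiration at
#'   zero or positive end-expiratory pressure).
#' @return An object of class `ct_volume`: a list with elements `hu`,
#'   `spacing` and `state`.
#' @examples
#' vol <- ct_volume(array(-700, c(8, 8, 8)), spacing = c(2, 2, 2))
#' dim(vol$hu)
#' @export
ct_volume <- function(hu, spacing, state = NULL) {
  if (!is.array(hu) || length(dim(hu)) != 3L)
    stop("`hu` must be a 3D array", call. = FALSE)
  if (any(dim(hu) < 8L))
    stop("`hu` must have shape >= 8 along every axis", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (mm)", call. = FALSE)
  rng <- range(hu, na.rm = TRUE)
  if (rng[1] < -1100 || rng[2] > 3100)
    stop("HU values outside the calibrated range [-1100, 3100]", call. = FALSE)
  if (!is.null(state)) state <- match.arg(state, .state_labels)
  structure(list(hu = hu, spacing = spacing, state = state),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$hu), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm", if (!is.null(x$state)) paste0(", state ", x$state), "\n", sep = "")
  cat("  HU range: ", paste(format(round(range(x$hu, na.rm = TRUE), 1)),
                            collapse = " .. "), "\n", sep = "")
  invisible(x)
}

is_ct_volume <- function(x) inherits(x, "ct_volume")

voxel_volume_mm3 <- function(spacing) prod(spacing)

#' Read a CT volume from a NIfTI file
#'
#' Reads a HU-calibrated NIfTI (`.nii` / `.nii.gz`) scalar volume and returns
#' a [ct_volume()] in the package's anatomical axis convention. Files whose
#' on-disk axis order differs from the convention are permuted with
#' `axis_perm`; the spacing is permuted consistently.
#'
#' @param path path to a NIfTI file.
#' @param state optional ventilation-state label (see [ct_volume()]).
#' @param axis_perm integer permutation of `1:3` mapping on-disk axes into the
#'   package convention: element `i` gives the on-disk axis that becomes
#'   convention axis `i`.
#' @return A [ct_volume()].
#' @details The voxel spacing is taken from the file header; a header with
#'   non-positive spacing is rejected rather than silently defaulting to 1 mm.
#' @export
read_ct_volume <- function(path, state = NULL, axis_perm = c(1L, 2L, 3L)) {
  axis_perm <- as.integer(axis_perm)
  if (!identical(sort(axis_perm), 1:3))
    stop("`axis_perm` must be a permutation of 1:3", call. = FALSE)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("'", path, "' is not a 3D scalar volume", call. = FALSE)
  spacing <- RNifti::pixdim(img)[seq_len(3L)]
  if (length(spacing) < 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'", path, "' has no usable voxel spacing in its header", call. = FALSE)
  if (!identical(axis_perm, 1:3)) {
    arr <- aperm(arr, axis_perm)
    spacing <- spacing[axis_perm]
  }
  ct_volume(arr, spacing, state = state)
}

#' Write a CT volume, mask or scalar map to NIfTI
#'
#' @param x a [ct_volume()], a `lung_mask`, a `strain_map`, or a plain 3D/4D
#'   numeric array.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm; taken from `x` when it carries one.
#' @param datatype NIfTI storage datatype (masks are written as `"uint8"`,
#'   continuous maps as `"float"`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path, spacing = NULL, datatype = NULL) {
  if (is_ct_volume(x)) {
    arr <- x$hu; spacing <- spacing %||% x$spacing
    datatype <- datatype %||% "float"
  } else if (inherits(x, "lung_mask")) {
    arr <- array(as.integer(x$mask), dim = dim(x$mask))
    spacing <- spacing %||% x$spacing
    datatype <- datatype %||% "uint8"
  } else if (inherits(x, "strain_map")) {
    arr <- x$values; spacing <- spacing %||% x$spacing
    datatype <- datatype %||% "float"
  } else if (is.array(x)) {
    arr <- x
    datatype <- datatype %||% "float"
  } else stop("cannot write object of class ", class(x)[1], call. = FALSE)
  if (is.null(spacing)) stop("`spacing` required when `x` carries none", call. = FALSE)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
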