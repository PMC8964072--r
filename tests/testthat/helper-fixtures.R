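# Shared fixtures: a small (32^3, 6 mm) noiseless phantom covering the same
# ~192 mm physical thorax as the default geometry, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

small_phantom <- function() {
  if (is.null(.fixture_env$ph))
    .fixture_env$ph <- make_phantom(
      phantom_config(shape = c(32, 32, 32), spacing = c(6, 6, 6)))
  .fixture_env$ph
}

small_mask <- function() {
  if (is.null(.fixture_env$mask))
    .fixture_env$mask <- segment_lungs(small_phantom()$volume)
  .fixture_env$mask
}

medium_phantom <- function() {
  if (is.null(.fixture_env$ph64))
    .fixture_env$ph64 <- make_phantom(
      phantom_config(shape = c(64, 64, 64), spacing = c(3, 3, 3)))
  .fixture_env$ph64
}

# single analytic ellipsoid lung at fine (1.2 mm) resolution: >= 64 voxels
# along the apicobasal and dorsoventral axes, where slab balance to 1% is
# achievable
fine_lung_mask <- function() {
  if (is.null(.fixture_env$fine)) {
    shape <- c(104, 76, 48); sp <- c(1.2, 1.2, 1.2)
    X <- lungstrain:::phantom_coords(shape, sp)
    semi <- c(58, 42, 25)
    inside <- (X[, 1] / semi[1])^2 + (X[, 2] / semi[2])^2 +
              (X[, 3] / semi[3])^2 <= 1
    .fixture_env$fine <- lungstrain:::new_lung_mask(array(inside, shape), sp)
  }
  .fixture_env$fine
}

# displacement field built directly from a closed-form u(X) (mm)
field_from_fun <- function(ufun, shape, spacing) {
  X <- lungstrain:::phantom_coords(shape, spacing)
  U <- ufun(X)
  u4 <- array(0, c(shape, 3L))
  for (k in 1:3) u4[, , , k] <- U[, k]
  displacement_field(u4, spacing)
}

lung_values <- function(strain) strain$values[!is.na(strain$values)]
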