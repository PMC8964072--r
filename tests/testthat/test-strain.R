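test_that("zero displacement gives zero strain everywhere", {
  ph <- small_phantom()
  fld <- field_from_fun(function(X) X * 0, dim(ph$volume$hu), ph$volume$spacing)
  sm <- recover_strain(fld, ph$mask, node_spacing_mm = 12)
  expect_equal(max(abs(lung_values(sm))), 0, tolerance = 1e-10)
})

test_that("uniform scaling recovers (s^3 - 1) x 100 and shear recovers zero", {
  ph <- small_phantom()
  shape <- dim(ph$volume$hu); sp <- ph$volume$spacing
  s <- 1.1
  fld <- field_from_fun(function(X) X * (s - 1), shape, sp)
  sm <- recover_strain(fld, ph$mask, node_spacing_mm = 12)
  expect_equal(mean(lung_values(sm)), (s^3 - 1) * 100, tolerance = 1e-6)
  expect_lt(max(abs(lung_values(sm) - (s^3 - 1) * 100)), 1e-6)

  gamma <- 0.2  # simple shear: u = (gamma * y, 0, 0), volume preserving
  fld2 <- field_from_fun(function(X) cbind(gamma * X[, 2], 0, 0), shape, sp)
  sm2 <- recover_strain(fld2, ph$mask, node_spacing_mm = 12)
  expect_lt(max(abs(lung_values(sm2))), 1e-8)
})

test_that("recovered strain matches closed-form on smooth analytic warps", {
  ph <- medium_phantom()
  msk <- ph$mask
  warps <- list(
    radial = make_warp("radial_inflation", centre_mm = c(0, 0, -32),
                       radius_mm = 60, peak_strain = 0.3),
    graded = make_warp("graded_dorsoventral", y_range_mm = c(-42, 42),
                       strain_ventral = 0.1, strain_dorsal = 0.4))
  for (nm in names(warps)) {
    fld <- warp_displacement_field(warps[[nm]], dim(msk$mask), msk$spacing)
    sm <- recover_strain(fld, msk, node_spacing_mm = 6)
    truth <- warp_strain_map(warps[[nm]], msk)
    err <- abs(lung_values(sm) - lung_values(truth))
    expect_lt(mean(err), 0.5)
    expect_lt(max(err), 2)
  }
})

test_that("halving the node spacing moves the lung-mean strain by < 1 point", {
  ph <- medium_phantom()
  w <- make_warp("radial_inflation", centre_mm = c(0, 0, -32),
                 radius_mm = 60, peak_strain = 0.3)
  fld <- warp_displacement_field(w, dim(ph$mask$mask), ph$mask$spacing)
  m1 <- mean(lung_values(recover_strain(fld, ph$mask, node_spacing_mm = 12)))
  m2 <- mean(lung_values(recover_strain(fld, ph$mask, node_spacing_mm = 6)))
  expect_lt(abs(m1 - m2), 1)
})

test_that("pullback leaves constants invariant and matches analytic composition", {
  ph <- small_phantom()
  shape <- dim(ph$volume$hu); sp <- ph$volume$spacing
  zero <- field_from_fun(function(X) X * 0, shape, sp)
  const_map <- strain_map(array(24, shape), sp, component = "DYNAMIC",
                          condition = "PEEP")
  expect_equal(pullback_dynamic(const_map, zero)$values, const_map$values)

  w_static <- make_warp("graded_dorsoventral", y_range_mm = c(-42, 42),
                        strain_ventral = 0.2, strain_dorsal = 0.5)
  f_static <- warp_displacement_field(w_static, shape, sp)
  # spatially varying "dynamic" map defined analytically in the PEEP frame
  g <- function(y) 20 + 0.2 * y
  X <- lungstrain:::phantom_coords(shape, sp)
  dyn_peep <- strain_map(array(g(X[, 2]), shape), sp, component = "DYNAMIC",
                         condition = "PEEP")
  pulled <- pullback_dynamic(dyn_peep, f_static)
  expected <- g(X[, 2] + w_static$u(X)[, 2])
  idx <- which(ph$mask$mask)
  expect_lt(max(abs(pulled$values[idx] - expected[idx])), 1)
})

test_that("total strain is the exact voxelwise sum of components", {
  shape <- c(8, 8, 8); sp <- c(2, 2, 2)
  st <- strain_map(array(46.9, shape), sp, component = "STATIC",
                   condition = "PEEP")
  dy <- strain_map(array(24.0, shape), sp, component = "DYNAMIC",
                   condition = "PEEP")
  tot <- compose_total(st, dy)
  expect_equal(unique(as.vector(tot$values)), 70.9)
  expect_identical(tot$component, "TOTAL")

  set.seed(3)
  a <- strain_map(array(rnorm(512, 40, 15), shape), sp, component = "STATIC",
                  condition = "PEEP")
  b <- strain_map(array(rnorm(512, 20, 10), shape), sp, component = "DYNAMIC",
                  condition = "PEEP")
  expect_equal(compose_total(a, b)$values - a$values - b$values,
               array(0, shape))

  zero <- strain_map(array(0, shape), sp, component = "STATIC",
                     condition = "PEEP")
  expect_equal(compose_total(zero, b)$values, b$values)
})

test_that("pullback and composition reject inconsistent frames", {
  shape <- c(8, 8, 8); sp <- c(2, 2, 2)
  dyn <- strain_map(array(1, shape), sp, component = "DYNAMIC",
                    condition = "PEEP", reference = "EE_PEEP")
  fld <- displacement_field(array(0, c(shape, 3)), sp,
                            reference = "EE_ZEEP", target = "EI_ZEEP")
  expect_error(pullback_dynamic(dyn, fld), "frame mismatch")
  a <- strain_map(array(1, shape), sp, component = "STATIC",
                  condition = "PEEP", reference = "EE_ZEEP")
  b <- strain_map(array(1, shape), sp, component = "DYNAMIC",
                  condition = "PEEP", reference = "EE_PEEP")
  expect_error(compose_total(a, b), "frame mismatch")
})

test_that("global strain formulas follow the volume-ratio definitions", {
  gs <- global_strains(lung_volumes(1000, 1300, 1000, 1240))
  expect_equal(gs$ls_static, 0)
  expect_equal(gs$ls_dynamic_zeep, 30)
  expect_equal(gs$ls_dynamic, 24)
  expect_equal(gs$ls_total, gs$ls_static + gs$ls_dynamic)

  # printed component means: 46.9 + 24.0 -> 70.9, i.e. 71 at integer precision
  v0 <- 1000
  gs2 <- global_strains(tibble::tibble(
    eelv_zeep = v0, eilv_zeep = 1.334 * v0,
    eelv_peep = 1.469 * v0, eilv_peep = 1.469 * v0 * 1.24))
  expect_equal(gs2$ls_static, 46.9, tolerance = 1e-9)
  expect_equal(gs2$ls_dynamic, 24.0, tolerance = 1e-9)
  expect_equal(gs2$ls_total, 70.9, tolerance = 1e-9)
  expect_equal(round(gs2$ls_total), 71)

  expect_error(global_strains(lung_volumes(0, 1, 1, 1)), "positive")
  expect_error(global_strains(tibble::tibble(eelv_zeep = -1, eilv_zeep = 1,
                                             eelv_peep = 1, eilv_peep = 1)),
               "positive")
})
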