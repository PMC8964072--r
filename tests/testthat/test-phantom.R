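test_that("phantom generation is deterministic and noise leaves truth unchanged", {
  cfg1 <- phantom_config(shape = c(32, 32, 32), spacing = c(6, 6, 6),
                         noise_sd = 15, seed = 5)
  a <- make_phantom(cfg1); b <- make_phantom(cfg1)
  expect_identical(a$volume$hu, b$volume$hu)
  cfg2 <- phantom_config(shape = c(32, 32, 32), spacing = c(6, 6, 6),
                         noise_sd = 15, seed = 6)
  c <- make_phantom(cfg2)
  expect_false(identical(a$volume$hu, c$volume$hu))
  expect_identical(a$mask$mask, c$mask$mask)               # same anatomy
  expect_identical(a$class_volumes, c$class_volumes)       # same ground truth
  expect_error(phantom_config(noise_sd = 10), "seed")
})

test_that("a uniform-HU lung classifies entirely into one compartment", {
  cfg <- phantom_config(shape = c(32, 32, 32), spacing = c(6, 6, 6),
                        hu_ventral = -701, hu_dorsal = -699)
  ph <- make_phantom(cfg)
  cls <- classify_aeration(ph$volume, ph$mask)$class_field
  expect_equal(unique(cls[!is.na(cls)]), 2L)  # all normoaerated
  expect_equal(ph$class_volumes$fraction[2], 1, tolerance = 1e-9)
})

test_that("analytic normoaerated fraction equals the ramp-geometry slab integral", {
  ph <- small_phantom()  # ramp -900 -> -300
  cv <- ph$class_volumes
  # normo spans HU <= -500.5: y position from the ramp inversion, volume
  # from the ellipsoid slab formula (independent re-derivation)
  ax <- ph$config$lung_semiaxes_mm
  b <- ax[2]
  y_cut <- -b + (-500.5 - -900) / (-300 - -900) * (2 * b)
  f <- function(y) y - y^3 / (3 * b^2)
  slab <- pi * ax[1] * ax[3] * (f(y_cut) - f(-b)) / 1000
  expect_equal(cv$volume_ml[cv$class == "normo"], 2 * slab, tolerance = 1e-9)
  expect_equal(sum(cv$fraction), 1, tolerance = 1e-9)
  expect_equal(cv$volume_ml[cv$class == "hyper"], 0)
})

test_that("an intraluminal bronchus creates a mid-dorsal hyperaerated signature", {
  cfg <- phantom_config(shape = c(64, 64, 64), spacing = c(3, 3, 3),
                        bronchus = TRUE, bronchus_radius_mm = 8)
  ph <- make_phantom(cfg)
  expect_gt(ph$class_volumes$volume_ml[1], 0)
  m <- segment_lungs(ph$volume)
  # bronchus lives in the right lung: hyper fraction appears there
  g <- partition_rois(lungstrain:::new_lung_mask(m$side == 2, m$spacing))
  fr <- aeration_fractions(classify_aeration(ph$volume, m), g)
  mid_dorsal <- fr$roi_dv >= 6 & !is.na(fr$hyper)
  expect_gt(max(fr$hyper[mid_dorsal]), 0)
  # and the measured hyper volume matches the analytic tube volume
  vox_ml <- prod(cfg$spacing) / 1000
  cls <- classify_aeration(ph$volume, ph$mask)$class_field
  measured <- sum(cls == 1L, na.rm = TRUE) * vox_ml
  expect_lt(abs(measured - ph$class_volumes$volume_ml[1]) /
            ph$class_volumes$volume_ml[1], 0.15)
  expect_equal(sum(ph$class_volumes$fraction), 1, tolerance = 1e-9)
})

test_that("analytic warps carry exact strain and stay invertible", {
  tr <- make_warp("translation", shift_mm = c(1, -2, 3))
  X <- matrix(rnorm(30, 0, 40), 10, 3)
  expect_equal(tr$jac(X), rep(1, 10))
  expect_equal(tr$inverse(X + tr$u(X)), X)

  af <- make_warp("affine", scale = c(1.1, 1.05, 1.2))
  expect_equal(unique(af$jac(X)), 1.1 * 1.05 * 1.2)
  expect_equal(af$inverse(X + af$u(X)), X, tolerance = 1e-12)

  rad <- make_warp("radial_inflation", centre_mm = c(0, 0, 0),
                   radius_mm = 50, peak_strain = 0.3)
  expect_equal(rad$jac(matrix(0, 1, 3)), 1.3, tolerance = 1e-9)
  Y <- X + rad$u(X)
  expect_equal(rad$inverse(Y), X, tolerance = 1e-2)
  expect_error(make_warp("radial_inflation", peak_strain = 40), "invertible")

  gr <- make_warp("graded_dorsoventral", y_range_mm = c(-42, 42),
                  strain_ventral = 0.1, strain_dorsal = 0.4)
  expect_equal(gr$jac(matrix(c(0, -42, 0), 1, 3)), 1.1)
  expect_equal(gr$jac(matrix(c(0, 42, 0), 1, 3)), 1.4)
  expect_equal(gr$inverse(X + gr$u(X)), X, tolerance = 1e-2)
  expect_error(make_warp("graded_dorsoventral", y_range_mm = c(-10, 10),
                         strain_ventral = 0.1, strain_dorsal = 5),
               "det <= 0")
})

test_that("warp composition chains displacement, Jacobian and inverse", {
  a <- make_warp("affine", scale = 1.1)
  b <- make_warp("graded_dorsoventral", y_range_mm = c(-42, 42),
                 strain_ventral = 0.05, strain_dorsal = 0.2)
  comp <- compose_warps(b, a)
  X <- matrix(rnorm(30, 0, 30), 10, 3)
  Xi <- X + a$u(X)
  expect_equal(X + comp$u(X), Xi + b$u(Xi))
  expect_equal(comp$jac(X), a$jac(X) * b$jac(Xi))
  expect_equal(comp$inverse(X + comp$u(X)), X, tolerance = 1e-2)
})

test_that("warped phantoms conserve tissue so volumes track the Jacobian", {
  ph <- small_phantom()
  ident <- make_warp("translation", shift_mm = c(0, 0, 0))
  same <- apply_warp_to_phantom(ph, ident)
  expect_equal(same$volume$hu, ph$volume$hu)
  expect_identical(same$mask$mask, ph$mask$mask)

  s <- 1.331^(1 / 3)  # uniform 33.1% volumetric inflation
  infl <- make_warp("affine", scale = s)
  tgt <- apply_warp_to_phantom(ph, infl)
  ratio <- lung_volume(tgt$mask) / lung_volume(ph$mask)
  expect_lt(abs(ratio - 1.331) / 1.331, 0.02)
  # segmented-volume global strain reproduces the warp's volume gain
  mz <- segment_lungs(ph$volume); mp <- segment_lungs(tgt$volume)
  gs <- global_strains(lung_volumes(lung_volume(mz), lung_volume(mz) * 1.0001,
                                    lung_volume(mp), lung_volume(mp) * 1.0001))
  expect_lt(abs(gs$ls_static - 33.1), 1.5)
  # gas content rescaled: inflated lung is darker (more gas) than source
  expect_lt(mean(tgt$volume$hu[tgt$mask$mask]), mean(ph$volume$hu[ph$mask$mask]))
})

test_that("graded warps give monotone dorsoventral ROI strain ramps", {
  ph <- small_phantom()
  m <- small_mask()
  w <- make_warp("graded_dorsoventral", y_range_mm = c(-42, 42),
                 strain_ventral = 0.1, strain_dorsal = 0.4)
  truth <- warp_strain_map(w, ph$mask)
  g <- partition_rois(lungstrain:::new_lung_mask(m$side == 1, m$spacing))
  rm <- aggregate_to_roi(truth, g)
  row_means <- colMeans(ifelse(rm$n > 0, rm$mean, NA), na.rm = TRUE)
  expect_true(all(diff(row_means) > 0))
  expect_lt(abs(row_means[1] - 10) , 5)
  expect_lt(abs(row_means[10] - 40), 5)
})
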