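reg_phantom <- function(seed = 1) {
  make_phantom(phantom_config(shape = c(32, 32, 32), spacing = c(6, 6, 6),
                              texture_amp_hu = 120, texture_seed = seed))
}

test_that("registering a volume to itself yields a near-zero field", {
  ph <- reg_phantom()
  m <- segment_lungs(ph$volume)
  f <- register_ffd(ph$volume, ph$volume, m,
                    registration_config(levels = 2, max_iter = 30))
  expect_lt(max(abs(f$u)) / min(ph$volume$spacing), 0.1)
})

test_that("a pure translation is recovered within half a voxel", {
  ph <- reg_phantom()
  m <- segment_lungs(ph$volume)
  w <- make_warp("translation", shift_mm = c(0, 3, 0))
  tgt <- apply_warp_to_phantom(ph, w)
  f <- register_ffd(ph$volume, tgt$volume, m,
                    registration_config(metric = "ssd", levels = 2,
                                        max_iter = 80))
  idx <- which(m$mask)
  rec <- c(mean(f$u[, , , 1][idx]), mean(f$u[, , , 2][idx]),
           mean(f$u[, , , 3][idx]))
  expect_lt(max(abs(rec - c(0, 3, 0))), 0.5 * min(ph$volume$spacing))
})

test_that("registration is deterministic and validates its inputs", {
  ph <- reg_phantom()
  m <- segment_lungs(ph$volume)
  w <- make_warp("translation", shift_mm = c(0, 3, 0))
  tgt <- apply_warp_to_phantom(ph, w)
  cfg <- registration_config(levels = 2, max_iter = 15)
  f1 <- register_ffd(ph$volume, tgt$volume, m, cfg)
  f2 <- register_ffd(ph$volume, tgt$volume, m, cfg)
  expect_identical(f1$u, f2$u)

  other <- ct_volume(ph$volume$hu, ph$volume$spacing * 2)
  expect_error(register_ffd(ph$volume, other, m, cfg), "share grid")
})

test_that("analytic objective gradients match finite differences", {
  set.seed(42)
  d <- c(12, 12, 12)
  f <- array(rnorm(prod(d)), d) * 100 - 500
  m <- array(rnorm(prod(d)), d) * 100 - 500
  msk <- array(FALSE, d); msk[4:9, 4:9, 4:9] <- TRUE
  spacing <- c(2, 2, 2)
  basis <- lapply(d, lungstrain:::bspline_basis, spacing_vox = 4)
  for (metric in c("ssd", "sstvd")) {
    ff <- if (metric == "sstvd") lungstrain:::hu_to_tissue_fraction(f) else f
    mm <- if (metric == "sstvd") lungstrain:::hu_to_tissue_fraction(m) else m
    prob <- lungstrain:::.ffd_level_problem(
      ff, mm, which(msk), spacing,
      list(x = basis[[1]], y = basis[[2]], z = basis[[3]]),
      metric, 1e-3, if (metric == "sstvd") 1 else -1000)
    par <- rnorm(3 * prob$nc, 0, 0.37)
    g <- prob$gr(par)
    ik <- sample(length(par), 10)
    gn <- vapply(ik, function(i) {
      e <- 1e-6
      p1 <- par; p1[i] <- p1[i] + e
      p2 <- par; p2[i] <- p2[i] - e
      (prob$fn(p1) - prob$fn(p2)) / (2 * e)
    }, numeric(1))
    expect_lt(max(abs(g[ik] - gn) / (abs(gn) + 1e-6)), 0.02,
              label = paste(metric, "gradient error"))
  }
})

test_that("warp_volume resamples correctly and reduces the masked SSD", {
  ph <- reg_phantom()
  m <- segment_lungs(ph$volume)
  zero <- displacement_field(array(0, c(dim(ph$volume$hu), 3)),
                             ph$volume$spacing)
  expect_equal(warp_volume(zero, ph$volume)$hu, ph$volume$hu * 1.0)

  w <- make_warp("translation", shift_mm = c(0, 6, 0))  # one voxel
  tgt <- apply_warp_to_phantom(ph, w)
  shift_field <- displacement_field(
    array(rep(c(0, 6, 0), each = prod(dim(ph$volume$hu))),
          c(dim(ph$volume$hu), 3)), ph$volume$spacing)
  back <- warp_volume(shift_field, tgt$volume)
  idx <- which(lungstrain:::binary_erode(m$mask, 1))
  expect_lt(mean(abs(back$hu[idx] - ph$volume$hu[idx])), 1)

  # composing warp_volume with the registration output maps moving ~ fixed
  f <- register_ffd(ph$volume, tgt$volume, m,
                    registration_config(metric = "ssd", levels = 2,
                                        max_iter = 80))
  warped <- warp_volume(f, tgt$volume)
  ssd_pre <- sum((tgt$volume$hu[idx] - ph$volume$hu[idx])^2)
  ssd_post <- sum((warped$hu[idx] - ph$volume$hu[idx])^2)
  expect_lt(ssd_post, 0.3 * ssd_pre)
})

test_that("forward and reverse registrations are inverse-consistent", {
  ph <- reg_phantom()
  m <- segment_lungs(ph$volume)
  w <- make_warp("radial_inflation", centre_mm = c(0, 0, -32),
                 radius_mm = 60, peak_strain = 0.15)
  tgt <- apply_warp_to_phantom(ph, w)
  m_tgt <- segment_lungs(tgt$volume)
  cfg <- registration_config(metric = "sstvd", levels = 2, max_iter = 100)
  fab <- register_ffd(ph$volume, tgt$volume, m, cfg)
  fba <- register_ffd(tgt$volume, ph$volume, m_tgt, cfg)
  # compose: x -> x + u_ab(x) -> + u_ba evaluated there; residual in voxels
  d <- dim(ph$volume$hu); sp <- ph$volume$spacing
  g <- lungstrain:::coord_grids(d)
  idx <- which(lungstrain:::binary_erode(m$mask, 1))
  xs <- g$x[idx] + fab$u[, , , 1][idx] / sp[1]
  ys <- g$y[idx] + fab$u[, , , 2][idx] / sp[2]
  zs <- g$z[idx] + fab$u[, , , 3][idx] / sp[3]
  res <- 0
  for (k in 1:3) {
    ub <- lungstrain:::trilinear_sample(fba$u[, , , k], xs, ys, zs, fill = 0)
    tot <- fab$u[, , , k][idx] + ub
    res <- res + (tot / sp[k])^2
  }
  expect_lt(mean(sqrt(res)), 1)  # < 1 voxel mean round-trip error
})

test_that("registration preserves orientation on nearly all lung voxels", {
  ph <- reg_phantom()
  m <- segment_lungs(ph$volume)
  w <- make_warp("graded_dorsoventral", y_range_mm = c(-42, 42),
                 strain_ventral = 0.1, strain_dorsal = 0.4)
  tgt <- apply_warp_to_phantom(ph, w)
  f <- register_ffd(ph$volume, tgt$volume, m,
                    registration_config(metric = "sstvd", levels = 2,
                                        max_iter = 120))
  J <- lungstrain:::dense_jacobian(f$u[, , , 1], f$u[, , , 2], f$u[, , , 3],
                                   ph$volume$spacing)$det
  expect_gt(mean(J[m$mask] > 0), 0.99)
})
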