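linear_phase3_breath <- function(v1 = 30, v2 = 60, vt = 150,
                                 p_at_v2 = 35, p_at_vt = 45, n = 300) {
  v <- seq(0, vt, length.out = n)
  p <- numeric(n)
  rise <- v > v1 & v < v2
  p[rise] <- p_at_v2 * (1 - cos(pi * (v[rise] - v1) / (v2 - v1))) / 2
  iii <- v >= v2
  p[iii] <- p_at_v2 + (p_at_vt - p_at_v2) * (v[iii] - v2) / (vt - v2)
  capno_breath(v, p)
}

test_that("phase segmentation finds the alveolar plateau", {
  br <- linear_phase3_breath()
  ph <- segment_phases(br)
  expect_lt(abs(ph$phase3[1] - 60), 5)
  expect_equal(ph$phase3[2], 150)
  expect_lt(ph$phase2[1], ph$phase3[1])

  flat0 <- capno_breath(seq(0, 100, length.out = 100), rep(0, 100))
  expect_error(segment_phases(flat0), "no phase III")

  # plateau from zero volume: phase III spans essentially the whole breath
  plateau <- capno_breath(seq(0, 100, length.out = 100), rep(38, 100))
  php <- segment_phases(plateau)
  expect_lt(php$phase3[1], 2)
})

test_that("alveolar pCO2 is the phase III fit at the volume midpoint", {
  br <- linear_phase3_breath(p_at_v2 = 35, p_at_vt = 45)
  expect_equal(alveolar_pco2(br), 40, tolerance = 0.2)

  flat <- capno_breath(seq(0, 100, length.out = 120),
                       c(rep(0, 20), rep(38, 100)))
  expect_equal(alveolar_pco2(flat), 38, tolerance = 0.3)

  set.seed(9)
  noisy <- linear_phase3_breath()
  noisy$pco2_mmhg <- pmax(noisy$pco2_mmhg + rnorm(nrow(noisy), 0, 0.5), 0)
  expect_lt(abs(alveolar_pco2(noisy) - 40), 0.5)
})

test_that("mixed expired pCO2 is the volume-weighted trace mean", {
  n <- 400
  v <- seq(0, 100, length.out = n)
  expect_equal(mixed_expired_pco2(capno_breath(v, rep(38, n))), 38)
  step <- ifelse(v <= 50, 0, 40)
  expect_equal(mixed_expired_pco2(capno_breath(v, step)), 20, tolerance = 0.15)
  # FECO2 x barometric identity: constant FCO2 = 0.05 at 760 mmHg
  br <- capno_breath(v, rep(0.05 * 760, n), barometric_mmhg = 760)
  expect_equal(mixed_expired_pco2(br), 38)
  expect_lte(mixed_expired_pco2(br), max(br$pco2_mmhg))
})

test_that("Bohr dead space follows its defining ratio", {
  expect_equal(bohr_dead_space(40, 40), 0)
  expect_equal(bohr_dead_space(40, 0), 1)
  expect_equal(bohr_dead_space(40, 20), 0.5)
  expect_equal(bohr_dead_space(40, 20), bohr_dead_space(80, 40))  # scale-free
  expect_error(bohr_dead_space(0, 0), "PACO2")
  expect_warning(bohr_dead_space(40, 45), "exceeds")
})

test_that("generated capnograms agree with their closed-form Bohr fraction", {
  # sharp-step breath: Bohr equals VD/VT exactly
  sharp <- make_capnogram(vt_ml = 150, vd_ml = 45, plateau_mmhg = 38,
                          slope_mmhg_per_ml = 0, phase2_halfwidth_ml = 0.4)
  expect_equal(sharp$analytic$bohr, 45 / 150, tolerance = 0.005)

  # noisy generated breaths across the physiological range: computed Bohr
  # within 0.02 of the analytic value
  targets <- seq(0.3, 0.7, length.out = 20)
  for (i in seq_along(targets)) {
    g <- make_capnogram(bohr = targets[i], noise_sd = 0.5, seed = 1000 + i)
    expect_equal(g$analytic$bohr, targets[i], tolerance = 1e-6)
    # high-dead-space breaths leave a short alveolar plateau, so the span
    # requirement is lowered accordingly
    got <- breath_dead_space(g$breath, min_span_frac = 0.15)
    expect_lt(abs(got$bohr - g$analytic$bohr), 0.02)
  }
})

test_that("capnogram traces round-trip through the flow CSV reader", {
  g <- make_capnogram(bohr = 0.5)
  n <- nrow(g$breath)
  t_s <- seq(0, 2, length.out = n)
  flow <- c(diff(g$breath$volume_ml) / diff(t_s), 0)  # constant-ish flow
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = t_s, flow_ml_s = flow,
                              pco2_mmhg = g$breath$pco2_mmhg), f,
                   row.names = FALSE)
  br <- read_capno_csv(f)
  expect_lt(abs(br$volume_ml[n] - g$breath$volume_ml[n]), 1)
  expect_lt(abs(breath_dead_space(br)$bohr - g$analytic$bohr), 0.02)
})

test_that("driving pressure and compliance come from the pause pressures", {
  peep <- mechanics_scalars(146, pplat_cmh2o = 12.3, peep_total_cmh2o = 5)
  expect_equal(peep$driving_pressure_cmh2o, 7.3)
  expect_equal(peep$cstat_ml_cmh2o, 20.0)
  zeep <- mechanics_scalars(146, pplat_cmh2o = 8.3, peep_total_cmh2o = 0)
  expect_equal(zeep$driving_pressure_cmh2o, 8.3)
  expect_error(mechanics_scalars(146, pplat_cmh2o = 4, peep_total_cmh2o = 5),
               "exceed")
  # data-frame-first interface
  df <- tibble::tibble(condition = c("ZEEP", "PEEP"), vt_ml = c(146, 146),
                       pplat_cmh2o = c(8.3, 12.3), peep_total_cmh2o = c(0, 5))
  out <- mechanics_scalars(df)
  expect_equal(out$driving_pressure_cmh2o, c(8.3, 7.3))
  expect_true(all(c("condition", "cstat_ml_cmh2o") %in% names(out)))
})

test_that("capno breath container validates its invariants", {
  expect_error(capno_breath(c(0, 1, 2), c(0, 1)), "lengths")
  expect_error(capno_breath(c(1, 2, 3), c(0, 0, 0)), "start at zero")
  expect_error(capno_breath(c(0, 2, 1), c(0, 0, 0)), "nondecreasing")
  expect_error(capno_breath(c(0, 1, 2), c(0, -1, 0)), ">= 0")
})
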