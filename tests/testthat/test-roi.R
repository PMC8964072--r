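test_that("a uniform slab partitions into 100 equal ROIs with equal planes", {
  mask <- array(FALSE, c(24, 24, 12))
  mask[3:22, 3:22, 3:10] <- TRUE
  g <- partition_rois(mask, c(4, 4, 4))
  expect_false(any(g$missing))
  expect_equal(sum(g$counts), sum(mask))
  expect_equal(as.vector(g$counts / sum(g$counts)),
               rep(0.01, 100), tolerance = 0.25)  # 1% +- rounding
  expect_lt(max(abs(g$ab_fractions - 0.1)), 0.011)
  expect_lt(max(abs(g$dv_fractions - 0.1)), 0.011)
  expect_true(all(diff(g$ab_planes) > 0))
})

test_that("ellipsoidal lungs give balanced slabs with missing corner ROIs", {
  fine <- fine_lung_mask()
  g <- partition_rois(fine)
  expect_lt(max(abs(g$ab_fractions - 0.1)), 0.01)
  expect_lt(max(abs(g$dv_fractions - 0.1)), 0.01)
  expect_false(g$missing[5, 5])        # centre present
  expect_equal(sum(g$counts), sum(fine$mask))
  expect_equal(!is.na(g$labels_ab), fine$mask)

  # coarse masks keep the structural guarantees even when slice granularity
  # limits the achievable balance
  m <- small_mask()
  for (side in 1:2) {
    gc <- partition_rois(lungstrain:::new_lung_mask(m$side == side, m$spacing))
    expect_equal(sum(gc$counts), sum(m$side == side))
    expect_equal(!is.na(gc$labels_ab), m$side == side)
  }
})

test_that("ROIs without tissue are flagged missing", {
  # slab with a notched corner: the notch spans whole slabs, so the
  # corresponding ROIs hold no tissue
  mask <- array(FALSE, c(24, 24, 12))
  mask[3:22, 3:22, 3:10] <- TRUE
  mask[3:6, 3:6, ] <- FALSE
  g <- partition_rois(mask, c(4, 4, 4))
  expect_true(g$missing[1, 1])
  expect_false(g$missing[5, 5])
  expect_equal(sum(g$counts), sum(mask))
  rm <- aggregate_to_roi(array(1, dim(mask)), g)
  expect_true(is.na(rm$mean[1, 1]))
})

test_that("a step-density slab spaces planes 2:1 to preserve volume", {
  # ventral half at half density (alternating empty slices along axis 1):
  # 12 half-density + 12 full-density dorsoventral slices = 18 tissue units,
  # so 6 slabs of 3 units each: two 6-slice ventral slabs, four 3-slice
  # dorsal slabs
  mask <- array(FALSE, c(20, 28, 10))
  mask[seq(3, 18, by = 2), 3:14, 3:8] <- TRUE   # half density, ventral
  mask[3:18, 15:26, 3:8] <- TRUE                # full density, dorsal
  g <- partition_rois(mask, c(4, 4, 4), n_dv = 6)
  widths <- diff(c(2 * 4, g$dv_planes, 26 * 4))
  expect_equal(widths[1:2], c(24, 24))
  expect_equal(widths[4:6], c(12, 12, 12))
  expect_lt(max(abs(g$dv_fractions - 1 / 6)), 1e-9)
})

test_that("partition fails on lungs thinner than the slab count", {
  mask <- array(FALSE, c(16, 16, 8))
  mask[5:9, 5:12, 2:7] <- TRUE  # only 5 apicobasal slices
  expect_error(partition_rois(mask, c(4, 4, 4)), "insufficient resolution")
})

test_that("ROI aggregation reproduces constants, indices, and skips NaNs", {
  m <- small_mask()
  g <- partition_rois(lungstrain:::new_lung_mask(m$side == 1, m$spacing))
  shape <- dim(m$mask)

  const <- array(7.5, shape)
  rm1 <- aggregate_to_roi(const, g)
  expect_equal(unique(rm1$mean[rm1$n > 0]), 7.5)
  expect_equal(unique(rm1$sd[rm1$n > 1]), 0)

  # field equal to the apicobasal ROI index reproduces the index exactly
  idxfield <- array(NA_real_, shape)
  sel <- !is.na(g$labels_ab)
  idxfield[sel] <- g$labels_ab[sel]
  rm2 <- aggregate_to_roi(idxfield, g)
  for (i in 1:10) expect_true(all(rm2$mean[i, rm2$n[i, ] > 0] == i))

  # NA outside the lung is ignored, not propagated
  expect_false(anyNA(rm2$mean[rm2$n > 0]))
})

test_that("quadrant summaries aggregate the 5x5 blocks", {
  m <- matrix(0, 10, 10); m[, 6:10] <- 1
  rmap <- structure(list(mean = m, sd = m * 0, n = matrix(10, 10, 10),
                         quantity = "test", condition = NULL),
                    class = "roi_map")
  qs <- quadrant_summary(rmap)
  expect_equal(qs$mean[qs$quadrant == "apicodorsal"], 1)
  expect_equal(qs$mean[qs$quadrant == "basodorsal"], 1)
  expect_equal(qs$mean[qs$quadrant == "apicoventral"], 0)
  expect_equal(qs$mean[qs$quadrant == "basoventral"], 0)

  chk <- outer(1:10, 1:10, function(i, j) (i + j) %% 2)  # checkerboard
  rmap$mean <- chk
  qs2 <- quadrant_summary(rmap)
  # oracle: direct stats of each 5x5 block
  blocks <- list(apicoventral = chk[1:5, 1:5], apicodorsal = chk[1:5, 6:10],
                 basoventral = chk[6:10, 1:5], basodorsal = chk[6:10, 6:10])
  for (q in names(blocks)) {
    expect_equal(qs2$mean[qs2$quadrant == q], mean(blocks[[q]]))
    expect_equal(qs2$sd[qs2$quadrant == q], sd(as.vector(blocks[[q]])))
  }
  expect_equal(qs2$sd, rep(0.51, 4), tolerance = 0.01)
  expect_equal(unique(qs2$n_rois), 25L)

  const <- rmap; const$mean <- matrix(3.2, 10, 10)
  expect_equal(quadrant_summary(const)$mean, rep(3.2, 4))
})

test_that("paired ROI tests detect large effects and respect Bonferroni", {
  mk_map <- function(m) structure(
    list(mean = m, sd = m * 0 + 1, n = matrix(50, 10, 10),
         quantity = "ts", condition = NULL), class = "roi_map")
  base <- matrix(30, 10, 10)
  set.seed(11)
  maps_a <- lapply(1:6, function(i) mk_map(base + rnorm(100, 0, 0.01)))

  # A == B: nothing significant
  same <- roi_paired_tests(maps_a, maps_a)
  expect_false(any(same$significant, na.rm = TRUE))

  # B = A + 10 with tiny noise: every tested ROI significant
  maps_b <- lapply(maps_a, function(m) { m$mean <- m$mean + 10 +
    rnorm(100, 0, 0.01); m })
  big <- roi_paired_tests(maps_a, maps_b)
  expect_true(all(big$significant))
  expect_equal(unique(big$n_tested), 100L)

  # Bonferroni arithmetic: raw p = 0.01 with 100 tests is not significant
  expect_equal(min(pmin(0.01 * 100, 1)), 1)
  expect_error(roi_paired_tests(maps_a[1:2], maps_b[1:2]), "3 subjects")
  expect_error(roi_paired_tests(maps_a, maps_b[1:3]), "lengths")
})

test_that("missing ROIs are excluded from the Bonferroni family", {
  mk_map <- function(m, n) structure(
    list(mean = m, sd = m * 0 + 1, n = n, quantity = "ts", condition = NULL),
    class = "roi_map")
  n <- matrix(50, 10, 10); n[1, 1] <- 0
  set.seed(4)
  a <- lapply(1:5, function(i) mk_map(matrix(rnorm(100, 30), 10, 10), n))
  b <- lapply(1:5, function(i) mk_map(matrix(rnorm(100, 31), 10, 10), n))
  res <- roi_paired_tests(a, b)
  expect_equal(unique(res$n_tested), 99L)
  expect_true(is.na(res$p[res$roi_ab == 1 & res$roi_dv == 1]))
})

test_that("static strain vs aeration-change correlation behaves like Pearson", {
  x <- seq(10, 60, length.out = 50)
  r1 <- correlate_static_delta(x, 0.004 * x)
  expect_equal(r1$r, 1.0)
  r2 <- correlate_static_delta(x, -0.01 * x)
  expect_equal(r2$r, -1.0)
  expect_error(correlate_static_delta(x, rep(0.5, 50)), "zero variance")
  expect_error(correlate_static_delta(x[1:2], x[1:2] * 2), "at least 3")

  set.seed(21)
  n <- 200; rho <- 0.7
  u <- rnorm(n); v <- rho * u + sqrt(1 - rho^2) * rnorm(n)
  r3 <- correlate_static_delta(u, v)
  expect_gt(r3$r, 0.6); expect_lt(r3$r, 0.8)
  expect_lt(r3$p, 1e-6)
})
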