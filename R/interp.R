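# Internal trilinear interpolation and finite-difference helpers.
# Coordinates are 1-based voxel indices (possibly fractional).

trilinear_sample <- function(arr, x, y, z, fill = NA_real_) {
  d <- dim(arr)
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(fill, length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1); z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  nx <- d[1]; nxy <- d[1] * d[2]
  i000 <- x0 + (y0 - 1) * nx + (z0 - 1) * nxy
  v <- arr[i000]            * (1 - fx) * (1 - fy) * (1 - fz) +
       arr[i000 + 1]        * fx       * (1 - fy) * (1 - fz) +
       arr[i000 + nx]       * (1 - fx) * fy       * (1 - fz) +
       arr[i000 + nx + 1]   * fx       * fy       * (1 - fz) +
       arr[i000 + nxy]      * (1 - fx) * (1 - fy) * fz +
       arr[i000 + nxy + 1]  * fx       * (1 - fy) * fz +
       arr[i000 + nxy + nx] * (1 - fx) * fy       * fz +
       arr[i000 + nxy + nx + 1] * fx   * fy       * fz
  out[inside] <- v
  out
}

# NaN-aware trilinear sampling: weights of NA corners are dropped and the
# remainder renormalized; samples with total valid weight below `min_weight`
# return NA.
trilinear_sample_na <- function(arr, x, y, z, min_weight = 0.25) {
  d <- dim(arr)
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(NA_real_, length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1); z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  nx <- d[1]; nxy <- d[1] * d[2]
  i000 <- x0 + (y0 - 1) * nx + (z0 - 1) * nxy
  acc <- numeric(length(x)); wacc <- numeric(length(x))
  offs <- c(0, 1, nx, nx + 1, nxy, nxy + 1, nxy + nx, nxy + nx + 1)
  wx <- list(1 - fx, fx); wy <- list(1 - fy, fy); wz <- list(1 - fz, fz)
  k <- 0L
  for (cz in 1:2) for (cy in 1:2) for (cx in 1:2) {
    k <- k + 1L
    w <- wx[[cx]] * wy[[cy]] * wz[[cz]]
    v <- arr[i000 + offs[k]]
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + w[ok] * v[ok]
    wacc[ok] <- wacc[ok] + w[ok]
  }
  res <- ifelse(wacc >= min_weight, acc / wacc, NA_real_)
  out[inside] <- res
  out
}

# trilinear interpolation together with its exact spatial gradient (partials
# of the interpolant wrt the sample coordinates, per voxel unit); exactness
# keeps the registration objective and its gradient mutually consistent
trilinear_sample_grad <- function(arr, x, y, z, fill = 0) {
  d <- dim(arr)
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  n <- length(x)
  out <- list(v = rep(fill, n), gx = numeric(n), gy = numeric(n),
              gz = numeric(n))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1); z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  nx <- d[1]; nxy <- d[1] * d[2]
  i000 <- x0 + (y0 - 1) * nx + (z0 - 1) * nxy
  c000 <- arr[i000];            c100 <- arr[i000 + 1]
  c010 <- arr[i000 + nx];       c110 <- arr[i000 + nx + 1]
  c001 <- arr[i000 + nxy];      c101 <- arr[i000 + nxy + 1]
  c011 <- arr[i000 + nxy + nx]; c111 <- arr[i000 + nxy + nx + 1]
  # collapse z, then y, then x, keeping the partials
  a00 <- c000 * (1 - fz) + c001 * fz; a10 <- c100 * (1 - fz) + c101 * fz
  a01 <- c010 * (1 - fz) + c011 * fz; a11 <- c110 * (1 - fz) + c111 * fz
  dz00 <- c001 - c000; dz10 <- c101 - c100
  dz01 <- c011 - c010; dz11 <- c111 - c110
  b0 <- a00 * (1 - fy) + a01 * fy; b1 <- a10 * (1 - fy) + a11 * fy
  dzb0 <- dz00 * (1 - fy) + dz01 * fy; dzb1 <- dz10 * (1 - fy) + dz11 * fy
  dyb0 <- a01 - a00; dyb1 <- a11 - a10
  v <- b0 * (1 - fx) + b1 * fx
  out$v[inside] <- v
  out$gx[inside] <- b1 - b0
  out$gy[inside] <- dyb0 * (1 - fx) + dyb1 * fx
  out$gz[inside] <- dzb0 * (1 - fx) + dzb1 * fx
  out
}

# central differences with one-sided boundaries, scaled by physical spacing;
# returns list of 3 arrays (d/dx1, d/dx2, d/dx3), units of arr per mm
array_gradient <- function(arr, spacing) {
  lapply(1:3, function(ax) {
    fwd <- shift_array(arr, ax, -1L, NA_real_)  # value at i+1
    bwd <- shift_array(arr, ax, 1L, NA_real_)   # value at i-1
    g <- (fwd - bwd) / (2 * spacing[ax])
    # one-sided at the two boundary slices
    d <- dim(arr)
    idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
    i1 <- idx; i1[[ax]] <- 1L
    i2 <- idx; i2[[ax]] <- 2L
    g <- do.call(`[<-`, c(list(g), i1, list(
      (do.call(`[`, c(list(arr), i2, list(drop = FALSE))) -
       do.call(`[`, c(list(arr), i1, list(drop = FALSE)))) / spacing[ax])))
    iN <- idx; iN[[ax]] <- d[ax]
    iN1 <- idx; iN1[[ax]] <- d[ax] - 1L
    g <- do.call(`[<-`, c(list(g), iN, list(
      (do.call(`[`, c(list(arr), iN, list(drop = FALSE))) -
       do.call(`[`, c(list(arr), iN1, list(drop = FALSE)))) / spacing[ax])))
    g
  })
}

# adjoint of the interior central-difference operator (boundaries truncated);
# used by the Jacobian term of the tissue-volume metric gradient
cdiff_adjoint <- function(arr, axis, spacing) {
  (shift_array(arr, axis, 1L, 0) - shift_array(arr, axis, -1L, 0)) / (2 * spacing[axis])
}

# mean-pool downsampling by 2 along every axis (trims odd tails)
downsample2 <- function(arr) {
  d <- dim(arr)
  d2 <- d %/% 2L
  a <- arr[seq_len(2L * d2[1]), seq_len(2L * d2[2]), seq_len(2L * d2[3]), drop = FALSE]
  a <- (a[seq(1, 2 * d2[1], 2), , , drop = FALSE] + a[seq(2, 2 * d2[1], 2), , , drop = FALSE]) / 2
  a <- (a[, seq(1, 2 * d2[2], 2), , drop = FALSE] + a[, seq(2, 2 * d2[2], 2), , drop = FALSE]) / 2
  a <- (a[, , seq(1, 2 * d2[3], 2), drop = FALSE] + a[, , seq(2, 2 * d2[3], 2), drop = FALSE]) / 2
  a
}

# voxel-center coordinate grids (1-based indices) as vectors aligned with
# column-major array order
coord_grids <- function(d) {
  list(
    x = rep.int(seq_len(d[1]), d[2] * d[3]),
    y = rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
    z = rep(seq_len(d[3]), each = d[1] * d[2])
  )
}
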