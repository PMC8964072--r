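# Internal cubic B-spline machinery for the free-form deformation model.
# The dense displacement along each component is a separable tensor-product
# cubic B-spline of a coefficient grid: U = C x1 Bx x2 By x3 Bz, evaluated
# with mode products (matrix multiplications on unfolded arrays).

bspline3 <- function(s) {
  a <- abs(s)
  out <- numeric(length(s))
  i1 <- a < 1
  out[i1] <- (4 - 6 * a[i1]^2 + 3 * a[i1]^3) / 6
  i2 <- a >= 1 & a < 2
  out[i2] <- (2 - a[i2])^3 / 6
  out
}

# basis matrix (n voxels x m control points) for one axis; control knots are
# spaced `spacing_vox` voxels apart with one knot beyond each end so the
# basis is a partition of unity over [1, n]
bspline_basis <- function(n, spacing_vox) {
  n_int <- max(1L, as.integer(ceiling((n - 1) / spacing_vox)))
  delta <- (n - 1) / n_int
  m <- n_int + 3L
  t_a <- 1 + (seq_len(m) - 2) * delta
  x <- seq_len(n)
  B <- outer(x, t_a, function(xi, ta) bspline3((xi - ta) / delta))
  list(B = B, m = m, delta = delta)
}

# mode-`mode` tensor-times-matrix product for a 3D array
ttm <- function(C, M, mode) {
  d <- dim(C)
  perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  A <- if (mode == 1L) C else aperm(C, perm)
  da <- dim(A)
  out <- M %*% matrix(A, da[1], da[2] * da[3])
  out <- array(out, c(nrow(M), da[2], da[3]))
  if (mode == 1L) out else aperm(out, order(perm))
}

ffd_dense <- function(C, Bx, By, Bz) {
  ttm(ttm(ttm(C, Bx, 1L), By, 2L), Bz, 3L)
}

# least-squares fit of coefficients to a dense field (separable normal
# equations; B has full column rank by construction)
ffd_fit <- function(U, Bx, By, Bz) {
  Px <- solve(crossprod(Bx) + diag(1e-10, ncol(Bx)), t(Bx))
  Py <- solve(crossprod(By) + diag(1e-10, ncol(By)), t(By))
  Pz <- solve(crossprod(Bz) + diag(1e-10, ncol(Bz)), t(Bz))
  ttm(ttm(ttm(U, Px, 1L), Py, 2L), Pz, 3L)
}

# second difference along an axis with zero boundary (convolution [1,-2,1]);
# self-adjoint, used for the bending-energy surrogate on coefficients
second_diff <- function(C, axis) {
  shift_array(C, axis, 1L, 0) - 2 * C + shift_array(C, axis, -1L, 0)
}

bending_energy <- function(Clist) {
  e <- 0
  for (C in Clist) for (ax in 1:3) e <- e + sum(second_diff(C, ax)^2)
  e / (3 * length(Clist[[1]]))
}

bending_gradient <- function(Clist) {
  lapply(Clist, function(C) {
    g <- array(0, dim(C))
    for (ax in 1:3) g <- g + 2 * second_diff(second_diff(C, ax), ax)
    g / (3 * length(C))
  })
}
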