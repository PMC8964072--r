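#' Displacement field container
#'
#' A dense per-voxel displacement field on the reference image grid. The
#' field maps reference-state material points to their target-state positions
#' (Lagrangian convention): a point at voxel-centre position `x` (mm) in the
#' reference state is found at `x + u(x)` in the target state.
#'
#' @param u 4D numeric array, reference volume shape by 3 components, in mm.
#' @param spacing voxel spacing (mm) of the reference grid.
#' @param reference,target ventilation-state labels of the two images.
#' @param info optional list of convergence diagnostics.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(u, spacing, reference = NULL, target = NULL,
                               info = NULL) {
  stopifnot(is.array(u), length(dim(u)) == 4L, dim(u)[4] == 3L)
  if (any(!is.finite(u))) stop("displacement field contains non-finite values",
                               call. = FALSE)
  structure(list(u = u, spacing = as.numeric(spacing),
                 reference = reference, target = target, info = info),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat("<displacement_field> ", paste(dim(x$u)[1:3], collapse = " x "),
      " voxels", sep = "")
  if (!is.null(x$reference)) cat(", ", x$reference, " -> ", x$target, sep = "")
  cat("; |u| max ", format(round(max(sqrt(
    x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)), 2)), " mm\n", sep = "")
  invisible(x)
}

#' Registration configuration
#'
#' Parameters of the multiresolution free-form-deformation (FFD) B-spline
#' registration.
#'
#' @param control_spacing_vox B-spline control-point spacing in voxels at the
#'   finest pyramid level (>= 2). Coarser levels reuse the same spacing on
#'   their decimated grids, so the physical control spacing halves from level
#'   to level.
#' @param levels number of multiresolution pyramid levels (>= 1).
#' @param metric similarity metric: `"ssd"` (sum of squared HU differences)
#'   or `"sstvd"` (sum of squared tissue-volume differences: the Jacobian-
#'   compensated tissue-density residual, appropriate when inflation changes
#'   lung HU between states).
#' @param bending_weight weight of the bending-energy surrogate (squared
#'   second differences of the control coefficients) relative to the
#'   variance-normalized image metric.
#' @param max_iter maximum L-BFGS-B iterations per level.
#' @param tol relative convergence tolerance on the objective.
#' @param mask_margin_vox margin (voxels, full resolution) applied to the
#'   fixed lung mask before restricting the metric: negative values erode
#'   (default -1, which treats the mixed partial-volume voxels of the lung
#'   boundary separately from interior parenchyma), positive values dilate.
#' @param boundary_weight relative metric weight of the boundary band (the
#'   in-mask voxels removed by the erosion).
#'   Boundary voxels carry the alignment information of the lung surface
#'   but are partial-volume mixtures whose residual cannot vanish at the
#'   true deformation; a small weight (default 0.05) keeps their guidance
#'   without letting them bias the interior strain. Only used when
#'   `mask_margin_vox < 0`.
#' @param presmooth number of passes of a separable 1/4-1/2-1/4 smoothing
#'   kernel applied to both images at the finest level before optimization
#'   (coarser pyramid levels are already band-limited by pooling). One pass
#'   (default) suppresses voxel noise and softens partial-volume edges.
#' @param seed stored for provenance; the optimization itself is
#'   deterministic (no stochastic sampling).
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(control_spacing_vox = 4, levels = 3L,
                                metric = c("ssd", "sstvd"),
                                bending_weight = 1e-3, max_iter = 200L,
                                tol = 1e-6, mask_margin_vox = -1L,
                                boundary_weight = 0, presmooth = 1L,
                                seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(control_spacing_vox >= 2, levels >= 1, bending_weight >= 0,
            max_iter >= 1)
  structure(list(control_spacing_vox = control_spacing_vox,
                 levels = as.integer(levels), metric = metric,
                 bending_weight = bending_weight,
                 max_iter = as.integer(max_iter), tol = tol,
                 mask_margin_vox = as.integer(mask_margin_vox),
                 boundary_weight = boundary_weight,
                 presmooth = as.integer(presmooth), seed = seed),
            class = "registration_config")
}

# HU -> tissue fraction in [0, 1] (air -1000 -> 0, water/soft tissue -> 1)
hu_to_tissue_fraction <- function(hu) pmin(pmax(1 + hu / 1000, 0), 1)

# separable 1/4-1/2-1/4 kernel with replicated edges
smooth_121 <- function(a, passes = 1L) {
  for (i in seq_len(passes)) for (ax in 1:3) {
    up <- shift_array(a, ax, 1L, NA); dn <- shift_array(a, ax, -1L, NA)
    up[is.na(up)] <- a[is.na(up)]; dn[is.na(dn)] <- a[is.na(dn)]
    a <- 0.5 * a + 0.25 * (up + dn)
  }
  a
}

# zero-padded central difference along one axis (derivative at i uses
# neighbours i-1, i+1 with out-of-range values 0); exactly self-adjoint with
# cdiff_adjoint, which the registration gradient relies on
cdiff_zero <- function(arr, axis, spacing) {
  (shift_array(arr, axis, -1L, 0) - shift_array(arr, axis, 1L, 0)) /
    (2 * spacing[axis])
}

# determinant of F = I + grad(u) from dense displacement components (mm) on
# a grid with physical `spacing`; `at` optionally restricts output to
# indices. `boundary = "one-sided"` (default, for strain recovery) uses
# one-sided differences at the volume faces; `"zero"` uses the zero-padded
# operator consistent with the registration gradient.
dense_jacobian <- function(u1, u2, u3, spacing, at = NULL,
                           boundary = "one-sided") {
  if (boundary == "zero") {
    g1 <- lapply(1:3, function(ax) cdiff_zero(u1, ax, spacing))
    g2 <- lapply(1:3, function(ax) cdiff_zero(u2, ax, spacing))
    g3 <- lapply(1:3, function(ax) cdiff_zero(u3, ax, spacing))
  } else {
    g1 <- array_gradient(u1, spacing)
    g2 <- array_gradient(u2, spacing)
    g3 <- array_gradient(u3, spacing)
  }
  pick <- function(a) if (is.null(at)) a else a[at]
  f11 <- 1 + pick(g1[[1]]); f12 <- pick(g1[[2]]); f13 <- pick(g1[[3]])
  f21 <- pick(g2[[1]]); f22 <- 1 + pick(g2[[2]]); f23 <- pick(g2[[3]])
  f31 <- pick(g3[[1]]); f32 <- pick(g3[[2]]); f33 <- 1 + pick(g3[[3]])
  list(det = f11 * (f22 * f33 - f23 * f32) -
             f12 * (f21 * f33 - f23 * f31) +
             f13 * (f21 * f32 - f22 * f31),
       F = list(f11 = f11, f12 = f12, f13 = f13,
                f21 = f21, f22 = f22, f23 = f23,
                f31 = f31, f32 = f32, f33 = f33))
}

cofactor_matrix <- function(F) {
  with(F, list(
    c11 = f22 * f33 - f23 * f32, c12 = -(f21 * f33 - f23 * f31),
    c13 = f21 * f32 - f22 * f31,
    c21 = -(f12 * f33 - f13 * f32), c22 = f11 * f33 - f13 * f31,
    c23 = -(f11 * f32 - f12 * f31),
    c31 = f12 * f23 - f13 * f22, c32 = -(f11 * f23 - f13 * f21),
    c33 = f11 * f22 - f12 * f21))
}

# single-level FFD objective/gradient pair (closure); images and mask are at
# the level's resolution, displacements in mm
.ffd_level_problem <- function(f, m, maskidx, spacing, basis, metric, lambda,
                               fill, wts = NULL) {
  d <- dim(f)
  g <- coord_grids(d)
  gx <- g$x[maskidx]; gy <- g$y[maskidx]; gz <- g$z[maskidx]
  fm <- f[maskidx]
  if (is.null(wts)) wts <- rep(1, length(maskidx))
  N <- sum(wts)
  s2f <- mean((fm - mean(fm))^2) + 1e-12
  Bx <- basis$x$B; By <- basis$y$B; Bz <- basis$z$B
  mdim <- c(basis$x$m, basis$y$m, basis$z$m)
  nc <- prod(mdim)
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL

  unpack <- function(par) {
    list(array(par[seq_len(nc)], mdim),
         array(par[nc + seq_len(nc)], mdim),
         array(par[2 * nc + seq_len(nc)], mdim))
  }

  forward <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$fw)
    C <- unpack(par)
    U <- lapply(C, ffd_dense, Bx = Bx, By = By, Bz = Bz)
    xs <- gx + U[[1]][maskidx] / spacing[1]
    ys <- gy + U[[2]][maskidx] / spacing[2]
    zs <- gz + U[[3]][maskidx] / spacing[3]
    smp <- trilinear_sample_grad(m, xs, ys, zs, fill = fill)
    mv <- smp$v
    if (metric == "sstvd") {
      jac <- dense_jacobian(U[[1]], U[[2]], U[[3]], spacing, at = maskidx,
                            boundary = "zero")
      r <- jac$det * mv - fm
    } else {
      jac <- NULL
      r <- mv - fm
    }
    e_img <- sum(wts * r^2) / (N * s2f)
    e_bend <- if (lambda > 0) bending_energy(C) else 0
    fw <- list(C = C, U = U, smp = smp, mv = mv, r = r,
               jac = jac, value = e_img + lambda * e_bend)
    cache$par <- par
    cache$fw <- fw
    fw
  }

  fn <- function(par) forward(par)$value

  gr <- function(par) {
    fw <- forward(par)
    w <- 2 * wts * fw$r / (N * s2f)
    # exact partials of the interpolant wrt displacement in mm
    gmv <- list(fw$smp$gx / spacing[1], fw$smp$gy / spacing[2],
                fw$smp$gz / spacing[3])
    G <- vector("list", 3L)
    if (metric == "sstvd") {
      detv <- fw$jac$det
      cof <- cofactor_matrix(fw$jac$F)
      wm <- w * fw$mv
      for (p in 1:3) {
        Gp <- array(0, d)
        Gp[maskidx] <- w * detv * gmv[[p]]
        for (q in 1:3) {
          W <- array(0, d)
          W[maskidx] <- wm * cof[[paste0("c", p, q)]]
          Gp <- Gp + cdiff_adjoint(W, q, spacing)
        }
        G[[p]] <- Gp
      }
    } else {
      for (p in 1:3) {
        Gp <- array(0, d)
        Gp[maskidx] <- w * gmv[[p]]
        G[[p]] <- Gp
      }
    }
    gc_list <- lapply(G, function(Gp) ttm(ttm(ttm(Gp, t(Bx), 1L), t(By), 2L),
                                          t(Bz), 3L))
    if (lambda > 0) {
      bg <- bending_gradient(fw$C)
      for (p in 1:3) gc_list[[p]] <- gc_list[[p]] + lambda * bg[[p]]
    }
    c(gc_list[[1]], gc_list[[2]], gc_list[[3]])
  }

  list(fn = fn, gr = gr, mdim = mdim, nc = nc,
       basis = list(Bx = Bx, By = By, Bz = Bz), unpack = unpack)
}

#' Free-form deformation image registration
#'
#' Registers `moving` to `fixed` with a multiresolution cubic B-spline
#' free-form deformation, returning the dense displacement field `u` on the
#' fixed image's grid such that material points of the fixed (reference)
#' state map to `x + u(x)` in the target state. The similarity metric is
#' evaluated inside a dilated fixed-lung mask; optimization is L-BFGS-B on
#' the control-point coefficients with a bending-energy penalty, and is
#' deterministic for given inputs and configuration.
#'
#' @param fixed,moving [ct_volume()]s on the same grid (identical shape and
#'   spacing).
#' @param fixed_mask optional `lung_mask` (or logical array) for the fixed
#'   image; when missing the whole volume is used.
#' @param cfg a [registration_config()].
#' @return A [displacement_field()] with convergence diagnostics in `info`.
#' @export
register_ffd <- function(fixed, moving, fixed_mask = NULL,
                         cfg = registration_config()) {
  stopifnot(is_ct_volume(fixed), is_ct_volume(moving))
  if (!isTRUE(all.equal(fixed$spacing, moving$spacing)) ||
      !identical(dim(fixed$hu), dim(moving$hu)))
    stop("fixed and moving volumes must share grid shape and spacing ",
         "(resample first)", call. = FALSE)
  f0 <- fixed$hu * 1.0
  m0 <- moving$hu * 1.0
  fill <- -1000
  if (cfg$metric == "sstvd") {
    f0 <- hu_to_tissue_fraction(f0)
    m0 <- hu_to_tissue_fraction(m0)
    fill <- 1.0
  }
  if (cfg$presmooth > 0L) {
    f0 <- smooth_121(f0, cfg$presmooth)
    m0 <- smooth_121(m0, cfg$presmooth)
  }
  if (is.null(fixed_mask)) {
    mk <- array(TRUE, dim(f0))
    wt <- array(1, dim(f0))
  } else {
    mm <- if (inherits(fixed_mask, "lung_mask")) fixed_mask$mask else fixed_mask
    stopifnot(identical(dim(mm), dim(f0)))
    if (cfg$mask_margin_vox > 0L) {
      mk <- binary_dilate(mm, cfg$mask_margin_vox)
      wt <- array(1, dim(f0)) * mk
    } else if (cfg$mask_margin_vox < 0L) {
      inner <- binary_erode(mm, -cfg$mask_margin_vox)
      mk <- mm
      wt <- array(0, dim(f0))
      wt[mk] <- cfg$boundary_weight
      wt[inner] <- 1
    } else {
      mk <- mm
      wt <- array(1, dim(f0)) * mk
    }
  }

  # image pyramid, coarsest first
  pyr <- vector("list", cfg$levels)
  fl <- f0; ml <- m0; kl <- mk * 1.0; wl <- wt; sp <- fixed$spacing
  for (l in seq_len(cfg$levels)) {
    pyr[[cfg$levels - l + 1L]] <- list(f = fl, m = ml, mask = kl > 0.25,
                                       weights = wl, spacing = sp)
    if (l < cfg$levels) {
      fl <- downsample2(fl); ml <- downsample2(ml); kl <- downsample2(kl)
      wl <- downsample2(wl)
      sp <- sp * 2
      if (any(dim(fl) < 8L))
        stop("volume too small for ", cfg$levels, " pyramid levels",
             call. = FALSE)
    }
  }

  info <- list(levels = list(), metric = cfg$metric)
  U <- NULL  # dense field (list of 3 arrays, mm) at the previous level
  for (l in seq_along(pyr)) {
    lev <- pyr[[l]]
    d <- dim(lev$f)
    basis <- list(x = bspline_basis(d[1], cfg$control_spacing_vox),
                  y = bspline_basis(d[2], cfg$control_spacing_vox),
                  z = bspline_basis(d[3], cfg$control_spacing_vox))
    maskidx <- which(lev$mask)
    if (length(maskidx) < 8L) stop("fixed mask empty at pyramid level ", l,
                                   call. = FALSE)
    prob <- .ffd_level_problem(lev$f, lev$m, maskidx, lev$spacing, basis,
                               cfg$metric, cfg$bending_weight, fill,
                               wts = lev$weights[maskidx])
    if (is.null(U)) {
      par0 <- numeric(3L * prob$nc)
    } else {
      # upsample previous dense field to this grid and refit coefficients
      g <- coord_grids(d)
      dc <- dim(U[[1]])
      xs <- pmin(pmax((g$x + 0.5) / 2, 1), dc[1])
      ys <- pmin(pmax((g$y + 0.5) / 2, 1), dc[2])
      zs <- pmin(pmax((g$z + 0.5) / 2, 1), dc[3])
      par0 <- unlist(lapply(U, function(uc) {
        uf <- array(trilinear_sample(uc, xs, ys, zs, fill = 0), d)
        ffd_fit(uf, basis$x$B, basis$y$B, basis$z$B)
      }), use.names = FALSE)
    }
    e0 <- prob$fn(par0)
    opt <- optim(par0, prob$fn, prob$gr, method = "L-BFGS-B",
                 control = list(maxit = cfg$max_iter,
                                factr = cfg$tol / .Machine$double.eps,
                                pgtol = 0))
    if (opt$value > e0 + 1e-12)
      stop("registration diverged at level ", l, ": objective ", e0, " -> ",
           opt$value, call. = FALSE)
    C <- prob$unpack(opt$par)
    U <- lapply(C, ffd_dense, Bx = prob$basis$Bx, By = prob$basis$By,
                Bz = prob$basis$Bz)
    info$levels[[l]] <- list(shape = d, start = e0, end = opt$value,
                             iterations = opt$counts[["function"]],
                             convergence = opt$convergence)
  }

  u4 <- array(0, c(dim(f0), 3L))
  for (p in 1:3) u4[, , , p] <- U[[p]]
  displacement_field(u4, fixed$spacing,
                     reference = fixed$state, target = moving$state,
                     info = info)
}

#' Warp a volume through a displacement field
#'
#' Resamples `vol` at `x + u(x)` with trilinear interpolation, pulling the
#' target-state image onto the reference grid. Out-of-domain samples take
#' `fill` (default -1000 HU, air).
#'
#' @param field a [displacement_field()] on `vol`'s grid.
#' @param vol a [ct_volume()] (the target-state image).
#' @param fill value for samples falling outside `vol`.
#' @return A [ct_volume()] on the reference grid.
#' @export
warp_volume <- function(field, vol, fill = -1000) {
  stopifnot(inherits(field, "displacement_field"), is_ct_volume(vol))
  d <- dim(vol$hu)
  if (!identical(dim(field$u)[1:3], d))
    stop("field and volume shapes differ", call. = FALSE)
  g <- coord_grids(d)
  xs <- g$x + as.vector(field$u[, , , 1]) / field$spacing[1]
  ys <- g$y + as.vector(field$u[, , , 2]) / field$spacing[2]
  zs <- g$z + as.vector(field$u[, , , 3]) / field$spacing[3]
  hu <- array(trilinear_sample(vol$hu, xs, ys, zs, fill = fill), d)
  ct_volume(hu, vol$spacing, state = field$reference)
}
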