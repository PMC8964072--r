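#' Phantom configuration
#'
#' Describes a synthetic supine thorax: a soft-tissue body ellipsoid in air
#' containing two ellipsoidal lung fields with a linear dorsoventral HU
#' (aeration) gradient, optional air-filled bronchial tubes, and Gaussian HU
#' noise. The defaults emulate a ~12 kg supine dog: two ~255 ml lungs
#' (~510 ml end-expiratory volume), ventral HU around -900 (well aerated)
#' grading to dorsal -300 (poorly aerated), soft-tissue body around +40 HU.
#'
#' @param shape volume shape in voxels (default 96^3).
#' @param spacing voxel spacing in mm (default 2 mm isotropic, matching
#'   2 mm reconstructed CT slices).
#' @param lung_semiaxes_mm semiaxes (apicobasal, dorsoventral, left-right)
#'   of each lung ellipsoid.
#' @param lung_offset_lr_mm left-right offset of each lung centre from the
#'   midline.
#' @param body_semiaxes_mm semiaxes of the body ellipsoid.
#' @param hu_ventral,hu_dorsal lung HU at the ventral and dorsal lung
#'   extremes (linear ramp along the dorsoventral axis); must satisfy
#'   `hu_ventral < hu_dorsal <= -100`.
#' @param hu_body soft-tissue HU.
#' @param noise_sd Gaussian HU noise SD; a `seed` is required when > 0.
#' @param texture_amp_hu amplitude (HU) of a smooth material-attached
#'   parenchymal texture (a fixed set of Gaussian blobs inside the lungs)
#'   emulating vascular markings; 0 (default) disables it. The texture
#'   deforms with the tissue, giving deformable registration the interior
#'   landmarks real lungs have; it perturbs the HU ramp, so leave it off
#'   when the analytic ramp class volumes are the quantity of interest.
#' @param texture_scale_mm correlation length of the texture blobs.
#' @param texture_seed RNG seed of the texture (independent of the noise
#'   seed so noise realizations share the same anatomy).
#' @param bronchus enable an air-filled (-1000 HU) bronchial tube inside the
#'   right lung (mid-dorsal), reproducing the intraluminal-air
#'   hyperaeration artifact.
#' @param bronchus_radius_mm,bronchus_hu tube radius and HU.
#' @param seed RNG seed for the noise.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(96, 96, 96), spacing = c(2, 2, 2),
                           lung_semiaxes_mm = c(58, 42, 25),
                           lung_offset_lr_mm = 32,
                           body_semiaxes_mm = c(80, 60, 70),
                           hu_ventral = -900, hu_dorsal = -300,
                           hu_body = 40, noise_sd = 0,
                           texture_amp_hu = 0, texture_scale_mm = 12,
                           texture_seed = 1L,
                           bronchus = FALSE, bronchus_radius_mm = 6,
                           bronchus_hu = -1000, seed = NULL) {
  stopifnot(length(shape) == 3L, all(shape >= 8), length(spacing) == 3L,
            all(spacing > 0))
  if (!(hu_ventral < hu_dorsal && hu_dorsal <= -100))
    stop("need hu_ventral < hu_dorsal <= -100", call. = FALSE)
  if (noise_sd > 0 && is.null(seed))
    stop("`seed` required when noise_sd > 0", call. = FALSE)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 lung_semiaxes_mm = lung_semiaxes_mm,
                 lung_offset_lr_mm = lung_offset_lr_mm,
                 body_semiaxes_mm = body_semiaxes_mm,
                 hu_ventral = hu_ventral, hu_dorsal = hu_dorsal,
                 hu_body = hu_body, noise_sd = noise_sd,
                 texture_amp_hu = texture_amp_hu,
                 texture_scale_mm = texture_scale_mm,
                 texture_seed = texture_seed,
                 bronchus = bronchus,
                 bronchus_radius_mm = bronchus_radius_mm,
                 bronchus_hu = bronchus_hu, seed = seed),
            class = "phantom_config")
}

# voxel-centre physical coordinates (mm, origin at the volume centre)
phantom_coords <- function(shape, spacing) {
  g <- coord_grids(shape)
  cbind((g$x - (shape[1] + 1) / 2) * spacing[1],
        (g$y - (shape[2] + 1) / 2) * spacing[2],
        (g$z - (shape[3] + 1) / 2) * spacing[3])
}

#' Generate a synthetic thorax phantom
#'
#' Builds the HU volume, the exact analytic lung mask (with left/right side
#' labels), and the analytic per-class aeration volumes implied by the
#' linear HU ramp over the ellipsoidal lung geometry. The analytic class
#' volumes are computed in closed form from the ellipsoid slab integral and
#' are independent of the voxelized image, so they can serve as ground truth
#' for the aeration pipeline.
#'
#' @param cfg a [phantom_config()].
#' @param state ventilation-state label for the volume (default `EE_ZEEP`).
#' @return A list of class `phantom`: `volume` ([ct_volume()]), `mask`
#'   (`lung_mask` with side labels), `class_volumes` (tibble of analytic
#'   per-class volumes in ml), `hu_at`/`in_lung` (analytic closures used by
#'   [apply_warp_to_phantom()]), and `config`.
#' @export
make_phantom <- function(cfg = phantom_config(), state = "EE_ZEEP") {
  stopifnot(inherits(cfg, "phantom_config"))
  ax <- cfg$lung_semiaxes_mm; bx <- cfg$body_semiaxes_mm
  off <- cfg$lung_offset_lr_mm
  if (any(abs(c(0, 0, off)) + ax >= bx))
    stop("lungs exceed the body envelope", call. = FALSE)
  y0 <- -ax[2]; y1 <- ax[2]  # dorsoventral lung extent (mm)
  ramp_hu <- function(y) cfg$hu_ventral +
    (cfg$hu_dorsal - cfg$hu_ventral) * pmin(pmax((y - y0) / (y1 - y0), 0), 1)

  in_ell <- function(X, centre, semi) {
    ((X[, 1] - centre[1]) / semi[1])^2 +
    ((X[, 2] - centre[2]) / semi[2])^2 +
    ((X[, 3] - centre[3]) / semi[3])^2 <= 1
  }
  in_bronchus <- function(X) {
    if (!cfg$bronchus) return(rep(FALSE, nrow(X)))
    # tube along the apicobasal axis in the right lung, slightly dorsal
    r2 <- (X[, 2] - 0.3 * ax[2])^2 + (X[, 3] - off)^2
    r2 <= cfg$bronchus_radius_mm^2 & abs(X[, 1]) <= 0.5 * ax[1]
  }
  in_lung <- function(X) in_ell(X, c(0, 0, -off), ax) |
                         in_ell(X, c(0, 0, off), ax)
  lung_side <- function(X) ifelse(X[, 3] < 0, 1L, 2L)
  texture_at <- function(X) rep(0, nrow(X))
  if (cfg$texture_amp_hu > 0) {
    # fixed Gaussian blobs inside the lungs, material-attached: evaluated at
    # source coordinates, so they deform with the tissue under any warp
    set.seed(cfg$texture_seed)
    K <- 80L
    ctrs <- cbind(stats::runif(K, -ax[1], ax[1]),
                  stats::runif(K, -ax[2], ax[2]),
                  sample(c(-off, off), K, replace = TRUE) +
                    stats::runif(K, -ax[3], ax[3]))
    amps <- stats::runif(K, -1, 1) * cfg$texture_amp_hu
    wids <- stats::runif(K, 0.7, 1.3) * cfg$texture_scale_mm
    texture_at <- function(X) {
      tex <- numeric(nrow(X))
      for (k in seq_len(K)) {
        d2 <- (X[, 1] - ctrs[k, 1])^2 + (X[, 2] - ctrs[k, 2])^2 +
              (X[, 3] - ctrs[k, 3])^2
        tex <- tex + amps[k] * exp(-d2 / (2 * wids[k]^2))
      }
      tex
    }
  }
  hu_at <- function(X) {
    hu <- rep(-1000, nrow(X))  # air background
    body <- in_ell(X, c(0, 0, 0), bx)
    hu[body] <- cfg$hu_body
    lung <- in_lung(X)
    hu_l <- ramp_hu(X[lung, 2])
    if (cfg$texture_amp_hu > 0)
      hu_l <- pmin(pmax(hu_l + texture_at(X[lung, , drop = FALSE]), -1000), -100)
    hu[lung] <- hu_l
    br <- in_bronchus(X) & lung
    hu[br] <- cfg$bronchus_hu
    hu
  }

  X <- phantom_coords(cfg$shape, cfg$spacing)
  hu <- hu_at(X)
  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed)
    hu <- hu + rnorm(length(hu), sd = cfg$noise_sd)
    hu <- pmin(pmax(hu, -1100), 3100)
  }
  vol <- ct_volume(array(hu, cfg$shape), cfg$spacing, state = state)
  lung <- in_lung(X)
  side <- array(0L, cfg$shape)
  side[lung] <- lung_side(X[lung, , drop = FALSE])
  mask <- new_lung_mask(array(lung, cfg$shape), cfg$spacing, side = side,
                        state = state)

  structure(list(volume = vol, mask = mask,
                 class_volumes = .analytic_class_volumes(cfg),
                 hu_at = hu_at, in_lung = in_lung,
                 lung_extent_dv = c(y0, y1), config = cfg),
            class = "phantom")
}

# closed-form ellipsoid slab volume between dorsoventral planes [p, q] (mm,
# lung-centred), for one lung with semiaxes (a, b, c):
# V = pi*a*c * [ y - y^3/(3 b^2) ] evaluated on [max(p,-b), min(q,b)]
.ellipsoid_slab_ml <- function(semi, p, q) {
  b <- semi[2]
  p <- max(p, -b); q <- min(q, b)
  if (q <= p) return(0)
  f <- function(y) y - y^3 / (3 * b^2)
  pi * semi[1] * semi[3] * (f(q) - f(p)) / 1000
}

.analytic_class_volumes <- function(cfg, thresholds = aeration_thresholds()) {
  ax <- cfg$lung_semiaxes_mm
  y0 <- -ax[2]; y1 <- ax[2]
  hu_v <- cfg$hu_ventral; hu_d <- cfg$hu_dorsal
  # invert the ramp: y position at which the lung HU crosses a bound
  y_of_hu <- function(hu) y0 + (hu - hu_v) / (hu_d - hu_v) * (y1 - y0)
  edges_hu <- c(-Inf, thresholds[["hyper_upper"]] + 0.5,
                thresholds[["normo_upper"]] + 0.5,
                thresholds[["poor_upper"]] + 0.5, Inf)
  vols <- vapply(1:4, function(k) {
    lo_hu <- max(edges_hu[k], min(hu_v, hu_d))
    hi_hu <- min(edges_hu[k + 1], max(hu_v, hu_d) + 1e-9)
    if (hi_hu <= lo_hu) return(0)
    2 * .ellipsoid_slab_ml(ax, y_of_hu(lo_hu), y_of_hu(hi_hu))
  }, numeric(1))
  # an enabled bronchus replaces lung tissue with -1000 HU air (hyper class);
  # its volume is the cylinder clipped to the lung, approximated by the full
  # cylinder (it is placed entirely inside the right lung)
  if (cfg$bronchus) {
    v_br <- pi * cfg$bronchus_radius_mm^2 * cfg$lung_semiaxes_mm[1] / 1000
    cls_br <- findInterval(cfg$bronchus_hu, edges_hu)
    ramp_cls <- findInterval(cfg$hu_ventral +
      (cfg$hu_dorsal - cfg$hu_ventral) * 0.65, edges_hu)
    vols[ramp_cls] <- vols[ramp_cls] - v_br
    vols[cls_br] <- vols[cls_br] + v_br
  }
  tibble::tibble(class = .aeration_classes, volume_ml = vols,
                 fraction = vols / sum(vols))
}

#' Analytic warps with closed-form strain
#'
#' Constructs an invertible analytic deformation with closed-form
#' displacement, Jacobian determinant and inverse, to serve as ground truth
#' for registration and strain recovery.
#'
#' Kinds:
#' * `"translation"`: rigid shift, zero strain. Params: `shift_mm` (3).
#' * `"affine"`: anisotropic scaling about `centre_mm`. Params: `scale`
#'   (scalar or length 3), strain `= (prod(scale) - 1) * 100` everywhere.
#' * `"radial_inflation"`: `u = beta * exp(-(r/R)^2) * (x - c)` about
#'   `centre_mm`, with `beta` chosen so the peak volumetric strain at the
#'   centre equals `peak_strain`; strain decays radially. Params:
#'   `centre_mm`, `radius_mm`, `peak_strain` (fraction, e.g. 0.15).
#' * `"graded_dorsoventral"`: purely dorsoventral stretch whose volumetric
#'   strain rises linearly from `strain_ventral` at `y_range_mm[1]` to
#'   `strain_dorsal` at `y_range_mm[2]` (fractions), emulating the
#'   gravitational strain gradient of a supine lung.
#'
#' @param kind warp family (see above).
#' @param ... parameters of the family.
#' @return An object of class `analytic_warp` with closures `u(X)`,
#'   `jac(X)`, `inverse(Y)` operating on n x 3 coordinate matrices (mm).
#' @export
make_warp <- function(kind = c("translation", "affine", "radial_inflation",
                               "graded_dorsoventral"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  w <- switch(kind,
    translation = {
      shift <- p$shift_mm %||% c(0, 0, 0)
      list(u = function(X) matrix(shift, nrow(X), 3, byrow = TRUE),
           jac = function(X) rep(1, nrow(X)),
           inverse = function(Y) sweep(Y, 2, shift))
    },
    affine = {
      s <- p$scale %||% 1.1
      if (length(s) == 1L) s <- rep(s, 3)
      if (prod(s) <= 0) stop("affine scale gives det <= 0", call. = FALSE)
      ctr <- p$centre_mm %||% c(0, 0, 0)
      list(u = function(X) sweep(sweep(X, 2, ctr), 2, s - 1, `*`),
           jac = function(X) rep(prod(s), nrow(X)),
           inverse = function(Y) sweep(sweep(sweep(Y, 2, ctr), 2, s, `/`),
                                       2, ctr, `+`))
    },
    radial_inflation = {
      ctr <- p$centre_mm %||% c(0, 0, 0)
      R <- p$radius_mm %||% 60
      s_pk <- p$peak_strain %||% 0.15
      beta <- (1 + s_pk)^(1 / 3) - 1
      # invertibility: 1 + d(g)/dr > 0 needs beta < 1/(2*exp(-1.5)) ~ 2.24
      if (beta <= -0.5 || beta >= 2.24)
        stop("peak_strain outside the invertible range", call. = FALSE)
      gfun <- function(r) beta * exp(-(r / R)^2)     # u = gfun(r) * (x - c)
      jacr <- function(r) {
        e <- beta * exp(-(r / R)^2)
        (1 + e - 2 * r^2 / R^2 * e) * (1 + e)^2
      }
      rr <- seq(0, 1e4, length.out = 20000)
      inv1d <- approxfun(rr * (1 + gfun(rr)), rr, rule = 2)
      list(u = function(X) {
             D <- sweep(X, 2, ctr)
             D * gfun(sqrt(rowSums(D^2)))
           },
           jac = function(X) {
             D <- sweep(X, 2, ctr)
             jacr(sqrt(rowSums(D^2)))
           },
           inverse = function(Y) {
             D <- sweep(Y, 2, ctr)
             rn <- sqrt(rowSums(D^2))
             r <- inv1d(rn)
             scale <- ifelse(rn > 0, r / rn, 1)
             sweep(D * scale, 2, ctr, `+`)
           })
    },
    graded_dorsoventral = {
      yr <- p$y_range_mm %||% c(-42, 42)
      sv <- p$strain_ventral %||% 0.1
      sdr <- p$strain_dorsal %||% 0.4
      dom <- p$domain_mm %||% 160
      anchor <- p$y_anchor_mm %||% 0
      y0 <- yr[1]; y1 <- yr[2]
      slope <- (sdr - sv) / (y1 - y0)
      # strain continues its linear dorsoventral gradient over the whole
      # domain (globally quadratic displacement, no curvature kinks); the
      # anchor (default: the lung centre) is the fixed point, so expansion
      # splits ventrally and dorsally instead of accumulating dorsally
      svy <- function(y) sv + slope * (y - y0)
      if (1 + svy(-dom) <= 0 || 1 + svy(dom) <= 0)
        stop("strain gradient gives det <= 0 inside the domain", call. = FALSE)
      fy0 <- function(y) sv * (y - y0) + slope * (y - y0)^2 / 2
      fy <- function(y) fy0(y) - fy0(anchor)
      yy <- seq(-dom, dom, length.out = 40000)
      inv1d <- approxfun(yy + fy(yy), yy, rule = 2)
      list(u = function(X) cbind(0, fy(X[, 2]), 0),
           jac = function(X) 1 + svy(X[, 2]),
           inverse = function(Y) cbind(Y[, 1], inv1d(Y[, 2]), Y[, 3]))
    })
  structure(c(w, list(kind = kind, params = p)), class = "analytic_warp")
}

#' Compose two analytic warps
#'
#' Returns the analytic warp `outer o inner` (apply `inner` first): the
#' displacement, Jacobian (chain rule) and inverse compose in closed form.
#'
#' @param outer,inner `analytic_warp`s.
#' @return An `analytic_warp`.
#' @export
compose_warps <- function(outer, inner) {
  stopifnot(inherits(outer, "analytic_warp"), inherits(inner, "analytic_warp"))
  structure(list(
    u = function(X) {
      Xi <- X + inner$u(X)
      Xi + outer$u(Xi) - X
    },
    jac = function(X) {
      Xi <- X + inner$u(X)
      outer$jac(Xi) * inner$jac(X)
    },
    inverse = function(Y) inner$inverse(outer$inverse(Y)),
    kind = paste0(outer$kind, " o ", inner$kind),
    params = list(outer = outer$params, inner = inner$params)),
    class = "analytic_warp")
}

#' Evaluate an analytic warp as a displacement field
#'
#' @param warp an `analytic_warp`.
#' @param shape,spacing reference grid (voxels, mm).
#' @param reference,target optional state labels.
#' @return A [displacement_field()] with the warp's displacement at every
#'   voxel centre.
#' @export
warp_displacement_field <- function(warp, shape, spacing,
                                    reference = NULL, target = NULL) {
  X <- phantom_coords(shape, spacing)
  U <- warp$u(X)
  u4 <- array(0, c(shape, 3L))
  for (k in 1:3) u4[, , , k] <- U[, k]
  displacement_field(u4, spacing, reference = reference, target = target)
}

#' Analytic volumetric strain map of a warp
#'
#' The closed-form strain `(det F - 1) * 100` of an analytic warp evaluated
#' at the reference lung voxels: the ground-truth counterpart of
#' [recover_strain()].
#'
#' @param warp an `analytic_warp`.
#' @param mask reference `lung_mask` (or logical array).
#' @param spacing voxel spacing (mm); taken from the mask when present.
#' @param component,condition labels for the [strain_map()].
#' @return A [strain_map()].
#' @export
warp_strain_map <- function(warp, mask, spacing = NULL,
                            component = "DYNAMIC", condition = "ZEEP") {
  if (inherits(mask, "lung_mask")) { spacing <- spacing %||% mask$spacing
                                     m <- mask$mask } else m <- mask
  shape <- dim(m)
  X <- phantom_coords(shape, spacing)
  vals <- array(NA_real_, shape)
  idx <- which(m)
  vals[idx] <- (warp$jac(X[idx, , drop = FALSE]) - 1) * 100
  strain_map(vals, spacing, component = component, condition = condition)
}

#' Warp a phantom into a target ventilation state
#'
#' Produces the CT image of the deformed phantom by evaluating the analytic
#' source HU at the inverse-warped voxel positions, and rescales lung HU so
#' that gas content is consistent with the local volume change: tissue
#' volume is conserved (inflation only adds gas), i.e.
#' `1 - gf_new = (1 - gf_old) / det F`. This makes segmented-volume strain
#' and displacement-field strain mutually consistent, as in a real
#' inflation.
#'
#' @param phantom a `phantom` from [make_phantom()].
#' @param warp an `analytic_warp`.
#' @param state state label of the produced volume.
#' @param noise_sd Gaussian HU noise added to the warped image; requires
#'   `seed`.
#' @param seed RNG seed for the noise.
#' @return A list: `volume` ([ct_volume()]), `mask` (exact warped
#'   `lung_mask`).
#' @export
apply_warp_to_phantom <- function(phantom, warp, state = NULL, noise_sd = 0,
                                  seed = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(warp, "analytic_warp"))
  cfg <- phantom$config
  if (noise_sd > 0 && is.null(seed))
    stop("`seed` required when noise_sd > 0", call. = FALSE)
  Y <- phantom_coords(cfg$shape, cfg$spacing)
  X <- warp$inverse(Y)
  # verify invertibility on the domain (round trip)
  rt <- X + warp$u(X)
  if (max(abs(rt - Y)) > max(cfg$spacing))
    stop("warp is not invertible on the phantom domain", call. = FALSE)
  hu <- phantom$hu_at(X)
  lung <- phantom$in_lung(X)
  detF <- warp$jac(X[lung, , drop = FALSE])
  if (any(detF <= 0)) stop("warp has det(F) <= 0 inside the lung", call. = FALSE)
  gf_old <- pmin(pmax(-hu[lung] / 1000, 0), 1)
  gf_new <- pmin(pmax(1 - (1 - gf_old) / detF, 0), 1)
  hu[lung] <- -1000 * gf_new
  if (noise_sd > 0) {
    set.seed(seed)
    hu <- hu + rnorm(length(hu), sd = noise_sd)
    hu <- pmin(pmax(hu, -1100), 3100)
  }
  side <- array(0L, cfg$shape)
  side[lung] <- ifelse(X[lung, 3] < 0, 1L, 2L)
  list(volume = ct_volume(array(hu, cfg$shape), cfg$spacing, state = state),
       mask = new_lung_mask(array(lung, cfg$shape), cfg$spacing,
                            side = side, state = state))
}

#' Generate a synthetic volumetric capnogram with known Bohr fraction
#'
#' Builds a piecewise breath on the expired-volume axis: phase I (airway
#' dead-space gas, zero CO2) up to `vd_ml - phase2_halfwidth_ml`, a
#' half-cosine phase II rise centred at the airway dead space `vd_ml`, and a
#' linear phase III (alveolar plateau) to end-expiration. The analytic
#' PACO2 (phase III midpoint), PECO2 (exact volume-weighted mean of the
#' pieces) and Bohr fraction are computed in closed form from the same
#' parameters, independently of the trace-analysis code paths they
#' validate.
#'
#' @param vt_ml tidal (expired) volume. Defaults emulate a ~12.4 kg dog at
#'   15 ml/kg.
#' @param vd_ml airway dead-space volume (phase II centre). Exactly one of
#'   `vd_ml` and `bohr` must be given; with `bohr`, `vd_ml` is solved so
#'   the analytic Bohr fraction matches.
#' @param bohr target analytic Bohr fraction (alternative to `vd_ml`).
#' @param plateau_mmhg pCO2 at the start of phase III.
#' @param slope_mmhg_per_ml phase III slope.
#' @param phase2_halfwidth_ml half-width of the sigmoid phase II.
#' @param barometric_mmhg barometric pressure.
#' @param noise_sd additive Gaussian pCO2 noise (mmHg); requires `seed`.
#' @param seed RNG seed for the noise.
#' @param n_samples samples on the volume axis.
#' @return A list: `breath` ([capno_breath()]), `analytic` (tibble with
#'   `paco2`, `peco2`, `bohr`, `vd_ml`).
#' @export
make_capnogram <- function(vt_ml = 186, vd_ml = NULL, bohr = NULL,
                           plateau_mmhg = 38, slope_mmhg_per_ml = 0.04,
                           phase2_halfwidth_ml = 12, barometric_mmhg = 760,
                           noise_sd = 0, seed = NULL, n_samples = 400L) {
  if (is.null(vd_ml) == is.null(bohr))
    stop("give exactly one of `vd_ml` or `bohr`", call. = FALSE)
  w <- phase2_halfwidth_ml
  analytic_for <- function(vd) {
    v2 <- vd + w
    paco2 <- plateau_mmhg + slope_mmhg_per_ml * (vt_ml - v2) / 2
    peco2 <- (plateau_mmhg * w + plateau_mmhg * (vt_ml - v2) +
              slope_mmhg_per_ml * (vt_ml - v2)^2 / 2) / vt_ml
    c(paco2 = paco2, peco2 = peco2, bohr = (paco2 - peco2) / paco2)
  }
  if (is.null(vd_ml)) {
    f <- function(vd) analytic_for(vd)[["bohr"]] - bohr
    lo <- w + 1e-6; hi <- vt_ml - w - 1e-6
    if (f(lo) > 0 || f(hi) < 0)
      stop("target Bohr fraction unreachable with these parameters", call. = FALSE)
    vd_ml <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  v1 <- vd_ml - w; v2 <- vd_ml + w
  if (v1 < 0 || v2 >= vt_ml)
    stop("inconsistent parameters: need 0 <= vd - w and vd + w < vt", call. = FALSE)
  if (noise_sd > 0 && is.null(seed))
    stop("`seed` required when noise_sd > 0", call. = FALSE)
  v <- seq(0, vt_ml, length.out = n_samples)
  p <- numeric(n_samples)
  ii <- v > v1 & v < v2
  p[ii] <- plateau_mmhg * (1 - cos(pi * (v[ii] - v1) / (2 * w))) / 2
  iii <- v >= v2
  p[iii] <- plateau_mmhg + slope_mmhg_per_ml * (v[iii] - v2)
  if (noise_sd > 0) {
    set.seed(seed)
    p <- pmax(p + rnorm(n_samples, sd = noise_sd), 0)
  }
  an <- analytic_for(vd_ml)
  list(breath = capno_breath(v, p, barometric_mmhg = barometric_mmhg),
       analytic = tibble::tibble(paco2 = an[["paco2"]], peco2 = an[["peco2"]],
                                 bohr = an[["bohr"]], vd_ml = vd_ml))
}
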