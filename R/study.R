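#' Study configuration for a synthetic PEEP study
#'
#' Defines the conditions of a simulated ZEEP/PEEP study on phantom
#' subjects: one thorax phantom per subject, deformed by graded
#' dorsoventral warps whose lung-mean volumetric strains match the study's
#' global strain levels (static ~47%, dynamic ~33% at ZEEP, ~24% at PEEP,
#' with ventral-to-dorsal gradients spanning the observed regional ranges),
#' plus volumetric capnograms and airway mechanics per condition.
#'
#' @param n_subjects number of phantom subjects.
#' @param shape,spacing phantom grid (voxels, mm). The default keeps the
#'   ~192 mm physical thorax of [phantom_config()].
#' @param noise_sd HU image noise per state.
#' @param texture_amp_hu amplitude of the material-attached parenchymal
#'   texture (see [phantom_config()]); registration needs interior
#'   landmarks, as real lungs provide through vascular markings.
#' @param subject_sd relative between-subject variability of the strain
#'   targets (SD of a multiplicative factor).
#' @param static_strain,dynamic_zeep,dynamic_peep length-2 fractions
#'   (ventral, dorsal) of the graded warps' volumetric strain.
#' @param bohr_zeep,bohr_peep target Bohr dead-space fractions of the
#'   generated capnograms.
#' @param mechanics list of per-condition `vt_ml`, `pplat_cmh2o`,
#'   `peep_total_cmh2o`.
#' @param registration a [registration_config()] used for all three
#'   registrations per subject.
#' @param node_spacing_mm strain-recovery mesh node spacing.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_subjects = 6L,
                         shape = c(96, 96, 96), spacing = c(2, 2, 2),
                         noise_sd = 20, texture_amp_hu = 120,
                         subject_sd = 0.1,
                         static_strain = c(0.30, 0.64),
                         dynamic_zeep = c(0.20, 0.47),
                         dynamic_peep = c(0.10, 0.38),
                         bohr_zeep = 0.62, bohr_peep = 0.55,
                         mechanics = list(
                           zeep = list(vt_ml = 186, pplat_cmh2o = 8.3,
                                       peep_total_cmh2o = 0),
                           peep = list(vt_ml = 186, pplat_cmh2o = 12.3,
                                       peep_total_cmh2o = 5)),
                         registration = registration_config(metric = "sstvd"),
                         node_spacing_mm = 8, seed = 1L) {
  stopifnot(n_subjects >= 1)
  structure(list(n_subjects = as.integer(n_subjects), shape = shape,
                 spacing = spacing, noise_sd = noise_sd,
                 texture_amp_hu = texture_amp_hu, subject_sd = subject_sd, static_strain = static_strain,
                 dynamic_zeep = dynamic_zeep, dynamic_peep = dynamic_peep,
                 bohr_zeep = bohr_zeep, bohr_peep = bohr_peep,
                 mechanics = mechanics, registration = registration,
                 node_spacing_mm = node_spacing_mm, seed = seed),
            class = "study_config")
}

#' Simulate the inputs of a ZEEP/PEEP phantom study
#'
#' Generates, per subject, the four CT ventilation states (EE/EI at
#' ZEEP/PEEP) with deterministic per-subject seeds, plus capnograms and a
#' mechanics table. The per-subject analytic ground truth (warps and their
#' lung-mean strains) is returned alongside but is not consumed by
#' [run_study()].
#'
#' @param cfg a [study_config()].
#' @return A list of class `study_inputs`: `subjects` (each with `states`,
#'   a named list of [ct_volume()]s, `capno`, `mechanics`), `truth` (tibble
#'   of per-subject target strains), and `config`.
#' @export
simulate_study_inputs <- function(cfg = study_config()) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(cfg$seed)
  sub_seeds <- sample.int(2^30, cfg$n_subjects * 8)
  sub_factors <- pmax(0.5, rnorm(cfg$n_subjects, 1, cfg$subject_sd))
  pc <- phantom_config(shape = cfg$shape, spacing = cfg$spacing)
  y_range <- c(-pc$lung_semiaxes_mm[2], pc$lung_semiaxes_mm[2])
  subjects <- vector("list", cfg$n_subjects)
  truth <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    k <- sub_factors[s]
    seeds <- sub_seeds[(s - 1) * 8 + 1:8]
    base_cfg <- phantom_config(shape = cfg$shape, spacing = cfg$spacing,
                               noise_sd = cfg$noise_sd,
                               texture_amp_hu = cfg$texture_amp_hu,
                               texture_seed = seeds[7], seed = seeds[1])
    ph <- make_phantom(base_cfg, state = "EE_ZEEP")
    w_static <- make_warp("graded_dorsoventral", y_range_mm = y_range,
                          strain_ventral = k * cfg$static_strain[1],
                          strain_dorsal = k * cfg$static_strain[2])
    w_dyn_z <- make_warp("graded_dorsoventral", y_range_mm = y_range,
                         strain_ventral = k * cfg$dynamic_zeep[1],
                         strain_dorsal = k * cfg$dynamic_zeep[2])
    # the PEEP dynamic warp lives in the EE_PEEP frame: its strain ramp
    # spans the statically inflated lung extent
    y_range_peep <- y_range +
      w_static$u(cbind(0, y_range, 0))[, 2]
    w_dyn_p <- make_warp("graded_dorsoventral", y_range_mm = y_range_peep,
                         strain_ventral = k * cfg$dynamic_peep[1],
                         strain_dorsal = k * cfg$dynamic_peep[2])
    states <- list(
      EE_ZEEP = ph$volume,
      EI_ZEEP = apply_warp_to_phantom(ph, w_dyn_z, state = "EI_ZEEP",
                                      noise_sd = cfg$noise_sd,
                                      seed = seeds[2])$volume,
      EE_PEEP = apply_warp_to_phantom(ph, w_static, state = "EE_PEEP",
                                      noise_sd = cfg$noise_sd,
                                      seed = seeds[3])$volume,
      EI_PEEP = apply_warp_to_phantom(
        ph, compose_warps(w_dyn_p, w_static), state = "EI_PEEP",
        noise_sd = cfg$noise_sd, seed = seeds[4])$volume)
    capno <- list(
      zeep = make_capnogram(vt_ml = cfg$mechanics$zeep$vt_ml,
                            bohr = cfg$bohr_zeep, noise_sd = 0.5,
                            seed = seeds[5]),
      peep = make_capnogram(vt_ml = cfg$mechanics$peep$vt_ml,
                            bohr = cfg$bohr_peep, noise_sd = 0.5,
                            seed = seeds[6]))
    mech <- dplyr::bind_rows(
      tibble::tibble(condition = "ZEEP", vt_ml = cfg$mechanics$zeep$vt_ml,
                     pplat_cmh2o = cfg$mechanics$zeep$pplat_cmh2o,
                     peep_total_cmh2o = cfg$mechanics$zeep$peep_total_cmh2o),
      tibble::tibble(condition = "PEEP", vt_ml = cfg$mechanics$peep$vt_ml,
                     pplat_cmh2o = cfg$mechanics$peep$pplat_cmh2o,
                     peep_total_cmh2o = cfg$mechanics$peep$peep_total_cmh2o))
    subjects[[s]] <- list(states = states, capno = capno, mechanics = mech,
                          phantom = ph)
    truth[[s]] <- tibble::tibble(
      subject = s, factor = k,
      ls_static = k * mean(cfg$static_strain) * 100,
      ls_dynamic_zeep = k * mean(cfg$dynamic_zeep) * 100,
      ls_dynamic_peep = k * mean(cfg$dynamic_peep) * 100,
      bohr_zeep = capno$zeep$analytic$bohr,
      bohr_peep = capno$peep$analytic$bohr)
  }
  structure(list(subjects = subjects, truth = dplyr::bind_rows(truth),
                 config = cfg), class = "study_inputs")
}

#' Run the full regional strain analysis on a study
#'
#' Executes, per subject: segmentation of the four ventilation states and
#' lung volumes; global strains; the three registrations (static:
#' EE_ZEEP to EE_PEEP; dynamic: EE to EI within each condition); strain
#' recovery; pull-back and additive composition of the total strain;
#' aeration maps and PEEP-ZEEP deltas; per-lung and pooled 10 x 10 ROI
#' maps and quadrant summaries; Bohr dead space and mechanics scalars.
#' Group level: per-ROI paired tests of dynamic strain between conditions
#' and the correlation of static strain with aeration change, over pooled
#' ROIs.
#'
#' @param inputs a `study_inputs` from [simulate_study_inputs()], or a list
#'   with the same `subjects` structure built from volumes read with
#'   [read_ct_volume()].
#' @param registration a [registration_config()]; defaults to the one in
#'   the inputs' study config when present.
#' @param node_spacing_mm strain-recovery mesh node spacing (mm).
#' @param seg segmentation configuration.
#' @return A list of class `study_report` with tibbles `volumes`, `global`,
#'   `roi` (long, per subject/side/quantity), `quadrants`, `group_maps`,
#'   `tests`, `correlations`, and `registration_info`. Subjects aborting at
#'   any stage are marked incomplete in `global` with the failure reason.
#' @export
run_study <- function(inputs, registration = NULL, node_spacing_mm = NULL,
                      seg = segmentation_config()) {
  cfg <- if (inherits(inputs, "study_inputs")) inputs$config else NULL
  registration <- registration %||% (if (!is.null(cfg)) cfg$registration
                                     else registration_config(metric = "sstvd"))
  node_spacing_mm <- node_spacing_mm %||% (if (!is.null(cfg)) cfg$node_spacing_mm else 8)
  subjects <- inputs$subjects
  n_sub <- length(subjects)

  res <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    res[[s]] <- tryCatch(
      .analyze_subject(subjects[[s]], s, registration, node_spacing_mm, seg),
      error = function(e) list(failed = conditionMessage(e), subject = s))
  }

  ok <- !vapply(res, function(r) !is.null(r$failed), logical(1))
  volumes <- dplyr::bind_rows(lapply(res[ok], `[[`, "volumes"))
  global <- dplyr::bind_rows(lapply(res, function(r) {
    if (!is.null(r$failed))
      return(tibble::tibble(subject = r$subject, complete = FALSE,
                            reason = r$failed))
    dplyr::mutate(r$global, complete = TRUE, reason = NA_character_)
  }))
  roi <- dplyr::bind_rows(lapply(res[ok], `[[`, "roi"))
  quadrants <- dplyr::bind_rows(lapply(res[ok], `[[`, "quadrants"))
  reg_info <- lapply(res[ok], `[[`, "registration_info")

  # group-level regional statistics on the pooled-lung maps
  tests <- NULL; correlations <- NULL; group_maps <- NULL
  if (sum(ok) >= 3L) {
    maps_z <- lapply(res[ok], function(r) r$maps$ts_dynamic_zeep)
    maps_p <- lapply(res[ok], function(r) r$maps$ts_dynamic_peep)
    tests <- roi_paired_tests(maps_z, maps_p)
    pool_static <- unlist(lapply(res[ok], function(r)
      as.vector(ifelse(r$maps$ts_static$n > 0, r$maps$ts_static$mean, NA))))
    correlations <- dplyr::bind_rows(lapply(.aeration_classes, function(cl) {
      dl <- unlist(lapply(res[ok], function(r) r$delta[[paste0("d_", cl)]]))
      tryCatch(correlate_static_delta(pool_static, dl, class = cl),
               error = function(e) tibble::tibble(class = cl, r = NA_real_,
                                                  p = NA_real_, n = NA_integer_))
    }))
  }
  if (sum(ok) >= 1L) {
    group_maps <- dplyr::summarise(
      dplyr::group_by(roi[roi$side == "pooled", ],
                      .data$quantity, .data$condition, .data$roi_ab, .data$roi_dv),
      mean = mean(.data$mean, na.rm = TRUE), n_subjects = sum(!is.na(.data$mean)),
      .groups = "drop")
  }

  structure(list(volumes = volumes, global = global, roi = roi,
                 quadrants = quadrants, group_maps = group_maps,
                 tests = tests, correlations = correlations,
                 registration_info = reg_info,
                 node_spacing_mm = node_spacing_mm),
            class = "study_report")
}

.analyze_subject <- function(sub, s, reg_cfg, node_spacing_mm, seg) {
  states <- lapply(sub$states, function(v)
    if (is.character(v)) read_ct_volume(v) else v)
  masks <- lapply(states, segment_lungs, cfg = seg)
  vols <- vapply(masks, lung_volume, numeric(1))
  lv <- lung_volumes(vols[["EE_ZEEP"]], vols[["EI_ZEEP"]],
                     vols[["EE_PEEP"]], vols[["EI_PEEP"]])
  gs <- global_strains(lv)

  f_static <- register_ffd(states$EE_ZEEP, states$EE_PEEP,
                           masks$EE_ZEEP, reg_cfg)
  f_dyn_z <- register_ffd(states$EE_ZEEP, states$EI_ZEEP,
                          masks$EE_ZEEP, reg_cfg)
  f_dyn_p <- register_ffd(states$EE_PEEP, states$EI_PEEP,
                          masks$EE_PEEP, reg_cfg)

  ts_static <- recover_strain(f_static, masks$EE_ZEEP, node_spacing_mm,
                              component = "STATIC", condition = "PEEP")
  ts_dyn_z <- recover_strain(f_dyn_z, masks$EE_ZEEP, node_spacing_mm,
                             component = "DYNAMIC", condition = "ZEEP")
  ts_dyn_p <- recover_strain(f_dyn_p, masks$EE_PEEP, node_spacing_mm,
                             component = "DYNAMIC", condition = "PEEP")
  ts_dyn_p_z <- pullback_dynamic(ts_dyn_p, f_static)
  ts_total <- compose_total(ts_static, ts_dyn_p_z)

  aer_z <- classify_aeration(states$EE_ZEEP, masks$EE_ZEEP)
  aer_p <- classify_aeration(states$EE_PEEP, masks$EE_PEEP)

  # per-lung ROI grids per reference state, plus tissue-weight pooling
  sides <- c(left = 1L, right = 2L)
  grids_z <- lapply(sides, function(sd) partition_rois(
    new_lung_mask(masks$EE_ZEEP$side == sd, masks$EE_ZEEP$spacing)))
  grids_p <- lapply(sides, function(sd) partition_rois(
    new_lung_mask(masks$EE_PEEP$side == sd, masks$EE_PEEP$spacing)))

  agg <- function(field, grids) lapply(grids, function(g)
    aggregate_to_roi(field, g))
  maps_by_side <- list(
    ts_dynamic_zeep = agg(ts_dyn_z, grids_z),
    ts_static = agg(ts_static, grids_z),
    ts_total = agg(ts_total, grids_z),
    ts_dynamic_peep = agg(ts_dyn_p, grids_p))
  pooled <- lapply(maps_by_side, function(two) pool_roi_maps(two$left, two$right))

  fr_z <- lapply(grids_z, function(g) aeration_fractions(aer_z, g))
  fr_p <- lapply(grids_p, function(g) aeration_fractions(aer_p, g))
  delta <- aeration_delta(
    .pool_fraction_tables(fr_z$left, fr_z$right, grids_z),
    .pool_fraction_tables(fr_p$left, fr_p$right, grids_p))

  roi_long <- dplyr::bind_rows(lapply(names(maps_by_side), function(q) {
    cond <- if (grepl("zeep", q)) "ZEEP" else "PEEP"
    dplyr::bind_rows(
      dplyr::mutate(tidy(maps_by_side[[q]]$left), side = "left"),
      dplyr::mutate(tidy(maps_by_side[[q]]$right), side = "right"),
      dplyr::mutate(tidy(pooled[[q]]), side = "pooled")) |>
      dplyr::mutate(quantity = q, condition = cond, subject = s)
  }))
  quad <- dplyr::bind_rows(lapply(names(pooled), function(q)
    dplyr::mutate(quadrant_summary(pooled[[q]]), quantity = q, subject = s)))

  capno_tbl <- NULL
  if (!is.null(sub$capno)) {
    capno_tbl <- dplyr::bind_rows(lapply(names(sub$capno), function(cond) {
      br <- sub$capno[[cond]]
      breath <- if (inherits(br, "capno_breath")) br else br$breath
      dplyr::mutate(breath_dead_space(breath), condition = toupper(cond))
    }))
  }
  mech_tbl <- if (!is.null(sub$mechanics)) mechanics_scalars(sub$mechanics)

  global <- dplyr::mutate(dplyr::bind_cols(lv, gs), subject = s)
  if (!is.null(capno_tbl)) {
    global$bohr_zeep <- capno_tbl$bohr[capno_tbl$condition == "ZEEP"][1]
    global$bohr_peep <- capno_tbl$bohr[capno_tbl$condition == "PEEP"][1]
  }
  if (!is.null(mech_tbl)) {
    global$dp_zeep <- mech_tbl$driving_pressure_cmh2o[mech_tbl$condition == "ZEEP"][1]
    global$dp_peep <- mech_tbl$driving_pressure_cmh2o[mech_tbl$condition == "PEEP"][1]
    global$cstat_zeep <- mech_tbl$cstat_ml_cmh2o[mech_tbl$condition == "ZEEP"][1]
    global$cstat_peep <- mech_tbl$cstat_ml_cmh2o[mech_tbl$condition == "PEEP"][1]
  }

  list(subject = s,
       volumes = dplyr::mutate(lv, subject = s),
       global = global,
       roi = roi_long, quadrants = quad,
       maps = pooled, delta = delta,
       registration_info = list(static = f_static$info,
                                dynamic_zeep = f_dyn_z$info,
                                dynamic_peep = f_dyn_p$info))
}

#' Pool two per-lung ROI maps into one tissue-weighted map
#'
#' ROIs are matched by their `(roi_ab, roi_dv)` index; the pooled mean is
#' the voxel-count-weighted mean of the two lungs' ROI means.
#'
#' @param left,right `roi_map`s with the same grid size.
#' @return An `roi_map`.
#' @export
pool_roi_maps <- function(left, right) {
  stopifnot(inherits(left, "roi_map"), inherits(right, "roi_map"))
  n <- left$n + right$n
  num <- ifelse(left$n > 0, left$mean * left$n, 0) +
         ifelse(right$n > 0, right$mean * right$n, 0)
  mu <- ifelse(n > 0, num / n, NA_real_)
  structure(list(mean = mu, sd = NA * mu, n = n,
                 quantity = left$quantity, condition = left$condition),
            class = "roi_map")
}

.pool_fraction_tables <- function(left, right, grids) {
  nl <- as.vector(grids$left$counts[cbind(left$roi_ab, left$roi_dv)])
  nr <- as.vector(grids$right$counts[cbind(right$roi_ab, right$roi_dv)])
  out <- left
  for (cl in .aeration_classes) {
    a <- ifelse(nl > 0, left[[cl]] * nl, 0)
    b <- ifelse(nr > 0, right[[cl]] * nr, 0)
    out[[cl]] <- ifelse(nl + nr > 0, (a + b) / (nl + nr), NA_real_)
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", nrow(x$global), " subjects (",
      sum(x$global$complete), " complete)\n", sep = "")
  if (any(x$global$complete)) {
    g <- x$global[x$global$complete, ]
    cat(sprintf("  LS_STATIC %.1f%%, LS_DYNAMIC %.1f%% (PEEP), LS_DYNAMIC,ZEEP %.1f%%, LS_TOTAL %.1f%%\n",
                mean(g$ls_static), mean(g$ls_dynamic),
                mean(g$ls_dynamic_zeep), mean(g$ls_total)))
  }
  invisible(x)
}

#' @export
tidy.study_report <- function(x, ...) {
  tidyr::pivot_longer(x$global[x$global$complete, ],
                      cols = -c("subject", "complete", "reason"),
                      names_to = "metric", values_to = "value")
}

#' @export
glance.study_report <- function(x, ...) {
  g <- x$global[x$global$complete, ]
  if (nrow(g) == 0) return(tibble::tibble(n_subjects = 0L))
  num <- g[vapply(g, is.numeric, logical(1))]
  num$subject <- NULL
  out <- tibble::as_tibble(as.list(colMeans(as.matrix(num), na.rm = TRUE)))
  dplyr::mutate(out, n_subjects = nrow(g), .before = 1)
}
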