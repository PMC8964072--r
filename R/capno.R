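#' Volumetric capnography breath container
#'
#' One breath's expired volume versus CO2 partial pressure. Samples are
#' ordered by expired volume, which must start at zero and be
#' nondecreasing.
#'
#' @param volume_ml expired volume samples (ml), `volume_ml[1] == 0`,
#'   nondecreasing.
#' @param pco2_mmhg CO2 partial pressure per sample (mmHg, >= 0).
#' @param barometric_mmhg barometric pressure (mmHg).
#' @param sampling_rate_hz nominal sampling rate (Hz).
#' @return An object of class `capno_breath` (a tibble with per-sample rows
#'   and breath-level attributes).
#' @export
capno_breath <- function(volume_ml, pco2_mmhg, barometric_mmhg = 760,
                         sampling_rate_hz = 200) {
  if (length(volume_ml) != length(pco2_mmhg))
    stop("volume and pco2 traces have different lengths", call. = FALSE)
  if (length(volume_ml) < 2L) stop("breath too short", call. = FALSE)
  if (abs(volume_ml[1]) > 1e-9)
    stop("expired volume must start at zero", call. = FALSE)
  if (any(diff(volume_ml) < -1e-9))
    stop("expired volume must be nondecreasing", call. = FALSE)
  if (any(pco2_mmhg < 0)) stop("pco2 must be >= 0", call. = FALSE)
  out <- tibble::tibble(volume_ml = as.numeric(volume_ml),
                        pco2_mmhg = as.numeric(pco2_mmhg))
  attr(out, "barometric_mmhg") <- barometric_mmhg
  attr(out, "sampling_rate_hz") <- sampling_rate_hz
  class(out) <- c("capno_breath", class(out))
  out
}

#' Read a flow/CO2 trace CSV and build breaths
#'
#' Expects columns `time_s`, `flow_ml_s`, `pco2_mmhg`; expired volume is
#' obtained by trapezoidal integration of the (expiratory, positive) flow
#' signal over time.
#'
#' @param path CSV path.
#' @param barometric_mmhg barometric pressure.
#' @return A `capno_breath` covering the recorded expiration.
#' @export
read_capno_csv <- function(path, barometric_mmhg = 760) {
  df <- utils::read.csv(path)
  need <- c("time_s", "flow_ml_s", "pco2_mmhg")
  if (!all(need %in% names(df)))
    stop("trace CSV needs columns ", paste(need, collapse = ", "), call. = FALSE)
  t <- df$time_s; f <- df$flow_ml_s
  v <- c(0, cumsum(diff(t) * (head(f, -1) + tail(f, -1)) / 2))
  dt <- diff(t)
  rate <- if (length(dt) > 0) 1 / stats::median(dt) else NA_real_
  capno_breath(v, df$pco2_mmhg, barometric_mmhg = barometric_mmhg,
               sampling_rate_hz = rate)
}

#' Segment the expiratory phases of a volumetric capnogram
#'
#' Phase III (the alveolar plateau) is found as the longest terminal segment
#' on the volume axis over which a linear fit of pCO2 versus volume leaves a
#' residual SD below `tol_mmhg` (and whose first sample lies on the fitted
#' line within `tol_mmhg`, so the tail of the phase II upstroke is not
#' absorbed into the plateau) while spanning at least `min_span_frac` of the
#' expired volume. Phase II is the region of steepest rise before it and
#' phase I the initial CO2-free segment.
#'
#' @param breath a [capno_breath()] with at least 50 samples.
#' @param tol_mmhg residual SD tolerance of the phase-III linear fit
#'   (default 1 mmHg).
#' @param min_span_frac minimum phase-III span as a fraction of expired
#'   volume (default 0.3).
#' @return A list of class `capno_phases`: sample index `iii_start`, volume
#'   bounds of the three phases (ml), and the phase-III fit.
#' @export
segment_phases <- function(breath, tol_mmhg = 1, min_span_frac = 0.3) {
  stopifnot(inherits(breath, "capno_breath"))
  v <- breath$volume_ml; p <- breath$pco2_mmhg
  n <- length(v)
  if (n < 50L) stop("breath has fewer than 50 samples", call. = FALSE)
  vt <- v[n]
  if (vt <= 0) stop("zero expired volume", call. = FALSE)
  # cumulative sums from the tail for O(1) suffix regressions
  best <- NA_integer_
  for (i in seq_len(n - 1L)) {
    if (vt - v[i] < min_span_frac * vt) break
    vi <- v[i:n]; pi <- p[i:n]
    if (max(vi) - min(vi) <= 0) next
    fit <- .linfit(vi, pi)
    r <- pi - (fit[1] + fit[2] * vi)
    fit_sd <- sqrt(mean(r^2))
    if (fit_sd < tol_mmhg && abs(r[1]) < tol_mmhg && mean(pi) > 1) {
      best <- i; break
    }
  }
  if (is.na(best)) stop("no phase III", call. = FALSE)
  iii_start <- best
  # phase I: initial near-zero segment (below 5% of the plateau level)
  plateau <- mean(p[iii_start:n])
  i_end <- 0L
  low <- p <= pmax(0.05 * plateau, 0.5)
  if (low[1]) i_end <- max(which(cumsum(!low) == 0))
  i_end <- min(i_end, iii_start - 1L)
  structure(list(
    iii_start = iii_start,
    phase1 = c(0, if (i_end >= 1L) v[i_end] else 0),
    phase2 = c(if (i_end >= 1L) v[i_end] else 0, v[iii_start]),
    phase3 = c(v[iii_start], vt),
    fit = .linfit(v[iii_start:n], p[iii_start:n])),
    class = "capno_phases")
}

.linfit <- function(x, y) {
  sx <- var(x)
  b <- if (sx > 0) stats::cov(x, y) / sx else 0
  a <- mean(y) - b * mean(x)
  c(intercept = a, slope = b)
}

.linfit_residual_sd <- function(x, y) {
  f <- .linfit(x, y)
  r <- y - (f[1] + f[2] * x)
  sqrt(mean(r^2))
}

#' Mean alveolar pCO2 from the phase III slope
#'
#' Linear fit of pCO2 versus volume over phase III, evaluated at the
#' phase-III volume midpoint.
#'
#' @param breath a [capno_breath()].
#' @param phases optional [segment_phases()] result (computed if missing).
#' @return PACO2 in mmHg.
#' @export
alveolar_pco2 <- function(breath, phases = NULL) {
  phases <- phases %||% segment_phases(breath)
  span <- phases$phase3
  if (diff(span) <= 0) stop("degenerate phase III (zero span)", call. = FALSE)
  mid <- mean(span)
  unname(phases$fit[1] + phases$fit[2] * mid)
}

#' Mixed expired pCO2
#'
#' The volume-weighted mean expired CO2: `FECO2 = (integral of FCO2 dV) / Vt`
#' with `FCO2 = pCO2 / Pb`, integrated trapezoidally on the volume axis (so
#' flow irregularities do not bias the result), then `PECO2 = FECO2 * Pb`.
#'
#' @param breath a [capno_breath()].
#' @return PECO2 in mmHg.
#' @export
mixed_expired_pco2 <- function(breath) {
  stopifnot(inherits(breath, "capno_breath"))
  v <- breath$volume_ml; p <- breath$pco2_mmhg
  vt <- v[length(v)]
  if (vt <= 0) stop("zero expired volume", call. = FALSE)
  integral <- sum(diff(v) * (head(p, -1) + tail(p, -1)) / 2)
  integral / vt
}

#' Bohr dead space fraction
#'
#' `VD/VT = (PACO2 - PECO2) / PACO2`: the fraction of tidal ventilation not
#' participating in CO2 exchange.
#'
#' @param paco2 mean alveolar pCO2 (mmHg, > 0).
#' @param peco2 mixed expired pCO2 (mmHg).
#' @return Dimensionless fraction in \[0, 1\] when `peco2 <= paco2`.
#' @examples
#' bohr_dead_space(40, 20)  # 0.5
#' @export
bohr_dead_space <- function(paco2, peco2) {
  if (any(paco2 <= 0)) stop("PACO2 must be > 0", call. = FALSE)
  if (any(peco2 > paco2))
    warning("PECO2 exceeds PACO2: check phase III detection")
  (paco2 - peco2) / paco2
}

#' Bohr dead space of one breath
#'
#' Convenience wrapper running [segment_phases()], [alveolar_pco2()] and
#' [mixed_expired_pco2()] on a breath.
#'
#' @param breath a [capno_breath()].
#' @param ... passed to [segment_phases()].
#' @return A one-row tibble: `paco2`, `peco2`, `bohr`, `vt_ml`.
#' @export
breath_dead_space <- function(breath, ...) {
  ph <- segment_phases(breath, ...)
  pa <- alveolar_pco2(breath, ph)
  pe <- mixed_expired_pco2(breath)
  tibble::tibble(paco2 = pa, peco2 = pe, bohr = bohr_dead_space(pa, pe),
                 vt_ml = breath$volume_ml[nrow(breath)])
}

#' Static compliance and driving pressure
#'
#' Driving pressure is the plateau pressure minus total PEEP; static
#' compliance is the tidal volume over the driving pressure. Accepts either
#' scalars or a data frame with columns `vt_ml`, `pplat_cmh2o`,
#' `peep_total_cmh2o` (extra columns pass through), so mechanics tables can
#' be piped directly.
#'
#' @param vt_ml tidal volume (ml) or a data frame as described.
#' @param pplat_cmh2o plateau pressure (cmH2O), from an end-inspiratory
#'   pause.
#' @param peep_total_cmh2o total PEEP (cmH2O), from an end-expiratory
#'   pause; 0 at ZEEP unless intrinsic PEEP was measured.
#' @return A tibble with `driving_pressure_cmh2o` and `cstat_ml_cmh2o`
#'   (appended to the input columns when a data frame was given).
#' @examples
#' mechanics_scalars(186, pplat_cmh2o = 12.3, peep_total_cmh2o = 5)
#' @export
mechanics_scalars <- function(vt_ml, pplat_cmh2o = NULL, peep_total_cmh2o = 0) {
  if (is.data.frame(vt_ml)) {
    df <- vt_ml
    need <- c("vt_ml", "pplat_cmh2o", "peep_total_cmh2o")
    if (!all(need %in% names(df)))
      stop("data frame needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    vt <- df$vt_ml; pp <- df$pplat_cmh2o; pe <- df$peep_total_cmh2o
  } else {
    df <- NULL
    vt <- vt_ml; pp <- pplat_cmh2o; pe <- peep_total_cmh2o
  }
  if (any(vt <= 0)) stop("tidal volume must be > 0", call. = FALSE)
  if (any(pp <= pe))
    stop("plateau pressure must exceed total PEEP", call. = FALSE)
  dp <- pp - pe
  cstat <- vt / dp
  if (is.null(df))
    tibble::tibble(driving_pressure_cmh2o = dp, cstat_ml_cmh2o = cstat)
  else
    dplyr::mutate(tibble::as_tibble(df), driving_pressure_cmh2o = dp,
                  cstat_ml_cmh2o = cstat)
}
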