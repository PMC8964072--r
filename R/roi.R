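#' Volume-preserving 10 x 10 ROI partition of one lung
#'
#' Cuts one lung with 9 planes along the apicobasal axis and, independently,
#' 9 planes along the dorsoventral axis, positioned so that the ten slabs
#' along each axis hold (as nearly as possible) equal tissue volume; the
#' plane intersections define a 10 x 10 grid of ROIs. Plane positions are
#' chosen on the marginal tissue-volume distribution by dynamic programming
#' minimizing the worst slab imbalance, so each slab holds 10% of the
#' lung's tissue volume up to the granularity of one voxel slice. ROIs
#' without lung tissue (e.g. grid corners of an ellipsoidal lung) are
#' flagged missing.
#'
#' @param mask a single-lung `lung_mask` or logical array (use `side` of
#'   [segment_lungs()]'s output to pick one lung).
#' @param spacing voxel spacing (mm); taken from the mask when present.
#' @param n_ab,n_dv number of slabs along the apicobasal and dorsoventral
#'   axes (default 10 each).
#' @return An object of class `roi_grid`: integer label arrays `labels_ab`,
#'   `labels_dv` (`NA` outside the lung), cut-plane positions `ab_planes`,
#'   `dv_planes` (mm), a `missing` logical matrix, per-ROI voxel `counts`,
#'   and the slab tissue fractions `ab_fractions`, `dv_fractions`.
#' @export
partition_rois <- function(mask, spacing = NULL, n_ab = 10L, n_dv = 10L) {
  if (inherits(mask, "lung_mask")) {
    spacing <- spacing %||% mask$spacing
    m <- mask$mask
  } else m <- mask
  if (is.null(spacing)) stop("`spacing` required", call. = FALSE)
  stopifnot(is.array(m), length(dim(m)) == 3L)
  d <- dim(m)

  cuts_ab <- .volume_cuts(apply(m, 1, sum), n_ab)
  cuts_dv <- .volume_cuts(apply(m, 2, sum), n_dv)

  lab_ab <- findInterval(seq_len(d[1]), c(-Inf, cuts_ab$cuts + 0.5))
  lab_dv <- findInterval(seq_len(d[2]), c(-Inf, cuts_dv$cuts + 0.5))
  labels_ab <- array(NA_integer_, d)
  labels_dv <- array(NA_integer_, d)
  idx <- which(m)
  g <- coord_grids(d)
  labels_ab[idx] <- lab_ab[g$x[idx]]
  labels_dv[idx] <- lab_dv[g$y[idx]]

  counts <- matrix(0, n_ab, n_dv)
  tab <- table(factor(labels_ab[idx], levels = seq_len(n_ab)),
               factor(labels_dv[idx], levels = seq_len(n_dv)))
  counts[] <- as.numeric(tab)

  structure(list(
    labels_ab = labels_ab, labels_dv = labels_dv,
    ab_planes = cuts_ab$cuts * spacing[1],
    dv_planes = cuts_dv$cuts * spacing[2],
    ab_fractions = cuts_ab$fractions, dv_fractions = cuts_dv$fractions,
    counts = counts, missing = counts == 0,
    n_ab = as.integer(n_ab), n_dv = as.integer(n_dv),
    spacing = spacing), class = "roi_grid")
}

# optimal consecutive partition of per-slice tissue counts into n slabs,
# minimizing the maximum |slab fraction - 1/n| (dynamic programming over cut
# positions); returns cut positions (slice index after which each plane
# falls) and realized slab fractions
.volume_cuts <- function(slice_counts, n) {
  nz <- which(slice_counts > 0)
  if (length(nz) == 0L) stop("empty mask", call. = FALSE)
  lo <- min(nz); hi <- max(nz)
  if (hi - lo + 1L < n)
    stop("insufficient resolution: lung spans fewer slices than slabs",
         call. = FALSE)
  cs <- slice_counts[lo:hi]
  S <- length(cs)
  total <- sum(cs)
  cum <- c(0, cumsum(cs)) / total
  target <- 1 / n
  # dp[k, j]: minimal worst deviation splitting slices 1..j into k slabs
  dp <- matrix(Inf, n, S)
  choice <- matrix(0L, n, S)
  dp[1, ] <- abs(cum[2:(S + 1)] - target)
  for (k in 2:n) {
    for (j in k:S) {
      i <- (k - 1):(j - 1)               # last cut after slice i
      dev <- abs((cum[j + 1] - cum[i + 1]) - target)
      cand <- pmax(dp[k - 1, i], dev)
      best <- which.min(cand)
      dp[k, j] <- cand[best]
      choice[k, j] <- i[best]
    }
  }
  cuts <- integer(n - 1)
  j <- S
  for (k in n:2) {
    cuts[k - 1] <- choice[k, j]
    j <- choice[k, j]
  }
  bounds <- c(0L, cuts, S)
  fractions <- diff(cum[bounds + 1])
  list(cuts = cuts + lo - 1L, fractions = fractions)
}

#' @export
print.roi_grid <- function(x, ...) {
  cat("<roi_grid> ", x$n_ab, " x ", x$n_dv, " ROIs, ",
      sum(!x$missing), " with tissue; worst slab imbalance ",
      sprintf("%.2f%%", 100 * max(abs(c(x$ab_fractions, x$dv_fractions) -
                                        1 / x$n_ab))), "\n", sep = "")
  invisible(x)
}

#' Aggregate a voxel field to the ROI grid
#'
#' Per-ROI mean and SD of a scalar field over the in-ROI lung voxels,
#' yielding the 10 x 10 array representation used for all regional results.
#' `NA` field values (voxels outside the lung) are ignored.
#'
#' @param field a [strain_map()], an `aeration_map` (its gas fraction), or a
#'   3D numeric array on the same grid as `grid`.
#' @param grid an `roi_grid` from [partition_rois()].
#' @return An object of class `roi_map`: matrices `mean`, `sd`, `n` plus the
#'   quantity label. Use [tidy()] for the long tibble form.
#' @export
aggregate_to_roi <- function(field, grid) {
  stopifnot(inherits(grid, "roi_grid"))
  if (inherits(field, "strain_map")) {
    vals <- field$values
    quantity <- paste0("TS_", field$component)
    condition <- field$condition
  } else if (inherits(field, "aeration_map")) {
    vals <- field$gas_fraction
    quantity <- "gas_fraction"
    condition <- NULL
  } else {
    vals <- field
    quantity <- "field"
    condition <- NULL
  }
  if (!identical(dim(vals), dim(grid$labels_ab)))
    stop("field and ROI grid have different shapes", call. = FALSE)
  idx <- which(!is.na(grid$labels_ab) & !is.na(vals))
  lin <- grid$labels_ab[idx] + (grid$labels_dv[idx] - 1L) * grid$n_ab
  v <- vals[idx]
  ncell <- grid$n_ab * grid$n_dv
  n <- .accumulate(lin, rep(1, length(lin)), ncell)
  s <- .accumulate(lin, v, ncell)
  s2 <- .accumulate(lin, v^2, ncell)
  mu <- ifelse(n > 0, s / n, NA_real_)
  sdv <- ifelse(n > 1, sqrt(pmax(0, (s2 - n * mu^2) / (n - 1))), NA_real_)
  structure(list(mean = matrix(mu, grid$n_ab, grid$n_dv),
                 sd = matrix(sdv, grid$n_ab, grid$n_dv),
                 n = matrix(n, grid$n_ab, grid$n_dv),
                 quantity = quantity, condition = condition),
            class = "roi_map")
}

#' @export
print.roi_map <- function(x, ...) {
  cat("<roi_map> ", x$quantity,
      if (!is.null(x$condition)) paste0(" (", x$condition, ")"), ": ",
      sum(x$n > 0), "/", length(x$n), " ROIs, grand mean ",
      format(round(mean(x$mean[x$n > 0]), 2)), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.roi_map <- function(x, ...) {
  tibble::tibble(
    roi_ab = rep(seq_len(nrow(x$mean)), ncol(x$mean)),
    roi_dv = rep(seq_len(ncol(x$mean)), each = nrow(x$mean)),
    mean = as.vector(x$mean), sd = as.vector(x$sd),
    n_voxels = as.vector(x$n),
    quadrant = quadrant_of(rep(seq_len(nrow(x$mean)), ncol(x$mean)),
                           rep(seq_len(ncol(x$mean)), each = nrow(x$mean)),
                           nrow(x$mean), ncol(x$mean)))
}

quadrant_of <- function(ab, dv, n_ab = 10L, n_dv = 10L) {
  apical <- ab <= n_ab / 2
  ventral <- dv <= n_dv / 2
  dplyr::case_when(
    apical & ventral ~ "apicoventral",
    apical & !ventral ~ "apicodorsal",
    !apical & ventral ~ "basoventral",
    TRUE ~ "basodorsal")
}

#' Quadrant summary of a 10 x 10 ROI map
#'
#' Mean and SD over the non-missing ROI means of each 5 x 5 quadrant block:
#' apical = rows 1-5, basal = rows 6-10, ventral = columns 1-5, dorsal =
#' columns 6-10.
#'
#' @param map2d an `roi_map` from [aggregate_to_roi()].
#' @return A tibble with columns `quadrant`, `mean`, `sd`, `n_rois`
#'   (quadrants with no tissue ROIs yield `NA`).
#' @export
quadrant_summary <- function(map2d) {
  stopifnot(inherits(map2d, "roi_map"))
  td <- tidy(map2d)
  td <- dplyr::filter(td, .data$n_voxels > 0)
  out <- dplyr::summarise(dplyr::group_by(td, .data$quadrant),
                          sd = sd(.data$mean), mean = mean(.data$mean),
                          n_rois = dplyr::n(), .groups = "drop")
  out <- out[c("quadrant", "mean", "sd", "n_rois")]
  full <- tibble::tibble(quadrant = c("apicoventral", "apicodorsal",
                                      "basoventral", "basodorsal"))
  dplyr::left_join(full, out, by = "quadrant")
}

#' Paired per-ROI tests between two conditions
#'
#' For each ROI, a two-sided paired t test of the subject-wise ROI means
#' between conditions A and B, Bonferroni-adjusted over the number of ROIs
#' actually tested (those non-missing in every subject). This is the
#' regional inference layer: per-ROI paired comparisons with family-wise
#' control over the grid.
#'
#' @param maps_a,maps_b lists of `roi_map`s (one per subject, paired by
#'   position).
#' @param alpha significance level on the adjusted p value.
#' @return A tibble with columns `roi_ab`, `roi_dv`, `mean_diff` (B - A),
#'   `t`, `df`, `p`, `p_adj`, `significant`, `n_tested` (the Bonferroni
#'   family size). ROIs missing in any subject have `NA` statistics.
#' @export
roi_paired_tests <- function(maps_a, maps_b, alpha = 0.05) {
  stopifnot(is.list(maps_a), is.list(maps_b))
  if (length(maps_a) != length(maps_b))
    stop("subject lists have different lengths", call. = FALSE)
  n_sub <- length(maps_a)
  if (n_sub < 3L) stop("need at least 3 subjects", call. = FALSE)
  get_means <- function(m) { stopifnot(inherits(m, "roi_map"))
    ifelse(m$n > 0, m$mean, NA_real_) }
  A <- vapply(maps_a, function(m) as.vector(get_means(m)),
              numeric(length(maps_a[[1]]$mean)))
  B <- vapply(maps_b, function(m) as.vector(get_means(m)),
              numeric(length(maps_b[[1]]$mean)))
  D <- B - A
  ok <- apply(!is.na(D), 1, all)
  n_tested <- sum(ok)
  md <- rowMeans(D)
  sdd <- apply(D, 1, sd)
  tstat <- md / (sdd / sqrt(n_sub))
  p <- 2 * pt(-abs(tstat), df = n_sub - 1)
  p[!ok] <- NA_real_
  md[!ok] <- NA_real_
  tstat[!ok] <- NA_real_
  p_adj <- pmin(p * n_tested, 1)
  nr <- nrow(maps_a[[1]]$mean); nc <- ncol(maps_a[[1]]$mean)
  tibble::tibble(
    roi_ab = rep(seq_len(nr), nc), roi_dv = rep(seq_len(nc), each = nr),
    mean_diff = md, t = tstat, df = n_sub - 1, p = p, p_adj = p_adj,
    significant = !is.na(p_adj) & p_adj < alpha, n_tested = n_tested)
}

#' Correlate regional static strain with aeration change
#'
#' Pearson correlation, over pooled non-missing ROIs, between the static
#' strain ROI means and the PEEP-minus-ZEEP change in an aeration class
#' fraction.
#'
#' @param ts_static an `roi_map` of static strain (or a numeric vector).
#' @param delta an [aeration_delta()] tibble (or a numeric vector paired
#'   with `ts_static`).
#' @param class aeration class to correlate against: `"hyper"`, `"normo"`,
#'   `"poor"` or `"non"` (ignored when `delta` is a vector).
#' @return A one-row tibble: `class`, `r`, `p`, `n`.
#' @export
correlate_static_delta <- function(ts_static, delta, class = "normo") {
  if (inherits(ts_static, "roi_map") && is.data.frame(delta)) {
    class <- match.arg(class, .aeration_classes)
    td <- tidy(ts_static)
    d <- dplyr::inner_join(td, delta, by = c("roi_ab", "roi_dv"))
    x <- d$mean
    y <- d[[paste0("d_", class)]]
  } else {
    x <- as.numeric(ts_static); y <- as.numeric(delta)
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired non-missing ROIs", call. = FALSE)
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance in one of the vectors", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(class = class, r = unname(ct$estimate), p = ct$p.value,
                 n = length(x))
}
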