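#' Radial intensity profile container
#'
#' Mean marker intensity (typically normalized to a nuclear counterstain)
#' per bin of distance from the colony edge, averaged across colonies.
#'
#' @param centers bin centers (um from colony edge).
#' @param mean per-bin mean intensity.
#' @param sem per-bin standard error across colonies (0 when a single
#'   colony is profiled).
#' @param n_colonies number of colonies averaged.
#' @param bin_width bin width in um.
#' @export
radial_profile <- function(centers, mean, sem = rep(0, length(mean)),
                           n_colonies = 1L, bin_width = NULL) {
  stopifnot(length(centers) == length(mean), length(sem) == length(mean))
  if (any(sem < 0, na.rm = TRUE)) stop("sem must be non-negative")
  structure(list(centers = centers, mean = mean, sem = sem,
                 n_colonies = as.integer(n_colonies),
                 bin_width = bin_width %||%
                   (if (length(centers) > 1) diff(centers[1:2]) else NA_real_)),
            class = c("radial_profile", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Time series of radial profiles
#'
#' @param times strictly increasing time points (hours).
#' @param centers shared bin centers (um from edge).
#' @param values time-by-bin matrix of mean intensities.
#' @export
profile_series <- function(times, centers, values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(times), ncol(values) == length(centers),
            !is.unsorted(times, strictly = TRUE))
  structure(list(times = times, centers = centers, values = values),
            class = c("profile_series", "list"))
}

as_list_of_matrices <- function(x) if (is.matrix(x)) list(x) else x

disc_kernel <- function(radius_px) {
  r <- max(1L, round(radius_px))
  sz <- 2L * r + 1L
  cc <- r + 1L
  k <- outer(seq_len(sz), seq_len(sz),
             function(i, j) (i - cc)^2 + (j - cc)^2 <= radius_px^2)
  matrix(as.numeric(k), sz, sz)
}

local_mean_over_mask <- function(img, pixmask, kernel) {
  num <- as.matrix(EBImage::filter2(img * pixmask, kernel))
  den <- as.matrix(EBImage::filter2(pixmask * 1, kernel))
  out <- num / den
  out[den <= 0] <- NA_real_
  out
}

bin_means <- function(values, idx, n_bins) {
  keep <- !is.na(idx) & !is.na(values)
  s <- tapply(values[keep], factor(idx[keep], levels = seq_len(n_bins)), mean)
  as.numeric(s)
}

#' DAPI-normalized nuclear radial profile
#'
#' Implements the normalized nuclear intensity recipe used for all fixed
#' marker quantifications: (1) nuclear pixels are extracted with the
#' nuclear mask; (2) for every nuclear pixel, the local mean of the marker
#' over nuclear pixels within a disc of radius `local_radius` is computed;
#' (3) likewise for the DAPI channel; (4) the marker local mean is divided
#' by the DAPI local mean; (5) the ratio is averaged within bins of
#' distance from the colony edge for each colony; (6) bins are averaged
#' across colonies, reported as mean and standard error.
#'
#' @param marker_images matrix or list of matrices (one per colony).
#' @param dapi_images matching DAPI channel(s).
#' @param nuclear_masks matching logical nuclear mask(s).
#' @param mask a [make_mask()] shared colony mask.
#' @param local_radius local averaging radius in um (default 120).
#' @param bin_width radial bin width in um (default 10).
#' @return a [radial_profile()]. Bins with no nuclear pixels are `NA`.
#' @export
nuclear_radial_profile <- function(marker_images, dapi_images, nuclear_masks,
                                   mask, local_radius = 120, bin_width = 10) {
  marker_images <- as_list_of_matrices(marker_images)
  dapi_images <- as_list_of_matrices(dapi_images)
  nuclear_masks <- as_list_of_matrices(nuclear_masks)
  n <- length(marker_images)
  stopifnot(length(dapi_images) == n, length(nuclear_masks) == n)
  eb <- edge_bins(mask, bin_width)
  kern <- disc_kernel(local_radius / mask$pixel_size)
  per_colony <- lapply(seq_len(n), function(i) {
    nm <- nuclear_masks[[i]] & TRUE
    if (!any(nm)) stop(sprintf("colony %d: empty nuclear mask", i))
    stopifnot(all(dim(nm) == dim(mask$grid)))
    m_avg <- local_mean_over_mask(marker_images[[i]], nm, kern)
    d_avg <- local_mean_over_mask(dapi_images[[i]], nm, kern)
    ratio <- m_avg / d_avg
    sel <- nm & mask$grid
    bin_means(ifelse(sel, ratio, NA), eb$index, eb$n_bins)
  })
  mat <- do.call(rbind, per_colony)
  mu <- colMeans(mat, na.rm = TRUE)
  mu[!is.finite(mu)] <- NA_real_
  sem <- if (n > 1) apply(mat, 2, stats::sd, na.rm = TRUE) / sqrt(n)
         else rep(0, ncol(mat))
  sem[is.na(mu)] <- NA_real_
  radial_profile(eb$centers, mu, sem, n, bin_width)
}

#' Non-membrane signal radial profile
#'
#' WNT activity readout from membrane-tagged reporters: the membrane mask
#' is subtracted from the colony mask and the signal is averaged over the
#' remaining (non-membrane) pixels in bins of edge distance, then across
#' colonies.
#'
#' @param signal_images matrix or list of matrices (one per colony).
#' @param membrane_masks matching logical membrane mask(s); must be subsets
#'   of the colony foreground.
#' @param mask a [make_mask()] colony mask.
#' @param bin_width radial bin width in um.
#' @return a [radial_profile()].
#' @export
nonmembrane_profile <- function(signal_images, membrane_masks, mask,
                                bin_width = 10) {
  signal_images <- as_list_of_matrices(signal_images)
  membrane_masks <- as_list_of_matrices(membrane_masks)
  n <- length(signal_images)
  stopifnot(length(membrane_masks) == n)
  eb <- edge_bins(mask, bin_width)
  per_colony <- lapply(seq_len(n), function(i) {
    mem <- membrane_masks[[i]] & TRUE
    if (any(mem & !mask$grid))
      stop(sprintf("colony %d: membrane mask extends outside the colony", i))
    nonmem <- mask$grid & !mem
    if (!any(nonmem))
      stop(sprintf("colony %d: membrane mask covers the whole colony", i))
    bin_means(ifelse(nonmem, signal_images[[i]], NA), eb$index, eb$n_bins)
  })
  mat <- do.call(rbind, per_colony)
  mu <- colMeans(mat, na.rm = TRUE)
  mu[!is.finite(mu)] <- NA_real_
  sem <- if (n > 1) apply(mat, 2, stats::sd, na.rm = TRUE) / sqrt(n)
         else rep(0, ncol(mat))
  radial_profile(eb$centers, mu, sem, n, bin_width)
}

#' Restrict a profile series to a time window
#'
#' Used e.g. to discard the initialization transient of a simulation
#' before wave tracking, mirroring the experimental situation where
#' recording starts after treatment.
#' @param series a [profile_series()].
#' @param t_min,t_max inclusive bounds (hours).
#' @export
window_series <- function(series, t_min = -Inf, t_max = Inf) {
  keep <- series$times >= t_min & series$times <= t_max
  profile_series(series$times[keep], series$centers,
                 series$values[keep, , drop = FALSE])
}

#' Track the inward signaling wave in a profile series
#'
#' The active signaling domain at each time is the contiguous run of bins
#' whose mean intensity exceeds half the spatiotemporal maximum of the
#' whole series (when several runs exceed it, the one containing that
#' time's maximum is used). Its outer boundary (`back`, smallest edge
#' distance) and inner boundary (`front`, largest edge distance) are traced
#' over time, and the advancing phase of the front -- from when it leaves
#' its initial position until it reaches the deepest bin or imaging ends --
#' is summarized by an ordinary least-squares line front = slope * t +
#' intercept.
#'
#' @param series a [profile_series()].
#' @return object of class `wave_track`: `threshold`, `times`, `front`,
#'   `back` (um from edge, NA when no bin is active), `fit` (slope um/h,
#'   intercept um, r_squared), `fit_window` (times used).
#' @export
track_wave <- function(series) {
  stopifnot(inherits(series, "profile_series"), length(series$times) >= 3)
  v <- series$values
  thr <- max(v, na.rm = TRUE) / 2
  if (!is.finite(thr) || thr <= 0)
    return(structure(list(threshold = thr, times = series$times,
                          front = rep(NA_real_, nrow(v)),
                          back = rep(NA_real_, nrow(v)),
                          fit = list(slope = NA_real_, intercept = NA_real_,
                                     r_squared = NA_real_),
                          fit_window = numeric()), class = "wave_track"))
  centers <- series$centers
  bw <- if (length(centers) > 1) diff(centers[1:2]) else 1
  front <- back <- rep(NA_real_, nrow(v))
  for (i in seq_len(nrow(v))) {
    act <- which(!is.na(v[i, ]) & v[i, ] > thr)
    if (!length(act)) next
    runs <- split(act, cumsum(c(1, diff(act) != 1)))
    imax <- which.max(v[i, ])
    run <- NULL
    for (r in runs) if (imax %in% r) run <- r
    if (is.null(run)) run <- runs[[which.max(vapply(runs, function(r) max(v[i, r]), 0))]]
    # boundary positions interpolated to the sub-bin threshold crossing
    lo <- min(run); hi <- max(run)
    back[i] <- if (lo > 1 && !is.na(v[i, lo - 1]))
      centers[lo] - bw * (v[i, lo] - thr) / (v[i, lo] - v[i, lo - 1])
    else centers[lo]
    front[i] <- if (hi < ncol(v) && !is.na(v[i, hi + 1]))
      centers[hi] + bw * (v[i, hi] - thr) / (v[i, hi] - v[i, hi + 1])
    else centers[hi]
  }
  fit <- list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_)
  window <- numeric()
  idx <- which(!is.na(front))
  if (length(idx) >= 2) {
    fr <- front[idx]
    moved <- which(fr > fr[1] + bw / 2)
    i_start <- if (length(moved)) max(1L, moved[1] - 1L) else 1L
    deepest <- max(centers)
    reached <- which(fr >= deepest - bw / 2)
    # advancing phase: until the front reaches the deepest bin, stops
    # advancing for good, or the series ends
    i_end <- if (length(reached)) reached[1] else max(which(fr == max(fr))[1], i_start + 1L)
    sel <- idx[i_start:i_end]
    if (length(sel) >= 2 && stats::var(series$times[sel]) > 0) {
      tt <- series$times[sel]; yy <- front[sel]
      cf <- stats::coef(stats::lm(yy ~ tt))
      pred <- cf[1] + cf[2] * tt
      ss_tot <- sum((yy - mean(yy))^2)
      r2 <- if (ss_tot > 0) 1 - sum((yy - pred)^2) / ss_tot else 0
      fit <- list(slope = unname(cf[2]), intercept = unname(cf[1]),
                  r_squared = r2)
      window <- tt
    }
  }
  structure(list(threshold = thr, times = series$times, front = front,
                 back = back, fit = fit, fit_window = window),
            class = "wave_track")
}

#' @export
print.wave_track <- function(x, ...) {
  cat(sprintf("<wave_track> threshold %.4g; front fit: %.3g um/h x t + %.3g um, R^2 = %.3g (window %g-%g h)\n",
              x$threshold, x$fit$slope, x$fit$intercept, x$fit$r_squared,
              if (length(x$fit_window)) min(x$fit_window) else NA,
              if (length(x$fit_window)) max(x$fit_window) else NA))
  invisible(x)
}

#' Displacement statistics of tracked cells
#'
#' Per-cell displacement (straight-line distance between first and last
#' observed positions), signed radial displacement (distance from the
#' colony centre at the end minus at the start; negative = inward), arc
#' displacement (|change in polar angle| times mean radius, a proxy for
#' angular movement), and progeny counts of founder cells (0 = no division
#' observed, 2 = one division, 3 = one daughter divided, 4 = both
#' daughters divided). Tracks with a single observation are excluded and
#' counted in the QC report.
#'
#' @param tracks data.frame with columns `track_id`, `t`, `x`, `y` and
#'   optionally `parent_id` (NA for founders).
#' @param colony_center numeric length-2 `(x, y)` in the same units as the
#'   track coordinates.
#' @param pixel_size scale factor to um (1 if coordinates are already um).
#' @return list with `cells` (per-track data.frame), `progeny` (per-founder
#'   counts), `n_excluded`, and `summary` (cohort means).
#' @export
track_stats <- function(tracks, colony_center, pixel_size = 1) {
  stopifnot(all(c("track_id", "t", "x", "y") %in% names(tracks)))
  spl <- split(tracks, tracks$track_id)
  ok <- vapply(spl, nrow, 0L) >= 2L
  n_excluded <- sum(!ok)
  spl <- spl[ok]
  rows <- lapply(spl, function(d) {
    d <- d[order(d$t), ]
    p0 <- c(d$x[1], d$y[1]); p1 <- c(d$x[nrow(d)], d$y[nrow(d)])
    r0 <- sqrt(sum((p0 - colony_center)^2)); r1 <- sqrt(sum((p1 - colony_center)^2))
    th0 <- atan2(p0[2] - colony_center[2], p0[1] - colony_center[1])
    th1 <- atan2(p1[2] - colony_center[2], p1[1] - colony_center[1])
    dth <- abs(atan2(sin(th1 - th0), cos(th1 - th0)))
    data.frame(track_id = d$track_id[1],
               displacement = sqrt(sum((p1 - p0)^2)) * pixel_size,
               radial_displacement = (r1 - r0) * pixel_size,
               arc_displacement = dth * mean(c(r0, r1)) * pixel_size,
               r_start = r0 * pixel_size)
  })
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  progeny <- NULL
  if ("parent_id" %in% names(tracks)) {
    kids <- split(tracks$track_id[!is.na(tracks$parent_id)],
                  tracks$parent_id[!is.na(tracks$parent_id)])
    kids <- lapply(kids, unique)
    n_leaves <- function(id) {
      ch <- kids[[as.character(id)]]
      if (is.null(ch)) 1L else sum(vapply(ch, n_leaves, 0L))
    }
    founders <- unique(tracks$track_id[is.na(tracks$parent_id)])
    pg <- vapply(founders, function(f) {
      nl <- n_leaves(f)
      if (nl == 1L) 0L else nl
    }, 0L)
    progeny <- data.frame(track_id = founders, progeny = pg)
  }
  list(cells = cells, progeny = progeny, n_excluded = n_excluded,
       summary = c(mean_displacement = mean(cells$displacement),
                   mean_radial_displacement = mean(cells$radial_displacement),
                   mean_arc_displacement = mean(cells$arc_displacement)))
}

#' Neighbourhood similarity index of labelled cells
#'
#' Fraction of cells whose neighbourhood (other cells within
#' `neighbor_radius`) contains more than `frac` same-label cells. Near 1 in
#' sorted (phase-separated) populations; near the mixing expectation in
#' well-mixed ones. Cells without neighbours are excluded from the
#' denominator; if every cell is isolated the index is undefined (NA).
#'
#' @param positions n-by-2 matrix of cell positions (um).
#' @param labels vector of cell-type labels, length n.
#' @param neighbor_radius neighbourhood radius in um (default 62).
#' @param frac similar-neighbour fraction a cell must exceed (default 0.6).
#' @return list with `index`, `n_with_neighbors`, `n_isolated`.
#' @export
similarity_index <- function(positions, labels, neighbor_radius = 62,
                             frac = 0.6) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(n >= 2, length(labels) == n)
  d <- as.matrix(stats::dist(positions))
  diag(d) <- Inf
  nb <- d <= neighbor_radius
  has <- rowSums(nb) > 0
  if (!any(has))
    return(list(index = NA_real_, n_with_neighbors = 0L, n_isolated = n))
  same <- outer(labels, labels, "==")
  sim <- vapply(which(has), function(i)
    sum(nb[i, ] & same[i, ]) / sum(nb[i, ]) > frac, TRUE)
  list(index = mean(sim), n_with_neighbors = sum(has),
       n_isolated = as.integer(n - sum(has)))
}

#' Write a radial profile or wave track as CSV
#'
#' Profiles are written with columns (bin_center_um, mean, sem,
#' n_colonies); wave tracks with (t, back_um, front_um).
#' @param x a [radial_profile()] or `wave_track`.
#' @param path output CSV path.
#' @export
write_quant_csv <- function(x, path) {
  if (inherits(x, "radial_profile")) {
    utils::write.csv(data.frame(bin_center_um = x$centers, mean = x$mean,
                                sem = x$sem, n_colonies = x$n_colonies),
                     path, row.names = FALSE)
  } else if (inherits(x, "wave_track")) {
    utils::write.csv(data.frame(t = x$times, back_um = x$back,
                                front_um = x$front), path, row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
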