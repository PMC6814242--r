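#' Phenomenological fate-assignment rules
#'
#' Maps simulated BMP/WNT/NODAL signaling histories onto the three fate
#' territories of the BMP4-treated colony: extra-embryonic CDX2+ cells at
#' the edge (EXE), a BRACHYURY+ mesodermal ring (MESO), and a pluripotent
#' SOX2+ centre (CENTER). The rules encode signaling *duration*, not
#' instantaneous level: extra-embryonic differentiation requires sustained
#' above-threshold BMP exposure, mesoderm requires sustained WNT and NODAL
#' exposure. Assignment precedence is EXE > MESO > CENTER; pixels whose
#' histories are identically zero stay NONE.
#'
#' @param bmp_level,bmp_duration BMP exposure threshold (signal units) and
#'   the cumulative hours above it required for EXE (default 20 h, the
#'   minimal BMP duration that yields CDX2+ edge cells).
#' @param wnt_level,wnt_duration WNT exposure threshold and required
#'   cumulative hours for MESO.
#' @param nodal_level,nodal_duration NODAL exposure threshold and required
#'   cumulative hours for MESO.
#' @return a list of class `fate_rules`.
#' @export
fate_rules <- function(bmp_level = 0.5, bmp_duration = 20,
                       wnt_level = 1, wnt_duration = 10,
                       nodal_level = 0.4, nodal_duration = 10) {
  p <- list(bmp_level = bmp_level, bmp_duration = bmp_duration,
            wnt_level = wnt_level, wnt_duration = wnt_duration,
            nodal_level = nodal_level, nodal_duration = nodal_duration)
  if (any(unlist(p) < 0)) stop("fate rule thresholds must be non-negative")
  structure(p, class = c("fate_rules", "list"))
}

# cumulative hours each pixel spends at or above `level`
exposure_time <- function(history, times, level) {
  stopifnot(length(dim(history)) == 3, dim(history)[3] == length(times))
  dt <- diff(times)
  acc <- matrix(0, dim(history)[1], dim(history)[2])
  for (k in seq_along(dt))
    acc <- acc + dt[k] * (history[, , k] >= level)
  acc
}

#' Assign fate territories from signaling histories
#'
#' @param bmp_history,u_history,v_history H x W x T arrays of BMP, WNT and
#'   NODAL signaling sampled at `times`.
#' @param times sampling times (hours), shared by the three histories.
#' @param rules a [fate_rules()] object.
#' @param mask a [make_mask()] object.
#' @return object of class `fate_map_result`: `labels` (H x W character
#'   matrix over EXE/MESO/CENTER/NONE, NA off-colony), `area_fraction`,
#'   `mean_edge_distance` (um) per fate.
#' @export
assign_fates <- function(bmp_history, u_history, v_history, times, rules,
                         mask) {
  dims <- dim(mask$grid)
  for (h in list(bmp_history, u_history, v_history))
    if (!all(dim(h)[1:2] == dims)) stop("history lattice does not match mask")
  bmp_t <- exposure_time(bmp_history, times, rules$bmp_level)
  wnt_t <- exposure_time(u_history, times, rules$wnt_level)
  nod_t <- exposure_time(v_history, times, rules$nodal_level)

  lab <- matrix(NA_character_, dims[1], dims[2])
  fg <- mask$grid
  any_signal <- (apply(bmp_history, c(1, 2), max) +
                 apply(u_history, c(1, 2), max) +
                 apply(v_history, c(1, 2), max)) > 0
  lab[fg] <- "NONE"
  lab[fg & any_signal] <- "CENTER"
  meso <- fg & any_signal & wnt_t >= rules$wnt_duration &
    nod_t >= rules$nodal_duration
  lab[meso] <- "MESO"
  exe <- fg & any_signal & bmp_t >= rules$bmp_duration
  lab[exe] <- "EXE"

  ed <- edge_distance(mask)$values
  fates <- c("EXE", "MESO", "CENTER", "NONE")
  af <- vapply(fates, function(f) sum(lab == f, na.rm = TRUE) / sum(fg), 0)
  med <- vapply(fates, function(f) {
    sel <- !is.na(lab) & lab == f
    if (any(sel)) mean(ed[sel]) else NA_real_
  }, 0)
  structure(list(labels = lab, area_fraction = af,
                 mean_edge_distance = med, rules = rules, mask = mask),
            class = "fate_map_result")
}

#' Fate map directly from a cascade simulation
#'
#' @param sim a [simulate_cascade()] result.
#' @param rules a [fate_rules()] object.
#' @export
fate_map_from_sim <- function(sim, rules) {
  dims <- dim(sim$mask$grid)
  nt <- length(sim$snapshots)
  arr <- function(field) {
    a <- array(0, c(dims, nt))
    for (k in seq_len(nt)) a[, , k] <- sim$snapshots[[k]][[field]]
    a
  }
  assign_fates(arr("b"), arr("u"), arr("v"), sim$times, rules, sim$mask)
}

#' @export
print.fate_map_result <- function(x, ...) {
  cat("<fate_map_result> area fractions:\n")
  print(round(x$area_fraction, 3))
  invisible(x)
}

#' Calibrate fate rules on a control colony
#'
#' Fixes the level thresholds from the control run itself (BMP: half its
#' input amplitude; WNT: half the spatiotemporal maximum of `u`, the same
#' convention used to define the active signaling domain; NODAL: the
#' model's autoactivation threshold) and then tunes the WNT/NODAL duration
#' requirement by grid search so that the deepest extent of the mesodermal
#' ring matches `meso_extent` (um from the edge). Calibration is done once,
#' on the reference geometry; the returned rules are then applied unchanged
#' to other sizes and shapes.
#'
#' @param sim control-run [simulate_cascade()] on the reference colony.
#' @param meso_extent target inner (deepest) boundary of the mesodermal
#'   ring, um from the colony edge.
#' @param bmp_duration required BMP exposure for the extra-embryonic edge
#'   fate (hours).
#' @param durations candidate WNT/NODAL duration requirements (hours).
#' @return calibrated [fate_rules()].
#' @export
calibrate_fate_rules <- function(sim, meso_extent = 160, bmp_duration = 20,
                                 durations = seq(2, 30, by = 1)) {
  u_max <- max(vapply(sim$snapshots, function(s) max(s$u), 0))
  base <- fate_rules(bmp_level = sim$bmp$amplitude / 2,
                     bmp_duration = bmp_duration,
                     wnt_level = u_max / 2, wnt_duration = 10,
                     nodal_level = sim$params$v_th, nodal_duration = 10)
  err <- vapply(durations, function(d) {
    r <- base; r$wnt_duration <- d; r$nodal_duration <- d
    fm <- fate_map_from_sim(sim, r)
    ext <- meso_max_extent(fm)
    if (is.na(ext)) Inf else abs(ext - meso_extent)
  }, 0)
  best <- durations[which.min(err)]
  base$wnt_duration <- best
  base$nodal_duration <- best
  base
}

meso_max_extent <- function(fm) {
  ed <- edge_distance(fm$mask)$values
  sel <- !is.na(fm$labels) & fm$labels == "MESO"
  if (!any(sel)) NA_real_ else max(ed[sel])
}

#' Inward extent of the mesodermal ring around the colony boundary
#'
#' Splits the colony into angular sectors about its centroid and reports,
#' per sector, the maximum edge distance reached by MESO pixels. On
#' circular colonies the metric is flat; on triangles and pacman shapes the
#' sectors facing corners show a deeper mesodermal territory -- the
#' corner inward-expansion phenotype.
#'
#' @param fates a [assign_fates()] result.
#' @param n_sectors number of angular sectors (default 36).
#' @return data.frame with `angle` (sector centre, degrees, 0 = +x,
#'   counter-clockwise) and `extent` (um; NA if the sector has no MESO).
#' @export
corner_expansion_metric <- function(fates, n_sectors = 36) {
  mask <- fates$mask
  g <- mask$grid
  H <- nrow(g); W <- ncol(g)
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  cx <- mean(xs[g]); cy <- mean(ys[g])
  ang <- atan2(cy - ys, xs - cx)  # +y up convention
  ed <- edge_distance(mask)$values
  sel <- !is.na(fates$labels) & fates$labels == "MESO"
  breaks <- seq(-pi, pi, length.out = n_sectors + 1)
  sector <- findInterval(ang, breaks, rightmost.closed = TRUE)
  extent <- vapply(seq_len(n_sectors), function(s) {
    p <- sel & sector == s
    if (any(p)) max(ed[p]) else NA_real_
  }, 0)
  available <- vapply(seq_len(n_sectors), function(s) {
    p <- g & sector == s
    if (any(p)) max(ed[p], na.rm = TRUE) else NA_real_
  }, 0)
  data.frame(angle = (breaks[-1] + breaks[-length(breaks)]) / 2 * 180 / pi,
             extent = extent, available = available,
             fraction = extent / available)
}

#' Compare corner and edge-midpoint mesodermal extent
#'
#' Summarizes [corner_expansion_metric()] at given boundary angles:
#' the mean extent over sectors nearest each corner angle versus sectors
#' nearest each midpoint angle.
#'
#' @param metric result of [corner_expansion_metric()].
#' @param corner_angles,midpoint_angles boundary angles in degrees.
#' @param normalize `"auto"` (default) compares raw extents when the
#'   corner and midpoint sectors offer similar maximum depth, and switches
#'   to extent fractions of the locally available depth when the geometry
#'   makes the depths unequal (e.g. the shallow mouth sectors of a pacman,
#'   where a raw comparison would be meaningless). `TRUE`/`FALSE` force
#'   fractions or raw extents.
#' @return list with `corner`, `midpoint` (mean extents), `ratio` and
#'   `normalized` (whether fractions were used).
#' @export
corner_vs_midpoint <- function(metric, corner_angles, midpoint_angles,
                               normalize = "auto") {
  nearest <- function(a, col) {
    d <- abs((metric$angle - a + 180) %% 360 - 180)
    metric[[col]][order(d)[1:2]]
  }
  pool <- function(angles, col)
    mean(unlist(lapply(angles, nearest, col = col)), na.rm = TRUE)
  if (identical(normalize, "auto")) {
    av_c <- pool(corner_angles, "available")
    av_m <- pool(midpoint_angles, "available")
    normalize <- abs(av_c - av_m) / max(av_c, av_m) > 0.15
  }
  col <- if (isTRUE(normalize)) "fraction" else "extent"
  corner <- pool(corner_angles, col)
  midpoint <- pool(midpoint_angles, col)
  list(corner = corner, midpoint = midpoint, ratio = corner / midpoint,
       normalized = isTRUE(normalize))
}
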