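#' Parameters of the activator-inhibitor reaction-diffusion model
#'
#' The generic two-species model used to ask whether an inward-moving
#' signaling wave can be the relaxation of a Turing (diffusion-driven)
#' instability. Reaction terms (per time step, inside the colony):
#' \deqn{\partial_t A = D_A \nabla^2 A + s_A A^2 / (k_I I (1 + \kappa_A A^2)) + k_A - kd_A A}
#' \deqn{\partial_t I = D_I \nabla^2 I + s_I A^2 - kd_I I}
#' Outside the colony production is zero and both species degrade at
#' `kd_out`; diffusion acts on the full lattice with periodic boundaries.
#' Units follow the lattice convention: diffusivities in px^2/step,
#' rates per step.
#'
#' @param D_A,D_I activator and inhibitor diffusivities (px^2/step).
#' @param s_A,s_I production rate constants.
#' @param k_I inhibitor coupling constant in the activator production.
#' @param k_A basal activator production.
#' @param kd_A,kd_I degradation rates inside the colony.
#' @param kappa_A activator saturation constant (0 disables saturation;
#'   positive values give stripe-forming rather than spot-forming patterns).
#' @param kd_out degradation rate outside the colony.
#' @param i_floor numerical floor for the inhibitor in the activator
#'   production denominator, so that inhibitor-free initial conditions stay
#'   finite.
#' @return a named list of class `rd_params`.
#' @export
rd_params <- function(D_A = 0.0025, D_I = 0.4, s_A = 0.01, s_I = 0.01,
                      k_I = 1, k_A = 0, kd_A = 0.001, kd_I = 0.008,
                      kappa_A = 0, kd_out = 0.01, i_floor = 1e-3) {
  p <- list(D_A = D_A, D_I = D_I, s_A = s_A, s_I = s_I, k_I = k_I,
            k_A = k_A, kd_A = kd_A, kd_I = kd_I, kappa_A = kappa_A,
            kd_out = kd_out, i_floor = i_floor)
  if (any(unlist(p) < 0)) stop("all rd_params fields must be non-negative")
  if (k_I <= 0) stop("k_I must be positive")
  structure(p, class = c("rd_params", "list"))
}

#' Stripe-forming parameter set
#'
#' Saturated activator production (`kappa_A = 0.25`) turns the spot-forming
#' Turing pattern into labyrinthine stripes; strong degradation outside the
#' colony sharpens the boundary.
#' @export
rd_params_stripes <- function() {
  rd_params(D_A = 0.005, D_I = 0.2, s_A = 0.1, s_I = 0.2,
            kd_A = 0.1, kd_I = 0.2, kappa_A = 0.25, kd_out = 0.5)
}

#' Initial condition for the activator-inhibitor model
#'
#' @param mode `"random_uniform"` (independent U(0, amplitude) noise in both
#'   species over the whole lattice), `"edge_high"` (activator at `amplitude`
#'   on the 2-pixel rim of the colony, inhibitor zero; the position at which
#'   signaling initiates experimentally), or `"zero"`.
#' @param amplitude initial field amplitude.
#' @param seed integer; fully determines the random field.
#' @return a list of class `rd_init`.
#' @export
rd_init <- function(mode = c("random_uniform", "edge_high", "zero"),
                    amplitude = 1, seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, amplitude = amplitude, seed = as.integer(seed)),
            class = c("rd_init", "list"))
}

init_fields <- function(init, mask) {
  g <- mask$grid
  H <- nrow(g); W <- ncol(g)
  zero <- matrix(0, H, W)
  switch(init$mode,
    zero = list(A = zero, I = zero),
    random_uniform = {
      rs <- local_rng(init$seed)
      A <- matrix(rs(H * W) * init$amplitude, H, W)
      I <- matrix(rs(H * W) * init$amplitude, H, W)
      list(A = A, I = I)
    },
    edge_high = {
      d <- edge_distance_px(g)
      A <- zero
      A[!is.na(d) & d < 2] <- init$amplitude
      list(A = A, I = zero)
    })
}

# uniform deviates from a private RNG stream that never disturbs the
# session RNG state
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    x <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    x
  }
}

#' Default explicit-Euler time step
#'
#' `0.8 * dx^2 / (4 * max(D_A, D_I))`: the 2D forward-Euler diffusion
#' stability bound with a 20% safety margin.
#' @param params an [rd_params()] object.
#' @param dx lattice spacing (px).
#' @export
rd_default_dt <- function(params, dx = 1) {
  0.8 * dx^2 / (4 * max(params$D_A, params$D_I))
}

#' Advance the activator-inhibitor fields
#'
#' One (or several) forward-Euler steps with a 5-point periodic Laplacian.
#' Production is confined to the colony; degradation acts everywhere
#' (`kd_out` outside). Negative concentrations are clamped to zero.
#'
#' @param state list with matrices `A`, `I` and time `t`.
#' @param params an [rd_params()] object.
#' @param mask a [make_mask()] object.
#' @param dt time step; must satisfy the explicit stability bound.
#' @param n_steps number of steps to take.
#' @return updated state (class `field_state`).
#' @export
rd_step <- function(state, params, mask, dt = rd_default_dt(params),
                    n_steps = 1L) {
  res <- rd_run_cpp(state$A, state$I, mask$grid, params, dt, as.integer(n_steps))
  if (res$diverged)
    stop(sprintf("reaction-diffusion step diverged after %d steps (max |A| = %.3g, max |I| = %.3g); reduce dt",
                 res$steps_done, max(abs(res$A)), max(abs(res$I))))
  structure(list(A = res$A, I = res$I, t = state$t + res$steps_done * dt,
                 max_rel_change = res$max_rel_change),
            class = c("field_state", "list"))
}

#' Simulate the activator-inhibitor model
#'
#' Runs the masked-lattice simulation from a seeded initial condition,
#' saving snapshots every `save_every` steps and reporting whether a steady
#' state (max relative change per step below `steady_tol`) was reached.
#'
#' @inheritParams rd_step
#' @param init an [rd_init()] object.
#' @param n_steps total number of Euler steps.
#' @param save_every snapshot interval in steps.
#' @param steady_tol per-step relative-change threshold declaring steady
#'   state.
#' @param stop_at_steady if TRUE, return as soon as steady state is
#'   detected.
#' @return object of class `rd_sim`: list with `snapshots` (list of field
#'   states), `times` (in steps), `steady`, `dt`, `params`, `mask`.
#' @export
simulate_rd <- function(params, mask, init, n_steps = 20000L,
                        save_every = 1000L, dt = rd_default_dt(params),
                        steady_tol = 1e-6, stop_at_steady = TRUE) {
  st <- c(init_fields(init, mask), list(t = 0))
  class(st) <- c("field_state", "list")
  snaps <- list(st)
  times <- 0
  steady <- FALSE
  done <- 0L
  while (done < n_steps) {
    k <- min(save_every, n_steps - done)
    st <- rd_step(st, params, mask, dt, k)
    done <- done + k
    snaps[[length(snaps) + 1L]] <- st
    times <- c(times, done)
    if (is.finite(st$max_rel_change) && st$max_rel_change < steady_tol) {
      steady <- TRUE
      if (stop_at_steady) break
    }
  }
  structure(list(snapshots = snaps, times = times, steady = steady,
                 dt = dt, params = params, mask = mask),
            class = c("rd_sim", "list"))
}

#' @export
print.rd_sim <- function(x, ...) {
  last <- x$snapshots[[length(x$snapshots)]]
  cat(sprintf("<rd_sim> %d snapshots to step %g (t = %g), steady = %s, max A = %.4g\n",
              length(x$snapshots), max(x$times), last$t, x$steady, max(last$A)))
  invisible(x)
}

#' Dominant wavelength of a periodic-lattice pattern
#'
#' Peak of the radially averaged power spectrum of the mean-subtracted
#' field, in pixels per cycle. Used to compare simulated Turing patterns
#' with the critical wavelength predicted by linear stability analysis.
#'
#' @param field numeric matrix on a periodic lattice (no mask).
#' @return list with `wavelength` (px), `frequency` (cycles/px) and the
#'   binned spectrum (`freq`, `power`).
#' @export
dominant_wavelength <- function(field) {
  f <- field - mean(field)
  P <- Mod(stats::fft(f))^2
  H <- nrow(f); W <- ncol(f)
  ki <- c(0:(H %/% 2), -((H - H %/% 2 - 1):1)) / H
  kj <- c(0:(W %/% 2), -((W - W %/% 2 - 1):1)) / W
  kk <- sqrt(outer(ki^2, kj^2, "+"))
  nb <- floor(min(H, W) / 2)
  bins <- seq(0, 0.5 + 1e-9, length.out = nb + 1)
  idx <- findInterval(kk, bins, rightmost.closed = TRUE)
  pw <- tapply(as.vector(P), as.vector(idx), sum)
  freq <- (bins[-1] + bins[-length(bins)]) / 2
  power <- rep(0, nb)
  ib <- as.integer(names(pw))
  keep <- ib >= 1 & ib <= nb
  power[ib[keep]] <- pw[keep]
  power[1] <- 0  # drop the near-DC bin
  pk <- which.max(power)
  # power-weighted centroid over the contiguous band around the peak:
  # robust against the coarse radial-frequency quantization at long
  # wavelengths on small lattices
  in_band <- power >= 0.3 * power[pk]
  runs <- split(which(in_band), cumsum(c(1, diff(which(in_band)) != 1)))
  band <- runs[[which(vapply(runs, function(r) pk %in% r, TRUE))]]
  f_hat <- sum(freq[band] * power[band]) / sum(power[band])
  list(wavelength = 1 / f_hat, frequency = f_hat,
       freq = freq, power = power)
}

#' Spot versus stripe morphology of a thresholded pattern
#'
#' Labels the connected components of `field > threshold` and returns their
#' area-weighted mean eccentricity. Isotropic spots give low values;
#' labyrinthine stripes give elongated, high-eccentricity components.
#'
#' @param field numeric matrix.
#' @param threshold threshold; default half of the field maximum.
#' @return list with `n_components`, `eccentricity` (area-weighted mean),
#'   and `areas`.
#' @export
pattern_morphology <- function(field, threshold = max(field) / 2) {
  bw <- matrix(as.numeric(field > threshold), nrow(field))
  lab <- EBImage::bwlabel(bw)
  n <- max(lab)
  if (n == 0)
    return(list(n_components = 0L, eccentricity = NA_real_, areas = numeric()))
  mom <- EBImage::computeFeatures.moment(lab)
  shp <- EBImage::computeFeatures.shape(lab)
  areas <- shp[, "s.area"]
  ecc <- sum(mom[, "m.eccentricity"] * areas) / sum(areas)
  list(n_components = as.integer(n), eccentricity = ecc, areas = areas)
}

#' Local maxima count of a smoothed field inside a mask
#'
#' Counts interior local maxima of the activator field (3x3 neighbourhood,
#' after light smoothing) -- a simple readout for multi-spot steady states.
#' @param field numeric matrix.
#' @param mask optional [make_mask()] object restricting the count.
#' @param min_height minimum height relative to the field maximum.
#' @export
count_local_maxima <- function(field, mask = NULL, min_height = 0.3) {
  k <- matrix(1 / 9, 3, 3)
  sm <- as.matrix(EBImage::filter2(field, k))
  H <- nrow(sm); W <- ncol(sm)
  is_max <- matrix(FALSE, H, W)
  core <- sm[2:(H - 1), 2:(W - 1)]
  nb <- list(sm[1:(H - 2), 2:(W - 1)], sm[3:H, 2:(W - 1)],
             sm[2:(H - 1), 1:(W - 2)], sm[2:(H - 1), 3:W],
             sm[1:(H - 2), 1:(W - 2)], sm[1:(H - 2), 3:W],
             sm[3:H, 1:(W - 2)], sm[3:H, 3:W])
  ok <- Reduce("&", lapply(nb, function(m) core > m))
  is_max[2:(H - 1), 2:(W - 1)] <- ok & core > min_height * max(sm)
  if (!is.null(mask)) is_max <- is_max & mask$grid
  sum(is_max)
}

#' Write simulation snapshots as a multi-page TIFF plus CSV manifest
#'
#' @param sim an [simulate_rd()] result.
#' @param field which field to write, `"A"` or `"I"`.
#' @param path output TIFF path; the manifest goes to `<path>.csv`.
#' @export
write_rd_snapshots <- function(sim, field = c("A", "I"), path) {
  field <- match.arg(field)
  imgs <- lapply(sim$snapshots, `[[`, field)
  mx <- max(1e-12, vapply(imgs, max, 0))
  tiff::writeTIFF(lapply(imgs, function(m) m / mx), path, bits.per.sample = 16L)
  man <- data.frame(step = sim$times,
                    t = sim$times * sim$dt,
                    max = vapply(imgs, max, 0),
                    mean = vapply(imgs, mean, 0))
  utils::write.csv(man, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
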