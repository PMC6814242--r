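#' Parameters of the BMP-driven WNT/NODAL cascade model
#'
#' Three-component model of the signaling cascade that patterns
#' micropatterned gastruloids: an imposed BMP input `b(x, t)` drives a
#' reaction-diffusion system in WNT signaling `u` and NODAL signaling `v`:
#' \deqn{\partial_t u = D_u \nabla^2 u + \beta_u + \alpha_b b + \alpha_u u^2/(K_u^2+u^2) - \gamma_u u}
#' \deqn{\partial_t v = D_v \nabla^2 v + \alpha_w u + \alpha_v [v \ge v_{th}] v^2/(K_v^2+v^2) - \gamma_v v}
#' Production terms act only inside the colony; degradation acts
#' everywhere, with a faster clearance (`gamma_out_*`) outside the colony
#' representing dilution into the bulk medium. NODAL autoactivates only
#' above the threshold `v_th`, which makes its inward wave self-propagating
#' once initiated by WNT. WNT autoactivation is kept subcritical: the wave
#' of WNT activity is carried by transport of ligand produced near the
#' colony edge, with autoactivation amplifying (not regenerating) it --
#' which is why blocking WNT secretion lowers levels but leaves the spatial
#' dynamics intact, as observed.
#'
#' Units: hours and micrometres. Defaults were calibrated once on the
#' 700-um circular colony to reproduce the observed control dynamics (a
#' steadily advancing inward WNT front over hours 24-46, a ring-shaped WNT
#' maximum near the edge, NODAL activation of the whole interior initiated
#' around hour 20) and are then used unchanged for every perturbation and
#' geometry.
#'
#' @param D_u,D_v diffusivities (um^2/h).
#' @param beta_u basal WNT production.
#' @param alpha_b BMP-to-WNT coupling.
#' @param alpha_u,K_u WNT autoactivation strength and half-saturation.
#' @param alpha_w WNT-to-NODAL coupling.
#' @param alpha_v,K_v NODAL autoactivation strength and half-saturation.
#' @param v_th NODAL autoactivation threshold.
#' @param gamma_u,gamma_v degradation rates inside the colony (per hour).
#' @param gamma_out_u,gamma_out_v clearance rates outside the colony.
#' @return a named list of class `cascade_params`.
#' @export
cascade_params <- function(D_u = 400, D_v = 1000,
                           beta_u = 5e-5, alpha_b = 0.1,
                           alpha_u = 0.005, K_u = 0.8,
                           alpha_w = 0.7, alpha_v = 0.5, K_v = 0.5,
                           v_th = 0.32, gamma_u = 0.02, gamma_v = 0.35,
                           gamma_out_u = 0.3, gamma_out_v = 6) {
  p <- list(D_u = D_u, D_v = D_v, beta_u = beta_u, alpha_b = alpha_b,
            alpha_u = alpha_u, K_u = K_u, alpha_w = alpha_w,
            alpha_v = alpha_v, K_v = K_v, v_th = v_th,
            gamma_u = gamma_u, gamma_v = gamma_v,
            gamma_out_u = gamma_out_u, gamma_out_v = gamma_out_v)
  if (any(unlist(p) < 0)) stop("all cascade_params fields must be non-negative")
  structure(p, class = c("cascade_params", "list"))
}

#' Imposed BMP signaling input
#'
#' Parametric stand-in for the measured BMP signaling dynamics: uniform
#' activity at `uniform_level * amplitude` across the colony until
#' `t_restrict`, then restriction to the colony edge as
#' `amplitude * exp(-dist_edge / edge_width)`. The restricted edge domain
#' signals at a higher level than the early uniform phase
#' (`uniform_level < 1`), reflecting the concentration of BMP activity at
#' the edge after receptor relocalization and inhibitor up-regulation.
#'
#' @param amplitude peak BMP signaling level at the restricted edge
#'   (arbitrary units).
#' @param t_restrict hour at which signaling becomes edge-restricted
#'   (default 12 h).
#' @param edge_width exponential width of the restricted edge domain (um).
#' @param uniform_level early uniform activity as a fraction of
#'   `amplitude` (default 0.15).
#' @return a list of class `bmp_input`.
#' @export
bmp_input <- function(amplitude = 1, t_restrict = 12, edge_width = 40,
                      uniform_level = 0.15) {
  stopifnot(amplitude >= 0, t_restrict >= 0, edge_width > 0,
            uniform_level >= 0, uniform_level <= 1)
  structure(list(amplitude = amplitude, t_restrict = t_restrict,
                 edge_width = edge_width, uniform_level = uniform_level),
            class = c("bmp_input", "list"))
}

#' Evaluate the BMP input on a mask at a given time
#'
#' @param bmp a [bmp_input()] object.
#' @param mask a [make_mask()] object.
#' @param t time in hours.
#' @return numeric matrix (0 outside the colony).
#' @export
bmp_field <- function(bmp, mask, t) {
  g <- mask$grid
  out <- matrix(0, nrow(g), ncol(g))
  if (t < bmp$t_restrict) {
    out[g] <- bmp$amplitude * (bmp$uniform_level %||% 1)
  } else {
    d <- edge_distance(mask)$values
    out[g] <- bmp$amplitude * exp(-d[g] / bmp$edge_width)
  }
  out
}

#' A perturbation event for cascade simulations
#'
#' Instantaneous parameter switch at `time` (hours): the named parameters
#' take the given values from `time` onwards. The chemical perturbations of
#' the assay map onto:
#' * LDN (BMP receptor inhibition): `alpha_b = 0`.
#' * IWP2 (WNT secretion inhibition), effect on WNT: `alpha_u = 0`.
#' * IWP2 effect on the NODAL wave: `alpha_u = 0` and `alpha_w = 0`.
#'
#' @param time hour of addition.
#' @param ... named parameter values, e.g. `alpha_b = 0`.
#' @export
perturbation <- function(time, ...) {
  set <- list(...)
  stopifnot(length(set) > 0, !is.null(names(set)), all(nzchar(names(set))))
  list(time = time, set = set)
}

#' @rdname perturbation
#' @export
perturb_ldn <- function(time) perturbation(time, alpha_b = 0)

#' @rdname perturbation
#' @export
perturb_iwp2 <- function(time) perturbation(time, alpha_u = 0)

#' @rdname perturbation
#' @export
perturb_wnt_secretion <- function(time)
  perturbation(time, alpha_u = 0, alpha_w = 0)

#' Simulate the WNT/NODAL cascade on a colony
#'
#' Forward-Euler integration of the cascade equations with periodic
#' boundary conditions on the full lattice and the BMP input held
#' piecewise-constant between its restriction time, perturbation times and
#' snapshot times. Deterministic: the model has no noise source.
#'
#' @param params a [cascade_params()] object.
#' @param mask a [make_mask()] object.
#' @param bmp a [bmp_input()] object.
#' @param t_end final time (hours; default 46, the steady-state readout).
#' @param perturbations list of [perturbation()] events.
#' @param save_every snapshot interval in hours.
#' @param dt Euler step (hours); default 80% of the diffusion stability
#'   bound, capped at 0.02 h to resolve the reactions.
#' @param init optional list with matrices `u` and/or `v` as initial
#'   fields (default: both zero).
#' @return object of class `cascade_sim`: list with `snapshots` (each
#'   holding `u`, `v`, `b`, `t`), `times`, `params`, `mask`, `bmp`.
#' @export
simulate_cascade <- function(params, mask, bmp = bmp_input(), t_end = 46,
                             perturbations = list(), save_every = 1,
                             dt = NULL, init = NULL) {
  dx2 <- mask$pixel_size^2
  if (is.null(dt))
    dt <- min(0.8 * dx2 / (4 * max(params$D_u, params$D_v)), 0.02)
  stopifnot(dt > 0, t_end > 0)
  if (length(perturbations) && any(vapply(perturbations, `[[`, 0, "time") > t_end))
    stop("perturbation times must lie within [0, t_end]")

  save_times <- seq(0, t_end, by = save_every)
  if (save_times[length(save_times)] < t_end)
    save_times <- c(save_times, t_end)
  events <- sort(unique(c(save_times, bmp$t_restrict,
                          vapply(perturbations, `[[`, 0, "time"))))
  events <- events[events > 0 & events <= t_end]

  g <- mask$grid
  u <- init$u %||% matrix(0, nrow(g), ncol(g))
  v <- init$v %||% matrix(0, nrow(g), ncol(g))
  stopifnot(all(dim(u) == dim(g)), all(dim(v) == dim(g)))
  p <- params
  t_now <- 0
  snaps <- list(list(u = u, v = v, b = bmp_field(bmp, mask, 0), t = 0))
  times <- 0

  for (te in events) {
    # apply switches scheduled at or before the start of this interval
    for (pe in perturbations)
      if (pe$time <= t_now + 1e-9)
        p[names(pe$set)] <- pe$set
    b <- bmp_field(bmp, mask, t_now)
    n <- max(1L, round((te - t_now) / dt))
    res <- cascade_run_cpp(u, v, b, g, p, dx2, (te - t_now) / n, n)
    if (res$diverged)
      stop(sprintf("cascade simulation diverged near t = %.2f h; reduce dt", t_now))
    u <- res$u; v <- res$v; t_now <- te
    if (any(abs(save_times - te) < 1e-9)) {
      snaps[[length(snaps) + 1L]] <- list(u = u, v = v,
                                          b = bmp_field(bmp, mask, te), t = te)
      times <- c(times, te)
    }
  }
  structure(list(snapshots = snaps, times = times, params = params,
                 mask = mask, bmp = bmp, perturbations = perturbations),
            class = c("cascade_sim", "list"))
}

#' Simulated WNT-secretion block acting on the NODAL wave
#'
#' Convenience wrapper: switches off both WNT autoactivation and the
#' WNT-to-NODAL coupling at `t_block`. Applied before the NODAL wave has
#' initiated this keeps NODAL edge-restricted; applied after initiation the
#' wave completes on its own -- the binary early/late phenotype.
#'
#' @inheritParams simulate_cascade
#' @param t_block hour of the block.
#' @export
simulate_cascade_nodal_block <- function(params, mask, bmp = bmp_input(),
                                         t_block, t_end = 46, ...) {
  simulate_cascade(params, mask, bmp, t_end = t_end,
                   perturbations = list(perturb_wnt_secretion(t_block)), ...)
}

#' @export
print.cascade_sim <- function(x, ...) {
  last <- x$snapshots[[length(x$snapshots)]]
  cat(sprintf("<cascade_sim> %d snapshots to t = %g h; max u = %.3g, max v = %.3g\n",
              length(x$snapshots), max(x$times), max(last$u), max(last$v)))
  invisible(x)
}

#' Radial profile series of a simulated field
#'
#' Bins each saved snapshot of `u`, `v` or `b` by distance from the colony
#' edge, producing the same profile-series structure used to quantify
#' imaging data, so wave fronts of simulations and experiments are tracked
#' by the same code.
#'
#' @param sim a [simulate_cascade()] or [simulate_rd()] result.
#' @param field `"u"`, `"v"`, `"b"` for cascade runs; `"A"`, `"I"` for
#'   activator-inhibitor runs.
#' @param bin_width radial bin width (um).
#' @return a `profile_series` object (see [profile_series()]).
#' @export
sim_profile_series <- function(sim, field = "u", bin_width = 10) {
  eb <- edge_bins(sim$mask, bin_width)
  idx <- eb$index[sim$mask$grid]
  is_cascade <- inherits(sim, "cascade_sim")
  times <- if (is_cascade) sim$times else sim$times * sim$dt
  profs <- lapply(sim$snapshots, function(s) {
    vals <- s[[field]][sim$mask$grid]
    as.numeric(tapply(vals, factor(idx, levels = seq_len(eb$n_bins)), mean))
  })
  profile_series(times = times, centers = eb$centers,
                 values = do.call(rbind, profs))
}
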