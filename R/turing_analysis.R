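# Reaction terms of the well-mixed activator-inhibitor system and their
# analytic Jacobian. Shared by the steady-state solver, the dispersion
# relation and the regime classifier.

rd_reactions <- function(A, I, p) {
  denom <- p$k_I * pmax(I, p$i_floor) * (1 + p$kappa_A * A^2)
  c(f = p$s_A * A^2 / denom + p$k_A - p$kd_A * A,
    g = p$s_I * A^2 - p$kd_I * I)
}

rd_jacobian_analytic <- function(A, I, p) {
  sat <- 1 + p$kappa_A * A^2
  f_A <- p$s_A * 2 * A / (p$k_I * I * sat^2) - p$kd_A
  f_I <- -p$s_A * A^2 / (p$k_I * I^2 * sat)
  g_A <- 2 * p$s_I * A
  g_I <- -p$kd_I
  matrix(c(f_A, g_A, f_I, g_I), 2, 2,
         dimnames = list(c("A", "I"), c("A", "I")))
}

rd_jacobian_numeric <- function(A, I, p) {
  h <- 1e-6 * max(abs(c(A, I)), 1)
  J <- matrix(0, 2, 2, dimnames = list(c("A", "I"), c("A", "I")))
  J[, 1] <- (rd_reactions(A + h, I, p) - rd_reactions(A - h, I, p)) / (2 * h)
  J[, 2] <- (rd_reactions(A, I + h, p) - rd_reactions(A, I - h, p)) / (2 * h)
  J
}

#' Homogeneous positive steady state of the activator-inhibitor system
#'
#' Eliminates the inhibitor through its nullcline (`I = s_I A^2 / kd_I`),
#' leaving a single monotone equation in the activator which is bracketed
#' and solved by `uniroot`. With all production terms zero the fixed point
#' is the origin.
#'
#' @param params an [rd_params()] object.
#' @param tol residual tolerance on the reaction terms.
#' @return list with `A`, `I`, `residual`, and `found` (FALSE when no
#'   positive fixed point exists, in which case Turing classification is
#'   not applicable).
#' @export
find_steady_state <- function(params, tol = 1e-9) {
  p <- params
  if (p$s_A == 0 && p$k_A == 0)
    return(list(A = 0, I = 0, residual = 0, found = TRUE))
  if (p$kd_A == 0 || p$kd_I == 0)
    return(list(A = NA_real_, I = NA_real_, residual = NA_real_, found = FALSE))
  # residual of the activator equation on the inhibitor nullcline;
  # strictly decreasing in A for A > 0
  resid <- function(A)
    p$s_A * p$kd_I / (p$k_I * p$s_I * (1 + p$kappa_A * A^2)) + p$k_A - p$kd_A * A
  if (p$s_I == 0) # inhibitor decays away: unbounded autocatalysis, no positive fixed point
    return(list(A = NA_real_, I = NA_real_, residual = NA_real_, found = FALSE))
  hi <- 1
  while (resid(hi) > 0 && hi < 1e12) hi <- hi * 2
  if (resid(hi) > 0)
    return(list(A = NA_real_, I = NA_real_, residual = NA_real_, found = FALSE))
  A <- stats::uniroot(resid, c(0, hi), tol = tol / 10)$root
  I <- p$s_I * A^2 / p$kd_I
  r <- rd_reactions(A, I, p)
  if (A <= 0 || I <= 0 || max(abs(r)) > max(tol, 1e-9 * max(A, I)))
    return(list(A = A, I = I, residual = max(abs(r)), found = FALSE))
  list(A = A, I = I, residual = max(abs(r)), found = TRUE)
}

#' Dispersion relation of the activator-inhibitor system
#'
#' Largest real part of the eigenvalues of `J - diag(D_A, D_I) k^2` as a
#' function of wavenumber `k` (units 1/px), evaluated at the homogeneous
#' steady state. Positive growth at finite `k` with a stable `k = 0` mode
#' is the signature of a diffusion-driven instability.
#'
#' @param params an [rd_params()] object.
#' @param k_values wavenumbers at which to evaluate the growth rate.
#' @return data.frame with columns `k` and `lambda`.
#' @export
dispersion_relation <- function(params, k_values = seq(0, 2, length.out = 401)) {
  ss <- find_steady_state(params)
  if (!ss$found) stop("no positive homogeneous steady state; dispersion relation undefined")
  J <- rd_jacobian_analytic(ss$A, ss$I, params)
  lam <- vapply(k_values, function(k) {
    Jk <- J - diag(c(params$D_A, params$D_I)) * k^2
    max(Re(eigen(Jk, only.values = TRUE)$values))
  }, 0)
  data.frame(k = k_values, lambda = lam)
}

#' Classify a parameter set with respect to the Turing instability
#'
#' Computes the homogeneous steady state, its Jacobian
#' `J = [[f_A, f_I], [g_A, g_I]]`, and the standard two-species conditions:
#' the state must be stable without diffusion (`tr J < 0`, `det J > 0`) and
#' destabilized by diffusion (`D_I f_A + D_A g_I > 2 sqrt(D_A D_I det J)`).
#' When unstable, the critical wavenumber is
#' `k_c^2 = (D_I f_A + D_A g_I) / (2 D_A D_I)` and the pattern wavelength
#' `2 pi / k_c`. Patterns whose wavelength exceeds the colony are flagged:
#' such an instability cannot shape fates within the colony.
#'
#' @param params an [rd_params()] object.
#' @param pixel_size um per pixel used to express the wavelength in um.
#' @param colony_diameter colony diameter in um used for the
#'   `wavelength_exceeds_colony` flag (NA to skip).
#' @return object of class `turing_report`.
#' @export
classify_turing <- function(params, pixel_size = 14, colony_diameter = NA) {
  ss <- find_steady_state(params)
  if (!ss$found) {
    return(structure(list(applicable = FALSE, steady_state = ss,
                          turing_unstable = NA), class = "turing_report"))
  }
  J <- rd_jacobian_analytic(ss$A, ss$I, params)
  Jn <- rd_jacobian_numeric(ss$A, ss$I, params)
  if (max(abs(J - Jn)) > 1e-6 * max(1, max(abs(J))))
    warning("analytic and numerical Jacobians disagree")
  trJ <- sum(diag(J)); detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  stable0 <- trJ < 0 && detJ > 0
  crit <- params$D_I * J[1, 1] + params$D_A * J[2, 2]
  unstable <- stable0 && params$D_A > 0 && params$D_I > 0 &&
    detJ > 0 && crit > 2 * sqrt(params$D_A * params$D_I * detJ)
  k_c <- wavelength <- max_growth <- NA_real_
  if (unstable) {
    k_c <- sqrt(crit / (2 * params$D_A * params$D_I))
    wavelength <- 2 * pi / k_c
    disp <- dispersion_relation(params, seq(0, 3 * k_c, length.out = 601))
    max_growth <- max(disp$lambda[disp$k > 0])
  }
  structure(list(
    applicable = TRUE,
    steady_state = c(A = ss$A, I = ss$I),
    jacobian = J,
    trace = trJ, det = detJ,
    stable_without_diffusion = stable0,
    turing_unstable = unstable,
    k_c = k_c,
    wavelength_px = wavelength,
    wavelength_um = wavelength * pixel_size,
    max_growth_rate = max_growth,
    wavelength_exceeds_colony =
      if (is.na(colony_diameter) || !unstable) NA
      else (wavelength * pixel_size) > colony_diameter
  ), class = "turing_report")
}

#' @export
print.turing_report <- function(x, ...) {
  if (!x$applicable) {
    cat("<turing_report> not applicable: no positive homogeneous steady state\n")
    return(invisible(x))
  }
  cat(sprintf("<turing_report> steady state A* = %.4g, I* = %.4g\n",
              x$steady_state["A"], x$steady_state["I"]))
  cat(sprintf("  stable without diffusion: %s; Turing unstable: %s\n",
              x$stable_without_diffusion, x$turing_unstable))
  if (isTRUE(x$turing_unstable))
    cat(sprintf("  k_c = %.4g /px, wavelength = %.4g px, max growth rate = %.4g\n",
                x$k_c, x$wavelength_px, x$max_growth_rate))
  invisible(x)
}
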