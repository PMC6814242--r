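test_that("printed parameter sets classify as inside/outside the Turing regime", {
  inside <- classify_turing(rd_params(D_A = 0.0025))
  outside <- classify_turing(rd_params(D_A = 0.014))
  expect_true(inside$turing_unstable)
  expect_true(inside$stable_without_diffusion)
  expect_gt(inside$k_c, 0)
  expect_gt(inside$max_growth_rate, 0)
  expect_false(outside$turing_unstable)
  expect_true(outside$stable_without_diffusion)
})

test_that("steady state matches the well-mixed ODE integrated to long times", {
  skip_if_not_installed("deSolve")
  for (p in list(rd_params(), rd_params_stripes())) {
    ss <- find_steady_state(p)
    expect_lt(ss$residual, 1e-9)
    rhs <- function(t, y, parms) {
      r <- gastrudyn:::rd_reactions(unname(y[1]), unname(y[2]), p)
      list(unname(r))
    }
    out <- deSolve::ode(y = c(A = ss$A * 1.5, I = ss$I * 0.5),
                        times = c(0, 1e5), func = rhs, parms = NULL,
                        method = "lsoda")
    expect_equal(unname(out[2, "A"]), ss$A, tolerance = 1e-5)
    expect_equal(unname(out[2, "I"]), ss$I, tolerance = 1e-5)
  }
})

test_that("production-free system has the origin as its fixed point", {
  ss <- find_steady_state(rd_params(s_A = 0, k_A = 0))
  expect_true(ss$found)
  expect_identical(c(ss$A, ss$I), c(0, 0))
})

test_that("dispersion relation has the textbook limits and matches a brute-force maximiser", {
  p <- rd_params(D_A = 0.0025)
  disp <- dispersion_relation(p, k_values = c(0, 0.2, 0.4359, 1, 5, 20))
  expect_lt(disp$lambda[1], 0)                 # stable well-mixed mode
  expect_lt(disp$lambda[6], disp$lambda[2])    # large k strongly damped
  expect_lt(disp$lambda[6], -0.9)  # approaches -(kd_A + D_A k^2)
  rep_ <- classify_turing(p)
  expect_equal(rep_$k_c, brute_force_kc(p), tolerance = 0.05)
  # the fastest-growing mode lies strictly inside the unstable band around
  # the critical wavenumber, with positive growth at k_c itself
  fine <- dispersion_relation(p, seq(0.01, 2, length.out = 400))
  k_star <- fine$k[which.max(fine$lambda)]
  expect_gt(max(fine$lambda), 0)
  expect_gt(dispersion_relation(p, rep_$k_c)$lambda, 0)
  expect_lt(abs(k_star - rep_$k_c), rep_$k_c)  # same band, same scale
})

test_that("analytic Jacobian agrees with central differences", {
  for (p in list(rd_params(), rd_params_stripes(),
                 rd_params(k_A = 0.002, kappa_A = 0.05))) {
    ss <- find_steady_state(p)
    Ja <- gastrudyn:::rd_jacobian_analytic(ss$A, ss$I, p)
    Jn <- gastrudyn:::rd_jacobian_numeric(ss$A, ss$I, p)
    expect_lt(max(abs(Ja - Jn)) / max(abs(Ja)), 1e-5)
  }
})

test_that("classification is invariant under rescaling time units", {
  p <- rd_params(D_A = 0.0025)
  c0 <- classify_turing(p)
  sc <- 3.7
  p2 <- rd_params(D_A = p$D_A * sc, D_I = p$D_I * sc, s_A = p$s_A * sc,
                  s_I = p$s_I * sc, kd_A = p$kd_A * sc, kd_I = p$kd_I * sc,
                  kd_out = p$kd_out * sc)
  c2 <- classify_turing(p2)
  expect_identical(c2$turing_unstable, c0$turing_unstable)
  expect_equal(c2$k_c, c0$k_c, tolerance = 1e-9)
  expect_equal(c2$max_growth_rate, c0$max_growth_rate * sc, tolerance = 1e-6)
})

test_that("equal diffusivities cannot destabilize a stable state", {
  p <- rd_params(D_A = 0.4, D_I = 0.4)
  rep_ <- classify_turing(p)
  expect_true(rep_$stable_without_diffusion)
  expect_false(rep_$turing_unstable)
})

test_that("a pattern wavelength larger than the colony is flagged as irrelevant", {
  rep_ <- classify_turing(rd_params(D_A = 0.0025), pixel_size = 14,
                          colony_diameter = 700)
  # wavelength ~14.4 px ~ 200 um < 700 um colony: not flagged
  expect_false(rep_$wavelength_exceeds_colony)
  rep2 <- classify_turing(rd_params(D_A = 0.0025), pixel_size = 14,
                          colony_diameter = 100)
  expect_true(rep2$wavelength_exceeds_colony)
})

test_that("classification agrees with simulated pattern formation for random draws", {
  base <- rd_params_stripes()
  rng <- local({set.seed(42); function() runif(1, 0.6, 1.6)})
  m <- full_lattice_mask(48)
  n_checked <- 0
  for (i in 1:20) {
    p <- rd_params(D_A = base$D_A * rng(), D_I = base$D_I * rng(),
                   s_A = base$s_A * rng(), s_I = base$s_I * rng(),
                   kd_A = base$kd_A * rng(), kd_I = base$kd_I * rng(),
                   kappa_A = base$kappa_A, kd_out = base$kd_out)
    rep_ <- classify_turing(p)
    if (!rep_$applicable || !rep_$stable_without_diffusion) next
    # skip near-marginal draws where a finite-time simulation cannot
    # decide (growth or decay of the fastest mode too slow to resolve)
    peak <- max(dispersion_relation(p, seq(0.05, 4, length.out = 200))$lambda)
    if (abs(peak) < 5e-3) next
    # linear stability concerns small perturbations of the homogeneous
    # state, so seed 5% noise around it (large kicks can excite
    # subcritical finite-amplitude patterns outside the linear band)
    ss <- find_steady_state(p)
    rs <- local({set.seed(100 + i); NULL})
    noise <- function() matrix(runif(48 * 48, -0.05, 0.05), 48, 48)
    st <- structure(list(A = ss$A * (1 + noise()), I = ss$I * (1 + noise()),
                         t = 0), class = c("field_state", "list"))
    A <- rd_step(st, p, m, n_steps = 4000L)$A
    patterned <- stats::sd(A) / mean(A) > 0.1
    expect_identical(patterned, isTRUE(rep_$turing_unstable),
                     label = sprintf("draw %d (growth %.3g)", i,
                                     rep_$max_growth_rate))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 8)
})
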