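# Plain-R nested-loop reference implementations, kept deliberately naive
# and independent of the compiled steppers.

naive_rd_step <- function(A, I, grid, p, dt) {
  H <- nrow(A); W <- ncol(A)
  An <- A; In <- I
  for (i in seq_len(H)) {
    up <- if (i == 1) H else i - 1
    dn <- if (i == H) 1 else i + 1
    for (j in seq_len(W)) {
      lf <- if (j == 1) W else j - 1
      rt <- if (j == W) 1 else j + 1
      lapA <- A[up, j] + A[dn, j] + A[i, lf] + A[i, rt] - 4 * A[i, j]
      lapI <- I[up, j] + I[dn, j] + I[i, lf] + I[i, rt] - 4 * I[i, j]
      if (grid[i, j]) {
        denom <- p$k_I * max(I[i, j], p$i_floor) * (1 + p$kappa_A * A[i, j]^2)
        pa <- p$s_A * A[i, j]^2 / denom + p$k_A
        pi_ <- p$s_I * A[i, j]^2
        ka <- p$kd_A; ki <- p$kd_I
      } else {
        pa <- 0; pi_ <- 0; ka <- p$kd_out; ki <- p$kd_out
      }
      An[i, j] <- max(0, A[i, j] + dt * (p$D_A * lapA + pa - ka * A[i, j]))
      In[i, j] <- max(0, I[i, j] + dt * (p$D_I * lapI + pi_ - ki * I[i, j]))
    }
  }
  list(A = An, I = In)
}

# brute-force grid search for the most unstable wavenumber of the
# two-species dispersion polynomial h(k^2)
brute_force_kc <- function(params) {
  ss <- gastrudyn::find_steady_state(params)
  J <- gastrudyn:::rd_jacobian_numeric(ss$A, ss$I, params)
  detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  k2 <- seq(1e-4, 20, length.out = 20001)
  h <- params$D_A * params$D_I * k2^2 -
    (params$D_I * J[1, 1] + params$D_A * J[2, 2]) * k2 + detJ
  sqrt(k2[which.min(h)])
}

expect_rel <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual - expected) / abs(expected), tol)
}

flat_det <- function(...) {
  # hand-built DE table rows for boundary-case checks
  df <- data.frame(...)
  df$log2_fc <- log2(df$fold_change)
  df$direction <- ifelse(df$fold_change >= 1, "up", "down")
  class(df) <- c("de_table", "data.frame")
  df
}

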