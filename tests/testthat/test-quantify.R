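test_that("constant marker over constant DAPI gives a flat ratio profile", {
  m <- quant_mask()
  H <- nrow(m$grid)
  nuc <- m$grid
  prof <- nuclear_radial_profile(matrix(3, H, H), matrix(1.5, H, H), nuc, m,
                                 local_radius = 120, bin_width = 20)
  expect_true(all(abs(prof$mean - 2) < 1e-9, na.rm = TRUE))
  expect_identical(prof$n_colonies, 1L)
  # ratio normalization: scaling both channels cancels
  prof2 <- nuclear_radial_profile(matrix(3, H, H) * 7, matrix(1.5, H, H) * 7,
                                  nuc, m, bin_width = 20)
  expect_equal(prof2$mean, prof$mean)
})

test_that("the 120-um local average smooths a checkerboard to its mean", {
  m <- quant_mask()
  H <- nrow(m$grid)
  chk <- outer(1:H, 1:H, function(i, j) (i + j) %% 2) * 2  # values 0/2, mean 1
  prof <- nuclear_radial_profile(chk, matrix(1, H, H), m$grid, m,
                                 local_radius = 120, bin_width = 20)
  inner <- prof$mean[prof$centers > 100]
  expect_true(all(abs(inner - 1) < 0.05, na.rm = TRUE))
})

test_that("a planted ring is recovered in the correct radial band", {
  m <- quant_mask()
  img <- gen_colony_images(m, recipes = list(
    BRA = function(d) exp(-((d - 120) / 30)^2)), nuclear_density = 5e-3,
    nuclear_radius = 8, seed = 4)
  # a small local-averaging radius keeps the planted ring sharp on this
  # 400-um test colony (the 120-um default is sized for 700-um colonies)
  prof <- nuclear_radial_profile(img$images$BRA, img$images$DAPI,
                                 img$nuclear_mask, m, local_radius = 30,
                                 bin_width = 20)
  expect_lt(abs(prof$centers[which.max(prof$mean)] - 120), 21)
})

test_that("membrane pixels are excluded from non-membrane profiles", {
  m <- quant_mask()
  H <- nrow(m$grid)
  mem <- m$grid & (matrix(1:H, H, H) %% 5 == 0)
  img <- matrix(2, H, H)
  img[mem] <- 20  # membrane 10x brighter
  prof <- nonmembrane_profile(img, mem, m, bin_width = 20)
  expect_true(all(abs(prof$mean - 2) < 1e-9, na.rm = TRUE))
  # an empty membrane mask means a plain whole-colony profile, so the
  # bright membrane rows now contribute
  prof0 <- nonmembrane_profile(img, matrix(FALSE, H, H), m, bin_width = 20)
  expect_false(anyNA(prof0$mean))
  expect_true(any(prof0$mean > 2.5))
  expect_error(nonmembrane_profile(img, m$grid, m), "whole colony")
})

test_that("wave tracking recovers planted front speeds within 5%", {
  for (speed in c(3, 6.02, 9)) {
    gw <- gen_wave_series(times = seq(24, 44, by = 1), speed = speed,
                          bin_width = 5)
    wt <- track_wave(gw$series)
    expect_rel(wt$fit$slope, speed, 0.05)
    expect_gt(wt$fit$r_squared, 0.98)
    expect_true(all(wt$back <= wt$front, na.rm = TRUE))
  }
  # intensity scale invariance: scaling profiles scales the threshold with them
  gw1 <- gen_wave_series(speed = 6, amplitude = 1)
  gw2 <- gen_wave_series(speed = 6, amplitude = 10)
  expect_equal(track_wave(gw1$series)$fit$slope,
               track_wave(gw2$series)$fit$slope, tolerance = 1e-9)
})

test_that("a stationary profile yields zero slope by convention", {
  gw <- gen_wave_series(speed = 0, times = seq(0, 10, 1))
  wt <- track_wave(gw$series)
  expect_true(is.na(wt$fit$slope) || abs(wt$fit$slope) < 0.3)
  # never-active series gives an empty track
  flat <- profile_series(0:5, c(5, 15, 25), matrix(0, 6, 3))
  wt0 <- track_wave(flat)
  expect_true(all(is.na(wt0$front)))
})

test_that("track statistics: stationary, rotating and drifting cells", {
  # stationary
  tr <- data.frame(track_id = 1, t = c(0, 1), x = c(50, 50), y = c(20, 20))
  st <- track_stats(tr, colony_center = c(0, 0))
  expect_identical(st$cells$displacement, 0)
  expect_identical(st$cells$radial_displacement, 0)
  # pure rotation at radius r
  r <- 100; th <- 0.3
  tr2 <- data.frame(track_id = 1, t = c(0, 1),
                    x = c(r, r * cos(th)), y = c(0, r * sin(th)))
  st2 <- track_stats(tr2, colony_center = c(0, 0))
  expect_lt(abs(st2$cells$radial_displacement), 1e-9)
  expect_equal(st2$cells$arc_displacement, r * th, tolerance = 1e-9)
  # single-point tracks are excluded and counted
  tr3 <- rbind(tr, data.frame(track_id = 2, t = 0, x = 1, y = 1))
  expect_identical(track_stats(tr3, c(0, 0))$n_excluded, 1L)
})

test_that("planted inward drift is recovered by the track statistics", {
  m <- quant_mask()
  gt <- gen_tracks(m, n_cells = 60, radial_drift = -10, seed = 5)
  st <- track_stats(gt$tracks, colony_center = gt$truth$center)
  expect_equal(unname(st$summary["mean_radial_displacement"]), -10,
               tolerance = 0.05)
})

test_that("similarity index: sorted populations score 1, mixtures match a Monte-Carlo oracle", {
  # all same label
  pos <- cbind(runif(30, 0, 100), runif(30, 0, 100))
  expect_identical(similarity_index(pos, rep("a", 30))$index, 1)
  # two segregated blocks far apart
  posb <- rbind(cbind(runif(40, 0, 100), runif(40, 0, 100)),
                cbind(runif(40, 500, 600), runif(40, 0, 100)))
  lab <- rep(c("a", "b"), each = 40)
  expect_identical(similarity_index(posb, lab)$index, 1)
  # permutation and rotation invariance
  perm <- sample(80)
  expect_identical(similarity_index(posb[perm, ], lab[perm])$index, 1)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_identical(similarity_index(posb %*% R, lab)$index, 1)
  # well-mixed labels on a dense grid: counting fraction matches a
  # Monte-Carlo estimate computed with an independent brute-force loop
  set.seed(8)
  g <- as.matrix(expand.grid(x = seq(0, 300, 20), y = seq(0, 300, 20)))
  reps <- replicate(40, {
    labs <- sample(c("a", "b"), nrow(g), replace = TRUE, prob = c(0.3, 0.7))
    got <- similarity_index(g, labs)$index
    # brute force oracle
    cnt <- 0; tot <- 0
    for (i in seq_len(nrow(g))) {
      d <- sqrt((g[, 1] - g[i, 1])^2 + (g[, 2] - g[i, 2])^2)
      nb <- which(d > 0 & d <= 62)
      if (!length(nb)) next
      tot <- tot + 1
      if (mean(labs[nb] == labs[i]) > 0.6) cnt <- cnt + 1
    }
    c(got = got, oracle = cnt / tot)
  })
  expect_equal(unname(reps["got", ]), unname(reps["oracle", ]))
  # all isolated cells: undefined
  iso <- similarity_index(rbind(c(0, 0), c(1000, 1000)), c("a", "b"))
  expect_true(is.na(iso$index))
})
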