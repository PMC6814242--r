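# Seeded-RNG helpers: generators draw from a private stream so that a
# (spec, seed) pair always produces identical output without disturbing
# the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv())
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-component seed from a top-level seed
#'
#' Counter-based fan-out: independent streams for sub-generators while one
#' integer reproduces an entire synthetic data set. Result stays below
#' 2^31.
#' @param seed top-level integer seed.
#' @param k component counter.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1103 * k) %% 2147483647)
}

#' Generate a radial profile series containing an inward-moving wave
#'
#' Emulates the measured signaling dynamics: a band of activity whose
#' outer boundary sits at `back_position` and whose inner boundary (the
#' wave front, in edge-distance coordinates) advances inward at constant
#' `speed` starting at `start_time`. Profiles are products of two logistic
#' shoulders, so the half-maximum crossing sits at the planted front
#' position up to O(rise/plateau) corrections.
#'
#' @param times sampling times (hours).
#' @param speed front speed (um/h).
#' @param start_time hour at which the front starts moving.
#' @param start_position initial front position (um from edge).
#' @param back_position stationary outer boundary (um from edge).
#' @param max_distance deepest bin center (um); defaults to a 700-um
#'   colony's inradius.
#' @param bin_width radial bin width (um).
#' @param amplitude plateau intensity.
#' @param rise logistic shoulder width (um).
#' @param noise_sd additive Gaussian noise on each bin.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return list with `series` (a [profile_series()]) and `truth`
#'   (data.frame of planted front positions per time).
#' @export
gen_wave_series <- function(times = seq(24, 44, by = 1), speed = 6,
                            start_time = 24, start_position = 20,
                            back_position = 10, max_distance = 350,
                            bin_width = 10, amplitude = 1, rise = 8,
                            noise_sd = 0, seed = 1L) {
  stopifnot(speed >= 0, length(times) >= 2)
  centers <- seq(bin_width / 2, max_distance, by = bin_width)
  front <- start_position + speed * pmax(0, times - start_time)
  front <- pmin(front, max_distance)
  vals <- t(vapply(seq_along(times), function(i) {
    amplitude / (1 + exp((centers - front[i]) / rise)) /
      (1 + exp((back_position - centers) / rise))
  }, numeric(length(centers))))
  if (noise_sd > 0)
    vals <- vals + with_local_seed(seed,
      matrix(stats::rnorm(length(vals), 0, noise_sd), nrow(vals)))
  list(series = profile_series(times, centers, vals),
       truth = data.frame(t = times, front = front))
}

#' Generate multi-channel colony images with known ground truth
#'
#' Emulates the immunofluorescence inputs of the quantification recipes:
#' nuclei are seeded uniformly over the colony, a DAPI channel marks them,
#' each fate-marker channel carries a planted radial mean profile on
#' nuclear pixels, and a membrane channel adds a bright rim around nuclei
#' for the membrane-subtraction recipe. The exact nuclear and membrane
#' masks used are returned, so recipes can be tested bit-exactly.
#'
#' @param mask a [make_mask()] object.
#' @param recipes named list of radial mean functions `g(edge_distance_um)`
#'   giving each marker channel's true marker/DAPI ratio.
#' @param dapi_level DAPI intensity on nuclear pixels.
#' @param nuclear_density nuclei per um^2 (default 2e-4, about 75 nuclei on
#'   a 700-um colony at 14 um/px).
#' @param nuclear_radius nucleus radius in um.
#' @param membrane_factor membrane channel brightness relative to the
#'   planted signal (only used for channel `"membrane_signal"`).
#' @param noise_sd additive Gaussian noise as a fraction of `dapi_level`.
#' @param seed RNG seed.
#' @return list with `images` (named list of matrices: DAPI, one per
#'   recipe, and `membrane_signal` built from the first recipe),
#'   `nuclear_mask`, `membrane_mask`, `truth` (the recipe functions).
#' @export
gen_colony_images <- function(mask, recipes, dapi_level = 1,
                              nuclear_density = 2e-4, nuclear_radius = 6,
                              membrane_factor = 10, noise_sd = 0,
                              seed = 1L) {
  g <- mask$grid
  H <- nrow(g); W <- ncol(g)
  ed <- edge_distance(mask)$values
  px_area <- mask$pixel_size^2
  n_nuc <- max(3L, round(nuclear_density * sum(g) * px_area))
  fg <- which(g)
  centers_idx <- with_local_seed(derive_seed(seed, 1),
                                 sample(fg, min(n_nuc, length(fg))))
  nuc <- matrix(FALSE, H, W)
  nuc[centers_idx] <- TRUE
  r_px <- nuclear_radius / mask$pixel_size
  if (r_px >= 1) {
    brush <- EBImage::makeBrush(2L * floor(r_px) + 1L, shape = "disc")
    nuc <- EBImage::dilate(nuc, brush) & TRUE
  }
  nuc <- nuc & g
  ring <- EBImage::dilate(nuc, EBImage::makeBrush(3L, shape = "box"))
  membrane <- (ring & !nuc) & g

  noise <- function(k) if (noise_sd > 0)
    with_local_seed(derive_seed(seed, 10 + k),
                    matrix(stats::rnorm(H * W, 0, noise_sd * dapi_level), H, W))
  else matrix(0, H, W)

  images <- list(DAPI = ifelse(nuc, dapi_level, 0) + noise(0))
  dvals <- ifelse(is.na(ed), 0, ed)
  for (k in seq_along(recipes)) {
    gk <- recipes[[k]]
    img <- ifelse(nuc, dapi_level * gk(dvals), 0) + noise(k)
    images[[names(recipes)[k]]] <- img
  }
  g1 <- recipes[[1]]
  memsig <- ifelse(g, g1(dvals), 0)
  memsig[membrane] <- memsig[membrane] * 0 + membrane_factor * max(memsig)
  images$membrane_signal <- memsig + noise(length(recipes) + 1)

  list(images = images, nuclear_mask = nuc, membrane_mask = membrane,
       truth = recipes)
}

#' Generate labelled cell tracks with planted drift and divisions
#'
#' Cells start uniformly over the colony; each time step adds an inward (or
#' outward) radial drift plus isotropic Brownian jitter. Divisions occur at
#' constant hazard; daughters inherit position and continue (one generation
#' of daughters may divide again, reproducing the 0/2/3/4 progeny
#' encoding). Ground truth (net planted drift, per-founder progeny code) is
#' returned alongside.
#'
#' @param mask a [make_mask()] object; positions are um from the colony
#'   centre.
#' @param n_cells number of founder cells.
#' @param duration,dt imaging span and interval (hours).
#' @param radial_drift total planted radial displacement over `duration`
#'   (um; negative = inward).
#' @param diffusion_sd per-step isotropic jitter (um).
#' @param division_rate per-cell divisions per hour.
#' @param seed RNG seed.
#' @return list with `tracks` (data.frame: track_id, parent_id, t, x, y,
#'   label) and `truth`.
#' @export
gen_tracks <- function(mask, n_cells = 50, duration = 27.5, dt = 0.5,
                       radial_drift = -10, diffusion_sd = 0,
                       division_rate = 0, seed = 1L) {
  ed <- edge_distance(mask)
  g <- mask$grid
  H <- nrow(g); W <- ncol(g)
  xs <- matrix(rep(0:(ncol(g) - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  cx <- mean(xs[g]); cy <- mean(ys[g])
  fg <- which(g & ed$values > abs(radial_drift) + 5)  # stay inside while drifting
  times <- seq(0, duration, by = dt)
  drift_per_step <- radial_drift / (length(times) - 1)

  with_local_seed(seed, {
    start_idx <- sample(fg, n_cells, replace = TRUE)
    rows <- list()
    next_id <- 0L
    truth_progeny <- integer(n_cells)
    for (ci in seq_len(n_cells)) {
      next_id <- next_id + 1L
      founder <- next_id
      # queue of (id, parent, start step, position, generation)
      queue <- list(list(id = founder, parent = NA_integer_, s = 1L,
                         x = (xs[start_idx[ci]] - cx) * mask$pixel_size,
                         y = (ys[start_idx[ci]] - cy) * mask$pixel_size,
                         gen = 0L))
      n_div <- 0L
      while (length(queue)) {
        cell <- queue[[1]]; queue <- queue[-1]
        x <- cell$x; y <- cell$y
        for (s in cell$s:length(times)) {
          rows[[length(rows) + 1L]] <-
            data.frame(track_id = cell$id, parent_id = cell$parent,
                       t = times[s], x = x, y = y)
          if (s == length(times)) break
          r <- sqrt(x^2 + y^2)
          if (r > 1e-9) {
            x <- x * (r + drift_per_step) / r
            y <- y * (r + drift_per_step) / r
          }
          if (diffusion_sd > 0) {
            x <- x + stats::rnorm(1, 0, diffusion_sd)
            y <- y + stats::rnorm(1, 0, diffusion_sd)
          }
          divides <- cell$gen < 2L && division_rate > 0 &&
            stats::runif(1) < division_rate * dt
          if (divides) {
            n_div <- n_div + 1L
            for (dgt in 1:2) {
              next_id <- next_id + 1L
              queue[[length(queue) + 1L]] <-
                list(id = next_id, parent = cell$id, s = s + 1L,
                     x = x, y = y, gen = cell$gen + 1L)
            }
            break
          }
        }
      }
      truth_progeny[ci] <- if (n_div == 0L) 0L else n_div + 1L
    }
    tracks <- do.call(rbind, rows)
    rownames(tracks) <- NULL
    list(tracks = tracks,
         truth = list(radial_drift = radial_drift,
                      progeny = truth_progeny,
                      center = c(0, 0)))
  })
}

#' Generate an FPKM-like expression matrix with planted DE structure
#'
#' Emulates the four-condition bulk RNA-seq design (a pluripotent
#' reference plus three treatments) with log-normal baseline abundances,
#' multiplicative log-normal replicate noise, and planted up-/
#' down-regulated gene sets per treatment with controlled overlap: counts
#' of genes shared by all three treatments, by each pair, and unique to
#' each.
#'
#' @param n_genes total genes.
#' @param conditions condition labels; the first is the reference.
#' @param n_reps replicates per condition.
#' @param n_shared,n_pair,n_unique planted genes per direction shared by
#'   all 3 treatments / per pair / per single treatment.
#' @param effect_fold planted fold change (default 8).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters
#'   for unplanted genes; planted genes use a floor of 5 FPKM so that they
#'   survive abundance filters by construction.
#' @param noise_sdlog replicate noise (log scale, default 0.2).
#' @param seed RNG seed.
#' @return list with `expr` (matrix), `conditions` (per column),
#'   `truth` (`up`, `down`: named list of planted gene sets per treatment).
#' @export
gen_expression <- function(n_genes = 2000,
                           conditions = c("mTeSR", "BMP", "BMP_SB", "BMP_IWP2"),
                           n_reps = 3, n_shared = c(up = 77, down = 54),
                           n_pair = c(up = 5, down = 8),
                           n_unique = c(up = 13, down = 25),
                           effect_fold = 8, baseline_meanlog = log(5),
                           baseline_sdlog = 1.2, noise_sdlog = 0.2,
                           seed = 1L) {
  treats <- conditions[-1]
  stopifnot(length(treats) == 3)
  n_planted <- sum(n_shared) + 3 * sum(n_pair) + 3 * sum(n_unique)
  stopifnot(n_genes > n_planted + 10)
  genes <- sprintf("G%05d", seq_len(n_genes))

  with_local_seed(seed, {
    base <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    names(base) <- genes
    pool <- genes
    take <- function(n) {
      sel <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      sel
    }
    pool <- sample(pool)
    sets <- list(up = stats::setNames(vector("list", 3), treats),
                 down = stats::setNames(vector("list", 3), treats))
    for (dir in c("up", "down")) {
      shared <- take(n_shared[[dir]])
      for (tr in treats) sets[[dir]][[tr]] <- shared
      pairs <- utils::combn(treats, 2, simplify = FALSE)
      for (pr in pairs) {
        gset <- take(n_pair[[dir]])
        for (tr in pr) sets[[dir]][[tr]] <- c(sets[[dir]][[tr]], gset)
      }
      for (tr in treats)
        sets[[dir]][[tr]] <- c(sets[[dir]][[tr]], take(n_unique[[dir]]))
    }
    planted <- unique(unlist(sets))
    base[planted] <- pmax(base[planted], 5)

    cond_of <- rep(conditions, each = n_reps)
    mu <- matrix(rep(base, length(cond_of)), n_genes,
                 dimnames = list(genes, NULL))
    for (tr in treats) {
      j <- cond_of == tr
      mu[sets$up[[tr]], j] <- mu[sets$up[[tr]], j] * effect_fold
      mu[sets$down[[tr]], j] <- mu[sets$down[[tr]], j] / effect_fold
    }
    expr <- mu * matrix(stats::rlnorm(length(mu), 0, noise_sdlog), n_genes)
    colnames(expr) <- paste(cond_of, sequence(rle(cond_of)$lengths), sep = "_")
    list(expr = expr, conditions = cond_of,
         truth = list(up = sets$up, down = sets$down,
                      planted = planted, baseline = base))
  })
}
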