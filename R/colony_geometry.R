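#' Construct a colony mask on a lattice
#'
#' Builds the boolean lattice describing which pixels of a square imaging
#' lattice are covered by a micropatterned colony. Simulation and
#' quantification both run on these masks; periodic boundary conditions are
#' applied to the full lattice, so the foreground must never touch the
#' lattice border (a margin of at least one pixel is enforced).
#'
#' Shape conventions (the micropattern geometries are rotationally free in
#' the experiment, so fixed orientations are adopted for reproducibility):
#' * `circle` -- disc of diameter `nominal_diameter` centred on the lattice.
#' * `triangle` -- equilateral, one vertex up, inscribed in the circle of
#'   diameter `nominal_diameter`, centred on the centroid.
#' * `pacman` -- the circle minus a 90 degree wedge with apex at the centre
#'   and bisector along +x (to the right).
#'
#' @param shape_label one of `"circle"`, `"triangle"`, `"pacman"`, or
#'   `"custom"` (then `grid` must be supplied).
#' @param nominal_diameter colony diameter in micrometres.
#' @param lattice_size lattice side length in pixels (lattice is square), or
#'   a length-2 vector `c(H, W)`.
#' @param pixel_size physical size of one pixel in micrometres. The default
#'   14 um/px maps a radius-25-px simulated colony to a 700-um experimental
#'   colony.
#' @param grid for `shape_label = "custom"`, a logical matrix to validate
#'   and wrap.
#' @return an object of class `colony_mask` with fields `grid` (logical
#'   H x W matrix), `pixel_size`, `shape_label`, `nominal_diameter`.
#' @export
make_mask <- function(shape_label = c("circle", "triangle", "pacman", "custom"),
                      nominal_diameter, lattice_size = 190, pixel_size = 14,
                      grid = NULL) {
  shape_label <- match.arg(shape_label)
  if (length(lattice_size) == 1L) lattice_size <- c(lattice_size, lattice_size)
  H <- as.integer(lattice_size[1]); W <- as.integer(lattice_size[2])

  if (shape_label == "custom") {
    if (is.null(grid)) stop("custom masks require `grid`")
    m <- new_colony_mask(grid, pixel_size, shape_label,
                         nominal_diameter = 2 * max(edge_distance_px(grid)) * pixel_size)
    return(m)
  }

  if (nominal_diameter <= 0)
    stop("nominal_diameter must be positive; an empty mask is not a colony")
  r_px <- nominal_diameter / (2 * pixel_size)
  need <- ceiling(2 * r_px) + 3L  # shape + >=1 px margin each side
  if (H < need || W < need)
    stop(sprintf("lattice %dx%d too small for %s of diameter %g um at %g um/px; need at least %dx%d",
                 H, W, shape_label, nominal_diameter, pixel_size, need, need))

  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  dx <- xs - cx
  dy <- cy - ys   # +y up in physical convention; rows grow downwards

  g <- switch(shape_label,
    circle = dx^2 + dy^2 <= r_px^2,
    pacman = {
      inside <- dx^2 + dy^2 <= r_px^2
      ang <- atan2(dy, dx)
      wedge <- abs(ang) <= pi / 4  # 90 deg, bisector along +x
      inside & !wedge
    },
    triangle = {
      # vertices on the circumscribed circle at 90, 210, 330 degrees
      va <- lapply(c(90, 210, 330) * pi / 180,
                   function(th) c(r_px * cos(th), r_px * sin(th)))
      inside_tri(dx, dy, va[[1]], va[[2]], va[[3]])
    })
  new_colony_mask(g, pixel_size, shape_label, nominal_diameter)
}

inside_tri <- function(px, py, a, b, c) {
  # half-plane test, consistent sign for all three edges
  cross <- function(v1, v2) (v2[1] - v1[1]) * (py - v1[2]) - (v2[2] - v1[2]) * (px - v1[1])
  d1 <- cross(a, b); d2 <- cross(b, c); d3 <- cross(c, a)
  (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
}

new_colony_mask <- function(grid, pixel_size, shape_label, nominal_diameter) {
  stopifnot(is.matrix(grid))
  grid <- grid & TRUE  # coerce to logical
  if (!any(grid)) stop("mask has empty foreground")
  if (any(grid[1, ]) || any(grid[nrow(grid), ]) ||
      any(grid[, 1]) || any(grid[, ncol(grid)]))
    stop("mask foreground touches the lattice border; periodic boundaries would wrap the colony onto itself")
  lab <- EBImage::bwlabel(matrix(as.numeric(grid), nrow(grid)))
  if (max(lab) != 1L)
    stop(sprintf("mask must have exactly one connected component, found %d", max(lab)))
  structure(list(grid = grid, pixel_size = pixel_size,
                 shape_label = shape_label,
                 nominal_diameter = nominal_diameter),
            class = "colony_mask")
}

#' Full-lattice mask for homogeneous-domain simulations
#'
#' A mask whose foreground covers the whole periodic lattice: every pixel
#' produces, none is "outside". This is the homogeneous system used to ask
#' whether a parameter set forms a pattern at all (the colony-free control
#' of the regime analysis); colony invariants (single component, border
#' margin) intentionally do not apply, and edge distances are undefined.
#'
#' @param lattice_size side length in pixels, or `c(H, W)`.
#' @param pixel_size um per pixel.
#' @export
full_lattice_mask <- function(lattice_size = 64, pixel_size = 14) {
  if (length(lattice_size) == 1L) lattice_size <- c(lattice_size, lattice_size)
  structure(list(grid = matrix(TRUE, lattice_size[1], lattice_size[2]),
                 pixel_size = pixel_size, shape_label = "full",
                 nominal_diameter = NA_real_),
            class = "colony_mask")
}

#' @export
print.colony_mask <- function(x, ...) {
  cat(sprintf("<colony_mask> %s, %g um nominal diameter, %dx%d px @ %g um/px, area %d px\n",
              x$shape_label, x$nominal_diameter, nrow(x$grid), ncol(x$grid),
              x$pixel_size, sum(x$grid)))
  invisible(x)
}

# Exact Euclidean distance transform in pixel units, 0 on boundary pixels.
# distmap() returns distance to the nearest background pixel; subtracting 1
# puts the zero on the outermost foreground rim (center-to-center metric).
edge_distance_px <- function(grid) {
  dm <- EBImage::distmap(matrix(as.numeric(grid), nrow(grid)), metric = "euclidean")
  d <- pmax(as.matrix(dm) - 1, 0)
  d[!grid] <- NA_real_
  d
}

#' Distance from the colony edge
#'
#' Euclidean distance transform of the mask, in micrometres, defined on
#' foreground pixels (NA outside). This is the x-axis of every radial
#' quantification: 0 on the outermost pixel rim, increasing inwards, bounded
#' by the inradius of the shape.
#'
#' @param mask a [make_mask()] object.
#' @return object of class `edge_distance_field`: list with `values`
#'   (H x W matrix, um, NA off-colony) and `max_distance` (um).
#' @export
edge_distance <- function(mask) {
  stopifnot(inherits(mask, "colony_mask"))
  if (identical(mask$shape_label, "full"))
    stop("edge distance is undefined for a full-lattice mask")
  d <- edge_distance_px(mask$grid) * mask$pixel_size
  structure(list(values = d, max_distance = max(d, na.rm = TRUE)),
            class = "edge_distance_field")
}

#' Bin foreground pixels by distance from the colony edge
#'
#' Shared binning machinery for radial profiles: every foreground pixel is
#' assigned to a bin of width `bin_width` in edge distance. Bins cover
#' `[0, max_distance]`; the outermost bin starts at 0.
#'
#' @param mask a [make_mask()] object.
#' @param bin_width bin width in micrometres (default 10).
#' @return list with `index` (integer H x W matrix, NA off-colony),
#'   `edges`, `centers` (um), `n_bins`, and `area` (pixels per bin).
#' @export
edge_bins <- function(mask, bin_width = 10) {
  ed <- edge_distance(mask)
  n_bins <- max(1L, ceiling((ed$max_distance + 1e-9) / bin_width))
  edges <- seq(0, n_bins * bin_width, by = bin_width)
  idx <- findInterval(ed$values, edges, rightmost.closed = TRUE)
  idx[idx > n_bins] <- n_bins
  storage.mode(idx) <- "integer"
  area <- tabulate(idx[!is.na(idx)], nbins = n_bins)
  list(index = idx, edges = edges,
       centers = edges[-length(edges)] + bin_width / 2,
       n_bins = n_bins, area = area)
}

#' Write / read a colony mask as TIFF plus JSON sidecar
#'
#' The mask is stored as a single-channel 0/255 TIFF; pixel size, shape
#' label and nominal diameter travel in a JSON sidecar `<path>.json`.
#'
#' @param mask a [make_mask()] object.
#' @param path TIFF file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "colony_mask"))
  tiff::writeTIFF(matrix(as.numeric(mask$grid), nrow(mask$grid)), path,
                  bits.per.sample = 8L)
  jsonlite::write_json(list(pixel_size = mask$pixel_size,
                            shape_label = mask$shape_label,
                            nominal_diameter = mask$nominal_diameter),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  new_colony_mask(img > 0.5, meta$pixel_size, meta$shape_label,
                  meta$nominal_diameter)
}
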