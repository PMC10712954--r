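# Deterministic renderer for the object family: a rounded-slab base whose
# horizontal profile bulges outward (convex) or inward (concave) with the
# concavity level, and three spheres attached to its top edge whose vertical
# offsets encode the alignment level. Orthographic projection, single
# directional light, Lambert shading, rendered by sphere-traced ray marching
# of a signed distance function (SDF). Pure arithmetic: the same spec always
# produces bit-identical pixels.

#' Renderer configuration
#'
#' Geometry and shading constants of the procedural renderer. All lengths are
#' in world units, where the 100x100 image frame spans \[-1, 1\] in both axes.
#'
#' @param image_size image side length in pixels.
#' @param base_halfwidth,base_halfheight,base_halfdepth half-extents of the
#'   base slab.
#' @param concavity_max absolute profile displacement (world units) at the
#'   extreme concavity levels; level 5 of 0..10 is flat.
#' @param sphere_radius,sphere_spacing radius of the three spheres and the
#'   horizontal offset of the outer two.
#' @param sphere_height height of the sphere centres above the base midline.
#' @param align_step vertical displacement per alignment level; the default
#'   (radius / 3) displaces by one sphere radius at level 3.
#' @param position_offset magnitude of the corner position translations.
#' @param ambient ambient luminance of lit surface (keeps every silhouette
#'   pixel strictly above the black background).
#' @param march_steps,march_eps,march_relax ray-marching controls.
#' @return a list of class `render_config`.
#' @export
render_config <- function(image_size = 100L,
                          base_halfwidth = 0.38,
                          base_halfheight = 0.35,
                          base_halfdepth = 0.22,
                          concavity_max = 0.18,
                          sphere_radius = 0.16,
                          sphere_spacing = 0.26,
                          sphere_height = 0.45,
                          align_step = 0.16 / 3,
                          position_offset = 0.42,
                          ambient = 0.12,
                          march_steps = 96L,
                          march_eps = 1.2e-3,
                          march_relax = 0.65) {
  structure(list(image_size = as.integer(image_size),
                 base_halfwidth = base_halfwidth,
                 base_halfheight = base_halfheight,
                 base_halfdepth = base_halfdepth,
                 concavity_max = concavity_max,
                 sphere_radius = sphere_radius,
                 sphere_spacing = sphere_spacing,
                 sphere_height = sphere_height,
                 align_step = align_step,
                 position_offset = position_offset,
                 ambient = ambient,
                 march_steps = as.integer(march_steps),
                 march_eps = march_eps,
                 march_relax = march_relax),
            class = "render_config")
}

# signed bulge parameter of a concavity level (strictly monotone, level 5 = 0)
concavity_param <- function(level, cfg) (level - 5) / 5 * cfg$concavity_max

# sphere centres (3 x 3 matrix, rows = spheres) for an alignment level:
# the left sphere moves up, the right sphere moves down.
sphere_centres <- function(level, cfg) {
  dy <- level * cfg$align_step
  rbind(c(-cfg$sphere_spacing, cfg$sphere_height + dy, 0),
        c(0,                   cfg$sphere_height,      0),
        c(cfg$sphere_spacing,  cfg$sphere_height - dy, 0))
}

# SDF of the object in object coordinates, vectorised over points.
# x, y, z: equal-length vectors. Returns a lower bound on the distance
# (exact for the spheres, conservative for the profiled slab).
object_sdf <- function(x, y, z, conc, centres, cfg) {
  hh <- cfg$base_halfheight
  yc <- pmin(pmax(y, -hh), hh)
  w <- cfg$base_halfwidth + conc * (1 - (yc / hh)^2)
  d <- pmax(abs(x) - w, abs(y) - hh, abs(z) - cfg$base_halfdepth)
  r <- cfg$sphere_radius
  for (k in 1:3) {
    dk <- sqrt((x - centres[k, 1])^2 + (y - centres[k, 2])^2 +
                 (z - centres[k, 3])^2) - r
    d <- pmin(d, dk)
  }
  d
}

rotation_matrix <- function(rx, ry, rz) {
  cr <- function(a) cos(a * pi / 180); sr <- function(a) sin(a * pi / 180)
  Rx <- rbind(c(1, 0, 0), c(0, cr(rx), -sr(rx)), c(0, sr(rx), cr(rx)))
  Ry <- rbind(c(cr(ry), 0, sr(ry)), c(0, 1, 0), c(-sr(ry), 0, cr(ry)))
  Rz <- rbind(c(cr(rz), -sr(rz), 0), c(sr(rz), cr(rz), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

light_direction <- function(location) {
  # unit vector pointing from the surface toward the light; the camera views
  # the scene from negative z
  v <- switch(location,
              front = c(0, 0, -1),
              left  = c(-0.8, 0, -0.6),
              right = c(0.8, 0, -0.6),
              up    = c(0, 0.8, -0.6),
              under = c(0, -0.8, -0.6))
  v / sqrt(sum(v^2))
}

position_offset_xy <- function(position, cfg) {
  o <- cfg$position_offset
  switch(position,
         center      = c(0, 0),
         lower_left  = c(-o, -o),
         lower_right = c(o, -o),
         upper_left  = c(-o, o),
         upper_right = c(o, o))
}

# conservative bounding-sphere radius of the object in object coordinates
bounding_radius <- function(cfg) {
  top <- cfg$sphere_height + 3 * cfg$align_step + cfg$sphere_radius
  wmax <- cfg$base_halfwidth + cfg$concavity_max
  sqrt(max(top, cfg$base_halfheight)^2 + max(wmax, cfg$sphere_spacing +
         cfg$sphere_radius)^2 + cfg$base_halfdepth^2) * 1.02
}

#' Render a stimulus image
#'
#' Deterministically renders a [stimulus_spec()] as a grayscale luminance
#' image on a black background. Rotations are applied as 3D rotation matrices
#' (x, then y, then z axis) before orthographic projection; shading is a
#' single-directional-light Lambert model; `size_scale` shrinks the projected
#' object about the image centre and `position` translates it to the named
#' corner.
#'
#' @param spec a [stimulus_spec()].
#' @param cfg a [render_config()].
#' @return an object of class `stimulus_image`: a list with `pixels` (a
#'   100x100 matrix of luminances in \[0, 1\], row 1 = top of the image) and
#'   `spec`.
#' @export
#' @examples
#' img <- render_stimulus(base_pair()$target)
#' brightness(img)
render_stimulus <- function(spec, cfg = render_config()) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- cfg$image_size
  px <- 2 / n
  tr <- spec$transform
  conc <- concavity_param(spec$shape$concavity_level, cfg)
  centres <- sphere_centres(spec$shape$alignment_level, cfg)
  R <- rotation_matrix(tr$rot_x, tr$rot_y, tr$rot_z)
  Rt <- t(R)
  s <- tr$size_scale
  off <- position_offset_xy(tr$position, cfg)

  # pixel-centre world coordinates; matrix element [row, col] maps to
  # flat index (col - 1) * n + row (column-major)
  u <- (seq_len(n) - (n + 1) / 2) * px
  v <- ((n + 1) / 2 - seq_len(n)) * px   # row 1 = top
  col_idx <- rep(seq_len(n), each = n)
  row_idx <- rep(seq_len(n), times = n)
  pu <- u[col_idx]
  pv <- v[row_idx]

  # Fold position and size into the ray, then rotate into the object frame:
  # world point q = (pu, pv, t); object point p = Rt %*% ((q - (off, 0)) / s).
  # Rays stay straight lines p(tt) = A + tt * Rt[, 3] with tt in object units.
  qx <- (pu - off[1]) / s
  qy <- (pv - off[2]) / s
  Ax <- Rt[1, 1] * qx + Rt[1, 2] * qy
  Ay <- Rt[2, 1] * qx + Rt[2, 2] * qy
  Az <- Rt[3, 1] * qx + Rt[3, 2] * qy

  rb <- bounding_radius(cfg)
  rho2 <- qx^2 + qy^2   # squared ray-to-origin distance (object frame)
  inside <- rho2 <= rb^2
  lum <- numeric(n * n)
  if (!any(inside))
    stop("object projected fully outside the image frame", call. = FALSE)

  idx <- which(inside)
  half <- sqrt(rb^2 - rho2[idx])      # object-frame half-chord
  tcur <- -half
  tmax <- half
  ax <- Ax[idx]; ay <- Ay[idx]; az <- Az[idx]
  mx <- Rt[1, 3]; my <- Rt[2, 3]; mz <- Rt[3, 3]  # unit ray direction
  done <- rep(FALSE, length(idx))
  hit <- rep(FALSE, length(idx))
  eps <- cfg$march_eps
  for (step in seq_len(cfg$march_steps)) {
    act <- which(!done)
    if (!length(act)) break
    tt <- tcur[act]
    d <- object_sdf(ax[act] + tt * mx, ay[act] + tt * my, az[act] + tt * mz,
                    conc, centres, cfg)
    h <- d < eps
    hit[act[h]] <- TRUE
    done[act[h]] <- TRUE
    tt <- tt + pmax(d, eps) * cfg$march_relax
    over <- tt > tmax[act]
    done[act[over & !h]] <- TRUE
    tcur[act] <- tt
  }

  if (any(hit)) {
    hi <- which(hit)
    hx <- ax[hi] + tcur[hi] * mx
    hy <- ay[hi] + tcur[hi] * my
    hz <- az[hi] + tcur[hi] * mz
    h <- 1e-3
    gx <- object_sdf(hx + h, hy, hz, conc, centres, cfg) -
      object_sdf(hx - h, hy, hz, conc, centres, cfg)
    gy <- object_sdf(hx, hy + h, hz, conc, centres, cfg) -
      object_sdf(hx, hy - h, hz, conc, centres, cfg)
    gz <- object_sdf(hx, hy, hz + h, conc, centres, cfg) -
      object_sdf(hx, hy, hz - h, conc, centres, cfg)
    gn <- sqrt(gx^2 + gy^2 + gz^2)
    gn[gn == 0] <- 1
    # normal in world frame: n_world = R %*% n_obj
    nx <- R[1, 1] * gx + R[1, 2] * gy + R[1, 3] * gz
    ny <- R[2, 1] * gx + R[2, 2] * gy + R[2, 3] * gz
    nz <- R[3, 1] * gx + R[3, 2] * gy + R[3, 3] * gz
    L <- light_direction(tr$light_location)
    lambert <- pmax(0, (nx * L[1] + ny * L[2] + nz * L[3]) / gn)
    lum[idx[hi]] <- cfg$ambient + (1 - cfg$ambient) * lambert
  } else {
    stop("object projected fully outside the image frame", call. = FALSE)
  }

  pixels <- matrix(pmin(pmax(lum, 0), 1), nrow = n, ncol = n)
  structure(list(pixels = pixels, spec = spec), class = "stimulus_image")
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat(sprintf("<stimulus_image> %dx%d, brightness %.4f\n",
              nrow(x$pixels), ncol(x$pixels), brightness(x)))
  print(x$spec)
  invisible(x)
}

#' Display a stimulus image
#'
#' @param x a `stimulus_image`.
#' @param ... passed to [graphics::image()].
#' @export
plot.stimulus_image <- function(x, ...) {
  m <- t(x$pixels)[, rev(seq_len(nrow(x$pixels)))]
  graphics::image(m, col = gray.colors(256, 0, 1), asp = 1, axes = FALSE, ...)
}

#' Mean luminance of an image
#'
#' @param img a `stimulus_image` or a numeric pixel matrix.
#' @return mean luminance over all pixels.
#' @export
brightness <- function(img) {
  mean(as_pixels(img))
}

#' Euclidean pixel dissimilarity between two images
#'
#' The Euclidean distance between the flattened pixel vectors: a metric on
#' the image set (non-negative, symmetric, zero only for identical images).
#'
#' @param a,b `stimulus_image`s or pixel matrices of equal dimensions.
#' @return a non-negative scalar.
#' @export
pixel_dissimilarity <- function(a, b) {
  pa <- as_pixels(a); pb <- as_pixels(b)
  if (!identical(dim(pa), dim(pb)))
    stop("images must have identical dimensions", call. = FALSE)
  sqrt(sum((pa - pb)^2))
}

as_pixels <- function(img) {
  if (inherits(img, "stimulus_image")) return(img$pixels)
  if (is.matrix(img) && is.numeric(img)) return(img)
  stop("expected a stimulus_image or a numeric matrix", call. = FALSE)
}

# Per-row silhouette widths (pixel counts above background) of an image.
silhouette_widths <- function(img) {
  rowSums(as_pixels(img) > 0)
}

# Render with memoisation in `cache` (an environment); used by the pair
# sampler and the pipeline, where the same spec recurs many times.
render_cached <- function(spec, cfg, cache) {
  key <- spec_id(spec)
  got <- cache[[key]]
  if (!is.null(got)) return(got)
  img <- render_stimulus(spec, cfg)
  cache[[key]] <- img
  img
}
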