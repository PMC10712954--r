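# Parametric object family: a body ("base") whose concavity varies over 11
# levels, with three spheres on top whose vertical alignment varies over 4
# levels, plus identity-preserving viewing transformations.

ROTATION_ANGLES <- seq(0L, 180L, by = 30L)
LIGHT_LOCATIONS <- c("front", "left", "right", "up", "under")
SIZE_SCALES     <- c(1.0, 0.8, 0.6)
POSITIONS       <- c("center", "lower_left", "lower_right",
                     "upper_left", "upper_right")
N_CONCAVITY     <- 11L
N_ALIGNMENT     <- 4L

#' Shape parameters of one object
#'
#' An object of the family is described by two integer indices: the concavity
#' level of its base (0 = maximally concave, 10 = maximally convex, 5 = flat)
#' and the alignment level of its three spheres (0 = horizontally aligned,
#' 3 = maximally misaligned along an upper-left to lower-right diagonal).
#' Both index-to-geometry maps are strictly monotone.
#'
#' @param concavity_level integer in 0..10.
#' @param alignment_level integer in 0..3.
#' @return an object of class `shape_params`.
#' @export
#' @examples
#' shape_params(0, 0)   # the trained target shape (concave, aligned)
#' shape_params(10, 3)  # the trained distractor shape (convex, misaligned)
shape_params <- function(concavity_level, alignment_level) {
  concavity_level <- as.integer(concavity_level)
  alignment_level <- as.integer(alignment_level)
  if (is.na(concavity_level) || concavity_level < 0L ||
      concavity_level >= N_CONCAVITY)
    stop("`concavity_level` must be an integer in 0..10", call. = FALSE)
  if (is.na(alignment_level) || alignment_level < 0L ||
      alignment_level >= N_ALIGNMENT)
    stop("`alignment_level` must be an integer in 0..3", call. = FALSE)
  structure(list(concavity_level = concavity_level,
                 alignment_level = alignment_level),
            class = "shape_params")
}

#' Viewing transformation of a stimulus
#'
#' Identity-preserving image transformations: rotation about the x, y and z
#' axes in 30 degree steps (0..180), light location, size scale relative to
#' the trained size, and screen position. The identity transformation is
#' `stim_transform()`.
#'
#' @param rot_x,rot_y,rot_z rotation angles in degrees, one of 0, 30, ..., 180.
#' @param light_location one of `"front"`, `"left"`, `"right"`, `"up"`,
#'   `"under"`.
#' @param size_scale one of 1.0, 0.8, 0.6.
#' @param position one of `"center"`, `"lower_left"`, `"lower_right"`,
#'   `"upper_left"`, `"upper_right"`.
#' @return an object of class `stim_transform`.
#' @export
stim_transform <- function(rot_x = 0, rot_y = 0, rot_z = 0,
                           light_location = "front",
                           size_scale = 1.0, position = "center") {
  rot_x <- as.integer(rot_x); rot_y <- as.integer(rot_y)
  rot_z <- as.integer(rot_z)
  for (a in list(rot_x, rot_y, rot_z))
    if (!a %in% ROTATION_ANGLES)
      stop("rotation angles must be in {0, 30, ..., 180} degrees",
           call. = FALSE)
  light_location <- match.arg(light_location, LIGHT_LOCATIONS)
  if (!size_scale %in% SIZE_SCALES)
    stop("`size_scale` must be one of 1.0, 0.8, 0.6", call. = FALSE)
  position <- match.arg(position, POSITIONS)
  structure(list(rot_x = rot_x, rot_y = rot_y, rot_z = rot_z,
                 light_location = light_location,
                 size_scale = size_scale, position = position),
            class = "stim_transform")
}

#' Full specification of one stimulus image
#'
#' Couples a shape, a viewing transformation and a task role. Roles other
#' than `"unassigned"` are only meaningful for shapes inside the selected
#' 4x4 sub-grid, where they derive from the grid position (see
#' [subgrid_roles()]).
#'
#' @param shape a [shape_params()] object.
#' @param transform a [stim_transform()] object.
#' @param role `"target"`, `"distractor"`, `"ambiguous"` or `"unassigned"`.
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(shape, transform = stim_transform(),
                          role = "unassigned") {
  stopifnot(inherits(shape, "shape_params"),
            inherits(transform, "stim_transform"))
  role <- match.arg(role, c("target", "distractor", "ambiguous", "unassigned"))
  structure(list(shape = shape, transform = transform, role = role),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<stimulus_spec> %s | conc %d align %d | rot (%d,%d,%d) light %s size %.1f pos %s\n",
    x$role, x$shape$concavity_level, x$shape$alignment_level,
    x$transform$rot_x, x$transform$rot_y, x$transform$rot_z,
    x$transform$light_location, x$transform$size_scale, x$transform$position))
  invisible(x)
}

# A short unique id string for one spec (used as pair/cache keys).
spec_id <- function(spec) {
  sprintf("c%da%d_x%dy%dz%d_%s_s%d_%s",
          spec$shape$concavity_level, spec$shape$alignment_level,
          spec$transform$rot_x, spec$transform$rot_y, spec$transform$rot_z,
          spec$transform$light_location,
          round(100 * spec$transform$size_scale),
          spec$transform$position)
}

#' Role labels of a 4x4 stimulus grid
#'
#' Within the selected 4x4 concavity-by-alignment grid, the anti-diagonal
#' holds the four ambiguous stimuli (interpretable as target or distractor);
#' the six cells on the concave/aligned side are targets and the six cells on
#' the convex/misaligned side are distractors.
#'
#' @param alignment_idx,concavity_idx 0-based positions within the 4x4 grid;
#'   concavity index 0 is the most concave of the four selected columns.
#' @return `"target"`, `"ambiguous"` or `"distractor"` (vectorised).
#' @export
#' @examples
#' table(outer(0:3, 0:3, Vectorize(subgrid_roles)))
subgrid_roles <- function(alignment_idx, concavity_idx) {
  s <- alignment_idx + concavity_idx
  ifelse(s < 3L, "target", ifelse(s == 3L, "ambiguous", "distractor"))
}

#' The trained base pair
#'
#' The maximally different pair of the design: the concave object with
#' horizontally aligned spheres (target) versus the convex object with
#' misaligned spheres (distractor), at the identity transformation.
#'
#' @param columns the four concavity levels of the selected 4x4 sub-grid
#'   (defaults to [default_subgrid_columns()]).
#' @return list with elements `target` and `distractor` ([stimulus_spec()]s).
#' @export
base_pair <- function(columns = default_subgrid_columns()) {
  stopifnot(length(columns) == 4L)
  list(
    target = stimulus_spec(shape_params(columns[1], 0L), role = "target"),
    distractor = stimulus_spec(shape_params(columns[4], 3L),
                               role = "distractor"))
}

#' Default concavity columns of the 4x4 sub-grid
#'
#' The four concavity levels (out of 0..10) used when no data-driven
#' sub-grid selection ([select_subgrid()]) is supplied: the two extremes
#' plus the symmetric near-uniform interior spacing.
#'
#' @return integer vector of length 4.
#' @export
default_subgrid_columns <- function() c(0L, 3L, 7L, 10L)
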