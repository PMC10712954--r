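# Stimulus-space bookkeeping: enumeration of the full transformation space,
# data-driven selection of the 4x4 sub-grid, the fixed training and testing
# protocols, and the candidate pool for the model-informed pair search.

spec_df_cols <- c("concavity", "alignment", "rot_x", "rot_y", "rot_z",
                  "light_location", "size_scale", "position", "role")

# one-row data.frame <-> stimulus_spec conversions
spec_to_row <- function(spec) {
  data.frame(concavity = spec$shape$concavity_level,
             alignment = spec$shape$alignment_level,
             rot_x = spec$transform$rot_x, rot_y = spec$transform$rot_y,
             rot_z = spec$transform$rot_z,
             light_location = spec$transform$light_location,
             size_scale = spec$transform$size_scale,
             position = spec$transform$position,
             role = spec$role, stringsAsFactors = FALSE)
}

spec_from_row <- function(row) {
  stimulus_spec(
    shape_params(row$concavity, row$alignment),
    stim_transform(row$rot_x, row$rot_y, row$rot_z, row$light_location,
                   row$size_scale, row$position),
    role = row$role)
}

#' Enumerate a stimulus sub-space
#'
#' Crosses the supplied axis levels into one row per stimulus specification.
#' The default arguments enumerate the full rendered set of the design: 4
#' alignment x 11 concavity x 7 x 7 x 7 rotations x 5 light locations =
#' 75,460 stimuli (size and position, which are applied in 2D after
#' rendering, are held at identity).
#'
#' @param alignment,concavity integer level vectors.
#' @param rot_x,rot_y,rot_z angle vectors (subsets of 0, 30, ..., 180).
#' @param light_location character vector of light locations.
#' @param size_scale,position transformation vectors.
#' @return a data.frame with one row per specification; `nrow()` equals the
#'   product of the axis cardinalities and every combination occurs exactly
#'   once.
#' @export
#' @examples
#' nrow(enumerate_space())  # 75460
enumerate_space <- function(alignment = 0:3, concavity = 0:10,
                            rot_x = ROTATION_ANGLES, rot_y = ROTATION_ANGLES,
                            rot_z = ROTATION_ANGLES,
                            light_location = LIGHT_LOCATIONS,
                            size_scale = 1.0, position = "center") {
  stopifnot(all(alignment %in% 0:3), all(concavity %in% 0:10),
            all(rot_x %in% ROTATION_ANGLES), all(rot_y %in% ROTATION_ANGLES),
            all(rot_z %in% ROTATION_ANGLES),
            all(light_location %in% LIGHT_LOCATIONS),
            all(size_scale %in% SIZE_SCALES), all(position %in% POSITIONS))
  g <- expand.grid(concavity = concavity, alignment = alignment,
                   rot_x = rot_x, rot_y = rot_y, rot_z = rot_z,
                   light_location = light_location,
                   size_scale = size_scale, position = position,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$role <- "unassigned"
  g
}

#' Select the 4x4 sub-grid from the 4x11 shape grid
#'
#' Chooses `k` concavity columns of the 4x11 concavity-by-alignment grid so
#' that pixel dissimilarity is as uniform as possible across the chosen span.
#' The search is exhaustive over all column subsets with a lexicographic
#' objective: (1) maximal end-to-end dissimilarity between the first and last
#' chosen column (the trained pair must remain maximally different), (2)
#' minimal variance of adjacent-column dissimilarities, (3) symmetric spacing
#' (smallest difference between the first and last gap), (4) lowest column
#' indices. Role labels follow the anti-diagonal rule of [subgrid_roles()].
#'
#' @param dissim optional precomputed 11x11 column dissimilarity matrix; when
#'   `NULL` the 44 grid stimuli are rendered and the matrix is computed as the
#'   mean [pixel_dissimilarity()] over the four alignment rows.
#' @param k number of columns to keep (default 4).
#' @param cfg a [render_config()] used when rendering is needed.
#' @return a list of class `subgrid_selection` with `columns` (the selected
#'   concavity levels), `roles` (4 x k matrix, rows = alignment levels),
#'   `dissim` and the achieved objective.
#' @export
select_subgrid <- function(dissim = NULL, k = 4L, cfg = render_config()) {
  nc <- N_CONCAVITY
  k <- as.integer(k)
  if (k > nc) stop("fewer than `k` columns available", call. = FALSE)
  if (is.null(dissim)) {
    imgs <- lapply(0:3, function(a)
      lapply(0:(nc - 1L), function(co)
        render_stimulus(stimulus_spec(shape_params(co, a)), cfg)))
    dissim <- matrix(0, nc, nc)
    for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
      d <- mean(vapply(1:4, function(a)
        pixel_dissimilarity(imgs[[a]][[i]], imgs[[a]][[j]]), numeric(1)))
      dissim[i, j] <- d; dissim[j, i] <- d
    }
  }
  stopifnot(is.matrix(dissim), nrow(dissim) == nc, ncol(dissim) == nc)

  subsets <- utils::combn(0:(nc - 1L), k)
  best <- NULL
  for (s in seq_len(ncol(subsets))) {
    cols <- subsets[, s]
    span <- dissim[cols[1] + 1L, cols[k] + 1L]
    gaps <- vapply(seq_len(k - 1L), function(i)
      dissim[cols[i] + 1L, cols[i + 1L] + 1L], numeric(1))
    key <- c(-span, stats::var(gaps), abs(gaps[1] - gaps[k - 1L]), cols)
    if (is.null(best) || lex_less(key, best$key))
      best <- list(cols = cols, key = key, gaps = gaps, span = span)
  }
  roles <- outer(0:3, 0:(k - 1L), subgrid_roles)
  rownames(roles) <- paste0("align", 0:3)
  colnames(roles) <- paste0("conc", best$cols)
  structure(list(columns = best$cols, roles = roles, dissim = dissim,
                 span = best$span, gaps = best$gaps),
            class = "subgrid_selection")
}

# strict lexicographic comparison of equal-length numeric keys
lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}

#' @export
print.subgrid_selection <- function(x, ...) {
  cat("<subgrid_selection> concavity columns:",
      paste(x$columns, collapse = ", "), "\n")
  cat("adjacent-column dissimilarities:",
      paste(sprintf("%.2f", x$gaps), collapse = ", "), "\n")
  print(x$roles)
  invisible(x)
}

# data.frame of the subgrid shapes with diagonal-rule roles
subgrid_shapes <- function(columns = default_subgrid_columns()) {
  g <- expand.grid(conc_idx = 0:(length(columns) - 1L), alignment = 0:3,
                   KEEP.OUT.ATTRS = FALSE)
  g$concavity <- columns[g$conc_idx + 1L]
  g$role <- subgrid_roles(g$alignment, g$conc_idx)
  g[, c("concavity", "alignment", "conc_idx", "role")]
}

# cross-join target specs x distractor specs into a pair table
cross_pairs <- function(targets, distractors, protocol) {
  nt <- nrow(targets); nd <- nrow(distractors)
  ti <- rep(seq_len(nt), each = nd)
  di <- rep(seq_len(nd), times = nt)
  t2 <- targets[ti, , drop = FALSE]
  d2 <- distractors[di, , drop = FALSE]
  names(t2) <- paste0("target_", names(t2))
  names(d2) <- paste0("distractor_", names(d2))
  out <- cbind(protocol = protocol,
               pair_id = sprintf("%s_%03d", protocol, seq_len(nt * nd)),
               t2, d2, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

row_of <- function(spec) spec_to_row(spec)

variant <- function(row, ...) {
  ch <- list(...)
  for (nm in names(ch)) row[[nm]] <- ch[[nm]]
  row
}

#' Stimulus pairs of a named protocol
#'
#' Returns the full pair list of one training or testing protocol of the
#' design. The fixed protocols are determined by the sub-grid `columns`; the
#' two model-informed protocols (`zero_vs_high`, `high_vs_zero`) additionally
#' need a `selection` produced by [filter_select()], from which the protocol
#' is assembled as the cross of the k selected targets and k selected
#' distractors.
#'
#' @param name protocol name; one of `"training"`, `"dimension_learning"`,
#'   `"transformations"`, `"rotation_x"`, `"rotation_y"`, `"rotation_z"`,
#'   `"light_location"`, `"size"`, `"position"`, `"combination_rotation"`,
#'   `"zero_vs_high"`, `"high_vs_zero"`.
#' @param columns concavity columns of the 4x4 sub-grid.
#' @param selection a `pair_selection` (only for the model-informed
#'   protocols).
#' @return an object of class `protocol_def`: list with `name`, `pairs` (a
#'   data.frame with `target_*` and `distractor_*` columns) and `old_pair`
#'   (the base pair).
#' @export
#' @examples
#' nrow(protocol_pairs("rotation_x")$pairs)  # 36
#' nrow(protocol_pairs("size")$pairs)        # 4
protocol_pairs <- function(name, columns = default_subgrid_columns(),
                           selection = NULL) {
  name <- match.arg(name, PROTOCOL_NAMES)
  bp <- base_pair(columns)
  tr <- row_of(bp$target); dr <- row_of(bp$distractor)
  rot6 <- seq(30L, 180L, by = 30L)

  pairs <- switch(
    name,
    training = cross_pairs(tr, dr, name),
    dimension_learning = {
      # three pairs: the base pair plus one concavity-only and one
      # alignment-only pair from the sub-grid (ambiguity-free cells)
      conc_t <- spec_to_row(stimulus_spec(shape_params(columns[1], 1L),
                                          role = "target"))
      conc_d <- spec_to_row(stimulus_spec(shape_params(columns[4], 1L),
                                          role = "distractor"))
      alig_t <- spec_to_row(stimulus_spec(shape_params(columns[2], 0L),
                                          role = "target"))
      alig_d <- spec_to_row(stimulus_spec(shape_params(columns[2], 3L),
                                          role = "distractor"))
      p <- rbind(cross_pairs(tr, dr, name),
                 cross_pairs(conc_t, conc_d, name),
                 cross_pairs(alig_t, alig_d, name))
      p$pair_id <- sprintf("%s_%03d", name, seq_len(nrow(p)))
      p
    },
    transformations = {
      tv <- rbind(variant(tr, rot_x = 30L), variant(tr, rot_y = 30L),
                  variant(tr, rot_z = 30L),
                  variant(tr, light_location = "under"),
                  variant(tr, size_scale = 0.8))
      dv <- rbind(variant(dr, rot_x = 30L), variant(dr, rot_y = 30L),
                  variant(dr, rot_z = 30L),
                  variant(dr, light_location = "under"),
                  variant(dr, size_scale = 0.8))
      cross_pairs(tv, dv, name)
    },
    rotation_x = cross_pairs(
      do.call(rbind, lapply(rot6, function(a) variant(tr, rot_x = a))),
      do.call(rbind, lapply(rot6, function(a) variant(dr, rot_x = a))), name),
    rotation_y = cross_pairs(
      do.call(rbind, lapply(rot6, function(a) variant(tr, rot_y = a))),
      do.call(rbind, lapply(rot6, function(a) variant(dr, rot_y = a))), name),
    rotation_z = cross_pairs(
      do.call(rbind, lapply(rot6, function(a) variant(tr, rot_z = a))),
      do.call(rbind, lapply(rot6, function(a) variant(dr, rot_z = a))), name),
    light_location = {
      lights <- c("under", "left", "right", "up")
      cross_pairs(
        do.call(rbind, lapply(lights, function(l)
          variant(tr, light_location = l))),
        do.call(rbind, lapply(lights, function(l)
          variant(dr, light_location = l))), name)
    },
    size = cross_pairs(
      rbind(variant(tr, size_scale = 0.8), variant(tr, size_scale = 0.6)),
      rbind(variant(dr, size_scale = 0.8), variant(dr, size_scale = 0.6)),
      name),
    position = {
      pos <- POSITIONS
      cross_pairs(
        do.call(rbind, lapply(pos, function(p)
          variant(tr, size_scale = 0.8, position = p))),
        do.call(rbind, lapply(pos, function(p)
          variant(dr, size_scale = 0.8, position = p))), name)
    },
    combination_rotation = cross_pairs(
      do.call(rbind, lapply(rot6, function(a)
        variant(tr, rot_x = a, rot_y = a, rot_z = a))),
      do.call(rbind, lapply(rot6, function(a)
        variant(dr, rot_x = a, rot_y = a, rot_z = a))), name),
    zero_vs_high = ,
    high_vs_zero = {
      if (is.null(selection) || !inherits(selection, "pair_selection"))
        stop("the model-informed protocols need a `selection` from ",
             "filter_select()", call. = FALSE)
      if (selection$profile != name)
        stop(sprintf("selection has profile '%s' but protocol '%s' was asked",
                     selection$profile, name), call. = FALSE)
      cross_pairs(selection$targets, selection$distractors, name)
    })

  structure(list(name = name, pairs = pairs, old_pair = bp),
            class = "protocol_def")
}

PROTOCOL_NAMES <- c("training", "dimension_learning", "transformations",
                    "rotation_x", "rotation_y", "rotation_z",
                    "light_location", "size", "position",
                    "combination_rotation", "zero_vs_high", "high_vs_zero")

#' Names of the nine testing protocols
#' @return character vector in design order.
#' @export
test_protocol_names <- function() {
  c("rotation_x", "rotation_y", "rotation_z", "light_location", "size",
    "position", "combination_rotation", "zero_vs_high", "high_vs_zero")
}

#' @export
print.protocol_def <- function(x, ...) {
  cat(sprintf("<protocol_def> %s: %d pairs\n", x$name, nrow(x$pairs)))
  invisible(x)
}

#' The labelled training stimuli
#'
#' The unique stimuli of the three training protocols (training, dimension
#' learning, transformations) with their target/distractor labels: the base
#' pair, the two one-dimension pairs, and the five singly-transformed
#' variants of each base-pair member.
#'
#' @param columns concavity columns of the 4x4 sub-grid.
#' @return a data.frame of stimulus specifications with a `role` column.
#' @export
training_stimuli <- function(columns = default_subgrid_columns()) {
  prot <- lapply(c("training", "dimension_learning", "transformations"),
                 protocol_pairs, columns = columns)
  rows <- do.call(rbind, lapply(prot, function(p) {
    t_cols <- grep("^target_", names(p$pairs))
    d_cols <- grep("^distractor_", names(p$pairs))
    t <- p$pairs[, t_cols]; names(t) <- sub("^target_", "", names(t))
    d <- p$pairs[, d_cols]; names(d) <- sub("^distractor_", "", names(d))
    rbind(t, d)
  }))
  rows <- unique(rows)
  rownames(rows) <- NULL
  rows
}

#' Candidate pool for the model-informed pair search
#'
#' The pool of stimuli from which candidate target/distractor pairs are
#' sampled: a subset of the sub-grid shapes (by default three target cells
#' and three distractor cells nearest the trained corners) crossed with all
#' rotation and light-location transformations. With three shapes per side
#' this yields 3 x 7^3 x 5 = 5145 stimuli per side and 5145^2 = 26,471,025
#' ordered candidate pairs.
#'
#' @param columns concavity columns of the 4x4 sub-grid.
#' @param target_cells,distractor_cells two-column matrices of (alignment,
#'   concavity-index) sub-grid cells to include; defaults pick the three
#'   cells adjacent to each trained corner. Pool membership is configurable
#'   because the deposited design does not pin it down.
#' @return list of class `candidate_pool` with data.frames `targets` and
#'   `distractors` and the ordered pair count `n_pairs`.
#' @export
candidate_pool <- function(columns = default_subgrid_columns(),
                           target_cells = rbind(c(0, 0), c(0, 1), c(1, 0)),
                           distractor_cells = rbind(c(3, 3), c(3, 2),
                                                    c(2, 3))) {
  build <- function(cells, role) {
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      a <- cells[i, 1]; ci <- cells[i, 2]
      if (subgrid_roles(a, ci) != role)
        stop(sprintf("cell (%d, %d) is not a %s cell", a, ci, role),
             call. = FALSE)
      g <- enumerate_space(alignment = a, concavity = columns[ci + 1L])
      g$role <- role
      g
    }))
  }
  t <- build(target_cells, "target")
  d <- build(distractor_cells, "distractor")
  structure(list(targets = t, distractors = d,
                 n_pairs = as.numeric(nrow(t)) * as.numeric(nrow(d))),
            class = "candidate_pool")
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat(sprintf(
    "<candidate_pool> %d targets x %d distractors = %s ordered pairs\n",
    nrow(x$targets), nrow(x$distractors),
    format(x$n_pairs, big.mark = ",")))
  invisible(x)
}

# Render every unique spec referenced by a pair table (target_* and
# distractor_* halves); returns a named list of stimulus_images keyed by
# spec_id, using/filling `cache`.
render_pair_images <- function(pairs, cfg = render_config(),
                               cache = new.env(parent = emptyenv())) {
  halves <- lapply(c("target_", "distractor_"), function(pre) {
    cols <- grep(paste0("^", pre), names(pairs))
    h <- pairs[, cols]
    names(h) <- sub(pre, "", names(h))
    h
  })
  specs <- unique(do.call(rbind, halves))
  out <- list()
  for (i in seq_len(nrow(specs))) {
    sp <- spec_from_row(specs[i, ])
    out[[spec_id(sp)]] <- render_cached(sp, cfg, cache)
  }
  out
}
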