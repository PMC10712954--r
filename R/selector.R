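# Model-informed stimulus-pair search: sample candidate target/distractor
# pairs from the transformation pool, summarise each by its mean
# classification score over the early (1-3) and late (11-13) sublayers,
# standardise those means against the candidate population, and keep pairs
# whose profile dissociates the two processing stages (zero-vs-high or
# high-vs-zero).

EARLY_LAYERS <- 1:3
LATE_LAYERS  <- 11:13

#' Sample candidate pairs from the stimulus pool
#'
#' Draws `n_iter` target/distractor pairs uniformly with replacement from the
#' candidate pool, renders them (with caching; the pool is far larger than
#' the draw, but duplicates cost nothing), and records each candidate's mean
#' classification score over the early (1-3) and late (11-13) sublayers.
#' Duplicate draws are collapsed.
#'
#' @param pool a [candidate_pool()].
#' @param ensemble fitted `decoder_ensemble`.
#' @param n_iter number of random draws (the design default is 10,000).
#' @param cfg render configuration.
#' @param seed sampling seed.
#' @param cache optional render cache environment.
#' @return a data.frame of class `candidate_set`: one row per unique
#'   candidate with target/distractor indices, `early_mean`, `late_mean` and
#'   per-layer scores.
#' @export
sample_candidates <- function(pool, ensemble, n_iter = 10000L,
                              cfg = render_config(), seed = NULL,
                              cache = new.env(parent = emptyenv())) {
  stopifnot(inherits(pool, "candidate_pool"))
  if (nrow(pool$targets) == 0L || nrow(pool$distractors) == 0L)
    stop("empty candidate pool", call. = FALSE)
  draws <- with_seed(seed, data.frame(
    ti = sample.int(nrow(pool$targets), n_iter, replace = TRUE),
    di = sample.int(nrow(pool$distractors), n_iter, replace = TRUE)))
  draws <- unique(draws)

  # distances of every unique stimulus referenced by the draws
  uniq_t <- sort(unique(draws$ti)); uniq_d <- sort(unique(draws$di))
  dist_for <- function(rows) {
    imgs <- lapply(seq_len(nrow(rows)), function(i)
      render_cached(spec_from_row(rows[i, ]), cfg, cache))
    predict(ensemble, imgs)
  }
  dt <- dist_for(pool$targets[uniq_t, , drop = FALSE])
  dd <- dist_for(pool$distractors[uniq_d, , drop = FALSE])
  rownames(dt) <- as.character(uniq_t)
  rownames(dd) <- as.character(uniq_d)

  scores <- dt[as.character(draws$ti), , drop = FALSE] -
    dd[as.character(draws$di), , drop = FALSE]
  out <- data.frame(target_idx = draws$ti, distractor_idx = draws$di,
                    early_mean = rowMeans(scores[, EARLY_LAYERS,
                                                 drop = FALSE]),
                    late_mean = rowMeans(scores[, LATE_LAYERS,
                                                drop = FALSE]))
  colnames(scores) <- paste0("score_", colnames(scores))
  out <- cbind(out, as.data.frame(scores))
  rownames(out) <- NULL
  attr(out, "pool") <- pool
  class(out) <- c("candidate_set", class(out))
  out
}

#' Standardise candidate scores
#'
#' Expresses each candidate's early- and late-layer mean classification
#' scores relative to the spread of the candidate population: the mean is
#' divided by the population standard deviation of the corresponding means
#' across all candidates.
#'
#' @param candidates a `candidate_set` from [sample_candidates()].
#' @return the candidate set with `early_z` and `late_z` columns; the two
#'   population SDs are attached as attribute `"sds"`.
#' @export
standardize_candidates <- function(candidates) {
  if (nrow(candidates) < 2L)
    stop("need at least two candidates to standardise", call. = FALSE)
  sd_e <- sd_pop(candidates$early_mean)
  sd_l <- sd_pop(candidates$late_mean)
  if (sd_e == 0 || sd_l == 0)
    stop("degenerate candidate population (zero spread)", call. = FALSE)
  candidates$early_z <- candidates$early_mean / sd_e
  candidates$late_z <- candidates$late_mean / sd_l
  attr(candidates, "sds") <- c(early = sd_e, late = sd_l)
  candidates
}

#' Selection criteria for the dissociating profiles
#'
#' @param profile `"zero_vs_high"` (early scores near zero, late scores
#'   high) or `"high_vs_zero"` (the reverse).
#' @param tau_zero maximum |z| of the near-zero side (SD units).
#' @param tau_high minimum z of the high side (SD units).
#' @param k stimulus pairs to keep (default 7 per profile).
#' @return a list of class `selection_criteria`.
#' @export
selection_criteria <- function(profile = c("zero_vs_high", "high_vs_zero"),
                               tau_zero = 0.5, tau_high = 1.5, k = 7L) {
  profile <- match.arg(profile)
  if (!(tau_zero < tau_high))
    stop("`tau_zero` must be smaller than `tau_high`", call. = FALSE)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  structure(list(profile = profile, tau_zero = tau_zero,
                 tau_high = tau_high, k = as.integer(k)),
            class = "selection_criteria")
}

#' Filter and rank candidates into a dissociating selection
#'
#' Keeps candidates matching the requested profile — `zero_vs_high`:
#' |early_z| <= tau_zero and late_z >= tau_high; `high_vs_zero`: |late_z| <=
#' tau_zero and early_z >= tau_high — ranks them by the high-side z
#' (descending, ties broken by candidate order), and greedily picks the top
#' `k` pairs with pairwise-distinct targets and distractors, so that the
#' protocol can be assembled as the k x k cross of the selected stimuli.
#'
#' @param candidates a standardised `candidate_set` (from
#'   [standardize_candidates()]; raw sets are standardised on the fly).
#' @param criteria a [selection_criteria()].
#' @return a list of class `pair_selection`: `profile`, `pairs` (the chosen
#'   candidate rows with z values), `targets` and `distractors` (spec
#'   data.frames for [protocol_pairs()]), `n_survivors` (size of the full
#'   filtered set), `sds`, `criteria`, and `short` = TRUE with a warning if
#'   fewer than `k` eligible pairs existed.
#' @export
filter_select <- function(candidates, criteria = selection_criteria()) {
  stopifnot(inherits(candidates, "candidate_set"),
            inherits(criteria, "selection_criteria"))
  if (is.null(candidates$early_z))
    candidates <- standardize_candidates(candidates)
  pool <- attr(candidates, "pool")

  keep <- if (criteria$profile == "zero_vs_high") {
    abs(candidates$early_z) <= criteria$tau_zero &
      candidates$late_z >= criteria$tau_high
  } else {
    abs(candidates$late_z) <= criteria$tau_zero &
      candidates$early_z >= criteria$tau_high
  }
  surv <- candidates[keep, , drop = FALSE]
  # rank by the profile contrast: the high-side z minus the magnitude of the
  # near-zero side. Ranking by the high side alone leaves the "zero" side
  # biased toward the population bulk (its z is not centred), which would
  # make the assembled protocol systematically solvable by the layers meant
  # to be at chance.
  contrast <- if (criteria$profile == "zero_vs_high")
    surv$late_z - abs(surv$early_z) else surv$early_z - abs(surv$late_z)
  surv <- surv[order(-contrast, surv$target_idx, surv$distractor_idx), ,
               drop = FALSE]

  picked <- integer(0)
  seen_t <- integer(0); seen_d <- integer(0)
  for (i in seq_len(nrow(surv))) {
    if (length(picked) >= criteria$k) break
    if (surv$target_idx[i] %in% seen_t ||
        surv$distractor_idx[i] %in% seen_d) next
    picked <- c(picked, i)
    seen_t <- c(seen_t, surv$target_idx[i])
    seen_d <- c(seen_d, surv$distractor_idx[i])
  }
  short <- length(picked) < criteria$k
  if (short)
    warning(sprintf(
      "only %d of the requested %d pairs available for profile %s",
      length(picked), criteria$k, criteria$profile), call. = FALSE)
  sel <- surv[picked, , drop = FALSE]
  targets <- pool$targets[sel$target_idx, , drop = FALSE]
  distractors <- pool$distractors[sel$distractor_idx, , drop = FALSE]
  rownames(targets) <- rownames(distractors) <- NULL
  structure(list(profile = criteria$profile, pairs = sel,
                 targets = targets, distractors = distractors,
                 n_survivors = nrow(surv), sds = attr(candidates, "sds"),
                 criteria = criteria, short = short),
            class = "pair_selection")
}

#' @export
print.pair_selection <- function(x, ...) {
  cat(sprintf(
    "<pair_selection> %s: %d of %d survivors kept (tau_zero %.2f, tau_high %.2f)\n",
    x$profile, nrow(x$pairs), x$n_survivors, x$criteria$tau_zero,
    x$criteria$tau_high))
  if (nrow(x$pairs)) {
    cols <- c("target_idx", "distractor_idx", "early_z", "late_z")
    print(x$pairs[, cols], digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Build both model-informed test protocols
#'
#' Convenience wrapper: samples candidates once, standardises them, selects
#' the `zero_vs_high` and `high_vs_zero` profiles, and assembles the two
#' k x k protocols.
#'
#' @param pool a [candidate_pool()].
#' @param ensemble fitted `decoder_ensemble`.
#' @param n_iter candidate draws.
#' @param tau_zero,tau_high,k selection thresholds (see
#'   [selection_criteria()]).
#' @param cfg,seed,cache as in [sample_candidates()].
#' @return list with `zero_vs_high` and `high_vs_zero` (`protocol_def`s),
#'   the two `pair_selection`s, and the candidate set.
#' @export
informed_protocols <- function(pool, ensemble, n_iter = 10000L,
                               tau_zero = 0.5, tau_high = 1.5, k = 7L,
                               cfg = render_config(), seed = NULL,
                               cache = new.env(parent = emptyenv())) {
  cand <- sample_candidates(pool, ensemble, n_iter, cfg, seed, cache)
  cand <- standardize_candidates(cand)
  sel_zh <- filter_select(cand, selection_criteria("zero_vs_high", tau_zero,
                                                   tau_high, k))
  sel_hz <- filter_select(cand, selection_criteria("high_vs_zero", tau_zero,
                                                   tau_high, k))
  list(zero_vs_high = protocol_pairs("zero_vs_high", selection = sel_zh),
       high_vs_zero = protocol_pairs("high_vs_zero", selection = sel_hz),
       selection_zero_vs_high = sel_zh, selection_high_vs_zero = sel_hz,
       candidates = cand)
}
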