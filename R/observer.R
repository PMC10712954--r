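# Synthetic observers: trial-level choice behaviour driven by a weighted
# combination of the decoder's layer scores through a probit choice rule
# with a lapse rate, embedded in the touchscreen session structure (old
# trials, correction trials, random reward).

#' Construct an observer model
#'
#' An observer converts the 13 per-sublayer classification scores of a
#' stimulus pair into a probability of choosing the target:
#' p = lambda / 2 + (1 - lambda) * Phi(sum(w_l * s_l) / sigma),
#' where w is a simplex of layer weights (which processing stages drive the
#' choice), sigma the decision noise and lambda the lapse rate (fraction of
#' trials answered at random).
#'
#' @param layer_weights 13 non-negative weights; normalised to sum to 1.
#' @param decision_noise positive probit noise sigma, in classification-score
#'   units.
#' @param lapse lapse rate in \[0, 1\].
#' @param species free-text tag (e.g. `"rat"`, `"human"`).
#' @return an object of class `observer_model`.
#' @export
observer_model <- function(layer_weights, decision_noise, lapse = 0,
                           species = "custom") {
  if (length(layer_weights) != 13L || any(layer_weights < 0) ||
      sum(layer_weights) <= 0)
    stop("`layer_weights` must be 13 non-negative values with positive sum",
         call. = FALSE)
  if (decision_noise <= 0)
    stop("`decision_noise` must be positive", call. = FALSE)
  stop_if_not_scalar_prob(lapse, "lapse")
  structure(list(layer_weights = layer_weights / sum(layer_weights),
                 decision_noise = decision_noise, lapse = lapse,
                 species = species),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  on <- which(x$layer_weights > 0)
  cat(sprintf(
    "<observer_model> %s: weights on sublayers %s, sigma %.3g, lapse %.2f\n",
    x$species, paste(range(on), collapse = "-"), x$decision_noise, x$lapse))
  invisible(x)
}

#' Rat-like and human-like observer presets
#'
#' Two illustrative observers bracketing the strategies of interest: the
#' rat-like observer reads out the convolutional sublayers 4-10 (with a
#' triangular profile decaying toward the deeper stages, so that the larger
#' score variance of the deep stages does not dominate the drive) and a high
#' lapse rate; the human-like observer reads out the fully connected
#' sublayers 11-13 with a low lapse rate. The decision-noise values are
#' relative sigmas: they are meant to be scaled by the across-pair spread of
#' the observer's weighted score (see [normalize_decision_noise()]; done
#' automatically by [simulate_study()]), which makes the presets transfer
#' across backbones and noise calibrations. They parameterise a synthetic
#' stand-in for real behaviour, not a fitted model; with the calibrated
#' decoder they place the rat-like observer near the low-60% regime and give
#' the human-like observer near-ceiling accuracy whenever its late-layer
#' scores support the choice.
#'
#' @param rat_noise,human_noise relative decision-noise sigmas.
#' @param rat_lapse,human_lapse lapse rates of the two presets.
#' @return list with elements `rat_like` and `human_like`.
#' @export
species_presets <- function(rat_noise = 2.0, human_noise = 0.5,
                            rat_lapse = 0.3, human_lapse = 0.05) {
  w_rat <- numeric(13); w_rat[4:10] <- 7:1
  w_hum <- numeric(13); w_hum[11:13] <- 1
  list(rat_like = observer_model(w_rat, rat_noise, rat_lapse, "rat"),
       human_like = observer_model(w_hum, human_noise, human_lapse,
                                   "human"))
}

#' Express an observer's decision noise in score units
#'
#' Rescales the observer's (relative) decision noise by the population SD of
#' its weighted score across a set of scored pairs, returning an observer
#' whose `decision_noise` is in absolute classification-score units.
#'
#' @param observer an [observer_model()].
#' @param scores pair x 13 score matrix or long [score_pairs()] table.
#' @return the observer with absolute `decision_noise`.
#' @export
normalize_decision_noise <- function(observer, scores) {
  m <- score_matrix(scores)
  drive <- drop(m %*% observer$layer_weights)
  s <- sd_pop(drive)
  if (s == 0) stop("zero spread of the weighted score", call. = FALSE)
  observer$decision_noise <- observer$decision_noise * s
  observer
}

#' Choice probability of an observer on scored pairs
#'
#' @param observer an [observer_model()].
#' @param pair_scores a 13-vector of per-sublayer classification scores, or
#'   a matrix with 13 columns (one row per pair).
#' @return probability (vector) of choosing the target.
#' @export
choice_probability <- function(observer, pair_scores) {
  if (is.null(dim(pair_scores)))
    pair_scores <- matrix(pair_scores, nrow = 1)
  stopifnot(ncol(pair_scores) == 13L, all(is.finite(pair_scores)))
  drive <- drop(pair_scores %*% observer$layer_weights)
  observer$lapse / 2 +
    (1 - observer$lapse) * stats::pnorm(drive / observer$decision_noise)
}

#' Session configuration
#'
#' The session structure of the touchscreen task: training sessions run 100
#' trials with veridical reward and correction trials after every error;
#' testing sessions run 120 trials of which one-third are old (base-pair)
#' trials with veridical reward and corrections, while new trials earn
#' random reward in 80% of cases and no corrections.
#'
#' @param phase `"testing"` or `"training"`.
#' @param max_trials first-presentation trials per session.
#' @param old_fraction fraction of old (base-pair) trials.
#' @param random_reward_rate reward probability on new trials in testing.
#' @param correction_trials `"all"`, `"old_only"` or `"none"`.
#' @param base_pair_exclusion_threshold minimum session accuracy on the base
#'   pair below which a test session is excluded from analysis.
#' @return a list of class `session_config`.
#' @export
session_config <- function(phase = c("testing", "training"),
                           max_trials = NULL, old_fraction = NULL,
                           random_reward_rate = 0.8,
                           correction_trials = NULL,
                           base_pair_exclusion_threshold = 0.65) {
  phase <- match.arg(phase)
  max_trials <- max_trials %||% if (phase == "testing") 120L else 100L
  old_fraction <- old_fraction %||% if (phase == "testing") 1 / 3 else 0
  correction_trials <- correction_trials %||%
    if (phase == "testing") "old_only" else "all"
  correction_trials <- match.arg(correction_trials,
                                 c("all", "old_only", "none"))
  stop_if_not_scalar_prob(old_fraction, "old_fraction")
  stop_if_not_scalar_prob(random_reward_rate, "random_reward_rate")
  stopifnot(max_trials >= 1L)
  structure(list(phase = phase, max_trials = as.integer(max_trials),
                 old_fraction = old_fraction,
                 random_reward_rate = random_reward_rate,
                 correction_trials = correction_trials,
                 base_pair_exclusion_threshold =
                   base_pair_exclusion_threshold),
            class = "session_config")
}

#' Wide score matrix of a score table
#'
#' Reshapes a long [score_pairs()] table into a pair x sublayer matrix of
#' classification scores (rownames = pair ids). Matrices pass through
#' unchanged.
#'
#' @param scores long score table or a matrix.
#' @return numeric matrix, pairs x sublayers.
#' @export
score_matrix <- function(scores) {
  if (is.matrix(scores)) return(scores)
  ids <- unique(scores$pair_id)
  layers <- unique(scores$layer)
  m <- matrix(NA_real_, length(ids), length(layers),
              dimnames = list(ids, layers))
  m[cbind(match(scores$pair_id, ids), match(scores$layer, layers))] <-
    scores$classification_score
  m
}

#' Simulate behavioural sessions
#'
#' Generates trial-level records for one observer on one protocol. New
#' trials draw a pair uniformly from the protocol; old trials present the
#' base pair. Choices are Bernoulli draws from [choice_probability()];
#' incorrect trials are followed by correction trials (repeats of the same
#' pair until correct, capped) where the session structure enables them.
#' Random reward on new test trials affects the `rewarded` flag only, never
#' correctness.
#'
#' @param observer an [observer_model()].
#' @param scores score table of the protocol's pairs (long data.frame from
#'   [score_pairs()] or a pair x 13 matrix with pair ids as rownames).
#' @param old_scores 13-vector of base-pair scores (required when
#'   `config$old_fraction > 0`).
#' @param config a [session_config()].
#' @param n_sessions number of sessions.
#' @param protocol protocol label for the records.
#' @param subject subject id label.
#' @param seed RNG seed.
#' @param max_corrections cap on consecutive correction trials.
#' @return a `trial table`: data.frame with columns `subject`, `species`,
#'   `protocol`, `session`, `pair_id`, `is_old`, `is_correction`, `correct`,
#'   `rewarded`.
#' @export
simulate_sessions <- function(observer, scores, old_scores = NULL,
                              config = session_config(), n_sessions = 1L,
                              protocol = "protocol", subject = "s1",
                              seed = NULL, max_corrections = 25L) {
  m <- score_matrix(scores)
  if (anyNA(m)) stop("unscored pair encountered", call. = FALSE)
  p_new <- choice_probability(observer, m)
  names(p_new) <- rownames(m)
  if (config$old_fraction > 0 && is.null(old_scores))
    stop("`old_scores` needed when sessions include old trials",
         call. = FALSE)
  p_old <- if (!is.null(old_scores))
    choice_probability(observer, old_scores) else NA_real_

  with_seed(seed, {
    recs <- vector("list", n_sessions)
    for (s in seq_len(n_sessions)) {
      nt <- config$max_trials
      n_old <- round(config$old_fraction * nt)
      is_old <- rep(FALSE, nt)
      if (n_old > 0) is_old[sample.int(nt, n_old)] <- TRUE
      pair <- ifelse(is_old, "old", sample(rownames(m), nt, replace = TRUE))
      p <- ifelse(is_old, p_old, p_new[pair])
      correct <- stats::runif(nt) < p
      rewarded <- ifelse(is_old | config$phase == "training",
                         correct,
                         stats::runif(nt) < config$random_reward_rate)
      corr_on <- switch(config$correction_trials,
                        all = rep(TRUE, nt),
                        old_only = is_old,
                        none = rep(FALSE, nt))
      # a correction run repeats the pair until correct (capped): its length
      # is 1 + a geometric number of failures, all trials incorrect but the
      # last
      err <- which(!correct & corr_on)
      n_corr <- integer(nt)
      last_ok <- rep(TRUE, nt)
      if (length(err)) {
        k <- 1L + stats::rgeom(length(err), pmax(p[err], 1e-12))
        capped <- k > max_corrections
        k[capped] <- max_corrections
        n_corr[err] <- k
        last_ok[err] <- !capped | (stats::runif(length(err)) < p[err])
      }
      reps <- 1L + n_corr
      idx <- rep(seq_len(nt), times = reps)
      pos <- sequence(reps)              # 1 = first presentation
      is_corr <- pos > 1L
      corr_correct <- pos == reps[idx] & last_ok[idx]  # only the run's last
      recs[[s]] <- data.frame(
        subject = subject, species = observer$species, protocol = protocol,
        session = s, pair_id = pair[idx], is_old = is_old[idx],
        is_correction = is_corr,
        correct = ifelse(is_corr, corr_correct, correct[idx]),
        rewarded = ifelse(is_corr, corr_correct, rewarded[idx]),
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, recs)
    rownames(tab) <- NULL
    tab
  })
}

#' @rdname simulate_sessions
#' @param object an `observer_model` (for the `simulate` method).
#' @param nsim number of sessions.
#' @param ... passed on to `simulate_sessions()`.
#' @export
simulate.observer_model <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_sessions(object, n_sessions = nsim, seed = seed, ...)
}

#' Simulate a full multi-protocol study
#'
#' Runs several subjects of one observer type through the training protocol
#' and all supplied test protocols, producing one pooled trial table.
#'
#' @param observer an [observer_model()] used for every subject.
#' @param ensemble fitted `decoder_ensemble` used to score the pairs.
#' @param protocols named list of `protocol_def`s (the test protocols).
#' @param n_subjects number of simulated subjects.
#' @param sessions_per_protocol test sessions per subject per protocol.
#' @param training_sessions training sessions per subject.
#' @param cfg,cache rendering configuration/cache.
#' @param seed master seed; per-subject/protocol seeds are derived from it.
#' @param normalize_noise treat the observer's decision noise as relative
#'   and rescale it by the across-pair SD of its weighted score over all
#'   supplied protocols (see [normalize_decision_noise()]).
#' @return a pooled trial table (see [simulate_sessions()]).
#' @export
simulate_study <- function(observer, ensemble, protocols, n_subjects = 3L,
                           sessions_per_protocol = 2L,
                           training_sessions = 1L, cfg = render_config(),
                           seed = NULL,
                           cache = new.env(parent = emptyenv()),
                           normalize_noise = TRUE) {
  bp <- base_pair()
  old_scores <- classification_score(
    ensemble, render_cached(bp$target, cfg, cache),
    render_cached(bp$distractor, cfg, cache))
  train_def <- protocol_pairs("training")
  train_scores <- score_matrix(score_pairs(ensemble, train_def, cfg, cache))
  score_tabs <- lapply(protocols, function(p)
    score_matrix(score_pairs(ensemble, p, cfg, cache)))
  if (normalize_noise)
    observer <- normalize_decision_noise(observer, do.call(rbind,
                                                           score_tabs))

  tabs <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("%s%02d", substr(observer$species, 1, 1), s)
    tabs[[length(tabs) + 1L]] <- simulate_sessions(
      observer, train_scores, old_scores = NULL,
      config = session_config("training"), n_sessions = training_sessions,
      protocol = "training", subject = sid,
      seed = derive_seed(seed, paste0(sid, "-training")))
    for (pn in names(protocols)) {
      tabs[[length(tabs) + 1L]] <- simulate_sessions(
        observer, score_tabs[[pn]], old_scores = old_scores,
        config = session_config("testing"),
        n_sessions = sessions_per_protocol, protocol = pn, subject = sid,
        seed = derive_seed(seed, paste0(sid, "-", pn)))
    }
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
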