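# Statistical analyses of trial tables and score tables: per-pair accuracy
# matrices with the design's exclusion rules, exact chance tests, layer-wise
# correlation profiles with permutation tests, split-half reliability with
# the Spearman-Brown prophecy, combined cross-dataset reliability, the
# 13-regressor layer regression, low-level image predictors (brightness,
# pixel similarity), and the species comparison.

#' Per-pair accuracy table with exclusion rules
#'
#' Computes per-pair accuracies for one protocol after applying the design's
#' exclusion rules: correction trials are always dropped; test sessions
#' whose base-pair (old-trial) accuracy falls below the exclusion threshold
#' are dropped entirely; old trials never enter the per-pair accuracies and
#' are reported separately.
#'
#' @param trials a trial table (see [simulate_sessions()]).
#' @param protocol protocol name to analyse.
#' @param threshold base-pair session-exclusion threshold (default 0.65).
#' @return list of class `performance_table`: `pairs` (data.frame `pair_id`,
#'   `n`, `correct`, `accuracy`), `old` (old-trial accuracy and count),
#'   `excluded_sessions`, `protocol`.
#' @export
accuracy_table <- function(trials, protocol, threshold = 0.65) {
  tt <- trials[trials$protocol == protocol, , drop = FALSE]
  if (!nrow(tt)) stop("protocol not present in trial table: ", protocol,
                      call. = FALSE)
  tt <- tt[!tt$is_correction, , drop = FALSE]
  degenerate_table <- function(old_acc = NA_real_, old_n = 0,
                               excluded = character(0)) {
    structure(list(pairs = data.frame(pair_id = character(0),
                                      n = integer(0), correct = integer(0),
                                      accuracy = numeric(0)),
                   old = c(accuracy = old_acc, n = old_n),
                   excluded_sessions = excluded, degenerate = TRUE,
                   protocol = protocol),
              class = "performance_table")
  }
  if (!nrow(tt)) return(degenerate_table())

  skey <- paste(tt$subject, tt$session)
  excluded <- character(0)
  old <- tt[tt$is_old, , drop = FALSE]
  if (nrow(old)) {
    acc_by_session <- tapply(old$correct, paste(old$subject, old$session),
                             mean)
    excluded <- names(acc_by_session)[acc_by_session < threshold]
    tt <- tt[!(skey %in% excluded), , drop = FALSE]
  }
  new <- tt[!tt$is_old, , drop = FALSE]
  if (!nrow(new)) {
    old2 <- tt[tt$is_old, , drop = FALSE]
    return(degenerate_table(if (nrow(old2)) mean(old2$correct) else
                              NA_real_, nrow(old2), excluded))
  }
  agg <- stats::aggregate(correct ~ pair_id, data = new,
                          FUN = function(x) c(n = length(x), k = sum(x)))
  pairs <- data.frame(pair_id = agg$pair_id,
                      n = agg$correct[, "n"],
                      correct = agg$correct[, "k"])
  pairs$accuracy <- pairs$correct / pairs$n
  old2 <- tt[tt$is_old, , drop = FALSE]
  structure(list(pairs = pairs,
                 old = c(accuracy = if (nrow(old2)) mean(old2$correct)
                                    else NA_real_,
                         n = nrow(old2)),
                 excluded_sessions = excluded, degenerate = FALSE,
                 protocol = protocol),
            class = "performance_table")
}

#' @export
print.performance_table <- function(x, ...) {
  cat(sprintf("<performance_table> %s: %d pairs", x$protocol,
              nrow(x$pairs)))
  if (nrow(x$pairs))
    cat(sprintf(", pooled accuracy %.3f",
                sum(x$pairs$correct) / sum(x$pairs$n)))
  if (length(x$excluded_sessions))
    cat(sprintf(", %d sessions excluded", length(x$excluded_sessions)))
  cat("\n")
  invisible(x)
}

#' Exact binomial test against chance
#'
#' Two-sided exact binomial test of k successes in n trials against a null
#' proportion, with the Clopper-Pearson 95% confidence interval.
#'
#' @param k,n successes and trials.
#' @param p0 null proportion (default 0.5, chance level).
#' @return list: `p_value`, `estimate`, `ci` (length 2), `k`, `n`.
#' @export
binomial_chance_test <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n, n >= 1)
  bt <- stats::binom.test(k, n, p = p0)
  list(p_value = bt$p.value, estimate = unname(bt$estimate),
       ci = as.numeric(bt$conf.int), k = k, n = n)
}

#' Per-layer correlation profile with permutation test
#'
#' Pearson correlation, per sublayer, between the per-pair behavioural
#' accuracies and the per-pair classification scores, with a one-sided
#' permutation test: the accuracy vector is permuted `n_perm` times and the
#' p-value is the (add-one corrected) fraction of permuted correlations at
#' least as large as the observed one.
#'
#' @param accuracies numeric vector of per-pair accuracies.
#' @param scores matrix of pair x sublayer classification scores (rows
#'   aligned with `accuracies`).
#' @param n_perm number of permutations (design default 1000).
#' @param seed permutation seed.
#' @return data.frame of class `correlation_profile`: `sublayer`, `layer`,
#'   `r`, `p_value`, `n_perm`, plus attribute `"n_pairs"`.
#' @export
layer_correlation_profile <- function(accuracies, scores, n_perm = 1000L,
                                      seed = NULL) {
  scores <- as.matrix(scores)
  stopifnot(length(accuracies) == nrow(scores))
  ok <- is.finite(accuracies) & apply(is.finite(scores), 1, all)
  a <- accuracies[ok]; s <- scores[ok, , drop = FALSE]
  if (length(a) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (n_perm < 1L) stop("`n_perm` must be positive", call. = FALSE)
  r_obs <- drop(stats::cor(a, s))
  perm_ge <- integer(ncol(s))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      r_b <- drop(stats::cor(sample(a), s))
      perm_ge <- perm_ge + (r_b >= r_obs)
    }
  })
  out <- data.frame(sublayer = seq_len(ncol(s)),
                    layer = colnames(s) %||% paste0("L", seq_len(ncol(s))),
                    r = r_obs,
                    p_value = (perm_ge + 1) / (n_perm + 1),
                    n_perm = n_perm, row.names = NULL)
  attr(out, "n_pairs") <- length(a)
  class(out) <- c("correlation_profile", class(out))
  out
}

#' Plot a correlation profile
#'
#' @param x a `correlation_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.correlation_profile <- function(x, ...) {
  graphics::plot(x$sublayer, x$r, type = "b", xlab = "sublayer",
                 ylab = "Pearson r", ylim = range(c(0, x$r)), ...)
  graphics::abline(h = 0, lty = 2)
  sig <- x$p_value < 0.05
  if (any(sig)) graphics::points(x$sublayer[sig], x$r[sig], pch = 16)
  invisible(x)
}

#' Split-half reliability of per-pair accuracies
#'
#' For each of `n_splits` random splits, the (non-correction, non-old)
#' trials of every pair are halved at random, per-pair accuracies are
#' computed in each half, and the two accuracy vectors are correlated across
#' pairs; the mean correlation over splits is returned.
#'
#' @param trials trial table restricted to the protocols of interest.
#' @param n_splits random splits (default 100).
#' @param seed split seed.
#' @return list of class `reliability`: `split_half_r`, `full_set_r`
#'   (Spearman-Brown corrected), `n_splits`, `n_pairs`.
#' @export
split_half_reliability <- function(trials, n_splits = 100L, seed = NULL) {
  tt <- trials[!trials$is_correction & !trials$is_old, , drop = FALSE]
  byp <- split(tt$correct, tt$pair_id)
  byp <- byp[vapply(byp, length, integer(1)) >= 2L]
  if (length(byp) < 3L)
    stop("need >= 3 pairs with >= 2 usable trials", call. = FALSE)
  rs <- with_seed(seed, vapply(seq_len(n_splits), function(b) {
    h <- vapply(byp, function(x) {
      n <- length(x)
      i <- sample.int(n, n %/% 2)
      c(mean(x[i]), mean(x[-i]))
    }, numeric(2))
    suppressWarnings(stats::cor(h[1, ], h[2, ]))
  }, numeric(1)))
  r <- mean(rs, na.rm = TRUE)
  structure(list(split_half_r = r, full_set_r = spearman_brown(r),
                 n_splits = n_splits, n_pairs = length(byp)),
            class = "reliability")
}

#' @export
print.reliability <- function(x, ...) {
  cat(sprintf(
    "<reliability> split-half r = %.3f, full-set (Spearman-Brown) r = %.3f (%d pairs, %d splits)\n",
    x$split_half_r, x$full_set_r, x$n_pairs, x$n_splits))
  invisible(x)
}

#' Spearman-Brown prophecy correction
#'
#' Extrapolates a split-half correlation to the reliability of the full test
#' (or a test lengthened by `factor`): r' = factor * r / (1 + (factor - 1) *
#' r). Monotone increasing on (-1, 1\] and fixes 0 and 1.
#'
#' @param r split-half correlation in (-1, 1\].
#' @param factor lengthening factor (default 2).
#' @return corrected correlation.
#' @export
#' @examples
#' spearman_brown(0.46)  # 0.63
spearman_brown <- function(r, factor = 2) {
  stopifnot(all(r > -1), all(r <= 1))
  factor * r / (1 + (factor - 1) * r)
}

#' Combined cross-dataset reliability
#'
#' The reliability ceiling for a correlation between two noisy datasets:
#' the geometric mean of their full-set reliabilities.
#'
#' @param r1,r2 full-set reliabilities in \[0, 1\].
#' @return sqrt(r1 * r2).
#' @export
#' @examples
#' combined_reliability(spearman_brown(0.40), spearman_brown(0.46))  # 0.60
combined_reliability <- function(r1, r2) {
  stopifnot(r1 >= 0, r1 <= 1, r2 >= 0, r2 <= 1)
  sqrt(r1 * r2)
}

#' Layer-wise multiple regression of accuracy on classification scores
#'
#' Ordinary least squares of the per-pair accuracies on the 13 per-sublayer
#' classification scores (with intercept). Reports R^2, the overall F test,
#' per-coefficient t statistics and p values, and sqrt(R^2) as the
#' correlation-scale equivalent of the model fit.
#'
#' @param accuracies per-pair accuracy vector.
#' @param scores pair x sublayer score matrix.
#' @return list of class `layer_regression`: `r_squared`, `correlation_scale`,
#'   `f_statistic`, `df`, `p_value`, `coefficients` (data.frame), `fit`.
#' @export
layer_regression <- function(accuracies, scores) {
  scores <- as.matrix(scores)
  stopifnot(length(accuracies) == nrow(scores))
  df <- data.frame(acc = accuracies, scores)
  fit <- stats::lm(acc ~ ., data = df)
  sm <- summary(fit)
  fs <- sm$fstatistic
  co <- as.data.frame(sm$coefficients[-1, , drop = FALSE])
  names(co) <- c("estimate", "se", "t", "p_value")
  co$layer <- colnames(scores) %||% rownames(co)
  structure(list(r_squared = sm$r.squared,
                 correlation_scale = sqrt(max(sm$r.squared, 0)),
                 f_statistic = unname(fs[1]),
                 df = unname(fs[2:3]),
                 p_value = if (!is.null(fs))
                   stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
                 else NA_real_,
                 coefficients = co, fit = fit),
            class = "layer_regression")
}

#' @export
print.layer_regression <- function(x, ...) {
  cat(sprintf(
    "<layer_regression> R^2 = %.3f (correlation scale %.2f), F(%d, %d) = %.2f, p = %.3g\n",
    x$r_squared, x$correlation_scale, x$df[1], x$df[2], x$f_statistic,
    x$p_value))
  invisible(x)
}

#' Brightness predictor of pair difficulty
#'
#' For every test pair, the brightness difference of the base pair minus the
#' brightness difference of the test pair:
#' (B(base target) - B(base distractor)) - (B(test target) - B(test
#' distractor)); optionally correlated with per-pair accuracies. Invariant
#' to a uniform brightness offset applied to every image.
#'
#' @param base_target,base_distractor `stimulus_image`s of the base pair.
#' @param target_images,distractor_images lists of test-pair images (aligned
#'   by pair).
#' @param accuracies optional per-pair accuracy vector to correlate with.
#' @return list: `values` (per pair), `r` (Pearson correlation with
#'   accuracy, or NA).
#' @export
brightness_predictor <- function(base_target, base_distractor,
                                 target_images, distractor_images,
                                 accuracies = NULL) {
  stopifnot(length(target_images) == length(distractor_images))
  d_base <- brightness(base_target) - brightness(base_distractor)
  d_test <- vapply(seq_along(target_images), function(i)
    brightness(target_images[[i]]) - brightness(distractor_images[[i]]),
    numeric(1))
  v <- d_base - d_test
  r <- if (!is.null(accuracies)) stats::cor(v, accuracies) else NA_real_
  list(values = v, r = r)
}

#' Pixel-similarity predictor of pair difficulty
#'
#' For every test pair, with similarity measure `sim`:
#' A = sim(base target, test distractor), B = sim(base target, test target),
#' C = sim(base distractor, test distractor), D = sim(base distractor, test
#' target); the predictor is (A + D) / 2 - (C + B) / 2 — how much the test
#' pair's stimuli resemble the *wrong* trained stimulus more than the right
#' one.
#'
#' @inheritParams brightness_predictor
#' @param sim similarity function of two images; default Pearson correlation
#'   of the flattened pixel vectors; `sim = "neg_euclidean"` uses negative
#'   [pixel_dissimilarity()].
#' @return list: `values`, `components` (A, B, C, D matrix), `r`.
#' @export
pixel_similarity_predictor <- function(base_target, base_distractor,
                                       target_images, distractor_images,
                                       accuracies = NULL,
                                       sim = c("pearson", "neg_euclidean")) {
  if (is.character(sim)) {
    sim <- switch(match.arg(sim),
                  pearson = function(a, b)
                    stats::cor(as.vector(as_pixels(a)),
                               as.vector(as_pixels(b))),
                  neg_euclidean = function(a, b) -pixel_dissimilarity(a, b))
  }
  stopifnot(length(target_images) == length(distractor_images))
  comp <- t(vapply(seq_along(target_images), function(i) {
    c(A = sim(base_target, distractor_images[[i]]),
      B = sim(base_target, target_images[[i]]),
      C = sim(base_distractor, distractor_images[[i]]),
      D = sim(base_distractor, target_images[[i]]))
  }, numeric(4)))
  v <- unname((comp[, "A"] + comp[, "D"]) / 2 -
                (comp[, "C"] + comp[, "B"]) / 2)
  r <- if (!is.null(accuracies)) stats::cor(v, accuracies) else NA_real_
  list(values = v, components = comp, r = r)
}

#' Species comparison of training-normalised test performance
#'
#' Computes per-subject training and test accuracies (correction and old
#' trials excluded), normalises each subject's test performance by
#' subtracting their training performance, and compares the two groups with
#' an unpaired t test. Additionally tests the protocol-pair contrast within
#' each species (paired t across subjects, e.g. zero-vs-high minus
#' high-vs-zero) and the species x protocol interaction (unpaired t on the
#' per-subject contrast).
#'
#' @param trials_a,trials_b trial tables of the two species/groups.
#' @param test_protocols protocols counted as test performance.
#' @param training_protocol protocol counted as training performance.
#' @param contrast length-2 protocol names for the within-species contrast.
#' @return list of class `species_comparison` with the per-subject tables
#'   and the three t tests.
#' @export
species_comparison <- function(trials_a, trials_b,
                               test_protocols = test_protocol_names(),
                               training_protocol = "training",
                               contrast = c("zero_vs_high",
                                            "high_vs_zero")) {
  per_subject <- function(tt) {
    tt <- tt[!tt$is_correction & !tt$is_old, , drop = FALSE]
    subs <- unique(tt$subject)
    do.call(rbind, lapply(subs, function(s) {
      x <- tt[tt$subject == s, , drop = FALSE]
      train <- mean(x$correct[x$protocol == training_protocol])
      test <- mean(x$correct[x$protocol %in% test_protocols])
      c1 <- mean(x$correct[x$protocol == contrast[1]])
      c2 <- mean(x$correct[x$protocol == contrast[2]])
      data.frame(subject = s, species = x$species[1], training = train,
                 test = test, normalized = test - train,
                 contrast = c1 - c2, stringsAsFactors = FALSE)
    }))
  }
  a <- per_subject(trials_a); b <- per_subject(trials_b)
  t_or_degen <- function(x, y = NULL, paired = FALSE) {
    v <- if (is.null(y)) stats::var(x) else stats::var(x) + stats::var(y)
    if (!is.finite(v) || v == 0)
      return(list(statistic = Inf, p_value = 0, degenerate = TRUE))
    tt <- if (is.null(y)) stats::t.test(x) else stats::t.test(x, y)
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter), degenerate = FALSE)
  }
  structure(list(
    subjects = rbind(a, b),
    normalized_test = t_or_degen(a$normalized, b$normalized),
    contrast_a = t_or_degen(a$contrast),
    contrast_b = t_or_degen(b$contrast),
    interaction = t_or_degen(a$contrast, b$contrast),
    contrast = contrast),
    class = "species_comparison")
}

#' @export
print.species_comparison <- function(x, ...) {
  sp <- split(x$subjects, x$subjects$species)
  for (s in names(sp))
    cat(sprintf("%s: training %.3f, test %.3f (n = %d)\n", s,
                mean(sp[[s]]$training), mean(sp[[s]]$test), nrow(sp[[s]])))
  cat(sprintf("normalized test difference: t = %.2f, p = %.3g\n",
              x$normalized_test$statistic, x$normalized_test$p_value))
  cat(sprintf("%s - %s interaction: t = %.2f, p = %.3g\n",
              x$contrast[1], x$contrast[2], x$interaction$statistic,
              x$interaction$p_value))
  invisible(x)
}
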