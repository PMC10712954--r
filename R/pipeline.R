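# End-to-end reproduction on synthetic data: stimulus generation, decoder
# fitting with noise calibration, model-informed pair selection, observer
# simulation, and the full statistical report, all driven by one seeded
# configuration and written to disk as plain-text artefacts.

#' Pipeline configuration
#'
#' One named seed per stochastic stage is derived from the master seed, so
#' identical configurations reproduce byte-identical reports.
#'
#' @param seed master seed.
#' @param noise_target,noise_iters training-accuracy target and averaging
#'   iterations of the noise calibration.
#' @param selector_iters candidate draws of the pair search.
#' @param tau_zero,tau_high,k pair-selection thresholds.
#' @param n_perm permutations of the correlation tests.
#' @param n_splits split-half repetitions.
#' @param n_subjects,sessions_per_protocol simulated study size per species.
#' @param write_images write the protocol stimuli as PNG files.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, noise_target = 0.75, noise_iters = 100L,
                       selector_iters = 10000L, tau_zero = 0.5,
                       tau_high = 1.5, k = 7L, n_perm = 1000L,
                       n_splits = 100L, n_subjects = 6L,
                       sessions_per_protocol = 4L, write_images = FALSE) {
  if (n_perm < 1L)
    stop("`n_perm` must be a positive number of permutations", call. = FALSE)
  stages <- c("calibration", "selector", "simulation-rat",
              "simulation-human", "analysis")
  structure(list(seed = as.integer(seed),
                 seeds = stats::setNames(
                   lapply(stages, function(s) derive_seed(seed, s)), stages),
                 noise_target = noise_target,
                 noise_iters = as.integer(noise_iters),
                 selector_iters = as.integer(selector_iters),
                 tau_zero = tau_zero, tau_high = tau_high, k = as.integer(k),
                 n_perm = as.integer(n_perm),
                 n_splits = as.integer(n_splits),
                 n_subjects = as.integer(n_subjects),
                 sessions_per_protocol = as.integer(sessions_per_protocol),
                 write_images = isTRUE(write_images)),
            class = "run_config")
}

#' Run the complete synthetic study and write a report
#'
#' Chains every stage of the package on synthetic data: renders the training
#' stimuli, calibrates the decoder's input noise, scores the fixed test
#' protocols, searches for the two model-informed protocols, simulates a
#' rat-like and a human-like study, and computes the full statistical report
#' (per-protocol accuracies, reliability, layer correlation profiles,
#' layer regression, low-level predictors, species comparison). All tabular
#' artefacts are CSV, the consolidated report is JSON, and a manifest with
#' MD5 hashes covers every file. Identical configurations produce identical
#' artefacts.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return (invisibly) the report list.
#' @export
reproduce <- function(config = run_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()
  stage <- function(name, expr) {
    say("[%s] ...", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  cache <- new.env(parent = emptyenv())
  cfg <- render_config()

  train <- training_stimuli()
  imgs <- stage("generate-stimuli", lapply(seq_len(nrow(train)), function(i)
    render_cached(spec_from_row(train[i, ]), cfg, cache)))

  bb <- synthetic_backbone()
  nm <- stage("train-decoder", calibrate_noise(
    bb, imgs, train$role, target = config$noise_target,
    iters = config$noise_iters, seed = config$seeds$calibration))
  ens <- nm$ensemble

  sel <- stage("select-pairs", informed_protocols(
    candidate_pool(), ens, n_iter = config$selector_iters,
    tau_zero = config$tau_zero, tau_high = config$tau_high, k = config$k,
    cfg = cfg, seed = config$seeds$selector, cache = cache))

  protocols <- c(
    stats::setNames(lapply(test_protocol_names()[1:7], protocol_pairs),
                    test_protocol_names()[1:7]),
    list(zero_vs_high = sel$zero_vs_high, high_vs_zero = sel$high_vs_zero))

  score_tab <- stage("score-pairs", do.call(rbind, lapply(protocols,
    function(p) score_pairs(ens, p, cfg, cache))))

  presets <- species_presets()
  trials_rat <- stage("simulate-rat", simulate_study(
    presets$rat_like, ens, protocols, n_subjects = config$n_subjects,
    sessions_per_protocol = config$sessions_per_protocol, cfg = cfg,
    seed = config$seeds$`simulation-rat`, cache = cache))
  trials_hum <- stage("simulate-human", simulate_study(
    presets$human_like, ens, protocols, n_subjects = config$n_subjects,
    sessions_per_protocol = config$sessions_per_protocol, cfg = cfg,
    seed = config$seeds$`simulation-human`, cache = cache))

  report <- stage("analyze", analyze_study(
    trials_rat, trials_hum, score_tab, protocols = protocols,
    n_perm = config$n_perm, n_splits = config$n_splits,
    seed = config$seeds$analysis, cache = cache, cfg = cfg))
  report$config <- unclass(config)
  report$noise <- list(sd = nm$sd, achieved = nm$achieved,
                       target = nm$target)
  report$selection <- list(
    zero_vs_high = sel$selection_zero_vs_high$pairs,
    high_vs_zero = sel$selection_high_vs_zero$pairs,
    n_survivors = c(
      zero_vs_high = sel$selection_zero_vs_high$n_survivors,
      high_vs_zero = sel$selection_high_vs_zero$n_survivors))

  utils::write.csv(score_tab, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(rbind(trials_rat, trials_hum),
                   file.path(out_dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(train, file.path(out_dir, "training_stimuli.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (config$write_images) {
    img_dir <- file.path(out_dir, "stimuli")
    dir.create(img_dir, showWarnings = FALSE)
    for (key in ls(cache))
      png::writePNG(cache[[key]]$pixels,
                    file.path(img_dir, paste0(key, ".png")))
  }
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.csv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  say("done in %.1f min", as.numeric(difftime(Sys.time(), t_start,
                                              units = "mins")))
  invisible(report)
}

# Full statistical report for a pair of simulated studies. score_tab is the
# long score table of all nine test protocols; protocols (optional) supplies
# the pair tables so the low-level image predictors can be computed.
analyze_study <- function(trials_rat, trials_hum, score_tab,
                          protocols = NULL, n_perm = 1000L,
                          n_splits = 100L, seed = NULL,
                          cfg = render_config(),
                          cache = new.env(parent = emptyenv())) {
  prots <- intersect(test_protocol_names(), unique(score_tab$protocol))
  smat <- score_matrix(score_tab)

  one_species <- function(trials, tag) {
    tabs <- lapply(prots, function(p) accuracy_table(trials, p))
    names(tabs) <- prots
    acc <- do.call(rbind, lapply(tabs, function(t) t$pairs))
    acc <- acc[match(rownames(smat), acc$pair_id), ]
    ok <- !is.na(acc$pair_id) & is.finite(acc$accuracy)
    pooled <- lapply(tabs, function(t) {
      if (!sum(t$pairs$n))
        return(list(p_value = NA_real_, estimate = NA_real_))
      binomial_chance_test(sum(t$pairs$correct), sum(t$pairs$n))
    })
    # a species can lose (almost) all usable pairs, e.g. when every session
    # trips the base-pair exclusion rule; the report then degrades to NULLs
    # instead of aborting the pipeline
    enough <- sum(ok) >= 3L
    rel <- tryCatch(split_half_reliability(
      trials[trials$protocol %in% prots, ], n_splits = n_splits,
      seed = derive_seed(seed, paste0(tag, "-split"))),
      error = function(e) NULL)
    prof <- if (enough) layer_correlation_profile(
      acc$accuracy[ok], smat[ok, , drop = FALSE], n_perm = n_perm,
      seed = derive_seed(seed, paste0(tag, "-perm")))
    reg <- if (enough)
      layer_regression(acc$accuracy[ok], smat[ok, , drop = FALSE])
    list(per_protocol = data.frame(
           protocol = prots,
           accuracy = vapply(pooled, function(b) b$estimate, numeric(1)),
           p_chance = vapply(pooled, function(b) b$p_value, numeric(1))),
         accuracies = stats::setNames(acc$accuracy[ok],
                                      acc$pair_id[ok]),
         reliability = if (!is.null(rel)) unclass(rel),
         correlation_profile = if (!is.null(prof)) as.data.frame(prof),
         regression = if (!is.null(reg))
           list(r_squared = reg$r_squared,
                correlation_scale = reg$correlation_scale,
                f_statistic = reg$f_statistic, df = reg$df,
                p_value = reg$p_value,
                coefficients = reg$coefficients))
  }
  rat <- one_species(trials_rat, "rat")
  hum <- one_species(trials_hum, "human")

  # low-level image predictors, correlated with each species' accuracies
  predictors <- NULL
  if (!is.null(protocols) && length(rat$accuracies) >= 3L) {
    bp <- base_pair()
    bt <- render_cached(bp$target, cfg, cache)
    bd <- render_cached(bp$distractor, cfg, cache)
    all_pairs <- do.call(rbind, lapply(protocols, function(p)
      if (inherits(p, "protocol_def")) p$pairs else p))
    imgs <- render_pair_images(all_pairs, cfg, cache)
    keyed <- function(prefix) lapply(seq_len(nrow(all_pairs)), function(i)
      imgs[[spec_id(spec_from_row(pair_half(all_pairs[i, ], prefix)))]])
    timgs <- keyed("target_"); dimgs <- keyed("distractor_")
    idx <- match(names(rat$accuracies), all_pairs$pair_id)
    bri <- brightness_predictor(bt, bd, timgs[idx], dimgs[idx])
    pxs <- pixel_similarity_predictor(bt, bd, timgs[idx], dimgs[idx])
    safe_cor <- function(x, y) {
      cc <- stats::complete.cases(x, y)
      if (sum(cc) >= 3) stats::cor(x[cc], y[cc]) else NA_real_
    }
    predictors <- list(
      brightness = list(values = bri$values,
                        r_rat = safe_cor(bri$values, rat$accuracies),
                        r_human = safe_cor(
                          bri$values,
                          hum$accuracies[names(rat$accuracies)])),
      pixel_similarity = list(values = pxs$values,
                              r_rat = safe_cor(pxs$values, rat$accuracies),
                              r_human = safe_cor(
                                pxs$values,
                                hum$accuracies[names(rat$accuracies)])))
  }
  shared <- intersect(names(rat$accuracies), names(hum$accuracies))
  xr <- rat$accuracies[shared]; xh <- hum$accuracies[shared]
  species_r <- if (length(shared) >= 3) stats::cor(xr, xh) else NA_real_

  comp <- species_comparison(trials_rat, trials_hum)
  list(rat = rat, human = hum,
       predictors = predictors,
       species_correlation = species_r,
       combined_reliability = combined_reliability(
         max(rat$reliability$full_set_r, 0),
         max(hum$reliability$full_set_r, 0)),
       species_comparison = list(
         subjects = comp$subjects,
         normalized_test = comp$normalized_test,
         interaction = comp$interaction))
}
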