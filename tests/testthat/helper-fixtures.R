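# Shared fixtures, built lazily once per test run. Everything is generated
# in code; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_render_cache <- function() fx("render_cache",
                                 function() new.env(parent = emptyenv()))

fx_training <- function() fx("training", function() {
  spec_df <- training_stimuli()
  imgs <- lapply(seq_len(nrow(spec_df)), function(i)
    render_cached_test(spec_from_df(spec_df[i, ])))
  list(spec_df = spec_df, images = imgs, labels = spec_df$role)
})

render_cached_test <- function(spec) {
  key <- paste0("img_", paste(unlist(spec_to_chr(spec)), collapse = "_"))
  if (is.null(.fx[[key]])) .fx[[key]] <- render_stimulus(spec)
  .fx[[key]]
}

spec_to_chr <- function(spec) {
  c(spec$shape$concavity_level, spec$shape$alignment_level,
    spec$transform$rot_x, spec$transform$rot_y, spec$transform$rot_z,
    spec$transform$light_location, spec$transform$size_scale,
    spec$transform$position)
}

# noiseless ensemble on the canonical training set
fx_ensemble <- function() fx("ensemble", function() {
  tr <- fx_training()
  fit_decoder(tr$images, tr$labels)
})

# calibrated ensemble: full 100-iteration calibration (shared by the
# acceptance tests)
fx_calibration <- function() fx("calibration", function() {
  tr <- fx_training()
  calibrate_noise(synthetic_backbone(), tr$images, tr$labels,
                  target = 0.75, iters = 100L, seed = 20230L)
})

# model-informed protocols from the calibrated ensemble
fx_selection <- function() fx("selection", function() {
  informed_protocols(candidate_pool(), fx_calibration()$ensemble,
                     n_iter = 1200L, seed = 20231L,
                     cache = fx_render_cache())
})

# all nine test protocols (fixed seven + the two informed ones)
fx_protocols <- function() fx("protocols", function() {
  sel <- fx_selection()
  c(stats::setNames(lapply(test_protocol_names()[1:7], protocol_pairs),
                    test_protocol_names()[1:7]),
    list(zero_vs_high = sel$zero_vs_high, high_vs_zero = sel$high_vs_zero))
})

# long score table of the nine test protocols under the calibrated ensemble
fx_scores <- function() fx("scores", function() {
  ens <- fx_calibration()$ensemble
  do.call(rbind, lapply(fx_protocols(), function(p)
    score_pairs(ens, p, cache = fx_render_cache())))
})

# simulated studies sized so that split-half reliability is high
fx_study <- function(species) fx(paste0("study_", species), function() {
  ens <- fx_calibration()$ensemble
  pre <- species_presets()
  obs <- if (species == "rat") pre$rat_like else pre$human_like
  simulate_study(obs, ens, fx_protocols(), n_subjects = 11L,
                 sessions_per_protocol = 20L,
                 seed = if (species == "rat") 401L else 402L,
                 cache = fx_render_cache())
})

# a minimal single-sublayer backbone honouring the backbone contract, for
# decoder unit tests on hand-made geometry
toy_backbone <- function(dim = 2L) {
  structure(list(sublayers = "lin1", dims = c(lin1 = dim),
                 input_size = dim, provenance = "toy",
                 forward = function(bb, px) list(lin1 = as.vector(px))),
            class = "backbone")
}

# tiny hand-made trial table builder
make_trials <- function(pair_id, correct, is_old = FALSE,
                        is_correction = FALSE, subject = "s1",
                        session = 1L, protocol = "p") {
  data.frame(subject = subject, species = "x", protocol = protocol,
             session = session, pair_id = pair_id, is_old = is_old,
             is_correction = is_correction, correct = correct,
             rewarded = correct, stringsAsFactors = FALSE)
}
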