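# Shared fixtures. Expensive end-to-end runs are computed lazily once per
# session and reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# uniform colour tile
solid_tile <- function(rgb, h = 64, w = 64) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# small demo cohort processed through featurization (no training)
small_cohort_run <- function(n = 8, seed = 21, effect_size = 0.3, ...) {
  cfg <- sim_config(n_donors = n, slide_px = 1024, seed = seed,
                    effect_size = effect_size, ...)
  co <- generate_cohort(cfg)
  pc <- pipeline_config(sim = cfg)
  ext <- default_extractor(pc$feature_dim)
  out <- lapply(seq_len(n), function(i) lfbmil:::process_slide(co[i, ], pc, ext))
  list(cfg = cfg, cohort = co, slides = out)
}

# the demo pipeline: the package's study conditions (120 slides, planted
# effect 0.3, label noise 0.1, 10 Monte Carlo folds)
demo_pipeline <- function() {
  fixture("demo_pipeline", function() {
    run_pipeline(pipeline_config(sim = sim_config(seed = 42)), verbose = FALSE)
  })
}

# matched null pipeline: no planted effect and permuted labels
null_pipeline <- function() {
  fixture("null_pipeline", function() {
    run_pipeline(pipeline_config(sim = sim_config(seed = 43, effect_size = 0),
                                 permute_labels = TRUE),
                 verbose = FALSE)
  })
}
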