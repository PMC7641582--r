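# Shared fixtures, built once per test run.

# A short synthetic word reused across vocoder/feature tests.
fixture_word <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synth_word_audio("w001", duration_ms = 500,
                                                   seed = 1)
    cache
  }
})

# Small prepared white/band-limited feature streams + matching neural data.
sim_encoding_dataset <- function(n_per_cell = 2, n_features = 3, n_sensors = 6,
                                 n_samples = 50, noise_sd = 0,
                                 lspec = lag_spec(), seed = 1,
                                 condition_gain = NULL, ...) {
  design <- make_design(n_per_cell, seed = seed)
  truth <- make_ground_truth(n_features, n_sensors, lspec, noise_sd = noise_sd,
                             condition_gain = condition_gain, seed = seed, ...)
  feats <- lapply(seq_len(nrow(design)), function(i) {
    prepare(synth_feature_stream(n_samples, n_features, seed = seed * 997 + i),
            lspec$fit_ms, zscore = FALSE)
  })
  neural <- synth_neural(feats, truth, design, seed = seed + 1)
  list(design = design, truth = truth, feats = feats, neural = neural,
       lspec = lspec)
}
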