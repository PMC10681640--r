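# Shared fixtures, built in code and cached per test run.

# small cohort reused across model tests
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(120, 0.6, 2, seed = 42)
    cache
  }
})

# one-region table for single-region simulations
one_region <- default_region_table(1)

# effect model with the latent-pathology and PET channels switched off:
# the clean generating model for estimator calibration simulations
calib_effect <- function(...) {
  effect_model(trend = "linear",
               latent_iim = c(t1_mu = 0, t1_sigma = 0,
                              flair_mu = 0, flair_sigma = 0),
               ...)
}

# simulate one region's model-ready data and fit one model
sim_and_fit <- function(visits, participants, effect, seed, model = "M1",
                        metric = "flair_mu",
                        region_table = one_region) {
  iim <- simulate_iim_table(visits, participants, effect, seed = seed,
                            region_table = region_table)
  morph <- simulate_morphometry(visits, participants, effect, seed = seed,
                                region_table = region_table)
  md <- assemble_model_data(iim, visits, participants, morph, region_table)
  md$value <- md[[metric]]
  fit_region(md, model, region_id = region_table$region_id[1], metric = metric)
}

# small reference atlas from mixture samples (cached)
small_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(grid_shape = c(24, 24, 24), n_regions = 8)
      hists <- lapply(1:3, function(i)
        histogram_from_samples(sample_reference_mixture(30000, spec, seed = i),
                               bins = 256))
      cache <<- list(spec = spec, atlas = build_reference(hists, n_iterations = 2))
    }
    cache
  }
})
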