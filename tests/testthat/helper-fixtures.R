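# Shared small fixtures, built once per test run.

tiny_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 2, size = 96, seed = 7, ...) {
    key <- paste(n, size, seed, ...)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_cohort(
        phantom_config(n_experiments = n, image_size = size, seed = seed, ...))
    }
    cache[[key]]
  }
})

# hand-built face geometry with exact requested fractions
demo_geometry <- function(size = 128, aar = 0.3, inf = 0.3, seed = 42) {
  withr::with_seed(seed, ttcseg:::face_geometry(
    image_size = size, radius_frac = 0.33, wall_frac = 0.5,
    aar_frac = aar, inf_frac = inf, theta_aar = stats::runif(1, 0, 2 * pi),
    fourier_out = list(amp = stats::runif(3, -0.025, 0.025),
                       phase = stats::runif(3, 0, 2 * pi)),
    fourier_in = list(amp = stats::runif(3, -0.04, 0.04),
                      phase = stats::runif(3, 0, 2 * pi))
  ))
}
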