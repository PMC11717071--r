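# Shared fixtures, all generated in code.

# tiny dataset on an arbitrary grid
toy_dataset <- function(n = 3, p = 5, seed = 11) {
  with_seed_local(seed, {
    spectral_dataset(seq(500, 900, length.out = p),
                     matrix(runif(n * p), n, p),
                     runif(n, 18, 28),
                     sample(c("A", "B"), n, replace = TRUE))
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# regression problem where y depends on 5 of `p` bands, the rest pure
# noise; signal sd is `snr` times the noise sd
informative_band_data <- function(seed, n = 120, p = 100, snr = 20,
                                  info = unique(pmax(1, round(
                                    seq(0.1, 0.9, length.out = 5) * p)))) {
  with_seed_local(seed, {
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    for (j in seq_along(info))
      X[, info[j]] <- y * snr * (0.5 + 0.1 * j) + rnorm(n)
    list(X = X, y = y, info = info)
  })
}

# smooth spectra whose response is exactly linear in the band depths
noiseless_linear_dataset <- function(seed = 1) {
  generate_synthetic(synthetic_spec(baseline_drift_sd = 0,
                                    sample_noise_sd = 0, roi_noise_sd = 0,
                                    analyte_jitter_sd = 0.3,
                                    rois_per_sample = 1, seed = seed))
}
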