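# Shared simulated fixtures, built lazily and cached for the session.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small fast library: one class, 4 species, short mass range.
small_sim_params <- function(seed = 42, ...) {
  sim_params(n_phyla = 1, n_classes_per_phylum = 1, n_genera_per_class = 4,
             n_species_per_genus = 1, n_specimens_per_species = 6,
             n_replicates = 2,
             peaks = c(phylum = 3, class = 4, genus = 3, species = 6),
             mass_range = c(2000, 8000), points_per_spectrum = 1500,
             seed = seed, ...)
}

# Library -> Hellinger specimen matrix, the full standard chain.
hellinger_matrix_from_library <- function(lib, pre = preprocess_params(),
                                          pk = peak_params()) {
  spectra <- lapply(lib$spectra, preprocess_pipeline, params = pre)
  pls <- lapply(spectra, detect_peaks, params = pk)
  binned <- bin_to_convergence(pls, pk$bin_tolerance)
  fm <- suppressWarnings(build_feature_matrix(binned, lib$manifest, "mean"))
  hellinger(fm)
}

# The full default 20-species x 8-specimen x 2-replicate library at the
# generator's default settings, processed once through the whole chain.
default_processed <- function() {
  cached("default_proc", function() {
    lib <- simulate_library(sim_params(seed = 2024))
    pre <- lapply(lib$spectra, preprocess_pipeline)
    pls <- lapply(pre, detect_peaks)
    binned <- bin_to_convergence(pls)
    hm <- hellinger(suppressWarnings(
      build_feature_matrix(binned, lib$manifest, "mean")))
    list(lib = lib, peaklists = pls, hellinger = hm)
  })
}
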