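#' Simulation parameters for synthetic fingerprint libraries
#'
#' Describes a hierarchical reference library of metazoan-like proteome
#' fingerprints. Peak masses are inherited down the taxonomy (phylum,
#' class, genus and species each contribute shared peaks), specimens
#' vary by lognormal intensity multipliers and Bernoulli peak dropout,
#' and measurements sit on a decaying exponential baseline with additive
#' Gaussian noise — the morphology of good-quality linear-mode MALDI-TOF
#' spectra in the 2-20 kDa range.
#'
#' The defaults describe a 20-species library (2 phyla x 2 classes x 5
#' genera x 1 species) with 8 specimens per species and 2 technical
#' replicates per specimen.
#'
#' @param n_phyla,n_classes_per_phylum,n_genera_per_class,n_species_per_genus
#'   Taxonomy shape (all >= 1).
#' @param n_specimens_per_species,n_replicates Library depth.
#' @param peaks Named vector: number of shared peaks contributed at each
#'   level (`phylum`, `class`, `genus`) and of `species`-specific peaks.
#' @param intensity_cv Lognormal coefficient of variation of
#'   specimen-level peak intensities (biological variability).
#' @param replicate_cv Lognormal CV of replicate-level intensity wobble
#'   (technical variability).
#' @param dropout_p Per-peak probability that a specimen lacks the peak.
#' @param mass_jitter_ppm SD of per-specimen peak-mass jitter (ppm;
#'   calibration drift).
#' @param species_intensity_scale Multiplier on species-specific peak
#'   intensities; values well below 1 create informative low-intensity
#'   peaks that a harsh SNR threshold destroys.
#' @param baseline Named vector `c(a, b)` of the baseline `a * exp(-b*m)`.
#' @param noise_sd Overall noise scale. Noise is shot-like (SD
#'   proportional to the square root of the local intensity, equal to
#'   `noise_sd/10` at intensity 100), the regime the pipeline's
#'   square-root transform is designed to stabilise.
#' @param noise_white Relative amplitude of the white (point-to-point)
#'   detector noise component.
#' @param noise_texture Relative amplitude of the smooth, bounded
#'   chemical-background texture (uniform marginal, correlated over
#'   `texture_corr_pts` grid points) that summed-shot spectra ride on.
#' @param texture_corr_pts Correlation length of the background texture
#'   in grid points.
#' @param peak_sigma Gaussian peak width (Da).
#' @param points_per_spectrum Uniform mass-grid size over `mass_range`.
#' @param mass_range Mass window (Da) of the simulated acquisitions.
#' @param min_separation Smallest allowed distance (Da) between peaks of
#'   one species (instrument resolution proxy).
#' @param seed Master seed; everything downstream derives from it.
#'
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_phyla = 2, n_classes_per_phylum = 2,
                       n_genera_per_class = 5, n_species_per_genus = 1,
                       n_specimens_per_species = 8, n_replicates = 2,
                       peaks = c(phylum = 4, class = 5, genus = 4,
                                 species = 10),
                       intensity_cv = 0.35, replicate_cv = 0.1,
                       dropout_p = 0.05, mass_jitter_ppm = 200,
                       species_intensity_scale = 1,
                       baseline = c(a = 800, b = 1.5e-4), noise_sd = 15,
                       noise_white = 0.5, noise_texture = 2.5,
                       texture_corr_pts = 10,
                       peak_sigma = 12, points_per_spectrum = 4500,
                       mass_range = c(2000, 20000), min_separation = 60,
                       seed = 1) {
  counts <- c(n_phyla, n_classes_per_phylum, n_genera_per_class,
              n_species_per_genus, n_specimens_per_species, n_replicates)
  if (any(counts < 1)) stop("all taxonomy/library counts must be >= 1")
  if (!all(c("phylum", "class", "genus", "species") %in% names(peaks)))
    stop("peaks must name phylum, class, genus and species counts")
  if (dropout_p < 0 || dropout_p > 1) stop("dropout_p must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (intensity_cv < 0 || replicate_cv < 0) stop("CVs must be >= 0")
  structure(list(n_phyla = n_phyla,
                 n_classes_per_phylum = n_classes_per_phylum,
                 n_genera_per_class = n_genera_per_class,
                 n_species_per_genus = n_species_per_genus,
                 n_specimens_per_species = n_specimens_per_species,
                 n_replicates = n_replicates, peaks = peaks,
                 intensity_cv = intensity_cv, replicate_cv = replicate_cv,
                 dropout_p = dropout_p,
                 mass_jitter_ppm = mass_jitter_ppm,
                 species_intensity_scale = species_intensity_scale,
                 baseline = baseline, noise_sd = noise_sd,
                 noise_white = noise_white,
                 noise_texture = noise_texture,
                 texture_corr_pts = as.integer(texture_corr_pts),
                 peak_sigma = peak_sigma,
                 points_per_spectrum = as.integer(points_per_spectrum),
                 mass_range = mass_range,
                 min_separation = min_separation, seed = seed),
            class = "sim_params")
}

# Draw k new peak masses uniformly in the (buffered) mass range, each at
# least min_separation from `existing` and from each other.
draw_masses <- function(k, existing, params) {
  if (k == 0L) return(numeric(0))
  lo <- params$mass_range[1L] + 3 * params$peak_sigma
  hi <- params$mass_range[2L] - 3 * params$peak_sigma
  out <- numeric(0)
  tries <- 0L
  while (length(out) < k) {
    tries <- tries + 1L
    if (tries > 1000L * k)
      stop("cannot place ", k, " peaks with min_separation ",
           params$min_separation, " in [", lo, ", ", hi, "]")
    cand <- runif(1, lo, hi)
    if (!length(c(existing, out)) ||
        min(abs(c(existing, out) - cand)) > params$min_separation)
      out <- c(out, cand)
  }
  sort(out)
}

base_intensity <- function(k) rlnorm(k, meanlog = log(800), sdlog = 0.6)

#' Generate hierarchical species fingerprint profiles
#'
#' Builds one profile per species. A species' peak set is the union of
#' peaks shared by its phylum, class and genus plus its own
#' species-specific peaks; shared peaks carry the same mass and base
#' intensity in every descendant species, so congeners resemble each
#' other more than members of different genera, and so on up the
#' hierarchy. Deterministic under the params seed.
#'
#' @param params A [sim_params()].
#' @return List of `species_profile` objects with fields `species`,
#'   `genus`, `class`, `phylum`, `peak_masses`, `base_intensities`,
#'   `peak_level`, `index`.
#' @export
make_taxonomy_profiles <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(derive_seed(params$seed, 101L))
  profiles <- list()
  idx <- 0L
  for (p in seq_len(params$n_phyla)) {
    p_name <- sprintf("P%d", p)
    p_mass <- draw_masses(params$peaks[["phylum"]], numeric(0), params)
    p_int <- base_intensity(length(p_mass))
    for (cl in seq_len(params$n_classes_per_phylum)) {
      c_name <- sprintf("%sC%d", p_name, cl)
      c_mass <- draw_masses(params$peaks[["class"]], p_mass, params)
      c_int <- base_intensity(length(c_mass))
      for (g in seq_len(params$n_genera_per_class)) {
        g_name <- sprintf("%sG%d", c_name, g)
        g_mass <- draw_masses(params$peaks[["genus"]],
                              c(p_mass, c_mass), params)
        g_int <- base_intensity(length(g_mass))
        for (s in seq_len(params$n_species_per_genus)) {
          s_name <- sprintf("%sS%d", g_name, s)
          s_mass <- draw_masses(params$peaks[["species"]],
                                c(p_mass, c_mass, g_mass), params)
          s_int <- base_intensity(length(s_mass)) *
            params$species_intensity_scale
          mass <- c(p_mass, c_mass, g_mass, s_mass)
          intens <- c(p_int, c_int, g_int, s_int)
          lev <- rep(c("phylum", "class", "genus", "species"),
                     c(length(p_mass), length(c_mass),
                       length(g_mass), length(s_mass)))
          o <- order(mass)
          idx <- idx + 1L
          profiles[[idx]] <- structure(
            list(species = s_name, genus = g_name, class = c_name,
                 phylum = p_name, sex = NA_character_,
                 peak_masses = mass[o], base_intensities = intens[o],
                 peak_level = lev[o], index = idx),
            class = "species_profile")
        }
      }
    }
  }
  profiles
}

#' Simulate one measurement of one specimen
#'
#' Gaussian-shaped peaks at the profile's (specimen-jittered) masses with
#' lognormal specimen- and replicate-level intensity multipliers and
#' Bernoulli peak dropout, on a decaying exponential baseline with
#' additive Gaussian noise, sampled on a uniform mass grid. Specimen-level
#' draws (multipliers, dropout, mass jitter) depend only on the specimen,
#' so technical replicates of one specimen agree biologically and differ
#' technically. Fully reproducible under (seed, profile, specimen,
#' replicate).
#'
#' @param profile A `species_profile` from [make_taxonomy_profiles()].
#' @param params A [sim_params()].
#' @param specimen_idx,replicate_idx Positive integer identifiers.
#' @return A [mass_spectrum()]; attribute `"truth"` holds a data frame of
#'   the specimen's jittered peak masses, simulated heights and a `kept`
#'   flag (dropout).
#' @export
simulate_spectrum <- function(profile, params, specimen_idx,
                              replicate_idx = 1L) {
  stopifnot(inherits(profile, "species_profile"),
            inherits(params, "sim_params"))
  np <- length(profile$peak_masses)
  # specimen-level biology: shared by all replicates of this specimen
  set.seed(derive_seed(params$seed, 7L, profile$index, specimen_idx))
  sln <- sqrt(log(1 + params$intensity_cv^2))
  sp_mult <- rlnorm(np, meanlog = -sln^2 / 2, sdlog = sln)
  kept <- runif(np) >= params$dropout_p
  jitter <- rnorm(np, 0, params$mass_jitter_ppm * 1e-6) *
    profile$peak_masses
  masses <- profile$peak_masses + jitter
  # replicate-level technical wobble and detector noise
  set.seed(derive_seed(params$seed, 13L, profile$index, specimen_idx,
                       replicate_idx))
  rln <- sqrt(log(1 + params$replicate_cv^2))
  rep_mult <- rlnorm(np, meanlog = -rln^2 / 2, sdlog = rln)
  heights <- profile$base_intensities * sp_mult * rep_mult
  grid <- seq(params$mass_range[1L], params$mass_range[2L],
              length.out = params$points_per_spectrum)
  step <- grid[2L] - grid[1L]
  y <- params$baseline[["a"]] * exp(-params$baseline[["b"]] * grid)
  sig <- params$peak_sigma
  for (j in which(kept)) {
    w <- which(abs(grid - masses[j]) <= 6 * sig)
    y[w] <- y[w] + heights[j] * exp(-(grid[w] - masses[j])^2 / (2 * sig^2))
  }
  if (params$noise_sd > 0) {
    n <- length(grid)
    z <- params$noise_white * rnorm(n)
    if (params$noise_texture > 0) {
      ts <- params$texture_corr_pts
      kx <- seq(-3L * ts, 3L * ts)
      kern <- exp(-kx^2 / (2 * ts^2)); kern <- kern / sum(kern)
      zt <- as.numeric(stats::filter(rnorm(n), kern, circular = TRUE))
      # bounded (uniform-marginal) smooth background: summed-shot spectra
      # ride on ripple, not on heavy-tailed point noise
      zt <- 2 * stats::pnorm(zt / stats::sd(zt)) - 1
      z <- z + params$noise_texture * zt
    }
    y <- y + z * params$noise_sd * sqrt(pmax(y, 0)) / 10
  }
  stem <- if (is.na(profile$sex)) profile$species else
    paste0(profile$species, ".", profile$sex)
  s <- mass_spectrum(grid, pmax(y, 0),
                     specimen_id = sprintf("%s_i%02d", stem, specimen_idx),
                     replicate_id = sprintf("r%d", replicate_idx),
                     species = profile$species, genus = profile$genus,
                     class = profile$class, phylum = profile$phylum,
                     sex = profile$sex)
  attr(s, "truth") <- data.frame(mass = masses, height = heights,
                                 kept = kept,
                                 level = profile$peak_level)
  s
}

#' Simulate a full reference library
#'
#' Crosses every species profile with `n_specimens_per_species` specimens
#' and `n_replicates` technical replicates. Deterministic under the
#' params seed.
#'
#' @param params A [sim_params()].
#' @param profiles Optional pre-built profiles (default
#'   [make_taxonomy_profiles()]).
#' @return A list with `spectra` (list of [mass_spectrum()]), `manifest`
#'   (the [read_collection()] schema, `file` left blank), and `truth`
#'   (per-spectrum true-peak tables).
#' @export
simulate_library <- function(params = sim_params(), profiles = NULL) {
  stopifnot(inherits(params, "sim_params"))
  profiles <- profiles %||% make_taxonomy_profiles(params)
  spectra <- list(); rows <- list(); truth <- list()
  for (pr in profiles) {
    for (i in seq_len(params$n_specimens_per_species)) {
      for (r in seq_len(params$n_replicates)) {
        s <- simulate_spectrum(pr, params, i, r)
        spectra[[length(spectra) + 1L]] <- s
        truth[[length(truth) + 1L]] <- attr(s, "truth")
        rows[[length(rows) + 1L]] <- data.frame(
          specimen_id = s$specimen_id, replicate_id = s$replicate_id,
          file = "", species = pr$species, genus = pr$genus,
          class = pr$class, phylum = pr$phylum, stringsAsFactors = FALSE)
      }
    }
  }
  list(spectra = spectra, manifest = do.call(rbind, rows), truth = truth)
}

#' Cryptic-species scenario
#'
#' Two species with identical peak masses whose intensities differ by a
#' fixed ratio on a subset of peaks — morphologically indistinguishable
#' lineages separable only through relative peak intensities.
#'
#' @param params A [sim_params()].
#' @param ratio Intensity ratio applied to every other peak of the second
#'   species (default 2.5).
#' @return A list of two `species_profile`s (same genus).
#' @export
make_cryptic_profiles <- function(params = sim_params(), ratio = 2.5) {
  base <- make_taxonomy_profiles(params)[[1L]]
  a <- base; b <- base
  a$species <- paste0(base$species, "a")
  b$species <- paste0(base$species, "b")
  b$index <- base$index + 1000L
  scale <- rep(c(ratio, 1), length.out = length(b$base_intensities))
  b$base_intensities <- b$base_intensities * scale
  list(a, b)
}

#' Sexual-dimorphism scenario
#'
#' One species in two sexes: both share the species' peak set, each sex
#' carries a few exclusive peaks, and a subset of shared peaks is
#' intensity-shifted between the sexes.
#'
#' @param params A [sim_params()].
#' @param n_sex_peaks Exclusive peaks per sex (default 3).
#' @param shift Intensity ratio applied to the first shared peaks in
#'   males (default 2).
#' @return A list of two `species_profile`s with `sex` set to
#'   `"F"` / `"M"`.
#' @export
make_sex_profiles <- function(params = sim_params(), n_sex_peaks = 3,
                              shift = 2) {
  base <- make_taxonomy_profiles(params)[[1L]]
  set.seed(derive_seed(params$seed, 777L))
  f_mass <- draw_masses(n_sex_peaks, base$peak_masses, params)
  m_mass <- draw_masses(n_sex_peaks, c(base$peak_masses, f_mass), params)
  mk <- function(sex, extra_mass, idx_off, shift_vec) {
    pr <- base
    pr$sex <- sex
    pr$index <- base$index + idx_off
    extra_int <- base_intensity(length(extra_mass))
    mass <- c(base$peak_masses, extra_mass)
    intens <- c(base$base_intensities * shift_vec, extra_int)
    lev <- c(base$peak_level, rep("sex", length(extra_mass)))
    o <- order(mass)
    pr$peak_masses <- mass[o]
    pr$base_intensities <- intens[o]
    pr$peak_level <- lev[o]
    pr
  }
  nshift <- min(4L, length(base$base_intensities))
  shift_m <- rep(1, length(base$base_intensities))
  shift_m[seq_len(nshift)] <- shift
  list(mk("F", f_mass, 2000L, rep(1, length(base$base_intensities))),
       mk("M", m_mass, 3000L, shift_m))
}

#' Match detected peaks against simulated truth
#'
#' Pairs each true (non-dropped) peak with the nearest detected peak
#' within `max(floor_da, tolerance * mass)` and reports recall (matched
#' true peaks / kept true peaks) and the spurious fraction (detected
#' peaks matching no true peak / all detected).
#'
#' @param detected A [peak_list()].
#' @param truth Truth table from [simulate_spectrum()].
#' @param tolerance Relative mass tolerance (default 0.002).
#' @param floor_da Absolute matching floor in Da (default 8, two grid
#'   steps of the default simulation grid).
#' @return A list with `recall`, `spurious`, `n_true`, `n_detected`.
#' @export
peak_recovery <- function(detected, truth, tolerance = 0.002,
                          floor_da = 8) {
  true_mass <- truth$mass[truth$kept]
  tol <- pmax(floor_da, tolerance * true_mass)
  if (!length(detected$mass))
    return(list(recall = 0, spurious = 0, n_true = length(true_mass),
                n_detected = 0L))
  matched_true <- vapply(seq_along(true_mass), function(i)
    any(abs(detected$mass - true_mass[i]) <= tol[i]), TRUE)
  tol_d <- pmax(floor_da, tolerance * detected$mass)
  matched_det <- vapply(seq_along(detected$mass), function(i)
    any(abs(true_mass - detected$mass[i]) <= tol_d[i]), TRUE)
  list(recall = if (length(true_mass)) mean(matched_true) else NA_real_,
       spurious = mean(!matched_det),
       n_true = length(true_mass), n_detected = length(detected$mass))
}
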