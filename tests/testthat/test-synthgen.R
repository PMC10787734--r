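test_that("taxonomy profiles nest correctly and share peaks by level", {
  p <- sim_params(n_phyla = 2, n_classes_per_phylum = 2,
                  n_genera_per_class = 2, n_species_per_genus = 2,
                  seed = 4)
  prof <- make_taxonomy_profiles(p)
  expect_length(prof, 16)
  expect_equal(length(unique(vapply(prof, `[[`, "", "species"))), 16)
  expect_equal(length(unique(vapply(prof, `[[`, "", "genus"))), 8)
  expect_equal(length(unique(vapply(prof, `[[`, "", "class"))), 4)
  expect_equal(length(unique(vapply(prof, `[[`, "", "phylum"))), 2)

  # congeners share exactly the phylum+class+genus peaks
  a <- prof[[1]]; b <- prof[[2]]
  expect_equal(a$genus, b$genus)
  shared <- intersect(a$peak_masses, b$peak_masses)
  expect_equal(sort(shared),
               sort(a$peak_masses[a$peak_level != "species"]))
  # different genera share only phylum+class peaks
  c_ <- prof[[3]]
  expect_equal(sort(intersect(a$peak_masses, c_$peak_masses)),
               sort(a$peak_masses[a$peak_level %in% c("phylum", "class")]))

  prof2 <- make_taxonomy_profiles(p)
  expect_identical(prof, prof2)
})

test_that("peak placement respects the mass range and resolution, or errors", {
  p <- sim_params(seed = 5)
  prof <- make_taxonomy_profiles(p)
  for (pr in prof[c(1, 10, 20)]) {
    expect_true(all(pr$peak_masses > 2000 & pr$peak_masses < 20000))
    expect_true(min(diff(sort(pr$peak_masses))) > p$min_separation)
  }
  tight <- sim_params(mass_range = c(2000, 2600), min_separation = 500,
                      seed = 5)
  expect_error(make_taxonomy_profiles(tight), "cannot place")
})

test_that("a noiseless simulation peaks exactly at the profile masses", {
  p <- sim_params(noise_sd = 0, dropout_p = 0, mass_jitter_ppm = 0,
                  baseline = c(a = 0, b = 0), seed = 6)
  pr <- make_taxonomy_profiles(p)[[1]]
  s <- simulate_spectrum(pr, p, 1, 1)
  step <- s$mass[2] - s$mass[1]
  i <- s$intensity
  locmax <- which(i > c(-1, i[-length(i)]) & i >= c(i[-1], -1) & i > 1e-9)
  expect_equal(length(locmax), length(pr$peak_masses))
  expect_true(all(abs(s$mass[locmax] -
                        sort(pr$peak_masses)) <= step + 1e-9))
})

test_that("full dropout leaves only baseline and noise", {
  p <- sim_params(dropout_p = 1, noise_sd = 0, seed = 6)
  pr <- make_taxonomy_profiles(p)[[1]]
  s <- simulate_spectrum(pr, p, 1, 1)
  expect_equal(s$intensity,
               p$baseline[["a"]] * exp(-p$baseline[["b"]] * s$mass),
               tolerance = 1e-12)
  expect_false(any(attr(s, "truth")$kept))
})

test_that("replicates share specimen biology but differ technically", {
  p <- sim_params(seed = 7)
  pr <- make_taxonomy_profiles(p)[[2]]
  r1 <- simulate_spectrum(pr, p, 1, 1)
  r2 <- simulate_spectrum(pr, p, 1, 2)
  other <- simulate_spectrum(pr, p, 2, 1)
  expect_equal(attr(r1, "truth")$kept, attr(r2, "truth")$kept)
  expect_equal(attr(r1, "truth")$mass, attr(r2, "truth")$mass)
  expect_false(isTRUE(all.equal(r1$intensity, r2$intensity)))
  expect_false(isTRUE(all.equal(attr(r1, "truth")$mass,
                                attr(other, "truth")$mass)))
  expect_identical(simulate_spectrum(pr, p, 1, 1)$intensity, r1$intensity)
})

test_that("library simulation crosses species, specimens and replicates", {
  p <- small_sim_params(seed = 8)
  lib <- simulate_library(p)
  expect_length(lib$spectra, 4 * 6 * 2)
  expect_equal(nrow(lib$manifest), length(lib$spectra))
  expect_equal(length(unique(lib$manifest$specimen_id)), 4 * 6)

  p2 <- small_sim_params(seed = 9)
  lib2 <- simulate_library(p2)
  expect_equal(lib2$manifest$species, lib$manifest$species)
  expect_false(isTRUE(all.equal(lib2$spectra[[1]]$intensity,
                                lib$spectra[[1]]$intensity)))
})

test_that("peak recovery scores a perfect detection as 1/0", {
  truth <- data.frame(mass = c(3000, 5000), height = c(1, 1),
                      kept = c(TRUE, TRUE))
  det <- peak_list(c(3001, 5002), c(1, 1), c(10, 10))
  r <- peak_recovery(det, truth)
  expect_equal(r$recall, 1)
  expect_equal(r$spurious, 0)
  det2 <- peak_list(c(3001, 9000), c(1, 1), c(10, 10))
  r2 <- peak_recovery(det2, truth)
  expect_equal(r2$recall, 0.5)
  expect_equal(r2$spurious, 0.5)
})

test_that("cryptic species differing only in intensity ratios are separable", {
  p <- sim_params(n_specimens_per_species = 12, mass_range = c(2000, 8000),
                  points_per_spectrum = 1500,
                  peaks = c(phylum = 3, class = 4, genus = 4, species = 8),
                  seed = 31)
  prof <- make_cryptic_profiles(p, ratio = 3)
  expect_equal(prof[[1]]$peak_masses, prof[[2]]$peak_masses)
  lib <- simulate_library(p, profiles = prof)
  hm <- hellinger_matrix_from_library(lib)
  m <- suppressWarnings(train_rf(hm, "species", ntree = 800, seed = 31))
  expect_lte(m$oob_error, 0.05)
})

test_that("planted sex-specific peaks surface among the top Gini ranks", {
  p <- sim_params(n_specimens_per_species = 10,
                  mass_range = c(2000, 8000), points_per_spectrum = 1500,
                  peaks = c(phylum = 3, class = 4, genus = 4, species = 8),
                  seed = 32)
  prof <- make_sex_profiles(p, n_sex_peaks = 3, shift = 2)
  expect_equal(vapply(prof, `[[`, "", "sex"), c("F", "M"))
  lib <- simulate_library(p, profiles = prof)
  hm <- hellinger_matrix_from_library(lib)
  sexes <- ifelse(grepl("\\.F_", hm$meta$specimen_id), "F", "M")
  m <- suppressWarnings(train_rf(hm, "custom", labels = sexes,
                                 ntree = 500, seed = 32))
  expect_lte(m$oob_error, 0.1)
  top <- gini_top_peaks(m, k = 10)
  planted <- unlist(lapply(prof, function(q)
    q$peak_masses[q$peak_level == "sex"]))
  hits <- vapply(planted, function(mm)
    any(abs(top$feature_mass - mm) <= 0.003 * mm), TRUE)
  expect_gte(mean(hits), 0.5)
})
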