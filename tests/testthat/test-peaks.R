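ms <- function(i, m = seq(2000, by = 10, length.out = length(i)), ...)
  mass_spectrum(m, i, ...)

pl <- function(m, int = rep(1, length(m)), id = "s1", rep_id = "r1")
  peak_list(m, int, rep(NA_real_, length(m)), specimen_id = id,
            replicate_id = rep_id)

test_that("noise is the scaled MAD, with an epsilon fallback for flat spectra", {
  s <- ms(c(1, 2, 3, 4, 100))
  expect_equal(estimate_noise(s), 1.4826)
  expect_equal(estimate_noise(ms(c(1, 2, 3, 4, 100) + 10)), 1.4826)
  expect_warning(n0 <- estimate_noise(ms(rep(3, 10))), "zero MAD")
  expect_gt(n0, 0)
  expect_lt(n0, 1e-10)
})

test_that("peak detection honours SNR threshold, window maximum and tie rule", {
  s <- ms(c(1, 2, 1, 9, 1, 4, 1))
  p1 <- detect_peaks(s, peak_params(snr = 3, hws = 1), noise = 1.0)
  expect_equal(p1$intensity, c(9, 4))
  expect_equal(p1$mass, s$mass[c(4, 6)])
  p2 <- detect_peaks(s, peak_params(snr = 3, hws = 2), noise = 1.0)
  expect_equal(p2$intensity, 9)
  p3 <- detect_peaks(s, peak_params(snr = 10, hws = 1), noise = 1.0)
  expect_length(p3, 0)
  tie <- detect_peaks(ms(c(0, 5, 5, 0)), peak_params(snr = 1, hws = 1),
                      noise = 1.0)
  expect_equal(tie$mass, ms(c(0, 5, 5, 0))$mass[2])
})

test_that("peak detection equals the naive quadratic scan on random spectra", {
  for (seed in 1:25) {
    s <- random_test_spectrum(150, seed)
    hws <- sample(1:9, 1)
    snr <- runif(1, 1, 6)
    noise <- estimate_noise(s)
    got <- detect_peaks(s, peak_params(snr = snr, hws = hws))
    want <- naive_peak_scan(s$intensity, snr, hws, noise)
    expect_equal(got$mass, s$mass[want])
  }
})

test_that("raising snr or hws never increases the peak count", {
  for (seed in 1:5) {
    s <- random_test_spectrum(300, seed)
    n_snr <- vapply(c(1, 2, 4, 8), function(q)
      length(detect_peaks(s, peak_params(snr = q, hws = 4))), 1L)
    expect_true(all(diff(n_snr) <= 0))
    n_hws <- vapply(c(1, 3, 6, 12), function(h)
      length(detect_peaks(s, peak_params(snr = 2, hws = h))), 1L)
    expect_true(all(diff(n_hws) <= 0))
  }
})

test_that("binning merges within tolerance and splits at the largest gap", {
  two <- list(pl(1000.0, id = "s1"), pl(1000.5, id = "s2"))
  b <- bin_peaks(two, 0.002)
  expect_equal(b$feature_masses, 1000.25)
  expect_equal(b$peaklists[[1]]$mass, 1000.25)
  expect_equal(b$peaklists[[2]]$mass, 1000.25)

  three <- list(pl(c(1000.0, 1003.0), id = "s1"), pl(1000.5, id = "s2"))
  b3 <- bin_peaks(three, 0.002)
  expect_equal(b3$feature_masses, c(1000.25, 1003.0))

  single <- list(pl(c(1000, 1100, 1200)))
  expect_equal(bin_peaks(single, 0.002)$feature_masses, c(1000, 1100, 1200))

  expect_error(bin_peaks(two, 0.5), "tolerance")
  expect_error(bin_peaks(list(pl(numeric(0))), 0.002), "non-empty")
})

test_that("a bin never takes two peaks from one spectrum", {
  close_pair <- list(pl(c(1000.0, 1000.8), id = "s1"), pl(1000.4, id = "s2"))
  b <- bin_peaks(close_pair, 0.002)
  for (f in b$feature_masses) {
    contrib <- vapply(b$peaklists, function(p) sum(p$mass == f), 1L)
    expect_true(all(contrib <= 1L))
  }
  expect_gt(length(b$feature_masses), 1L)
})

test_that("repeated binning reaches the brute-force fixed point", {
  pls <- list(pl(1000.0, id = "s1"), pl(1001.9, id = "s2"),
              pl(1003.8, id = "s3"))
  conv <- bin_to_convergence(pls, 0.002)
  mass <- c(1000.0, 1001.9, 1003.8); src <- c(1, 2, 3)
  expect_equal(conv$feature_masses, brute_bin_fixed_point(mass, src, 0.002))

  set.seed(21)
  for (rep in 1:10) {
    lists <- lapply(1:4, function(k)
      pl(sort(2000 + cumsum(runif(12, 0.5, 12))), id = paste0("s", k)))
    conv <- bin_to_convergence(lists, 0.003)
    mass <- unlist(lapply(lists, `[[`, "mass"))
    src <- rep(1:4, each = 12)
    expect_equal(conv$feature_masses,
                 brute_bin_fixed_point(mass, src, 0.003),
                 tolerance = 1e-9)
  }
})

test_that("already-converged input terminates after one confirming round", {
  pls <- list(pl(c(1000, 1500)), pl(c(1000, 1500), id = "s2"))
  conv <- bin_to_convergence(pls, 0.002)
  expect_equal(conv$n_rounds, 2L)
  expect_equal(conv$feature_masses, c(1000, 1500))
})

test_that("feature matrix build respects absence, replicate policy and drops dead columns", {
  binned <- list(peaklists = list(
    pl(c(1000, 1200), c(0.2, 0.5), id = "a", rep_id = "r1"),
    pl(c(1000), c(0.4), id = "a", rep_id = "r2"),
    pl(c(1200), c(0.9), id = "b", rep_id = "r1")),
    feature_masses = c(1000, 1200))
  fm <- build_feature_matrix(binned, NULL, "mean")
  expect_equal(unname(fm$values["a", ]), c(0.3, 0.25))
  expect_equal(unname(fm$values["b", ]), c(0, 0.9))

  sep <- build_feature_matrix(binned, NULL, "separate")
  expect_equal(nrow(sep$values), 3)

  md <- data.frame(specimen_id = c("a", "b", "ghost"), species = "S",
                   genus = "G", class = "C", phylum = "P")
  expect_error(build_feature_matrix(binned, md, "mean"), "ghost")
})

test_that("Hellinger rows are unit vectors of square-rooted proportions", {
  md <- data.frame(specimen_id = c("a", "b"), replicate_id = NA,
                   species = "S", genus = "G", class = "C", phylum = "P")
  fm <- feature_matrix(rbind(c(1, 3), c(1, 0)), c(1000, 2000), md)
  h <- hellinger(fm)
  expect_equal(unname(h$values[1, ]), c(0.5, sqrt(3) / 2))
  expect_equal(unname(h$values[2, ]), c(1, 0))
  expect_equal(rowSums(h$values^2), c(a = 1, b = 1), tolerance = 1e-12,
               ignore_attr = TRUE)

  fm10 <- feature_matrix(rbind(c(10, 30), c(1, 0)), c(1000, 2000), md)
  expect_equal(hellinger(fm10)$values, h$values)

  fm0 <- feature_matrix(rbind(c(0, 0), c(1, 2)), c(1000, 2000), md)
  expect_error(hellinger(fm0), "a")
})
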