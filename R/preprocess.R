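#' Preprocessing parameters
#'
#' Bundles the tunable settings of the deterministic conditioning chain
#' applied to every raw spectrum before peak detection:
#' trim to a common mass window, square-root variance stabilisation,
#' Savitzky-Golay smoothing, SNIP baseline removal, TIC normalisation.
#'
#' @param trim_lo,trim_hi Mass window kept (Da; closed interval).
#'   Defaults 2000-20000 Da, the window the workflow was designed for.
#' @param sg_half_window Savitzky-Golay half window in points (window
#'   length `2*hw+1`); `0` skips smoothing.
#' @param sg_polyorder Savitzky-Golay polynomial degree (`< 2*hw+1`).
#' @param baseline_iterations SNIP clipping iterations (default 22, the
#'   optimum found by OOB-error grid search); `0` skips baseline removal.
#' @param snip_decreasing Run the SNIP window schedule from wide to narrow
#'   instead of narrow to wide.
#'
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(trim_lo = 2000, trim_hi = 20000,
                              sg_half_window = 10, sg_polyorder = 3,
                              baseline_iterations = 22,
                              snip_decreasing = FALSE) {
  if (!(trim_lo < trim_hi)) stop("trim_lo must be < trim_hi")
  if (sg_half_window < 0) stop("sg_half_window must be >= 0")
  if (sg_half_window > 0 && sg_polyorder >= 2 * sg_half_window + 1)
    stop("sg_polyorder must be < 2*sg_half_window + 1")
  if (baseline_iterations < 0) stop("baseline_iterations must be >= 0")
  structure(list(trim_lo = trim_lo, trim_hi = trim_hi,
                 sg_half_window = as.integer(sg_half_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 baseline_iterations = as.integer(baseline_iterations),
                 snip_decreasing = isTRUE(snip_decreasing)),
            class = "preprocess_params")
}

#' Trim a spectrum to a mass window
#'
#' Keeps points with `lo <= mass <= hi` (closed interval); metadata is
#' preserved.
#'
#' @param s A [mass_spectrum()].
#' @param lo,hi Window bounds in Da.
#' @return The trimmed [mass_spectrum()].
#' @export
trim_spectrum <- function(s, lo = 2000, hi = 20000) {
  stopifnot(inherits(s, "mass_spectrum"))
  if (!(lo < hi)) stop("lo must be < hi")
  keep <- s$mass >= lo & s$mass <= hi
  if (!any(keep))
    stop(sprintf("no points survive trimming to [%g, %g] Da", lo, hi))
  replace_intensity(s, s$intensity[keep], mass = s$mass[keep])
}

#' Square-root intensity transform
#'
#' Variance stabilisation for count-like ion intensities.
#'
#' @param s A [mass_spectrum()].
#' @return The transformed [mass_spectrum()].
#' @export
sqrt_transform <- function(s) {
  stopifnot(inherits(s, "mass_spectrum"))
  if (any(s$intensity < 0)) stop("negative intensities")
  replace_intensity(s, sqrt(s$intensity))
}

# Central Savitzky-Golay convolution weights for window 2h+1, degree p:
# the row of the least-squares hat matrix that evaluates the fit at the
# window centre.
sg_weights <- function(half_window, polyorder) {
  x <- seq(-half_window, half_window)
  X <- outer(x, 0:polyorder, `^`)
  H <- solve(crossprod(X), t(X))   # (X'X)^-1 X'
  H[1L, ]                          # value of the fit at x = 0
}

# Least-squares polynomial fit over indices `idx`, evaluated at index i.
sg_edge_value <- function(y, idx, i, polyorder) {
  x <- idx - i
  p <- min(polyorder, length(idx) - 1L)
  X <- outer(x, 0:p, `^`)
  beta <- qr.coef(qr(X), y[idx])
  sum(beta * c(1, rep(0, p)))      # polynomial at x = 0 is the intercept
}

#' Savitzky-Golay smoothing
#'
#' Each point is replaced by the centre value of a least-squares polynomial
#' of degree `polyorder` fitted to the `2*half_window+1` surrounding
#' intensities. Smoothing operates on the sample index (the mass axis is
#' treated as equally spaced). Near the edges the polynomial is fitted on
#' the truncated window.
#'
#' @param s A [mass_spectrum()].
#' @param half_window Half window size in points.
#' @param polyorder Polynomial degree (`< 2*half_window+1`).
#' @return The smoothed [mass_spectrum()]. Slight negative undershoot can
#'   occur and is removed later by baseline subtraction.
#' @export
savitzky_golay <- function(s, half_window = 10, polyorder = 3) {
  stopifnot(inherits(s, "mass_spectrum"))
  h <- as.integer(half_window)
  n <- length(s$intensity)
  if (h < 1L) stop("half_window must be >= 1")
  if (polyorder >= 2L * h + 1L) stop("polyorder must be < 2*half_window+1")
  if (n < 2L * h + 1L)
    stop(sprintf("spectrum (%d points) shorter than window (%d points)",
                 n, 2L * h + 1L))
  y <- s$intensity
  w <- sg_weights(h, polyorder)
  sm <- as.numeric(stats::filter(y, w, method = "convolution", sides = 2))
  for (i in seq_len(h)) {
    sm[i] <- sg_edge_value(y, seq_len(min(n, i + h)), i, polyorder)
    j <- n - i + 1L
    sm[j] <- sg_edge_value(y, seq(max(1L, j - h), n), j, polyorder)
  }
  replace_intensity(s, sm)
}

#' SNIP baseline estimation
#'
#' Statistics-sensitive non-linear iterative peak clipping: for window
#' half-width `k` running from 1 to `iterations` (or the reverse when
#' `decreasing`), every interior point is replaced by
#' `min(y_i, (y_(i-k) + y_(i+k)) / 2)`. Points closer than `k` to either
#' edge are left unchanged at that `k`. The result is a baseline estimate
#' that never exceeds the input.
#'
#' @param s A [mass_spectrum()].
#' @param iterations Number of clipping iterations (max window half-width);
#'   must be `< length(s$mass)`.
#' @param decreasing Run the window schedule wide-to-narrow.
#' @return Numeric baseline vector, same length as the spectrum.
#' @export
snip_baseline <- function(s, iterations = 22, decreasing = FALSE) {
  stopifnot(inherits(s, "mass_spectrum"))
  m <- as.integer(iterations)
  n <- length(s$intensity)
  if (m < 1L) stop("iterations must be >= 1")
  if (m >= n) stop("iterations must be < number of points")
  y <- s$intensity
  ks <- if (decreasing) m:1L else 1L:m
  for (k in ks) {
    if (k + 1L > n - k) next   # no interior points at this window
    i <- (k + 1L):(n - k)
    y[i] <- pmin(y[i], (y[i - k] + y[i + k]) / 2)
  }
  y
}

#' Subtract a baseline
#'
#' Negative differences are clamped to zero.
#'
#' @param s A [mass_spectrum()].
#' @param baseline Numeric vector of the same length.
#' @return The corrected [mass_spectrum()].
#' @export
subtract_baseline <- function(s, baseline) {
  stopifnot(inherits(s, "mass_spectrum"))
  if (length(baseline) != length(s$intensity))
    stop("baseline length does not match spectrum length")
  replace_intensity(s, pmax(s$intensity - baseline, 0))
}

#' Total-ion-current normalisation
#'
#' Scales intensities so they sum to one, making spectra with different
#' absolute ion yields comparable.
#'
#' @param s A [mass_spectrum()].
#' @return The normalised [mass_spectrum()].
#' @export
tic_normalize <- function(s) {
  stopifnot(inherits(s, "mass_spectrum"))
  tot <- sum(s$intensity)
  if (tot <= 0) stop("cannot TIC-normalize an all-zero spectrum")
  replace_intensity(s, s$intensity / tot)
}

#' Full preprocessing pipeline
#'
#' Applies, in order: trim, square-root transform, Savitzky-Golay
#' smoothing, SNIP baseline subtraction, TIC normalisation. The chain is
#' deterministic; stage errors are reported with the stage name.
#'
#' @param s A [mass_spectrum()].
#' @param params A [preprocess_params()].
#' @return The preprocessed [mass_spectrum()] (intensities sum to 1).
#' @export
preprocess_pipeline <- function(s, params = preprocess_params()) {
  stopifnot(inherits(s, "mass_spectrum"),
            inherits(params, "preprocess_params"))
  s <- with_stage("trim", trim_spectrum(s, params$trim_lo, params$trim_hi))
  s <- with_stage("sqrt", sqrt_transform(s))
  if (params$sg_half_window > 0L)
    s <- with_stage("smooth",
                    savitzky_golay(s, params$sg_half_window,
                                   params$sg_polyorder))
  if (params$baseline_iterations > 0L) {
    b <- with_stage("baseline",
                    snip_baseline(s, params$baseline_iterations,
                                  params$snip_decreasing))
    s <- with_stage("baseline", subtract_baseline(s, b))
  }
  with_stage("normalize", tic_normalize(s))
}
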