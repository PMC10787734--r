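# Independent brute-force oracles used to cross-check the implementation.

# Per-index local polynomial least squares via lm(): the reference for
# Savitzky-Golay smoothing, including truncated edge windows.
sg_oracle <- function(y, half_window, polyorder) {
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1L, i - half_window):min(n, i + half_window)
    x <- idx - i
    p <- min(polyorder, length(idx) - 1L)
    fit <- lm(y[idx] ~ poly(x, degree = p, raw = TRUE))
    out[i] <- unname(predict(fit, newdata = data.frame(x = 0)))
  }
  out
}

# Naive quadratic-scan peak detector: literal transcription of the rule
# "maximum of the window, exact ties keep the leftmost point".
naive_peak_scan <- function(intensity, snr, hws, noise) {
  n <- length(intensity)
  idx <- integer(0)
  for (i in seq_len(n)) {
    if (intensity[i] <= snr * noise) next
    win <- max(1L, i - hws):min(n, i + hws)
    others <- setdiff(win, i)
    if (all(intensity[i] >= intensity[others])) {
      ties <- others[intensity[others] == intensity[i]]
      if (!length(ties) || all(ties > i)) idx <- c(idx, i)
    }
  }
  idx
}

# Brute-force one binning pass on a pooled peak table (mass, spectrum id):
# independent recursive implementation used to cross-check
# bin_to_convergence. Returns the peaks re-labelled by their bin mean.
brute_bin_once <- function(mass, src, tol) {
  o <- order(mass)
  recurse <- function(idx) {
    m <- mass[idx]
    if (length(m) == 1L) return(list(idx))
    mu <- mean(m)
    if (all(abs(m - mu) <= tol * mu) && !anyDuplicated(src[idx]))
      return(list(idx))
    j <- which.max(diff(m))
    c(recurse(idx[1:j]), recurse(idx[(j + 1):length(idx)]))
  }
  groups <- recurse(o)
  out <- mass
  for (g in groups) out[g] <- mean(mass[g])
  out
}

brute_bin_fixed_point <- function(mass, src, tol) {
  prev <- -1L
  repeat {
    mass <- brute_bin_once(mass, src, tol)
    if (length(unique(mass)) == prev) break
    prev <- length(unique(mass))
  }
  sort(unique(mass))
}

# A reproducible rough random spectrum for oracle tests.
random_test_spectrum <- function(n, seed) {
  set.seed(seed)
  mass_spectrum(seq(2000, by = 4, length.out = n),
                abs(rnorm(n, 5, 3)) + sample(0:1, n, TRUE) * rexp(n, 1 / 10))
}
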