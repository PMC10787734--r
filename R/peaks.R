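#' Peak-picking parameters
#'
#' @param snr Signal-to-noise threshold: a point must exceed
#'   `snr * noise` to qualify as a peak. Default 3, the value found to
#'   minimise random-forest OOB error.
#' @param hws Half window size in points for the local-maximum test.
#'   Default 7 (OOB-error optimum).
#' @param bin_tolerance Relative mass tolerance of cross-spectrum binning
#'   (default 0.002, i.e. 0.2% of the bin mass).
#'
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(snr = 3, hws = 7, bin_tolerance = 0.002) {
  if (snr <= 0) stop("snr must be > 0")
  if (hws < 1) stop("hws must be >= 1")
  if (bin_tolerance <= 0 || bin_tolerance >= 0.1)
    stop("bin_tolerance must be in (0, 0.1)")
  structure(list(snr = snr, hws = as.integer(hws),
                 bin_tolerance = bin_tolerance),
            class = "peak_params")
}

#' Construct a peak list
#'
#' @param mass Peak masses (Da), strictly increasing.
#' @param intensity Peak intensities.
#' @param snr Signal-to-noise ratio of each peak.
#' @param specimen_id,replicate_id Identifiers of the source measurement.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(mass, intensity, snr = rep(NA_real_, length(mass)),
                      specimen_id = NA_character_,
                      replicate_id = NA_character_) {
  if (length(mass) != length(intensity) || length(mass) != length(snr))
    stop("mass, intensity and snr must have equal length")
  if (length(mass) > 1L && is.unsorted(mass, strictly = TRUE))
    stop("peak masses must be strictly increasing")
  structure(list(mass = as.numeric(mass), intensity = as.numeric(intensity),
                 snr = as.numeric(snr),
                 specimen_id = as.character(specimen_id),
                 replicate_id = as.character(replicate_id)),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks | specimen %s rep %s\n",
              length(x$mass), x$specimen_id, x$replicate_id))
  invisible(x)
}

#' @export
length.peak_list <- function(x) length(x$mass)

#' Estimate spectrum noise
#'
#' Robust global noise scale: `1.4826 * median(|I - median(I)|)` over the
#' whole (trimmed, preprocessed) spectrum. A zero MAD (e.g. constant
#' intensities) falls back to a machine-epsilon-scaled value with a
#' warning.
#'
#' @param s A [mass_spectrum()].
#' @return Noise level (same units as the intensities).
#' @export
estimate_noise <- function(s) {
  stopifnot(inherits(s, "mass_spectrum"))
  if (length(s$intensity) < 2L) stop("need at least 2 points")
  noise <- 1.4826 * median(abs(s$intensity - median(s$intensity)))
  if (noise == 0) {
    warning("zero MAD; falling back to machine-epsilon-scaled noise")
    noise <- .Machine$double.eps * max(1, max(abs(s$intensity)))
  }
  noise
}

#' Detect peaks
#'
#' Point `i` is a peak iff its intensity exceeds `snr * noise` and it is
#' the maximum of the window `[i - hws, i + hws]`; exact intensity ties
#' within a window keep only the leftmost point.
#'
#' @param s A preprocessed [mass_spectrum()].
#' @param params A [peak_params()].
#' @param noise Optional fixed noise level; default [estimate_noise()].
#' @return A [peak_list()] (possibly empty), sorted by mass.
#' @export
detect_peaks <- function(s, params = peak_params(), noise = NULL) {
  stopifnot(inherits(s, "mass_spectrum"), inherits(params, "peak_params"))
  I <- s$intensity
  n <- length(I)
  noise <- noise %||% estimate_noise(s)
  thr <- params$snr * noise
  h <- min(params$hws, n - 1L)
  # strictly above every earlier window point, and >= every later one:
  # this keeps exactly the leftmost point of any tied run
  left_ok <- rep(TRUE, n); right_ok <- rep(TRUE, n)
  for (d in seq_len(h)) {
    left_ok <- left_ok & (I > c(rep(-Inf, d), I[seq_len(n - d)]))
    right_ok <- right_ok & (I >= c(I[-seq_len(d)], rep(-Inf, d)))
  }
  idx <- which(left_ok & right_ok & I > thr)
  peak_list(s$mass[idx], I[idx], snr = I[idx] / noise,
            specimen_id = s$specimen_id, replicate_id = s$replicate_id)
}

# Strict recursive binning of pooled, mass-sorted peaks. A candidate group
# becomes a bin iff every member lies within tolerance of the group mean
# AND no source spectrum contributes two peaks; otherwise the group is
# split at its largest internal mass gap (leftmost on ties) and the halves
# are revisited.
strict_bin_groups <- function(mass, source, tolerance) {
  n <- length(mass)
  bins <- vector("list", n)
  nb <- 0L
  stack <- list(c(1L, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- rng[1L]; b <- rng[2L]
    m <- mass[a:b]
    mu <- mean(m)
    ok <- (b == a) ||
      (all(abs(m - mu) <= tolerance * mu) &&
         !anyDuplicated(source[a:b]))
    if (ok) {
      nb <- nb + 1L
      bins[[nb]] <- a:b
    } else {
      j <- which.max(diff(m))          # leftmost largest gap
      stack[[length(stack) + 1L]] <- c(a + j, b)
      stack[[length(stack) + 1L]] <- c(a, a + j - 1L)
    }
  }
  bins[seq_len(nb)]
}

#' Bin peaks across spectra
#'
#' Pools all peaks, sorted by mass, and groups them into bins under a
#' strict rule: every member must deviate from the bin's mean mass by at
#' most `tolerance * mean`, and no spectrum may contribute two peaks to
#' one bin. Groups violating either rule are split at their largest
#' internal mass gap and re-examined. Member peaks are re-labelled with
#' the bin's mean mass.
#'
#' @param peaklists A list of [peak_list()] objects (at least one
#'   non-empty).
#' @param tolerance Relative mass tolerance, in `(0, 0.1)`.
#' @return A list with `peaklists` (re-labelled) and `feature_masses`.
#' @export
bin_peaks <- function(peaklists, tolerance = 0.002) {
  if (tolerance <= 0 || tolerance >= 0.1)
    stop("tolerance must be in (0, 0.1)")
  if (!length(peaklists) || all(vapply(peaklists, length, 1L) == 0L))
    stop("need at least one non-empty peak list")
  src <- rep(seq_along(peaklists), vapply(peaklists, length, 1L))
  mass <- unlist(lapply(peaklists, `[[`, "mass"), use.names = FALSE)
  o <- order(mass)
  mass <- mass[o]; src <- src[o]
  groups <- strict_bin_groups(mass, src, tolerance)
  bin_mass <- vapply(groups, function(g) mean(mass[g]), 1)
  bo <- order(bin_mass)
  groups <- groups[bo]; bin_mass <- bin_mass[bo]
  new_mass <- numeric(length(mass))
  for (g in seq_along(groups)) new_mass[groups[[g]]] <- bin_mass[g]
  # scatter re-labelled masses back into per-spectrum lists
  orig_pos <- unlist(lapply(peaklists, function(p) seq_len(length(p))),
                     use.names = FALSE)[o]
  out <- peaklists
  for (i in seq_along(peaklists)) {
    sel <- src == i
    relab <- new_mass[sel][order(orig_pos[sel])]
    oo <- order(relab)
    out[[i]] <- peak_list(relab[oo], peaklists[[i]]$intensity[oo],
                          peaklists[[i]]$snr[oo],
                          specimen_id = peaklists[[i]]$specimen_id,
                          replicate_id = peaklists[[i]]$replicate_id)
  }
  list(peaklists = out, feature_masses = bin_mass)
}

#' Bin peaks repeatedly until the feature count stabilises
#'
#' Applies [bin_peaks()] to the re-labelled peaks again and again until
#' two successive rounds yield the same number of distinct feature masses.
#' The feature count is non-increasing and bounded below by one, so the
#' loop always terminates.
#'
#' @inheritParams bin_peaks
#' @return A list with `peaklists`, `feature_masses` and `n_rounds`.
#' @export
bin_to_convergence <- function(peaklists, tolerance = 0.002) {
  prev <- -1L
  rounds <- 0L
  res <- list(peaklists = peaklists)
  repeat {
    res <- bin_peaks(res$peaklists, tolerance)
    rounds <- rounds + 1L
    count <- length(res$feature_masses)
    if (count == prev) break
    prev <- count
  }
  list(peaklists = res$peaklists, feature_masses = res$feature_masses,
       n_rounds = rounds)
}

#' Build a specimen-by-feature intensity matrix
#'
#' Each cell is the (binned) peak intensity of that specimen at that
#' feature mass, zero where the peak is absent. With
#' `replicate_policy = "mean"` technical replicates of a specimen are
#' averaged per feature (absences count as zero); with `"separate"` every
#' replicate keeps its own row. All-zero feature columns are dropped with
#' a warning.
#'
#' @param binned Result of [bin_to_convergence()] (or [bin_peaks()]).
#' @param metadata Data frame keyed by `specimen_id` with taxon columns
#'   (`species`, `genus`, `class`, `phylum`); may be `NULL` if the peak
#'   lists themselves were derived from labelled spectra read via
#'   [read_collection()] and you attach labels later.
#' @param replicate_policy `"mean"` or `"separate"`.
#' @return A [feature_matrix()].
#' @export
build_feature_matrix <- function(binned, metadata = NULL,
                                 replicate_policy = c("mean", "separate")) {
  replicate_policy <- match.arg(replicate_policy)
  pls <- binned$peaklists
  fmass <- binned$feature_masses
  key <- fmt_mass(fmass)
  vals <- matrix(0, nrow = length(pls), ncol = length(fmass),
                 dimnames = list(NULL, key))
  spec_id <- character(length(pls)); rep_id <- character(length(pls))
  for (i in seq_along(pls)) {
    p <- pls[[i]]
    j <- match(fmt_mass(p$mass), key)
    if (anyNA(j))
      stop("peak list ", i, " contains masses outside the converged ",
           "feature set; re-run binning")
    vals[i, j] <- p$intensity
    spec_id[i] <- p$specimen_id
    rep_id[i] <- p$replicate_id
  }
  meta_for <- function(ids) {
    out <- data.frame(specimen_id = ids, replicate_id = NA_character_,
                      species = NA_character_, genus = NA_character_,
                      class = NA_character_, phylum = NA_character_,
                      stringsAsFactors = FALSE)
    if (!is.null(metadata)) {
      md <- as.data.frame(metadata)
      names(md) <- tolower(names(md))
      if (!"specimen_id" %in% names(md))
        stop("metadata must contain a specimen_id column")
      missing_ids <- setdiff(md$specimen_id, ids)
      if (length(missing_ids))
        stop("specimen(s) with zero surviving replicates: ",
             paste(missing_ids, collapse = ", "))
      k <- match(ids, md$specimen_id)
      for (cn in intersect(c("species", "genus", "class", "phylum"),
                           names(md)))
        out[[cn]] <- as.character(md[[cn]])[k]
    }
    out
  }
  if (replicate_policy == "mean") {
    agg <- rowsum(vals, group = spec_id, reorder = FALSE)
    counts <- as.integer(table(factor(spec_id, levels = rownames(agg))))
    vals <- agg / counts
    meta <- meta_for(rownames(agg))
  } else {
    meta <- meta_for(spec_id)
    meta$replicate_id <- rep_id
  }
  zero <- colSums(vals) == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero feature column(s) dropped")
    vals <- vals[, !zero, drop = FALSE]
    fmass <- fmass[!zero]
  }
  if (!length(fmass)) stop("no non-zero features remain")
  feature_matrix(vals, fmass, meta)
}

#' Hellinger transform
#'
#' Row-wise square-root of relative abundances:
#' `x' = sqrt(x / rowsum)`, so each row's squared values sum to one. The
#' standard stabilisation for composition-like intensity data before
#' classification.
#'
#' @param x A [feature_matrix()].
#' @return The transformed [feature_matrix()].
#' @export
hellinger <- function(x) {
  stopifnot(inherits(x, "feature_matrix"))
  rs <- rowSums(x$values)
  if (any(rs <= 0))
    stop("all-zero row(s) in feature matrix: ",
         paste(x$meta$specimen_id[rs <= 0], collapse = ", "))
  x$values <- sqrt(x$values / rs)
  x
}
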