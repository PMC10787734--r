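# Per-specimen taxonomy block pulled out of a list of labelled spectra.
spectra_metadata <- function(spectra) {
  df <- data.frame(
    specimen_id = vapply(spectra, `[[`, "", "specimen_id"),
    species = vapply(spectra, `[[`, "", "species"),
    genus = vapply(spectra, `[[`, "", "genus"),
    class = vapply(spectra, `[[`, "", "class"),
    phylum = vapply(spectra, `[[`, "", "phylum"),
    stringsAsFactors = FALSE)
  unique(df)
}

#' Cartesian grid of data-processing settings
#'
#' Expands the full product of SNIP baseline iterations, peak-picking
#' half window sizes and SNR thresholds. The defaults are the canonical
#' optimisation ranges (baseline and HWS 5-30, SNR 3-20; 12,168
#' combinations).
#'
#' @param baseline_iterations,hws,snr Integer/numeric vectors of settings.
#' @return Data frame with one row per combination.
#' @export
make_processing_grid <- function(baseline_iterations = 5:30, hws = 5:30,
                                 snr = 3:20) {
  if (!length(baseline_iterations) || !length(hws) || !length(snr))
    stop("empty grid")
  expand.grid(baseline_iterations = baseline_iterations, hws = hws,
              snr = snr, KEEP.OUT.ATTRS = FALSE)
}

# One grid-point evaluation: preprocessed spectra -> peaks -> converged
# bins -> Hellinger matrix -> RF OOB error.
eval_grid_point <- function(pre_spectra, meta, hws, snr, tolerance,
                            replicate_policy, ntree, mtry, seed) {
  pls <- lapply(pre_spectra, detect_peaks,
                params = peak_params(snr = snr, hws = hws,
                                     bin_tolerance = tolerance))
  if (all(vapply(pls, length, 1L) == 0L))
    return(list(n_features = 0L, oob_error = 1.0, n_bin_rounds = 0L,
                degenerate = TRUE))
  binned <- bin_to_convergence(pls, tolerance)
  fm <- suppressWarnings(
    build_feature_matrix(binned, meta, replicate_policy))
  model <- suppressWarnings(
    train_rf(hellinger(fm), "species", ntree = ntree, mtry = mtry,
             seed = seed))
  list(n_features = length(fm$feature_masses),
       oob_error = model$oob_error, n_bin_rounds = binned$n_rounds,
       degenerate = FALSE)
}

#' Grid search of data-processing hyperparameters
#'
#' For every combination of baseline iterations, half window size and SNR:
#' preprocess the raw spectra, detect and bin peaks to convergence, build
#' the Hellinger feature matrix and train a species-level random forest,
#' recording its OOB error as the objective. Each grid point uses a seed
#' derived from the master seed and the grid coordinates, so rows are
#' individually reproducible and evaluation order is irrelevant.
#'
#' A grid point at which the workflow degenerates (no features, or a
#' specimen losing all peaks) is recorded with `oob_error = 1` and
#' `degenerate = TRUE`.
#'
#' @param spectra List of labelled raw [mass_spectrum()] objects.
#' @param grid Data frame from [make_processing_grid()].
#' @param base_params [preprocess_params()] supplying the non-varied
#'   settings (trim window, smoothing).
#' @param tolerance Binning tolerance (relative).
#' @param replicate_policy Passed to [build_feature_matrix()].
#' @param min_specimens Minimum specimens per species (default 6).
#' @param filter_low Drop under-sampled species instead of erroring.
#' @param ntree,mtry Forest parameters per grid point.
#' @param seed Master seed.
#' @return A `grid_result` data frame, sorted by ascending OOB error,
#'   with columns `baseline_iterations`, `hws`, `snr`, `n_features`,
#'   `oob_error`, `n_bin_rounds`, `degenerate`.
#' @export
grid_search <- function(spectra, grid = make_processing_grid(),
                        base_params = preprocess_params(),
                        tolerance = 0.002,
                        replicate_policy = c("mean", "separate"),
                        min_specimens = 6, filter_low = FALSE,
                        ntree = 2000, mtry = 35, seed = 1) {
  replicate_policy <- match.arg(replicate_policy)
  if (!nrow(grid)) stop("empty grid")
  meta <- spectra_metadata(spectra)
  counts <- table(meta$species)
  low <- names(counts)[counts < min_specimens]
  if (length(low)) {
    if (!filter_low)
      stop("species below min_specimens (", min_specimens, "): ",
           paste(low, collapse = ", "), "; set filter_low = TRUE to drop")
    spectra <- Filter(function(s) !(s$species %in% low), spectra)
    meta <- meta[!(meta$species %in% low), , drop = FALSE]
  }
  rows <- vector("list", nrow(grid))
  for (b in unique(grid$baseline_iterations)) {
    pp <- base_params
    pp$baseline_iterations <- as.integer(b)
    pre <- lapply(spectra, preprocess_pipeline, params = pp)
    for (r in which(grid$baseline_iterations == b)) {
      h <- grid$hws[r]; sn <- grid$snr[r]
      pt <- tryCatch(
        eval_grid_point(pre, meta, h, sn, tolerance, replicate_policy,
                        ntree, mtry,
                        seed = derive_seed(seed, b, h, round(sn * 1000))),
        error = function(e) list(n_features = 0L, oob_error = 1.0,
                                 n_bin_rounds = 0L, degenerate = TRUE))
      rows[[r]] <- data.frame(baseline_iterations = b, hws = h, snr = sn,
                              n_features = pt$n_features,
                              oob_error = pt$oob_error,
                              n_bin_rounds = pt$n_bin_rounds,
                              degenerate = pt$degenerate)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$oob_error, out$n_features, out$snr, out$hws,
                   out$baseline_iterations), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("grid_result", "data.frame")
  out
}

#' Recommend processing settings from a grid result
#'
#' Returns the parameters of the row with the lowest OOB error; ties are
#' broken by fewer features, then lower SNR, lower HWS, lower baseline
#' iterations.
#'
#' @param grid A `grid_result` from [grid_search()].
#' @return A list with `preprocess` ([preprocess_params()]), `peaks`
#'   ([peak_params()]) and the winning `row`.
#' @export
recommend_settings <- function(grid) {
  if (!nrow(grid)) stop("empty grid result")
  o <- order(grid$oob_error, grid$n_features, grid$snr, grid$hws,
             grid$baseline_iterations)
  best <- grid[o[1L], , drop = FALSE]
  list(preprocess = preprocess_params(
         baseline_iterations = best$baseline_iterations),
       peaks = peak_params(snr = best$snr, hws = best$hws),
       row = best)
}

#' Binomial GAM on grid-search results
#'
#' Models the OOB error (as a binomial proportion with `weights` trials
#' per analysis) on penalized smooth terms of baseline iterations, HWS
#' and SNR (logit link), quantifying which processing step drives
#' classification success. Constant predictors are dropped with a
#' warning; predictors with fewer than 3 unique values enter linearly.
#'
#' @param grid A `grid_result` from [grid_search()].
#' @param weights Number of specimens behind each OOB error (scalar or
#'   per-row vector) — the binomial denominator.
#' @param k Maximum basis dimension per smooth term (default 5; the
#'   responses of interest are near-linear, so small bases suffice).
#' @return A `gam_summary` list: `terms` (edf, ref_df, chi_sq, p_value
#'   per predictor), `intercept`, `r_sq_adj`, `deviance_explained`
#'   (percent), `dropped`, and the fitted `gam` object.
#' @export
fit_gam <- function(grid, weights, k = 5) {
  if (nrow(grid) < 10L) stop("need at least 10 grid rows")
  w <- rep_len(weights, nrow(grid))
  preds <- c("baseline_iterations", "hws", "snr")
  dropped <- character(0)
  terms <- character(0)
  smooth_terms <- character(0)
  for (p in preds) {
    nu <- length(unique(grid[[p]]))
    if (nu < 2L) {
      warning("constant predictor dropped: ", p)
      dropped <- c(dropped, p)
    } else if (nu < 3L) {
      terms <- c(terms, p)
    } else {
      kk <- min(k, nu)
      terms <- c(terms, sprintf("s(%s, k = %d)", p, kk))
      smooth_terms <- c(smooth_terms, p)
    }
  }
  if (!length(terms)) stop("no non-constant predictors")
  df <- as.data.frame(grid)
  df$succ <- round((1 - df$oob_error) * w)
  df$fail <- round(w) - df$succ
  fml <- as.formula(paste("cbind(succ, fail) ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(fml, family = binomial(link = "logit"), data = df)
  sm <- summary(fit)
  tab <- data.frame(term = character(0), edf = numeric(0),
                    ref_df = numeric(0), chi_sq = numeric(0),
                    p_value = numeric(0))
  if (!is.null(sm$s.table) && nrow(sm$s.table)) {
    st <- sm$s.table
    tab <- rbind(tab, data.frame(
      term = sub("^s\\((.*)\\)$", "\\1", rownames(st)),
      edf = st[, "edf"], ref_df = st[, "Ref.df"],
      chi_sq = st[, "Chi.sq"], p_value = st[, "p-value"]))
  }
  pt <- sm$p.table
  lin <- setdiff(rownames(pt), "(Intercept)")
  if (length(lin))
    tab <- rbind(tab, data.frame(
      term = lin, edf = 1, ref_df = 1,
      chi_sq = pt[lin, "z value"]^2, p_value = pt[lin, "Pr(>|z|)"]))
  tab$p_value <- pmin(pmax(tab$p_value, 0), 1)
  rownames(tab) <- NULL
  structure(list(terms = tab,
                 intercept = unname(pt["(Intercept)", "Estimate"]),
                 r_sq_adj = sm$r.sq,
                 deviance_explained = 100 * sm$dev.expl,
                 dropped = dropped, gam = fit),
            class = "gam_summary")
}

#' @export
print.gam_summary <- function(x, ...) {
  cat(sprintf("<gam_summary> intercept %.3f | adj R^2 %.3f | deviance explained %.1f%%\n",
              x$intercept, x$r_sq_adj, x$deviance_explained))
  print(x$terms, digits = 3)
  invisible(x)
}

#' Specimens-per-species saturation analysis
#'
#' How many specimens per species does a reference library need? For each
#' library size `n` in `n_range` and each of `reps` replicates, `n`
#' specimens per eligible species (those with at least `min_pool`
#' specimens) are sampled without replacement, a species-level forest is
#' trained and its OOB error recorded. Every (n, rep) cell uses a derived
#' seed, so the whole table is reproducible.
#'
#' @param x Hellinger-transformed specimen-level [feature_matrix()].
#' @param n_range Length-2 vector: smallest and largest specimens per
#'   species (default `c(2, 11)`).
#' @param reps Resampled data sets per `n` (default 100).
#' @param min_pool Minimum specimens a species needs to be eligible
#'   (default 11).
#' @param ntree,mtry Forest parameters.
#' @param seed Master seed.
#' @return A `saturation_result` list: `results` (n, rep, oob_error) and
#'   `summary` (mean/sd/min/max OOB error per n).
#' @export
specimen_saturation <- function(x, n_range = c(2, 11), reps = 100,
                                min_pool = 11, ntree = 2000, mtry = 35,
                                seed = 1) {
  stopifnot(inherits(x, "feature_matrix"))
  if (reps < 1) stop("reps must be >= 1")
  counts <- table(x$meta$species)
  eligible <- names(counts)[counts >= min_pool]
  if (length(eligible) < 2L)
    stop("need at least 2 species with >= ", min_pool, " specimens")
  x <- subset_rows(x, x$meta$species %in% eligible)
  ns <- seq(n_range[1L], n_range[2L])
  if (min(ns) < 2L) stop("n_range must start at >= 2")
  rows <- vector("list", length(ns) * reps)
  r <- 0L
  for (n in ns) {
    for (rep_i in seq_len(reps)) {
      set.seed(derive_seed(seed, n, rep_i))
      idx <- unlist(lapply(eligible, function(sp) {
        sample(which(x$meta$species == sp), n)
      }), use.names = FALSE)
      model <- suppressWarnings(
        train_rf(subset_rows(x, idx), "species", ntree = ntree,
                 mtry = mtry, seed = derive_seed(seed, n, rep_i, 7L)))
      r <- r + 1L
      rows[[r]] <- data.frame(n = n, rep = rep_i,
                              oob_error = model$oob_error)
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(results$oob_error, results$n),
                                function(v) data.frame(
                                  mean = mean(v), sd = stats::sd(v),
                                  min = min(v), max = max(v))))
  summ <- cbind(n = as.integer(rownames(summ)), summ)
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ),
            class = "saturation_result")
}

#' @export
print.saturation_result <- function(x, ...) {
  cat(sprintf("<saturation_result> %d fits, n = %d..%d\n",
              nrow(x$results), min(x$summary$n), max(x$summary$n)))
  print(x$summary, digits = 3)
  invisible(x)
}
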