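#' Arc-length atypicality score
#'
#' Quality score of a TIC-normalized spectrum: the total variation of the
#' intensity trace divided by its maximum,
#' `A = sum(|I[i+1] - I[i]|) / max(I)`. Noisy or atypical spectra wander
#' up and down far more than clean peak-on-baseline traces of the same
#' peak height, so higher scores indicate lower quality. This score is an
#' explicit re-specification of the screening statistic used in common
#' MALDI QC tooling; it is not bit-compatible with any of them.
#'
#' @param s A TIC-normalized [mass_spectrum()].
#' @return Non-negative score (unitless).
#' @export
a_score <- function(s) {
  stopifnot(inherits(s, "mass_spectrum"))
  mx <- max(s$intensity)
  if (mx == 0) stop("a_score undefined for an all-zero spectrum")
  sum(abs(diff(s$intensity))) / mx
}

#' Screen a spectrum collection for quality
#'
#' Computes [a_score()] for every spectrum and flags scores above the
#' Tukey upper fence `Q3 + 1.5 * IQR` as `"review"` and above
#' `Q3 + 3 * IQR` as `"discard"`. If the discards leave a species with a
#' single specimen, that remaining specimen is flagged `"discard"` as
#' well (a one-specimen species cannot support training).
#'
#' @param spectra A list of at least 5 [mass_spectrum()] objects.
#' @return A `qc_report`: data frame with `specimen_id`, `replicate_id`,
#'   `species`, `a_score`, `flag`, plus attributes `fence_review` and
#'   `fence_discard`.
#' @export
screen_spectra <- function(spectra) {
  if (length(spectra) < 5L)
    stop("need at least 5 spectra to define screening fences")
  scores <- vapply(spectra, a_score, 1)
  q <- quantile(scores, c(0.25, 0.75), names = FALSE)
  iqr <- q[2L] - q[1L]
  fence_review <- q[2L] + 1.5 * iqr
  fence_discard <- q[2L] + 3 * iqr
  flag <- rep("keep", length(scores))
  flag[scores > fence_review] <- "review"
  flag[scores > fence_discard] <- "discard"
  rep_df <- data.frame(
    specimen_id = vapply(spectra, `[[`, "", "specimen_id"),
    replicate_id = vapply(spectra, `[[`, "", "replicate_id"),
    species = vapply(spectra, `[[`, "", "species"),
    a_score = scores, flag = flag, stringsAsFactors = FALSE)
  # species reduced to a single specimen by discards lose that specimen too
  labelled <- !is.na(rep_df$species)
  if (any(labelled)) {
    kept <- rep_df[labelled & rep_df$flag != "discard", , drop = FALSE]
    n_spec <- tapply(kept$specimen_id, kept$species,
                     function(x) length(unique(x)))
    lone <- names(n_spec)[n_spec == 1L]
    if (length(lone))
      rep_df$flag[rep_df$species %in% lone] <- "discard"
  }
  structure(rep_df, fence_review = fence_review,
            fence_discard = fence_discard,
            class = c("qc_report", "data.frame"))
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d spectra | review fence %.3g, discard fence %.3g\n",
              nrow(x), attr(x, "fence_review"), attr(x, "fence_discard")))
  print(table(flag = x$flag))
  invisible(x)
}
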