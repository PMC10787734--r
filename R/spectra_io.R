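#' Construct a mass spectrum
#'
#' A `mass_spectrum` holds one single-specimen MALDI-TOF measurement: an
#' ascending mass axis in Daltons, non-negative intensities in arbitrary
#' units, and the specimen / replicate / taxonomy metadata used downstream.
#' Taxon fields may be `NA` for query-only spectra.
#'
#' @param mass Numeric vector of m/z values (Da), strictly increasing.
#' @param intensity Numeric vector of intensities, same length, `>= 0`.
#' @param specimen_id,replicate_id Identifier strings.
#' @param species,genus,class,phylum,sex Taxon labels (optional).
#'
#' @return An object of class `mass_spectrum`.
#' @export
#' @examples
#' s <- mass_spectrum(c(2000, 2100), c(5, 7), specimen_id = "sp1")
#' length(s$mass)
mass_spectrum <- function(mass, intensity,
                          specimen_id = NA_character_,
                          replicate_id = NA_character_,
                          species = NA_character_, genus = NA_character_,
                          class = NA_character_, phylum = NA_character_,
                          sex = NA_character_) {
  mass <- as.numeric(mass)
  intensity <- as.numeric(intensity)
  if (length(mass) != length(intensity))
    stop("mass and intensity must have equal length")
  if (length(mass) < 1L) stop("empty spectrum")
  if (anyNA(mass) || anyNA(intensity) || any(!is.finite(mass)) ||
      any(!is.finite(intensity)))
    stop("non-finite values in spectrum")
  if (length(mass) > 1L && is.unsorted(mass, strictly = TRUE))
    stop("mass axis must be strictly increasing")
  if (any(intensity < 0)) stop("negative intensities not allowed")
  structure(
    list(mass = mass, intensity = intensity,
         specimen_id = as.character(specimen_id),
         replicate_id = as.character(replicate_id),
         species = as.character(species), genus = as.character(genus),
         class = as.character(class), phylum = as.character(phylum),
         sex = as.character(sex)),
    class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %d points, %.1f-%.1f Da",
              length(x$mass), min(x$mass), max(x$mass)))
  if (!is.na(x$specimen_id))
    cat(sprintf(" | specimen %s rep %s", x$specimen_id, x$replicate_id))
  if (!is.na(x$species)) cat(sprintf(" | %s", x$species))
  cat("\n")
  invisible(x)
}

# Rebuild a spectrum with new intensities, keeping metadata.
replace_intensity <- function(s, intensity, mass = s$mass) {
  s$mass <- mass
  s$intensity <- intensity
  s
}

# Sort points by mass and merge duplicate masses by summing intensities
# (conservative for ion counts).
canonicalise_points <- function(mass, intensity) {
  o <- order(mass)
  mass <- mass[o]; intensity <- intensity[o]
  if (anyDuplicated(mass)) {
    intensity <- as.numeric(rowsum(intensity, group = mass))
    mass <- sort(unique(mass))
  }
  list(mass = mass, intensity = intensity)
}

#' Read a single spectrum file
#'
#' Reads a two-column (mass, intensity) CSV/TSV file, or one spectrum from
#' an mzML file (via \pkg{mzR}). Points are sorted by ascending mass;
#' duplicate masses are merged by summing their intensities.
#'
#' @param path Path to the spectrum file.
#' @param format One of `"auto"` (by extension), `"csv"`, `"tsv"`, `"mzml"`.
#' @param scan Scan number to read from an mzML file (default first).
#' @param ... Metadata fields passed on to [mass_spectrum()].
#'
#' @return A [mass_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "tsv", "mzml"),
                          scan = 1L, ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     tab = "tsv", mzml = "mzml",
                     stop("cannot infer format from extension: ", path))
  }
  pts <- if (format == "mzml") {
    read_mzml_points(path, scan)
  } else {
    read_xsv_points(path, sep = if (format == "csv") "," else "\t")
  }
  if (length(pts$mass) == 0L) stop("empty spectrum: ", path)
  pts <- canonicalise_points(pts$mass, pts$intensity)
  mass_spectrum(pts$mass, pts$intensity, ...)
}

# Parse a two-column delimited text spectrum, reporting the offending
# line/field on failure. An optional single header line is tolerated.
read_xsv_points <- function(path, sep) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty spectrum: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  numeric_first <- length(first) >= 2L && !anyNA(first[1:2])
  # a non-numeric first row with >= 2 fields is a header; anything else
  # is data and must satisfy the two-numeric-fields contract below
  start <- if (!numeric_first && length(fields[[1L]]) >= 2L) 2L else 1L
  if (start > length(fields)) stop("empty spectrum: ", path)
  mass <- numeric(0); intensity <- numeric(0)
  for (i in seq(start, length(fields))) {
    f <- trimws(fields[[i]])
    if (length(f) < 2L)
      stop(sprintf("parse error in %s line %d: expected 2 fields, got %d",
                   path, lineno[i], length(f)))
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (anyNA(v))
      stop(sprintf("parse error in %s line %d field %d: not numeric ('%s')",
                   path, lineno[i], which(is.na(v))[1L],
                   f[which(is.na(v))[1L]]))
    mass[length(mass) + 1L] <- v[1L]
    intensity[length(intensity) + 1L] <- v[2L]
  }
  list(mass = mass, intensity = intensity)
}

read_mzml_points <- function(path, scan = 1L) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h), add = TRUE)
  p <- mzR::peaks(h, scan)
  list(mass = p[, 1L], intensity = p[, 2L])
}

#' Read a spectrum collection from a manifest
#'
#' The manifest is a CSV table with (case-insensitive) columns
#' `specimen_id`, `replicate_id`, `file`, `species`, `genus`, `class`,
#' `phylum`; taxon columns may be blank. One spectrum is read per row, in
#' row order, with the row's metadata attached.
#'
#' @param manifest Path to the manifest CSV (or an already-read data frame).
#' @param spectra_dir Directory that `file` entries are relative to.
#'
#' @return A list of [mass_spectrum()] objects.
#' @export
read_collection <- function(manifest, spectra_dir = ".") {
  m <- if (is.data.frame(manifest)) manifest else
    read.csv(manifest, stringsAsFactors = FALSE, check.names = FALSE)
  names(m) <- tolower(trimws(names(m)))
  need <- c(META_COLS[1:2], "file", META_COLS[3:6])
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest lacks required column(s): ", paste(miss, collapse = ", "))
  key <- paste(m$specimen_id, m$replicate_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (specimen_id, replicate_id) in manifest: ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "))
  paths <- file.path(spectra_dir, m$file)
  absent <- !file.exists(paths)
  if (any(absent))
    stop("manifest references missing file(s): ",
         paste(m$file[absent], collapse = ", "))
  blank2na <- function(x) { x <- as.character(x); x[!nzchar(trimws(x))] <- NA; x }
  lapply(seq_len(nrow(m)), function(i) {
    read_spectrum(paths[i],
                  specimen_id = m$specimen_id[i],
                  replicate_id = m$replicate_id[i],
                  species = blank2na(m$species)[i],
                  genus = blank2na(m$genus)[i],
                  class = blank2na(m$class)[i],
                  phylum = blank2na(m$phylum)[i])
  })
}

#' Construct a feature matrix
#'
#' Rows are specimens (or replicates), columns are binned mass features.
#'
#' @param values Numeric matrix, one row per specimen/replicate, `>= 0`.
#' @param feature_masses Strictly increasing bin masses (Da), one per column.
#' @param meta Data frame with columns `specimen_id`, `replicate_id`,
#'   `species`, `genus`, `class`, `phylum`; one row per matrix row.
#'
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_masses, meta) {
  values <- as.matrix(values)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty feature matrix")
  if (length(feature_masses) != ncol(values))
    stop("feature_masses length must match ncol(values)")
  if (length(feature_masses) > 1L &&
      is.unsorted(feature_masses, strictly = TRUE))
    stop("feature_masses must be strictly increasing")
  if (any(values < 0)) stop("feature intensities must be >= 0")
  if (!is.data.frame(meta) || nrow(meta) != nrow(values))
    stop("meta must be a data.frame with one row per matrix row")
  miss <- setdiff(META_COLS, names(meta))
  if (length(miss))
    stop("meta lacks column(s): ", paste(miss, collapse = ", "))
  meta <- meta[, META_COLS, drop = FALSE]
  colnames(values) <- fmt_mass(feature_masses)
  rownames(values) <- make.unique(
    ifelse(is.na(meta$replicate_id), meta$specimen_id,
           paste(meta$specimen_id, meta$replicate_id, sep = ".")))
  structure(list(values = values,
                 feature_masses = as.numeric(feature_masses),
                 meta = meta),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d rows x %d features (%.1f-%.1f Da), %d species\n",
              nrow(x$values), ncol(x$values),
              min(x$feature_masses), max(x$feature_masses),
              length(unique(x$meta$species[!is.na(x$meta$species)]))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# Feature column names with 4-decimal masses; collisions after rounding are
# disambiguated with a numeric suffix (and a warning).
feature_colnames <- function(feature_masses) {
  nm <- fmt_mass(feature_masses)
  if (anyDuplicated(nm)) {
    warning("feature names clash after 4-decimal rounding; ",
            "suffixing duplicates")
    dup <- duplicated(nm)
    nm <- stats::ave(nm, nm, FUN = function(v) {
      if (length(v) == 1L) v else c(v[1L], paste0(v[-1L], "_", seq_len(length(v) - 1L) + 1L))
    })
  }
  nm
}

#' Write / read a feature matrix as CSV
#'
#' Metadata columns precede feature columns; feature columns are named by
#' their bin mass with four decimals. The round trip is lossless to 12
#' significant digits.
#'
#' @param x A [feature_matrix()].
#' @param path Output CSV path.
#' @export
write_feature_matrix <- function(x, path) {
  stopifnot(inherits(x, "feature_matrix"))
  if (nrow(x$values) == 0L) stop("empty feature matrix")
  vals <- x$values
  colnames(vals) <- feature_colnames(x$feature_masses)
  df <- cbind(x$meta, as.data.frame(vals, check.names = FALSE))
  # full (15 sig digit) decimal representation keeps 12-digit round trips
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- format(df[[j]], digits = 15,
                                               scientific = FALSE, trim = TRUE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty feature matrix file: ", path)
  names(df)[seq_along(META_COLS)] <- tolower(names(df)[seq_along(META_COLS)])
  miss <- setdiff(META_COLS, names(df))
  if (length(miss))
    stop("feature matrix file lacks metadata column(s): ",
         paste(miss, collapse = ", "))
  meta <- df[, META_COLS, drop = FALSE]
  for (j in seq_along(meta)) meta[[j]] <- as.character(meta[[j]])
  feat <- df[, setdiff(names(df), META_COLS), drop = FALSE]
  if (ncol(feat) == 0L) stop("no feature columns in ", path)
  masses <- as.numeric(sub("_[0-9]+$", "", names(feat)))
  if (anyNA(masses))
    stop("unparseable feature column name(s): ",
         paste(names(feat)[is.na(masses)], collapse = ", "))
  if (anyDuplicated(masses)) {
    # collided 4-decimal names carry a suffix; spread them by sub-resolution
    # epsilons so the mass axis stays strictly increasing
    warning("duplicate feature masses after rounding; separating by 1e-5 Da")
    masses <- masses + stats::ave(masses, masses, FUN = seq_along) * 1e-5
  }
  vals <- as.matrix(feat)
  feature_matrix(vals, masses, meta)
}
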