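#' Subset rows of a feature matrix
#'
#' @param x A [feature_matrix()].
#' @param i Row index (logical or integer).
#' @return A [feature_matrix()] with the selected rows.
#' @export
subset_rows <- function(x, i) {
  stopifnot(inherits(x, "feature_matrix"))
  feature_matrix(x$values[i, , drop = FALSE], x$feature_masses,
                 x$meta[i, , drop = FALSE])
}

labels_at_level <- function(x, label_level, labels = NULL) {
  if (label_level == "custom") {
    if (is.null(labels)) stop("label_level = 'custom' requires `labels`")
    labels <- as.character(labels)
    if (length(labels) != nrow(x$values))
      stop("labels length must match number of rows")
    return(labels)
  }
  out <- x$meta[[label_level]]
  if (anyNA(out))
    stop("missing ", label_level, " label for row(s): ",
         paste(which(is.na(out)), collapse = ", "))
  as.character(out)
}

#' Train a random-forest fingerprint model
#'
#' Trains a random forest on (Hellinger-transformed) peak intensities and
#' stores, per class, the empirical distribution of out-of-bag (OOB)
#' assignment probabilities of that class's own training rows — the
#' fraction of OOB trees voting the true class. These distributions drive
#' the post-hoc acceptance test of [identify_specimens()].
#'
#' @param x A [feature_matrix()], normally Hellinger-transformed
#'   (see [hellinger()]).
#' @param label_level Taxonomic level of the class labels, or `"custom"`.
#' @param labels Character labels when `label_level = "custom"`.
#' @param ntree Number of trees (default 2000).
#' @param mtry Variables tried per split (default 35); clamped to
#'   `floor(sqrt(n_features))` with a warning when it exceeds the number
#'   of features.
#' @param seed RNG seed; fixes the model and its OOB error.
#'
#' @return A `fingerprint_model`: the forest plus `classes`, `oob_error`,
#'   `oob_votes`, `oob_predicted`, `oob_prob_by_class`, `labels`,
#'   `feature_masses`, the training values, and the call parameters.
#' @export
train_rf <- function(x, label_level = c("species", "genus", "class",
                                        "phylum", "custom"),
                     labels = NULL, ntree = 2000, mtry = 35, seed = 1) {
  stopifnot(inherits(x, "feature_matrix"))
  label_level <- match.arg(label_level)
  y <- labels_at_level(x, label_level, labels)
  tab <- table(y)
  if (length(tab) < 2L) stop("need at least 2 classes")
  if (any(tab < 2L))
    stop("class(es) with a single row: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  nf <- ncol(x$values)
  if (mtry > nf) {
    mtry <- max(1L, floor(sqrt(nf)))
    warning("mtry exceeds feature count; clamped to ", mtry)
  }
  yf <- factor(y)
  set.seed(seed)
  rf <- randomForest::randomForest(x = x$values, y = yf,
                                   ntree = ntree, mtry = mtry)
  oob_pred <- as.character(rf$predicted)
  oob_error <- mean(oob_pred != y)
  votes <- rf$votes  # OOB vote fractions, rows x classes
  own <- votes[cbind(seq_along(y), match(y, colnames(votes)))]
  structure(list(forest = rf, classes = levels(yf),
                 label_level = label_level,
                 ntree = ntree, mtry = mtry, seed = seed,
                 oob_error = oob_error,
                 oob_votes = votes, oob_predicted = oob_pred,
                 oob_prob_by_class = split(own, y),
                 labels = y,
                 feature_masses = x$feature_masses,
                 train_values = x$values, train_meta = x$meta),
            class = "fingerprint_model")
}

#' @export
print.fingerprint_model <- function(x, ...) {
  cat(sprintf("<fingerprint_model> %d classes (%s level) | %d features | ntree %d, mtry %d | OOB error %.4f\n",
              length(x$classes), x$label_level,
              length(x$feature_masses), x$ntree, x$mtry, x$oob_error))
  invisible(x)
}

#' Empirical post-hoc tail probability
#'
#' Left-tail proportion of a stored empirical distribution at `prob`:
#' the fraction of reference values `<= prob`. Used to compare a query's
#' assignment probability against the OOB assignment probabilities of the
#' predicted class.
#'
#' @param stored Numeric vector of reference probabilities.
#' @param prob Query assignment probability (vectorised).
#' @return Values in `[0, 1]`, monotone non-decreasing in `prob`.
#' @export
posthoc_probability <- function(stored, prob) {
  vapply(prob, function(p) mean(stored <= p), 1)
}

# Match query feature masses onto a model's feature set within a relative
# mass tolerance. Unmatched model features are imputed 0; unmatched query
# features are dropped with a warning.
align_query_values <- function(model, values, query_masses,
                               tolerance = 0.002) {
  fm <- model$feature_masses
  if (length(query_masses) != ncol(values))
    stop("query_masses length must match ncol(values)")
  out <- matrix(0, nrow = nrow(values), ncol = length(fm),
                dimnames = list(rownames(values), fmt_mass(fm)))
  used <- logical(length(query_masses))
  for (j in seq_along(fm)) {
    d <- abs(query_masses - fm[j])
    k <- which.min(d)
    if (length(k) && d[k] <= tolerance * fm[j]) {
      out[, j] <- values[, k]
      used[k] <- TRUE
    }
  }
  if (!any(used))
    stop("no query feature overlaps the model's feature masses")
  if (any(!used))
    warning(sum(!used), " query feature(s) outside the model feature set dropped")
  out
}

#' Build a query feature matrix on a model's feature set
#'
#' Re-bins query peak lists against a trained model's feature masses:
#' each query peak is assigned to the nearest model feature within the
#' relative mass `tolerance` (peaks matching no feature are ignored),
#' replicates are aggregated as in [build_feature_matrix()], and rows
#' are Hellinger-transformed. The result can be passed straight to
#' [identify_specimens()].
#'
#' @param model A [train_rf()] model.
#' @param peaklists List of [peak_list()] objects (query measurements).
#' @param metadata Optional taxon table keyed by `specimen_id`.
#' @param replicate_policy `"mean"` or `"separate"`.
#' @param tolerance Relative mass tolerance (default 0.002).
#' @return A Hellinger-transformed [feature_matrix()] aligned to the
#'   model's features.
#' @export
query_matrix_from_peaks <- function(model, peaklists, metadata = NULL,
                                    replicate_policy = c("mean", "separate"),
                                    tolerance = 0.002) {
  stopifnot(inherits(model, "fingerprint_model"))
  replicate_policy <- match.arg(replicate_policy)
  fm <- model$feature_masses
  aligned <- lapply(peaklists, function(p) {
    if (!length(p$mass))
      return(peak_list(numeric(0), numeric(0), numeric(0),
                       p$specimen_id, p$replicate_id))
    j <- vapply(p$mass, function(m) {
      k <- which.min(abs(fm - m))
      if (abs(fm[k] - m) <= tolerance * fm[k]) k else NA_integer_
    }, 1L)
    keep <- !is.na(j)
    # several peaks can fall on one feature: keep the most intense
    inten <- tapply(p$intensity[keep], j[keep], max)
    idx <- as.integer(names(inten))
    o <- order(fm[idx])
    peak_list(fm[idx][o], as.numeric(inten)[o],
              rep(NA_real_, length(idx)),
              specimen_id = p$specimen_id, replicate_id = p$replicate_id)
  })
  if (all(vapply(aligned, length, 1L) == 0L))
    stop("no query peak matches the model's feature masses")
  # carry the unmatched peak intensity as a pseudo-feature so the
  # Hellinger denominator reflects the whole fingerprint, as it does for
  # training rows whose every peak became a feature
  rest_mass <- max(fm) * 1.5
  aligned <- lapply(seq_along(aligned), function(i) {
    a <- aligned[[i]]
    rest <- sum(peaklists[[i]]$intensity) - sum(a$intensity)
    if (rest <= 0) return(a)
    peak_list(c(a$mass, rest_mass), c(a$intensity, rest),
              c(a$snr, NA_real_), a$specimen_id, a$replicate_id)
  })
  qfm <- suppressWarnings(
    build_feature_matrix(list(peaklists = aligned,
                              feature_masses = c(fm, rest_mass)),
                         metadata, replicate_policy))
  qfm <- hellinger(qfm)
  keep <- qfm$feature_masses < rest_mass
  feature_matrix(qfm$values[, keep, drop = FALSE],
                 qfm$feature_masses[keep], qfm$meta)
}

#' Identify query specimens with a fingerprint model
#'
#' Predicts the majority-vote class for each query row, records the vote
#' fraction (`prob`), and runs the empirical post-hoc test: `posthoc_p`
#' is the fraction of the predicted class's stored OOB assignment
#' probabilities that are `<= prob`; the identification is accepted iff
#' `posthoc_p > alpha`. Vote ties between classes are broken towards the
#' lexicographically first class label.
#'
#' @param model A [train_rf()] model.
#' @param query A [feature_matrix()] or numeric matrix of query rows.
#' @param query_masses Feature masses of the query columns (taken from the
#'   `feature_matrix` if omitted). Features are aligned to the model's
#'   masses within `tolerance`; absent features are imputed 0.
#' @param alpha Acceptance threshold of the post-hoc test (default 0.05).
#' @param tolerance Relative mass tolerance of feature alignment.
#' @return Data frame with `query_id`, `predicted`, `prob`, `posthoc_p`,
#'   `accepted`.
#' @export
identify_specimens <- function(model, query, query_masses = NULL,
                               alpha = 0.05, tolerance = 0.002) {
  stopifnot(inherits(model, "fingerprint_model"))
  if (inherits(query, "feature_matrix")) {
    query_masses <- query_masses %||% query$feature_masses
    values <- query$values
  } else {
    values <- as.matrix(query)
    if (is.null(query_masses))
      stop("query_masses required for a plain matrix query")
  }
  if (!isTRUE(all.equal(query_masses, model$feature_masses,
                        tolerance = 1e-12)))
    values <- align_query_values(model, values, query_masses, tolerance)
  else
    colnames(values) <- fmt_mass(model$feature_masses)
  votes <- predict(model$forest, values, type = "vote")
  if (is.null(dim(votes)))
    votes <- matrix(votes, nrow = 1,
                    dimnames = list(rownames(values)[1],
                                    colnames(model$forest$votes)))
  # columns are factor levels, already in lexicographic order:
  # ties.method = "first" implements the lexicographic tie-break
  jmax <- max.col(votes, ties.method = "first")
  predicted <- colnames(votes)[jmax]
  prob <- votes[cbind(seq_len(nrow(votes)), jmax)]
  posthoc_p <- vapply(seq_along(predicted), function(i)
    posthoc_probability(model$oob_prob_by_class[[predicted[i]]], prob[i]), 1)
  data.frame(query_id = rownames(values) %||% as.character(seq_along(predicted)),
             predicted = predicted, prob = prob,
             posthoc_p = posthoc_p, accepted = posthoc_p > alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Leave-one-out species identification
#'
#' For every specimen in turn: remove it (all of it — the matrix is
#' expected at specimen level, replicates already aggregated), retrain the
#' species-level forest on the remainder, and identify the held-out
#' specimen with the post-hoc test. Summaries report the fraction of
#' correct identifications and of correct-and-accepted ("true positive")
#' identifications, overall and per class / phylum.
#'
#' @param x Hellinger-transformed specimen-level [feature_matrix()].
#' @param min_specimens Minimum specimens a species needs to take part
#'   (default 6).
#' @param filter_low Drop species below `min_specimens` (with a report)
#'   instead of erroring.
#' @param alpha Post-hoc acceptance threshold.
#' @param ntree,mtry Forest size parameters (see [train_rf()]).
#' @param seed Master seed; each refit uses a derived per-specimen seed.
#' @return A list with `identifications` (one row per specimen, incl. the
#'   true species), `summary`, `per_class`, `per_phylum`,
#'   `excluded_species`.
#' @export
loo_species_identification <- function(x, min_specimens = 6,
                                       filter_low = FALSE, alpha = 0.05,
                                       ntree = 2000, mtry = 35, seed = 1) {
  stopifnot(inherits(x, "feature_matrix"))
  counts <- table(x$meta$species)
  low <- names(counts)[counts < min_specimens]
  if (length(low)) {
    if (!filter_low)
      stop("species below min_specimens (", min_specimens, "): ",
           paste(low, collapse = ", "), "; set filter_low = TRUE to drop")
    x <- subset_rows(x, !(x$meta$species %in% low))
  }
  n <- nrow(x$values)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    model <- suppressWarnings(
      train_rf(subset_rows(x, -i), "species", ntree = ntree, mtry = mtry,
               seed = derive_seed(seed, i)))
    id <- identify_specimens(model, subset_rows(x, i), alpha = alpha)
    id$query_id <- x$meta$specimen_id[i]
    id$species <- x$meta$species[i]
    id$class <- x$meta$class[i]
    id$phylum <- x$meta$phylum[i]
    res[[i]] <- id
  }
  ids <- do.call(rbind, res)
  ids$correct <- ids$predicted == ids$species
  ids$tp <- ids$correct & ids$accepted
  grp_summary <- function(g) {
    do.call(rbind, lapply(split(ids, g), function(d)
      data.frame(n = nrow(d), correct = mean(d$correct),
                 accepted_correct = mean(d$tp))))
  }
  list(identifications = ids,
       summary = data.frame(n = nrow(ids), correct = mean(ids$correct),
                            accepted_correct = mean(ids$tp)),
       per_class = grp_summary(ids$class),
       per_phylum = grp_summary(ids$phylum),
       excluded_species = low)
}

#' Higher-taxon fallback classification
#'
#' Emulates querying a reference library with a species it does not
#' contain: for each species in turn, all of its rows are removed, a
#' forest is trained on class- or phylum-level labels of the remainder,
#' and the removed specimens are classified at that level with the
#' post-hoc test. A species that is the sole member of its higher-taxon
#' category is skipped with a warning (its category would vanish from
#' training).
#'
#' @param x Hellinger-transformed specimen-level [feature_matrix()].
#' @param level `"class"` or `"phylum"`.
#' @inheritParams loo_species_identification
#' @return A list with `identifications`, `per_category` (n, correct
#'   fraction, accepted-correct fraction), `summary`, `skipped_species`.
#' @export
highertax_fallback <- function(x, level = c("class", "phylum"),
                               alpha = 0.05, ntree = 2000, mtry = 35,
                               seed = 1) {
  stopifnot(inherits(x, "feature_matrix"))
  level <- match.arg(level)
  cats <- labels_at_level(x, level)
  if (length(unique(cats)) < 2L)
    stop("need at least 2 ", level, " categories")
  species <- x$meta$species
  res <- list(); skipped <- character(0)
  for (sp in unique(species)) {
    hold <- species == sp
    if (!any(cats[!hold] == cats[hold][1L])) {
      warning("species ", sp, " is the sole member of its ", level,
              "; skipped")
      skipped <- c(skipped, sp)
      next
    }
    model <- suppressWarnings(
      train_rf(subset_rows(x, !hold), level, ntree = ntree, mtry = mtry,
               seed = derive_seed(seed, which(unique(species) == sp))))
    id <- identify_specimens(model, subset_rows(x, hold), alpha = alpha)
    id$query_id <- x$meta$specimen_id[hold]
    id$species <- sp
    id$truth <- cats[hold]
    res[[length(res) + 1L]] <- id
  }
  if (!length(res)) stop("every species was skipped")
  ids <- do.call(rbind, res)
  ids$correct <- ids$predicted == ids$truth
  ids$tp <- ids$correct & ids$accepted
  per_cat <- do.call(rbind, lapply(split(ids, ids$truth), function(d)
    data.frame(n = nrow(d), correct = mean(d$correct),
               accepted_correct = mean(d$tp))))
  list(identifications = ids, per_category = per_cat,
       summary = data.frame(n = nrow(ids), correct = mean(ids$correct),
                            accepted_correct = mean(ids$tp)),
       skipped_species = skipped)
}

#' Congeneric affinity of excluded species
#'
#' For every species that has at least one congener in the library:
#' remove the species, retrain the species-level forest, classify the
#' removed specimens, and record the fraction assigned to a congeneric
#' species. The overall value is the specimen-weighted mean.
#'
#' @param x Hellinger-transformed specimen-level [feature_matrix()].
#' @inheritParams loo_species_identification
#' @return A list with `overall` (fraction of specimens classified as a
#'   congener) and `per_species` (species, genus, n, congeneric fraction).
#' @export
congeneric_affinity <- function(x, ntree = 2000, mtry = 35, seed = 1) {
  stopifnot(inherits(x, "feature_matrix"))
  sp_genus <- unique(x$meta[, c("species", "genus")])
  genus_n <- table(sp_genus$genus)
  eligible <- sp_genus$species[sp_genus$genus %in%
                                 names(genus_n)[genus_n >= 2L]]
  if (!length(eligible))
    stop("no genus with at least two species in the library")
  rows <- list()
  for (sp in eligible) {
    hold <- x$meta$species == sp
    gen <- x$meta$genus[hold][1L]
    congeners <- setdiff(sp_genus$species[sp_genus$genus == gen], sp)
    model <- suppressWarnings(
      train_rf(subset_rows(x, !hold), "species", ntree = ntree,
               mtry = mtry, seed = derive_seed(seed, match(sp, eligible))))
    id <- identify_specimens(model, subset_rows(x, hold))
    rows[[length(rows) + 1L]] <-
      data.frame(species = sp, genus = gen, n = sum(hold),
                 congeneric = mean(id$predicted %in% congeners),
                 stringsAsFactors = FALSE)
  }
  per_species <- do.call(rbind, rows)
  list(overall = sum(per_species$congeneric * per_species$n) /
         sum(per_species$n),
       per_species = per_species)
}

#' Top discriminating peaks by Gini importance
#'
#' Ranks features by the forest's mean decrease in Gini impurity and
#' attaches, per class, the mean (Hellinger) intensity of each feature —
#' the data behind importance heat maps.
#'
#' @param model A [train_rf()] model.
#' @param k Number of top features (default 30; clamped with a warning).
#' @return Data frame: `feature_mass`, `importance` (non-increasing), one
#'   mean-intensity column per class.
#' @export
gini_top_peaks <- function(model, k = 30) {
  stopifnot(inherits(model, "fingerprint_model"))
  imp <- model$forest$importance[, "MeanDecreaseGini"]
  if (k > length(imp)) {
    warning("k exceeds feature count; clamped to ", length(imp))
    k <- length(imp)
  }
  o <- order(imp, decreasing = TRUE)[seq_len(k)]
  out <- data.frame(feature_mass = model$feature_masses[o],
                    importance = as.numeric(imp[o]))
  for (cl in model$classes)
    out[[paste0("mean_", cl)]] <-
      colMeans(model$train_values[model$labels == cl, o, drop = FALSE])
  out
}

#' Hierarchical clustering with feature-bootstrap node support
#'
#' Clusters rows (Euclidean distance of Hellinger intensities) and scores
#' every internal node by the percentage of `B` feature-bootstrap
#' replicates (columns resampled with replacement) in which the node's
#' leaf set reappears.
#'
#' @param x A Hellinger-transformed [feature_matrix()].
#' @param linkage `"average"` or `"ward"` (Ward's D2).
#' @param B Number of bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @return A list with `hclust`, `phylo` (node labels = support %),
#'   `support` (per internal node), and `newick`.
#' @export
cluster_bootstrap <- function(x, linkage = c("average", "ward"), B = 100,
                              seed = 1) {
  stopifnot(inherits(x, "feature_matrix"))
  linkage <- match.arg(linkage)
  if (B < 1) stop("B must be >= 1")
  if (nrow(x$values) < 3L) stop("need at least 3 rows to cluster")
  method <- if (linkage == "ward") "ward.D2" else "average"
  X <- x$values
  hc <- hclust(dist(X), method = method)
  ref <- ape::as.phylo(hc)
  set.seed(seed)
  boots <- lapply(seq_len(B), function(b) {
    cols <- sample.int(ncol(X), replace = TRUE)
    ape::as.phylo(hclust(dist(X[, cols, drop = FALSE]), method = method))
  })
  cnt <- ape::prop.clades(ref, boots, rooted = TRUE)
  cnt[is.na(cnt)] <- 0
  support <- 100 * cnt / B
  ref$node.label <- format(support, trim = TRUE)
  list(hclust = hc, phylo = ref, support = support,
       newick = ape::write.tree(ref))
}
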