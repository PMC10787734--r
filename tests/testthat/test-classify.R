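# Direct construction of labelled feature matrices keeps these tests fast.
toy_matrix <- function(n_per_class, centers, noise = 0.02, seed = 1,
                       species = NULL, genus = NULL, class_ = NULL,
                       phylum = NULL) {
  set.seed(seed)
  k <- nrow(centers)
  species <- species %||% paste0("S", seq_len(k))
  X <- do.call(rbind, lapply(seq_len(k), function(c_) {
    t(replicate(n_per_class,
                pmax(centers[c_, ] + rnorm(ncol(centers), 0, noise), 0)))
  }))
  meta <- data.frame(
    specimen_id = paste0("sp", seq_len(nrow(X))),
    replicate_id = NA_character_,
    species = rep(species, each = n_per_class),
    genus = rep(genus %||% paste0("G", seq_len(k)), each = n_per_class),
    class = rep(class_ %||% "C1", each = n_per_class),
    phylum = rep(phylum %||% "P1", each = n_per_class))
  feature_matrix(X, seq(2000, by = 500, length.out = ncol(centers)), meta)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

disjoint_centers <- rbind(c(1, 1, 1, 0, 0, 0, 0.2, 0.2),
                          c(0, 0, 0, 1, 1, 1, 0.2, 0.2))

test_that("well-separated classes give near-zero OOB error across seeds", {
  for (seed in 1:10) {
    fm <- toy_matrix(8, disjoint_centers, seed = seed)
    m <- train_rf(fm, "species", ntree = 300, mtry = 3, seed = seed)
    expect_lte(m$oob_error, 0.02)
  }
})

test_that("randomly permuted labels give chance-level OOB error", {
  errs <- vapply(1:10, function(seed) {
    fm <- toy_matrix(12, disjoint_centers, seed = seed)
    set.seed(seed + 100)
    fm$meta$species <- sample(fm$meta$species)
    suppressWarnings(
      train_rf(fm, "species", ntree = 300, mtry = 3,
               seed = seed)$oob_error)
  }, 1)
  expect_gte(mean(errs), 0.4)
  expect_lte(mean(errs), 0.6)
  expect_true(all(errs >= 0.25 & errs <= 0.75))
})

test_that("training is reproducible under a fixed seed and validates inputs", {
  fm <- toy_matrix(6, disjoint_centers)
  m1 <- train_rf(fm, "species", ntree = 200, mtry = 3, seed = 9)
  m2 <- train_rf(fm, "species", ntree = 200, mtry = 3, seed = 9)
  expect_equal(m1$oob_error, m2$oob_error)
  expect_equal(m1$oob_votes, m2$oob_votes)

  expect_warning(train_rf(fm, "species", ntree = 100, mtry = 35, seed = 1),
                 "clamped")
  bad <- subset_rows(fm, -1)
  expect_error(suppressWarnings(
    train_rf(subset_rows(bad, bad$meta$species != "S1" |
                           bad$meta$specimen_id == "sp2"),
             "species", ntree = 50, seed = 1)), "single row")
})

test_that("stored OOB distributions recount to the reported OOB error", {
  fm <- toy_matrix(8, disjoint_centers, noise = 0.25, seed = 3)
  m <- train_rf(fm, "species", ntree = 500, mtry = 3, seed = 3)
  votes <- m$oob_votes
  recount <- colnames(votes)[max.col(votes, ties.method = "first")]
  expect_equal(mean(recount != m$labels), m$oob_error)
  expect_equal(sort(unname(unlist(m$oob_prob_by_class))),
               sort(votes[cbind(seq_along(m$labels),
                                match(m$labels, colnames(votes)))]))
})

test_that("posthoc probability is the empirical left tail and is monotone", {
  stored <- c(0.4, 0.6, 0.8, 1.0)
  expect_equal(posthoc_probability(stored, 0.6), 0.5)
  expect_equal(posthoc_probability(stored, 1.0), 1.0)
  expect_equal(posthoc_probability(stored, 0.39), 0.0)
  probs <- seq(0, 1, by = 0.05)
  expect_true(all(diff(posthoc_probability(stored, probs)) >= 0))
})

test_that("identification returns the own class with acceptance on separable data", {
  fm <- toy_matrix(8, disjoint_centers, seed = 5)
  m <- train_rf(fm, "species", ntree = 300, mtry = 3, seed = 5)
  ids <- identify_specimens(m, fm)
  expect_equal(ids$predicted, fm$meta$species)
  expect_true(all(ids$prob >= 0 & ids$prob <= 1))
  expect_true(all(ids$accepted == (ids$posthoc_p > 0.05)))
  expect_true(all(ids$accepted))
})

test_that("query features are aligned by mass, imputing absences", {
  fm <- toy_matrix(8, disjoint_centers, seed = 6)
  m <- train_rf(fm, "species", ntree = 300, mtry = 3, seed = 6)
  # query with a shuffled subset of features plus an unknown one
  keep <- c(1, 2, 3, 4, 5, 6)
  qv <- fm$values[1:4, keep, drop = FALSE]
  qv <- cbind(qv, extra = 0.5)
  qm <- fm$feature_masses[keep] + 0.05   # within tolerance
  expect_warning(ids <- identify_specimens(m, qv, query_masses = c(qm, 12000)),
                 "dropped")
  expect_equal(ids$predicted, fm$meta$species[1:4])
  expect_error(identify_specimens(m, qv[, 1:2], query_masses = c(1, 2)),
               "no query feature")
})

test_that("leave-one-out identification is perfect on separable data and reports exclusions", {
  centers3 <- rbind(c(1, 1, 1, 0, 0, 0, 0.2, 0.2, 0, 0),
                    c(0, 0, 0, 1, 1, 1, 0.2, 0.2, 0, 0),
                    c(0.2, 0, 0, 0, 0, 0.2, 0, 0, 1, 1))
  fm <- toy_matrix(6, centers3, seed = 7)
  loo <- loo_species_identification(fm, min_specimens = 6, ntree = 200,
                                    mtry = 3, seed = 7)
  expect_equal(loo$summary$correct, 1)
  expect_lte(loo$summary$accepted_correct, loo$summary$correct)
  expect_equal(nrow(loo$identifications), nrow(fm$values))

  # a species below the threshold errors, or is dropped when filtered
  fm2 <- subset_rows(fm, -1)
  expect_error(loo_species_identification(fm2, min_specimens = 6,
                                          ntree = 50, seed = 1),
               "below min_specimens")
  loo2 <- suppressWarnings(
    loo_species_identification(fm2, min_specimens = 6,
                               filter_low = TRUE, ntree = 200,
                               mtry = 3, seed = 7))
  expect_equal(loo2$excluded_species, "S1")
  expect_false("S1" %in% loo2$identifications$species)
})

test_that("higher-taxon fallback classifies held-out species and skips lone members", {
  centers <- rbind(c(1, 1, 0.6, 0, 0, 0, 0.3, 0),
                   c(1, 1, 0, 0.6, 0, 0, 0, 0.3),
                   c(0, 0, 0.3, 0, 1, 1, 0.6, 0),
                   c(0, 0, 0, 0.3, 1, 1, 0, 0.6))
  fm <- toy_matrix(6, centers, noise = 0.05, seed = 8,
                   class_ = c("C1", "C1", "C2", "C2"))
  fb <- highertax_fallback(fm, "class", ntree = 300, mtry = 3, seed = 8)
  expect_gte(fb$summary$correct, 0.9)
  expect_true(all(fb$per_category$accepted_correct <=
                    fb$per_category$correct))

  fm_lone <- toy_matrix(6, centers, noise = 0.05, seed = 8,
                        class_ = c("C1", "C1", "C1", "C2"))
  expect_warning(fb2 <- highertax_fallback(fm_lone, "class", ntree = 200,
                                           mtry = 3, seed = 8),
                 "sole member")
  expect_equal(fb2$skipped_species, "S4")
})

test_that("congeneric affinity exceeds chance when congeners share peaks", {
  # genus pairs share half their peaks; unrelated genera share none
  centers <- rbind(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
                   c(1, 1, 0, 0, 1, 1, 0, 0, 0, 0, 0, 0),
                   c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 0, 0),
                   c(0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 1, 1))
  fm <- toy_matrix(6, centers, noise = 0.08, seed = 9,
                   genus = c("Ga", "Ga", "Gb", "Gb"))
  ca <- congeneric_affinity(fm, ntree = 300, mtry = 3, seed = 9)
  expect_true(all(ca$per_species$congeneric >= 0 &
                    ca$per_species$congeneric <= 1))
  expect_gt(ca$overall, 1 / 3)   # chance: 1 congener among 3 classes
  expect_equal(nrow(ca$per_species), 4)

  fm_solo <- toy_matrix(6, centers[1:2, ], noise = 0.05, seed = 9,
                        genus = c("Ga", "Gb"))
  expect_error(congeneric_affinity(fm_solo, ntree = 50, seed = 1),
               "no genus")
})

test_that("Gini ranking finds the discriminating feature and ignores constants", {
  centers <- rbind(c(0.5, 0.5, 0.9, 0.5), c(0.5, 0.5, 0.1, 0.5))
  fm <- toy_matrix(10, centers, noise = 0.03, seed = 10)
  fm$values[, 4] <- 0.5   # exactly constant
  m <- train_rf(fm, "species", ntree = 500, mtry = 2, seed = 10)
  top <- gini_top_peaks(m, k = 4)
  expect_equal(top$feature_mass[1], fm$feature_masses[3])
  expect_true(all(diff(top$importance) <= 0))
  const_imp <- top$importance[top$feature_mass == fm$feature_masses[4]]
  expect_lte(const_imp, 1e-6 * sum(top$importance))
  expect_true(all(c("mean_S1", "mean_S2") %in% names(top)))
  expect_warning(gini_top_peaks(m, k = 99), "clamped")
})

test_that("bootstrap clustering gives full support to well-separated groups", {
  set.seed(12)
  X <- rbind(matrix(rnorm(5 * 20, 0, 0.05), 5) + rep(c(1, 0), each = 10)[col(matrix(0, 5, 20))],
             matrix(rnorm(5 * 20, 0, 0.05), 5) + rep(c(0, 1), each = 10)[col(matrix(0, 5, 20))])
  X <- pmax(X, 0)
  meta <- data.frame(specimen_id = paste0("sp", 1:10),
                     replicate_id = NA, species = rep(c("A", "B"), each = 5),
                     genus = "G", class = "C", phylum = "P")
  fm <- feature_matrix(X, seq(2000, by = 100, length.out = 20), meta)
  cb <- cluster_bootstrap(fm, "average", B = 50, seed = 1)
  expect_equal(length(cb$phylo$tip.label), 10)
  # the two 5-leaf group nodes must be fully supported
  grp <- cutree(cb$hclust, k = 2)
  expect_equal(unname(table(grp)), c(5L, 5L), ignore_attr = TRUE)
  # root plus both 5-leaf group nodes are recovered in every replicate
  expect_gte(sum(cb$support == 100), 3)
  cb2 <- cluster_bootstrap(fm, "average", B = 50, seed = 1)
  expect_equal(cb$support, cb2$support)
  expect_match(cb$newick, "^\\(")
  expect_error(cluster_bootstrap(fm, B = 0), "B must be")
})
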