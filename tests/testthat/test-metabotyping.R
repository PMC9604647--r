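test_that("choose_k votes follow the planted number of blobs", {
  centers3 <- rbind(c(0, 0), c(8, 0), c(0, 8))  # >= 6 SD separation
  b3 <- make_blobs(60, centers3, sd = 1, seed = 1)
  imp3 <- as_imputation_set(b3$X)
  res3 <- choose_k(imp3, c("x1", "x2"), k_range = 2:6,
                   n_gap_references = 20, n_init = 10, seed = 2)
  expect_equal(res3$k, 3)
  expect_gte(sum(res3$votes == 3), 4)  # Hartigan's <=10 rule may overshoot

  b2 <- make_blobs(80, rbind(c(0, 0), c(8, 8)), sd = 1, seed = 3)
  res2 <- choose_k(as_imputation_set(b2$X), c("x1", "x2"), k_range = 2:6,
                   n_gap_references = 20, n_init = 10, seed = 4)
  expect_equal(res2$k, 2)
  expect_gte(sum(res2$votes == 2), 4)
})

test_that("the gap statistic votes the smallest k on structureless data", {
  for (s in 1:3) {
    b <- make_blobs(300, rbind(c(0, 0, 0)), sd = 1, seed = s)
    res <- choose_k(as_imputation_set(b$X), c("x1", "x2", "x3"),
                    k_range = 2:6, n_gap_references = 20, n_init = 5,
                    seed = s)
    expect_equal(unname(res$votes["gap"]), 2)
  }
})

test_that("choose_k refuses k_range beyond n/10", {
  b <- make_blobs(10, rbind(c(0, 0), c(5, 5)), seed = 1)
  expect_error(choose_k(as_imputation_set(b$X), c("x1", "x2"),
                        k_range = 2:5), "n/10")
})

test_that("consensus with identical imputations equals a single k-means run", {
  b <- make_blobs(50, rbind(c(0, 0), c(4, 0), c(0, 4)), sd = 1, seed = 5)
  Z <- scale(b$X)
  imp <- as_imputation_set(list(Z, Z, Z))
  imp$standardized <- TRUE
  model <- kmeans_consensus(imp, c("x1", "x2"), k = 3, seed = 6)
  single <- metabotyper:::.kmeans_best(Z[, c("x1", "x2")], 3, n_init = 25,
                                       seed = 6)
  expect_identical(model$assignment, unname(single$cluster))
  expect_equal(model$centroids, single$centers, ignore_attr = TRUE)
  expect_equal(sum(tabulate(model$assignment, 3)), nrow(Z))
})

test_that("consensus is invariant to the order of the imputations", {
  set.seed(7)
  b <- make_blobs(60, rbind(c(0, 0), c(4, 0), c(0, 4)), sd = 1.2, seed = 7)
  mats <- lapply(1:3, function(i) scale(b$X + rnorm(length(b$X), sd = 0.05)))
  imp <- as_imputation_set(mats); imp$standardized <- TRUE
  rev_imp <- as_imputation_set(rev(mats)); rev_imp$standardized <- TRUE
  m1 <- order_clusters(kmeans_consensus(imp, c("x1", "x2"), seed = 8))
  m2 <- order_clusters(kmeans_consensus(rev_imp, c("x1", "x2"), seed = 8))
  expect_identical(m1$assignment, m2$assignment)
})

test_that("label alignment undoes arbitrary centroid permutations", {
  ref <- rbind(c(0, 0), c(5, 0), c(0, 5))
  for (p in metabotyper:::.permutations(3)) {
    perm_found <- metabotyper:::.align_labels(ref, ref[order(p), ])
    expect_equal(ref[order(p), ][perm_found, ], ref)
  }
})

test_that("cluster ordering follows composite unfavorability", {
  model <- structure(
    list(model_id = 1L, parameter_subset = c("glucose", "hdlc"), k = 3,
         per_imputation_centroids = list(),
         centroids = rbind(c(1, -1), c(0, 0), c(-1, 1)),
         assignment = rep(1:3, times = c(10, 20, 30)),
         ordering_scores = NULL, smallest_cluster_n = 10,
         admissible = NA, settings = list()),
    class = "metabotype_model")
  colnames(model$centroids) <- c("glucose", "hdlc")
  ordered <- order_clusters(model)
  # centroid (glucose=+1, hdlc=-1) is least favorable -> becomes cluster 3
  expect_equal(ordered$ordering_scores, c(-1, 0, 1))
  expect_equal(ordered$assignment[1], 3L)   # was cluster 1
  expect_equal(ordered$assignment[40], 1L)  # was cluster 3
  # relabeling input clusters does not change the final ordering
  relabeled <- model
  relabeled$centroids <- model$centroids[c(3, 1, 2), , drop = FALSE]
  relabeled$assignment <- match(model$assignment, c(3L, 1L, 2L))
  ordered2 <- order_clusters(relabeled)
  expect_identical(ordered2$assignment, ordered$assignment)
})

test_that("consensus recovers planted structure under missingness", {
  co <- generate_cohort(generator_config(
    n_participants = 900, missing_rate = 0.05, nonfasting_rate = 0,
    seed = 9))
  X <- as.matrix(co[, clinical_parameters()$parameter])
  imp <- z_standardize(impute_chained(X, m = 3, iterations = 5, seed = 10))
  model <- order_clusters(kmeans_consensus(
    imp, clinical_parameters()$parameter, k = 3, seed = 11))
  expect_gt(mclust::adjustedRandIndex(model$assignment, co$latent_group),
            0.9)
  # unfavorability ordering tracks the latent risk ordering
  mean_latent <- tapply(co$latent_group, model$assignment, mean)
  expect_true(all(diff(mean_latent) > 0))
})

test_that("model enumeration is exhaustive, ordered, and validated", {
  pool <- c("glucose", "bmi", "uric_acid", "hdlc", "non_hdlc", "tg")
  subs <- enumerate_models(pool, min_size = 3)
  expect_length(subs, 42)  # C(6,3)+C(6,4)+C(6,5)+C(6,6)
  expect_equal(names(subs), as.character(1:42))
  expect_true(all(lengths(subs) >= 3))
  expect_length(enumerate_models(pool, min_size = length(pool)), 1)

  explicit <- list(c("glucose", "bmi", "uric_acid", "hdlc", "non_hdlc"),
                   c("glucose", "tg", "hdlc", "non_hdlc"))
  got <- enumerate_models(pool, explicit = explicit)
  expect_equal(got[[1]], sort(explicit[[1]]))
  expect_equal(got[[2]], sort(explicit[[2]]))
  expect_error(enumerate_models(pool, explicit = c(explicit, explicit[1])),
               "duplicate")
  expect_error(enumerate_models(pool, explicit = list(c("glucose", "nope"))),
               "outside")
})

test_that("admissibility implements the 5%-or-150 disjunction", {
  mk <- function(smallest) structure(
    list(model_id = 1L, parameter_subset = c("a", "b"), k = 3,
         smallest_cluster_n = smallest, admissible = NA),
    class = "metabotype_model")
  expect_true(check_admissible(mk(372), 3001)$admissible)
  expect_false(check_admissible(mk(149), 3001)$admissible)
  expect_true(check_admissible(mk(150), 3001)$admissible)   # 150 arm
  expect_true(check_admissible(mk(151), 2000)$admissible)
  expect_true(check_admissible(mk(120), 2000)$admissible)   # 5% arm: 120 >= 100
  expect_false(check_admissible(mk(120), 3001,
                                mode = "conjunctive")$admissible)
  expect_true(check_admissible(mk(151), 3001,
                               mode = "disjunctive")$admissible)
})

test_that("model ranking orders by incidence with documented tie-breaks", {
  n <- 60
  mk_model <- function(id, subset, assignment) structure(
    list(model_id = id, parameter_subset = subset, k = 3,
         assignment = assignment, ordering_scores = c(-1, 0, 1),
         smallest_cluster_n = min(tabulate(assignment, 3)),
         admissible = TRUE),
    class = "metabotype_model")
  assign_a <- rep(1:3, each = 20)
  co <- flag_cohort(n, fu_t2d = c(rep(FALSE, 40), rep(c(TRUE, FALSE), 10)))
  # model A cluster 3: 10/20 incident; model B cluster 3 = rows 21..40: 0/20
  mA <- mk_model(1L, c("glucose", "bmi"), assign_a)
  mB <- mk_model(2L, c("tg", "hdlc"), c(rep(1, 20), rep(3, 20), rep(2, 20)))
  rk <- rank_models(list(mB, mA), co, "t2d")
  expect_equal(rk$model_id, c(1L, 2L))
  expect_equal(rk$incidence, c(0.5, 0))
  expect_equal(rk$rank, 1:2)

  # identical incidence and counts: fewer parameters wins
  mC <- mk_model(3L, c("glucose", "bmi", "tg"), assign_a)
  rk2 <- rank_models(list(mC, mA), co, "t2d")
  expect_equal(rk2$model_id, c(1L, 3L))

  # baseline-positive participants never count as at risk
  co2 <- flag_cohort(n, base_t2d = rep(TRUE, n))
  expect_warning(expect_error(rank_models(list(mA), co2, "t2d"),
                              "no rankable"),
                 "empty cluster-3 at-risk")
})
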