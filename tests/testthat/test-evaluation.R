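test_that("pooled median/IQR averages the per-imputation summaries", {
  X <- matrix(c(1, 2, 3, 10, 20, 30), 6, 1, dimnames = list(NULL, "v"))
  groups <- rep(c("a", "b"), each = 3)
  # zero missingness: identical to the plain median/IQR
  imp <- as_imputation_set(list(X, X))
  res <- pooled_median_iqr(imp, "v", groups)
  expect_equal(res$median, c(2, 20))
  expect_equal(res$iqr, c(1, 10))

  # m = 2 with group medians 10 and 12 -> pooled 11
  X1 <- matrix(c(9, 10, 11), 3, 1, dimnames = list(NULL, "v"))
  X2 <- matrix(c(11, 12, 13), 3, 1, dimnames = list(NULL, "v"))
  res2 <- pooled_median_iqr(as_imputation_set(list(X1, X2)), "v",
                            rep("g", 3))
  expect_equal(res2$median, 11)
  expect_error(pooled_median_iqr(imp, "v", factor(groups,
                                                  levels = c("a", "b", "c"))),
               "empty group")
})

test_that("the unfavorable cluster has the highest pooled glucose median", {
  co <- generate_cohort(generator_config(n_participants = 600,
                                         missing_rate = 0,
                                         nonfasting_rate = 0, seed = 21))
  X <- as.matrix(co[, clinical_parameters()$parameter])
  imp <- impute_chained(X, m = 2, iterations = 2, seed = 22)
  res <- pooled_median_iqr(imp, "glucose", co$latent_group)
  expect_equal(which.max(res$median), 3L)
  expect_true(all(diff(res$median) > 0))
})

test_that("Kruskal-Wallis matches a brute-force rank-sum oracle", {
  values <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  groups <- rep(c("a", "b", "c"), each = 3)
  res <- test_across_groups(values, groups, "continuous")
  # oracle: H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2, no ties
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(3 * (tapply(r, groups, mean) - (N + 1) / 2)^2)
  expect_equal(res$statistic, H, tolerance = 1e-9)
  expect_equal(res$p_value, pchisq(H, df = 2, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(res$test, "kruskal_wallis")
  expect_equal(res$n_used, 9)
})

test_that("chi-square matches the hand-computed statistic", {
  values <- rep(c("x", "y"), times = c(40, 60))
  groups <- c(rep("g1", 30), rep("g2", 40), rep("g3", 30))
  # contingency table constructed to keep all expected counts >= 5
  res <- test_across_groups(values, groups, "categorical")
  tab <- table(values, groups)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  X2 <- sum((tab - expected)^2 / expected)
  expect_equal(res$test, "chi_square")
  expect_equal(res$statistic, X2, tolerance = 1e-9)
  expect_equal(res$p_value, pchisq(X2, df = 2, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("low expected counts switch to Fisher's exact test", {
  values <- rep(c("x", "y"), times = c(6, 54))
  groups <- rep(c("g1", "g2", "g3"), each = 20)
  res <- test_across_groups(values, groups, "categorical")
  expect_equal(res$test, "fisher")
  tab <- table(values, groups)
  expect_equal(res$p_value, fisher.test(tab)$p.value, tolerance = 1e-9)
})

test_that("degenerate inputs give p = 1 with a flag", {
  res <- test_across_groups(rep(5, 10), rep(c("a", "b"), 5), "continuous")
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("Dunn post hoc p-values are Bonferroni-adjusted and monotone", {
  set.seed(31)
  values <- c(rnorm(20), rnorm(20, 1), rnorm(20, 4))
  groups <- rep(c("a", "b", "c"), each = 20)
  res <- test_across_groups(values, groups, "continuous")
  expect_length(res$posthoc, 3)
  expect_true(all(res$posthoc >= 0 & res$posthoc <= 1))
  # the widely separated pair is at least as significant as the close one
  expect_lte(res$posthoc[["a vs c"]], res$posthoc[["a vs b"]])
  # adjusted p = min(1, raw p * 3): recompute one pair by hand
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tc <- sum(ties^3 - ties) / (12 * (N - 1))
  z <- (mean(r[groups == "a"]) - mean(r[groups == "b"])) /
    sqrt((N * (N + 1) / 12 - tc) * (1 / 20 + 1 / 20))
  expect_equal(res$posthoc[["a vs b"]],
               min(1, 2 * pnorm(-abs(z)) * 3), tolerance = 1e-12)
})

test_that("group tests hold their nominal type-I error", {
  set.seed(41)
  n_rep <- 400
  rejections <- vapply(seq_len(n_rep), function(i) {
    values <- rnorm(45)
    groups <- rep(c("a", "b", "c"), each = 15)
    test_across_groups(values, groups, "continuous")$p_value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("prevalence handles composites, denominators, and missingness", {
  co <- flag_cohort(10,
    base_hypertension = c(TRUE, TRUE, FALSE, FALSE, FALSE, NA, FALSE,
                          FALSE, FALSE, FALSE),
    base_t2d = c(FALSE, TRUE, TRUE, FALSE, FALSE, NA, FALSE, FALSE,
                 FALSE, FALSE))
  tab <- prevalence_table(co, outcomes = c("hypertension", "any_metabolic"))
  ht <- tab[tab$outcome == "hypertension", ]
  expect_equal(ht$cases, 2)
  expect_equal(ht$denominator, 9)  # one missing flag
  # composite: any member TRUE -> TRUE; row 6 all-NA members -> missing
  am <- tab[tab$outcome == "any_metabolic", ]
  expect_equal(am$cases, 3)
  expect_equal(am$denominator, 9)
  # percentages recompute from their own counts and denominators
  expect_equal(tab$percent, 100 * tab$cases / tab$denominator)
  tab_all <- prevalence_table(co, outcomes = "hypertension",
                              denominator = "all")
  expect_equal(tab_all$denominator, 10)
})

test_that("incidence uses the baseline-free at-risk set", {
  co <- flag_cohort(8,
    in_followup = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    base_t2d = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    fu_t2d = c(NA, TRUE, FALSE, FALSE, NA, TRUE, NA, FALSE))
  tab <- incidence_table(co, outcomes = "t2d")
  # at risk: baseline-free, in follow-up, non-missing status -> rows 2,3,4,6,8
  expect_equal(tab$denominator, 5)
  expect_equal(tab$cases, 2)
  expect_equal(tab$percent, 40)
  # baseline-positive row 1 is never at risk nor incident
  co$fu_t2d[1] <- TRUE
  expect_equal(incidence_table(co, outcomes = "t2d")$cases, 2)
})

test_that("empty at-risk sets yield missing, not zero, incidence", {
  co <- flag_cohort(4, base_mi = rep(TRUE, 4))
  tab <- incidence_table(co, outcomes = "mi")
  expect_equal(tab$denominator, 0)
  expect_true(is.na(tab$percent))
})

test_that("incidence partitions each cluster exactly", {
  co <- generate_cohort(quick_config(n = 500, seed = 43))
  cl <- sample(1:3, 500, replace = TRUE)
  members <- composite_members("any_metabolic")
  base <- metabotyper:::.composite_status(co, paste0("base_", members))
  fu <- metabotyper:::.composite_status(co, paste0("fu_", members))
  at_risk <- !is.na(base) & !base & co$in_followup & !is.na(fu)
  tab <- incidence_table(co, outcomes = "any_metabolic", by_cluster = cl)
  for (g in 1:3) {
    n_g <- sum(cl == g)
    incident <- tab$cases[tab$cluster == g]
    healthy_at_risk <- tab$denominator[tab$cluster == g] - incident
    excluded <- sum(cl == g & !at_risk)
    expect_equal(incident + healthy_at_risk + excluded, n_g)
  }
})
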