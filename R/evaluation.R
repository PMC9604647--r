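# ---- pooled descriptives -------------------------------------------------

#' Pooled median and IQR across imputed data sets
#'
#' For each group, the median and interquartile range are computed within
#' each completed data set and then averaged over the m imputations, so a
#' single descriptive value is reported per group despite the multiple
#' imputations.
#'
#' @param imp an `imputation_set` (natural or standardized scale).
#' @param variable parameter name.
#' @param groups vector of group labels, one per participant.
#' @return data.frame with one row per group: `group`, `n`, `median`,
#'   `iqr`.
#' @export
pooled_median_iqr <- function(imp, variable, groups) {
  stopifnot(inherits(imp, "imputation_set"))
  stopifnot(variable %in% colnames(imp$completed[[1]]))
  groups <- as.factor(groups)
  if (any(table(groups) == 0))
    stop("empty group: ", paste(levels(groups)[table(groups) == 0],
                                collapse = ", "), call. = FALSE)
  stats_by_imp <- lapply(imp$completed, function(Z) {
    v <- Z[, variable]
    t(vapply(levels(groups), function(g) {
      x <- v[groups == g]
      c(median = stats::median(x), iqr = stats::IQR(x))
    }, numeric(2)))
  })
  g <- nlevels(groups)
  med <- rowMeans(matrix(vapply(stats_by_imp, function(s) s[, "median"],
                                numeric(g)), g))
  iqr <- rowMeans(matrix(vapply(stats_by_imp, function(s) s[, "iqr"],
                                numeric(g)), g))
  data.frame(group = levels(groups), n = as.vector(table(groups)),
             median = med, iqr = iqr, row.names = NULL,
             stringsAsFactors = FALSE)
}

# ---- group-difference tests ---------------------------------------------

#' Test a variable for differences across metabotype clusters
#'
#' Continuous variables: Kruskal-Wallis test (with tie correction) plus
#' Dunn's pairwise post hoc test, Bonferroni-adjusted over the number of
#' pairs. Categorical variables: Pearson's chi-square test, switching to
#' Fisher's exact test when any expected cell count is below 5. Analysis
#' is complete-case per variable; the number of observations used is
#' reported.
#'
#' @param values vector of values (numeric, or categorical for
#'   `type = "categorical"`).
#' @param groups vector of group labels.
#' @param type `"continuous"` or `"categorical"`.
#' @return a `group_test_result`: list with `test`, `statistic`,
#'   `p_value`, `posthoc` (pairwise Bonferroni-adjusted p-values, for
#'   continuous variables), `n_used`, `degenerate`.
#' @export
test_across_groups <- function(values, groups,
                               type = c("continuous", "categorical")) {
  type <- match.arg(type)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(as.factor(groups))[keep]
  groups <- droplevels(groups)
  if (nlevels(groups) < 2)
    stop("need at least 2 non-empty groups", call. = FALSE)
  n_used <- length(values)

  if (type == "continuous") {
    if (length(unique(values)) == 1) {
      return(structure(list(test = "kruskal_wallis", statistic = 0,
                            p_value = 1, posthoc = NULL, n_used = n_used,
                            degenerate = TRUE),
                       class = "group_test_result"))
    }
    kw <- stats::kruskal.test(values, groups)
    posthoc <- .dunn_posthoc(values, groups)
    res <- list(test = "kruskal_wallis",
                statistic = unname(kw$statistic), p_value = kw$p.value,
                posthoc = posthoc, n_used = n_used, degenerate = FALSE)
  } else {
    tab <- table(values, groups)
    if (length(unique(values)) == 1) {
      return(structure(list(test = "chi_square", statistic = 0,
                            p_value = 1, posthoc = NULL, n_used = n_used,
                            degenerate = TRUE),
                       class = "group_test_result"))
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tab, workspace = 2e7)
      res <- list(test = "fisher", statistic = NA_real_,
                  p_value = ft$p.value, posthoc = NULL, n_used = n_used,
                  degenerate = FALSE)
    } else {
      cs <- stats::chisq.test(tab, correct = FALSE)
      res <- list(test = "chi_square", statistic = unname(cs$statistic),
                  p_value = cs$p.value, posthoc = NULL, n_used = n_used,
                  degenerate = FALSE)
    }
  }
  structure(res, class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(x$test, ": statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 3), ", n = ", x$n_used,
      if (x$degenerate) " (degenerate data)", "\n", sep = "")
  if (!is.null(x$posthoc)) {
    cat("post hoc (Dunn, Bonferroni-adjusted):\n")
    print(signif(x$posthoc, 3))
  }
  invisible(x)
}

# Dunn's test: pairwise z statistics on mean ranks with tie correction,
# Bonferroni-adjusted over the number of pairs
.dunn_posthoc <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  n_pairs <- length(pairs)
  p_adj <- vapply(pairs, function(pr) {
    i <- groups == pr[1]; j <- groups == pr[2]
    z <- (mean(r[i]) - mean(r[j])) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / sum(i) + 1 / sum(j)))
    min(1, 2 * stats::pnorm(-abs(z)) * n_pairs)
  }, numeric(1))
  names(p_adj) <- vapply(pairs, paste, character(1), collapse = " vs ")
  p_adj
}

# ---- prevalence and incidence tables ------------------------------------

#' Baseline prevalence of diseases and composite outcomes
#'
#' Counts prevalent cases at baseline, per disease and composite outcome,
#' overall or stratified by cluster. A composite outcome is present when
#' any member disease is present, absent when all members are observed
#' absent, and missing otherwise. Percentages can be computed over the
#' participants with non-missing status (`denominator = "observed"`,
#' default) or over all participants (`denominator = "all"`); the
#' denominator used is always reported.
#'
#' @param cohort a `cohort_table`.
#' @param outcomes character vector of disease and/or composite names
#'   (default: all six diseases plus both composites).
#' @param by_cluster optional vector of cluster labels, one per row.
#' @param denominator `"observed"` or `"all"`.
#' @return data.frame with columns `outcome`, `cluster` (if stratified),
#'   `cases`, `denominator`, `percent`.
#' @export
prevalence_table <- function(cohort,
                             outcomes = c(DISEASE_NAMES, "any_metabolic",
                                          "any_cvd"),
                             by_cluster = NULL,
                             denominator = c("observed", "all")) {
  .rate_table(cohort, outcomes, by_cluster, match.arg(denominator),
              wave = "baseline")
}

#' Cumulative incidence of diseases and composite outcomes at follow-up
#'
#' Counts incident cases over the follow-up interval. The at-risk set per
#' outcome consists of participants free of the outcome at baseline who
#' participate in follow-up and have non-missing follow-up status; the
#' cumulative incidence is incident cases divided by the at-risk count.
#' An empty at-risk set yields a missing (not zero) percentage.
#'
#' @inheritParams prevalence_table
#' @return data.frame with columns `outcome`, `cluster` (if stratified),
#'   `cases`, `denominator` (at-risk count), `percent`.
#' @export
incidence_table <- function(cohort,
                            outcomes = c(DISEASE_NAMES, "any_metabolic",
                                         "any_cvd"),
                            by_cluster = NULL) {
  .rate_table(cohort, outcomes, by_cluster, denominator = "observed",
              wave = "followup")
}

.rate_table <- function(cohort, outcomes, by_cluster, denominator, wave) {
  strata <- if (is.null(by_cluster)) factor(rep("all", nrow(cohort)))
            else as.factor(by_cluster)
  rows <- list()
  for (oc in outcomes) {
    members <- composite_members(oc)
    base <- .composite_status(cohort, paste0("base_", members))
    if (wave == "baseline") {
      status <- base
      eligible <- rep(TRUE, nrow(cohort))
    } else {
      fu <- .composite_status(cohort, paste0("fu_", members))
      eligible <- !is.na(base) & !base & cohort$in_followup & !is.na(fu)
      status <- fu
    }
    for (g in levels(strata)) {
      in_g <- strata == g
      if (wave == "baseline") {
        denom <- if (denominator == "all") sum(in_g)
                 else sum(in_g & !is.na(status))
        cases <- sum(status[in_g], na.rm = TRUE)
      } else {
        denom <- sum(in_g & eligible)
        cases <- sum(status[in_g & eligible])
      }
      rows[[length(rows) + 1]] <- data.frame(
        outcome = oc, cluster = g, cases = cases, denominator = denom,
        percent = if (denom > 0) 100 * cases / denom else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(by_cluster)) out$cluster <- NULL
  out
}
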