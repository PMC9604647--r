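# Three tree-ensemble variable-importance methods used to choose the
# clustering parameter pool, plus the top-50% selection rule.
#
# All methods canonicalize predictor column order internally (alphabetical)
# before fitting, so scores do not depend on the order in which columns are
# supplied.

.as_predictor_frame <- function(X) {
  X <- as.data.frame(X)
  if (is.null(colnames(X))) stop("X must have column names")
  X[, order(colnames(X)), drop = FALSE]
}

.check_outcome <- function(y) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2)
    stop("outcome must have at least 2 classes", call. = FALSE)
  if (any(table(y) < 2))
    stop("every outcome class needs at least 2 members", call. = FALSE)
  droplevels(y)
}

# dense 1..p ranking, ties broken by larger raw score then name
.importance_ranks <- function(scores) {
  ord <- order(-scores, names(scores))
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores)
  names(ranks) <- names(scores)
  ranks
}

.new_importance_report <- function(method, scores, settings,
                                   null_importances = NULL,
                                   fitted_null = NULL, p_values = NULL) {
  structure(
    list(method = method, variable_scores = scores,
         null_importances = null_importances, fitted_null = fitted_null,
         p_values = p_values, ranks = .importance_ranks(scores),
         settings = settings),
    class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Variable importance (", x$method, ")\n", sep = "")
  ord <- order(x$ranks)
  df <- data.frame(rank = x$ranks[ord],
                   score = signif(x$variable_scores[ord], 4))
  if (!is.null(x$p_values)) df$p_value <- signif(x$p_values[ord], 3)
  print(df)
  invisible(x)
}

# ---- random-forest Gini importance --------------------------------------

#' Random-forest Gini importance
#'
#' Impurity-decrease importance from a random-forest classifier: the total
#' decrease in Gini impurity over all splits on a variable, summed over the
#' ensemble.
#'
#' @param X predictor matrix or data.frame (named columns).
#' @param y categorical outcome with >= 2 classes.
#' @param n_trees number of trees (default 500).
#' @param min_node_size minimal node size (default 1, the classification
#'   default).
#' @param seed integer seed.
#' @return named numeric vector of non-negative importance scores, in the
#'   input column order.
#' @export
rf_gini_importance <- function(X, y, n_trees = 500, min_node_size = 1,
                               seed = 1L) {
  Xc <- .as_predictor_frame(X)
  y <- .check_outcome(y)
  d <- cbind(Xc, .outcome = y)
  fit <- ranger::ranger(dependent.variable.name = ".outcome", data = d,
                        num.trees = n_trees, importance = "impurity",
                        min.node.size = min_node_size,
                        num.threads = 1, seed = seed)
  fit$variable.importance[colnames(X)]
}

# ---- PIMP: permutation importance with fitted null ----------------------

#' Permutation variable importance with a fitted null distribution (PIMP)
#'
#' Calibrates random-forest Gini importance by permuting the outcome:
#' the outcome vector is permuted `n_perm` times and the forest importances
#' recomputed each time, giving per-variable null importances. For each
#' variable, candidate distributions (normal, log-normal, gamma) are fitted
#' to the null by maximum likelihood; the family with the largest
#' Kolmogorov-Smirnov p-value is selected, and the variable's p-value is
#' one minus the fitted CDF at the observed importance. When no family
#' fits (all KS p-values < 0.05) or the null is degenerate, the empirical
#' p-value `(1 + #\{null >= observed\}) / (1 + n_perm)` is used instead.
#'
#' @inheritParams rf_gini_importance
#' @param n_perm number of outcome permutations (>= 20; default 100).
#' @param ks_threshold minimum KS p-value for a parametric family to be
#'   accepted (default 0.05).
#' @return an `importance_report` with `variable_scores`,
#'   `null_importances` (p x n_perm), `fitted_null` (per-variable family,
#'   parameters, KS p-value or `"empirical"`), `p_values` and `ranks`.
#' @export
pimp <- function(X, y, n_trees = 500, n_perm = 100, min_node_size = 1,
                 ks_threshold = 0.05, seed = 1L) {
  stopifnot(n_perm >= 20)
  y <- .check_outcome(y)
  true_imp <- rf_gini_importance(X, y, n_trees = n_trees,
                                 min_node_size = min_node_size, seed = seed)
  p <- length(true_imp)
  null_imp <- matrix(NA_real_, p, n_perm,
                     dimnames = list(names(true_imp), NULL))
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(length(y)), simplify = FALSE)
  for (b in seq_len(n_perm)) {
    null_imp[, b] <- rf_gini_importance(X, y[perms[[b]]], n_trees = n_trees,
                                        min_node_size = min_node_size,
                                        seed = seed + b)
  }
  fitted_null <- vector("list", p)
  names(fitted_null) <- names(true_imp)
  p_values <- numeric(p)
  names(p_values) <- names(true_imp)
  for (v in names(true_imp)) {
    nv <- null_imp[v, ]
    fit <- .fit_null_distribution(nv, ks_threshold)
    fitted_null[[v]] <- fit
    if (identical(fit$family, "empirical")) {
      p_values[v] <- (1 + sum(nv >= true_imp[v])) / (1 + n_perm)
    } else {
      p_values[v] <- 1 - fit$cdf(true_imp[v])
    }
  }
  .new_importance_report(
    "PIMP", true_imp,
    settings = list(n_trees = n_trees, n_perm = n_perm,
                    min_node_size = min_node_size, seed = seed),
    null_importances = null_imp, fitted_null = fitted_null,
    p_values = p_values)
}

# fit {normal, log-normal, gamma} to null importances by ML and pick the
# family with the largest KS p-value; empirical fallback otherwise
.fit_null_distribution <- function(nv, ks_threshold = 0.05) {
  if (length(unique(nv)) == 1) {
    warning("degenerate null importances; using empirical p-value",
            call. = FALSE)
    return(list(family = "empirical"))
  }
  candidates <- list()
  try_family <- function(name) {
    tryCatch({
      fit <- suppressWarnings(fitdistrplus::fitdist(nv, name))
      ks <- suppressWarnings(do.call(
        stats::ks.test,
        c(list(nv, paste0("p", name)), as.list(fit$estimate))))
      list(family = name, estimate = fit$estimate, ks_p = ks$p.value)
    }, error = function(e) NULL)
  }
  fams <- c("norm", "lnorm", "gamma")
  if (any(nv <= 0)) fams <- "norm"  # positive-support families need nv > 0
  for (f in fams) {
    res <- try_family(f)
    if (!is.null(res)) candidates[[f]] <- res
  }
  ks_ps <- vapply(candidates, `[[`, numeric(1), "ks_p")
  if (!length(candidates) || all(ks_ps < ks_threshold))
    return(list(family = "empirical"))
  best <- candidates[[which.max(ks_ps)]]
  cdf_fun <- switch(best$family,
    norm  = function(q) stats::pnorm(q, best$estimate[["mean"]],
                                     best$estimate[["sd"]]),
    lnorm = function(q) stats::plnorm(q, best$estimate[["meanlog"]],
                                      best$estimate[["sdlog"]]),
    gamma = function(q) stats::pgamma(q, best$estimate[["shape"]],
                                      best$estimate[["rate"]]))
  list(family = best$family, estimate = best$estimate, ks_p = best$ks_p,
       cdf = cdf_fun)
}

# ---- CVPVI: cross-validated permutation importance ----------------------

#' Cross-validated permutation variable importance (CVPVI)
#'
#' For each of `n_folds` stratified folds, a random forest is trained on
#' the in-fold data and its misclassification error computed on the
#' held-out fold; each predictor is then permuted `n_perm` times in the
#' held-out fold and the average error increase recorded. The score is the
#' error increase averaged over folds, so it is free of in-sample bias.
#'
#' @inheritParams rf_gini_importance
#' @param n_folds number of cross-validation folds (default 10).
#' @param n_trees trees per fold (default 1000).
#' @param n_perm permutations per predictor per fold (default 100).
#' @return an `importance_report` (no p-values; scores may be negative for
#'   uninformative predictors).
#' @export
cvpvi <- function(X, y, n_folds = 10, n_trees = 1000, n_perm = 100,
                  min_node_size = 1, seed = 1L) {
  Xc <- .as_predictor_frame(X)
  y <- .check_outcome(y)
  n <- nrow(Xc)
  if (n / n_folds < 20)
    stop("fewer than 20 observations per fold; reduce n_folds",
         call. = FALSE)
  set.seed(seed)
  # stratified fold assignment: shuffle within class, deal out 1..n_folds
  fold <- integer(n)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  vars <- colnames(Xc)
  delta <- matrix(0, length(vars), n_folds,
                  dimnames = list(vars, NULL))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < 2)
      stop("training fold with a single outcome class", call. = FALSE)
    d <- cbind(Xc[tr, , drop = FALSE], .outcome = y[tr])
    fit <- ranger::ranger(dependent.variable.name = ".outcome", data = d,
                          num.trees = n_trees,
                          min.node.size = min_node_size,
                          num.threads = 1, seed = seed + f)
    hold <- Xc[!tr, , drop = FALSE]
    y_hold <- y[!tr]
    # a fixed prediction seed makes majority-vote tie-breaking identical
    # across calls, so permuting a constant column scores exactly 0
    pred <- function(newdata)
      predict(fit, newdata, num.threads = 1, seed = seed + f)$predictions
    base_err <- mean(pred(hold) != y_hold)
    for (v in vars) {
      delta_sum <- 0
      for (b in seq_len(n_perm)) {
        perm <- hold
        perm[[v]] <- perm[[v]][sample.int(nrow(perm))]
        delta_sum <- delta_sum + (mean(pred(perm) != y_hold) - base_err)
      }
      delta[v, f] <- delta_sum / n_perm
    }
  }
  scores <- rowMeans(delta)[colnames(X)]
  .new_importance_report(
    "CVPVI", scores,
    settings = list(n_folds = n_folds, n_trees = n_trees, n_perm = n_perm,
                    min_node_size = min_node_size, seed = seed))
}

# ---- gradient-boosting total-gain importance ----------------------------

#' Gradient-boosting gain importance
#'
#' Fits a gradient-boosted tree classifier and scores each variable by the
#' fractional contribution of its splits to the total gain of the model;
#' scores sum to 1 and variables never used in a split score 0.
#'
#' @inheritParams rf_gini_importance
#' @param nrounds boosting rounds (default 50).
#' @param max_depth tree depth (default 6).
#' @param eta learning rate (default 0.3).
#' @return an `importance_report` with scores summing to 1.
#' @export
gb_gain_importance <- function(X, y, nrounds = 50, max_depth = 6, eta = 0.3,
                               seed = 1L) {
  Xc <- .as_predictor_frame(X)
  y <- .check_outcome(y)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(Xc),
                                 label = as.integer(y) - 1L)
  bst <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = nlevels(y),
                  max_depth = max_depth, eta = eta, nthread = 1),
    data = dtrain, nrounds = nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = bst)
  scores <- stats::setNames(rep(0, ncol(Xc)), colnames(Xc))
  scores[imp$Feature] <- imp$Gain
  scores <- scores / sum(scores)
  .new_importance_report(
    "GBGAIN", scores[colnames(X)],
    settings = list(nrounds = nrounds, max_depth = max_depth, eta = eta,
                    seed = seed))
}

# ---- top-50% selection ---------------------------------------------------

#' Select the clustering parameter pool from importance reports
#'
#' Each method's top set is its `ceiling(top_fraction * p)` best-ranked
#' variables; the selected set is the intersection of all top sets, ordered
#' by mean rank across methods. Variables in `nonstandard` (parameters not
#' routinely available in primary care; by default insulin) are flagged and
#' removed from the downstream clustering pool while remaining part of the
#' selected set.
#'
#' @param reports list of `importance_report`s over the same variables.
#' @param top_fraction fraction of variables per method top set
#'   (default 0.5).
#' @param nonstandard variables excluded from the clustering pool for
#'   availability reasons (default `"insulin"`).
#' @param fallback what to do when the intersection is empty: `"error"`
#'   (default) or `"vote"` (keep variables present in a majority of top
#'   sets).
#' @return a `selection_result`: list with `selected`,
#'   `excluded_nonstandard`, `clustering_pool`, `per_method_top_sets`,
#'   `top_fraction`.
#' @export
select_parameters <- function(reports, top_fraction = 0.5,
                              nonstandard = "insulin",
                              fallback = c("error", "vote")) {
  fallback <- match.arg(fallback)
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, logical(1), "importance_report")))
  varsets <- lapply(reports, function(r) sort(names(r$variable_scores)))
  if (!all(vapply(varsets, identical, logical(1), varsets[[1]])))
    stop("reports cover different variable sets", call. = FALSE)
  p <- length(varsets[[1]])
  k_top <- ceiling(top_fraction * p)
  top_sets <- lapply(reports, function(r)
    names(sort(r$ranks))[seq_len(k_top)])
  names(top_sets) <- vapply(reports, `[[`, character(1), "method")
  selected <- Reduce(intersect, top_sets)
  if (!length(selected)) {
    if (fallback == "error")
      stop("intersection of per-method top sets is empty; ",
           "consider select_parameters(..., fallback = \"vote\")",
           call. = FALSE)
    votes <- table(unlist(top_sets))
    selected <- names(votes)[votes > length(top_sets) / 2]
    if (!length(selected))
      stop("no variable reaches a majority of top sets", call. = FALSE)
  }
  mean_rank <- rowMeans(vapply(reports, function(r) r$ranks[selected],
                               numeric(length(selected))))
  selected <- selected[order(mean_rank, selected)]
  excluded <- intersect(nonstandard, selected)
  structure(
    list(selected = selected,
         excluded_nonstandard = excluded,
         clustering_pool = setdiff(selected, excluded),
         per_method_top_sets = top_sets,
         top_fraction = top_fraction),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Parameter selection (top ", x$top_fraction * 100, "% in all methods)\n",
      sep = "")
  cat("  selected:       ", paste(x$selected, collapse = ", "), "\n")
  if (length(x$excluded_nonstandard))
    cat("  non-standard:   ", paste(x$excluded_nonstandard, collapse = ", "),
        " (removed from clustering pool)\n")
  cat("  clustering pool:", paste(x$clustering_pool, collapse = ", "), "\n")
  invisible(x)
}

#' Outcome labels for supervised importance from unsupervised structure
#'
#' Variable importance requires a categorical outcome, but the metabotype
#' workflow deliberately uses no disease endpoint. This helper derives the
#' outcome from the metabolic structure itself: a k-means clustering (k =
#' 3) of all standardized parameters in the first imputed data set. Any
#' other label column can be supplied to the importance functions instead.
#'
#' @param imp a standardized `imputation_set`.
#' @param k number of clusters (default 3).
#' @param n_init number of k-means++ restarts (default 25).
#' @param seed integer seed.
#' @return integer factor of cluster labels.
#' @export
clustering_outcome <- function(imp, k = 3, n_init = 25, seed = 1L) {
  stopifnot(inherits(imp, "imputation_set"), isTRUE(imp$standardized))
  km <- .kmeans_best(imp$completed[[1]], k = k, n_init = n_init, seed = seed)
  factor(km$cluster)
}
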