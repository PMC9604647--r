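# ---- k-means core --------------------------------------------------------

# k-means++ center seeding on the rows of Z
.kmeanspp_centers <- function(Z, k) {
  n <- nrow(Z)
  centers <- matrix(NA_real_, k, ncol(Z))
  centers[1, ] <- Z[sample.int(n, 1), ]
  d2 <- rowSums((Z - matrix(centers[1, ], n, ncol(Z), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    idx <- sample.int(n, 1, prob = pmax(d2, 1e-300))
    centers[j + 1, ] <- Z[idx, ]
    d2 <- pmin(d2, rowSums((Z - matrix(centers[j + 1, ], n, ncol(Z),
                                       byrow = TRUE))^2))
  }
  centers
}

# best-of-n_init k-means with k-means++ seeding; re-seeds on degenerate
# solutions (empty cluster) up to 10 times
.kmeans_best <- function(Z, k, n_init = 25, seed = 1L) {
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- NULL
    for (attempt in 1:10) {
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(Z, centers = .kmeanspp_centers(Z, k),
                                       iter.max = 100)),
        error = function(e) NULL)
      if (!is.null(fit) && all(fit$size > 0)) break
      fit <- NULL
    }
    if (is.null(fit))
      stop("k-means produced an empty cluster in 10 re-seeded attempts",
           call. = FALSE)
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

# ---- cluster-number diagnostics -----------------------------------------

#' Choose the number of clusters by a battery of indices
#'
#' Computes five cluster-number indices on the first imputed data set for
#' every k in `k_range` and returns the majority-vote k: Calinski-Harabasz
#' (maximize), average silhouette width (maximize), Davies-Bouldin
#' (minimize), Hartigan's rule (smallest k with H(k) <= 10), and the gap
#' statistic (first k within one SE of the first local maximum, following
#' the original proposal). The vote is diagnostic: the metabotype models
#' themselves always use k = 3 for comparability.
#'
#' @param imp a standardized `imputation_set`.
#' @param subset parameter names to cluster on (>= 2).
#' @param k_range candidate numbers of clusters (default 2:8).
#' @param n_gap_references number of null reference data sets for the gap
#'   statistic (default 50).
#' @param n_init k-means restarts per k (default 25).
#' @param seed integer seed.
#' @return list with `k` (majority vote; ties go to the smaller k) and
#'   `votes` (per-index choice).
#' @export
choose_k <- function(imp, subset, k_range = 2:8, n_gap_references = 50,
                     n_init = 25, seed = 1L) {
  stopifnot(inherits(imp, "imputation_set"), length(subset) >= 2)
  Z <- imp$completed[[1]][, subset, drop = FALSE]
  n <- nrow(Z)
  if (max(k_range) > n / 10)
    stop("k_range exceeds n/10; too few observations per cluster",
         call. = FALSE)
  ks <- sort(unique(as.integer(k_range)))
  fits <- lapply(c(ks, max(ks) + 1L), function(k)
    .kmeans_best(Z, k, n_init = n_init, seed = seed))
  names(fits) <- as.character(c(ks, max(ks) + 1L))

  tot_ss <- sum(scale(Z, scale = FALSE)^2)
  ch <- sil <- db <- numeric(length(ks))
  dmat <- stats::dist(Z)
  for (i in seq_along(ks)) {
    k <- ks[i]
    fit <- fits[[as.character(k)]]
    W <- fit$tot.withinss
    ch[i] <- ((tot_ss - W) / (k - 1)) / (W / (n - k))
    sil[i] <- mean(cluster::silhouette(fit$cluster, dmat)[, "sil_width"])
    db[i] <- .davies_bouldin(Z, fit)
  }
  # Hartigan: H(k) = (W_k / W_{k+1} - 1) (n - k - 1); smallest k <= 10
  hart <- vapply(ks, function(k) {
    (fits[[as.character(k)]]$tot.withinss /
       fits[[as.character(k + 1L)]]$tot.withinss - 1) * (n - k - 1)
  }, numeric(1))
  hart_k <- if (any(hart <= 10)) ks[which(hart <= 10)[1]] else ks[which.min(hart)]

  set.seed(seed + 1000L)
  gap <- cluster::clusGap(Z, FUN = function(x, k)
    if (k == 1) stats::kmeans(x, 1) else .kmeans_best(x, k, n_init = 5,
                                                      seed = seed + k),
    K.max = max(ks), B = n_gap_references, verbose = FALSE)
  gap_k <- cluster::maxSE(gap$Tab[, "gap"], gap$Tab[, "SE.sim"],
                          method = "firstSEmax")
  gap_k <- min(max(gap_k, min(ks)), max(ks))

  votes <- c(calinski_harabasz = ks[which.max(ch)],
             silhouette = ks[which.max(sil)],
             davies_bouldin = ks[which.min(db)],
             hartigan = hart_k,
             gap = gap_k)
  tab <- table(votes)
  k_win <- as.integer(names(tab)[which.max(tab)])  # ties -> smaller k
  list(k = k_win, votes = votes)
}

.davies_bouldin <- function(Z, fit) {
  k <- nrow(fit$centers)
  scatter <- vapply(seq_len(k), function(j) {
    rows <- fit$cluster == j
    sqrt(mean(rowSums((Z[rows, , drop = FALSE] -
      matrix(fit$centers[j, ], sum(rows), ncol(Z), byrow = TRUE))^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(fit$centers))
  mean(vapply(seq_len(k), function(j) {
    max(vapply(setdiff(seq_len(k), j), function(l)
      (scatter[j] + scatter[l]) / cd[j, l], numeric(1)))
  }, numeric(1)))
}

# ---- consensus k-means over imputations ---------------------------------

#' Consensus k-means clustering across multiply imputed data sets
#'
#' Runs k-means (k-means++ seeding, `n_init` restarts, best within-cluster
#' sum of squares) independently on the chosen parameter subset in each
#' completed data set, using the same seed set in each so that identical
#' inputs give identical solutions. The cluster labels of imputations
#' 2..m are aligned to imputation 1 by the label permutation minimizing
#' the total squared distance between centroids (exhaustive over the k!
#' permutations). The consensus label of a participant is the majority
#' vote over aligned labels; ties are resolved by the nearest
#' mean-aligned centroid.
#'
#' @param imp a standardized `imputation_set`.
#' @param subset parameter names to cluster on (>= 2).
#' @param k number of clusters (default 3).
#' @param n_init number of restarts (default 25).
#' @param model_id optional integer identifier.
#' @param seed integer seed.
#' @return a `metabotype_model`: list with `model_id`, `parameter_subset`,
#'   `k`, `per_imputation_centroids` (aligned), `centroids` (mean aligned
#'   centroids), `assignment` (consensus labels, unordered until
#'   [order_clusters()]), `ordering_scores` (NULL until ordered),
#'   `smallest_cluster_n`, `admissible` (NA until [check_admissible()]).
#' @export
kmeans_consensus <- function(imp, subset, k = 3, n_init = 25,
                             model_id = NA_integer_, seed = 1L) {
  stopifnot(inherits(imp, "imputation_set"), isTRUE(imp$standardized),
            length(subset) >= 2)
  if (k > 5)
    stop("label alignment is exhaustive over k! permutations; k <= 5 only",
         call. = FALSE)
  fits <- lapply(seq_len(imp$m), function(i)
    .kmeans_best(imp$completed[[i]][, subset, drop = FALSE], k,
                 n_init = n_init, seed = seed))
  ref <- fits[[1]]$centers
  labels <- matrix(NA_integer_, nrow(imp$completed[[1]]), imp$m)
  centroids <- vector("list", imp$m)
  for (i in seq_len(imp$m)) {
    perm <- .align_labels(ref, fits[[i]]$centers)
    # cluster perm[j] of imputation i plays the role of reference cluster j
    labels[, i] <- match(fits[[i]]$cluster, perm)
    centroids[[i]] <- fits[[i]]$centers[perm, , drop = FALSE]
    rownames(centroids[[i]]) <- NULL
  }
  mean_centroids <- Reduce(`+`, centroids) / imp$m
  colnames(mean_centroids) <- subset

  votes <- t(apply(labels, 1, tabulate, nbins = k))
  consensus <- max.col(votes, ties.method = "first")
  top <- votes[cbind(seq_len(nrow(votes)), consensus)]
  tied <- rowSums(votes == top) > 1
  if (any(tied)) {
    # mean participant position across imputations vs mean centroids
    pos <- Reduce(`+`, lapply(imp$completed, function(Z)
      Z[tied, subset, drop = FALSE]))/imp$m
    d <- vapply(seq_len(k), function(j)
      rowSums((pos - matrix(mean_centroids[j, ], nrow(pos), length(subset),
                            byrow = TRUE))^2), numeric(nrow(pos)))
    consensus[tied] <- max.col(-matrix(d, nrow = sum(tied)),
                               ties.method = "first")
  }
  sizes <- tabulate(consensus, nbins = k)
  structure(
    list(model_id = model_id, parameter_subset = subset, k = k,
         per_imputation_centroids = centroids, centroids = mean_centroids,
         assignment = consensus, ordering_scores = NULL,
         smallest_cluster_n = min(sizes), admissible = NA,
         settings = list(n_init = n_init, seed = seed)),
    class = "metabotype_model")
}

# +1 for every parameter except HDLc; accepts non-panel variable names
.default_directions <- function(parameters) {
  sgn <- rep(1, length(parameters))
  names(sgn) <- parameters
  sgn[parameters == "hdlc"] <- -1
  sgn
}

# permutation p minimizing sum_j || other[p[j], ] - ref[j, ] ||^2
.align_labels <- function(ref, other) {
  k <- nrow(ref)
  perms <- .permutations(k)
  costs <- vapply(perms, function(p)
    sum((other[p, , drop = FALSE] - ref)^2), numeric(1))
  perms[[which.min(costs)]]
}

#' @export
print.metabotype_model <- function(x, ...) {
  cat("Metabotype model",
      if (!is.na(x$model_id)) paste0("#", x$model_id), "\n")
  cat("  parameters:", paste(x$parameter_subset, collapse = ", "), "\n")
  cat("  cluster sizes:", paste(tabulate(x$assignment, x$k), collapse = "/"),
      if (!is.null(x$ordering_scores)) "(ordered 1=healthy .. 3=unfavorable)",
      "\n")
  if (!is.na(x$admissible))
    cat("  admissible:", x$admissible, "\n")
  invisible(x)
}

# ---- cluster ordering ----------------------------------------------------

#' Order clusters from metabolically favorable to unfavorable
#'
#' Computes each cluster's composite unfavorability -- the mean over the
#' clustering parameters of the signed standardized cluster centroid
#' (signs from [risk_directions()]: +1 where higher is worse, -1 for
#' HDLc) -- and relabels clusters in ascending order, so cluster 1 is the
#' healthy metabotype and cluster 3 the unfavorable one. Exact ties are
#' broken by the cluster mean of glucose (when glucose is a clustering
#' parameter) and then by descending cluster size.
#'
#' @param model a `metabotype_model` from [kmeans_consensus()].
#' @param directions named sign vector; defaults to [risk_directions()]
#'   for panel parameters and +1 (higher = less favorable) for any other
#'   variable.
#' @return the model with relabeled `assignment`, reordered centroids and
#'   `ordering_scores` (ascending composite unfavorability).
#' @export
order_clusters <- function(model,
                           directions = .default_directions(model$parameter_subset)) {
  stopifnot(inherits(model, "metabotype_model"))
  stopifnot(all(model$parameter_subset %in% names(directions)))
  sgn <- directions[model$parameter_subset]
  composite <- drop(model$centroids %*% sgn) / length(sgn)
  glu <- if ("glucose" %in% model$parameter_subset)
    model$centroids[, "glucose"] else rep(0, model$k)
  sizes <- tabulate(model$assignment, model$k)
  ord <- order(composite, glu, -sizes)
  relabel <- match(seq_len(model$k), ord)
  model$assignment <- relabel[model$assignment]
  model$centroids <- model$centroids[ord, , drop = FALSE]
  model$per_imputation_centroids <- lapply(model$per_imputation_centroids,
                                           function(C) C[ord, , drop = FALSE])
  model$ordering_scores <- composite[ord]
  model$smallest_cluster_n <- min(tabulate(model$assignment, model$k))
  model
}

# ---- model enumeration and admissibility --------------------------------

#' Enumerate candidate parameter subsets for metabotype models
#'
#' Either returns a validated explicit list of subsets, or enumerates all
#' subsets of the pool with at least `min_size` parameters, in
#' deterministic order (by size, then lexicographically), each with a
#' stable `model_id`.
#'
#' @param pool character vector of clustering parameters.
#' @param min_size smallest subset size (default 3).
#' @param explicit optional list of character vectors; must be unique and
#'   drawn from the pool.
#' @return named list of parameter subsets; names are `model_id`s.
#' @export
#' @examples
#' length(enumerate_models(letters[1:6]))  # 42 subsets of size >= 3
enumerate_models <- function(pool, min_size = 3, explicit = NULL) {
  stopifnot(length(pool) >= 1)
  if (!is.null(explicit)) {
    explicit <- lapply(explicit, function(s) sort(as.character(s)))
    keys <- vapply(explicit, paste, character(1), collapse = "|")
    if (anyDuplicated(keys))
      stop("duplicate subsets in explicit model list", call. = FALSE)
    bad <- !vapply(explicit, function(s) all(s %in% pool), logical(1))
    if (any(bad))
      stop("explicit subset(s) outside the parameter pool: ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    names(explicit) <- seq_along(explicit)
    return(explicit)
  }
  pool <- sort(pool)
  sizes <- seq(from = min_size, to = length(pool))
  subsets <- unlist(lapply(sizes, function(sz)
    utils::combn(pool, sz, simplify = FALSE)), recursive = FALSE)
  names(subsets) <- seq_along(subsets)
  subsets
}

#' Admissibility of a metabotype model
#'
#' A model is admissible when its smallest cluster contains at least
#' `min_fraction` of the participants *or* at least `min_n` participants
#' (disjunctive reading; set `mode = "conjunctive"` to require both).
#'
#' @param model a `metabotype_model`.
#' @param n_total number of clustered participants.
#' @param min_fraction minimum smallest-cluster fraction (default 0.05).
#' @param min_n minimum smallest-cluster count (default 150).
#' @param mode `"disjunctive"` (default) or `"conjunctive"`.
#' @return the model with `admissible` set.
#' @export
check_admissible <- function(model, n_total, min_fraction = 0.05,
                             min_n = 150,
                             mode = c("disjunctive", "conjunctive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "metabotype_model"))
  s <- model$smallest_cluster_n
  by_fraction <- s >= min_fraction * n_total
  by_count <- s >= min_n
  model$admissible <- if (mode == "disjunctive") by_fraction || by_count
                      else by_fraction && by_count
  model
}

# ---- incidence-based model ranking --------------------------------------

#' Rank metabotype models by disease incidence in the unfavorable cluster
#'
#' For each model, computes the cumulative incidence of the composite
#' outcome in cluster 3 (the unfavorable metabotype): incident cases
#' divided by the at-risk set (cluster-3 members free of the outcome at
#' baseline, participating in follow-up, with non-missing follow-up
#' status). Models are ranked by descending incidence; ties are broken by
#' the larger incident count, then the smaller parameter subset, then
#' lexicographic subset order. Models whose cluster 3 has an empty at-risk
#' set are excluded with a warning.
#'
#' @param models list of ordered `metabotype_model`s (see
#'   [order_clusters()]); assignments must align with the rows of
#'   `cohort`.
#' @param cohort the retained `cohort_table` the models were fitted on.
#' @param outcome composite outcome name (`"any_metabolic"`, `"any_cvd"`,
#'   or a single disease).
#' @return a `model_ranking`: data.frame with one row per model
#'   (`model_id`, `n_parameters`, `parameters`, `cluster3_n`, `at_risk`,
#'   `incident`, `incidence`, `rank`) plus attributes `outcome` and
#'   `best_model_id`.
#' @export
rank_models <- function(models, cohort, outcome) {
  stopifnot(length(models) >= 1,
            all(vapply(models, inherits, logical(1), "metabotype_model")))
  members <- composite_members(outcome)
  rows <- lapply(models, function(m) {
    if (is.null(m$ordering_scores))
      stop("models must be ordered with order_clusters() before ranking",
           call. = FALSE)
    in3 <- m$assignment == m$k
    base <- .composite_status(cohort, paste0("base_", members))
    fu <- .composite_status(cohort, paste0("fu_", members))
    at_risk <- in3 & !is.na(base) & !base & cohort$in_followup & !is.na(fu)
    data.frame(model_id = m$model_id,
               n_parameters = length(m$parameter_subset),
               parameters = paste(m$parameter_subset, collapse = "+"),
               cluster3_n = sum(in3),
               at_risk = sum(at_risk),
               incident = sum(fu[at_risk]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  empty <- tab$at_risk == 0
  if (any(empty)) {
    warning("excluding model(s) with empty cluster-3 at-risk set: ",
            paste(tab$model_id[empty], collapse = ", "), call. = FALSE)
    tab <- tab[!empty, , drop = FALSE]
    if (!nrow(tab)) stop("no rankable models", call. = FALSE)
  }
  tab$incidence <- tab$incident / tab$at_risk
  ord <- order(-tab$incidence, -tab$incident, tab$n_parameters,
               tab$parameters)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(tab, outcome = outcome, best_model_id = tab$model_id[1],
            class = c("model_ranking", "data.frame"))
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("Model ranking by cluster-3 cumulative incidence of",
      attr(x, "outcome"), "\n")
  NextMethod()
  cat("best model:", attr(x, "best_model_id"), "\n")
  invisible(x)
}

# composite disease status from a set of flag columns:
# TRUE if any observed TRUE, FALSE if all observed FALSE, NA otherwise
.composite_status <- function(cohort, cols) {
  flags <- as.matrix(cohort[, cols, drop = FALSE])
  any_true <- rowSums(flags, na.rm = TRUE) > 0
  all_obs_false <- rowSums(is.na(flags)) == 0 & !any_true
  ifelse(any_true, TRUE, ifelse(all_obs_false, FALSE, NA))
}
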