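# ---- exclusions and derived variables -----------------------------------

#' Apply the baseline exclusion cascade
#'
#' Removes participants in a fixed order: (1) those who did not fast for at
#' least 8 h before blood draw, (2) those with missing fasting glucose,
#' (3) those with more than `max_missing_fraction` missing values among the
#' 14 clinical parameters. The order is fixed so the per-step counts are
#' well defined when criteria overlap.
#'
#' @param cohort a `cohort_table`.
#' @param max_missing_fraction maximum tolerated fraction of missing
#'   parameter values (default 0.10).
#' @return a list with `cohort` (the retained rows) and `report`, an
#'   `exclusion_report` with counts `n_input`, `n_nonfasting`,
#'   `n_missing_glucose`, `n_high_missing`, `n_retained`.
#' @export
apply_exclusions <- function(cohort, max_missing_fraction = 0.10) {
  stopifnot(is.data.frame(cohort),
            "fasting_hours_ok" %in% names(cohort),
            "glucose" %in% names(cohort))
  n_input <- nrow(cohort)

  keep1 <- cohort$fasting_hours_ok %in% TRUE
  n_nonfasting <- sum(!keep1)
  cohort <- cohort[keep1, , drop = FALSE]

  keep2 <- !is.na(cohort$glucose)
  n_missing_glucose <- sum(!keep2)
  cohort <- cohort[keep2, , drop = FALSE]

  pm <- as.matrix(cohort[, PARAM_NAMES])
  frac <- rowMeans(is.na(pm))
  keep3 <- frac <= max_missing_fraction
  n_high_missing <- sum(!keep3)
  cohort <- cohort[keep3, , drop = FALSE]

  if (nrow(cohort) == 0)
    stop("no participants retained after exclusions", call. = FALSE)

  report <- structure(
    list(n_input = n_input, n_nonfasting = n_nonfasting,
         n_missing_glucose = n_missing_glucose,
         n_high_missing = n_high_missing, n_retained = nrow(cohort)),
    class = "exclusion_report")
  list(cohort = cohort, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion cascade:\n")
  cat("  input:               ", x$n_input, "\n")
  cat("  - non-fasting:       ", x$n_nonfasting, "\n")
  cat("  - missing glucose:   ", x$n_missing_glucose, "\n")
  cat("  - >10% missing:      ", x$n_high_missing, "\n")
  cat("  retained:            ", x$n_retained, "\n")
  invisible(x)
}

#' Derive non-HDL cholesterol
#'
#' Non-HDL cholesterol is total cholesterol minus HDL cholesterol, the
#' aggregate of atherogenic lipoprotein cholesterol.
#'
#' @param tc total cholesterol (mmol/L).
#' @param hdlc HDL cholesterol (mmol/L), with `hdlc <= tc`.
#' @return non-HDL cholesterol (mmol/L); vectorized.
#' @export
#' @examples
#' derive_non_hdl(5.44, 1.39)  # 4.05
derive_non_hdl <- function(tc, hdlc) {
  if (any(is.na(tc) | is.na(hdlc)))
    stop("tc and hdlc must be non-missing", call. = FALSE)
  if (any(hdlc <= 0)) stop("hdlc must be positive", call. = FALSE)
  if (any(tc < hdlc))
    stop("tc must be >= hdlc", call. = FALSE)
  tc - hdlc
}

#' Categorize BMI by the WHO cut points
#'
#' Intervals are left-closed, right-open: underweight < 18.5, normal
#' 18.5-<25, overweight 25-<30, obese >= 30 kg/m2.
#'
#' @param bmi body mass index (kg/m2), positive; vectorized, NA passed
#'   through.
#' @return factor with levels underweight/normal/overweight/obese.
#' @export
#' @examples
#' categorize_bmi(c(18.5, 24.99, 25, 30))
categorize_bmi <- function(bmi) {
  if (any(!is.na(bmi) & bmi <= 0))
    stop("bmi must be positive", call. = FALSE)
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obese"))
}

# ---- chained-equations imputation ---------------------------------------

#' Impute missing parameter values by chained equations
#'
#' Multiple imputation by chained equations with predictive mean matching
#' (PMM) for continuous columns. Each incomplete column is visited in order
#' of increasing missingness and regressed on all other columns (current
#' completed values); regression coefficients are drawn from their
#' approximate posterior (Bayesian linear regression with a draw of the
#' residual variance), a predicted value is formed for each missing cell,
#' and the imputed value is sampled from the `donors` observed values whose
#' predictions are closest. Cycling is repeated `iterations` times, and the
#' whole procedure is run independently `m` times.
#'
#' Observed cells are never modified; for fixed `seed` the result is
#' reproducible.
#'
#' @param parameters numeric matrix (participants x parameters), possibly
#'   with missing cells; columns must be named.
#' @param m number of completed data sets (default 5).
#' @param iterations chained-equation cycles per data set (default 10).
#' @param donors PMM donor pool size (default 5).
#' @param seed integer seed.
#' @return an `imputation_set`: list with `m`, `iterations`, `completed`
#'   (list of m complete matrices), `missing_mask`, `standardized` (FALSE),
#'   `column_means`/`column_sds` (filled by [z_standardize()]), `seed`.
#' @export
impute_chained <- function(parameters, m = 5, iterations = 10, donors = 5,
                           seed = 1L) {
  X <- as.matrix(parameters)
  if (is.null(colnames(X))) stop("parameter matrix must have column names")
  storage.mode(X) <- "double"
  miss <- is.na(X)
  fully_missing <- colnames(X)[colSums(!miss) == 0]
  if (length(fully_missing))
    stop("column(s) fully missing: ", paste(fully_missing, collapse = ", "),
         call. = FALSE)
  thin <- colnames(X)[colSums(!miss) < 2]
  if (length(thin))
    stop("column(s) with fewer than 2 observed values: ",
         paste(thin, collapse = ", "), call. = FALSE)

  set.seed(seed)
  completed <- vector("list", m)
  if (!any(miss)) {
    for (i in seq_len(m)) completed[[i]] <- X
  } else {
    n_miss <- colSums(miss)
    visit <- order(n_miss)                 # increasing missingness
    visit <- visit[n_miss[visit] > 0]
    for (i in seq_len(m)) {
      Z <- X
      # initial fill: random draw from the observed values of the column
      for (j in which(n_miss > 0)) {
        obs <- Z[!miss[, j], j]
        Z[miss[, j], j] <- sample(obs, n_miss[j], replace = TRUE)
      }
      for (it in seq_len(iterations)) {
        for (j in visit) {
          Z[miss[, j], j] <- .pmm_draw(Z, j, miss[, j], donors)
        }
      }
      completed[[i]] <- Z
    }
  }
  structure(
    list(m = m, iterations = iterations, completed = completed,
         missing_mask = miss, standardized = FALSE,
         column_means = NULL, column_sds = NULL, seed = as.integer(seed)),
    class = "imputation_set")
}

# one PMM update of column j given current completed matrix Z
.pmm_draw <- function(Z, j, miss_j, donors) {
  y_obs <- Z[!miss_j, j]
  A_obs <- cbind(1, Z[!miss_j, -j, drop = FALSE])
  A_mis <- cbind(1, Z[miss_j, -j, drop = FALSE])
  fit <- stats::lm.fit(A_obs, y_obs)
  beta <- fit$coefficients
  rank <- fit$rank
  piv <- fit$qr$pivot[seq_len(rank)]
  df <- max(length(y_obs) - rank, 1)
  sigma2 <- sum(fit$residuals^2) / stats::rchisq(1, df)
  # parameter draw: beta* ~ N(beta, sigma2 (A'A)^-1), via the QR of A
  R <- qr.R(fit$qr)[seq_len(rank), seq_len(rank), drop = FALSE]
  beta_star <- beta
  beta_star[piv] <- beta[piv] +
    backsolve(R, stats::rnorm(rank)) * sqrt(sigma2)
  pred_obs <- drop(A_obs[, piv, drop = FALSE] %*% beta[piv])
  pred_mis <- drop(A_mis[, piv, drop = FALSE] %*% beta_star[piv])
  vapply(pred_mis, function(pm) {
    d <- abs(pred_obs - pm)
    pool <- order(d)[seq_len(min(donors, length(d)))]
    y_obs[pool[sample.int(length(pool), 1)]]
  }, numeric(1))
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("Imputation set: m =", x$m, ", iterations =", x$iterations, "\n")
  cat("  participants:", nrow(x$completed[[1]]),
      " parameters:", ncol(x$completed[[1]]), "\n")
  cat("  missing cells imputed:", sum(x$missing_mask),
      if (isTRUE(x$standardized)) " (standardized)" else "", "\n")
  invisible(x)
}

# ---- standardization -----------------------------------------------------

#' z-standardize an imputation set
#'
#' Centers and scales every parameter column within each completed data
#' set (sample SD, n-1 denominator). The per-imputation means and SDs are
#' stored so the transform can be inverted exactly.
#'
#' @param imp an `imputation_set` from [impute_chained()].
#' @return the standardized `imputation_set`.
#' @seealso [inverse_standardize()]
#' @export
z_standardize <- function(imp) {
  stopifnot(inherits(imp, "imputation_set"))
  if (isTRUE(imp$standardized)) return(imp)
  means <- sds <- vector("list", imp$m)
  for (i in seq_len(imp$m)) {
    Z <- imp$completed[[i]]
    mu <- colMeans(Z)
    sd <- apply(Z, 2, stats::sd)
    degenerate <- colnames(Z)[sd == 0]
    if (length(degenerate))
      stop("zero-variance column(s): ", paste(degenerate, collapse = ", "),
           call. = FALSE)
    imp$completed[[i]] <- sweep(sweep(Z, 2, mu, "-"), 2, sd, "/")
    means[[i]] <- mu; sds[[i]] <- sd
  }
  imp$column_means <- means
  imp$column_sds <- sds
  imp$standardized <- TRUE
  imp
}

#' @rdname z_standardize
#' @export
inverse_standardize <- function(imp) {
  stopifnot(inherits(imp, "imputation_set"), isTRUE(imp$standardized))
  for (i in seq_len(imp$m)) {
    imp$completed[[i]] <- sweep(
      sweep(imp$completed[[i]], 2, imp$column_sds[[i]], "*"),
      2, imp$column_means[[i]], "+")
  }
  imp$standardized <- FALSE
  imp
}
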