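# shared fixture builders for the test suite

# small fast generator config
quick_config <- function(n = 300, seed = 1, ...) {
  generator_config(n_participants = n, seed = seed, ...)
}

# bare cohort with explicit disease flags, for rate-table tests:
# each argument is a logical vector (NA allowed); all diseases not named
# are FALSE everywhere
flag_cohort <- function(n, in_followup = rep(TRUE, n), ...) {
  co <- data.frame(participant_id = seq_len(n))
  flags <- list(...)
  for (d in metabotyper:::DISEASE_NAMES) {
    b <- paste0("base_", d); f <- paste0("fu_", d)
    co[[b]] <- if (b %in% names(flags)) flags[[b]] else rep(FALSE, n)
    co[[f]] <- if (f %in% names(flags)) flags[[f]] else rep(FALSE, n)
  }
  co$in_followup <- in_followup
  class(co) <- c("cohort_table", "data.frame")
  co
}

# k Gaussian blobs in d dimensions with centers `sep` apart per coordinate
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  X <- do.call(rbind, lapply(seq_len(k), function(j) {
    matrix(stats::rnorm(n_per * ncol(centers), mean = 0, sd = sd),
           n_per) + matrix(centers[j, ], n_per, ncol(centers), byrow = TRUE)
  }))
  colnames(X) <- paste0("x", seq_len(ncol(centers)))
  list(X = X, labels = rep(seq_len(k), each = n_per))
}

# wrap a complete (or list of) matrices as a standardized imputation set
as_imputation_set <- function(matrices, standardized = FALSE) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  imp <- structure(
    list(m = length(matrices), iterations = 0, completed = matrices,
         missing_mask = matrix(FALSE, nrow(matrices[[1]]),
                               ncol(matrices[[1]])),
         standardized = FALSE, column_means = NULL, column_sds = NULL,
         seed = 0L),
    class = "imputation_set")
  if (standardized) imp <- z_standardize(imp)
  imp
}

# planted-signal design: 3-class outcome, one informative column
planted_signal_data <- function(n = 400, p = 8, shift = 1, seed = 1) {
  set.seed(seed)
  y <- factor(sample(1:3, n, TRUE))
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  X[, 1] <- X[, 1] + (as.integer(y) - 2) * shift
  list(X = X, y = y)
}
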