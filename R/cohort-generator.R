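# ---- generator configuration -------------------------------------------

#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the configuration consumed by [generate_cohort()].
#' The defaults emulate a population-based cardiometabolic cohort with a
#' baseline examination and one follow-up wave about seven years later:
#' three latent metabolic groups (healthy / intermediate / unfavorable) with
#' group-specific parameter locations, group-dependent prevalence and
#' incidence of six cardiometabolic diseases, and group-dependent follow-up
#' retention (the least healthy group drops out most).
#'
#' @param n_participants number of baseline participants (default 3001).
#' @param latent_proportions probabilities of the three latent groups,
#'   summing to 1.
#' @param component_means 14 x 3 numeric matrix of per-parameter location
#'   (natural scale; the median for log-normal parameters) per latent group.
#'   Rows must be named by parameter.
#' @param component_cvs named numeric vector: per-parameter coefficient of
#'   variation within a latent group.
#' @param log_scale_params parameters simulated log-normally (right-skewed
#'   biomarkers); locations are interpreted as medians.
#' @param sex_effect named numeric vector: additive shift applied to male
#'   participants (natural scale).
#' @param p_male probability of male sex.
#' @param missing_rate fraction of parameter cells set missing, in [0, 0.1].
#' @param missing_mechanism `"mcar"` (default) or `"mar"`; under MAR the
#'   per-row missingness rate increases across baseline BMI tertiles
#'   (0.5x / 1x / 1.5x the nominal rate).
#' @param disease_base_logit named numeric vector (6 diseases): logit of
#'   baseline prevalence in latent group 1.
#' @param disease_group_effects 6 x 2 matrix: additive logit shifts for
#'   groups 2 and 3 relative to group 1, rows named by disease.
#' @param incident_base_logit,incident_group_effects same structure for
#'   incident disease at follow-up, among participants disease-free at
#'   baseline.
#' @param followup_retention per-latent-group probability of taking part in
#'   the follow-up examination.
#' @param nonfasting_rate fraction of participants flagged as having fasted
#'   less than 8 h before blood draw.
#' @param disease_missing_rate small fraction of disease flags set missing.
#' @param shared_factor_sd standard deviation of an optional shared
#'   "adiposity" factor added on top of the group structure (default 0 =
#'   off); its per-parameter loadings are fixed internally.
#' @param seed integer seed; every draw in [generate_cohort()] is
#'   reproducible given the seed.
#' @return an object of class `generator_config` (a validated list).
#' @export
#' @examples
#' cfg <- generator_config(n_participants = 200, seed = 1)
#' cohort <- generate_cohort(cfg)
generator_config <- function(n_participants = 3001,
                             latent_proportions = c(0.40, 0.48, 0.12),
                             component_means = default_component_means(),
                             component_cvs = default_component_cvs(),
                             log_scale_params = LOG_SCALE_PARAMS,
                             sex_effect = default_sex_effect(),
                             p_male = 0.483,
                             missing_rate = 0.05,
                             missing_mechanism = c("mcar", "mar"),
                             disease_base_logit = default_disease_logits()$base,
                             disease_group_effects = default_disease_logits()$effects,
                             incident_base_logit = default_incident_logits()$base,
                             incident_group_effects = default_incident_logits()$effects,
                             followup_retention = c(0.753, 0.697, 0.597),
                             nonfasting_rate = 0.0175,
                             disease_missing_rate = 0.002,
                             shared_factor_sd = 0,
                             seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    latent_proportions = latent_proportions,
    component_means = component_means,
    component_cvs = component_cvs,
    log_scale_params = log_scale_params,
    sex_effect = sex_effect,
    p_male = p_male,
    missing_rate = missing_rate,
    missing_mechanism = match.arg(missing_mechanism),
    disease_base_logit = disease_base_logit,
    disease_group_effects = disease_group_effects,
    incident_base_logit = incident_base_logit,
    incident_group_effects = incident_group_effects,
    followup_retention = followup_retention,
    nonfasting_rate = nonfasting_rate,
    disease_missing_rate = disease_missing_rate,
    shared_factor_sd = shared_factor_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  fail <- function(field, msg)
    stop("invalid generator config: field '", field, "' ", msg, call. = FALSE)
  if (length(cfg$n_participants) != 1 || is.na(cfg$n_participants) ||
      cfg$n_participants < 1)
    fail("n_participants", "must be a positive count")
  if (length(cfg$latent_proportions) != 3 ||
      any(cfg$latent_proportions < 0) ||
      abs(sum(cfg$latent_proportions) - 1) > 1e-12)
    fail("latent_proportions", "must be 3 probabilities summing to 1")
  if (!is.matrix(cfg$component_means) ||
      !identical(sort(rownames(cfg$component_means)), sort(PARAM_NAMES)) ||
      ncol(cfg$component_means) != 3)
    fail("component_means", "must be a 14 x 3 matrix with parameter rownames")
  log_rows <- cfg$component_means[cfg$log_scale_params, , drop = FALSE]
  if (any(log_rows <= 0))
    fail("component_means", "must be strictly positive for log-scale parameters")
  if (!all(PARAM_NAMES %in% names(cfg$component_cvs)) ||
      any(cfg$component_cvs <= 0))
    fail("component_cvs", "must name every parameter with a positive CV")
  if (!all(cfg$log_scale_params %in% PARAM_NAMES))
    fail("log_scale_params", "contains unknown parameter names")
  for (field in c("missing_rate", "nonfasting_rate", "disease_missing_rate",
                  "p_male")) {
    v <- cfg[[field]]
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1)
      fail(field, "must be a single rate in [0, 1]")
  }
  if (cfg$missing_rate > 0.1)
    fail("missing_rate", "must not exceed 0.1")
  if (length(cfg$followup_retention) != 3 ||
      any(cfg$followup_retention < 0 | cfg$followup_retention > 1))
    fail("followup_retention", "must be 3 probabilities in [0, 1]")
  for (field in c("disease_base_logit", "incident_base_logit")) {
    if (!identical(sort(names(cfg[[field]])), sort(DISEASE_NAMES)))
      fail(field, "must name all 6 diseases")
  }
  for (field in c("disease_group_effects", "incident_group_effects")) {
    m <- cfg[[field]]
    if (!is.matrix(m) || ncol(m) != 2 ||
        !identical(sort(rownames(m)), sort(DISEASE_NAMES)))
      fail(field, "must be a 6 x 2 matrix with disease rownames")
  }
  if (cfg$shared_factor_sd < 0) fail("shared_factor_sd", "must be >= 0")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator configuration\n")
  cat("  participants:", x$n_participants,
      " latent proportions:", paste(x$latent_proportions, collapse = "/"), "\n")
  cat("  missing rate:", x$missing_rate, "(", x$missing_mechanism, ")",
      " non-fasting rate:", x$nonfasting_rate, "\n")
  cat("  follow-up retention by group:",
      paste(round(x$followup_retention, 3), collapse = "/"), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Per-group parameter locations. Columns are the healthy, intermediate and
# unfavorable groups; values follow the typical profile of a middle-aged
# European cohort stratified by metabolic health (glucose, BMI, uric acid
# and liver enzymes rise across groups, HDLc falls).
default_component_means <- function() {
  m <- rbind(
    tg         = c(0.82, 1.46, 1.76),
    bmi        = c(24.2, 28.2, 33.2),
    uric_acid  = c(243.5, 334.1, 375.3),
    glucose    = c(89, 96, 122),
    insulin    = c(6.6, 10.0, 18.0),
    hdlc       = c(1.70, 1.26, 1.18),
    non_hdlc   = c(3.59, 4.49, 4.01),
    hba1c      = c(5.3, 5.5, 6.1),
    hs_crp     = c(0.76, 1.38, 2.49),
    ggt        = c(0.31, 0.50, 0.63),
    got        = c(0.38, 0.43, 0.45),
    gpt        = c(0.28, 0.40, 0.48),
    ap         = c(1.00, 1.14, 1.21),
    leukocytes = c(5.3, 5.9, 6.3)
  )
  colnames(m) <- c("healthy", "intermediate", "unfavorable")
  m[PARAM_NAMES, ]
}

# Within-group coefficients of variation; chosen so that adjacent group
# locations sit roughly 0.5-2 within-group SDs apart per parameter --
# groups overlap in any single parameter but adjacent groups are several
# pooled SDs apart in the standardized 14-dimensional space, so the
# planted structure is reliably recoverable by clustering.
default_component_cvs <- function() {
  c(tg = 0.28, bmi = 0.065, uric_acid = 0.12, glucose = 0.055,
    insulin = 0.40, hdlc = 0.12, non_hdlc = 0.145, hba1c = 0.05,
    hs_crp = 0.80, ggt = 0.40, got = 0.16, gpt = 0.28, ap = 0.16,
    leukocytes = 0.20)
}

# Modest additive male-female differences on the natural scale.
default_sex_effect <- function() {
  eff <- rep(0, length(PARAM_NAMES))
  names(eff) <- PARAM_NAMES
  eff["uric_acid"] <- 30
  eff["hdlc"] <- -0.2
  eff["glucose"] <- 2
  eff["ggt"] <- 0.05
  eff
}

# Baseline disease probabilities per latent group, expressed as a group-1
# logit plus logit shifts for groups 2 and 3.
default_disease_logits <- function() {
  p <- rbind(
    hypertension  = c(0.210, 0.429, 0.766),
    t2d           = c(0.0126, 0.036, 0.470),
    dyslipidemia  = c(0.085, 0.120, 0.302),
    hyperuricemia = c(0.013, 0.040, 0.108),
    mi            = c(0.010, 0.026, 0.078),
    stroke        = c(0.016, 0.022, 0.054)
  )
  lg <- .logit(p)
  list(base = lg[, 1],
       effects = cbind(g2 = lg[, 2] - lg[, 1], g3 = lg[, 3] - lg[, 1]))
}

# Incident disease probabilities per latent group among the baseline-free.
default_incident_logits <- function() {
  p <- rbind(
    hypertension  = c(0.096, 0.114, 0.136),
    t2d           = c(0.015, 0.044, 0.302),
    dyslipidemia  = c(0.030, 0.092, 0.172),
    hyperuricemia = c(0.005, 0.024, 0.095),
    mi            = c(0.002, 0.020, 0.024),
    stroke        = c(0.011, 0.015, 0.046)
  )
  lg <- .logit(p)
  list(base = lg[, 1],
       effects = cbind(g2 = lg[, 2] - lg[, 1], g3 = lg[, 3] - lg[, 1]))
}

# loadings of the optional shared adiposity factor (per SD of the factor)
.shared_factor_loadings <- function() {
  l <- rep(0, length(PARAM_NAMES))
  names(l) <- PARAM_NAMES
  l[c("bmi", "tg", "insulin", "hs_crp", "glucose")] <-
    c(1.5, 0.15, 1.5, 0.4, 2.0)
  l
}

# ---- cohort generation ---------------------------------------------------

#' Generate a synthetic two-wave cohort with planted metabolic structure
#'
#' Draws a baseline cohort and one follow-up wave from the mixture model
#' described by a [generator_config()]. Each participant belongs to one of
#' three latent metabolic groups; the 14 clinical parameters are drawn
#' conditionally independently given the group (normal, or log-normal for
#' right-skewed biomarkers), baseline and incident diseases follow logistic
#' models with group effects, and follow-up participation depends on the
#' group. The latent group is recorded in the output for validation only
#' and is never consumed by the analysis pipeline.
#'
#' Incident disease flags are drawn only for participants who are free of
#' the disease at baseline and participate in the follow-up; all other
#' follow-up flags are missing.
#'
#' @param config a [generator_config()].
#' @return a `cohort_table`: a data.frame with one row per participant and
#'   columns `participant_id`, `fasting_hours_ok`, the 14 parameters,
#'   socio-demographics (`sex`, `age_years`, `education_class`,
#'   `activity_class`, `smoking_class`, `alcohol_class`),
#'   `base_<disease>` logical baseline flags, `in_followup`,
#'   `fu_<disease>` logical incident flags, and `latent_group`.
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  n <- config$n_participants
  set.seed(config$seed)

  group <- sample.int(3L, n, replace = TRUE, prob = config$latent_proportions)
  male <- stats::runif(n) < config$p_male

  p <- length(PARAM_NAMES)
  X <- matrix(NA_real_, n, p, dimnames = list(NULL, PARAM_NAMES))
  fac <- if (config$shared_factor_sd > 0)
    stats::rnorm(n, 0, config$shared_factor_sd) else numeric(n)
  loadings <- .shared_factor_loadings()
  for (j in seq_len(p)) {
    par <- PARAM_NAMES[j]
    mu <- config$component_means[par, group]
    cv <- config$component_cvs[[par]]
    if (par %in% config$log_scale_params) {
      sdlog <- sqrt(log(1 + cv^2))
      x <- stats::rlnorm(n, meanlog = log(mu), sdlog = sdlog)
    } else {
      x <- stats::rnorm(n, mean = mu, sd = cv * mu)
    }
    x <- x + male * config$sex_effect[[par]] + fac * loadings[[par]]
    X[, j] <- pmax(x, 0.01 * mu)  # biomarkers are strictly positive
  }

  age_mu <- c(51, 57, 65)[group]
  age <- round(pmin(pmax(stats::rnorm(n, age_mu, 13), 25), 90))
  education <- sample(c("<10y", "10-<12y", ">=12y"), n, replace = TRUE,
                      prob = c(0.087, 0.500, 0.413))
  activity <- sample(c("active", "inactive"), n, replace = TRUE,
                     prob = c(0.548, 0.452))
  smoking <- sample(c("smoker", "ex-smoker", "never"), n, replace = TRUE,
                    prob = c(0.175, 0.406, 0.419))
  alcohol <- sample(c(">=40g/d", "20-<40g/d", "0-<20g/d", "0g/d"), n,
                    replace = TRUE, prob = c(0.112, 0.180, 0.407, 0.301))

  base_dis <- matrix(NA, n, length(DISEASE_NAMES),
                     dimnames = list(NULL, DISEASE_NAMES))
  for (d in DISEASE_NAMES) {
    eta <- config$disease_base_logit[[d]] +
      c(0, config$disease_group_effects[d, ])[group]
    base_dis[, d] <- stats::runif(n) < .expit(eta)
  }

  in_fu <- stats::runif(n) < config$followup_retention[group]

  fu_dis <- matrix(NA, n, length(DISEASE_NAMES),
                   dimnames = list(NULL, DISEASE_NAMES))
  for (d in DISEASE_NAMES) {
    eta <- config$incident_base_logit[[d]] +
      c(0, config$incident_group_effects[d, ])[group]
    at_risk <- in_fu & !base_dis[, d]
    draw <- stats::runif(n) < .expit(eta)
    fu_dis[at_risk, d] <- draw[at_risk]
  }

  # missingness on parameter cells
  if (config$missing_rate > 0) {
    if (config$missing_mechanism == "mcar") {
      rate <- matrix(config$missing_rate, n, p)
    } else {
      tert <- cut(X[, "bmi"], stats::quantile(X[, "bmi"], c(0, 1/3, 2/3, 1)),
                  include.lowest = TRUE, labels = FALSE)
      rate <- matrix(config$missing_rate * c(0.5, 1, 1.5)[tert], n, p)
    }
    X[matrix(stats::runif(n * p), n, p) < rate] <- NA_real_
  }
  if (config$disease_missing_rate > 0) {
    drop_b <- matrix(stats::runif(n * length(DISEASE_NAMES)), n) <
      config$disease_missing_rate
    base_dis[drop_b] <- NA
    drop_f <- matrix(stats::runif(n * length(DISEASE_NAMES)), n) <
      config$disease_missing_rate
    fu_dis[drop_f & in_fu] <- NA
  }

  nonfasting <- stats::runif(n) < config$nonfasting_rate

  out <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    fasting_hours_ok = !nonfasting,
    as.data.frame(X),
    sex = ifelse(male, "male", "female"),
    age_years = age,
    education_class = education,
    activity_class = activity,
    smoking_class = smoking,
    alcohol_class = alcohol,
    stringsAsFactors = FALSE
  )
  for (d in DISEASE_NAMES) out[[paste0("base_", d)]] <- base_dis[, d]
  out$in_followup <- in_fu
  for (d in DISEASE_NAMES) out[[paste0("fu_", d)]] <- fu_dis[, d]
  out$latent_group <- group
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", nrow(x), "participants,",
      sum(x$in_followup), "in follow-up\n")
  miss <- sum(is.na(as.matrix(x[, PARAM_NAMES])))
  cat("  missing parameter cells:", miss, "\n")
  NextMethod()
}

# ---- cohort I/O ----------------------------------------------------------

#' Write or read a cohort as CSV with a JSON data dictionary
#'
#' `write_cohort()` writes the cohort as UTF-8 CSV (missing cells as empty
#' strings) plus a sidecar `cohort.dictionary.json` describing each column
#' (name, type, unit, allowed categories). `read_cohort()` reads it back,
#' restoring column types.
#'
#' @param cohort a `cohort_table`.
#' @param dir output directory (created if absent).
#' @return `write_cohort()` returns the CSV path invisibly; `read_cohort()`
#'   returns a `cohort_table`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(cohort, csv, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  units <- stats::setNames(clinical_parameters()$unit,
                           clinical_parameters()$parameter)
  dict <- lapply(names(cohort), function(nm) {
    col <- cohort[[nm]]
    list(
      name = nm,
      type = if (is.logical(col)) "boolean"
             else if (is.numeric(col)) "numeric" else "categorical",
      unit = if (nm %in% names(units)) units[[nm]] else NULL,
      categories = if (is.character(col)) sort(unique(stats::na.omit(col)))
                   else NULL
    )
  })
  jsonlite::write_json(dict, file.path(dir, "cohort.dictionary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(csv)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  csv <- file.path(dir, "cohort.csv")
  if (!file.exists(csv)) stop("no cohort.csv in ", dir, call. = FALSE)
  x <- utils::read.csv(csv, stringsAsFactors = FALSE, na.strings = "",
                       fileEncoding = "UTF-8")
  for (nm in c("fasting_hours_ok", "in_followup",
               paste0("base_", DISEASE_NAMES), paste0("fu_", DISEASE_NAMES)))
    if (nm %in% names(x)) x[[nm]] <- as.logical(x[[nm]])
  class(x) <- c("cohort_table", "data.frame")
  x
}
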