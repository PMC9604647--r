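#' Clinical parameter panel
#'
#' Names of the 14 candidate clustering parameters, their measurement units,
#' and related constants used throughout the package. The panel consists of
#' standard laboratory parameters routinely measured in primary care, plus
#' BMI; non-HDL cholesterol replaces total cholesterol, LDL cholesterol and
#' the TC/HDL ratio because of its higher prognostic value.
#'
#' @return `clinical_parameters()` returns a data.frame with columns
#'   `parameter`, `unit` and `log_scale` (whether the parameter is simulated
#'   log-normally by [generate_cohort()]).
#' @export
#' @examples
#' clinical_parameters()
clinical_parameters <- function() {
  data.frame(
    parameter = PARAM_NAMES,
    unit = c("mmol/L", "kg/m2", "umol/L", "mg/dL", "uU/mL", "mmol/L",
             "mmol/L", "%", "mg/L", "ukat/L", "ukat/L", "ukat/L",
             "ukat/L", "10^9/L"),
    log_scale = PARAM_NAMES %in% LOG_SCALE_PARAMS,
    stringsAsFactors = FALSE
  )
}

# canonical column order for the 14-parameter panel
PARAM_NAMES <- c("tg", "bmi", "uric_acid", "glucose", "insulin", "hdlc",
                 "non_hdlc", "hba1c", "hs_crp", "ggt", "got", "gpt", "ap",
                 "leukocytes")

# right-skewed parameters drawn log-normally by the generator
LOG_SCALE_PARAMS <- c("tg", "hs_crp", "ggt", "got", "gpt", "insulin")

# the six diseases tracked at baseline and follow-up
DISEASE_NAMES <- c("hypertension", "t2d", "dyslipidemia", "hyperuricemia",
                   "mi", "stroke")

#' Composite cardiometabolic outcomes
#'
#' The two composite outcomes used for model evaluation: `any_metabolic`
#' (hypertension, type 2 diabetes, dyslipidemia, or hyperuricemia/gout) and
#' `any_cvd` (myocardial infarction or stroke). A composite is present when
#' at least one member disease is present.
#'
#' @param name one of `"any_metabolic"`, `"any_cvd"`, or the name of a
#'   single disease (returned as a singleton set).
#' @return character vector of member disease names.
#' @export
#' @examples
#' composite_members("any_metabolic")
composite_members <- function(name) {
  switch(name,
    any_metabolic = c("hypertension", "t2d", "dyslipidemia", "hyperuricemia"),
    any_cvd = c("mi", "stroke"),
    {
      if (!name %in% DISEASE_NAMES)
        stop("unknown outcome: ", name, call. = FALSE)
      name
    }
  )
}

#' Risk direction of clustering parameters
#'
#' Sign vector operationalizing "metabolically favorable": +1 means higher
#' values are less favorable (glucose, TG, non-HDLc, uric acid, BMI,
#' insulin, and the inflammation/liver panel), -1 means higher values are
#' more favorable (HDLc only). Used by [order_clusters()] to label clusters
#' 1 (healthy) to 3 (unfavorable).
#'
#' @param parameters character vector of parameter names; defaults to the
#'   full 14-parameter panel.
#' @return named numeric vector of +1/-1 signs.
#' @export
risk_directions <- function(parameters = PARAM_NAMES) {
  stopifnot(all(parameters %in% PARAM_NAMES))
  sgn <- rep(1, length(parameters))
  names(sgn) <- parameters
  sgn[parameters == "hdlc"] <- -1
  sgn
}

# all permutations of 1..k, as a list (k! small: used for label alignment)
.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- .permutations(k - 1L)
    for (p in rest) {
      v <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, v[p])
    }
  }
  out
}

# logit/expit helpers
.logit <- function(p) log(p / (1 - p))
.expit <- function(x) 1 / (1 + exp(-x))
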