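# Eleven published models / guideline rules for selecting newly diagnosed
# prostate cancer patients for bone-scan staging, implemented as vectorized
# predicates over complete (post-imputation) patient records, plus the
# ordinal / continuous risk scores needed for discrimination and
# calibration. Inequality thresholds are read exactly as printed in the
# sources: ">" strict, ">=" inclusive.

require_complete <- function(records, vars) {
  for (v in vars) {
    if (!v %in% names(records)) {
      stop("missing column '", v, "'", call. = FALSE)
    }
    if (anyNA(records[[v]])) {
      stop("predictor '", v,
           "' has missing values; staging models run on complete ",
           "(post-imputation) records only", call. = FALSE)
    }
  }
  invisible(records)
}

model_inputs <- function(records, vars = c("psa_ng_ml", "gleason_primary",
                                           "gleason_secondary", "t_stage")) {
  require_complete(records, vars)
  out <- list()
  if ("psa_ng_ml" %in% vars) out$psa <- records$psa_ng_ml
  if (all(c("gleason_primary", "gleason_secondary") %in% vars)) {
    out$gg <- isup_grade_group(records$gleason_primary,
                               records$gleason_secondary)
    out$gs <- records$gleason_primary + records$gleason_secondary
  }
  if ("t_stage" %in% vars) out$t_rank <- t_stage_rank(records$t_stage)
  out
}

#' Wang bone-scan decision score D
#'
#' D = -6.40 + 2.39*[T4] + 0.87*ln(PSA + 1) + 0.93*[Gleason >= 4+3] + 2.169.
#' Higher PSA, T4 disease and Gleason >= 4+3 all increase D.
#'
#' @param psa PSA at diagnosis (ng/mL), positive.
#' @param t_stage clinical T-stage label(s).
#' @param gleason_primary,gleason_secondary Gleason patterns.
#' @return numeric score D.
#' @export
wang_score <- function(psa, t_stage, gleason_primary, gleason_secondary) {
  if (anyNA(psa) || anyNA(t_stage) || anyNA(gleason_primary) ||
      anyNA(gleason_secondary)) {
    stop("wang_score requires complete predictors", call. = FALSE)
  }
  if (any(psa <= 0)) stop("psa must be positive", call. = FALSE)
  gg <- isup_grade_group(gleason_primary, gleason_secondary)
  t4 <- as.numeric(as.character(t_stage) == "T4")
  gs43 <- as.numeric(gg >= 3)
  -6.40 + 2.39 * t4 + 0.87 * log(psa + 1) + 0.93 * gs43 + 2.169
}

#' Wang predicted probability of a positive bone scan
#'
#' Inverse logit of the Wang linear predictor convention (the score D).
#'
#' @inheritParams wang_score
#' @return probability in (0, 1).
#' @export
wang_risk <- function(psa, t_stage, gleason_primary, gleason_secondary) {
  stats::plogis(wang_score(psa, t_stage, gleason_primary, gleason_secondary))
}

#' Guideline and literature staging rules
#'
#' Each classifier returns a logical vector, `TRUE` meaning the rule selects
#' the patient for a staging bone scan:
#' * `classify_eau()` — EAU 2020 recommendation: PSA > 20, T >= T2c, or
#'   Gleason >= 4+3 (intermediate risk with 4+3 disease, or high risk).
#' * `classify_eau_high_risk()` — EAU high-risk patients only: PSA > 20,
#'   Gleason sum >= 8, or T >= T3.
#' * `classify_aua()` — AUA 2018, unfavourable intermediate risk and higher:
#'   PSA > 20, PSA > 10 with Gleason 3+4, Gleason >= 4+3, or T >= T2b.
#' * `classify_nccn()` — NCCN 2019, unfavourable intermediate and higher:
#'   T >= T3, PSA > 20, Gleason sum >= 8, or any of T2b-T2c / Gleason sum 7 /
#'   PSA 10-20 together with >= 50% positive biopsy cores.
#' * `classify_osullivan()` — PSA > 20, T4, or Gleason >= 4+3.
#' * `classify_ho()` — PSA > 10 or suspected nodal involvement on imaging.
#' * `classify_simple_psa()` — scan when PSA strictly exceeds `threshold`
#'   (Chybowski strategies at 10 and 20 ng/mL; Lai at 10 ng/mL).
#' * `classify_briganti()` — Gleason sum >= 8, or PSA > 10 in T2-T3 disease
#'   (T2a-T3c inclusive).
#'
#' @param records complete patient records.
#' @param threshold PSA cut-point in ng/mL (for `classify_simple_psa`).
#' @return logical scan / no-scan vector.
#' @name staging_rules
NULL

#' @rdname staging_rules
#' @export
classify_eau <- function(records) {
  x <- model_inputs(records)
  x$psa > 20 | x$t_rank >= 6 | x$gg >= 3
}

#' @rdname staging_rules
#' @export
classify_eau_high_risk <- function(records) {
  x <- model_inputs(records)
  x$psa > 20 | x$gs >= 8 | x$t_rank >= 7
}

#' @rdname staging_rules
#' @export
classify_aua <- function(records) {
  x <- model_inputs(records)
  x$psa > 20 | (x$psa > 10 & x$gg == 2) | x$gg >= 3 | x$t_rank >= 5
}

#' @rdname staging_rules
#' @export
classify_nccn <- function(records) {
  x <- model_inputs(records, c("psa_ng_ml", "gleason_primary",
                               "gleason_secondary", "t_stage",
                               "pct_pos_cores"))
  inter <- (x$t_rank %in% 5:6) | x$gs == 7 | (x$psa >= 10 & x$psa <= 20)
  x$t_rank >= 7 | x$psa > 20 | x$gs >= 8 |
    (inter & records$pct_pos_cores >= 50)
}

#' @rdname staging_rules
#' @export
classify_osullivan <- function(records) {
  x <- model_inputs(records)
  x$psa > 20 | x$t_rank == 10 | x$gg >= 3
}

#' @rdname staging_rules
#' @export
classify_ho <- function(records) {
  require_complete(records, c("psa_ng_ml", "n_stage_positive"))
  records$psa_ng_ml > 10 | records$n_stage_positive
}

#' @rdname staging_rules
#' @export
classify_simple_psa <- function(records, threshold) {
  require_complete(records, "psa_ng_ml")
  records$psa_ng_ml > threshold
}

#' @rdname staging_rules
#' @export
classify_briganti <- function(records) {
  x <- model_inputs(records)
  x$gs >= 8 | (x$psa > 10 & x$t_rank >= 4 & x$t_rank <= 9)
}

#' Five-tier prognostic grouping (Gnanapragasam / Cambridge)
#'
#' Group 1: grade group 1, PSA < 10, T1-T2. Group 2: exactly one of grade
#' group 2 or PSA 10-20. Group 3: grade group 3, or grade group 2 together
#' with PSA 10-20. Group 4: exactly one of grade group 4, PSA > 20, or T3.
#' Group 5: Gleason 9-10 (grade group 5), T4, or any two of the Group-4
#' criteria. The Group-5 rule is sourced from the model's development
#' publication (not restated by every validation) and can be replaced via
#' `group5`.
#'
#' @param records complete patient records.
#' @param group5 optional predicate `function(records) -> logical` replacing
#'   the default Group-5 criteria.
#' @return integer group 1-5.
#' @export
classify_gnanapragasam <- function(records, group5 = NULL) {
  x <- model_inputs(records)
  t3 <- x$t_rank >= 7 & x$t_rank <= 9
  n4 <- (x$gg == 4) + (x$psa > 20) + t3
  g5 <- if (is.null(group5)) {
    x$gg == 5 | x$t_rank == 10 | n4 >= 2
  } else {
    group5(records)
  }
  n2 <- (x$gg == 2) + (x$psa >= 10 & x$psa <= 20)
  g3 <- x$gg == 3 | n2 == 2
  out <- rep(1L, nrow(records))
  out[n2 == 1] <- 2L
  out[g3] <- 3L
  out[n4 >= 1] <- 4L
  out[g5] <- 5L
  out
}

#' @rdname staging_rules
#' @export
classify_isup <- function(records) {
  require_complete(records, c("gleason_primary", "gleason_secondary"))
  isup_grade_group(records$gleason_primary, records$gleason_secondary)
}

# Nominal risk strata used only as ordinal discrimination scores for the
# guideline models (the guidelines themselves publish no numeric risks).
eau_risk_group <- function(records) {
  x <- model_inputs(records)
  high <- x$psa > 20 | x$gg >= 4 | x$t_rank >= 7
  inter <- !high & (x$psa >= 10 | x$gg >= 2 | x$t_rank %in% 5:6)
  ifelse(high, 3L, ifelse(inter, 2L, 1L))
}

aua_risk_group <- function(records) {
  x <- model_inputs(records)
  high <- x$psa > 20 | x$gg >= 4 | x$t_rank >= 7
  unfav <- !high & (x$gg == 3 | (x$psa > 10 & x$gg == 2) | x$t_rank %in% 5:6)
  fav <- !high & !unfav & (x$gg == 2 | x$psa >= 10)
  ifelse(high, 4L, ifelse(unfav, 3L, ifelse(fav, 2L, 1L)))
}

nccn_risk_group <- function(records) {
  scan <- classify_nccn(records)
  x <- model_inputs(records)
  high <- x$t_rank >= 7 | x$psa > 20 | x$gs >= 8
  fav <- !scan & (x$gg == 2 | (x$psa >= 10 & x$psa <= 20) |
                    x$t_rank %in% 5:6)
  ifelse(high, 4L, ifelse(scan, 3L, ifelse(fav, 2L, 1L)))
}

briganti_risk_group <- function(records) {
  x <- model_inputs(records)
  high <- classify_briganti(records)
  inter <- !high & (x$gs == 7 | x$psa > 10)
  ifelse(high, 3L, ifelse(inter, 2L, 1L))
}

lai_risk_group <- function(records) {
  require_complete(records, "psa_ng_ml")
  psa <- records$psa_ng_ml
  ifelse(psa > 50, 4L, ifelse(psa > 20, 3L, ifelse(psa > 10, 2L, 1L)))
}

#' Registry of staging models and strategies
#'
#' Assembles the eleven validated models into one structure: per model a
#' `kind` (continuous or categorical), a score function used for
#' discrimination (predicted probability, or ordinal group rank), the
#' scan/no-scan strategies derived from it, its source-recommended
#' strategies, and optional per-group development-study positivity rates
#' used as numeric predicted risks for calibration.
#'
#' The shipped `group_risks` are the development studies' overall positivity
#' rates (single values, documented placeholders); per-group rates live in
#' the sources' supplements and can be supplied as named vectors (one rate
#' per group label) to enable calibration for categorical models.
#'
#' @param group_risks named list: model name -> numeric scalar (overall
#'   rate, placeholder) or named vector of per-group rates in (0,1).
#' @param continuous_forms named list of `function(records) -> probability`
#'   supplying the continuous forms this validation cannot reprint (the Ho
#'   equation and the Chybowski risk graph).
#' @param wang_direction `"printed"` scans when D < 0 as the source's rule
#'   is printed; `"inverted"` scans when D >= 0 (the direction the
#'   risk-increasing coefficients suggest).
#' @param gnana_group5 optional Group-5 predicate override, passed to
#'   [classify_gnanapragasam()].
#' @return an object of class `model_registry`.
#' @export
model_registry <- function(group_risks = default_group_risks(),
                           continuous_forms = list(),
                           wang_direction = c("printed", "inverted"),
                           gnana_group5 = NULL) {
  wang_direction <- match.arg(wang_direction)
  bad <- vapply(group_risks, function(r)
    any(!is.finite(r) | r <= 0 | r >= 1), logical(1))
  if (any(bad)) {
    stop_stage("config", "group risks must lie strictly in (0, 1): ",
               paste(names(group_risks)[bad], collapse = ", "))
  }

  wang_fn <- function(records) {
    wang_risk(records$psa_ng_ml, records$t_stage,
              records$gleason_primary, records$gleason_secondary)
  }
  wang_strategy <- if (wang_direction == "printed") {
    function(records) wang_score(records$psa_ng_ml, records$t_stage,
                                 records$gleason_primary,
                                 records$gleason_secondary) < 0
  } else {
    function(records) wang_score(records$psa_ng_ml, records$t_stage,
                                 records$gleason_primary,
                                 records$gleason_secondary) >= 0
  }
  gnana_fn <- function(records) {
    classify_gnanapragasam(records, group5 = gnana_group5)
  }

  models <- list(
    chybowski = list(
      label = "Chybowski 1991", kind = "continuous",
      score = continuous_forms$chybowski %||%
        function(records) {
          require_complete(records, "psa_ng_ml")
          records$psa_ng_ml   # risk graph is monotone in PSA
        },
      prob = continuous_forms$chybowski,
      strategies = list(
        `psa-gt-10` = function(r) classify_simple_psa(r, 10),
        `psa-gt-20` = function(r) classify_simple_psa(r, 20)),
      recommended = c("psa-gt-10", "psa-gt-20")
    ),
    osullivan = list(
      label = "O'Sullivan 2003", kind = "categorical",
      score = function(r) as.integer(classify_osullivan(r)) + 1L,
      groups = function(r) ifelse(classify_osullivan(r), "high", "low"),
      strategies = list(osullivan = classify_osullivan),
      recommended = "osullivan"
    ),
    briganti = list(
      label = "Briganti 2010", kind = "categorical",
      score = briganti_risk_group,
      groups = function(r) c("low", "intermediate",
                             "high")[briganti_risk_group(r)],
      strategies = list(briganti = classify_briganti),
      recommended = "briganti"
    ),
    lai = list(
      label = "Lai 2011", kind = "categorical",
      score = lai_risk_group,
      groups = function(r) c("psa<=10", "psa10-20", "psa20-50",
                             "psa>50")[lai_risk_group(r)],
      strategies = list(`psa-gt-10` = function(r) classify_simple_psa(r, 10)),
      recommended = "psa-gt-10"
    ),
    ho = list(
      label = "Ho 2013", kind = "continuous",
      score = continuous_forms$ho %||%
        function(records) {
          require_complete(records, c("psa_ng_ml", "n_stage_positive"))
          log(records$psa_ng_ml) + 2 * records$n_stage_positive
        },
      prob = continuous_forms$ho,
      strategies = list(`ho-rule` = classify_ho),
      recommended = "ho-rule"
    ),
    wang = list(
      label = "Wang 2013", kind = "continuous",
      score = wang_fn, prob = wang_fn,
      strategies = list(`wang-d` = wang_strategy),
      recommended = "wang-d"
    ),
    gnanapragasam = list(
      label = "Gnanapragasam-Cambridge", kind = "categorical",
      score = gnana_fn,
      groups = function(r) paste0("group", gnana_fn(r)),
      strategies = list(
        `gnana-group3` = function(r) gnana_fn(r) >= 3L,
        `gnana-group4` = function(r) gnana_fn(r) >= 4L,
        `gnana-group5` = function(r) gnana_fn(r) >= 5L),
      recommended = c("gnana-group3", "gnana-group4")
    ),
    isup = list(
      label = "ISUP grade grouping", kind = "categorical",
      score = classify_isup,
      groups = function(r) paste0("gg", classify_isup(r)),
      strategies = list(`isup-gg3` = function(r) classify_isup(r) >= 3L),
      recommended = "isup-gg3"
    ),
    aua = list(
      label = "AUA 2018", kind = "categorical",
      score = aua_risk_group, groups = NULL,
      strategies = list(`aua-2018` = classify_aua),
      recommended = "aua-2018"
    ),
    eau = list(
      label = "EAU 2020", kind = "categorical",
      score = eau_risk_group, groups = NULL,
      strategies = list(`eau-2020` = classify_eau,
                        `eau-high-only` = classify_eau_high_risk),
      recommended = "eau-2020"
    ),
    nccn = list(
      label = "NCCN 2019", kind = "categorical",
      score = nccn_risk_group, groups = NULL,
      strategies = list(`nccn-2019` = classify_nccn),
      recommended = "nccn-2019"
    )
  )

  structure(list(models = models, group_risks = group_risks,
                 wang_direction = wang_direction),
            class = "model_registry")
}

#' Development-study overall positivity rates (placeholders)
#'
#' Single published overall rates per source; per-group rates (needed to
#' calibrate categorical models) must be supplied by the user.
#'
#' @return named list of scalar rates.
#' @export
default_group_risks <- function() {
  list(chybowski = 0.14, osullivan = 0.16, briganti = 0.03, lai = 0.29,
       ho = 0.36, wang = 0.13, gnanapragasam = 0.08, isup = 0.08)
}

registry_model <- function(registry, model_name) {
  m <- registry$models[[model_name]]
  if (is.null(m)) {
    stop_stage("config", "unregistered model: ", model_name)
  }
  m
}

#' Continuous predicted risk from a registered model
#'
#' @param registry a [model_registry()].
#' @param model_name registered model name.
#' @param records complete patient records.
#' @return probabilities in (0, 1).
#' @export
predict_continuous <- function(registry, model_name, records) {
  m <- registry_model(registry, model_name)
  if (is.null(m$prob)) {
    stop("continuous form unavailable for model '", model_name,
         "'; supply it via model_registry(continuous_forms = ...)",
         call. = FALSE)
  }
  p <- m$prob(records)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("continuous form for '", model_name,
         "' returned values outside [0, 1]", call. = FALSE)
  }
  p
}

#' Development-study predicted risk for a categorical model's group
#'
#' @param registry a [model_registry()].
#' @param model_name registered model name.
#' @param risk_group group label(s).
#' @return numeric predicted risk(s) in (0, 1).
#' @export
categorical_predicted_risk <- function(registry, model_name, risk_group) {
  r <- registry$group_risks[[model_name]]
  if (is.null(r) || is.null(names(r)) || !all(risk_group %in% names(r))) {
    stop("no numeric predicted risk configured for model '", model_name,
         "' (group-level development rates required)", call. = FALSE)
  }
  unname(r[risk_group])
}

#' All scan/no-scan strategies in a registry
#'
#' Flattens the per-model strategy lists and adds the scan-all and
#' scan-none references.
#'
#' @param registry a [model_registry()].
#' @return named list; each element has `fn` (predicate), `model`, and
#'   `recommended` (was this strategy recommended by its source?).
#' @export
registry_strategies <- function(registry) {
  out <- list(
    `scan-all` = list(fn = function(r) rep(TRUE, nrow(r)),
                      model = "reference", recommended = FALSE),
    `scan-none` = list(fn = function(r) rep(FALSE, nrow(r)),
                       model = "reference", recommended = FALSE)
  )
  for (nm in names(registry$models)) {
    m <- registry$models[[nm]]
    for (s in names(m$strategies)) {
      if (is.null(out[[s]])) {
        out[[s]] <- list(fn = m$strategies[[s]], model = nm,
                         recommended = s %in% m$recommended)
      }
    }
  }
  out
}
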