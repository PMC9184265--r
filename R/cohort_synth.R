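#' Clinical T-stage levels in anatomical order
#'
#' Ordered from T1a (impalpable, incidental) to T4 (fixed/invading adjacent
#' structures), the ordering every staging rule in the registry relies on.
#'
#' @export
T_STAGE_LEVELS <- c("T1a", "T1b", "T1c", "T2a", "T2b", "T2c",
                    "T3a", "T3b", "T3c", "T4")

#' Numeric rank of a clinical T-stage
#'
#' @param t_stage character or factor of T-stage labels.
#' @return integer rank 1 (T1a) to 10 (T4); `NA` propagates.
#' @export
t_stage_rank <- function(t_stage) {
  r <- match(as.character(t_stage), T_STAGE_LEVELS)
  bad <- !is.na(t_stage) & is.na(r)
  if (any(bad)) {
    stop("unknown T-stage label(s): ",
         paste(unique(as.character(t_stage)[bad]), collapse = ", "),
         call. = FALSE)
  }
  r
}

#' Configuration for the synthetic registry-cohort generator
#'
#' Builds the full parameter set describing the simulated world: predictor
#' distributions, the latent logistic model for bone-scan positivity,
#' selective-scanning probabilities, missing-at-random masking probabilities
#' (conditional on treatment setting and latent risk stratum), and
#' exponential survival with a hazard multiplier for scan-positive disease.
#'
#' Defaults emulate the marginal structure of a population-based prostate
#' cancer registry: median PSA about 8 ng/mL, about 37% of Gleason sum <= 6,
#' roughly 38% of patients receiving a staging scan (concentrated in higher
#' risk strata and in the public setting), positivity among scanned patients
#' near 8.7%, and heavy predictor missingness for PSA (~40%), clinical
#' T-stage and nodal stage (~77%), biopsy cores (~17%) and Gleason (~2%).
#' The latent-model intercept shipped here was fixed once with
#' [calibrate_positivity_intercept()] against the 8.7% target.
#'
#' @param n_patients number of patients to simulate.
#' @param seed master seed; per-stage substreams (generation, masking,
#'   survival) are derived from it so stages are independently reproducible.
#' @param predictors,risk,scanning,missingness,survival optional lists of
#'   overrides merged over the defaults (see the returned object for the
#'   available fields).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 2000, seed = 1,
                             predictors = list(), risk = list(),
                             scanning = list(), missingness = list(),
                             survival = list()) {
  # setting x stratum missingness probabilities (rows public/private,
  # columns low/intermediate/high) chosen so the implied marginals sit near
  # the registry's pre-imputation missingness fractions.
  mmat <- function(pub, priv) {
    m <- rbind(public = pub, private = priv)
    colnames(m) <- c("low", "intermediate", "high")
    m
  }
  def <- list(
    n_patients = n_patients,
    seed = seed,
    predictors = list(
      age_mean = 67.9, age_sd = 8.5, age_range = c(34, 98),
      psa_meanlog = log(8.2), psa_sdlog = 0.75,
      # grade-group frequencies (GG1..GG5); GG4/GG5 split the ">= 8" mass
      gleason_probs = c(0.365, 0.265, 0.162, 0.130, 0.078),
      t_group_probs = c(T1 = 0.636, T2 = 0.287, T3 = 0.051, T4 = 0.027),
      t_within = list(T1 = c(T1a = 0.05, T1b = 0.05, T1c = 0.90),
                      T2 = c(T2a = 0.40, T2b = 0.30, T2c = 0.30),
                      T3 = c(T3a = 0.60, T3b = 0.30, T3c = 0.10)),
      nodal_rate = 0.05,
      cores_shape1 = 1.2, cores_shape2 = 2.2,
      private_rate = 0.45,
      year_range = c(2005, 2019)
    ),
    risk = list(
      # latent log-odds of a positive staging bone scan
      intercept = -6.2669,          # calibrated: 8.7% positivity among scanned
      b_log_psa = 0.80,             # per unit log(PSA)
      b_gleason = 0.55,             # per grade group above GG1
      b_t = 0.25,                   # per T-stage rank above T1a
      b_nodal = 1.50                # clinical N1
    ),
    scanning = list(
      prob = mmat(pub  = c(0.13, 0.38, 0.62),
                  priv = c(0.10, 0.30, 0.50)),
      indeterminate_rate = 0.036,
      offset_range = c(0L, 139L),   # days from diagnosis to scan
      resolve_rate = 0.90           # indeterminates resolvable on follow-up
    ),
    missingness = list(
      psa     = mmat(c(0.38, 0.34, 0.28), c(0.55, 0.50, 0.42)),
      gleason = mmat(c(0.02, 0.02, 0.02), c(0.03, 0.03, 0.03)),
      t_stage = mmat(c(0.74, 0.70, 0.62), c(0.88, 0.85, 0.80)),
      cores   = mmat(c(0.14, 0.12, 0.10), c(0.24, 0.22, 0.18)),
      nodal   = mmat(c(0.74, 0.70, 0.60), c(0.86, 0.84, 0.78))
    ),
    survival = list(
      base_rate = 0.0021,           # monthly hazard, scan-negative
      hr_positive = 6,              # hazard ratio for scan-positive disease
      followup_range = c(6, 174)    # administrative censoring, months
    )
  )
  modify <- function(base, over) {
    for (nm in names(over)) base[[nm]] <- over[[nm]]
    base
  }
  cfg <- def
  cfg$predictors  <- modify(cfg$predictors, predictors)
  cfg$risk        <- modify(cfg$risk, risk)
  cfg$scanning    <- modify(cfg$scanning, scanning)
  cfg$missingness <- modify(cfg$missingness, missingness)
  cfg$survival    <- modify(cfg$survival, survival)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1L ||
      cfg$n_patients < 1 || cfg$n_patients != floor(cfg$n_patients)) {
    stop_stage("config", "n_patients must be a positive integer")
  }
  probs <- c(cfg$predictors$gleason_probs, cfg$predictors$t_group_probs,
             cfg$predictors$nodal_rate, cfg$predictors$private_rate,
             unlist(cfg$scanning$prob), cfg$scanning$indeterminate_rate,
             cfg$scanning$resolve_rate, unlist(cfg$missingness))
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    stop_stage("config", "all probabilities must lie in [0, 1]")
  }
  for (nm in names(cfg$missingness)) {
    m <- cfg$missingness[[nm]]
    if (!is.matrix(m) || !identical(dim(m), c(2L, 3L))) {
      stop_stage("config", "missingness$", nm,
                 " must be a 2x3 matrix (setting x stratum)")
    }
  }
  invisible(cfg)
}

# Representative (primary, secondary) Gleason pattern for each grade group.
gg_to_patterns <- function(gg) {
  prim <- c(3L, 3L, 4L, 4L, 4L)[gg]
  sec  <- c(3L, 4L, 3L, 4L, 5L)[gg]
  list(primary = prim, secondary = sec)
}

#' ISUP grade group from Gleason primary + secondary patterns
#'
#' Grade group 1 = Gleason sum <= 6, 2 = 3+4, 3 = 4+3, 4 = sum 8,
#' 5 = sum 9-10.
#'
#' @param primary,secondary integer Gleason patterns (3-5).
#' @return integer grade group 1-5; `NA` if either pattern is missing.
#' @export
isup_grade_group <- function(primary, secondary) {
  s <- primary + secondary
  gg <- ifelse(s <= 6, 1L,
        ifelse(s == 7 & primary == 3, 2L,
        ifelse(s == 7, 3L,
        ifelse(s == 8, 4L, 5L))))
  gg[!is.finite(s)] <- NA_integer_
  as.integer(gg)
}

# Coarse clinical risk stratum on true (pre-masking) values; drives the
# selective-scanning and masking mechanisms.
risk_stratum <- function(psa, gg, t_rank) {
  high <- psa > 20 | gg >= 4 | t_rank >= 6          # >= T2c
  low  <- !high & psa < 10 & gg == 1 & t_rank <= 4  # <= T2a
  out <- ifelse(high, "high", ifelse(low, "low", "intermediate"))
  factor(out, levels = c("low", "intermediate", "high"))
}

latent_linear_predictor <- function(risk, psa, gg, t_rank, nodal) {
  risk$intercept + risk$b_log_psa * log(psa) +
    risk$b_gleason * (gg - 1) + risk$b_t * (t_rank - 1) +
    risk$b_nodal * as.numeric(nodal)
}

#' Generate a synthetic registry cohort
#'
#' Simulates `n_patients` newly diagnosed prostate cancer patients:
#' complete predictors are drawn first, bone-scan positivity is generated
#' from the latent logistic model, a staging scan is performed selectively
#' (probability depending on risk stratum and treatment setting), survival
#' is exponential with a configurable hazard ratio for scan-positive
#' disease, and finally missing-at-random masking is applied to predictors.
#' The complete pre-masking record is retained in a parallel truth table.
#'
#' @param config a [generator_config()].
#' @return a `data.frame` of patient records with attributes
#'   `truth` (pre-masking table incl. `p_positive`, `true_scan_positive`,
#'   `risk_stratum`, `scanned`), `followup_labels` (named vector of
#'   positive/negative follow-up results for the resolvable indeterminate
#'   scans) and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop_stage("config", "config must be a generator_config object")
  }
  validate_generator_config(config)
  n <- as.integer(config$n_patients)
  pr <- config$predictors

  gen <- with_seed(derive_seed(config$seed, "generation"), {
    age <- pmin(pmax(stats::rnorm(n, pr$age_mean, pr$age_sd),
                     pr$age_range[1]), pr$age_range[2])
    psa <- stats::rlnorm(n, pr$psa_meanlog, pr$psa_sdlog)
    gg <- sample.int(5L, n, replace = TRUE, prob = pr$gleason_probs)
    tgrp <- sample(names(pr$t_group_probs), n, replace = TRUE,
                   prob = pr$t_group_probs)
    t_stage <- character(n)
    for (g in c("T1", "T2", "T3")) {
      idx <- tgrp == g
      if (any(idx)) {
        t_stage[idx] <- sample(names(pr$t_within[[g]]), sum(idx),
                               replace = TRUE, prob = pr$t_within[[g]])
      }
    }
    t_stage[tgrp == "T4"] <- "T4"
    nodal <- stats::runif(n) < pr$nodal_rate
    cores <- 100 * stats::rbeta(n, pr$cores_shape1, pr$cores_shape2)
    setting <- ifelse(stats::runif(n) < pr$private_rate, "private", "public")
    year <- sample(seq(pr$year_range[1], pr$year_range[2]), n, replace = TRUE)

    t_rank <- t_stage_rank(t_stage)
    stratum <- risk_stratum(psa, gg, t_rank)
    lp <- latent_linear_predictor(config$risk, psa, gg, t_rank, nodal)
    p_pos <- stats::plogis(lp)
    true_pos <- stats::runif(n) < p_pos

    sc <- config$scanning
    p_scan <- sc$prob[cbind(match(setting, c("public", "private")),
                            as.integer(stratum))]
    scanned <- stats::runif(n) < p_scan
    indet <- scanned & stats::runif(n) < sc$indeterminate_rate
    offset <- ifelse(scanned,
                     sample(seq(sc$offset_range[1], sc$offset_range[2]),
                            n, replace = TRUE),
                     NA_integer_)
    resolve <- stats::runif(n) < sc$resolve_rate
    list(age = age, psa = psa, gg = gg, t_stage = t_stage, nodal = nodal,
         cores = cores, setting = setting, year = year, stratum = stratum,
         p_pos = p_pos, true_pos = true_pos, scanned = scanned,
         indet = indet, offset = offset, resolve = resolve)
  })

  sv <- config$survival
  surv <- with_seed(derive_seed(config$seed, "survival"), {
    rate <- sv$base_rate * ifelse(gen$true_pos, sv$hr_positive, 1)
    event_time <- stats::rexp(n, rate)
    censor <- stats::runif(n, sv$followup_range[1], sv$followup_range[2])
    list(time = pmin(event_time, censor), dead = event_time <= censor)
  })

  pats <- gg_to_patterns(gen$gg)
  scan_result <- rep("none", n)
  scan_result[gen$scanned] <- ifelse(gen$true_pos[gen$scanned],
                                     "positive", "negative")
  scan_result[gen$indet] <- "indeterminate"

  cohort <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age_years = gen$age,
    psa_ng_ml = gen$psa,
    gleason_primary = pats$primary,
    gleason_secondary = pats$secondary,
    pct_pos_cores = gen$cores,
    t_stage = factor(gen$t_stage, levels = T_STAGE_LEVELS, ordered = TRUE),
    n_stage_positive = gen$nodal,
    scan_result = factor(scan_result,
                         levels = c("positive", "negative",
                                    "indeterminate", "none")),
    scan_offset_days = as.integer(gen$offset),
    treatment_setting = factor(gen$setting, levels = c("public", "private")),
    survival_months = surv$time,
    dead = surv$dead,
    year_of_diagnosis = as.integer(gen$year),
    stringsAsFactors = FALSE
  )

  truth <- cohort
  truth$scan_result <- NULL
  truth$scan_offset_days <- NULL
  truth$p_positive <- gen$p_pos
  truth$true_scan_positive <- gen$true_pos
  truth$risk_stratum <- gen$stratum
  truth$scanned <- gen$scanned

  # MAR masking conditional on treatment setting and latent risk stratum
  cohort <- with_seed(derive_seed(config$seed, "masking"), {
    row_i <- match(gen$setting, c("public", "private"))
    col_i <- as.integer(gen$stratum)
    mask <- function(var) {
      p <- config$missingness[[var]][cbind(row_i, col_i)]
      stats::runif(n) < p
    }
    cohort$psa_ng_ml[mask("psa")] <- NA_real_
    mg <- mask("gleason")
    cohort$gleason_primary[mg] <- NA_integer_
    cohort$gleason_secondary[mg] <- NA_integer_
    cohort$t_stage[mask("t_stage")] <- NA
    cohort$pct_pos_cores[mask("cores")] <- NA_real_
    cohort$n_stage_positive[mask("nodal")] <- NA
    cohort
  })

  labs <- character(0)
  if (any(gen$indet & gen$resolve)) {
    keep <- gen$indet & gen$resolve
    labs <- ifelse(gen$true_pos[keep], "positive", "negative")
    names(labs) <- cohort$patient_id[keep]
  }

  attr(cohort, "truth") <- truth
  attr(cohort, "followup_labels") <- labs
  attr(cohort, "config") <- config
  cohort
}

#' Calibrate the latent positivity intercept to a target marginal
#'
#' Solves for the latent-model intercept so that the analytic positivity
#' rate among scanned patients, averaged over a large simulated predictor
#' sample with scan-probability weights, equals `target`. Used once to fix
#' the default configuration; exposed so alternative worlds can be
#' re-calibrated the same way.
#'
#' @param config a [generator_config()] (its intercept is ignored).
#' @param target desired expected positivity among scanned patients.
#' @param n size of the predictor sample used for the integration.
#' @param seed seed for that sample.
#' @return the calibrated intercept (numeric scalar).
#' @export
calibrate_positivity_intercept <- function(config, target = 0.087,
                                           n = 200000, seed = 1) {
  pr <- config$predictors
  smp <- with_seed(seed, {
    psa <- stats::rlnorm(n, pr$psa_meanlog, pr$psa_sdlog)
    gg <- sample.int(5L, n, replace = TRUE, prob = pr$gleason_probs)
    tgrp <- sample(names(pr$t_group_probs), n, replace = TRUE,
                   prob = pr$t_group_probs)
    t_stage <- character(n)
    for (g in c("T1", "T2", "T3")) {
      idx <- tgrp == g
      if (any(idx)) {
        t_stage[idx] <- sample(names(pr$t_within[[g]]), sum(idx),
                               replace = TRUE, prob = pr$t_within[[g]])
      }
    }
    t_stage[tgrp == "T4"] <- "T4"
    nodal <- stats::runif(n) < pr$nodal_rate
    setting <- ifelse(stats::runif(n) < pr$private_rate, "private", "public")
    list(psa = psa, gg = gg, t_rank = t_stage_rank(t_stage), nodal = nodal,
         setting = setting)
  })
  stratum <- risk_stratum(smp$psa, smp$gg, smp$t_rank)
  w <- config$scanning$prob[cbind(match(smp$setting, c("public", "private")),
                                  as.integer(stratum))]
  risk0 <- config$risk
  risk0$intercept <- 0
  lp0 <- latent_linear_predictor(risk0, smp$psa, smp$gg, smp$t_rank,
                                 smp$nodal)
  f <- function(b0) sum(stats::plogis(b0 + lp0) * w) / sum(w) - target
  stats::uniroot(f, c(-30, 10), tol = 1e-8)$root
}

#' Restrict scan results to staging scans
#'
#' Scans performed more than `window_days` after diagnosis are not staging
#' scans: their result is set to `none` (and the offset cleared) so the
#' outcome is treated as unknown and imputed downstream. The boundary is
#' inclusive: a scan on day `window_days` counts as staging.
#'
#' @param records cohort table of patient records.
#' @param window_days staging window in days (default 140 = 20 weeks).
#' @return the cohort with out-of-window scans reclassified to `none`.
#' @export
flag_staging_scans <- function(records, window_days = 140) {
  if (!is.numeric(window_days) || window_days <= 0) {
    stop_stage("staging", "window_days must be positive")
  }
  off <- records$scan_offset_days
  if (any(!is.na(off) & off < 0)) {
    stop_stage("staging", "negative scan offsets are invalid")
  }
  has_scan <- records$scan_result != "none"
  if (any(has_scan & is.na(off))) {
    stop_stage("staging", "scan result present without a scan offset")
  }
  out <- !is.na(off) & off > window_days
  records$scan_result[out] <- "none"
  records$scan_offset_days[out] <- NA_integer_
  records
}

#' Resolve indeterminate scans using follow-up information
#'
#' Indeterminate staging scans with a follow-up label become positive or
#' negative; those without a label are set to `none` so their outcome is
#' imputed with the never-scanned patients.
#'
#' @param records cohort table.
#' @param followup_labels named character vector `patient_id -> "positive"`
#'   or `"negative"`; names must identify indeterminate patients only.
#'   Defaults to the generator's own follow-up labels when present.
#' @return the cohort with no remaining indeterminate results.
#' @export
reclassify_indeterminate <- function(records,
                                     followup_labels =
                                       attr(records, "followup_labels")) {
  labs <- followup_labels %||% character(0)
  if (length(labs)) {
    if (is.null(names(labs)) || any(!nzchar(names(labs)))) {
      stop_stage("staging", "followup_labels must be named by patient_id")
    }
    if (!all(labs %in% c("positive", "negative"))) {
      stop_stage("staging", "labels must be 'positive' or 'negative'")
    }
    idx <- match(names(labs), records$patient_id)
    if (anyNA(idx)) {
      stop_stage("staging", "label for unknown patient_id")
    }
    if (any(records$scan_result[idx] != "indeterminate")) {
      stop_stage("staging", "label supplied for a non-indeterminate patient")
    }
    records$scan_result[idx] <- unname(labs)
  }
  left <- records$scan_result == "indeterminate"
  records$scan_result[left] <- "none"
  records$scan_offset_days[left] <- NA_integer_
  records
}

#' Write / read a cohort as delimited text
#'
#' Comma-separated with a header row and `""` as the missing-value marker;
#' the truth table, when present, goes to a `<path>.truth.csv` sidecar.
#'
#' @param cohort cohort table (from [generate_cohort()] or [read_cohort()]).
#' @param path file path for the main table.
#' @param truth write the truth sidecar if the cohort carries one?
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort `data.frame` (with the truth attribute restored if
#'   the sidecar exists).
#' @export
write_cohort <- function(cohort, path, truth = TRUE) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  tt <- attr(cohort, "truth")
  if (truth && !is.null(tt)) {
    utils::write.csv(tt, paste0(path, ".truth.csv"), row.names = FALSE,
                     na = "")
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  x$t_stage <- factor(x$t_stage, levels = T_STAGE_LEVELS, ordered = TRUE)
  x$scan_result <- factor(x$scan_result,
                          levels = c("positive", "negative",
                                     "indeterminate", "none"))
  x$treatment_setting <- factor(x$treatment_setting,
                                levels = c("public", "private"))
  x$scan_offset_days <- as.integer(x$scan_offset_days)
  tp <- paste0(path, ".truth.csv")
  if (file.exists(tp)) {
    tt <- utils::read.csv(tp, stringsAsFactors = FALSE, na.strings = "")
    tt$t_stage <- factor(tt$t_stage, levels = T_STAGE_LEVELS, ordered = TRUE)
    tt$risk_stratum <- factor(tt$risk_stratum,
                              levels = c("low", "intermediate", "high"))
    attr(x, "truth") <- tt
  }
  x
}
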