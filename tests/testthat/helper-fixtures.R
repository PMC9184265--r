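# Shared fixtures: record builders, brute-force oracles, and small
# imputed-set stand-ins used across the suite.

# A complete patient record (or several) with overridable fields.
make_records <- function(n = 1, psa = 5, t_stage = "T1c", gp = 3, gs = 3,
                         cores = 30, nodal = FALSE, age = 68,
                         surv = 60, dead = FALSE, setting = "public",
                         year = 2012) {
  data.frame(
    patient_id = sprintf("R%04d", seq_len(n)),
    age_years = rep_len(age, n),
    psa_ng_ml = rep_len(psa, n),
    gleason_primary = rep_len(gp, n),
    gleason_secondary = rep_len(gs, n),
    pct_pos_cores = rep_len(cores, n),
    t_stage = factor(rep_len(t_stage, n), levels = T_STAGE_LEVELS,
                     ordered = TRUE),
    n_stage_positive = rep_len(nodal, n),
    scan_result = factor(rep("none", n),
                         levels = c("positive", "negative",
                                    "indeterminate", "none")),
    scan_offset_days = rep(NA_integer_, n),
    treatment_setting = factor(rep_len(setting, n),
                               levels = c("public", "private")),
    survival_months = rep_len(surv, n),
    dead = rep_len(dead, n),
    year_of_diagnosis = rep_len(year, n),
    stringsAsFactors = FALSE
  )
}

# Random complete records for property-style checks.
random_records <- function(n, seed = 1) {
  set.seed(seed)
  gg <- sample.int(5, n, replace = TRUE)
  pats <- list(p = c(3L, 3L, 4L, 4L, 4L)[gg],
               s = c(3L, 4L, 3L, 4L, 5L)[gg])
  make_records(
    n = n,
    psa = exp(rnorm(n, log(9), 1)),
    t_stage = sample(T_STAGE_LEVELS, n, replace = TRUE),
    gp = pats$p, gs = pats$s,
    cores = runif(n, 0, 100),
    nodal = runif(n) < 0.05
  )
}

# Brute-force pairwise-concordance AUC (independent oracle).
brute_auc <- function(scores, y) {
  pos <- scores[as.logical(y)]
  neg <- scores[!as.logical(y)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Naive per-patient net-benefit recount (independent oracle).
naive_nb <- function(scan, positive, pt) {
  n <- length(scan)
  tp <- 0
  fp <- 0
  for (i in seq_len(n)) {
    if (scan[i]) {
      if (positive[i]) tp <- tp + 1 else fp <- fp + 1
    }
  }
  tp / n - (fp / n) * pt / (1 - pt)
}

# Wrap one or more complete datasets (with a scan_positive column) as an
# imputed_cohort_set so curve/validation functions can run on them.
fake_imputed_set <- function(datasets) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  structure(list(datasets = datasets, m = length(datasets),
                 iterations = 0L, seed = 0L, spec = NULL,
                 imputed_cells = NULL, warnings = character(0)),
            class = "imputed_cohort_set")
}

# Small default synthetic cohort, memoised per (n, seed).
small_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 800, seed = 7) {
    key <- paste0("n", n, "_", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_cohort(
        generator_config(n_patients = n, seed = seed))
    }
    cache[[key]]
  }
})
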