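# Multiple imputation by chained equations for the registry cohort.
#
# The modelled variables are log(PSA), percent positive cores, ISUP grade
# group, T-stage rank, nodal stage, and the staging-scan outcome. Continuous
# and ordinal variables use predictive-mean matching (k donors, Bayesian
# parameter draw); binary variables use a Bayesian logistic draw. Survival
# enters every conditional model as (log time, event indicator); treatment
# setting, age and diagnosis year are always predictors. Observed cells are
# never altered.

imput_vars <- function() {
  c("log_psa", "cores", "gg", "t_rank", "nodal", "scan_pos")
}

#' Default per-variable conditional-model specification
#'
#' @param k_donors number of predictive-mean-matching donors.
#' @return named list mapping each modelled variable to its method.
#' @export
default_imputation_spec <- function(k_donors = 5) {
  list(log_psa = "pmm", cores = "pmm", gg = "pmm", t_rank = "pmm",
       nodal = "logreg", scan_pos = "logreg", k_donors = k_donors)
}

# Build the numeric working frame the chained equations run on.
build_working_frame <- function(cohort) {
  scan_pos <- ifelse(cohort$scan_result == "positive", 1,
              ifelse(cohort$scan_result == "negative", 0, NA))
  if (any(cohort$scan_result == "indeterminate")) {
    stop_stage("impute",
               "indeterminate scans remain; run reclassify_indeterminate()",
               " before imputation")
  }
  data.frame(
    log_psa = log(cohort$psa_ng_ml),
    cores = cohort$pct_pos_cores,
    gg = as.numeric(isup_grade_group(cohort$gleason_primary,
                                     cohort$gleason_secondary)),
    t_rank = as.numeric(t_stage_rank(cohort$t_stage)),
    nodal = as.numeric(cohort$n_stage_positive),
    scan_pos = scan_pos,
    age = cohort$age_years,
    log_time = log(cohort$survival_months + 1),
    dead = as.numeric(cohort$dead),
    private = as.numeric(cohort$treatment_setting == "private"),
    year = cohort$year_of_diagnosis
  )
}

draw_coefs <- function(fit) {
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  ok <- !is.na(b)
  bd <- b
  Vok <- V[ok, ok, drop = FALSE]
  # clamp tiny asymmetries before the Cholesky
  Vok <- (Vok + t(Vok)) / 2
  R <- tryCatch(chol(Vok), error = function(e) NULL)
  if (!is.null(R)) {
    bd[ok] <- b[ok] + drop(t(R) %*% stats::rnorm(sum(ok)))
  }
  bd[!ok] <- 0
  bd
}

lin_pred <- function(X, beta) drop(X %*% beta)

# Predictive-mean matching with a Bayesian linear-model draw: observed
# predictions use the ML fit, missing-row predictions use drawn
# coefficients; each missing cell takes the observed value of one of the
# k nearest donors.
impute_pmm <- function(y, X, miss, k) {
  obs <- !miss
  fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  df <- max(fit$df.residual, 1)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / stats::rchisq(1, df)
  XtX <- crossprod(X[obs, , drop = FALSE])
  XtXi <- tryCatch(solve(XtX + diag(1e-8, ncol(XtX))),
                   error = function(e) NULL)
  beta_d <- beta
  if (!is.null(XtXi)) {
    R <- tryCatch(chol((XtXi + t(XtXi)) / 2), error = function(e) NULL)
    if (!is.null(R)) {
      beta_d <- beta + sqrt(sigma2) * drop(t(R) %*% stats::rnorm(ncol(X)))
    }
  }
  yhat_obs <- lin_pred(X[obs, , drop = FALSE], beta)
  yhat_mis <- lin_pred(X[miss, , drop = FALSE], beta_d)
  yobs <- y[obs]
  out <- vapply(yhat_mis, function(yh) {
    d <- abs(yhat_obs - yh)
    donors <- order(d)[seq_len(min(k, length(d)))]
    yobs[donors[sample.int(length(donors), 1)]]
  }, numeric(1))
  out
}

impute_logreg <- function(y, X, miss) {
  obs <- !miss
  fit <- suppressWarnings(
    stats::glm.fit(X[obs, , drop = FALSE], y[obs],
                   family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  # asymptotic draw from the fitted model's sampling distribution
  w <- fit$weights
  XtWX <- crossprod(X[obs, , drop = FALSE] * sqrt(w))
  Vi <- tryCatch(solve(XtWX + diag(1e-8, ncol(XtWX))),
                 error = function(e) NULL)
  beta_d <- beta
  if (!is.null(Vi)) {
    R <- tryCatch(chol((Vi + t(Vi)) / 2), error = function(e) NULL)
    if (!is.null(R)) beta_d <- beta + drop(t(R) %*% stats::rnorm(ncol(X)))
  }
  p <- stats::plogis(lin_pred(X[miss, , drop = FALSE], beta_d))
  as.numeric(stats::runif(sum(miss)) < p)
}

#' Multiple imputation by chained equations
#'
#' Imputes the cohort's missing predictors and missing staging-scan
#' outcomes, producing `m` complete datasets. Variables are visited in
#' increasing order of missingness (ties broken alphabetically); each
#' dataset runs on its own random substream derived from `seed`, so the
#' set is reproducible and datasets are exchangeable.
#'
#' @param cohort cohort table (indeterminate scans already resolved).
#' @param m number of imputed datasets.
#' @param iterations chained-equation sweeps per dataset.
#' @param seed master seed.
#' @param spec per-variable method specification, see
#'   [default_imputation_spec()].
#' @return an object of class `imputed_cohort_set`: list with `datasets`
#'   (each the cohort plus a complete logical `scan_positive` column),
#'   `m`, `iterations`, `seed`, `spec`, and `warnings`.
#' @export
mice_impute <- function(cohort, m = 5, iterations = 10, seed = 1,
                        spec = default_imputation_spec()) {
  if (m < 1 || iterations < 1) {
    stop_stage("impute", "m and iterations must be >= 1")
  }
  W <- build_working_frame(cohort)
  vars <- imput_vars()
  miss <- vapply(W[vars], function(x) is.na(x), logical(nrow(W)))
  frac <- colMeans(miss)
  if (any(frac == 1)) {
    stop_stage("impute", "variable(s) 100% missing: ",
               paste(vars[frac == 1], collapse = ", "))
  }
  to_impute <- vars[frac > 0]
  warnings_log <- character(0)

  complete_one <- function(sub_seed) {
    with_seed(sub_seed, {
      Z <- W
      # initial fill: random draws from the observed margin
      for (v in to_impute) {
        mi <- miss[, v]
        Z[[v]][mi] <- sample(Z[[v]][!mi], sum(mi), replace = TRUE)
      }
      visit <- to_impute[order(frac[to_impute], to_impute)]
      for (it in seq_len(iterations)) {
        for (v in visit) {
          mi <- miss[, v]
          preds <- setdiff(names(Z), v)
          X <- cbind(`(Intercept)` = 1,
                     as.matrix(Z[preds]))
          y <- W[[v]]
          y[mi] <- Z[[v]][mi]
          res <- tryCatch({
            if (spec[[v]] == "logreg") {
              impute_logreg(W[[v]], X, mi)
            } else {
              impute_pmm(W[[v]], X, mi, k = spec$k_donors %||% 5)
            }
          }, error = function(e) NULL)
          if (is.null(res)) {
            warnings_log <<- c(warnings_log, sprintf(
              "conditional fit failed for '%s'; fell back to marginal draw",
              v))
            res <- sample(W[[v]][!mi], sum(mi), replace = TRUE)
          }
          Z[[v]][mi] <- res
        }
      }
      Z
    })
  }

  datasets <- vector("list", m)
  for (i in seq_len(m)) {
    Z <- if (length(to_impute)) {
      complete_one(derive_seed(seed, paste0("impute-", i)))
    } else {
      W
    }
    d <- cohort
    attr(d, "truth") <- NULL
    attr(d, "followup_labels") <- NULL
    attr(d, "config") <- NULL
    mi_psa <- miss[, "log_psa"]
    d$psa_ng_ml[mi_psa] <- exp(Z$log_psa[mi_psa])
    mi_c <- miss[, "cores"]
    d$pct_pos_cores[mi_c] <- pmin(pmax(Z$cores[mi_c], 0), 100)
    mi_g <- miss[, "gg"]
    if (any(mi_g)) {
      pats <- gg_to_patterns(as.integer(round(Z$gg[mi_g])))
      d$gleason_primary[mi_g] <- pats$primary
      d$gleason_secondary[mi_g] <- pats$secondary
    }
    mi_t <- miss[, "t_rank"]
    d$t_stage[mi_t] <- T_STAGE_LEVELS[as.integer(round(Z$t_rank[mi_t]))]
    mi_n <- miss[, "nodal"]
    d$n_stage_positive[mi_n] <- Z$nodal[mi_n] > 0.5
    d$scan_positive <- Z$scan_pos > 0.5
    datasets[[i]] <- d
  }

  structure(list(datasets = datasets, m = m, iterations = iterations,
                 seed = seed, spec = spec,
                 imputed_cells = miss,
                 warnings = unique(warnings_log)),
            class = "imputed_cohort_set")
}

#' @export
print.imputed_cohort_set <- function(x, ...) {
  cat("Imputed cohort set:", x$m, "datasets,", x$iterations,
      "iterations, seed", x$seed, "\n")
  fr <- colMeans(x$imputed_cells)
  cat("Imputed fraction per variable:\n")
  print(round(fr[fr > 0], 3))
  if (length(x$warnings)) cat(length(x$warnings), "warning(s) logged\n")
  invisible(x)
}

#' Pool a statistic across imputed datasets by Rubin's rules
#'
#' Pooled estimate is the mean; total variance combines the mean
#' within-imputation variance and the between-imputation sample variance
#' inflated by (1 + 1/m). Degrees of freedom follow the Barnard-Rubin
#' small-sample formula when a complete-data df is supplied, and the
#' classic large-sample formula otherwise.
#'
#' @param estimates per-dataset estimates.
#' @param variances per-dataset squared standard errors.
#' @param dfcom complete-data degrees of freedom (default `Inf`).
#' @param conf confidence level for the pooled interval.
#' @return object of class `pooled_estimate`: estimate, within_var,
#'   between_var, total_var, df, ci95.
#' @export
rubin_pool <- function(estimates, variances, dfcom = Inf, conf = 0.95) {
  m <- length(estimates)
  if (m == 0 || length(variances) != m) {
    stop("estimates and variances must be non-empty and equal length",
         call. = FALSE)
  }
  if (any(variances < 0)) stop("variances must be >= 0", call. = FALSE)
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- if (m > 1) stats::var(estimates) else 0
  total <- ubar + (1 + 1 / m) * b
  if (m == 1 || b == 0 || total == 0) {
    df <- if (is.finite(dfcom)) dfcom else Inf
  } else {
    lambda <- (1 + 1 / m) * b / total
    df_old <- (m - 1) / lambda^2
    if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- df_old * df_obs / (df_old + df_obs)
    } else {
      df <- df_old
    }
  }
  half <- if (total > 0) {
    stats::qt(1 - (1 - conf) / 2, df) * sqrt(total)
  } else 0
  structure(list(estimate = qbar, within_var = ubar, between_var = b,
                 total_var = total, df = df, m = m,
                 ci95 = c(qbar - half, qbar + half)),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("pooled estimate %.*f [%.*f, %.*f] (m = %d, total var %.3g)\n",
              digits, x$estimate, digits, x$ci95[1], digits, x$ci95[2],
              x$m, x$total_var))
  invisible(x)
}

#' Kaplan-Meier diagnostic for imputed scan outcomes
#'
#' Compares survival between patients with observed positive scans and
#' patients whose positive scan was imputed (and likewise for negatives).
#' Under a sound imputation model the observed and imputed curves of the
#' same polarity should agree.
#'
#' @param imputed_set an [mice_impute()] result.
#' @param cohort the original (pre-imputation) cohort, used to identify
#'   which outcomes were observed.
#' @return a long `data.frame` with columns dataset, stratum, time, n_risk,
#'   n_event, surv; strata with zero events are listed in the
#'   `no_event_strata` attribute (their median survival is undefined).
#' @export
km_diagnostic <- function(imputed_set, cohort) {
  observed <- cohort$scan_result %in% c("positive", "negative")
  out <- vector("list", imputed_set$m)
  flagged <- character(0)
  for (i in seq_len(imputed_set$m)) {
    d <- imputed_set$datasets[[i]]
    stratum <- paste0(ifelse(observed, "observed-", "imputed-"),
                      ifelse(d$scan_positive, "positive", "negative"))
    fit <- survival::survfit(
      survival::Surv(d$survival_months, d$dead) ~ stratum)
    s <- summary(fit, censored = TRUE)
    lev <- sub("^stratum=", "", as.character(s$strata))
    out[[i]] <- data.frame(dataset = i, stratum = lev, time = s$time,
                           n_risk = s$n.risk, n_event = s$n.event,
                           surv = s$surv)
    ev <- tapply(s$n.event, lev, sum)
    flagged <- union(flagged, names(ev)[ev == 0])
  }
  res <- do.call(rbind, out)
  attr(res, "no_event_strata") <- flagged
  res
}

#' Serialize / load an imputed cohort set as delimited text
#'
#' One CSV per dataset plus a JSON manifest (m, iterations, seed, spec
#' hash).
#'
#' @param imputed_set an `imputed_cohort_set`.
#' @param dir output directory (created if needed).
#' @return `write_imputed_set()` returns `dir` invisibly;
#'   `read_imputed_set()` returns an `imputed_cohort_set`.
#' @export
write_imputed_set <- function(imputed_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(imputed_set$m)) {
    utils::write.csv(imputed_set$datasets[[i]],
                     file.path(dir, sprintf("dataset_%03d.csv", i)),
                     row.names = FALSE, na = "")
  }
  spec_hash <- sum(utf8ToInt(paste(
    names(imputed_set$spec),
    vapply(imputed_set$spec, paste, character(1)), collapse = "|")))
  manifest <- list(m = imputed_set$m, iterations = imputed_set$iterations,
                   seed = imputed_set$seed, spec_hash = spec_hash)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_imputed_set
#' @export
read_imputed_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  files <- sort(list.files(dir, pattern = "^dataset_\\d+\\.csv$",
                           full.names = TRUE))
  datasets <- lapply(files, function(f) {
    d <- utils::read.csv(f, stringsAsFactors = FALSE, na.strings = "")
    d$t_stage <- factor(d$t_stage, levels = T_STAGE_LEVELS, ordered = TRUE)
    d$scan_result <- factor(d$scan_result,
                            levels = c("positive", "negative",
                                       "indeterminate", "none"))
    d$treatment_setting <- factor(d$treatment_setting,
                                  levels = c("public", "private"))
    d
  })
  structure(list(datasets = datasets, m = manifest$m,
                 iterations = manifest$iterations, seed = manifest$seed,
                 spec = NULL, imputed_cells = NULL, warnings = character(0)),
            class = "imputed_cohort_set")
}
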