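# Calibration and discrimination of the staging models against the
# (imputed) bone-scan outcome, pooled across imputed datasets by Rubin's
# rules.

check_calibration_inputs <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  if (anyNA(predicted) || anyNA(observed)) {
    stop("missing values in calibration inputs", call. = FALSE)
  }
  if (length(unique(predicted)) < 2) {
    stop("undefined calibration: constant predictions", call. = FALSE)
  }
  if (length(unique(observed)) < 2) {
    stop("undefined calibration: single-class outcomes", call. = FALSE)
  }
}

#' Calibration slope
#'
#' Coefficient of logit(predicted risk) in a logistic regression of the
#' observed binary outcome. Ideal value 1; below 1 indicates predictions
#' too spread (overfitting-type behaviour), above 1 too compressed.
#' Predictions are clipped into (eps, 1 - eps) before the logit.
#'
#' @param predicted predicted risks in (0, 1).
#' @param observed binary outcomes (0/1 or logical).
#' @param eps clipping bound for the logit transform.
#' @return list with `estimate` and `variance`.
#' @export
calibration_slope <- function(predicted, observed, eps = 1e-6) {
  observed <- as.numeric(observed)
  check_calibration_inputs(predicted, observed)
  lp <- stats::qlogis(clip01(predicted, eps))
  fit <- suppressWarnings(
    stats::glm(observed ~ lp, family = stats::binomial()))
  list(estimate = unname(stats::coef(fit)["lp"]),
       variance = unname(stats::vcov(fit)["lp", "lp"]))
}

#' Calibration-in-the-large (calibration intercept)
#'
#' Intercept of a logistic regression of the outcome with logit(predicted)
#' as an offset (slope fixed at one). Ideal value 0; positive means risk
#' is under-estimated on average, negative over-estimated.
#'
#' @inheritParams calibration_slope
#' @return list with `estimate` and `variance`.
#' @export
calibration_in_the_large <- function(predicted, observed, eps = 1e-6) {
  observed <- as.numeric(observed)
  check_calibration_inputs(predicted, observed)
  lp <- stats::qlogis(clip01(predicted, eps))
  fit <- suppressWarnings(
    stats::glm(observed ~ 1 + offset(lp), family = stats::binomial()))
  list(estimate = unname(stats::coef(fit)[1]),
       variance = unname(stats::vcov(fit)[1, 1]))
}

#' Rank-based AUC with DeLong variance
#'
#' Concordance probability that a positive patient scores higher than a
#' negative one, ties counted one half; the variance is the standard
#' DeLong rank-statistic estimator.
#'
#' @param scores predicted scores (any monotone scale).
#' @param observed binary outcomes.
#' @return list with `estimate` and `variance`.
#' @export
auc_estimate <- function(scores, observed) {
  observed <- as.logical(observed)
  if (length(scores) != length(observed) || anyNA(scores) ||
      anyNA(observed)) {
    stop("scores and outcomes must be complete and equal length",
         call. = FALSE)
  }
  n1 <- sum(observed)
  n0 <- sum(!observed)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both outcome classes required", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[observed]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong placement components
  rx <- rank(scores[observed], ties.method = "average")
  ry <- rank(scores[!observed], ties.method = "average")
  v10 <- (r[observed] - rx) / n0          # P(score_neg < score_pos_i)
  v01 <- 1 - (r[!observed] - ry) / n1     # P(score_neg_j < score_pos)
  s10 <- if (n1 > 1) stats::var(v10) else 0
  s01 <- if (n0 > 1) stats::var(v01) else 0
  list(estimate = auc, variance = s10 / n1 + s01 / n0)
}

# Per-dataset numeric predicted risks for a model, or NULL with a reason
# when calibration is not defined for it (guideline models without numeric
# risks; categorical models with too few distinct risk levels).
model_predicted_risks <- function(registry, model_name, records,
                                  min_levels = 4) {
  m <- registry_model(registry, model_name)
  p <- if (m$kind == "continuous") {
    if (is.null(m$prob)) return(list(risks = NULL,
                                     reason = "no continuous form"))
    predict_continuous(registry, model_name, records)
  } else {
    if (is.null(m$groups)) {
      return(list(risks = NULL, reason = "no numeric predicted risks"))
    }
    g <- m$groups(records)
    ok <- tryCatch(categorical_predicted_risk(registry, model_name, g),
                   error = function(e) NULL)
    if (is.null(ok)) {
      return(list(risks = NULL, reason = "no numeric predicted risks"))
    }
    ok
  }
  if (length(unique(p)) < min_levels) {
    return(list(risks = NULL,
                reason = sprintf("fewer than %d distinct risk levels",
                                 min_levels)))
  }
  list(risks = p, reason = NULL)
}

#' Pooled validation of all registered models
#'
#' Within each imputed dataset computes, per model, the AUC (continuous
#' probability, or ordinal group rank as score) and - where the model has
#' numeric predicted risks with at least `min_levels` distinct values -
#' the calibration slope and calibration-in-the-large; pools each metric
#' across datasets with Rubin's rules. Models without numeric risks, or
#' with three or fewer risk levels, are reported with the metric excluded
#' rather than silently dropped.
#'
#' @param imputed_set an [mice_impute()] result.
#' @param registry a [model_registry()].
#' @param models model names to validate (default: all registered).
#' @param min_levels minimum distinct predicted-risk levels required for
#'   calibration (default 4: models with three or fewer risk groups are
#'   excluded).
#' @return object of class `model_validation`: a `data.frame` with columns
#'   model, metric, estimate, se, ci_low, ci_high, m, excluded, reason,
#'   n_failed.
#' @export
pooled_validation <- function(imputed_set, registry,
                              models = names(registry$models),
                              min_levels = 4) {
  rows <- list()
  for (mn in models) {
    mod <- registry_model(registry, mn)
    aucs <- list()
    slopes <- list()
    inters <- list()
    fails <- 0L
    cal_reason <- NULL
    for (d in imputed_set$datasets) {
      y <- d$scan_positive
      res <- tryCatch({
        sc <- mod$score(d)
        a <- auc_estimate(sc, y)
        pr <- model_predicted_risks(registry, mn, d, min_levels)
        list(a = a, pr = pr)
      }, error = function(e) NULL)
      if (is.null(res)) {
        fails <- fails + 1L
        next
      }
      aucs[[length(aucs) + 1L]] <- res$a
      if (is.null(res$pr$risks)) {
        cal_reason <- res$pr$reason
      } else {
        sl <- tryCatch(calibration_slope(res$pr$risks, y),
                       error = function(e) NULL)
        ci <- tryCatch(calibration_in_the_large(res$pr$risks, y),
                       error = function(e) NULL)
        if (is.null(sl) || is.null(ci)) {
          cal_reason <- "undefined calibration"
        } else {
          slopes[[length(slopes) + 1L]] <- sl
          inters[[length(inters) + 1L]] <- ci
        }
      }
    }
    pool_rows <- function(metric, lst, excluded_reason = NULL) {
      if (length(lst) == 0) {
        return(data.frame(model = mn, metric = metric, estimate = NA_real_,
                          se = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, m = 0L, excluded = TRUE,
                          reason = excluded_reason %||% "no estimates",
                          n_failed = fails))
      }
      p <- rubin_pool(vapply(lst, `[[`, numeric(1), "estimate"),
                      vapply(lst, `[[`, numeric(1), "variance"))
      data.frame(model = mn, metric = metric, estimate = p$estimate,
                 se = sqrt(p$total_var), ci_low = p$ci95[1],
                 ci_high = p$ci95[2], m = p$m, excluded = FALSE,
                 reason = NA_character_, n_failed = fails)
    }
    rows[[length(rows) + 1L]] <- rbind(
      pool_rows("auc", aucs),
      pool_rows("calibration_slope", slopes, cal_reason),
      pool_rows("calibration_in_the_large", inters, cal_reason))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("model_validation", "data.frame")
  out
}

#' @export
print.model_validation <- function(x, digits = 2, ...) {
  cat("Model validation (Rubin-pooled across imputed datasets)\n\n")
  wide <- function(metric) {
    s <- x[x$metric == metric, ]
    ifelse(s$excluded, "-",
           sprintf("%.*f [%.*f, %.*f]", digits, s$estimate,
                   digits, s$ci_low, digits, s$ci_high))
  }
  tab <- data.frame(model = unique(x$model),
                    `cal. intercept` = wide("calibration_in_the_large"),
                    `cal. slope` = wide("calibration_slope"),
                    AUC = wide("auc"), check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write validation results as delimited text
#'
#' @param validation a [pooled_validation()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_validation <- function(validation, path) {
  utils::write.csv(as.data.frame(validation), path, row.names = FALSE,
                   na = "")
  invisible(path)
}
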