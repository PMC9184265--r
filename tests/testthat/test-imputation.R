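# Chained-equations imputation and Rubin's-rules pooling.

test_that("Rubin pooling matches hand computations and its identities", {
  # m = 1: pooling degenerates to the single estimate
  p1 <- rubin_pool(0.5, 0.04)
  expect_equal(p1$estimate, 0.5)
  expect_equal(p1$total_var, 0.04)
  expect_equal(p1$between_var, 0)

  # estimates {1, 3} with zero within-variance: between = sample var = 2,
  # total = 0 + (1 + 1/2) * 2 = 3
  p2 <- rubin_pool(c(1, 3), c(0, 0))
  expect_equal(p2$estimate, 2)
  expect_equal(p2$between_var, 2)
  expect_equal(p2$total_var, 3)

  # all estimates equal: between vanishes, total = within
  p3 <- rubin_pool(rep(0.3, 5), rep(0.01, 5))
  expect_equal(p3$between_var, 0)
  expect_equal(p3$total_var, 0.01)

  # identity and order invariance over random cases
  set.seed(1)
  for (i in 1:20) {
    m <- sample(2:10, 1)
    est <- rnorm(m)
    v <- runif(m)
    p <- rubin_pool(est, v)
    expect_equal(p$total_var,
                 p$within_var + (1 + 1 / m) * p$between_var)
    o <- sample.int(m)
    expect_equal(rubin_pool(est[o], v[o])$estimate, p$estimate)
    expect_equal(rubin_pool(est[o], v[o])$total_var, p$total_var)
    expect_true(p$ci95[1] <= p$estimate && p$estimate <= p$ci95[2])
  }
  expect_error(rubin_pool(numeric(0), numeric(0)), "non-empty")
  expect_error(rubin_pool(c(1, 2), c(0.1, -0.1)), ">= 0")

  # Barnard-Rubin df never exceeds the complete-data df
  p4 <- rubin_pool(c(0.2, 0.5, 0.4), c(0.01, 0.012, 0.011), dfcom = 50)
  expect_lt(p4$df, 50)
})

test_that("a complete cohort passes through imputation unchanged", {
  co <- small_cohort(300, seed = 3)
  co <- flag_staging_scans(co)
  co <- reclassify_indeterminate(co)
  # make everything observed: fill from truth, scan everyone
  tt <- attr(co, "truth")
  co$psa_ng_ml <- tt$psa_ng_ml
  co$gleason_primary <- tt$gleason_primary
  co$gleason_secondary <- tt$gleason_secondary
  co$t_stage <- tt$t_stage
  co$pct_pos_cores <- tt$pct_pos_cores
  co$n_stage_positive <- tt$n_stage_positive
  co$scan_result <- factor(ifelse(tt$true_scan_positive, "positive",
                                  "negative"),
                           levels = levels(co$scan_result))
  co$scan_offset_days <- 1L
  imp <- mice_impute(co, m = 3, iterations = 2, seed = 9)
  for (d in imp$datasets) {
    expect_equal(d$psa_ng_ml, co$psa_ng_ml)
    expect_identical(d$scan_positive, tt$true_scan_positive)
  }
})

test_that("imputation is deterministic and never alters observed cells", {
  co <- small_cohort(500, seed = 11)
  co <- reclassify_indeterminate(flag_staging_scans(co))
  imp1 <- mice_impute(co, m = 3, iterations = 3, seed = 21)
  imp2 <- mice_impute(co, m = 3, iterations = 3, seed = 21)
  expect_identical(imp1$datasets, imp2$datasets)
  imp3 <- mice_impute(co, m = 3, iterations = 3, seed = 22)
  expect_false(identical(imp1$datasets, imp3$datasets))

  obs_psa <- !is.na(co$psa_ng_ml)
  obs_scan <- co$scan_result %in% c("positive", "negative")
  for (d in imp1$datasets) {
    # observed cells identical across datasets and to the input
    expect_identical(d$psa_ng_ml[obs_psa], co$psa_ng_ml[obs_psa])
    expect_identical(d$scan_positive[obs_scan],
                     co$scan_result[obs_scan] == "positive")
    # completeness of modelled variables
    expect_false(anyNA(d$psa_ng_ml))
    expect_false(anyNA(d$t_stage))
    expect_false(anyNA(d$gleason_primary))
    expect_false(anyNA(d$pct_pos_cores))
    expect_false(anyNA(d$n_stage_positive))
    expect_false(anyNA(d$scan_positive))
    # imputed categories stay in their domains
    expect_true(all(d$pct_pos_cores >= 0 & d$pct_pos_cores <= 100))
    expect_true(all(as.character(d$t_stage) %in% T_STAGE_LEVELS))
  }
})

test_that("imputation requires resolved indeterminates and some signal", {
  co <- small_cohort(200, seed = 4)
  if (!any(co$scan_result == "indeterminate")) {
    co$scan_result[1] <- "indeterminate"
    co$scan_offset_days[1] <- 5L
  }
  expect_error(mice_impute(co), "indeterminate")

  co2 <- reclassify_indeterminate(flag_staging_scans(co))
  co2$psa_ng_ml[] <- NA_real_
  expect_error(mice_impute(co2), "100% missing")
  expect_error(mice_impute(reclassify_indeterminate(co), m = 0), ">= 1")
})

test_that("MAR-masked positivity is recovered within Monte-Carlo error", {
  co <- generate_cohort(generator_config(n_patients = 3000, seed = 17))
  co <- reclassify_indeterminate(flag_staging_scans(co))
  tt <- attr(co, "truth")
  imp <- mice_impute(co, m = 5, iterations = 5, seed = 33)
  masked <- co$scan_result == "none"
  est <- vapply(imp$datasets, function(d) mean(d$scan_positive[masked]),
                numeric(1))
  v <- est * (1 - est) / sum(masked)
  pooled <- rubin_pool(est, v)
  truth_rate <- mean(tt$true_scan_positive[masked])
  se <- sqrt(pooled$total_var)
  expect_lt(abs(pooled$estimate - truth_rate), 4 * se)
})

test_that("KM diagnostic separates scan-positive strata as configured", {
  cfg <- generator_config(n_patients = 4000, seed = 29,
                          survival = list(hr_positive = 4))
  co <- reclassify_indeterminate(flag_staging_scans(generate_cohort(cfg)))
  imp <- mice_impute(co, m = 2, iterations = 3, seed = 8)
  km <- km_diagnostic(imp, co)
  expect_true(all(c("dataset", "stratum", "time", "surv") %in% names(km)))
  s60 <- function(str, ds) {
    k <- km[km$stratum == str & km$dataset == ds & km$time <= 60, ]
    if (!nrow(k)) return(NA_real_)
    min(k$surv)
  }
  for (ds in 1:2) {
    # configured hazard ratio shows up in both observed and imputed strata
    expect_lt(s60("observed-positive", ds), s60("observed-negative", ds))
    expect_lt(s60("imputed-positive", ds), s60("imputed-negative", ds))
  }
})

test_that("an all-censored stratum yields a flat curve at one", {
  co <- make_records(60, psa = 5, surv = 24, dead = FALSE)
  co$scan_result[1:30] <- "positive"
  co$scan_offset_days[1:30] <- 1L
  co$scan_result[31:60] <- "negative"
  co$scan_offset_days[31:60] <- 1L
  co$dead <- c(rep(FALSE, 30), rep(TRUE, 30))
  imp <- mice_impute(co, m = 1, iterations = 1, seed = 1)
  km <- km_diagnostic(imp, co)
  pos <- km[km$stratum == "observed-positive", ]
  expect_true(all(pos$surv == 1))
  expect_true("observed-positive" %in% attr(km, "no_event_strata"))
})

test_that("imputed sets round-trip through the directory serialization", {
  co <- small_cohort(200, seed = 5)
  co <- reclassify_indeterminate(flag_staging_scans(co))
  imp <- mice_impute(co, m = 2, iterations = 2, seed = 13)
  dir <- tempfile("impset_")
  write_imputed_set(imp, dir)
  back <- read_imputed_set(dir)
  expect_equal(back$m, 2)
  expect_equal(back$datasets[[1]]$psa_ng_ml, imp$datasets[[1]]$psa_ng_ml,
               tolerance = 1e-12)
  expect_identical(back$datasets[[2]]$scan_positive,
                   imp$datasets[[2]]$scan_positive)
})
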