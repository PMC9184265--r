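# Staging-model rules: printed thresholds, score arithmetic, nesting and
# monotonicity properties.

test_that("Wang score D reproduces the printed formula", {
  # all indicator terms zero, log term vanishing: D -> -6.40 + 2.169
  expect_equal(wang_score(1e-9, "T1c", 3, 3), -4.231, tolerance = 1e-6)
  # PSA 20, T4, Gleason 4+3: hand computation on the printed coefficients
  expect_equal(wang_score(20, "T4", 4, 3),
               -6.40 + 2.39 + 0.87 * log(21) + 0.93 + 2.169,
               tolerance = 1e-12)
  expect_equal(wang_score(20, "T4", 4, 3), 1.7377, tolerance = 1e-4)
  # strictly increasing in PSA
  expect_lt(wang_score(9.99, "T1c", 3, 3), wang_score(10.01, "T1c", 3, 3))
  expect_error(wang_score(NA, "T1c", 3, 3), "complete")
  expect_error(wang_score(-1, "T1c", 3, 3), "positive")
})

test_that("Wang risk is the inverse logit of D and monotone in PSA", {
  expect_equal(wang_risk(20, "T4", 4, 3),
               plogis(wang_score(20, "T4", 4, 3)))
  psa <- seq(1, 100, by = 1)
  r <- wang_risk(psa, rep("T2a", 100), rep(3, 100), rep(4, 100))
  expect_true(all(diff(r) > 0))
})

test_that("guideline and literature rules match their printed criteria", {
  cases <- list(
    # fn, record overrides, expected scan decision
    list(classify_eau, list(psa = 25, t_stage = "T1c", gp = 3, gs = 3), TRUE),
    list(classify_eau, list(psa = 5, t_stage = "T1c", gp = 3, gs = 4), FALSE),
    list(classify_eau, list(psa = 5, t_stage = "T1c", gp = 4, gs = 3), TRUE),
    list(classify_eau, list(psa = 5, t_stage = "T2c", gp = 3, gs = 3), TRUE),
    list(classify_eau_high_risk, list(psa = 25), TRUE),
    list(classify_eau_high_risk,
         list(psa = 8, t_stage = "T2a", gp = 4, gs = 3), FALSE),
    list(classify_eau_high_risk, list(gp = 4, gs = 4, psa = 5), TRUE),
    list(classify_eau_high_risk, list(t_stage = "T3a", psa = 5), TRUE),
    list(classify_aua, list(psa = 12, gp = 3, gs = 4, t_stage = "T1c"), TRUE),
    list(classify_aua, list(psa = 12, gp = 3, gs = 3, t_stage = "T1c"), FALSE),
    list(classify_aua, list(psa = 5, gp = 3, gs = 3, t_stage = "T2b"), TRUE),
    list(classify_nccn,
         list(psa = 8, gp = 3, gs = 4, cores = 60, t_stage = "T1c"), TRUE),
    list(classify_nccn,
         list(psa = 8, gp = 3, gs = 4, cores = 40, t_stage = "T1c"), FALSE),
    list(classify_nccn,
         list(psa = 21, gp = 3, gs = 3, cores = 0, t_stage = "T1a"), TRUE),
    list(classify_osullivan, list(t_stage = "T4", psa = 1), TRUE),
    list(classify_osullivan, list(psa = 21), TRUE),
    list(classify_osullivan,
         list(psa = 5, t_stage = "T2a", gp = 3, gs = 4), FALSE),
    list(classify_briganti, list(gp = 4, gs = 4, t_stage = "T1c", psa = 4),
         TRUE),
    list(classify_briganti, list(psa = 12, t_stage = "T2a"), TRUE),
    list(classify_briganti, list(psa = 12, t_stage = "T1c"), FALSE),
    list(classify_ho, list(psa = 5, nodal = TRUE), TRUE),
    list(classify_ho, list(psa = 10.5, nodal = FALSE), TRUE),
    list(classify_ho, list(psa = 5, nodal = FALSE), FALSE)
  )
  for (cs in cases) {
    rec <- do.call(make_records, c(list(n = 1), cs[[2]]))
    expect_identical(cs[[1]](rec), cs[[3]],
                     info = paste(deparse(substitute(cs[[1]])),
                                  paste(names(cs[[2]]),
                                        unlist(cs[[2]]), collapse = " ")))
  }
})

test_that("PSA thresholds are strict as printed", {
  expect_false(classify_simple_psa(make_records(psa = 10.0), 10))
  expect_true(classify_simple_psa(make_records(psa = 10.1), 10))
  expect_false(classify_simple_psa(make_records(psa = 20.0), 20))
})

test_that("ISUP grade groups map Gleason patterns correctly", {
  expect_equal(isup_grade_group(3, 3), 1L)
  expect_equal(isup_grade_group(3, 4), 2L)
  expect_equal(isup_grade_group(4, 3), 3L)
  expect_equal(isup_grade_group(4, 4), 4L)
  expect_equal(isup_grade_group(3, 5), 4L)
  expect_equal(isup_grade_group(4, 5), 5L)
  expect_true(is.na(isup_grade_group(NA, 4)))

  expect_equal(classify_isup(make_records(gp = 4, gs = 3)), 3L)
  expect_equal(classify_isup(make_records(gp = 3, gs = 4)), 2L)
})

test_that("five-tier grouping assigns printed boundary cases", {
  g <- function(...) classify_gnanapragasam(make_records(...))
  expect_equal(g(gp = 4, gs = 3, psa = 5, t_stage = "T1c"), 3L)
  expect_equal(g(gp = 4, gs = 4, psa = 5, t_stage = "T1c"), 4L)
  expect_equal(g(gp = 3, gs = 3, psa = 4, t_stage = "T1c"), 1L)
  expect_equal(g(gp = 3, gs = 4, psa = 15, t_stage = "T1c"), 3L)  # two of
  expect_equal(g(gp = 3, gs = 4, psa = 5, t_stage = "T1c"), 2L)
  expect_equal(g(gp = 4, gs = 5, psa = 5, t_stage = "T1c"), 5L)
  expect_equal(g(gp = 3, gs = 3, psa = 5, t_stage = "T4"), 5L)
  expect_equal(g(gp = 4, gs = 4, psa = 25, t_stage = "T1c"), 5L)  # two of
})

test_that("strategies are total, deterministic and properly nested", {
  recs <- random_records(600, seed = 42)
  eau <- classify_eau(recs)
  eau_hi <- classify_eau_high_risk(recs)
  expect_false(anyNA(eau))
  expect_identical(eau, classify_eau(recs))
  # high-risk-only scans a subset of the full EAU recommendation
  expect_true(all(!eau_hi | eau))
  g <- classify_gnanapragasam(recs)
  expect_true(all(!(g >= 5) | (g >= 4)))
  expect_true(all(!(g >= 4) | (g >= 3)))
  # single-predictor monotonicity: raising PSA never flips scan -> no-scan
  r2 <- recs
  r2$psa_ng_ml <- r2$psa_ng_ml + 10
  expect_true(all(classify_simple_psa(recs, 10) <=
                    classify_simple_psa(r2, 10)))
  expect_true(all(eau <= classify_eau(r2)))
})

test_that("models refuse incomplete records", {
  rec <- make_records()
  rec$psa_ng_ml <- NA_real_
  expect_error(classify_eau(rec), "missing")
  expect_error(classify_nccn(rec), "missing")
})

test_that("continuous forms: built-in Wang, config-supplied lookups, errors", {
  reg <- model_registry()
  rec <- make_records(psa = 20, t_stage = "T4", gp = 4, gs = 3)
  expect_equal(predict_continuous(reg, "wang", rec),
               wang_risk(20, "T4", 4, 3))
  # Ho's equation is not printed in the validation source: explicit error
  expect_error(predict_continuous(reg, "ho", rec), "form unavailable")
  expect_error(predict_continuous(reg, "chybowski", rec),
               "form unavailable")
  expect_error(predict_continuous(reg, "nosuch", rec), "unregistered")

  # user-supplied lookup passes straight through
  reg2 <- model_registry(continuous_forms = list(
    chybowski = function(r) ifelse(r$psa_ng_ml == 10, 0.1, 0.25)))
  expect_equal(predict_continuous(reg2, "chybowski",
                                  make_records(psa = 10)), 0.1)
})

test_that("group-level predicted risks pass through and validate", {
  gr <- default_group_risks()
  gr$lai <- c(`psa<=10` = 0.05, `psa10-20` = 0.15, `psa20-50` = 0.29,
              `psa>50` = 0.6)
  reg <- model_registry(group_risks = gr)
  expect_equal(categorical_predicted_risk(reg, "lai", "psa20-50"), 0.29)
  # no per-group configuration: guideline models have no numeric risk
  expect_error(categorical_predicted_risk(model_registry(), "eau", "high"),
               "no numeric predicted risk")
  expect_error(model_registry(group_risks = list(lai = 1.5)), "0, 1")
})

test_that("Wang strategy follows the printed direction unless inverted", {
  rec_low <- make_records(psa = 1, t_stage = "T1c", gp = 3, gs = 3)
  rec_high <- make_records(psa = 100, t_stage = "T4", gp = 4, gs = 4)
  s_printed <- registry_strategies(model_registry())[["wang-d"]]$fn
  # printed rule: scan when D < 0 (low-risk record has D < 0)
  expect_true(s_printed(rec_low))
  expect_false(s_printed(rec_high))
  s_inv <- registry_strategies(
    model_registry(wang_direction = "inverted"))[["wang-d"]]$fn
  expect_false(s_inv(rec_low))
  expect_true(s_inv(rec_high))
})
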