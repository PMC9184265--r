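# Net-benefit decision curves, preference conversions, optimal map.

test_that("preference ratio, threshold probability and NWT are consistent", {
  expect_equal(ratio_to_pt(1, 99), 0.01)
  expect_equal(ratio_to_pt(1, 1), 0.5)
  expect_equal(ratio_to_pt(7, 93), 0.07)
  expect_error(ratio_to_pt(0, 9), "positive")
  expect_error(ratio_to_pt(1, -1), "positive")

  expect_equal(pt_to_nwt(0.01)$nwt, 100)
  expect_equal(pt_to_nwt(0.01)$nwt_display, 100L)
  expect_equal(pt_to_nwt(ratio_to_pt(1, 39))$nwt_display, 40L)
  n3 <- pt_to_nwt(ratio_to_pt(3, 97))
  expect_equal(n3$nwt, 100 / 3, tolerance = 1e-12)
  expect_equal(n3$nwt_display, 33L)
  expect_error(pt_to_nwt(0), "strictly")
  expect_error(pt_to_nwt(1), "strictly")

  # round trip across the whole default grid
  g <- pt_grid()
  expect_equal(pt_to_nwt(g)$nwt * g, rep(1, length(g)))
})

test_that("net benefit evaluates its closed form and bounds", {
  expect_equal(net_benefit(0, 0, 100, 0.05), 0)
  # perfect strategy attains the prevalence at every threshold
  for (pt in c(0.01, 0.05, 0.099)) {
    expect_equal(net_benefit(87, 0, 1000, pt), 0.087)
  }
  # scan-all at the printed positivity and a 1:39 preference
  expect_equal(net_benefit(87, 913, 1000, 0.025),
               0.087 - 0.913 * 0.025 / 0.975, tolerance = 1e-12)
  expect_error(net_benefit(1, 1, 0, 0.05), "positive")
  expect_error(net_benefit(60, 60, 100, 0.05), "invalid counts")
  expect_error(net_benefit(1, 1, 10, 1), "strictly")
})

test_that("curve values equal a naive per-patient recount", {
  co <- small_cohort(200, seed = 19)
  co <- reclassify_indeterminate(flag_staging_scans(co))
  imp <- mice_impute(co, m = 2, iterations = 2, seed = 3)
  reg <- model_registry()
  grid <- pt_grid(0.01, 0.1, 0.01)

  for (nm in c("eau-2020", "psa-gt-10", "gnana-group5", "scan-all")) {
    cu <- fixed_strategy_curve(nm, imp, grid, reg)
    fn <- registry_strategies(reg)[[nm]]$fn
    for (j in c(1, 5, 10)) {
      ref <- mean(vapply(imp$datasets, function(d)
        naive_nb(fn(d), d$scan_positive, grid[j]), numeric(1)))
      expect_equal(cu$nb[j], ref, tolerance = 1e-12)
    }
  }
  # continuous model curve against the same oracle
  cu <- continuous_model_curve("wang", imp, reg, grid)
  for (j in c(2, 7)) {
    ref <- mean(vapply(imp$datasets, function(d) {
      p <- predict_continuous(reg, "wang", d)
      naive_nb(p >= grid[j], d$scan_positive, grid[j])
    }, numeric(1)))
    expect_equal(cu$nb[j], ref, tolerance = 1e-12)
  }
})

test_that("degenerate strategies give the reference curves", {
  co <- small_cohort(200, seed = 19)
  co <- reclassify_indeterminate(flag_staging_scans(co))
  imp <- mice_impute(co, m = 2, iterations = 2, seed = 3)
  reg <- model_registry()
  none <- fixed_strategy_curve("scan-none", imp, registry = reg)
  expect_true(all(none$nb == 0))
  all_ref <- fixed_strategy_curve("scan-all", imp, registry = reg)
  everybody <- fixed_strategy_curve(function(r) rep(TRUE, nrow(r)), imp)
  expect_equal(everybody$nb, all_ref$nb)
  # strategies unknown to the registry are refused
  expect_error(fixed_strategy_curve("scan-some", imp, registry = reg),
               "unregistered")
})

test_that("net-benefit identities hold across strategies and thresholds", {
  co <- small_cohort(800, seed = 7)
  co <- reclassify_indeterminate(flag_staging_scans(co))
  imp <- mice_impute(co, m = 3, iterations = 3, seed = 41)
  reg <- model_registry()
  d <- dca(imp, reg)
  prev <- d$prevalence
  for (cu in d$curves) {
    expect_true(all(cu$nb <= prev + 1e-12))
    # with any false positives, nb strictly decreases in pt
    if (cu$fp_frac[1] > 0 && all(diff(cu$tp_frac) == 0)) {
      expect_true(all(diff(cu$nb) < 0))
    }
  }
  # scan-all crosses zero where threshold odds equal prevalence odds
  sa <- d$curves[["scan-all"]]
  root <- prev  # pt/(1-pt) = prev/(1-prev) at pt = prev
  expect_true(all(sa$nb[sa$pt < root - 1e-9] > 0))
  expect_true(all(sa$nb[sa$pt > root + 1e-9] < 0))
})

test_that("optimal map merges winners and prefers fewer scans on ties", {
  grid <- pt_grid(0.01, 0.1, 0.01)
  mk <- function(name, tp, fp, n) {
    data.frame(strategy = name, pt = grid,
               nb = tp / n - (fp / n) * grid / (1 - grid),
               scanned_frac = (tp + fp) / n,
               tp_frac = tp / n, fp_frac = fp / n)
  }
  # single curve: one segment spanning the grid
  m1 <- optimal_strategy_map(list(mk("only", 80, 920, 1000)))
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$pt_lo, grid[1])
  expect_equal(m1$pt_hi, grid[length(grid)])

  # two curves crossing once: nb_A - nb_B = -0.01 + 0.55 * odds, zero at
  # odds = 1/55, i.e. pt ~ 0.0179 -> B wins below, A above
  a <- mk("selective", 50, 150, 1000)
  b <- mk("broad", 60, 700, 1000)
  m2 <- optimal_strategy_map(list(a, b))
  expect_equal(nrow(m2), 2L)
  expect_equal(m2$strategy, c("broad", "selective"))
  expect_equal(m2$pt_hi[1], 0.01)   # only the first grid point
  expect_equal(m2$pt_lo[2], 0.02)

  # exact tie: the strategy scanning fewer patients wins
  t1 <- mk("lean", 50, 100, 1000)
  t2 <- t1
  t2$strategy <- "bulky"
  t2$scanned_frac <- 0.9
  m3 <- optimal_strategy_map(list(t2, t1))
  expect_equal(unique(m3$strategy), "lean")

  expect_error(optimal_strategy_map(list()), "no curves")
  short <- mk("short", 10, 10, 100)[1:3, ]
  expect_error(optimal_strategy_map(list(a, short)), "share one grid")
})

test_that("calibrated continuous curve dominates its own fixed thresholds", {
  # empirically calibrated risk groups: within each group the positive
  # fraction equals the predicted risk exactly, so thresholding at pt is
  # optimal not just in expectation but on the realized counts
  groups <- list(c(p = 0.02, n = 100), c(p = 0.05, n = 80),
                 c(p = 0.10, n = 60), c(p = 0.25, n = 40))
  p <- unlist(lapply(groups, function(g) rep(g["p"], g["n"])))
  y <- unlist(lapply(groups, function(g) {
    k <- g["p"] * g["n"]
    c(rep(TRUE, k), rep(FALSE, g["n"] - k))
  }))
  n <- length(p)
  recs <- make_records(n)
  recs$true_risk <- unname(p)
  recs$scan_positive <- unname(y)
  reg <- model_registry(continuous_forms = list(
    chybowski = function(r) r$true_risk))
  imp <- fake_imputed_set(recs)
  grid <- pt_grid(0.01, 0.1, 0.005)
  cont <- continuous_model_curve("chybowski", imp, reg, grid)
  # exhaustive comparison against every threshold-derived fixed strategy
  for (thr in unique(round(p, 2))) {
    fixed <- fixed_strategy_curve(function(r) r$true_risk >= thr, imp, grid)
    expect_true(all(cont$nb >= fixed$nb - 1e-12))
  }
  # predictions all below the grid floor degenerate to scan-none
  reg2 <- model_registry(continuous_forms = list(
    chybowski = function(r) rep(1e-4, nrow(r))))
  cont2 <- continuous_model_curve("chybowski", imp, reg2, grid)
  expect_true(all(cont2$nb == 0))
})

test_that("recommended-vs-best flags mis-calibrated continuous models", {
  co <- small_cohort(800, seed = 7)
  co <- reclassify_indeterminate(flag_staging_scans(co))
  imp <- mice_impute(co, m = 2, iterations = 3, seed = 51)
  reg <- model_registry()
  tab <- recommended_vs_best_table(imp, reg, models = "wang",
                                   grid = pt_grid(0.01, 0.1, 0.01))
  expect_true(all(c("model", "strategy", "pt", "nb_recommended",
                    "nb_best", "gap", "discrepancy") %in% names(tab)))
  # the within-model best can never fall below the recommended strategy
  expect_true(all(tab$gap >= -1e-9))
})
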