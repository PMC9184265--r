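# Net-benefit decision-curve analysis over a preference-ratio /
# number-willing-to-test axis. A strategy's net benefit at threshold
# probability p_t is
#
#     nb = TP/n - (FP/n) * p_t / (1 - p_t),
#
# where TP and FP count scanned patients with and without a positive bone
# scan. Fixed strategies are straight evaluations of one predicate at
# every p_t; a continuous model scans at risk >= p_t. Counts are averaged
# across imputed datasets (they are linear, so mean-of-nb equals
# nb-of-mean-counts).

#' Preference-ratio / threshold-probability / NWT conversions
#'
#' A preference ratio a:b corresponds to threshold probability
#' p_t = a/(a+b); the number-willing-to-test is 1/p_t, displayed as its
#' integer floor (the convention that reproduces the printed boundaries
#' 100, 40, 33, 14, 13, 10).
#'
#' @param a,b positive reals of the preference ratio a:b.
#' @param pt threshold probability in (0, 1).
#' @return `ratio_to_pt()` returns p_t; `pt_to_nwt()` returns a list with
#'   `nwt` (real) and `nwt_display` (integer floor).
#' @export
ratio_to_pt <- function(a, b) {
  if (any(!is.finite(a) | !is.finite(b) | a <= 0 | b <= 0)) {
    stop("preference ratio components must be positive", call. = FALSE)
  }
  a / (a + b)
}

#' @rdname ratio_to_pt
#' @export
pt_to_nwt <- function(pt) {
  if (any(!is.finite(pt) | pt <= 0 | pt >= 1)) {
    stop("pt must lie strictly in (0, 1)", call. = FALSE)
  }
  nwt <- 1 / pt
  # tolerance guards the floor against binary representation of e.g. 0.01
  list(nwt = nwt, nwt_display = as.integer(floor(nwt + 1e-9)))
}

#' Default threshold-probability grid
#'
#' p_t from 0.01 to 0.10 in steps of 0.001: preference ratios 1:99 (NWT
#' 100) through 1:9 (NWT 10), the assessed range.
#'
#' @param from,to,by grid bounds and step.
#' @return numeric vector of thresholds.
#' @export
pt_grid <- function(from = 0.01, to = 0.10, by = 0.001) {
  g <- seq(from, to, by = by)
  if (any(g <= 0 | g >= 1)) stop("grid must lie in (0, 1)", call. = FALSE)
  g
}

#' Net benefit of counted scan decisions
#'
#' @param true_pos,false_pos counts of scanned patients with / without a
#'   positive bone scan.
#' @param n cohort size.
#' @param pt threshold probability (vectorized).
#' @return net benefit (vectorized over `pt`).
#' @export
net_benefit <- function(true_pos, false_pos, n, pt) {
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (any(true_pos < 0 | false_pos < 0 | true_pos + false_pos > n)) {
    stop("invalid counts", call. = FALSE)
  }
  if (any(pt <= 0 | pt >= 1)) {
    stop("pt must lie strictly in (0, 1)", call. = FALSE)
  }
  true_pos / n - (false_pos / n) * pt / (1 - pt)
}

nb_curve_frame <- function(name, grid, tp_frac, fp_frac, scanned_frac) {
  nwt <- pt_to_nwt(grid)
  data.frame(strategy = name, pt = grid,
             nwt = nwt$nwt, nwt_display = nwt$nwt_display,
             nb = tp_frac - fp_frac * grid / (1 - grid),
             scanned_frac = scanned_frac,
             tp_frac = tp_frac, fp_frac = fp_frac)
}

# Mean tp/fp/scanned fractions of a fixed predicate across imputed datasets.
strategy_fractions <- function(fn, imputed_set) {
  tp <- fp <- sc <- 0
  for (d in imputed_set$datasets) {
    scan <- fn(d)
    if (anyNA(scan)) stop("strategy returned NA", call. = FALSE)
    n <- nrow(d)
    tp <- tp + sum(scan & d$scan_positive) / n
    fp <- fp + sum(scan & !d$scan_positive) / n
    sc <- sc + mean(scan)
  }
  m <- imputed_set$m
  list(tp = tp / m, fp = fp / m, scanned = sc / m)
}

#' Decision curve of a fixed staging strategy
#'
#' Classifies every patient in every imputed dataset with the strategy
#' predicate, averages the true-/false-positive fractions across datasets,
#' and evaluates the net benefit at each grid threshold (a straight line
#' in the count fractions, re-weighted at each p_t).
#'
#' @param strategy a predicate `function(records) -> logical`, or the name
#'   of a registered strategy (then `registry` is required).
#' @param imputed_set an [mice_impute()] result.
#' @param grid threshold grid, see [pt_grid()].
#' @param registry optional [model_registry()] for name lookup.
#' @param name curve label.
#' @return a `data.frame` (class `nb_curve`) with columns strategy, pt,
#'   nwt, nwt_display, nb, scanned_frac, tp_frac, fp_frac.
#' @export
fixed_strategy_curve <- function(strategy, imputed_set, grid = pt_grid(),
                                 registry = NULL, name = NULL) {
  if (is.character(strategy)) {
    if (is.null(registry)) {
      stop("a registry is required to look strategies up by name",
           call. = FALSE)
    }
    all_s <- registry_strategies(registry)
    if (is.null(all_s[[strategy]])) {
      stop_stage("config", "unregistered strategy: ", strategy)
    }
    name <- name %||% strategy
    strategy <- all_s[[strategy]]$fn
  }
  name <- name %||% "strategy"
  fr <- strategy_fractions(strategy, imputed_set)
  out <- nb_curve_frame(name, grid, fr$tp, fr$fp, fr$scanned)
  class(out) <- c("nb_curve", "data.frame")
  out
}

#' Decision curve of a continuous model
#'
#' At each grid threshold p_t the model scans patients with predicted risk
#' >= p_t; counts are averaged across imputed datasets.
#'
#' @param model_name registered model with a continuous probability form.
#' @param imputed_set an [mice_impute()] result.
#' @param registry a [model_registry()].
#' @param grid threshold grid.
#' @param name curve label (default the model name).
#' @return an `nb_curve` data frame.
#' @export
continuous_model_curve <- function(model_name, imputed_set, registry,
                                   grid = pt_grid(), name = NULL) {
  name <- name %||% model_name
  tp <- fp <- sc <- numeric(length(grid))
  for (d in imputed_set$datasets) {
    p <- predict_continuous(registry, model_name, d)
    n <- nrow(d)
    for (j in seq_along(grid)) {
      scan <- p >= grid[j]
      tp[j] <- tp[j] + sum(scan & d$scan_positive) / n
      fp[j] <- fp[j] + sum(scan & !d$scan_positive) / n
      sc[j] <- sc[j] + mean(scan)
    }
  }
  m <- imputed_set$m
  out <- nb_curve_frame(name, grid, tp / m, fp / m, sc / m)
  class(out) <- c("nb_curve", "data.frame")
  out
}

#' Optimal-strategy map
#'
#' For each grid threshold, the strategy with maximal net benefit; ties
#' are broken toward the strategy scanning fewer patients (at equal net
#' benefit the scanning burden is the only differentiator). Consecutive
#' identical winners are merged into segments.
#'
#' @param curves list of `nb_curve` data frames sharing one grid.
#' @param tol numeric tolerance for ties.
#' @return a `data.frame` with columns pt_lo, pt_hi, nwt_hi, nwt_lo,
#'   strategy (segments partition the grid in increasing pt).
#' @export
optimal_strategy_map <- function(curves, tol = 1e-12) {
  if (length(curves) == 0) stop("no curves supplied", call. = FALSE)
  grid <- curves[[1]]$pt
  for (cu in curves) {
    if (!isTRUE(all.equal(cu$pt, grid))) {
      stop("curves must share one grid", call. = FALSE)
    }
  }
  nb <- vapply(curves, function(cu) cu$nb, numeric(length(grid)))
  scf <- vapply(curves, function(cu) cu$scanned_frac[1], numeric(1))
  nms <- vapply(curves, function(cu) cu$strategy[1], character(1))
  win <- vapply(seq_along(grid), function(i) {
    v <- nb[i, ]
    best <- v >= max(v) - tol
    cand <- which(best)
    cand[which.min(scf[cand])]
  }, integer(1))
  runs <- rle(win)
  hi <- cumsum(runs$lengths)
  lo <- c(1, utils::head(hi, -1) + 1)
  data.frame(pt_lo = grid[lo], pt_hi = grid[hi],
             nwt_hi = pt_to_nwt(grid[lo])$nwt_display,
             nwt_lo = pt_to_nwt(grid[hi])$nwt_display,
             strategy = nms[runs$values])
}

#' Recommended versus best strategy within each continuous model
#'
#' For each continuous model, compares the net benefit of its
#' source-recommended fixed strategies against the best achievable net
#' benefit from any threshold of that model at each grid point (the
#' model's own decision curve maximized over thresholds). A positive gap
#' flags a discrepancy - typically a symptom of mis-calibration.
#'
#' @param imputed_set an [mice_impute()] result.
#' @param registry a [model_registry()].
#' @param models continuous model names (default: all with a probability
#'   form).
#' @param grid threshold grid.
#' @param tol gap above which a discrepancy is flagged.
#' @return `data.frame` with columns model, strategy, pt, nb_recommended,
#'   nb_best, gap, discrepancy.
#' @export
recommended_vs_best_table <- function(imputed_set, registry,
                                      models = NULL, grid = pt_grid(),
                                      tol = 1e-9) {
  if (is.null(models)) {
    models <- names(registry$models)[vapply(registry$models, function(m)
      !is.null(m$prob), logical(1))]
  }
  rows <- list()
  for (mn in models) {
    mod <- registry_model(registry, mn)
    # candidate thresholds: pooled quantiles of the model's predictions,
    # plus a scan-all (0) and scan-none (above max) threshold
    allp <- unlist(lapply(imputed_set$datasets, function(d)
      predict_continuous(registry, mn, d)))
    cand <- sort(unique(c(0, unname(stats::quantile(allp, seq(0, 1, 0.02)))),
                 decreasing = FALSE))
    cand <- c(cand, max(allp) * (1 + 1e-9) + 1e-12)
    nbmat <- matrix(0, length(grid), length(cand))
    for (d in imputed_set$datasets) {
      p <- predict_continuous(registry, mn, d)
      n <- nrow(d)
      for (k in seq_along(cand)) {
        scan <- p >= cand[k]
        tp <- sum(scan & d$scan_positive) / n
        fp <- sum(scan & !d$scan_positive) / n
        nbmat[, k] <- nbmat[, k] + tp - fp * grid / (1 - grid)
      }
    }
    nbmat <- nbmat / imputed_set$m
    best <- apply(nbmat, 1, max)
    for (s in mod$recommended) {
      rec <- fixed_strategy_curve(s, imputed_set, grid, registry)
      rows[[length(rows) + 1L]] <- data.frame(
        model = mn, strategy = s, pt = grid,
        nb_recommended = rec$nb, nb_best = best,
        gap = best - rec$nb, discrepancy = best - rec$nb > tol)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Decision-curve analysis of staging strategies
#'
#' The package's central comparison: evaluates every requested strategy
#' (plus the scan-all and scan-none references and, optionally, the
#' decision curves of continuous models) on the imputed cohort set over
#' the preference grid, and derives the optimal-strategy map.
#'
#' @param imputed_set an [mice_impute()] result.
#' @param registry a [model_registry()].
#' @param strategies names of fixed strategies to evaluate (default: all
#'   registered, plus the references).
#' @param continuous names of continuous models whose full decision curves
#'   are added (default: those with a registered probability form).
#' @param grid threshold grid, see [pt_grid()].
#' @return object of class `dca`: list with `curves` (one long
#'   `data.frame`), `map` (optimal-strategy segments), `prevalence`
#'   (pooled positivity), and `grid`.
#' @export
dca <- function(imputed_set, registry,
                strategies = names(registry_strategies(registry)),
                continuous = NULL, grid = pt_grid()) {
  all_s <- registry_strategies(registry)
  unknown <- setdiff(strategies, names(all_s))
  if (length(unknown)) {
    stop_stage("config", "unregistered strategy: ",
               paste(unknown, collapse = ", "))
  }
  if (is.null(continuous)) {
    continuous <- names(registry$models)[vapply(registry$models, function(m)
      !is.null(m$prob), logical(1))]
  }
  curves <- list()
  for (s in strategies) {
    curves[[s]] <- fixed_strategy_curve(s, imputed_set, grid, registry)
  }
  for (mn in continuous) {
    nm <- paste0(mn, "-curve")
    curves[[nm]] <- continuous_model_curve(mn, imputed_set, registry, grid,
                                           name = nm)
  }
  prev <- mean(vapply(imputed_set$datasets, function(d)
    mean(d$scan_positive), numeric(1)))
  structure(list(curves = curves,
                 table = do.call(rbind, c(curves,
                                          list(make.row.names = FALSE))),
                 map = optimal_strategy_map(curves),
                 prevalence = prev, grid = grid),
            class = "dca")
}

#' @export
print.dca <- function(x, ...) {
  cat("Decision-curve analysis:", length(x$curves), "strategies,",
      length(x$grid), "thresholds, pooled positivity",
      sprintf("%.3f", x$prevalence), "\n\nOptimal strategy by preference:\n")
  m <- x$map
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  p_t %.3f-%.3f (NWT %d-%d): %s\n", m$pt_lo[i], m$pt_hi[i],
                m$nwt_hi[i], m$nwt_lo[i], m$strategy[i]))
  }
  invisible(x)
}

#' @export
summary.dca <- function(object, ...) object$map

#' @export
plot.dca <- function(x, strategies = names(x$curves), ylim = NULL, ...) {
  nb <- vapply(x$curves[strategies], function(cu) cu$nb,
               numeric(length(x$grid)))
  if (is.null(ylim)) ylim <- c(min(0, nb), max(nb))
  graphics::matplot(x$grid, nb, type = "l", lty = 1,
                    col = seq_len(ncol(nb)),
                    xlab = expression(p[t]), ylab = "net benefit",
                    ylim = ylim, ...)
  graphics::abline(h = 0, col = "grey70")
  graphics::legend("topright", legend = strategies, lty = 1,
                   col = seq_len(ncol(nb)), cex = 0.7, bty = "n")
  invisible(x)
}

#' Write decision-curve outputs as delimited text
#'
#' @param x a [dca()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dca <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$table, file.path(dir, "curves.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(x$map, file.path(dir, "optimal_map.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}
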