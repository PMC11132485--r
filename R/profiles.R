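# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Chi-squared threshold for profile-likelihood confidence intervals
#'
#' The offset `Delta_alpha` above the minimum objective that delimits a
#' pointwise confidence interval: the `level`-quantile of the chi-squared
#' distribution with 1 degree of freedom.
#'
#' @param level Confidence level in (0, 1), e.g. 0.95.
#' @return Scalar threshold (3.841 for 0.95, 0.989 for 0.68).
#' @export
chi2_threshold <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1)
    stop("'level' must be a probability strictly between 0 and 1",
         call. = FALSE)
  stats::qchisq(level, df = 1L)
}

# re-optimize the co-parameters with `target` pinned at `value`;
# multistart: supplied warm starts + n_random uniform draws in the box
reoptimize_pinned <- function(obj, warm_starts, n_random = 2L, seed = 1L) {
  starts <- warm_starts
  if (length(obj$lower) > 0L && n_random > 0L) {
    rand <- with_seed(seed, {
      lapply(seq_len(n_random), function(i)
        stats::runif(length(obj$lower), obj$lower, obj$upper))
    })
    starts <- c(starts, rand)
  }
  if (length(obj$lower) == 0L)
    return(list(par = numeric(0), value = obj$fn(numeric(0))))
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, obj$lower), obj$upper)
    # looser tolerance than the global fit's polish: profile values are
    # compared against chi-squared offsets of order 1, not machine epsilon
    res <- polish_local(obj$fn, s, obj$lower, obj$upper, rounds = 2L,
                        factr = 1e5)
    if (is.null(best) || res$value < best$value) best <- res
  }
  best
}

default_profile_grid <- function(theta_i, bounds_i, n = 41L, decades = 1L) {
  lo <- bounds_i[1L]; hi <- bounds_i[2L]
  if (theta_i > 0) {
    g_lo <- max(theta_i / 10^decades, lo, .Machine$double.xmin)
    g_hi <- min(theta_i * 10^decades, hi)
    if (g_lo <= 0) g_lo <- g_hi * 1e-6
    grid <- exp(seq(log(g_lo), log(g_hi), length.out = n))
  } else {
    grid <- seq(lo, hi, length.out = n)
  }
  sort(unique(c(grid, min(max(theta_i, lo), hi))))
}

#' Profile likelihood of one kinetic parameter
#'
#' For each value of the target parameter on a grid around its maximum
#' likelihood estimate, the remaining active parameters are re-optimized
#' (warm-started from the neighbouring grid point's co-parameters, plus the
#' global optimum and random restarts) and the minimized objective recorded:
#' `PL(theta_i) = min over theta_j (j != i) of MLE(theta)`.
#'
#' @param data Measured tissue curve, a [sampled_signal()].
#' @param vif Plasma input on the same grid.
#' @param kind Model kind.
#' @param theta_hat The global optimum: a `fit_result` from [fit_global()]
#'   (preferred) or a [pk_params()] object.
#' @param target Name of the profiled parameter (one of the kind's active
#'   parameters).
#' @param grid_spec Either a numeric vector of grid values, or a list with
#'   `n` (points, default 41) and `decades` (half-span in decades around the
#'   estimate, default 1, i.e. a log-spaced grid over
#'   \[theta/10, 10 theta\] intersected with the fit bounds).
#' @param config A [fit_config()]; defaults to the one inside `theta_hat`
#'   when that is a `fit_result`.
#' @param n_restarts Random restarts per grid point (on top of warm starts).
#' @return Object of class `likelihood_profile`: `target`, `grid`,
#'   `pl_values`, `co_params` (matrix, one row per grid point), `theta_hat`,
#'   `mle_ref` (objective at the optimum), `warnings`.
#' @export
profile_likelihood <- function(data, vif, kind, theta_hat, target,
                               grid_spec = NULL, config = NULL,
                               n_restarts = 2L) {
  kind <- match_kind(kind)
  if (inherits(theta_hat, "fit_result")) {
    if (is.null(config)) config <- theta_hat$config
    if (missing(kind) || is.null(kind)) kind <- theta_hat$kind
    theta_hat <- theta_hat$theta_hat
  }
  if (is.null(config)) config <- fit_config()
  stopifnot(inherits(theta_hat, "pk_params"), inherits(config, "fit_config"))
  active <- active_params(kind)
  if (!target %in% active)
    stop("'", target, "' is not an active parameter of the ", kind, " model",
         call. = FALSE)
  th_i <- theta_hat[[target]]
  b_i <- config$bounds[[target]]
  warn <- character(0)
  if (is.numeric(grid_spec)) {
    grid <- sort(unique(as.numeric(grid_spec)))
  } else {
    gs <- if (is.list(grid_spec)) grid_spec else list()
    grid <- default_profile_grid(th_i, b_i,
                                 n = if (is.null(gs$n)) 41L else gs$n,
                                 decades = if (is.null(gs$decades)) 1L
                                           else gs$decades)
  }
  if (th_i < min(grid) || th_i > max(grid))
    warn <- c(warn, "grid does not contain the optimum's neighbourhood")

  mle_ref <- mle_objective(theta_hat, data, vif, kind, config$sigma)
  # parameters pinned by degenerate bounds are not co-parameters
  pinned_by_bounds <- names(config$bounds)[vapply(config$bounds,
    function(b) b[1L] == b[2L], logical(1L))]
  co_names <- setdiff(active, c(target, pinned_by_bounds))
  hat_co <- vapply(co_names, function(nm) theta_hat[[nm]], numeric(1L))

  n_g <- length(grid)
  pl <- numeric(n_g)
  co <- matrix(NA_real_, n_g, length(co_names),
               dimnames = list(NULL, co_names))
  i_center <- which.min(abs(grid - th_i))
  # walk outwards from the optimum in both directions, warm-starting each
  # point from its inner neighbour
  order_idx <- c(seq(i_center, 1L), if (i_center < n_g) seq(i_center + 1L, n_g))
  prev_right <- prev_left <- hat_co
  for (k in seq_along(order_idx)) {
    i <- order_idx[k]
    obj <- make_objective(data, vif, kind, config$sigma, config$bounds,
                          pinned = stats::setNames(list(grid[i]), target))
    warmv <- if (i <= i_center) prev_left else prev_right
    warm <- list(warmv[obj$free], hat_co[obj$free])
    res <- reoptimize_pinned(obj, warm, n_random = n_restarts,
                             seed = derive_seed(config$seed, 1000L + i))
    pl[i] <- res$value
    if (length(obj$free) > 0L) co[i, obj$free] <- res$par
    full <- hat_co
    full[obj$free] <- res$par
    if (i <= i_center) prev_left <- full else prev_right <- full
  }
  structure(list(target = target, grid = grid, pl_values = pl,
                 co_params = co, theta_hat = theta_hat, kind = kind,
                 mle_ref = mle_ref, config = config, warnings = warn),
            class = "likelihood_profile")
}

#' @export
print.likelihood_profile <- function(x, ...) {
  cat(sprintf(
    "likelihood_profile of '%s' (%s): %d points in [%.4g, %.4g], MLE ref %.6g\n",
    x$target, x$kind, length(x$grid), min(x$grid), max(x$grid), x$mle_ref))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Profile-likelihood confidence interval
#'
#' The confidence interval at `level` is the set of target values whose
#' profile likelihood stays within `chi2_threshold(level)` of the minimum
#' objective.  Threshold crossings are located by linear interpolation
#' between grid points; a side that never crosses inside the profiled grid
#' is flagged open (non-finite), with the grid edge reported as its bound.
#'
#' @param profile A [profile_likelihood()] result.
#' @param level Confidence level (0.68, 0.80, 0.95, or any value in (0,1)).
#' @return Object of class `confidence_interval`: `level`, `lower`, `upper`,
#'   `finite` (logical length 2), `threshold`.
#' @export
confidence_interval <- function(profile, level) {
  stopifnot(inherits(profile, "likelihood_profile"))
  delta <- chi2_threshold(level)
  thr <- profile$mle_ref + delta
  g <- profile$grid; pl <- profile$pl_values
  i0 <- which.min(pl)
  cross <- function(i_from, i_to) {
    # first crossing of thr between consecutive points walking i_from->i_to
    idx <- seq(i_from, i_to)
    for (k in seq_along(idx)[-1L]) {
      a <- idx[k - 1L]; b <- idx[k]
      if (pl[a] <= thr && pl[b] > thr) {
        f <- (thr - pl[a]) / (pl[b] - pl[a])
        return(g[a] + f * (g[b] - g[a]))
      }
    }
    NA_real_
  }
  lower <- if (i0 > 1L) cross(i0, 1L) else NA_real_
  upper <- if (i0 < length(g)) cross(i0, length(g)) else NA_real_
  structure(list(level = level, threshold = thr,
                 lower = if (is.na(lower)) min(g) else lower,
                 upper = if (is.na(upper)) max(g) else upper,
                 finite = c(lower = !is.na(lower), upper = !is.na(upper))),
            class = "confidence_interval")
}

#' @export
print.confidence_interval <- function(x, ...) {
  fmt <- function(v, fin, side)
    if (fin) sprintf("%.6g", v) else sprintf("open (grid edge %.6g)", v)
  cat(sprintf("%.0f%% CI: [%s, %s]\n", 100 * x$level,
              fmt(x$lower, x$finite[["lower"]]),
              fmt(x$upper, x$finite[["upper"]])))
  invisible(x)
}

#' Classify the practical identifiability of a profiled parameter
#'
#' A parameter is `identifiable` at the stated level when both confidence
#' bounds are finite; `flat` (structural-non-identifiability-like) when the
#' profile's total variation over the full grid is below 5% of the
#' chi-squared threshold; otherwise `practically_non_identifiable`.
#'
#' @param profile A [profile_likelihood()] result.
#' @param level Confidence level.
#' @return Object of class `identifiability_verdict`: `verdict`, `level`,
#'   `open_sides`, `ci`.
#' @export
classify <- function(profile, level) {
  ci <- confidence_interval(profile, level)
  delta <- chi2_threshold(level)
  variation <- max(profile$pl_values) - min(profile$pl_values)
  verdict <- if (variation < 0.05 * delta) "flat"
  else if (all(ci$finite)) "identifiable"
  else "practically_non_identifiable"
  structure(list(verdict = verdict, level = level,
                 open_sides = names(ci$finite)[!ci$finite],
                 flat_variation = variation, ci = ci,
                 target = profile$target),
            class = "identifiability_verdict")
}

#' @export
print.identifiability_verdict <- function(x, ...) {
  cat(sprintf("'%s' at %.0f%%: %s%s\n", x$target, 100 * x$level, x$verdict,
              if (length(x$open_sides))
                paste0(" (open: ", paste(x$open_sides, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Compensating profiles of the co-parameters
#'
#' Perturbs the target parameter on a linear grid around its maximum
#' likelihood estimate (default +/-50%) and records the re-optimized values
#' of every other active parameter, revealing which co-parameters compensate
#' for the perturbation (a hallmark of weak identifiability).
#'
#' @inheritParams profile_likelihood
#' @param span Fractional half-range of the perturbation (0.5 = +/-50%).
#' @param n Number of grid points.
#' @return Object of class `compensating_profiles`: `target`, `grid`,
#'   `traces` (matrix of co-parameters), `objective`.
#' @export
compensating_profiles <- function(data, vif, kind, theta_hat, target,
                                  span = 0.5, config = NULL, n = 21L) {
  if (inherits(theta_hat, "fit_result")) {
    if (is.null(config)) config <- theta_hat$config
    theta_hat <- theta_hat$theta_hat
  }
  if (is.null(config)) config <- fit_config()
  kind <- match_kind(kind)
  th_i <- theta_hat[[target]]
  b_i <- config$bounds[[target]]
  grid <- seq(max(th_i * (1 - span), b_i[1L]),
              min(th_i * (1 + span), b_i[2L]), length.out = n)
  # warm-start-only re-optimization keeps the traces on the continuous
  # solution branch through the optimum (random restarts can hop to
  # objective-equivalent branches and fracture the trace)
  prof <- profile_likelihood(data, vif, kind, theta_hat, target,
                             grid_spec = grid, config = config,
                             n_restarts = 0L)
  structure(list(target = target, grid = prof$grid,
                 traces = prof$co_params, objective = prof$pl_values,
                 theta_hat = theta_hat, kind = kind),
            class = "compensating_profiles")
}

# output ----------------------------------------------------------------

#' Write a likelihood profile (grid, PL, co-parameters) to CSV
#'
#' @param profile A [profile_likelihood()] or [compensating_profiles()]
#'   result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  if (inherits(profile, "likelihood_profile")) {
    df <- data.frame(profile$target, profile$grid, profile$pl_values,
                     profile$co_params, check.names = FALSE)
    names(df) <- c("target", profile$target, "pl",
                   colnames(profile$co_params))
  } else if (inherits(profile, "compensating_profiles")) {
    df <- data.frame(profile$target, profile$grid, profile$objective,
                     profile$traces, check.names = FALSE)
    names(df) <- c("target", profile$target, "objective",
                   colnames(profile$traces))
  } else stop("unsupported profile object", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an identifiability verdict to JSON
#'
#' @param verdict An [classify()] result.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
verdict_json <- function(verdict, path = NULL) {
  stopifnot(inherits(verdict, "identifiability_verdict"))
  js <- jsonlite::toJSON(
    list(target = verdict$target, verdict = verdict$verdict,
         level = verdict$level, open_sides = verdict$open_sides,
         flat_variation = verdict$flat_variation,
         flatness_convention = "total variation < 0.05 * chi2 threshold",
         ci = list(lower = verdict$ci$lower, upper = verdict$ci$upper,
                   finite = as.list(verdict$ci$finite))),
    auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Plot a likelihood profile with confidence thresholds
#'
#' Base-graphics panel in the style of profile-likelihood identifiability
#' figures: the profile versus the target parameter (log x-axis for positive
#' grids) with horizontal threshold lines at the 68/80/95% chi-squared
#' offsets and the optimum marked.
#'
#' @param x A [profile_likelihood()] result.
#' @param levels Confidence levels to draw as thresholds.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.likelihood_profile <- function(x, levels = c(0.68, 0.80, 0.95), ...) {
  uselog <- all(x$grid > 0)
  graphics::plot(x$grid, x$pl_values, type = "l", lwd = 2,
                 log = if (uselog) "x" else "",
                 xlab = x$target, ylab = "profile likelihood", ...)
  cols <- c("steelblue", "darkorange", "firebrick")
  for (i in seq_along(levels)) {
    graphics::abline(h = x$mle_ref + chi2_threshold(levels[i]),
                     lty = 2, col = cols[(i - 1L) %% 3L + 1L])
  }
  graphics::points(x$theta_hat[[x$target]], x$mle_ref, pch = 19,
                   col = "red")
  graphics::legend("topright", bty = "n", lty = 2, col = cols,
                   legend = sprintf("%.0f%%", 100 * levels))
  invisible(x)
}

#' Plot compensating-profile traces
#'
#' @param x A [compensating_profiles()] result.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.compensating_profiles <- function(x, ...) {
  if (ncol(x$traces) == 0L) {
    graphics::plot.new()
    graphics::title(main = "no co-parameters")
    return(invisible(x))
  }
  sc <- scale(x$traces, center = FALSE,
              scale = apply(abs(x$traces), 2L, max) + 1e-300)
  graphics::matplot(x$grid, sc, type = "l", lwd = 2,
                    xlab = x$target, ylab = "co-parameter (scaled)", ...)
  graphics::legend("topright", bty = "n", lty = seq_len(ncol(x$traces)),
                   col = seq_len(ncol(x$traces)),
                   legend = colnames(x$traces))
  invisible(x)
}
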