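#' Default box bounds for the kinetic parameters
#'
#' Wide physiological boxes containing all parameter regimes the nested
#' models are exercised with: `ktrans` in \[1e-6, 1\] 1/s, `ve` in
#' \[1e-3, 1\], `vp` in \[0, 1\], `lam` in \[0, 0.1\] 1/s.
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_bounds <- function() {
  list(ktrans = c(1e-6, 1),
       ve     = c(1e-3, 1),
       vp     = c(0, 1),
       lam    = c(0, 0.1))
}

#' Configuration for global model fitting
#'
#' @param bounds Named list of `c(lower, upper)` box bounds per parameter;
#'   a parameter whose lower and upper bound coincide is held fixed at that
#'   value and excluded from the search.
#' @param swarm Particle-swarm size.
#' @param iters Iteration budget per restart.
#' @param restarts Number of independent swarm restarts.
#' @param seed Master seed; per-restart streams are derived from it.
#' @param sigma Noise standard deviation entering the least-squares
#'   objective.  The default 0.05 is the fallback for noise-free synthetic
#'   data, where sigma only rescales the objective (and hence the
#'   confidence-interval thresholds) without moving the optimum.
#' @param polish Apply a deterministic local refinement (`optim` L-BFGS-B)
#'   from the best swarm position.
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(bounds = default_bounds(), swarm = 50L, iters = 500L,
                       restarts = 3L, seed = 1L, sigma = 0.05,
                       polish = TRUE) {
  stopifnot(is.list(bounds), swarm >= 2L, iters >= 1L, restarts >= 1L,
            sigma > 0)
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2L || b[1L] > b[2L])
      stop("bounds for '", nm, "' must be c(lower, upper) with lower <= upper",
           call. = FALSE)
  }
  structure(list(bounds = bounds, swarm = as.integer(swarm),
                 iters = as.integer(iters), restarts = as.integer(restarts),
                 seed = as.integer(seed), sigma = sigma, polish = polish),
            class = "fit_config")
}

#' Least-squares maximum-likelihood objective
#'
#' `MLE(theta) = (1/sigma^2) * sum_i (y_i^D - y_i^M(theta))^2` where `y^D`
#' is the measured tissue curve and `y^M` the forward curve of the chosen
#' model kind.  Equivalent to the negative log-likelihood (up to a constant)
#' under additive Gaussian noise of constant standard deviation `sigma`.
#'
#' @param theta A [pk_params()] object.
#' @param data Measured tissue curve, a [sampled_signal()].
#' @param vif Plasma input on the same grid.
#' @param kind Model kind.
#' @param sigma Noise standard deviation (> 0).
#' @return Scalar objective value (>= 0).
#' @export
mle_objective <- function(theta, data, vif, kind, sigma) {
  assert_signal(data); assert_signal(vif)
  assert_same_grid(data, vif)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  model <- ct_model(kind, vif, theta)
  sum((data$values - model$values)^2) / sigma^2
}

#' Estimate the noise level of a tissue curve
#'
#' The objective's `sigma` is taken as the inverse of the data
#' signal-to-noise ratio, with SNR = peak enhancement over the standard
#' deviation of the pre-contrast baseline samples.  Noise-free synthetic
#' curves have zero baseline SD; in that case the configured default is
#' returned.
#'
#' @param data Tissue curve, a [sampled_signal()].
#' @param n_baseline Number of leading pre-contrast samples (>= 2).
#' @param default_sigma Value returned when the baseline SD is zero.
#' @return Scalar sigma estimate.
#' @export
estimate_sigma <- function(data, n_baseline = 3L, default_sigma = 0.05) {
  assert_signal(data)
  n_baseline <- as.integer(n_baseline)
  if (n_baseline < 2L)
    stop("need at least 2 baseline samples to estimate noise", call. = FALSE)
  if (n_baseline > length(data$times))
    stop("n_baseline exceeds the number of samples", call. = FALSE)
  base <- data$values[seq_len(n_baseline)]
  sd_base <- stats::sd(base)
  peak <- max(data$values) - mean(base)
  if (sd_base == 0 || peak <= 0) return(default_sigma)
  sd_base / peak
}

# internal objective over the free (searched) parameters ----------------

# forward curves for a whole batch of parameter vectors at once:
# km is an m x 4 matrix with columns ktrans, ve, vp, lam; returns m x n
ct_curves_matrix <- function(kind, times, cp, km) {
  n <- length(times)
  v <- cumtrapz(times, cp)
  ktrans <- km[, 1L]; ve <- km[, 2L]; vp <- km[, 3L]; lam <- km[, 4L]
  if (kind == "PM")
    return(outer(vp, cp) + outer(ktrans, v))
  kep <- ktrans / ve
  dt <- diff(times)
  conv <- matrix(0, nrow(km), n)
  acc <- numeric(nrow(km))
  for (i in 2:n) {
    h <- dt[i - 1L]
    x <- kep * h
    E <- exp(-x)
    small <- x < 1e-3
    A <- ifelse(small, 1 - x / 2 + x^2 / 6, (1 - E) / x)
    B <- ifelse(small, 0.5 - x / 6 + x^2 / 24, 1 / x - (1 - E) / x^2)
    acc <- E * acc + h * (cp[i - 1L] * A + (cp[i] - cp[i - 1L]) * B)
    conv[, i] <- acc
  }
  out <- conv * ktrans
  if (kind %in% c("eTK", "LTK")) out <- out + outer(vp, cp)
  if (kind == "LTK") out <- out + outer(lam, v)
  out
}

# Returns list(fn, fn_mat, free, lower, upper, build): fn maps a numeric
# vector of free parameters to the objective, fn_mat a matrix of them
# (one row per candidate); pinned entries are held at fixed values.
make_objective <- function(data, vif, kind, sigma, bounds,
                           pinned = list()) {
  kind <- match_kind(kind)
  active <- active_params(kind)
  full <- c(ktrans = 0, ve = 1, vp = 0, lam = 0)
  for (nm in names(pinned)) full[[nm]] <- pinned[[nm]]
  # bounds with lower == upper pin the parameter as well
  for (nm in active) {
    if (!nm %in% names(bounds)) next
    b <- bounds[[nm]]
    if (b[1L] == b[2L] && !nm %in% names(pinned)) {
      pinned[[nm]] <- b[1L]
      full[[nm]] <- b[1L]
    }
  }
  free <- setdiff(active, names(pinned))
  build <- function(x) {
    full[free] <- x
    pk_params(full[["ktrans"]], full[["ve"]], full[["vp"]], full[["lam"]])
  }
  fn <- function(x) {
    p <- tryCatch(build(x), error = function(e) NULL)
    if (is.null(p)) return(Inf)
    mle_objective(p, data, vif, kind, sigma)
  }
  times <- data$times; yD <- data$values; cp <- vif$values
  fn_mat <- function(X) {
    # X: m x length(free); candidates are assumed inside the box
    km <- matrix(full, nrow(X), 4L, byrow = TRUE,
                 dimnames = list(NULL, names(full)))
    if (length(free)) km[, free] <- X
    curves <- ct_curves_matrix(kind, times, cp, km)
    rowSums((curves - matrix(yD, nrow(X), length(yD), byrow = TRUE))^2) /
      sigma^2
  }
  list(fn = fn, fn_mat = fn_mat, free = free,
       lower = vapply(free, function(nm) bounds[[nm]][1L], numeric(1L)),
       upper = vapply(free, function(nm) bounds[[nm]][2L], numeric(1L)),
       build = build)
}

# global-best particle swarm with constriction-style coefficients;
# deterministic for a fixed seed, early exit on stagnation
pso_optimize <- function(fn, lower, upper, swarm = 50L, iters = 500L,
                         seed = NULL, stall_limit = 100L, ftol = 1e-14,
                         fn_mat = NULL) {
  d <- length(lower)
  if (!is.null(seed)) set.seed(as.integer(seed))
  evaluate <- if (is.null(fn_mat)) function(P) apply(P, 1L, fn) else fn_mat
  range <- upper - lower
  pos <- matrix(stats::runif(swarm * d, rep(lower, each = swarm),
                             rep(upper, each = swarm)), nrow = swarm)
  vel <- matrix((stats::runif(swarm * d) - 0.5) * rep(range, each = swarm) / 2,
                nrow = swarm)
  fvals <- evaluate(pos)
  pbest <- pos; pbest_f <- fvals
  gi <- which.min(fvals)
  gbest <- pos[gi, ]; gbest_f <- fvals[gi]
  w <- 0.7298; c1 <- 1.49618; c2 <- 1.49618
  stall <- 0L
  for (it in seq_len(iters)) {
    r1 <- matrix(stats::runif(swarm * d), nrow = swarm)
    r2 <- matrix(stats::runif(swarm * d), nrow = swarm)
    vel <- w * vel + c1 * r1 * (pbest - pos) +
      c2 * r2 * (matrix(gbest, swarm, d, byrow = TRUE) - pos)
    vmax <- matrix(range / 2, swarm, d, byrow = TRUE)
    vel <- pmin(pmax(vel, -vmax), vmax)
    pos <- pos + vel
    # reflect at the box boundary
    lo <- matrix(lower, swarm, d, byrow = TRUE)
    hi <- matrix(upper, swarm, d, byrow = TRUE)
    below <- pos < lo; above <- pos > hi
    pos[below] <- (2 * lo - pos)[below]
    pos[above] <- (2 * hi - pos)[above]
    pos <- pmin(pmax(pos, lo), hi)
    vel[below | above] <- -0.5 * vel[below | above]
    fvals <- evaluate(pos)
    imp <- fvals < pbest_f
    pbest[imp, ] <- pos[imp, , drop = FALSE]
    pbest_f[imp] <- fvals[imp]
    gi <- which.min(pbest_f)
    if (pbest_f[gi] < gbest_f - 1e-18) {
      gbest_f <- pbest_f[gi]; gbest <- pbest[gi, ]
      stall <- 0L
    } else stall <- stall + 1L
    if (gbest_f < ftol || stall >= stall_limit) break
  }
  list(par = gbest, value = gbest_f, iterations = it)
}

# deterministic local refinement within the box.  Runs a few rounds of
# L-BFGS-B with the finite-difference step rescaled to the current iterate
# (the kinetic parameters span several orders of magnitude, so a fixed
# absolute step would destroy the numerical gradient for the small rates).
polish_local <- function(fn, par, lower, upper, rounds = 3L, factr = 1) {
  best <- list(par = par, value = fn(par))
  if (length(par) == 0L) return(best)
  for (r in seq_len(rounds)) {
    psc <- pmax(abs(best$par), 1e-4 * (upper - lower), 1e-9)
    res <- tryCatch(
      stats::optim(best$par, fn, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 1000L, factr = factr, pgtol = 0,
                                  parscale = psc,
                                  ndeps = rep(1e-7, length(par)))),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) break
    improved <- res$value < best$value - 1e-14 * (1 + abs(best$value))
    if (res$value < best$value)
      best <- list(par = pmin(pmax(res$par, lower), upper),
                   value = res$value)
    if (!improved) break
  }
  best
}

derive_seed <- function(seed, k) {
  as.integer(((as.double(seed) %% 65536) * 32749 + 104729 * as.double(k)) %%
               2147483647)
}

#' Global maximum-likelihood fit of a transport model
#'
#' Minimises [mle_objective()] over the model kind's active parameters with
#' a particle-swarm global search (multiple independent restarts) followed
#' by a deterministic local polish.  Reproducible for a fixed master seed.
#'
#' @param data Measured tissue curve, a [sampled_signal()].
#' @param vif Plasma input on the same grid.
#' @param kind Model kind, see [active_params()].
#' @param config A [fit_config()].
#' @return Object of class `fit_result`: `theta_hat` ([pk_params()]),
#'   `objective_value`, `kind`, `free` (searched parameter names),
#'   `restart_values`, `config`.
#' @export
fit_global <- function(data, vif, kind, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  kind <- match_kind(kind)
  obj <- make_objective(data, vif, kind, config$sigma, config$bounds)
  best <- NULL
  restart_values <- numeric(config$restarts)
  for (r in seq_len(config$restarts)) {
    res <- pso_optimize(obj$fn, obj$lower, obj$upper, swarm = config$swarm,
                        iters = config$iters,
                        seed = derive_seed(config$seed, r),
                        fn_mat = obj$fn_mat)
    if (config$polish)
      res <- polish_local(obj$fn, res$par, obj$lower, obj$upper)
    restart_values[r] <- res$value
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || !is.finite(best$value))
    stop("optimizer exhausted its budget without a finite objective",
         call. = FALSE)
  structure(list(theta_hat = obj$build(best$par),
                 objective_value = best$value,
                 kind = kind, free = obj$free,
                 restart_values = restart_values,
                 config = config),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s): objective %.6g\n", x$kind,
              x$objective_value))
  print(x$theta_hat)
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit A `fit_result` from [fit_global()].
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
fit_result_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  js <- jsonlite::toJSON(
    list(kind = fit$kind, theta_hat = unclass(fit$theta_hat),
         objective_value = fit$objective_value, free = fit$free,
         restart_values = fit$restart_values, seed = fit$config$seed,
         sigma = fit$config$sigma),
    auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
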