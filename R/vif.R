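#' Parker population vascular input function parameters
#'
#' The Parker VIF models the arterial plasma concentration after a contrast
#' bolus as a mixture of two Gaussians (first pass and recirculation) plus an
#' exponential washout gated by a sigmoid.  The defaults are the constants
#' used for the artificial-VIF brain study, in seconds/mM units.
#'
#' @param A1,A2 Gaussian scaling constants (mM s).
#' @param T1,T2 Gaussian centres (s).
#' @param sigma1,sigma2 Gaussian widths (s), strictly positive.
#' @param alpha Exponential amplitude (mM).
#' @param beta Exponential decay constant (1/s).
#' @param l Sigmoid width (1/s).
#' @param tau Sigmoid centre (s).
#' @return Object of class `parker_vif_params`.
#' @seealso [parker_vif()], [parker_vif_signal()]
#' @export
parker_vif_params <- function(A1 = 48.54, A2 = 18.64,
                              T1 = 10.2276, T2 = 21.9,
                              sigma1 = 3.378, sigma2 = 7.92,
                              alpha = 1.05, beta = 0.0028,
                              l = 0.6346, tau = 28.98) {
  p <- list(A1 = A1, A2 = A2, T1 = T1, T2 = T2, sigma1 = sigma1,
            sigma2 = sigma2, alpha = alpha, beta = beta, l = l, tau = tau)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1L))))
    stop("all Parker VIF parameters must be finite scalars", call. = FALSE)
  if (p$sigma1 <= 0 || p$sigma2 <= 0)
    stop("sigma1 and sigma2 must be > 0", call. = FALSE)
  if (any(unlist(p[c("A1", "A2", "alpha", "beta", "l")]) < 0))
    stop("A1, A2, alpha, beta, l must be >= 0", call. = FALSE)
  structure(p, class = "parker_vif_params")
}

#' Evaluate the Parker VIF
#'
#' @param t Time(s) since bolus arrival, in seconds; nonnegative, finite.
#' @param params A [parker_vif_params()] object.
#' @return Plasma concentration in mM, same length as `t`.
#' @examples
#' p <- parker_vif_params()
#' parker_vif(c(0, 10, 60), p)
#' @export
parker_vif <- function(t, params = parker_vif_params()) {
  if (!inherits(params, "parker_vif_params"))
    stop("'params' must be a parker_vif_params object", call. = FALSE)
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric", call. = FALSE)
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  g <- function(A, T0, s)
    A / (s * sqrt(2 * pi)) * exp(-(t - T0)^2 / (2 * s^2))
  g(params$A1, params$T1, params$sigma1) +
    g(params$A2, params$T2, params$sigma2) +
    params$alpha * exp(-params$beta * t) /
      (1 + exp(-params$l * (t - params$tau)))
}

#' Parker VIF sampled on an acquisition grid
#'
#' Produces the VIF as a [sampled_signal()] on a dynamic acquisition grid:
#' zero concentration during the pre-contrast baseline frames, then the
#' analytic Parker curve with its clock started at the first post-baseline
#' frame.
#'
#' @param grid A grid from [default_time_grid()].
#' @param params A [parker_vif_params()] object.
#' @return A [sampled_signal()] labelled `"parker_vif"`.
#' @export
parker_vif_signal <- function(grid = default_time_grid(),
                              params = parker_vif_params()) {
  times <- grid$times
  vals <- numeric(length(times))
  post <- times >= grid$t_bolus
  vals[post] <- parker_vif(times[post] - grid$t_bolus, params)
  sampled_signal(times, vals, label = "parker_vif")
}

#' Add graded multiplicative-amplitude Gaussian noise to a VIF
#'
#' Emulates the noise carried by individually measured (ROI-derived) input
#' functions: at each sample the noise amplitude is `level` times the
#' noise-free value, and the noise itself is standard normal, i.e.
#' `noisy(t_i) = vif(t_i) + level * vif(t_i) * z_i` with iid `z_i ~ N(0,1)`.
#' Values are not clipped at zero by default, consistent with an additive
#' Gaussian measurement model.
#'
#' @param vif A [sampled_signal()].
#' @param level Noise amplitude as a fraction of the signal (e.g. 0.05 for
#'   5%); must be >= 0.
#' @param seed Integer seed making the draw reproducible.
#' @param clip_negative If `TRUE`, truncate negative noisy values at zero.
#' @return A new [sampled_signal()] on the same grid.
#' @export
add_vif_noise <- function(vif, level, seed, clip_negative = FALSE) {
  assert_signal(vif)
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level < 0)
    stop("'level' must be a single nonnegative number", call. = FALSE)
  vals <- vif$values
  if (level > 0) {
    z <- local_rnorm(length(vals), seed)
    vals <- vals + level * vals * z
    if (clip_negative) vals <- pmax(vals, 0)
  }
  sampled_signal(vif$times, vals,
                 label = sprintf("%s+%.0f%%noise", vif$label, 100 * level))
}

# draw n standard normals under 'seed' without disturbing the caller's RNG
local_rnorm <- function(n, seed) {
  if (missing(seed) || is.null(seed))
    return(stats::rnorm(n))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  stats::rnorm(n)
}

#' Serialize Parker VIF parameters to JSON
#'
#' @param params A [parker_vif_params()] object.
#' @param path Optional path; if given the JSON is written there.
#' @return JSON string, invisibly when `path` is given.
#' @export
parker_vif_params_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "parker_vif_params"))
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
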