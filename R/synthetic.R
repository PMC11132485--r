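#' Reference kinetic parameter sets for the enhancement-curve archetypes
#'
#' Ground-truth Leaky Tofts-Kety parameter rows used to forward-simulate the
#' three characteristic contrast-enhancement patterns: Type I (persistent
#' rise), Type II (plateau), Type III (wash-out).  Two tissue settings are
#' provided: `"AA"` (the fully artificial study) and `"RA"` (the
#' measured-input study, whose Type III row deliberately sits near the
#' `Kep = Ktrans/ve` singularity with `ve` at its lower search bound and
#' `lam = 0`, stressing the fitter).
#'
#' @param type Curve type, `"I"`, `"II"`, or `"III"`.
#' @param case Parameter table, `"AA"` or `"RA"`.
#' @return A [pk_params()] object.
#' @export
reference_params <- function(type = c("I", "II", "III"),
                             case = c("AA", "RA")) {
  type <- match.arg(type)
  case <- match.arg(case)
  tab <- if (case == "AA") {
    list(I   = c(0.0025, 0.9, 0.05, 0.01),
         II  = c(0.009, 0.5, 0.1, 0.001),
         III = c(0.03, 0.5, 0.1, 0.001))
  } else {
    list(I   = c(0.0025, 0.9, 0.05, 0.001),
         II  = c(0.009, 0.5, 0.1, 0.001),
         III = c(0.008, 0.001, 0.9, 0))
  }
  r <- tab[[type]]
  pk_params(ktrans = r[1L], ve = r[2L], vp = r[3L], lam = r[4L])
}

#' Scenario specification for the synthetic-data generator
#'
#' Encodes one study condition: which enhancement-curve archetype to
#' simulate, and how much realism (noise) to inject.  The three cases are
#' `"AA"` (noise-free analytic input, noise-free curve), `"RA_like"` (noisy
#' input emulating an individually measured vessel ROI, noise-free curve),
#' and `"RR_like"` (noisy input and noisy curve, a synthetic surrogate for
#' fully measured data).
#'
#' @param type Curve type `"I"`, `"II"`, `"III"`.
#' @param case `"AA"`, `"RA_like"`, or `"RR_like"`.
#' @param vif_noise Amplitude of the input-function noise as a fraction;
#'   default 0 for AA, 0.10 otherwise.
#' @param ca_snr Signal-to-noise ratio of the tissue curve for RR_like
#'   (default 20); ignored otherwise.
#' @param seed Integer seed; the scenario is a pure function of
#'   (spec, seed).
#' @param grid Acquisition grid from [default_time_grid()].
#' @param vif_params Parker constants, a [parker_vif_params()].
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(type = c("I", "II", "III"),
                          case = c("AA", "RA_like", "RR_like"),
                          vif_noise = NULL, ca_snr = 20, seed = 1L,
                          grid = default_time_grid(),
                          vif_params = parker_vif_params()) {
  type <- match.arg(type)
  case <- match.arg(case)
  if (is.null(vif_noise)) vif_noise <- if (case == "AA") 0 else 0.10
  if (case == "AA" && vif_noise != 0)
    stop("the AA case is noise-free by definition", call. = FALSE)
  if (case != "AA" && vif_noise <= 0)
    stop(case, " requires a positive vif_noise level", call. = FALSE)
  structure(list(type = type, case = case, vif_noise = vif_noise,
                 ca_snr = ca_snr, seed = as.integer(seed), grid = grid,
                 vif_params = vif_params),
            class = "scenario_spec")
}

#' Generate one synthetic study scenario
#'
#' Forward-simulates the Leaky Tofts-Kety model with the reference
#' parameters of the requested curve type.  For `AA` the input is the clean
#' analytic Parker curve and the tissue curve is exact; `RA_like` generates
#' the curve from a noisy input (the noisy input is also what a fitter would
#' see, mirroring a measured-vessel workflow); `RR_like` additionally
#' corrupts the tissue curve with additive Gaussian noise at the specified
#' SNR.
#'
#' @param spec A [scenario_spec()].
#' @return List with `vif` (the input function a fitter would use) and `ca`
#'   ([sampled_signal()]s) and `truth` (the generating [pk_params()]).
#' @details The cases differ in how the returned `vif` relates to the input
#'   that generated `ca`.  In `RA_like` the curve is simulated *with* the
#'   noisy input (the measured-input workflow: whatever input was measured
#'   is also what drives the simulated data).  In `RR_like` the curve is
#'   simulated with the clean input and then noise-corrupted, while the
#'   returned `vif` is an independent noisy measurement of that input --
#'   as with real tissue data, the measured input is not the input that
#'   produced the data, and this mismatch (not just the additive curve
#'   noise) is what flattens likelihood profiles.
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  truth <- reference_params(spec$type,
                            if (spec$case == "AA") "AA" else "RA")
  vif_clean <- parker_vif_signal(spec$grid, spec$vif_params)
  vif <- vif_clean
  if (spec$case != "AA")
    vif <- add_vif_noise(vif_clean, spec$vif_noise,
                         seed = derive_seed(spec$seed, 11L))
  gen_vif <- if (spec$case == "RA_like") vif else vif_clean
  ca <- ct_ltk(gen_vif, truth)
  if (spec$case == "RR_like")
    ca <- add_ca_noise(ca, spec$ca_snr, seed = derive_seed(spec$seed, 13L))
  ca$label <- sprintf("ca_%s_type%s", spec$case, spec$type)
  list(vif = vif, ca = ca, truth = truth)
}

#' Add additive Gaussian noise to a tissue curve
#'
#' Constant-variance additive Gaussian noise with standard deviation
#' `peak(ca)/snr`, matching the measurement model the least-squares
#' objective assumes.
#'
#' @param ca Tissue curve, a [sampled_signal()].
#' @param snr Signal-to-noise ratio (> 0).
#' @param seed Integer seed.
#' @return Noisy [sampled_signal()] on the same grid.
#' @export
add_ca_noise <- function(ca, snr, seed) {
  assert_signal(ca)
  if (!is.numeric(snr) || length(snr) != 1L || !is.finite(snr) || snr <= 0)
    stop("'snr' must be a single positive number", call. = FALSE)
  sd_noise <- max(ca$values) / snr
  vals <- ca$values + sd_noise * local_rnorm(length(ca$values), seed)
  sampled_signal(ca$times, vals, label = sprintf("%s+snr%g", ca$label, snr))
}

#' Moving-average smoothing with a fractional smoothing factor
#'
#' Centred moving average whose window is a fraction `gamma` of the series
#' length: `w = max(3, nearest odd integer to gamma * N)` for `gamma > 0`,
#' and `w = 1` (identity) for `gamma = 0`.  Near the series ends the window
#' shrinks symmetrically so the filter stays centred and mean-preserving.
#'
#' @param signal A [sampled_signal()].
#' @param gamma Smoothing factor in \[0, 1\]; larger values mean wider
#'   windows and stronger smoothing.
#' @return Smoothed [sampled_signal()].
#' @export
smooth_moving_average <- function(signal, gamma) {
  assert_signal(signal)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0 || gamma > 1)
    stop("'gamma' must be a single number in [0, 1]", call. = FALSE)
  n <- length(signal$values)
  if (gamma == 0 || n < 3L) return(signal)
  w <- round(gamma * n)
  if (w %% 2L == 0L) w <- w + 1L
  w <- max(3L, w)
  half <- (w - 1L) %/% 2L
  x <- signal$values
  out <- vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)  # shrink symmetrically at the ends
    mean(x[(i - h):(i + h)])
  }, numeric(1L))
  sampled_signal(signal$times, out,
                 label = sprintf("%s~ma%.2f", signal$label, gamma))
}

#' Materialize scenario fixtures on disk
#'
#' Writes, for every combination of curve type and case, the paired
#' input/curve CSVs plus a JSON sidecar with the generating truth and
#' scenario settings.
#'
#' @param dir Output directory (created if needed).
#' @param types,cases Combinations to generate.
#' @param seed Master seed.
#' @return Invisibly, a data.frame listing the written files.
#' @export
write_scenario_fixtures <- function(dir, types = c("I", "II", "III"),
                                    cases = c("AA", "RA_like", "RR_like"),
                                    seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (case in cases) for (type in types) {
    spec <- scenario_spec(type, case, seed = seed)
    sc <- generate_scenario(spec)
    stem <- file.path(dir, sprintf("%s_type%s", case, type))
    write_signal_csv(sc$vif, paste0(stem, "_vif.csv"))
    write_signal_csv(sc$ca, paste0(stem, "_ca.csv"))
    writeLines(jsonlite::toJSON(
      list(type = type, case = case, vif_noise = spec$vif_noise,
           ca_snr = spec$ca_snr, seed = spec$seed,
           truth = unclass(sc$truth)),
      auto_unbox = TRUE, digits = NA), paste0(stem, "_truth.json"))
    rows[[paste(case, type)]] <- data.frame(case = case, type = type,
                                            stem = stem)
  }
  invisible(do.call(rbind, rows))
}
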