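#' Time-stamped concentration signal
#'
#' `sampled_signal` is the universal exchange type of the package: a pair of
#' equal-length numeric vectors giving sampling times (seconds) and
#' contrast-agent concentrations (mM), used both for vascular input functions
#' (VIF) and tissue enhancement curves.
#'
#' @param times Numeric vector of sampling times in seconds, strictly
#'   increasing, first element >= 0.
#' @param values Numeric vector of concentrations in mM, finite, same length
#'   as `times`.
#' @param label Free-text label carried along for printing and file output.
#' @return An object of class `sampled_signal`: a list with elements `times`,
#'   `values`, `label`.
#' @examples
#' s <- sampled_signal(c(0, 1, 2), c(0, 0.5, 0.4), label = "toy")
#' length(s)
#' @export
sampled_signal <- function(times, values, label = "") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length", call. = FALSE)
  if (length(times) < 1L)
    stop("signal must contain at least one sample", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("'times' and 'values' must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (times[1L] < 0)
    stop("times must start at or after 0", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  structure(list(times = times, values = values, label = as.character(label)[1L]),
            class = "sampled_signal")
}

#' @export
length.sampled_signal <- function(x) length(x$times)

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("sampled_signal%s: %d samples, t in [%g, %g] s, peak %.4g mM\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$times), x$times[1L], x$times[length(x$times)],
              max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.sampled_signal <- function(x, ...) {
  data.frame(time_s = x$times, conc_mM = x$values)
}

#' Default dynamic acquisition grid
#'
#' Sampling grid modelled on a T1-weighted brain DCE-MRI acquisition:
#' `n_frames` dynamic frames at `dt` seconds temporal resolution, of which the
#' first `n_baseline` frames precede contrast administration (zero
#' concentration).  The contrast clock (used by [parker_vif_signal()]) starts
#' at the first post-baseline frame.
#'
#' @param n_frames Number of dynamic frames after the baseline block.
#' @param dt Frame spacing in seconds.
#' @param n_baseline Number of pre-contrast baseline frames.
#' @return List with `times` (length `n_baseline + n_frames`), `n_baseline`,
#'   and `t_bolus`, the time of the first post-baseline frame.
#' @export
default_time_grid <- function(n_frames = 32L, dt = 6.03, n_baseline = 3L) {
  n_frames <- as.integer(n_frames)
  n_baseline <- as.integer(n_baseline)
  stopifnot(n_frames >= 1L, n_baseline >= 0L, dt > 0)
  n <- n_baseline + n_frames
  times <- seq(0, by = dt, length.out = n)
  list(times = times, n_baseline = n_baseline, t_bolus = times[n_baseline + 1L])
}

#' Read a concentration signal from a delimited text file
#'
#' Expects two columns, time (s) then concentration (mM); a header line is
#' detected and skipped automatically.  Separator is sniffed among comma,
#' tab, and semicolon.
#'
#' @param path Path to the file.
#' @param label Label attached to the returned signal (defaults to the file
#'   name).
#' @return A [sampled_signal()].
#' @export
load_vif_csv <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(";", first, fixed = TRUE)) ";"
         else if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  header <- is.na(suppressWarnings(as.numeric(strsplit(first, sep)[[1L]][1L])))
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = header,
                      colClasses = "numeric", strip.white = TRUE),
    error = function(e) stop("could not parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(df) < 2L)
    stop("expected two columns (time_s, conc_mM) in ", path, call. = FALSE)
  sampled_signal(df[[1L]], df[[2L]], label = label)
}

#' Write a concentration signal to CSV
#'
#' Two-column `time_s, conc_mM` dialect, the same one [load_vif_csv()] reads.
#'
#' @param signal A [sampled_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "sampled_signal"))
  utils::write.csv(as.data.frame(signal), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# shared internal checks ------------------------------------------------

assert_signal <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "sampled_signal"))
    stop("'", arg, "' must be a sampled_signal", call. = FALSE)
  invisible(x)
}

assert_same_grid <- function(a, b) {
  if (length(a$times) != length(b$times) ||
      max(abs(a$times - b$times)) > 1e-9)
    stop("signals must share the same time grid", call. = FALSE)
  invisible(TRUE)
}

# cumulative trapezoid integral of values over times, same length as input
cumtrapz <- function(times, values) {
  n <- length(times)
  if (n == 1L) return(0)
  c(0, cumsum(diff(times) * (values[-n] + values[-1L]) / 2))
}
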