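#' Coefficients of the observable differential equation
#'
#' Eliminating the unobserved compartment states from the Leaky Tofts-Kety
#' system leaves a single ODE in the observable tissue concentration `y`,
#' the input `u` (the VIF), its derivative, and its running integral `v`:
#' `y' + a1 y + a2 u + a3 u' + a4 v = 0`.  The four coefficients are
#' polynomial in the kinetic parameters and are the currency of the
#' structural-identifiability argument: they are what the data can determine.
#'
#' @param a1,a2,a3,a4 Real coefficients.
#' @return Object of class `observable_coefficients`.
#' @export
observable_coefficients <- function(a1, a2, a3, a4) {
  a <- list(a1 = a1, a2 = a2, a3 = a3, a4 = a4)
  if (!all(vapply(a, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1L))))
    stop("coefficients must be finite scalars", call. = FALSE)
  structure(a, class = "observable_coefficients")
}

#' @export
print.observable_coefficients <- function(x, ...) {
  cat(sprintf("observable_coefficients: a1=%.6g a2=%.6g a3=%.6g a4=%.6g\n",
              x$a1, x$a2, x$a3, x$a4))
  invisible(x)
}

#' Map kinetic parameters to observable-ODE coefficients
#'
#' The forward half of the structural-identifiability argument:
#' `a1 = Ktrans/ve^2`, `a2 = -Ktrans - Ktrans/ve^2 - lambda`, `a3 = -vp`,
#' `a4 = -(Ktrans/ve^2) lambda`.  For admissible parameters with
#' `Ktrans > 0`: `a1 > 0`, `a2 < 0`, `a3 <= 0` (zero iff `vp = 0`), and
#' `a4 <= 0` (zero iff `lambda = 0`).
#'
#' @param p A [pk_params()] object with `ve > 0`.
#' @return An [observable_coefficients()] object.
#' @examples
#' coefficients_from_params(pk_params(0.0025, 0.9, 0.05, 0.01))
#' @export
coefficients_from_params <- function(p) {
  stopifnot(inherits(p, "pk_params"))
  if (p$ve <= 0) stop("ve must be > 0", call. = FALSE)
  r <- p$ktrans / p$ve^2
  observable_coefficients(a1 = r,
                          a2 = -p$ktrans - r - p$lam,
                          a3 = -p$vp,
                          a4 = -r * p$lam)
}

#' Invert observable-ODE coefficients to kinetic parameters (closed form)
#'
#' The inverse half of the structural-identifiability argument.  Solving the
#' coefficient system uniquely for the kinetic parameters gives
#' `Ktrans = a4/a1 - a1 - a2`, `ve = sqrt(a4/a1^2 - 1 - a2/a1)`,
#' `vp = -a3`, `lambda = -a4/a1`.  Existence of a real `ve` requires the
#' feasibility condition `a2 <= a4/a1 - a1`, which holds automatically for
#' coefficients produced by admissible parameters.  The existence of this
#' unique inverse is the structural identifiability of the Leaky Tofts-Kety
#' model; the nested sub-models inherit it as constrained special cases.
#'
#' @param a An [observable_coefficients()] object with `a1 > 0`.
#' @return A [pk_params()] object reproducing `a` exactly.
#' @export
params_from_coefficients <- function(a) {
  stopifnot(inherits(a, "observable_coefficients"))
  if (a$a1 <= 0)
    stop("infeasible coefficients: a1 must be > 0", call. = FALSE)
  ktrans <- a$a4 / a$a1 - a$a1 - a$a2
  ve2 <- a$a4 / a$a1^2 - 1 - a$a2 / a$a1   # = ktrans / a1
  if (ve2 < 0)
    stop("infeasible coefficients: a2 <= a4/a1 - a1 violated ",
         "(no real ve exists)", call. = FALSE)
  if (ktrans < 0)
    stop("infeasible coefficients: implied Ktrans is negative", call. = FALSE)
  pk_params(ktrans = ktrans, ve = sqrt(ve2), vp = -a$a3, lam = -a$a4 / a$a1)
}

#' Residual of the observable ODE on sampled data
#'
#' Numerically evaluates `y' + a1 y + a2 u + a3 u' + a4 v` on a shared time
#' grid (derivatives by central differences with one-sided ends, `v` by
#' cumulative trapezoid) and returns its discrete L2 norm.  For a tissue
#' curve generated by the Leaky Tofts-Kety model with matching parameters
#' the residual is discretisation-limited and vanishes under grid
#' refinement.
#'
#' @param y Tissue curve, a [sampled_signal()].
#' @param u Input (VIF) on the same grid.
#' @param a An [observable_coefficients()] object.
#' @return Scalar L2 norm of the residual.
#' @export
observable_residual <- function(y, u, a) {
  assert_signal(y); assert_signal(u)
  stopifnot(inherits(a, "observable_coefficients"))
  assert_same_grid(y, u)
  t <- y$times
  v <- cumtrapz(t, u$values)
  r <- finite_diff(t, y$values) + a$a1 * y$values + a$a2 * u$values +
    a$a3 * finite_diff(t, u$values) + a$a4 * v
  sqrt(sum(r^2))
}

# central differences, one-sided at the ends
finite_diff <- function(t, x) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) / (t[2L] - t[1L])
  d[n] <- (x[n] - x[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L) {
    i <- 2:(n - 1L)
    d[i] <- (x[i + 1L] - x[i - 1L]) / (t[i + 1L] - t[i - 1L])
  }
  d
}

#' Serialize parameters and coefficients to JSON
#'
#' Audit-trail helper writing a kinetic parameter vector together with its
#' observable-ODE coefficients.
#'
#' @param p A [pk_params()] object.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
structural_json <- function(p, path = NULL) {
  a <- coefficients_from_params(p)
  js <- jsonlite::toJSON(list(params = unclass(p), coefficients = unclass(a)),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
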