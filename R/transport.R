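#' Kinetic parameter vector for the nested transport models
#'
#' @param ktrans Forward volume-transfer constant plasma -> EES (1/s).
#' @param ve Fractional extravascular extracellular (EES) volume, in (0, 1].
#' @param vp Fractional plasma volume, in \[0, 1\].
#' @param lam Unidirectional plasma -> leakage-compartment transfer constant
#'   (1/s); only the Leaky Tofts-Kety model uses it.
#' @return Object of class `pk_params` with fields `ktrans`, `ve`, `vp`,
#'   `lam`.
#' @details The reflux rate is the derived quantity `kep = ktrans / ve`.
#'   Note that `ve + vp <= 1` is deliberately not enforced: the model family
#'   is routinely exercised with parameter sets violating it and the fitting
#'   machinery only imposes per-parameter box bounds.
#' @export
pk_params <- function(ktrans, ve = 1, vp = 0, lam = 0) {
  p <- list(ktrans = ktrans, ve = ve, vp = vp, lam = lam)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1L))))
    stop("pk_params fields must be finite scalars", call. = FALSE)
  if (ktrans < 0) stop("ktrans must be >= 0", call. = FALSE)
  if (ve <= 0 || ve > 1) stop("ve must be in (0, 1]", call. = FALSE)
  if (vp < 0 || vp > 1) stop("vp must be in [0, 1]", call. = FALSE)
  if (lam < 0) stop("lam must be >= 0", call. = FALSE)
  structure(p, class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf(
    "pk_params: Ktrans=%.4g 1/s, ve=%.4g, vp=%.4g, lambda=%.4g 1/s (Kep=%.4g)\n",
    x$ktrans, x$ve, x$vp, x$lam, x$ktrans / x$ve))
  invisible(x)
}

#' @export
as.numeric.pk_params <- function(x, ...) {
  c(ktrans = x$ktrans, ve = x$ve, vp = x$vp, lam = x$lam)
}

# model kinds -----------------------------------------------------------

MODEL_KINDS <- c("PM", "TK", "eTK", "LTK")

#' Active parameters of a model kind
#'
#' The four nested models use different subsets of the kinetic parameter
#' vector: Patlak (PM) uses Ktrans and vp; Tofts-Kety (TK) uses Ktrans and
#' ve; extended Tofts-Kety (eTK) adds vp; Leaky Tofts-Kety (LTK) uses all
#' four including the leakage rate.
#'
#' @param kind One of `"PM"`, `"TK"`, `"eTK"`, `"LTK"`.
#' @return Character vector of active parameter names.
#' @export
active_params <- function(kind) {
  kind <- match_kind(kind)
  switch(kind,
         PM  = c("ktrans", "vp"),
         TK  = c("ktrans", "ve"),
         eTK = c("ktrans", "ve", "vp"),
         LTK = c("ktrans", "ve", "vp", "lam"))
}

match_kind <- function(kind) {
  match.arg(kind, MODEL_KINDS)
}

# forward models --------------------------------------------------------

#' Tissue concentration under the Patlak model
#'
#' `Ct(t) = vp Cp(t) + Ktrans \int_0^t Cp`.  Unidirectional uptake with no
#' reflux; appropriate for low permeability and short acquisitions.
#'
#' @param vif Plasma input as a [sampled_signal()].
#' @param p A [pk_params()] object (uses `ktrans`, `vp`).
#' @return Tissue curve as a [sampled_signal()] on the VIF grid.
#' @export
ct_patlak <- function(vif, p) {
  assert_signal(vif)
  stopifnot(inherits(p, "pk_params"))
  v <- cumtrapz(vif$times, vif$values)
  sampled_signal(vif$times, p$vp * vif$values + p$ktrans * v, label = "ct_PM")
}

# exponential-kernel convolution Ktrans * int_0^t Cp(s) exp(-kep (t-s)) ds
# evaluated by the O(n) recursion I_i = e^{-kep dt} I_{i-1} + (interval term).
#
# method "exact": the interval term integrates the kernel against a
# piecewise-linear Cp analytically, so the recursion is the exact solution
# of the exchange ODE for the interpolated input.  This stays accurate for
# arbitrarily stiff kep (the reference parameter sets include ve = 0.001,
# i.e. kep*dt ~ 50, where any fixed-order quadrature of the boundary layer
# fails).  Small kep*dt uses a series expansion to avoid cancellation.
#
# method "trapezoid": composite trapezoid quadrature of the same integral,
# kept as the transparent low-order reference.
#
# Both are stable for large kep (no positive exponentials appear).
exp_convolution <- function(times, cp, ktrans, kep,
                            method = c("exact", "trapezoid")) {
  method <- match.arg(method)
  n <- length(times)
  out <- numeric(n)
  if (ktrans == 0 || n == 1L) return(out)
  dt <- diff(times)
  decay <- exp(-kep * dt)
  acc <- 0
  for (i in 2:n) {
    h <- dt[i - 1L]
    if (method == "trapezoid") {
      inc <- h / 2 * (cp[i - 1L] * decay[i - 1L] + cp[i])
    } else {
      inc <- exact_interval_term(cp[i - 1L], cp[i], h, kep,
                                 decay[i - 1L])
    }
    acc <- decay[i - 1L] * acc + inc
    out[i] <- acc
  }
  ktrans * out
}

# int_0^h (c0 + (c1-c0) s/h) exp(-kep (h-s)) ds, exactly; E = exp(-kep h)
exact_interval_term <- function(c0, c1, h, kep, E) {
  x <- kep * h
  if (x < 1e-3) {
    # series of A = (1-E)/x and B = 1/x - (1-E)/x^2 around x = 0
    A <- 1 - x / 2 + x^2 / 6
    B <- 0.5 - x / 6 + x^2 / 24
    return(h * (c0 * A + (c1 - c0) * B))
  }
  one_minus_E <- -expm1(-x)
  A <- one_minus_E / x
  B <- 1 / x - one_minus_E / x^2
  h * (c0 * A + (c1 - c0) * B)
}

#' Tissue concentration under the Tofts-Kety model
#'
#' `Ct(t) = Ktrans \int_0^t Cp(s) exp(-Kep (t-s)) ds` with
#' `Kep = Ktrans/ve`: bidirectional plasma/EES exchange, negligible plasma
#' volume.
#'
#' @inheritParams ct_patlak
#' @param method Kernel quadrature: `"exact"` (default) integrates the
#'   exponential kernel against the piecewise-linear input analytically and
#'   stays accurate for arbitrarily stiff reflux rates; `"trapezoid"` is the
#'   transparent low-order reference quadrature.
#' @export
ct_tk <- function(vif, p, method = c("exact", "trapezoid")) {
  assert_signal(vif)
  stopifnot(inherits(p, "pk_params"))
  kep <- p$ktrans / p$ve
  sampled_signal(vif$times,
                 exp_convolution(vif$times, vif$values, p$ktrans, kep,
                                 method = method),
                 label = "ct_TK")
}

#' Tissue concentration under the extended Tofts-Kety model
#'
#' Tofts-Kety plus the vascular contribution `vp Cp(t)`.
#'
#' @inheritParams ct_tk
#' @export
ct_etk <- function(vif, p, method = c("exact", "trapezoid")) {
  tk <- ct_tk(vif, p, method = method)
  sampled_signal(vif$times, p$vp * vif$values + tk$values, label = "ct_eTK")
}

#' Tissue concentration under the Leaky Tofts-Kety model
#'
#' Extended Tofts-Kety plus a unidirectional leakage compartment:
#' `Ct(t) = vp Cp + Ktrans \int Cp exp(-Kep (t-s)) ds + lambda \int Cp`.
#'
#' @inheritParams ct_tk
#' @export
ct_ltk <- function(vif, p, method = c("exact", "trapezoid")) {
  etk <- ct_etk(vif, p, method = method)
  v <- cumtrapz(vif$times, vif$values)
  sampled_signal(vif$times, etk$values + p$lam * v, label = "ct_LTK")
}

#' Evaluate any model kind's forward curve
#'
#' @param kind Model kind, see [active_params()].
#' @inheritParams ct_tk
#' @return Tissue curve as a [sampled_signal()].
#' @export
ct_model <- function(kind, vif, p, method = c("exact", "trapezoid")) {
  kind <- match_kind(kind)
  switch(kind,
         PM  = ct_patlak(vif, p),
         TK  = ct_tk(vif, p, method = method),
         eTK = ct_etk(vif, p, method = method),
         LTK = ct_ltk(vif, p, method = method))
}

#' ODE-integration oracle for the forward models
#'
#' Independent route to the tissue curve: the compartment states (EES
#' concentration, and for LTK the leakage concentration) are integrated
#' numerically with `deSolve::lsoda`, the VIF being linearly interpolated
#' between its samples, and the tissue concentration assembled as
#' `vp Cp + ve Ce (+ CL)`.  Initial compartment concentrations are zero.
#' Used to cross-check the convolution-form solutions.
#'
#' @inheritParams ct_model
#' @param rtol,atol Integrator tolerances.
#' @return Tissue curve as a [sampled_signal()].
#' @export
ct_ode_oracle <- function(kind, vif, p, rtol = 1e-10, atol = 1e-12) {
  kind <- match_kind(kind)
  assert_signal(vif)
  stopifnot(inherits(p, "pk_params"))
  cp_fun <- stats::approxfun(vif$times, vif$values, rule = 2)
  eff <- list(ktrans = p$ktrans,
              kep = if (kind %in% c("TK", "eTK", "LTK")) p$ktrans / p$ve else 0,
              # PM and LTK carry a unidirectional uptake term
              lam = switch(kind, PM = p$ktrans, LTK = p$lam, 0))
  deriv <- function(t, y, parms) {
    cp <- cp_fun(t)
    list(c(dCeve = parms$ktrans * cp - parms$kep * y[1L],
           dCL = parms$lam * cp))
  }
  sol <- tryCatch(
    deSolve::lsoda(c(ceve = 0, cl = 0), vif$times, deriv, eff,
                   rtol = rtol, atol = atol),
    warning = function(w) stop("ODE integration failed: ",
                               conditionMessage(w), call. = FALSE),
    error = function(e) stop("ODE integration failed: ",
                             conditionMessage(e), call. = FALSE))
  # sol[, "ceve"] integrates ve*dCe/dt = Ktrans*Cp - Kep*(ve*Ce), i.e. ve*Ce
  ct <- switch(kind,
               PM  = p$vp * vif$values + sol[, "cl"],
               TK  = sol[, "ceve"],
               eTK = p$vp * vif$values + sol[, "ceve"],
               LTK = p$vp * vif$values + sol[, "ceve"] + sol[, "cl"])
  sampled_signal(vif$times, as.numeric(ct), label = paste0("ct_ode_", kind))
}
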