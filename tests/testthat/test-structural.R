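test_that("coefficient map reproduces hand-computed values", {
  # Type I row: Ktrans=0.0025, ve=0.9, vp=0.05, lam=0.01
  a <- coefficients_from_params(pk_params(0.0025, 0.9, 0.05, 0.01))
  expect_equal(a$a1, 0.0025 / 0.81, tolerance = 1e-12)
  expect_equal(a$a2, -0.0025 - 0.0025 / 0.81 - 0.01, tolerance = 1e-12)
  expect_equal(a$a3, -0.05)
  expect_equal(a$a4, -(0.0025 / 0.81) * 0.01, tolerance = 1e-12)

  # lam = 0 zeroes the integral coefficient
  expect_equal(coefficients_from_params(pk_params(0.01, 0.5, 0.1, 0))$a4, 0)

  # ve = 1, lam = 0: a1 = Ktrans, a2 = -2 Ktrans
  a <- coefficients_from_params(pk_params(0.03, 1, 0, 0))
  expect_equal(a$a1, 0.03)
  expect_equal(a$a2, -0.06)
})

test_that("coefficient signs follow the admissible-parameter pattern", {
  for (p in random_pk(50L, seed = 7L)) {
    a <- coefficients_from_params(p)
    expect_gt(a$a1, 0)
    expect_lt(a$a2, 0)
    expect_lte(a$a3, 0)
    expect_lte(a$a4, 0)
    expect_identical(a$a4 == 0, p$lam == 0)
  }
})

test_that("closed-form inversion is the exact inverse (structural identifiability)", {
  # reference row round-trips to >= 10 significant digits
  p0 <- pk_params(0.0025, 0.9, 0.05, 0.01)
  p1 <- params_from_coefficients(coefficients_from_params(p0))
  expect_equal(as.numeric(p1), as.numeric(p0), tolerance = 1e-11)

  # property sweep over random admissible draws
  for (p in random_pk(100L, seed = 99L)) {
    a <- coefficients_from_params(p)
    back <- params_from_coefficients(a)
    rel <- abs(as.numeric(back) - as.numeric(p)) /
      pmax(abs(as.numeric(p)), 1e-300)
    rel[as.numeric(p) == 0] <- abs(as.numeric(back))[as.numeric(p) == 0]
    expect_lt(max(rel), 1e-10)
  }
})

test_that("nested special cases round-trip as constrained inversions", {
  # TK-like (vp = 0, lam = 0), eTK-like (lam = 0), PM has its own 2-par form
  for (p in list(pk_params(0.01, 0.4, 0, 0),
                 pk_params(0.02, 0.3, 0.12, 0))) {
    back <- params_from_coefficients(coefficients_from_params(p))
    expect_equal(as.numeric(back), as.numeric(p), tolerance = 1e-12)
    expect_equal(back$lam, p$lam)  # a4 = 0 maps back to lam = 0 exactly
  }
})

test_that("infeasible coefficient vectors are rejected with a reason", {
  expect_error(params_from_coefficients(
    observable_coefficients(-1, -1, 0, 0)), "a1")
  # a2 > a4/a1 - a1 makes ve^2 negative
  expect_error(params_from_coefficients(
    observable_coefficients(a1 = 0.01, a2 = 0.5, a3 = 0, a4 = 0)),
    "a2")
  # feasibility holds automatically on the admissible region
  for (p in random_pk(50L, seed = 5L)) {
    a <- coefficients_from_params(p)
    expect_lte(a$a2, a$a4 / a$a1 - a$a1)
  }
})

# integrate the observable ODE y' = -(a1 y + a2 u + a3 u' + a4 v) for the
# smooth analytic input, giving a trajectory that satisfies the equation
# the residual discretizes (independent oracle: deSolve + analytic input)
observable_trajectory <- function(times, a, pv = parker_vif_params()) {
  u <- function(t) parker_vif(t, pv)
  du <- function(t) (parker_vif(t + 1e-4, pv) - parker_vif(max(t - 1e-4, 0), pv)) /
    (ifelse(t > 1e-4, 2e-4, 1e-4))
  rhs <- function(t, y, parms) {
    list(c(-(a$a1 * y[1L] + a$a2 * u(t) + a$a3 * du(t) + a$a4 * y[2L]),
           u(t)))  # y[2] accumulates v = int u
  }
  sol <- deSolve::lsoda(c(y = 0, v = 0), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  sampled_signal(times, sol[, "y"])
}

test_that("observable residual vanishes on trajectories of the observable ODE", {
  a <- coefficients_from_params(reference_params("II", "AA"))
  smooth_grid <- function(refine)
    default_time_grid(n_frames = 64L * refine, dt = 3 / refine,
                      n_baseline = 0L)$times
  res_at <- function(refine) {
    times <- smooth_grid(refine)
    u <- sampled_signal(times, parker_vif(times))
    y <- observable_trajectory(times, a)
    # normalize by grid size so refinement levels are comparable
    observable_residual(y, u, a) / sqrt(length(times))
  }
  r <- c(res_at(1L), res_at(4L), res_at(16L))
  expect_true(all(diff(r) < 0))
  expect_lt(r[3L], r[1L] / 10)

  # perturbing a coefficient strictly increases the residual
  times <- smooth_grid(4L)
  u <- sampled_signal(times, parker_vif(times))
  y <- observable_trajectory(times, a)
  a_bad <- observable_coefficients(1.5 * a$a1, a$a2, a$a3, a$a4)
  expect_gt(observable_residual(y, u, a_bad),
            2 * observable_residual(y, u, a))

  # zero signals give a zero residual
  z <- sampled_signal(times, rep(0, length(times)))
  expect_equal(observable_residual(z, z, a), 0)

  # mismatched grids are rejected
  y2 <- sampled_signal(y$times[-1], y$values[-1])
  expect_error(observable_residual(y2, u, a), "grid")
})

test_that("structural JSON audit trail round-trips", {
  p <- reference_params("I", "AA")
  back <- jsonlite::fromJSON(structural_json(p))
  expect_equal(back$params$ktrans, p$ktrans)
  expect_equal(back$coefficients$a1, coefficients_from_params(p)$a1)
})
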