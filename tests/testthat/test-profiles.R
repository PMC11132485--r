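# single-parameter linear toy: Patlak with vp pinned at 0, so the model is
# Ct = theta * g with g the running integral of the input, and both the
# profile and its confidence interval have closed forms:
#   PL(theta) = PL(theta_hat) + (theta - theta_hat)^2 * S / sigma^2,
#   half-width at level alpha = sigma * sqrt(Delta_alpha / S),  S = sum(g^2)
linear_toy <- function(theta_star = 0.01, sigma = 0.05, seed = 21L) {
  vif <- aa_vif()
  g <- c(0, cumsum(diff(vif$times) *
                     (vif$values[-length(vif$values)] +
                        vif$values[-1L]) / 2))
  set.seed(seed)
  y <- theta_star * g + stats::rnorm(length(g), 0, sigma)
  b <- default_bounds()
  b$vp <- c(0, 0)
  list(vif = vif, g = g,
       data = sampled_signal(vif$times, y),
       theta_hat = sum(y * g) / sum(g^2), S = sum(g^2),
       config = fit_config(bounds = b, swarm = 20L, iters = 150L,
                           restarts = 1L, seed = 5L, sigma = sigma))
}

test_that("chi-squared thresholds match the 1-df quantiles", {
  expect_equal(chi2_threshold(0.95), 3.841459, tolerance = 1e-6)
  expect_equal(chi2_threshold(0.68), 0.9889465, tolerance = 1e-6)
  expect_equal(chi2_threshold(0.80), 1.642374, tolerance = 1e-6)
  # diverges monotonically as the level approaches 1
  lv <- c(0.9, 0.99, 0.999, 0.9999)
  expect_true(all(diff(sapply(lv, chi2_threshold)) > 0))
  expect_error(chi2_threshold(0), "between")
  expect_error(chi2_threshold(1), "between")
})

test_that("profile likelihood is self-consistent at the optimum", {
  fit <- aa_fit_typeI()
  prof <- profile_likelihood(aa_curve("I"), aa_vif(), "LTK", fit, "ktrans",
                             grid_spec = list(n = 15L))
  i_hat <- which.min(abs(prof$grid - fit$theta_hat$ktrans))
  expect_lt(abs(prof$pl_values[i_hat] - prof$mle_ref), 1e-6 * (1 + prof$mle_ref))
  # PL >= MLE(theta_hat) everywhere up to re-optimization slack
  expect_true(all(prof$pl_values >= prof$mle_ref - 1e-6 * (1 + prof$mle_ref)))
})

test_that("linear toy model yields the closed-form parabola and CI", {
  toy <- linear_toy()
  fit <- fit_global(toy$data, toy$vif, "PM", toy$config)
  expect_equal(fit$theta_hat$ktrans, toy$theta_hat, tolerance = 1e-6)

  grid <- seq(0.8, 1.2, length.out = 21L) * toy$theta_hat
  prof <- profile_likelihood(toy$data, toy$vif, "PM", fit, "ktrans",
                             grid_spec = grid)
  sigma <- toy$config$sigma
  expected <- prof$mle_ref + (prof$grid - toy$theta_hat)^2 * toy$S / sigma^2
  expect_equal(prof$pl_values, expected, tolerance = 1e-4)

  for (lv in c(0.68, 0.80, 0.95)) {
    ci <- confidence_interval(prof, lv)
    half <- sigma * sqrt(chi2_threshold(lv) / toy$S)
    expect_true(all(ci$finite))
    expect_equal(ci$upper - toy$theta_hat, half, tolerance = 0.01)
    expect_equal(toy$theta_hat - ci$lower, half, tolerance = 0.01)
  }
})

test_that("confidence intervals are nested across levels", {
  toy <- linear_toy()
  fit <- fit_global(toy$data, toy$vif, "PM", toy$config)
  prof <- profile_likelihood(toy$data, toy$vif, "PM", fit, "ktrans",
                             grid_spec = list(n = 31L))
  ci68 <- confidence_interval(prof, 0.68)
  ci80 <- confidence_interval(prof, 0.80)
  ci95 <- confidence_interval(prof, 0.95)
  expect_lte(ci95$lower, ci80$lower)
  expect_lte(ci80$lower, ci68$lower)
  expect_gte(ci95$upper, ci80$upper)
  expect_gte(ci80$upper, ci68$upper)
})

# construct a likelihood_profile object directly to exercise the
# classification logic on controlled shapes
fake_profile <- function(grid, pl, mle_ref = min(pl)) {
  structure(list(target = "ktrans", grid = grid, pl_values = pl,
                 co_params = matrix(numeric(0), length(grid), 0L),
                 theta_hat = pk_params(grid[which.min(pl)], 0.5, 0, 0),
                 kind = "LTK", mle_ref = mle_ref, config = fit_config(),
                 warnings = character(0)),
            class = "likelihood_profile")
}

test_that("classification separates identifiable, open, and flat shapes", {
  g <- seq(0.001, 0.01, length.out = 41L)

  parab <- fake_profile(g, 1e6 * (g - 0.005)^2)
  v <- classify(parab, 0.95)
  expect_identical(v$verdict, "identifiable")

  flat <- fake_profile(g, rep(0.01, 41L) + seq(0, 1e-4, length.out = 41L))
  v <- classify(flat, 0.95)
  expect_identical(v$verdict, "flat")
  ci <- confidence_interval(flat, 0.95)
  expect_false(any(ci$finite))
  # open sides are reported at the grid edges, never as silent sentinels
  expect_equal(ci$lower, min(g))
  expect_equal(ci$upper, max(g))

  # monotone rise: lower side open, upper side crossing located
  mono <- fake_profile(g, c(rep(0.02, 20L),
                            seq(0.02, 40, length.out = 21L)))
  ci <- confidence_interval(mono, 0.95)
  expect_false(ci$finite[["lower"]])
  expect_true(ci$finite[["upper"]])
  v <- classify(mono, 0.95)
  expect_identical(v$verdict, "practically_non_identifiable")
  expect_identical(v$open_sides, "lower")
})

test_that("compensating profiles trace co-parameter adjustment", {
  # use the noisy-input setting, where compensation is nearly perfect and
  # the decoupling structure shows cleanly (on noise-free data nothing can
  # compensate and every trace distorts)
  sc <- generate_scenario(scenario_spec("I", "RA_like", seed = 11L))
  cfg <- light_config(seed = 4L)
  fit <- fit_global(sc$ca, sc$vif, "LTK", cfg)

  cp <- compensating_profiles(sc$ca, sc$vif, "LTK", fit, "lam", n = 11L)
  expect_identical(colnames(cp$traces), c("ktrans", "ve", "vp"))
  # vp is decoupled from lam: its trace stays nearly flat ...
  expect_lt(diff(range(cp$traces[, "vp"])), 0.1 * fit$theta_hat$vp)
  # ... while ktrans and ve absorb the perturbation
  expect_gt(diff(range(cp$traces[, "ktrans"])), 0.2 * fit$theta_hat$ktrans)
  expect_gt(diff(range(cp$traces[, "ve"])), 0.2 * fit$theta_hat$ve)

  # varying Ktrans: ve and lam compensate, vp again stays put
  cp2 <- compensating_profiles(sc$ca, sc$vif, "LTK", fit, "ktrans", n = 11L)
  expect_lt(diff(range(cp2$traces[, "vp"])), 0.15 * fit$theta_hat$vp)
  expect_gt(diff(range(cp2$traces[, "ve"])), 0.2 * fit$theta_hat$ve)
  expect_gt(diff(range(cp2$traces[, "lam"])), 0.2 * fit$theta_hat$lam)

  # a single-parameter model has an empty co-set
  toy <- linear_toy()
  toyfit <- fit_global(toy$data, toy$vif, "PM", toy$config)
  cp0 <- compensating_profiles(toy$data, toy$vif, "PM", toyfit, "ktrans",
                               n = 5L, config = toy$config)
  expect_identical(ncol(cp0$traces), 0L)
})

test_that("profile and verdict outputs serialize", {
  toy <- linear_toy()
  fit <- fit_global(toy$data, toy$vif, "PM", toy$config)
  prof <- profile_likelihood(toy$data, toy$vif, "PM", fit, "ktrans",
                             grid_spec = list(n = 11L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), length(prof$grid))
  expect_equal(back$pl, prof$pl_values, tolerance = 1e-9)

  v <- classify(prof, 0.95)
  js <- jsonlite::fromJSON(verdict_json(v))
  expect_identical(js$verdict, v$verdict)
  expect_equal(js$level, 0.95)
})
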