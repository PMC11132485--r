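test_that("mle_objective implements the scaled least-squares form", {
  t <- c(0, 1)
  data <- sampled_signal(t, c(0, 2))
  vif <- sampled_signal(t, c(0, 0))
  p0 <- pk_params(0, 0.5, 0, 0)  # model curve identically zero

  # single informative point: ((2-0)/0.5)^2 ... with sigma=0.5 -> 4/0.25
  expect_equal(mle_objective(p0, data, vif, "LTK", sigma = 0.5),
               (2 - 0)^2 / 0.5^2)
  # doubling sigma divides the objective by 4
  o1 <- mle_objective(p0, data, vif, "LTK", sigma = 0.1)
  o2 <- mle_objective(p0, data, vif, "LTK", sigma = 0.2)
  expect_equal(o1 / o2, 4, tolerance = 1e-12)

  # data generated by the model evaluate to zero
  vif2 <- aa_vif()
  p <- reference_params("I", "AA")
  ca <- ct_ltk(vif2, p)
  expect_equal(mle_objective(p, ca, vif2, "LTK", 0.05), 0)

  expect_error(mle_objective(p, ca, vif2, "LTK", 0), "positive")
  bad <- sampled_signal(vif2$times[-1], ca$values[-1])
  expect_error(mle_objective(p, bad, vif2, "LTK", 0.05), "grid")
})

test_that("estimate_sigma inverts the data SNR with a noise-free fallback", {
  # noise-free synthetic curve: zero baseline SD -> configured default
  expect_equal(estimate_sigma(aa_curve("I"), 3L, default_sigma = 0.07), 0.07)

  # constructed curve: baseline SD 0.1, peak enhancement 2.0 -> sigma 0.05
  base <- c(-0.1, 0.1, -0.1, 0.1)  # SD = 0.11547, mean 0
  vals <- c(base, 2.0, 1.5)
  s <- sampled_signal(seq_along(vals) - 1, vals)
  expect_equal(estimate_sigma(s, 4L), stats::sd(base) / 2.0)

  expect_error(estimate_sigma(s, 1L), "baseline")

  # Monte-Carlo: known noise SD recovered within 30% at n_baseline = 10
  peak <- 2; sigma0 <- 0.04
  ests <- sapply(1:200, function(sd) {
    set.seed(sd)
    vals <- c(stats::rnorm(10, 0, sigma0), rep(peak, 5))
    estimate_sigma(sampled_signal(0:14, vals), 10L) })
  expect_equal(mean(ests), sigma0 / peak, tolerance = 0.3)
})

test_that("global fit recovers the generating parameters on clean data", {
  fit <- aa_fit_typeI()
  truth <- reference_params("I", "AA")
  rel <- abs(as.numeric(fit$theta_hat) - as.numeric(truth)) /
    as.numeric(truth)
  expect_lt(max(rel), 0.01)
  expect_lt(fit$objective_value, 1e-10)

  # the located optimum clearly beats a 10% perturbation of the truth
  perturbed <- pk_params(truth$ktrans * 1.1, truth$ve * 1.1,
                         truth$vp * 1.1, truth$lam * 1.1)
  obj_pert <- mle_objective(perturbed, aa_curve("I"), aa_vif(), "LTK", 0.05)
  expect_lt(fit$objective_value, 1e-6 * obj_pert)
})

test_that("fit is reproducible and sigma only rescales the objective", {
  ca <- aa_curve("I"); vif <- aa_vif()
  f1 <- fit_global(ca, vif, "LTK", light_config(seed = 11L))
  f2 <- fit_global(ca, vif, "LTK", light_config(seed = 11L))
  expect_identical(as.numeric(f1$theta_hat), as.numeric(f2$theta_hat))

  f3 <- fit_global(ca, vif, "LTK", light_config(seed = 11L, sigma = 0.1))
  expect_equal(as.numeric(f3$theta_hat), as.numeric(f1$theta_hat),
               tolerance = 1e-4)
})

test_that("degenerate purely vascular data is fit exactly by eTK", {
  # data = vp * Cp has two objective-equivalent explanations inside the
  # search box: a purely vascular one (Ktrans ~ 0, vp = 0.1) and a
  # fast-exchange one (Kep >> 1/dt, where the EES term collapses to
  # ve * Cp).  The fit must reproduce the curve exactly either way, and the
  # total instantaneous fraction must equal the generating vp.
  vif <- aa_vif()
  data <- sampled_signal(vif$times, 0.1 * vif$values)
  fit <- fit_global(data, vif, "eTK", light_config(seed = 3L))
  expect_lt(fit$objective_value, 1e-8)
  model <- ct_etk(vif, fit$theta_hat)
  expect_equal(model$values, data$values, tolerance = 1e-5)
  kep_dt <- fit$theta_hat$ktrans / fit$theta_hat$ve * 6.03
  instantaneous <- fit$theta_hat$vp +
    if (kep_dt > 5) fit$theta_hat$ve else 0
  expect_equal(instantaneous, 0.1, tolerance = 0.01)
})

test_that("restart seeds land on the same optimum on clean Type I data", {
  ca <- aa_curve("I"); vif <- aa_vif()
  truth <- reference_params("I", "AA")
  hits <- sapply(1:10, function(s) {
    fit <- fit_global(ca, vif, "LTK",
                      fit_config(swarm = 25L, iters = 200L, restarts = 1L,
                                 seed = s))
    max(abs(as.numeric(fit$theta_hat) - as.numeric(truth)) /
          as.numeric(truth))
  })
  expect_gte(sum(hits < 0.01), 9L)
})

test_that("bounds with lower == upper pin a parameter out of the search", {
  vif <- aa_vif()
  truth <- pk_params(0.009, 0.5, 0, 0)
  data <- ct_tk(vif, truth)
  b <- default_bounds()
  b$ve <- c(0.5, 0.5)
  fit <- fit_global(data, vif, "TK",
                    fit_config(bounds = b, swarm = 20L, iters = 100L,
                               restarts = 1L, seed = 2L))
  expect_identical(fit$free, "ktrans")
  expect_equal(fit$theta_hat$ve, 0.5)
  expect_equal(fit$theta_hat$ktrans, 0.009, tolerance = 1e-4)
})

test_that("fit results serialize to JSON", {
  js <- jsonlite::fromJSON(fit_result_json(aa_fit_typeI()))
  expect_equal(js$kind, "LTK")
  expect_true(js$objective_value >= 0)
  expect_equal(sort(js$free), sort(active_params("LTK")))
})
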