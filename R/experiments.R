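#' Fit study across models, curve types, and cases
#'
#' Fits the requested model kinds to synthetic scenarios for every
#' combination of enhancement-curve type and study case, one row per
#' combination.  Failures in individual scenarios are recorded in the row
#' and do not abort the run.
#'
#' @param types Curve types to include.
#' @param cases Study cases to include (`"AA"`, `"RA_like"`, `"RR_like"`).
#' @param kinds Model kinds to fit.
#' @param seed Master seed.
#' @param config A [fit_config()] template; its seed is re-derived per row.
#' @return A data.frame with the scenario labels, fitted parameters,
#'   generating truth, objective value, and an `error` column (NA on
#'   success).
#' @export
run_fit_study <- function(types = c("I", "II", "III"), cases = "AA",
                          kinds = "LTK", seed = 1L,
                          config = fit_config()) {
  rows <- list()
  i <- 0L
  for (case in cases) for (type in types) for (kind in kinds) {
    i <- i + 1L
    row <- data.frame(case = case, type = type, kind = kind,
                      ktrans = NA_real_, ve = NA_real_, vp = NA_real_,
                      lam = NA_real_, objective = NA_real_,
                      true_ktrans = NA_real_, true_ve = NA_real_,
                      true_vp = NA_real_, true_lam = NA_real_,
                      seed = NA_integer_, error = NA_character_,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      spec <- scenario_spec(type, case, seed = derive_seed(seed, i))
      sc <- generate_scenario(spec)
      sigma <- estimate_sigma(sc$ca, n_baseline = spec$grid$n_baseline,
                              default_sigma = config$sigma)
      cfg <- config
      cfg$sigma <- sigma
      cfg$seed <- derive_seed(seed, 100L + i)
      fit <- fit_global(sc$ca, sc$vif, kind, cfg)
      th <- fit$theta_hat
      row[c("ktrans", "ve", "vp", "lam")] <-
        c(th$ktrans, th$ve, th$vp, th$lam)
      row$objective <- fit$objective_value
      row[c("true_ktrans", "true_ve", "true_vp", "true_lam")] <-
        as.numeric(as.numeric(sc$truth))
      row$seed <- cfg$seed
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[i]] <- res
  }
  if (length(rows) == 0L)
    return(data.frame(case = character(0), type = character(0),
                      kind = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# highest level in `levels` whose CI is finite on both sides; 0 if none
highest_finite_level <- function(profile, levels = c(0.68, 0.80, 0.95)) {
  finite <- vapply(levels, function(lv)
    all(confidence_interval(profile, lv)$finite), logical(1L))
  if (!any(finite)) 0 else max(levels[finite])
}

majority_value <- function(x) {
  tb <- table(x)
  as.numeric(names(tb)[which.max(tb)])  # ties resolve to the smaller value
}

noise_ladder_one <- function(level, seed, type, config, grid, vif_params,
                             target) {
  truth <- reference_params(type, "AA")
  vif_clean <- parker_vif_signal(grid, vif_params)
  ca <- ct_ltk(vif_clean, truth)          # data stay noise-free
  vif_fit <- if (level > 0)
    add_vif_noise(vif_clean, level, seed = seed) else vif_clean
  cfg <- config
  cfg$seed <- derive_seed(seed, 3L)
  fit <- fit_global(ca, vif_fit, "LTK", cfg)
  # The thresholds need sigma = the noise level actually visible in this
  # rung's data-model pairing.  The curve itself is noise-free (its baseline
  # SD is 0), so the observable noise is the residual left by the best fit:
  # sigma^2 = SSR(theta_hat)/N, the maximum-likelihood variance estimate.
  # The profile statistic then is N*(SSR(theta)/SSR(theta_hat) - 1), the
  # standard unknown-variance likelihood-ratio form: a perfect fit gives an
  # arbitrarily steep profile, and growing input noise genuinely flattens
  # it instead of inflating it against a fixed threshold.
  n <- length(ca$times)
  resid_sd <- sqrt(fit$objective_value * cfg$sigma^2 / n)
  cfg_pl <- cfg
  cfg_pl$sigma <- max(resid_sd, 1e-12)
  prof <- profile_likelihood(ca, vif_fit, "LTK", fit, target,
                             config = cfg_pl)
  list(fit = fit, profile = prof)
}

#' Input-noise ladder: identifiability versus VIF noise
#'
#' Reproduces the graded input-noise study: the tissue curve is the clean
#' Type I forward simulation, while the input function handed to the fitter
#' carries per-element Gaussian noise of amplitude 0/5/10/15% of the clean
#' input.  For each level and noise seed the model is refit, the target
#' parameter profiled, and the highest confidence level (among 68/80/95%)
#' with a finite two-sided interval recorded; a per-level majority verdict
#' over seeds is reported alongside the per-seed detail.
#'
#' @param levels Noise amplitudes as fractions.
#' @param n_seeds Noise realizations per level.
#' @param type Curve type (default `"I"`).
#' @param target Profiled parameter (default `"ktrans"`).
#' @param seed Master seed.
#' @param config A [fit_config()] template.
#' @param grid Acquisition grid.
#' @param vif_params Parker constants.
#' @return List with `detail` (per level x seed data.frame) and `summary`
#'   (per level: majority highest finite level, fraction of seeds with a
#'   finite 95% interval).
#' @export
run_noise_ladder <- function(levels = c(0, 0.05, 0.10, 0.15), n_seeds = 10L,
                             type = "I", target = "ktrans", seed = 1L,
                             config = fit_config(),
                             grid = default_time_grid(),
                             vif_params = parker_vif_params()) {
  detail <- list()
  k <- 0L
  for (lv in levels) {
    seeds_here <- if (lv == 0) 1L else n_seeds  # level 0 is deterministic
    for (s in seq_len(seeds_here)) {
      k <- k + 1L
      run <- noise_ladder_one(lv, derive_seed(seed, 17L * k), type, config,
                              grid, vif_params, target)
      hi <- highest_finite_level(run$profile)
      v95 <- classify(run$profile, 0.95)
      detail[[k]] <- data.frame(
        level = lv, seed_index = s,
        ktrans_hat = run$fit$theta_hat$ktrans,
        objective = run$fit$objective_value,
        highest_finite = hi, finite95 = hi >= 0.95,
        verdict95 = v95$verdict, stringsAsFactors = FALSE)
    }
  }
  detail <- do.call(rbind, detail)
  summary <- do.call(rbind, lapply(split(detail, detail$level), function(d) {
    data.frame(level = d$level[1L],
               majority_highest_finite = majority_value(d$highest_finite),
               frac_finite95 = mean(d$finite95),
               n_seeds = nrow(d))
  }))
  rownames(summary) <- NULL
  summary <- summary[order(summary$level), ]
  list(detail = detail, summary = summary)
}

#' Smoothing ladder: identifiability versus data smoothing
#'
#' Reproduces the data-smoothing study on the fully noisy surrogate
#' scenario: an RR-like Type I curve (noisy input and noisy tissue curve)
#' is smoothed with the moving-average operator at increasing smoothing
#' factors before fitting and profiling.  Stronger smoothing reduces the
#' effective data noise, so the profile steepens and identifiability can be
#' recovered at low confidence levels.
#'
#' @param gammas Smoothing factors in \[0, 1\].
#' @param n_seeds Noise realizations per factor.
#' @param type Curve type.
#' @param target Profiled parameter.
#' @param seed Master seed.
#' @param config A [fit_config()] template.
#' @param ca_snr SNR of the surrogate tissue-curve noise.
#' @param vif_noise Amplitude of the surrogate input noise.
#' @return List with `detail` and per-gamma `summary` (majority highest
#'   finite level, mean profile variation).
#' @export
run_smoothing_ladder <- function(gammas = c(0, 0.05, 0.10, 0.15),
                                 n_seeds = 10L, type = "I",
                                 target = "ktrans", seed = 1L,
                                 config = fit_config(), ca_snr = 20,
                                 vif_noise = 0.10) {
  detail <- list()
  k <- 0L
  for (g in gammas) for (s in seq_len(n_seeds)) {
    k <- k + 1L
    spec <- scenario_spec(type, "RR_like", vif_noise = vif_noise,
                          ca_snr = ca_snr, seed = derive_seed(seed, 23L * s))
    sc <- generate_scenario(spec)
    data_s <- smooth_moving_average(sc$ca, g)
    sigma <- estimate_sigma(data_s, n_baseline = spec$grid$n_baseline,
                            default_sigma = config$sigma)
    cfg <- config
    cfg$sigma <- sigma
    cfg$seed <- derive_seed(seed, 29L * k)
    row <- data.frame(gamma = g, seed_index = s, ktrans_hat = NA_real_,
                      highest_finite = NA_real_, verdict95 = NA_character_,
                      pl_variation = NA_real_, error = NA_character_,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      fit <- fit_global(data_s, sc$vif, "LTK", cfg)
      prof <- profile_likelihood(data_s, sc$vif, "LTK", fit, target)
      row$ktrans_hat <- fit$theta_hat$ktrans
      row$highest_finite <- highest_finite_level(prof)
      row$verdict95 <- classify(prof, 0.95)$verdict
      row$pl_variation <- max(prof$pl_values) - min(prof$pl_values)
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    detail[[k]] <- res
  }
  detail <- do.call(rbind, detail)
  summary <- do.call(rbind, lapply(split(detail, detail$gamma), function(d) {
    ok <- is.na(d$error)
    data.frame(gamma = d$gamma[1L],
               majority_highest_finite =
                 if (any(ok)) majority_value(d$highest_finite[ok]) else NA,
               frac_flat95 = mean(d$verdict95[ok] == "flat"),
               mean_pl_variation = mean(d$pl_variation[ok]),
               n_ok = sum(ok))
  }))
  rownames(summary) <- NULL
  summary <- summary[order(summary$gamma), ]
  list(detail = detail, summary = summary)
}
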