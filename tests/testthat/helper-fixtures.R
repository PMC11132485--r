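# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

aa_grid <- function() fixture("grid", function() default_time_grid())

aa_vif <- function() fixture("vif", function() parker_vif_signal(aa_grid()))

aa_curve <- function(type = "I") {
  fixture(paste0("ca_", type), function()
    ct_ltk(aa_vif(), reference_params(type, "AA")))
}

# a light configuration for unit tests; acceptance tests use the defaults
light_config <- function(seed = 1L, sigma = 0.05) {
  fit_config(swarm = 25L, iters = 200L, restarts = 2L, seed = seed,
             sigma = sigma)
}

# global LTK fit of the clean Type I curve, reused across test files
aa_fit_typeI <- function() {
  fixture("fit_typeI", function()
    fit_global(aa_curve("I"), aa_vif(), "LTK", light_config()))
}

# random admissible kinetic parameters, away from the ve singularity
random_pk <- function(n, seed = 123L) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    pk_params(ktrans = 10^stats::runif(1, -4, -1),
              ve = stats::runif(1, 0.05, 1),
              vp = stats::runif(1, 0, 0.5),
              lam = 10^stats::runif(1, -4, -1)))
}
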