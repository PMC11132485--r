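# dceident

Structural and practical identifiability analysis for the nested family of
contrast-agent transport models used with dynamic contrast-enhanced MRI
(DCE-MRI): Patlak (PM), Tofts–Kety (TK), extended Tofts–Kety (eTK), and
Leaky Tofts–Kety (LTK).

DCE-MRI transport models compress a tissue concentration time course
$C_t(t)$, driven by a vascular input function (VIF) $C_p(t)$, into kinetic
parameters with clinical meaning: the forward transfer constant $K^{trans}$
(1/s), the fractional EES volume $v_e$, the fractional plasma volume $v_p$,
and (LTK only) a unidirectional leakage rate $\lambda$ (1/s).  The package
answers two questions about these parameters:

* **Structural identifiability** — the LTK model reduces to one ODE in the
  observable, $\dot y + a_1 y + a_2 u + a_3 \dot u + a_4 v = 0$ (with $u$
  the input and $v$ its running integral), whose coefficients invert in
  closed form to the kinetic parameters
  ($K^{trans} = a_4/a_1 - a_1 - a_2$, $v_p = -a_3$,
  $\lambda = -a_4/a_1$, $v_e = \sqrt{a_4/a_1^2 - 1 - a_2/a_1}$).
  The inversion is implemented, and the round-trip identity is verified to
  $10^{-10}$ over random parameter draws.
* **Practical identifiability** — profile likelihoods
  $PL(\theta_i)=\min_{\theta_{j\neq i}}\sigma^{-2}\sum_k(y_k^D-y_k^M)^2$
  with chi-squared (1 df) confidence intervals at 68/80/95%, verdict
  classification (identifiable / practically non-identifiable / flat), and
  compensating-profile traces, driven by particle-swarm global fits.

Everything runs on synthetic data: an analytic population VIF (two
Gaussians plus a sigmoid-gated exponential), forward simulations of the
three canonical enhancement archetypes (persistent / plateau / wash-out),
graded VIF-noise injection, tissue-curve noise, and moving-average
smoothing.  Two perturbation studies — the input-noise ladder and the
smoothing ladder — quantify how noise destroys, and smoothing restores,
practical identifiability.

## Worked example

```r
library(dceident)

grid  <- default_time_grid()            # 32 frames at 6.03 s + 3 baseline
vif   <- parker_vif_signal(grid)        # analytic VIF, peak ~6 mM
truth <- reference_params("I", "AA")    # persistent-curve parameter row
ca    <- ct_ltk(vif, truth)             # noise-free forward simulation

fit <- fit_global(ca, vif, "LTK", fit_config(seed = 1))
fit
#> fit_result (LTK): objective 2.93234e-18
#> pk_params: Ktrans=0.0025 1/s, ve=0.9, vp=0.05, lambda=0.01 1/s (Kep=0.002778)

prof <- profile_likelihood(ca, vif, "LTK", fit, "ktrans")
classify(prof, 0.95)
confidence_interval(prof, 0.80)
```

The fit recovers the generating parameters (`Ktrans = 0.0025` 1/s,
`ve = 0.9`, `vp = 0.05`, `lambda = 0.01` 1/s) to around eight significant
digits with an objective at numerical zero — the structural-identifiability
promise made concrete.  The profile likelihood then shows what noise-free
data of this length can and cannot pin down at each confidence level.

The perturbation studies are one call each:

```r
run_noise_ladder(levels = c(0, 0.05, 0.10, 0.15), n_seeds = 10, seed = 1)
run_smoothing_ladder(gammas = c(0, 0.05, 0.10, 0.15), n_seeds = 10, seed = 1)
```

Each returns per-seed detail plus a per-rung majority verdict: the highest
confidence level at which the $K^{trans}$ profile still closes a finite
two-sided interval.

See `vignettes/identifiability.Rmd` for the full model and methods account,
including every numerical convention (noise scale $\sigma$, profile grids,
flatness threshold, smoothing window rule) and known limitations.

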