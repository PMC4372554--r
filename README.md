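# tdfmix

Bayesian stable isotope mixing models (SIMMs) for diet reconstruction, with
the two questions a controlled feeding study lets you ask of the same model:

* **What are the trophic discrimination factors (TDFs)?** When the diet is
  known (a captive consumer fed recorded prey), estimate the per-isotope
  offset between consumer tissue and diet.
* **How much prior information does a SIMM need?** When TDFs are given,
  estimate diet proportions under a gradient of Dirichlet priors, find the
  *minimum informative prior* whose posterior is statistically
  indistinguishable from a reference diet, and quantify bias, precision, and
  accuracy of the posterior against that reference.

The motivating system is a captive gray wolf colony fed white-tailed deer,
beaver, and Canada goose, with δ¹³C and δ¹⁵N measured in prey muscle and
wolf hair; all of the package's machinery is general over K sources and J
isotopes.

## The model

For consumer *i* and isotope *j*, with K sources,

```
X_ij = Σ_k p_k (s_jk + c_j) + ε_ij
s_jk ~ Normal(μ_jk, ω_jk²),  p ~ Dirichlet(α),  ε_ij ~ Normal(0, σ_j²)
```

so marginally `X_ij ~ Normal( Σ_k p_k (μ_jk + c_j),
Σ_k p_k² (ω_jk² + τ_j²) + σ_j² )`, where `τ_j` is the SD of the TDF `c_j`.
`simm()` samples this posterior in two modes:

* **diet mode** — `p` is the target; `c_j`, `τ_j` are fixed at a supplied
  TDF set and `p` carries a Dirichlet(α) prior;
* **tdf mode** — `c_j` is the target under vague Uniform(0, 10) priors; `p`
  carries the (informative) Dirichlet fitted to the known diet, and τ = 0.

Residual SDs `σ_j` get Uniform(0, 10) priors in both modes (removable with
`residual = FALSE`). Sampling is adaptive Metropolis-within-Gibbs — a random
walk on the softmax-transformed simplex for `p`, Gaussian random walks for
`c_j` and `log σ_j` — with convergence monitored by the Gelman–Rubin PSRF.

Around the model sit the rest of the pipeline stages:
`bootstrap_diet()` (diet composition from feeding records with per-item
masses drawn uniformly from literature ranges), `fit_dirichlet_mle()`
(maximum-likelihood Dirichlet for the bootstrap draws),
`equivalence_test()` / `candidate_schedule()` / `minimum_informative_prior()`
(the stepwise prior search), `evaluate_posterior()` / `compare_models()`
(bias, Monte-Carlo variance, MSE = variance + bias²), a synthetic-data
generator matching the model's generative assumptions, and the drivers
`run_captive_study()` / `run_field_study()`.

## Worked example

Estimate the captive diet from feeding records, then the wolf TDFs:

```r
library(tdfmix)
inp <- captive_study_inputs()   # published summaries: Table-style inputs

rec  <- generate_feeding_records(inp$counts, inp$window,
                                 inp$n_consumers, seed = 1)
diet <- bootstrap_diet(rec, inp$mass_ranges,
                       cutoff_date = inp$cutoff_date, B = 1000, seed = 2)
diet
#> Bootstrap diet estimate (1000 iterations, 241 items)
#>        deer beaver goose
#> mean  0.944  0.019 0.037
#> sd    0.003  0.002 0.001
#> 2.5%  0.938  0.015 0.034
#> 97.5% 0.950  0.023 0.040

cons <- simulate_consumers(inp$consumer_summary, 10, seed = 3)
fit <- simm(inp$sources, cons, mode = "tdf", diet = inp$diet_alpha,
            mcmc = mcmc_control(burn_in = 10000, n_samples = 5000, thin = 5),
            seed = 4)
summary(fit)
#>    parameter  mean    sd lower95 upper95  psrf
#>      p[deer] 0.939 0.010   0.919   0.957 1.000
#>    p[beaver] 0.021 0.006   0.011   0.034 1.001
#>     p[goose] 0.040 0.008   0.026   0.057 1.000
#>      c[d13C] 1.849 0.719   0.472   3.273 1.000
#>      c[d15N] 2.889 0.321   2.247   3.517 1.000
#>  sigma[d13C] 0.670 0.559   0.022   2.120 1.002
#>  sigma[d15N] 0.302 0.250   0.010   0.954 1.000
```

The wolves ate almost pure deer (94% by bootstrapped biomass), and the
posterior discrimination factors for this simulated cohort are about 1.85‰
(δ¹³C) and 2.89‰ (δ¹⁵N) — each cohort of 10 consumers is simulated from the
published hair summary, so single-cohort estimates scatter around the
~1.97 / ~3.04 values recovered on average. All PSRFs are below 1.1, so the
three chains agree.

Diet mode under a non-informative prior shows why priors matter here:

```r
flat <- dirichlet_spec(c(deer = 1, beaver = 1, goose = 1))
dfit <- simm(inp$sources, cons, mode = "diet", tdf = inp$tdf_fox,
             prior = flat,
             mcmc = mcmc_control(burn_in = 10000, n_samples = 5000, thin = 5),
             seed = 5)
evaluate_posterior(dfit, inp$diet_alpha, n = 1000,
                   seed = 6)[, c("source", "mean", "bias", "variance", "mse")]
#>   source mean  bias variance   mse
#> 1   deer 0.52 -0.42   0.0072 0.183
#> 2 beaver 0.25  0.23   0.0111 0.063
#> 3  goose 0.23  0.19   0.0134 0.050
```

With fox TDFs and a flat prior the posterior puts only ~52% on deer —
biased low by ~0.4 against the estimated diet. `minimum_informative_prior()`
walks the candidate schedule until the equivalence test passes.

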