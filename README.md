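# dwellmix

Kinetic analysis of single-molecule binding events and mRNA decay, built
around the truncated exponential-mixture maximum-likelihood method used in
single-molecule TIRF co-localization assays of RNA–protein binding (such
as Hfq/Crc binding to the *Pseudomonas aeruginosa* *amiE* mRNA).

A dwell time is the duration of one observed binding event between a
labelled RNA and an immobilized protein. With several kinetic classes of
complexes present, un-binned dwell times follow an exponential mixture,
observed only inside the window set by the camera (minimum resolvable
interval *t*<sub>m</sub>, recording length *t*<sub>x</sub>):

    f(t) = [ Σ_k (a_k/τ_k) exp(−t/τ_k) ]
           / [ Σ_k a_k (exp(−t_m/τ_k) − exp(−t_x/τ_k)) ]

The package provides:

* **Simulation** of dwell-time data with frame quantization, window
  truncation and competing Cy5 photobleaching (`simulate_dwells()`), of
  intensity traces with planted events (`simulate_traces()`), and of
  normalized mRNA decay time courses (`simulate_decay()`);
* **Event calling** from intensity traces with explicit threshold and gap
  rules (`call_events()`);
* **Maximum-likelihood fitting** of the truncated K-exponential mixture
  with multi-start optimization (`fit_mixture()`) and BIC model selection
  (`select_K()`);
* **Uncertainty**: bootstrap standard errors (`bootstrap_fit()`), error
  propagation for the residual amplitude (`propagate_residual_sigma()`),
  binomial histogram error bars (`histogram_bar_sigma()`), and two-tailed
  unpaired condition comparisons (`compare_conditions()`);
* **Half-life estimation** for rifampicin-chase experiments: 16S-reference
  normalization, the exponential-trendline estimator *t*½ = ln2/*k*, the
  linear-trendline fallback *t*½ = 50/*k**, and an automatic choice
  between them (`normalize_to_reference()`, `fit_first_order()`,
  `fit_linear()`, `choose_method()`);
* **Figures**: rastergrams, dwell-time survival curves, decay curves.

The `analysis/` directory holds the numbered workflow scripts
(`01_simulate_dwells.R` … `06_figures.R`) that run the whole study on
synthetic data and write tables and figures under `results/`.

## Worked example

Simulate dwell times at the two-state operating point of the assay
(weights 0.56/0.44 on lifetimes 2 s/60 s, 0.1 s frames, 180 s window),
fit the truncated mixture, and compare the stable-complex amplitude with
the Crc-shifted condition:

```r
library(dwellmix)

models <- study_models()
w      <- obs_window(0.1, 180)

d  <- simulate_dwells(models$amiE102, w, sim_config(5000, seed = 42))
f  <- fit_mixture(d, K = 2)
f
#> Truncated exponential-mixture fit (K = 2, n = 4758 events)
#> Exponential mixture model (K = 2)
#>  component   weight lifetime_s
#>          1 0.558397    2.08596
#>          2 0.441603   64.75690
#>   log-likelihood -17265.1903 | BIC 34555.78 | converged: TRUE
```

The fit recovers the generating parameters: ~56% of events are unstable
complexes with a ~2 s lifetime, ~44% stable complexes near 60 s (the
upward drift of the long lifetime reflects its truncation by the 180 s
window at finite n). Bootstrap errors and the between-condition test:

```r
b  <- bootstrap_fit(d, K = 2, n_boot = 1000, seed = 1)

dC <- simulate_dwells(models$amiE102_Crc, w, sim_config(5000, seed = 43))
bC <- bootstrap_fit(dC, K = 2, n_boot = 1000, seed = 1)

a  <- subset(b$summary,  parameter == "a2")   # stable fraction, no Crc
aC <- subset(bC$summary, parameter == "a2")   # stable fraction, with Crc
compare_conditions(a$estimate, a$sigma, aC$estimate, aC$sigma,
                   parameter = "a_long", labels = c("no_Crc", "Crc"))
#> a_long: no_Crc = 0.4416 vs Crc = 0.6883 | z = -20.05 | two-tailed p = 2.208e-89 *
```

The stable-complex fraction rises from ~0.44 to ~0.69 in the presence of
Crc — the kinetic signature of Crc locking Hfq onto the RNA — and the
shift is overwhelmingly significant at these event counts.

Half-lives from decay series:

```r
fit_first_order(simulate_decay(1.7, 0:8, "first_order"))
#> Half-life (first_order): t1/2 = 1.7 min | rate = 0.4077 1/min | R^2 = 1.0000 (n = 9)
fit_linear(simulate_decay(10.4, 0:8, "linear"))
#> Half-life (linear): t1/2 = 10.4 min | rate = 4.808 %/min | R^2 = 1.0000 (n = 9)
```

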