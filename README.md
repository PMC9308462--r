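# naresflow

Breath-by-breath respiration metrics for rorqual whales from animal-borne
video tags.

Suction-cup tags with surface-facing cameras record a whale's nares
(blowholes) during every surfacing. The aperture area of the open nares on
each video frame is a relative proxy for instantaneous airflow, and its time
series over one inhalation carries far more information than a simple breath
count. `naresflow` is a tested pipeline for that analysis:

* **Per-breath metrics** — inhalation duration, maximum nares area, and the
  integrated area

  $$IA = \sum_{i=1}^{n-1} \frac{A_i + A_{i+1}}{2}\,(t_{i+1} - t_i)
  \quad \text{(px·s)},$$

  the trapezoid time-integral of frame area $A_i$ over the frame timestamps
  $t_i$, with per-whale normalization (camera placement makes raw areas
  incomparable across whales) and an every-frame vs every-other-frame
  sensitivity check.
* **Dive segmentation** — submersions longer than 90 s are dives, shorter
  ones inter-breath intervals (IBIs); the threshold is also derivable from
  the bimodal log-duration distribution as the geometric midpoint of a
  two-component Gaussian mixture on log durations.
* **Surface sequences and breath types** — breaths between two dives form a
  sequence (IBIs do not split it); the first breath after a dive is
  *initial*, the last before a dive *terminal*, the rest *middle*.
* **Lunge detection** — feeding lunges from 10-Hz speed and jerk (norm of
  the acceleration first difference per unit time): a >3 m/s speed peak
  with ≥50% deceleration within 5 s and a ≥20 m/s³ jerk transient.
* **Statistics** — maximum-likelihood GLMMs with whale-level random
  intercepts (gamma/log for durations, beta/logit for normalized areas,
  Poisson/log for breath counts), Bonferroni-corrected pairwise breath-type
  contrasts on the link scale, second-degree polynomial dive-effort models
  compared by AIC, Wald 95% intervals, and paired t-tests.
* **Synthetic deployments** — a generator with known ground truth (lognormal
  duration mixture, trapezoidal expansion curves, injected lunges,
  multiplicative breath-type effects) so every stage has a
  parameter-recovery test.

## Worked example

```r
library(naresflow)

cfg <- naresflow_config(seed = 7)
manifest <- run_pipeline(cfg, out_dir = "run1",
                         simulate_args = list(n_whales = 6, hours = 3))
res <- attr(manifest, "results")
res$fits$duration
#> <model_fit> duration ~ breath_type + (1 | whale_id)
#>   family: gamma(link = log), ML/Laplace
#>   n = 853 observations, groups: whale_id=6
#>   AIC = -789.256, logLik = 399.628
#>
#>                 term  estimate      se    ci_lo    ci_hi        z          p
#>          (Intercept) -0.439047 0.14375 -0.72079 -0.15730 -3.05428  2.256e-03
#>    breath_typemiddle  0.001765 0.01905 -0.03556  0.03909  0.09266  9.262e-01
#>  breath_typeterminal  0.701250 0.02403  0.65415  0.74835 29.18415 3.081e-187
```

`exp(0.70125) = 2.02`: terminal breaths are twice as long as initial
breaths, recovering the generator's true multiplier of 2. The contrast table
(`res$contrasts`) flags both terminal pairs for all three metrics at the
Bonferroni-adjusted criterion of 0.05/3 and neither initial–middle pair,
and `res$effort$total_inhalation_duration$table` ranks the six dive-effort
models (previous/upcoming dive × duration/lunges/both) by AIC.

The pipeline writes tidy CSVs (`breaths.csv`, `sequences.csv`, `lunges.csv`,
`contrasts.csv`, `model_coefficients.csv`, `dive_effort_models.csv`) plus a
JSON run manifest with the config snapshot, seed, record counts and output
digests; identical seeds give byte-identical outputs.

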