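# cptddm

Drift-diffusion analysis of cued continuous performance task (CPT-AX) data
in developmental samples.

Children born very preterm are at elevated risk of inattention, but
standard reaction-time summaries (hit rate, mean RT, RT variability,
commission errors) confound the cognitive processes that produce them.
`cptddm` implements the full analysis chain for asking *which* process
relates to parent-rated inattention: it scores go/no-go performance on a
400-trial CPT-AX session, estimates the EZ diffusion model per child,
checks model fit by supersubject simulation, and runs the group-comparison
and individual-differences inference stage. A synthetic-cohort generator
produces trial-level data with the statistical structure such studies
assume (two groups, diffusion-generated go responses, drift rate coupled
to inattention), so every stage can be validated end to end against known
ground truth.

## The model

On each go trial, noisy evidence accumulates from an unbiased starting
point `a/2` at mean rate *v* (drift rate, information-processing
efficiency) until it reaches `a` (respond) or 0 (withhold); boundary
separation *a* indexes response caution, and nondecision time *Ter*
absorbs encoding and motor time. The EZ variant estimates (*v*, *a*,
*Ter*) in closed form from three per-child summaries — go-trial accuracy
*Pc*, mean correct RT, and variance of correct RT — via, with
*L* = logit(*Pc*) and scaling constant *s* = 0.1:

    v   = sign(Pc - 1/2) * s * [ L (L Pc^2 - L Pc + Pc - 1/2) / VRT ]^(1/4)
    a   = s^2 L / v
    Ter = MRT - (a / 2v) * (1 - y) / (1 + y),   y = exp(-v a / s^2)

The transform is exactly invertible (`ez_forward()`), which gives both a
machine-precision round-trip test and an analytic oracle for the Euler
first-passage simulator used in goodness of fit. Children with a 100% hit
rate have undefined parameters (logit(1) is infinite) and are excluded
rather than edge-corrected.

The inference stage mirrors the standard reporting for such designs:
Pillai-trace MANCOVA (Type-III) of seven performance measures on group
with age as covariate; age-partialed correlations between each measure and
parent-rated inattention, pooled and per group; Fisher r-to-z comparison
of the group correlations; hierarchical regression with group and age
forced and the task measures competing by p-to-enter/p-to-remove stepwise
entry; and a forced-entry regression adding group × measure interactions.

## Worked example

```r
library(cptddm)

cohort <- generate_cohort(cohort_config(), seed = 2)   # 33 VP + 32 term
trials <- simulate_cohort_trials(cohort, seed = 2)     # 400 trials/child
fit    <- ezddm(trials, cohort = cohort)
fit
#> EZ diffusion model fit: 65 children, 10 excluded (perfect_accuracy, chance_accuracy)
#>   mean v = 0.184, a = 0.106, Ter = 0.254 s (s = 0.1)

summary(fit)[c("group", "n", "hit_rate_pct", "mrt_ms", "v", "a", "ter")]
#>   group  n hit_rate_pct mrt_ms     v     a   ter
#> 1  term 26         81.2    466 0.174 0.107 0.248
#> 2    VP 29         83.4    472 0.193 0.106 0.259

goodness_of_fit(fit, n_trials = 1000, seed = 2)[
  c("group", "sim_accuracy_pct", "obs_accuracy_pct", "sim_mrt_ms", "obs_mrt_ms")]
#>   group sim_accuracy_pct obs_accuracy_pct sim_mrt_ms obs_mrt_ms
#> 1  term             85.4            81.25      458.7      465.8
#> 2    VP             86.7            83.45      466.5      471.5

tab <- cohort_table(fit)
partial_correlation(tab$swan_inattention, tab$v, controls = tab$age_years)
#> partial r = -0.273 (n = 54, 1 control), p = 0.04755

hierarchical_stepwise_regression(tab)
#> Model 1: R2 = 0.061 (dR2 = 0.061), F(2, 51) = 1.647, p = 0.2027, n = 54
#> ...
#> Model 2: R2 = 0.154 (dR2 = 0.093), F(3, 50) = 3.023, p = 0.03814, n = 54
#>     v                beta = -0.308  p = 0.02319
#> stepwise-retained candidates: v
```

Reading the output: ten of 65 simulated children scored at an accuracy
where EZ parameters are undefined and were excluded. Higher parent-rated
inattention goes with lower fitted drift after controlling age
(r = −0.27 here), and of the three competing task measures it is drift
rate that carries unique variance beyond group and age in this cohort.
Supersubject simulation at group-averaged parameters reproduces the
observed accuracy and mean RT to within a few points/milliseconds. With
only 40 go trials, drift, hit rate and RT variability are highly
intercorrelated, so in some replicate cohorts one of the other measures
wins the stepwise competition — `run_pipeline()` writes all of these
tables (plus MANCOVA, Fisher comparisons and a JSON manifest) for a full
deterministic run.

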