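---
title: "Methods: EZ diffusion modelling of CPT-AX performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EZ diffusion modelling of CPT-AX performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cptddm)
```

## The task and its scoring

The cued continuous performance task presents a continuous stream of
shapes, 250 ms each with a 1400 ms interstimulus interval, in four blocks
of 100 trials. A response is required only when the target immediately
follows the cue; each block contains 10 such go pairs, 10 cues without a
following target, 10 uncued targets and filler distractors, giving 40 go
and 360 no-go trials per session (a 10% go rate). Responses count from
stimulus onset up to the onset of the next stimulus, 1650 ms later.

`generate_trial_sequence()` reproduces this structure under minimal
pseudorandomisation constraints: fixed per-block category counts;
non-overlapping go pairs with at least two intervening trials between
consecutive pairs; and no cue ever immediately followed by a target
outside a designated go pair (including across block boundaries), so the
category labels and the stimulus stream never disagree. Nothing else about
the order is constrained — published task descriptions rarely specify
more, and none of the analyses here depend on finer ordering structure.
All children in a simulated cohort receive the same sequence, as in a
fixed-order administration.

Scoring uses one hit definition throughout: a go trial responded to
between 200 and 1650 ms from target onset. Sub-200 ms responses are
treated as anticipations and count as misses — they are removed from the
accuracy numerator, not merely from the RT pool, so the accuracy entering
the diffusion fit and the reported hit rate can never disagree. RT
variability is the sample (n − 1) standard deviation over hit RTs.
Commission errors are counted over all 360 no-go trials without subtype
breakdown; empirically their rates are too low to support one.

## The EZ diffusion model

For a participant with go-trial accuracy $P_c$, mean correct RT $M_{RT}$
(seconds) and correct-RT variance $V_{RT}$ (s²), the EZ transform with
logit $L = \ln\!\frac{P_c}{1-P_c}$ and scaling constant $s$ gives

$$v = \operatorname{sign}(P_c - \tfrac12)\, s
      \left[\frac{L\,(L P_c^2 - L P_c + P_c - \tfrac12)}{V_{RT}}\right]^{1/4},
\qquad a = \frac{s^2 L}{v},$$

$$T_{er} = M_{RT} - \frac{a}{2v}\cdot\frac{1-y}{1+y},
\qquad y = e^{-va/s^2}.$$

The model assumes an unbiased starting point ($a/2$) and no cross-trial
parameter variability; it is exactly identified, so `ez_forward()` is its
exact inverse and within-sample moment residuals are identically zero
(which is why the fit object has no `residuals()` method — model adequacy
is assessed by simulation instead, below).

Choices a user can change, with defaults and reasons:

* **Scaling constant `s = 0.1`.** The conventional within-trial noise
  scaling; under it, second-scale RTs in this population give drifts near
  0.2 and boundaries near 0.11. Rescaling `s` by a factor *c* rescales
  fitted *v* and *a* by *c* and leaves $T_{er}$ and all predicted
  observables unchanged (a tested invariant), so the choice is purely
  conventional.
* **RT unit: seconds.** Required for parameter magnitudes on the scale
  above.
* **Window `c(200, 1650)` ms.** The task's response window; the windowed
  accuracy is also the EZ input $P_c$, keeping the two scoring surfaces
  consistent.
* **No edge correction at $P_c = 1$.** Perfect scorers are excluded with
  reason `"perfect_accuracy"` rather than shrunk toward attainable
  accuracy: with 40 go trials the corrected estimates are dominated by the
  correction, and exclusion is the established practice this package
  follows. $P_c = 0.5$ (logit zero) and fewer than two hits are likewise
  excluded, with their own reason codes.
* **Below-chance accuracy** yields a negative drift via the sign term, and
  a fitted $T_{er}$ may come out negative when the observed mean RT is
  implausibly fast; both are reported with warnings rather than silently
  clamped — transparency over repair.

## Trial-level simulation and goodness of fit

`simulate_diffusion_trials()` simulates the underlying Wiener process by
Euler–Maruyama steps $\Delta x = v\,dt + s\sqrt{dt}\,\epsilon$ from $a/2$
to absorption. A discretely monitored process systematically overshoots a
continuously monitored barrier — by $\zeta(1/2)/\sqrt{2\pi}\,\cdot
s\sqrt{dt} \approx 0.5826\, s\sqrt{dt}$ per crossing in expectation — so
plain discrete absorption at $0$ and $a$ carries an $O(\sqrt{dt})$
first-passage bias that is far from negligible at practical step sizes
(about +5% on mean decision time at `dt = 0.001` for parameters typical of
this population). The simulator therefore applies the standard continuity
correction, shifting both absorbing thresholds inward by
$0.5826\,s\sqrt{dt}$; the residual bias, measured against the closed-form
moments, is below 1% on accuracy, mean decision time and RT variance at
`dt = 0.001` (the default) and below it again at `dt = 5\times10^{-4}`.
The test suite asserts this agreement at $10^6$ trials within three
Monte-Carlo standard errors plus a 1% discretisation allowance.

Goodness of fit follows the supersubject procedure: fitted parameters are
arithmetically averaged across children within each group (not refit to
pooled data), 1000 trials are simulated per group at the averaged
parameters, and simulated accuracy, mean correct RT and correct-RT
quantiles (10/30/50/70/90%) are compared with the observed group means.
Simulated RTs beyond the 1650 ms deadline are censored to misses exactly
as real responses would be.

## The synthetic cohort generator

`cohort_config()` defines the study conditions the generator emulates:
33 very-preterm and 32 term-born children; ages N(9.6, 1.0) and
N(9.1, 1.1) years; SWAN inattention N(−0.70, 9.89) and N(−6.58, 12.23);
group-mean diffusion parameters (v, a, Ter) of (0.211, 0.112, 0.253 s)
and (0.191, 0.112, 0.267 s). Between-child SDs — 0.092 for drift, 0.023
for boundary, 0.075 s for nondecision time — are derived from the group
standard errors those means are reported with (SD = SE·√n). Latent drift
follows

$$v_i = \bar v_{g(i)} + \beta\, z(\mathrm{SWAN}_i) + \eta_i,$$

with $z$ standardised by the group's configured moments and the residual
SD chosen so the total drift SD stays at 0.092. The coupling
$\beta = -0.050$ was calibrated once, by replicate simulation, so that the
pooled age-partialed correlation between inattention and *fitted* drift is
about −0.37 — the effect size such cohorts show; it is the only
inattention–performance pathway in the generator (drift-mediated
coupling). Latent drift and boundary are truncated at 0 and nondecision
time at 0.05 s (physical validity); no-go false alarms are Bernoulli per
trial with a Beta-distributed per-child rate of mean 2.4% and uniform
300–1650 ms response times. One term-born child's SWAN score is set
missing by default, reproducing the familiar situation where the
questionnaire sample is one short of the task sample (regressions at
N = 64 by listwise deletion, MANCOVA at N = 65).

What the generator does *not* emulate: time-on-task fatigue and block
effects, attentional lapses or mind-wandering mixtures, sequential
dependencies after errors, distractor-identity effects, and any
measure–inattention pathway other than drift. Passing tests therefore
show that the pipeline recovers the structure this generator puts in —
not that real children behave like the generator. Because all go-trial
structure flows through the diffusion process, fitted drift, hit rate and
RT variability are strongly intercorrelated at 40 trials per child, and in
a sizeable minority of replicate cohorts a measure other than drift wins
the stepwise competition; at larger cohort sizes drift is retained
essentially always (a tested property). Excluding perfect scorers (about
8–10 of 65 children at these parameter values) also range-restricts the
drift distribution and slightly attenuates the pooled correlation.

## The inference stage

* **Partial correlations** use the residual method (Pearson correlation of
  the residuals after projecting both variables on an intercept plus
  controls), with $t = r\sqrt{(n-2-k)/(1-r^2)}$ on $n-2-k$ df. Fisher
  comparisons of two independent (partial) correlations use the arctanh
  transform with the raw group sizes in the $1/(n-3)$ variance terms; this
  convention reproduces the worked group contrasts for hit rate
  (z = 0.22) and drift (z = 0.32) from the printed correlations and group
  sizes.
* **MANCOVA** uses unique (Type-III) sums of squares: the hypothesis
  cross-product for each effect is the increase in the error cross-product
  when that term is dropped, Pillai's trace is
  $V=\operatorname{tr}[H(H+E)^{-1}]$, and the standard F approximation is
  applied (for a single-df effect, df = (p, N − rank − p + 1), so seven
  outcomes at N = 65 give (7, 56)). The implementation is plain matrix
  algebra on `lm.fit` residuals; the test suite cross-checks it against an
  independent Type-III MANOVA implementation.
* **Stepwise regression** uses p-to-enter 0.05 and p-to-remove 0.10, the
  defaults of the software such analyses are conventionally run in; both
  are arguments. Group and age are forced; candidates are entered by
  smallest partial-F p-value and re-checked for removal after each entry;
  forced terms are never removed. All variables, including the 0/1 group
  dummy (term = 0), are z-scored on the listwise-complete sample, so
  coefficients are standardized betas; entry decisions are
  scale-invariant. The selection is verified in tests against an
  independent all-subsets/greedy oracle computed from raw $R^2$
  increments.
* **The interaction regression** is fully forced-entry in three steps
  (group + age; + measures; + group × measure products), with measures
  mean-centered before forming products so the interaction block's
  $\Delta R^2$ is invariant to location shifts; the block F test comes
  from the nested-model comparison.

Listwise deletion is applied once per analysis over the variables that
analysis uses; the MANCOVA (which does not involve SWAN) therefore runs
at the full post-exclusion N while SWAN analyses drop the missing rating.

## Determinism and problem sizes

Every stochastic stage takes a seed; `run_pipeline()` derives per-stage
and per-child substream seeds from one master seed, and two runs with the
same configuration and seed produce byte-identical output directories
(for this reason the outputs carry a config hash but no timestamps). The
test suite validates the simulator against the closed forms at
2×10^5–10^6 trials, parameter recovery at 10^4 trials × 100 replicates,
and the replicate-cohort properties at 100 default-size cohorts plus 20
large (150 + 150) cohorts — sizes at which the Monte-Carlo standard
errors are comfortably inside the asserted tolerances.

## Known limitations

EZ estimates only the three core parameters; starting-point bias and
cross-trial variabilities are fixed by assumption, and misses are modelled
as lower-boundary absorptions (plus deadline censoring) rather than as a
separate non-decision lapse process. The commission process is
deliberately minimal (Bernoulli with uniform RTs) and should not be used
to study no-go RT distributions. The stepwise procedure inherits the known
instability of data-driven selection among collinear predictors at small
N; the package reports it because it is the field's reporting convention,
alongside the forced-entry interaction analysis which does not select.
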