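# asimed

Composite **Activity–Sleep Index** scoring and **single-mediator path
analysis** for pooled two-arm behaviour-change trials.

Interventions that target both physical activity and sleep raise a question
that neither behaviour answers alone: does improving the *overall* pattern
of activity and sleep mediate the intervention's effect on mental health
and quality of life? `asimed` is for trial analysts and methodologists who
want that analysis chain as tested, reusable code:

1. **ASI scoring** — twelve behaviour dimensions (six activity, six sleep
   health), each min–max rescaled to 0–10 against bounds pooled over all
   assessment points and both arms, summed to the ASI-12 (0–120) and the
   six-dimension short form ASI-6 (0–60). High scores = lower-risk
   behaviour.
2. **Mediation** — product-of-coefficients estimation with study-indicator
   and baseline adjustment: `a` (intervention → mediator), `b` (mediator →
   outcome), `c′` (direct), `c` (total), `ab = a·b`, and the proportion
   mediated `100·ab/c`. The 95% CI for `ab` is a bias-corrected bootstrap
   (participant resampling, `z₀`-shifted percentile endpoints, B = 5000 by
   default). Missing follow-ups are handled by full-information maximum
   likelihood over the missingness patterns of the follow-up
   mediator–outcome pair.
3. **Descriptives** — pooled-SD Cohen's d, DASS-21 severity banding and
   improvement coding, completer/non-completer comparisons.
4. **Synthetic cohorts** — a generator that emulates a pooled pair of
   m-health RCTs (80/80 and 110/55 randomisations; 190 intervention vs 135
   control) with known true paths and logistic missing-at-random attrition,
   so every stage is testable against ground truth.

See `vignettes/activity-sleep-mediation.Rmd` for the model, assumptions and
design decisions.

## Worked example

```r
library(asimed)

# simulate the pooled two-trial design (true a = 3.0 ASI units,
# true b for depression = -0.10 per ASI unit), then score the index
cohort <- simulate_cohort(cohort_config(seed = 11))
bounds <- compute_bounds(cohort)
scored <- score_asi(cohort, bounds)

fit <- mediate(scored, mediation_spec("dass_depression", boot = 5000), seed = 7)
print(fit)
#> Mediation of dass_depression via asi12 at 3 months (FIML)
#>   A    3.130 (1.281)   B   -0.129 (0.037)
#>   Direct    0.067 (0.814)   C   -0.325 (0.829)
#>   AB  -0.404 (0.203) [-0.941, -0.080]
#>   proportion mediated: 124%
```

Reading the output: the intervention raised the ASI-12 by **3.13** points
(`A`, SE 1.28); each ASI point was associated with **−0.13** depression
points (`B`); the mediated effect is their product, **AB = −0.40**, whose
bias-corrected bootstrap interval `[−0.94, −0.08]` excludes zero — the
index mediates the effect at this sample size even though the direct effect
(`Direct`, 0.07) is null. A proportion mediated above 100% is a warning
sign, not a finding: the total effect `C` (−0.33, SE 0.83) is too close to
zero at n = 325 for the ratio to be stable, which is why the package floors
and flags it.

Recomputing a published effect size from the pooled-trial reference tables
shipped with the package:

```r
r <- pooled_trial_reference()$group_summaries[1, ]  # ASI-12 at 3 months
cohens_d(r$mean_int, r$sd_int, r$n_int, r$mean_con, r$sd_con, r$n_con)
#> Cohen's d = 0.42 (0.17, 0.66)
```

A command-line front end (`inst/cli/asimed`) exposes `simulate`, `score`,
`mediate` and `run-all` subcommands over the same functions.

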