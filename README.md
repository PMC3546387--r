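# coxtvcsim

Simulate survival times from Cox proportional-hazards models with a
**time-varying covariate**, and use the simulator to run Monte-Carlo power
studies for time-varying treatments.

Monte-Carlo evaluation of survival methods needs a data-generating process
that can produce event times whose hazard depends on a covariate that
changes *during* follow-up — a transplant received mid-study, episodic
medication use, or cumulative dose. Coding such exposures as fixed baseline
covariates induces immortal-time bias (the hazard ratio is biased toward
benefit), so simulation studies of the corrected, counting-process analysis
need exact generators for the time-varying model itself. coxtvcsim provides
them for biostatisticians designing such simulations or power calculations.

## The model and the generator

Event times follow

```
h(t | x, z(·)) = h0(t) · exp(βt·z(t) + β′x),
```

with `h0` an exponential, Weibull (`h0 = λνt^(ν−1)`), or Gompertz
(`h0 = λe^(αt)`) baseline, `η = β′x` the fixed linear predictor and `z(t)`
one of: a single 0→1 switch at `t0`, an alternating binary exposure with
any number of switches, a linear dose `z(t) = kt`, or a constant. Times
are generated by inverse-transform sampling, `T = H⁻¹(−log u)` with
`u ~ U(0,1)`, where the subject-specific cumulative hazard
`H(t) = ∫₀ᵗ h0(s)·exp(βt·z(s) + η) ds` is inverted **in closed form**:
piecewise over the exposure intervals for binary exposures (any family),
via logarithms for the exponential/Gompertz linear dose, and via the
incomplete-gamma quantile for the Weibull linear dose with a protective
effect. A numerical root-finding inverse of the integral-defined `H` ships
alongside as an independent oracle, and every closed form is tested
against it. Saturating hazards (Gompertz `α < 0`, protective doses) yield
an `Inf` never-event sentinel that censoring later converts to a censored
record.

Downstream, the package censors cohorts (administrative at the p-th event
percentile, or uniform per-subject), expands subjects into start–stop
counting-process records for `survival::coxph()`, and estimates power over
a hazard-ratio grid for five treatment scenarios against a configurable
synthetic covariate population.

## Worked example

Four subjects with different fixed linear predictors, a protective
treatment (HR = 0.5) switched on at day 2000, a Weibull(λ = 0.001,
ν = 0.6) baseline:

```r
library(coxtvcsim)

b    <- bh_weibull(0.001, 0.6)
subj <- make_subjects(eta = c(0, 0.3, -0.2, 0.5), beta_t = log(0.5),
                      trajectory = traj_single_switch(2000))
(drawn <- draw_event_times(subj, b, seed = 42))
#> # A tibble: 4 × 6
#>      id   eta beta_t trajectory     u    time
#>   <int> <dbl>  <dbl> <list>     <dbl>   <dbl>
#> 1     1   0   -0.693 <trj_sng_> 0.915   1776.
#> 2     2   0.3 -0.693 <trj_sng_> 0.937    637.
#> 3     3  -0.2 -0.693 <trj_sng_> 0.286 610559.
#> 4     4   0.5 -0.693 <trj_sng_> 0.830   3325.
```

Each `time` solves `H(T) = −log u` for that subject: subject 2 (high
risk, large `u`) dies at day 637 before ever being treated; subject 3
(low risk, small `u`) survives far beyond the switch. Censor so 32% of
subjects are observed to fail, then expand to start–stop records:

```r
out <- censor_fixed_percentile(drawn$time, p = 0.32)
expand_counting_process(subj, out)
#> # A tibble: 4 × 6
#>   subject_id start  stop status     z   eta
#>        <int> <dbl> <dbl>  <int> <dbl> <dbl>
#> 1          1     0 1730.      0     0   0
#> 2          2     0  637.      1     0   0.3
#> 3          3     0 1730.      0     0  -0.2
#> 4          4     0 1730.      0     0   0.5
```

The 32nd-percentile cutoff here falls at day 1730, before the switch, so
every record is untreated (`z = 0`) and only subject 2's final record
carries the event. A small power study (two scenarios, two hazard ratios):

```r
pg <- estimate_power(n_subjects = 1000, n_replicates = 100,
                     hr_grid = c(0.5, 0.7), scenarios = c("S1", "S2"),
                     censoring = "fixed_percentile", n_pop = 20000, seed = 7)
tidy(pg)
#> # A tibble: 4 × 9
#>   scenario censoring     hr     n replicates power  mc_se pct_died_pre_treatment
#>   <chr>    <chr>      <dbl> <dbl>      <int> <dbl>  <dbl>                  <dbl>
#> 1 S1       fixed_per…   0.5  1000        100  1    0                         0
#> 2 S1       fixed_per…   0.7  1000        100  0.88 0.0325                    0
#> 3 S2       fixed_per…   0.5  1000        100  0.94 0.0237                   29.2
#> 4 S2       fixed_per…   0.7  1000        100  0.53 0.0499                   28.6
```

`power` is the fraction of replicates whose time-varying Cox fit rejects
the null for treatment at α = 0.05, `mc_se` its binomial Monte-Carlo
standard error, and `pct_died_pre_treatment` the percentage of
treatment-assigned subjects who die before their treatment day — the
mechanism that drains power from mid-follow-up treatments (scenario S2)
relative to baseline-fixed ones (S1). `autoplot(pg)` draws the power
curves.

A command-line shim is installed at `inst/cli/coxtvcsim`
(`coxtvcsim simulate ...` writes a counting-process CSV,
`coxtvcsim power --config cfg.yaml` runs a configured power study); every
output is accompanied by a YAML manifest sufficient to reproduce it.

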