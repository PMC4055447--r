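# fertcurves

Parametric models for age-specific fertility schedules.

## What this is for

An age-specific fertility rate (ASFR) schedule records, for each age `x`
of the fertile period, the births per woman per year. Demographers
summarize such schedules with parametric curves of the form

    g(x; R, θ) = R · h(x; θ)

where `h` is a unit density over age and `R` is the total fertility rate.
Most schedules are single-humped, but several countries show **bimodal**
patterns that classical bell curves cannot follow. `fertcurves` is for
anyone who needs to fit, diagnose and compare such curves: its
centerpiece is the **flexible generalized skew-logistic (FGSL)** density

    f(y; μ, σ, α, β) = (2/σ) · e^{-z} / [ (1 + e^{-z})² (1 + e^{-αz - βz³}) ],
    z = (y − μ)/σ,

a logistic base density skewed through the Azzalini construction
`f = 2 f₀ G(w)` by a logistic cdf with the cubic odd argument
`w(z) = αz + βz³`. With four shape parameters plus the level `R`, the
family covers unimodal *and* bimodal schedules (it has at most two
modes). The package also implements the families it is traditionally
compared against — the Hadwiger curve and its two-component mixture, the
normal-mixture curve, the 13-parameter quadratic spline, and the
normal-based analogue (FGSN) — behind one registry, and fits any of them
by box-constrained nonlinear least squares, minimizing the residual sum
of squares ("resnorm")

    S = Σₓ { g(x; R, θ) − fₓ }²

with seeded multistart Levenberg–Marquardt. Models are compared by
resnorm, the standard criterion for these curves.

## Worked example

Fit the skew-logistic model to a bundled bimodal fixture, inspect the
mode structure, and compare against two competitors:

```r
library(fertcurves)
s <- preset_schedules()$noisy_bimodal     # bimodal truth + noise (sd 0.003)

fit <- fit_model("skew_logistic_fgsl", s, n_starts = 8, seed = 1)
print(fit)
#> Fertility model fit: skew_logistic_fgsl
#>   parameters:
#>         R        mu     sigma     alpha      beta
#>  1.828650 30.251700  8.270230  1.008360 -0.923628
#>   resnorm: 0.000362218   converged: TRUE   (best of 8 starts, start #2)

count_modes("skew_logistic_fgsl", fit$params)
#> 2 mode(s)
#>        age     height
#> 1 17.13887 0.05548847
#> 2 33.76463 0.06220777

compare_models(c("skew_logistic_fgsl", "skew_normal_fgsn", "hadwiger"),
               s, n_starts = 8, seed = 1)
#> Fertility model comparison [synthetic skew_logistic_fgsl (noise_sd=0.003, seed=42)] — ranked by resnorm (ascending):
#>               model n_params     resnorm converged rank
#>  skew_logistic_fgsl        5 0.000362218      TRUE    1
#>    skew_normal_fgsn        5 0.000389714      TRUE    2
#>            hadwiger        3 0.008311150      TRUE    3
```

Reading the output: the fitted curve recovers the generating truth
(R = 1.8, μ = 30, σ = 8, α = 1, β = −0.8) closely and reproduces its two
humps near ages 17 and 34 (heights in births/woman/year). In the
comparison, the two five-parameter flexible skew families track the
bimodal schedule about twenty times better (in resnorm) than the
three-parameter unimodal Hadwiger curve, with the skew-logistic slightly
ahead of the skew-normal; `rank` orders by resnorm ascending.

Real data comes in through `read_schedule()`, which accepts plain
`age,asfr` CSV and the Human Fertility Database period-ASFR layout
(`Year Age ASFR`, with `"12-"`/`"55+"` open ages and `"."` missing
markers handled):

```r
irl <- read_schedule("IRLasfrRR.txt", dialect = "hfd", year = 2005)
fit_model("skew_logistic_fgsl", irl)
```

## Command line

The installed `exec/fertcurves` script exposes the same workflow as
subcommands, with JSON or text output:

```sh
fertcurves simulate --model skew_logistic_fgsl \
    --params R=1.8,mu=30,sigma=8,alpha=1,beta=-0.8 \
    --noise-sd 0.003 --seed 42 --out sim.csv
fertcurves fit     --input sim.csv --model skew_logistic_fgsl --out fit.json
fertcurves compare --input sim.csv --models skew_logistic_fgsl,hadwiger
fertcurves modes   --input sim.csv --model skew_logistic_fgsl --format text
```

All subcommands are deterministic under `--seed`; results go to `--out`
(or stdout) and diagnostics to stderr.

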