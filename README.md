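# zmtcp

Mechanistic tumor-control-probability (TCP) modelling for hypofractionated
prostate HDR mono-brachytherapy, for medical physicists and radiobiology
modellers comparing fractionation schedules.

Clinical registries report better long-term control for three 11 Gy
fractions spread over four weeks than for two 14 Gy fractions over two
weeks — surprising, because a longer treatment gives a repopulating tumor
more time to regrow. `zmtcp` implements the analysis that rationalises this
through initial hypoxia and progressive *resensitization*: the tumor starts
radioresistant and reoxygenates during treatment, so late fractions hit a
more vulnerable target, and only sufficiently prolonged schedules collect
that benefit.

## The model

Individual tumor control is the extinction probability of a clonogen
birth-death process (Zaider-Minerbo) for fractionated delivery: with
fractions at times `T_1 = 0 < … < T_n` (days), doses `d_i` (Gy), `N_0`
initial clonogens and repopulation rate `λ`,

    TCP = [ 1 − S(T_n) e^{λT_n} /
            (1 + S(T_n) e^{λT_n} Σ_{k<n} S(T_k)^{-1} (e^{−λT_k} − e^{−λT_{k+1}})) ]^{N_0}

with linear-quadratic survival whose coefficients rise as the tumor
reoxygenates:

    log S(T_k) = − Σ_{i≤k} [ α(T_i) d_i + β(T_i) d_i² ]
    α(t) = α₀ e^{−bt²/2} + α_m (1 − e^{−bt²/2}),   β(t) = β₀ (α(t)/α₀)²

Population TCP is the mean individual TCP over a cohort with normal
inter-patient spread in `(α₀, α_m, β₀)`, filtered to a plausible
time-averaged α/β window (3.5-6 Gy). The shipped defaults are the
calibrated study configuration (`ᾱ₀ = 0.12`, `ᾱ_m = 0.23` Gy⁻¹,
`β̄₀ = ᾱ₀/4.5` Gy⁻², SDs 0.02/0.02/0.01, `N₀ = 10⁸`, `λ = 0.02` day⁻¹,
`b = 0.066` day⁻²). An exact stochastic birth-death simulator provides an
independent cross-check of the analytic formula, and a random-search
calibrator fits the population parameters to observed cohort control rates.

## Worked example

```r
library(zmtcp)

pop <- population_distribution(n_samples = 10000, seed = 7)  # calibrated defaults
kin <- tumor_kinetics(n0 = 1e8, lambda = 0.02)
two_wk <- fx_schedule(c(0, 14), 14)      # 2 x 14 Gy, days 0 and 14

population_tcp(pop, two_wk, kin, b = 0.066)
#> <population_tcp> 2 fractions, b = 0.066 day^-2: TCP = 89.4% (se 0.23 pp, n = 10000)

run_matrix(stock_scenarios(seed = 7, n_samples = 10000))
#>   label          population_tcp      se
#> 1 2F/14d b=0.066          0.894 0.00230
#> 2 3F/28d b=0.066          0.932 0.00175
#> 3 2F/7d b=0.066           0.786 0.00319
#> 4 3F/14d b=0.066          0.908 0.00205
#> 5 2F/14d b=1              0.894 0.00229
#> 6 3F/28d b=1              0.932 0.00175
#> 7 2F/7d b=1               0.902 0.00219
#> 8 3F/14d b=1              0.943 0.00156

find_iso_tcp_dose(two_wk, target_tcp = 0.96, pop, kin, b = 0.066)
#> [1] 14.7
```

Reading the matrix: under slow resensitization (`b = 0.066` day⁻²) the
four-week three-fraction schedule beats the two-week two-fraction one
(93.2% vs 89.4%), and compressing the two-fraction schedule to one week
costs ~11 pp because the second fraction then arrives before the tumor has
resensitized. Under fast resensitization (`b = 1`) the shortened schedules
catch up — the prolonged schedules are insensitive to `b`, which is the
argument for preferring them when the true rate is unknown. The last line
inverts the dose-response: raising the dose per fraction to ~14.7 Gy lifts
the two-fraction schedule to 96% population TCP. Each result object also
carries the individual-TCP distribution (`tidy()`, `tcp_histogram()`,
`autoplot()`); the two-fraction histograms are near-dichotomous, with a
small subgroup close to zero control probability.

The full pipeline — scenario matrix, dose sweep and iso-dose solve, the
frozen-hypoxic/frozen-sensitive anti-hypotheses, the parameter-sensitivity
grid, histograms, and synthetic cohorts compared against the clinical
failure counts (5/107 and 15/103) — runs from one seeded YAML config:

```r
run_study(default_run_config(), out_dir = "study_out")
```

See `vignettes/tcp-resensitization.Rmd` for the model assumptions, the
sampling rules (resampling, α/β window, common random numbers) and known
limitations.

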