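# fermkin

Analysis toolkit for high-density batch fermentation of lactic acid
bacteria. Given timed observations of viable count (lg CFU/mL), lactic
acid (g/L) and glucose consumption (g/L), fermkin fits the coupled kinetic
models standard in this field, analyses orthogonal screening designs, and
optimizes medium composition with a neural-network surrogate searched by a
genetic algorithm. It is aimed at fermentation scientists and bioprocess
engineers who want these computations reproducible, tested and scriptable
rather than spread across point-and-click tools.

## The models

**Growth** — logistic kinetics on the log-scale count, with an offset for
the non-zero inoculum:

    X(t) = a·e^{ct} / [1 − (a/b)(1 − e^{ct})] + d

where `a` is the initial logistic increment, `b` the carrying-capacity
increment (X_max), `c` the maximum specific growth rate μ_max (1/h), and
`d` the baseline initial load.

**Product** — the Luedeking–Piret law dP/dt = m·dX̃/dt + n·X̃ integrated
against the logistic increment X̃:

    P(t) = P₀ + m·X̃(t) + (n·b/c)·ln D(t),   D(t) = 1 − (a/b)(1 − e^{ct})

**Substrate** — the modified Luedeking–Piret mirror image:

    S(t) = S₀ − M·X̃(t) − (N·b/c)·ln D(t)

All three are fitted by bound-constrained Levenberg–Marquardt least
squares with the field's constraint protocol (product/substrate fits hold
`a` and `c` fixed at the growth estimates). RMSE uses denominator n − p
with p the number of *free* coefficients.

The design/optimization side provides the L9(3³) orthogonal array with
exact main-effects ANOVA (classical η², Tukey HSD on residual df 2),
Box–Behnken design generation, a Bayesian-regularized 3-h-1 tanh
perceptron trained by Levenberg–Marquardt with MacKay evidence updates,
and a real-coded GA (population 50, crossover 0.8, elitism 0.05, 20-
generation / 1e-6 stall rule) that maximizes the surrogate via fitness
negation.

## Worked example

The package ships the published batch-culture table (8 time points, 0–14 h)
as `load_builtin("table3")`:

```r
library(fermkin)

series <- load_builtin("table3")
fit <- fit_growth(series)
fit
#> Kinetic fit: growth model
#>   coef estimate    lower    upper fixed
#> 1    a 0.047726 0.029901 0.065552 FALSE
#> 2    b 2.105899 2.039444 2.172354 FALSE
#> 3    c 0.682959 0.624749 0.741170 FALSE
#> 4    d 7.581684 7.531584 7.631785 FALSE
#> R-squared 0.9998 | RMSE 0.0156 (dfe = 4) | converged in 13 iterations
```

The culture grows at μ_max ≈ 0.683 h⁻¹ from a 7.58 lg CFU/mL inoculum and
gains about 2.11 lg units before saturating; the curve explains 99.98% of
the variance. The product and substrate fits reuse the growth estimates:

```r
fit_product(series, growth_fit = fit)$r_squared     # 0.9990
coef(fit_substrate(series, growth_fit = fit))[c("M", "N")]
#>        M        N
#> 1.865940 0.102708
```

Glucose consumption is dominated by the growth-associated term (M ≈ 1.87 g
glucose per lg-unit of growth) with a small maintenance draw (N ≈ 0.10).

Screening-design ANOVA on the packaged L9 buffer-salt table:

```r
an <- main_effects_anova(load_builtin("table1"))
an[2:4, c("source", "f", "p", "eta_squared")]
#>                  source         f          p eta_squared
#> 2        sodium_acetate  5.046512 0.16538462   0.1202882
#> 3      ammonium_citrate 20.255814 0.04704595   0.4828160
#> 4 dipotassium_phosphate 15.651163 0.06005587   0.3730599
```

Ammonium citrate is the dominant factor (F = 20.26, p = 0.047, η² = 0.48).
And the surrogate + GA loop on a synthetic Box–Behnken response surface
with a known interior optimum:

```r
rec <- recovery_experiment("ann_ga", n_reps = 5, seed = 0, noise_sd = 0)
apply(rec[, c("err_frac_1", "err_frac_2", "err_frac_3")], 2, median)
#> err_frac_1 err_frac_2 err_frac_3
#> 0.03610981 0.03669244 0.02247494
```

The GA lands within 2–4% of each variable's range of the true optimum
(median over 5 seeds).

## Layout

- `R/` — fixtures and I/O, kinetics, DOE/ANOVA, ANN surrogate, GA, assay
  arithmetic, synthetic-data generators, pipeline runner
- `tests/testthat/` — unit, property and end-to-end reproduction tests
- `vignettes/fermkin-methods.Rmd` — models, conventions and design
  decisions in detail
- `scripts/acceptance.R` — headline-quantity reproduction script
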