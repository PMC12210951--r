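---
title: "Models and methods in fermkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fermkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

fermkin analyses high-density batch fermentations of lactic acid bacteria:
it fits coupled kinetic models to viable-count / lactate / glucose time
series, decomposes orthogonal-array screening experiments, and optimizes
medium composition through a neural-network surrogate searched by a genetic
algorithm. This vignette explains each model, the conventions the package
commits to, and what its synthetic-data tests do and do not demonstrate.

## Kinetic models

Biomass is tracked as `lg CFU/mL` (base-10 log of viable count), and the
logistic law is applied directly to that log-scale quantity. This is
unconventional — logistic growth is usually posed on linear biomass — but it
is the established practice in this application area and the package
reproduces it as such, without reinterpretation.

**Growth.** The logistic increment
$\tilde X(t) = a e^{ct} / D(t)$ with $D(t) = 1 - (a/b)(1 - e^{ct})$
solves $d\tilde X/dt = c\,\tilde X (1 - \tilde X/b)$, and the observed
count is $X(t) = \tilde X(t) + d$:

* `a` — initial logistic increment (lg CFU/mL),
* `b` — carrying-capacity increment $X_{max}$ (lg CFU/mL),
* `c` — maximum specific growth rate $\mu_{max}$ (1/h),
* `d` — baseline initial load (lg CFU/mL), an offset correcting for the
  non-zero inoculum.

For $t \ge 0$ and $a, b > 0$ the denominator satisfies $D(t) \ge 1$, so the
curve is defined on the whole fitting domain even when the optimizer
explores $a > b$.

**Product (Luedeking–Piret).** $dP/dt = m\,d\tilde X/dt + n\,\tilde X$
splits lactic acid production into a growth-associated part (`m`) and a
non-growth-associated part (`n`). Integrated against the logistic
increment:
$P(t) = P_0 + m\,\tilde X(t) + (n b / c)\,\ln D(t)$.
The differential form applies `n` to the logistic increment, not to the
offset count $\tilde X + d$; the integrated expression is the exact
integral of that form, and the package implements both consistently
(`ode_rhs()` vs `eval_product()`, cross-checked by numeric integration to
1e-6 in the tests).

**Substrate (modified Luedeking–Piret).**
$S(t) = S_0 - M\,\tilde X(t) - (N b / c)\,\ln D(t)$, the mirror image with
growth-associated consumption `M` and maintenance consumption `N`.

### Fitting protocol and conventions

`fit_growth()`, `fit_product()` and `fit_substrate()` use bound-constrained
Levenberg–Marquardt least squares (minpack.lm) started from the constraint
tables in `default_constraints()`, which reproduce the published fitting
protocol: growth coefficients all bounded below by zero; the product and
substrate fits hold `a` and `c` fixed at the growth estimates rounded to
4 decimals, and re-fit `b` from 2 upward. Key conventions:

* **Degrees of freedom.** RMSE uses denominator $n - p$ where $p$ counts
  only *freely estimated* coefficients; fixed coefficients (lower bound ==
  upper bound) are substituted, excluded from $p$ and from the covariance.
  On the packaged 8-point batch table this convention — and only this one —
  reproduces the reference pair R² = 0.9998, RMSE = 0.0156 for the growth
  fit.
* **Residual glucose reconstruction.** The batch table records *cumulative
  glucose consumed*; the substrate model is fitted to $K -$ consumed for a
  caller-chosen initial charge `K` (default 30.44 g/L). All outputs except
  the fitted intercept `s0` are invariant to `K` (exactly in theory, to
  ~1e-7 in floating point because the solver path differs).
* **Weights.** Fits are unweighted and use the column means; printed
  standard deviations are stored in the fixtures but not used, since the
  original protocol specifies no weighting.
* **Confidence intervals.** Wald intervals from the linearized-Jacobian
  covariance, $\hat\theta \pm t_{1-\alpha/2,\,dfe}\,se$. A singular
  Jacobian yields unbounded intervals with a warning rather than a failure.
* **Solver.** Levenberg–Marquardt with box bounds (`minpack.lm::nls.lm`),
  at most 1000 iterations, function/parameter tolerances 1e-15 and gradient
  tolerance 1e-10. Deterministic: no random restarts. On the packaged data
  the product-model objective is nearly flat in (`m`, `n`, `b`) — the
  reference intervals for those coefficients span $\pm 10^5$–$10^7$ — so
  individual product coefficients are solver-dependent while the fitted
  curve, R² and RMSE are stable. The substrate objective is similarly
  shallow; the package's optimum has a lower SSE than the reference point
  estimate, and both lie inside all reference intervals.

Inputs with fewer than $p + 1$ points are rejected outright.

## Orthogonal-array ANOVA

`main_effects_anova()` decomposes a 9-run L9(3³) table into three 2-df main
effects and a 2-df residual using the closed-form level-sum identities;
p-values come from the exact F(2,2) distribution, with no correction across
factors. Effect size is **classical eta-squared**, SS_factor / SS_total —
not partial eta-squared; classical is the definition under which the three
effect sizes sum to the model R². An intercept row (SS = 9 × grand mean²)
is included to mirror the conventional report layout, though it plays no
role in factor testing. `tukey_hsd()` compares level means with the
studentized range on the residual mean square (df 2). `best_levels()`
reports the per-factor argmax of level means, breaking ties toward the
lowest level index; it makes no attempt to second-guess a practitioner's
choice when the margin between levels is within noise.

## Neural-network surrogate

`train_bayesian_lm()` trains a single-hidden-layer perceptron (tanh hidden
units, linear output; default 3-3-1) by Levenberg–Marquardt on the
evidence-framework objective $F = \beta\,SSE + \alpha\,SSW$. After each
accepted step the MacKay updates re-estimate
$\gamma = k - 2\alpha\,\mathrm{tr}(H^{-1})$ (with $H = 2\beta J^TJ +
2\alpha I$), $\alpha = \gamma / (2\,SSW)$ and $\beta = (n - \gamma) /
(2\,SSE)$. Numerical choices worth knowing:

* **Burn-in.** The updates start only after a burn-in (default 25 epochs)
  with $\alpha$ frozen small. Updating from a cold start is unstable: with
  weights near their random initialization, $\alpha = \gamma/(2\,SSW)$ is
  large, which shrinks the weights, which raises $\alpha$ again — a
  feedback loop terminating at the constant predictor.
* **Fixed decay for small designs.** The evidence updates presuppose more
  observations than well-determined parameters. On a 15-run Box–Behnken
  design a 3-3-1 net already has 16 weights, so $(n - \gamma)$ is
  meaningless; passing `decay =` trains with a fixed ratio
  $\alpha/\beta$ instead (weight decay), which gives the smooth
  minimum-norm behaviour a surrogate needs.
* **Topology and interior optima.** A single hidden layer of tanh units
  computes a sum of *monotone ridge functions*. With only 3 hidden units
  whose input directions are linearly independent, the gradient cannot
  vanish in the interior, so a strict interior maximum is not
  representable — the surrogate's box-maximum sits on the boundary. Medium
  optimization searching for an interior optimum therefore needs a wider
  layer; the recovery harness uses 8 hidden units (roughly two per
  curvature direction), fixed decay 0.01 and 3 seeded restarts keeping the
  lowest regularized objective. The 3-3-1 default is retained everywhere
  a surrogate is merely fitted rather than optimized over.
* **Scaling.** Inputs and target are min-max scaled to [-1, 1]
  (`fit_scaler()`); training metrics are reported in the scaled space and
  `fit_surrogate()$predict` returns raw units. Reported metric magnitudes
  therefore depend on the space, which each report states.
* **Determinism.** Weight initialization is seeded uniform [-0.5, 0.5];
  the same seed reproduces the trained weights bit-for-bit.

`kfold_cv()` shuffles with a seed, trains one net per fold, and reports
per-fold scaled-space metrics plus a pooled raw-scale Q² (all held-out
predictions against the overall mean). The pooled Q² is the summary to
trust on small designs: per-fold R² is undefined on folds of one point and
wildly unstable on folds of three. Note that honest held-out prediction of
a *15-run Box–Behnken design* is information-limited — each run is the only
observation in its region, so leave-3-out prediction of a
quadratic-dominated surface fails for any smooth model regardless of
regularization. The package's CV generalization test therefore uses a
45-point random design over the same surface, where Q² ≈ 0.9 is
achievable; the 15-run design is still what the surrogate is *trained* on
for optimization.

## Genetic algorithm

`ga_minimize()` is a real-coded GA with the study-standard configuration:
population 50, up to 300 generations, crossover probability 0.8, elite
fraction 0.05, and a stall rule stopping when the best fitness changes by
less than 1e-6 over 20 consecutive generations. Where the configuration
leaves detail open, the package commits to:

* elite count = ceiling(fraction × population) (3 with the defaults),
  matching common GA-toolbox rounding;
* initialization by uniform sampling within the bounds; selection by
  stochastic universal sampling on rank weights $1/\sqrt{rank}$;
* arithmetic blend crossover per pair with mixing ratio ~U(0,1);
* adaptive Gaussian mutation with per-generation scale decay
  $0.1 \cdot range / (1 + g/50)$, clipped at the bounds;
* the stall metric tracks the incumbent *best* fitness (not the mean),
  the natural reading of a fitness-change threshold.

Maximization is done by minimizing the negated objective
(`negate_objective()`). With at least one elite the best fitness is
monotone non-increasing, and an identical seed reproduces the full
trajectory. `parameter_sweep()` tabulates convergence across setting grids
(population 30–100, crossover 0.6–0.9, iteration caps 100–500 are the
ranges worth exploring) with seeded replicates.

## Synthetic data and what the tests show

`simulate_fermentation()` draws noise-free trajectories from the closed
forms at the packaged reference coefficients (time grid 0–14 h by 2) and
adds independent homoscedastic Gaussian noise per channel (defaults: 0.02
lg for counts, 0.15 g/L for lactate and glucose, matching the order of the
published replicate scatter). Heteroscedastic noise, plate-count error
structure, and autocorrelated sensor drift are *not* emulated: parameter
recovery passing at these settings shows the estimator is sound under the
model's own assumptions, not that real series are this clean.

`simulate_bbd()` evaluates a quadratic response surface (`quad_surface()`)
at the coded Box–Behnken runs. The default surface has its maximum strictly
inside the coded box at (0.25, -0.3, 0.2), peak 9.6 lg CFU/mL, diagonal
curvature (-0.5, -0.4, -0.6) with mild -0.05 interactions, and noise sd
0.02 lg — a realistic viable-count surface with an interior optimum, which
is the property the surrogate-plus-GA loop must recover. (The original
study's reported optimum lay partly outside its stated design box after an
unspecified bound adjustment, so recovery is only testable inside a known
box.) `surface_argmax()` provides the linear-algebra cross-check of the
generator's ground truth.

`recovery_experiment()` is the Monte Carlo harness: the kinetics stage
refits 100 noisy series (median relative error of the growth rate `c` is
~2% at noise 0.02, against a 5% acceptance bound); the ann_ga stage runs
the full surrogate + GA loop on 5 seeds (median per-variable optimum error
2–4% of the coded range, against a 5% bound). Problem sizes — 8-point
series, 15-run designs, 100 and 5 replicates, GA capped at 120 generations
in the harness — were chosen to exercise every code path at desk scale.

## Known limitations

* The logistic-on-log-counts formulation is inherited from the application
  area; its parameters do not map cleanly onto linear-scale growth theory.
* Product-model coefficients are not individually identifiable on 8-point
  batch data (flat objective); only the fitted curve and fit statistics
  are stable.
* The evidence-framework updates are unreliable when observations do not
  comfortably exceed the weight count; use fixed decay there.
* The GA handles box bounds only; no nonlinear constraints.
* `run_pipeline()` orchestrates the packaged stages; it is a reproducibility
  convenience, not a general workflow engine.
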