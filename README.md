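# bmlr

Bayesian multivariate logistic regression for superiority and inferiority
decision-making in two-arm randomized trials with multiple correlated binary
endpoints and observable treatment heterogeneity.

Trials routinely record several binary outcomes per subject (an event
recurring short-term, dependency long-term, ...), and the effect of a
treatment may differ across patients with different covariate values.
Univariate analyses ignore the correlation between endpoints; stratified
multivariate analyses pay the full sample-size price for every subgroup.
bmlr implements a regression framework that does neither, for
biostatisticians designing or analyzing such trials:

* **Model.** The joint outcome vector over `K` endpoints takes one of
  `Q = 2^K` configurations; their probabilities follow a multinomial
  logistic regression with treatment, covariate and interaction terms
  (all-failure configuration as reference, coefficients fixed at zero).
  Endpoint correlations are encoded in the configuration probabilities and
  may vary freely over covariates. The posterior is sampled by an exact
  Polya-Gamma Gibbs sampler (Devroye-type alternating-series PG(1, z)
  draws, compiled; bit-reproducible under a seed), with Brooks-Gelman
  convergence diagnostics.
* **Transformation.** Every posterior draw is mapped to the probability
  scale: joint configuration probabilities `phi_T(x)` per counterfactual
  arm, endpoint success probabilities `theta_Tk(x)` (selection sums over
  configurations), treatment differences
  `delta_k(x) = theta_1k(x) - theta_0k(x)`, and a weighted difference
  `delta_w = sum_k w_k delta_k`. Populations are fixed covariate values or
  empirical marginalization over observed covariate rows in an interval
  (average treatment effect as the special case "all rows").
* **Decision.** Any / All / Compensatory rules with strict region
  boundaries. The Compensatory rule thresholds `P(delta_w > 0 | y)` at
  `p_cut = 1 - alpha`; the Any and All rules threshold per-endpoint
  posterior probabilities (`max_k P(delta_k > 0 | y)` against the
  multiplicity-corrected `1 - alpha/K`, and `min_k` against `1 - alpha`),
  the evaluation that holds the Type I error at its nominal level (the
  vignette derives why thresholding the union-region probability itself
  would more than double it). Two-sided variants halve alpha; left-sided
  testing covers failure-coded outcomes without recoding.
* **Design.** A priori per-arm sample sizes: iterative search over a
  K-variate-normal power approximation (Any/All) and a closed form on
  weighted success probabilities (Compensatory), e.g.
  `required_n("compensatory", 0.6, 0.5, weights = 1)` gives n = 303 per
  arm for 80% power at one-sided alpha 0.05.
* **Evaluation.** A synthetic-trial generator with exact ground truth
  (margins + pairwise correlations at anchor covariate values, inverted to
  coefficients), stratified Dirichlet (mB) and univariate logistic (uLR)
  reference analyses, and a simulation harness for bias, Type I error,
  power and convergence.

## A worked example

Generate a heterogeneous trial (conditional effects (0.25, 0.15) at one
standard deviation below the covariate mean, (0.15, 0.05) above; endpoint
correlation 0.2), fit the model, and decide for the trial population and a
low-covariate subpopulation:

```r
library(bmlr)
spec  <- dgm_preset("ES3", "normal", rho = 0.2, weights = c(0.75, 0.25))
trial <- generate_trial(spec, n_per_arm = 1000, seed = 7)
ana <- analyze_trial(
  trial, c("y1", "y2"), "treat", covariates = "z",
  populations = list(ATE = pop_all(), low = pop_interval("z", -Inf, -1)),
  rules = list(decision_rule("any"),
               decision_rule("compensatory", weights = c(0.75, 0.25))),
  weights = c(0.75, 0.25), chains = 2, iter = 2000, burnin = 500, seed = 8)
ana$decisions[, c("population", "rule", "p_cut", "p_superior", "conclusion")]
#> # A tibble: 4 × 5
#>   population rule         p_cut p_superior conclusion
#>   <chr>      <chr>        <dbl>      <dbl> <chr>
#> 1 ATE        any          0.975          1 superior
#> 2 ATE        compensatory 0.95           1 superior
#> 3 low        any          0.975          1 superior
#> 4 low        compensatory 0.95           1 superior
```

`p_superior` is the Monte-Carlo posterior probability that the treatment
difference lies in the rule's superiority region; it exceeds the threshold
`p_cut`, so each rule concludes superiority — correctly, since the
generating mechanism has positive effects everywhere. The effect estimates
behind these decisions sit in `ana$summaries` on the probability scale
(posterior mean, 95% interval, `P(delta > 0)`):

```r
subset(ana$summaries, quantity %in% c("delta_1", "delta_2", "delta_w"))
#> # A tibble: 6 × 7
#>   population quantity estimate std_error conf_low conf_high prob_positive
#>   <chr>      <chr>       <dbl>     <dbl>    <dbl>     <dbl>         <dbl>
#> 1 ATE        delta_1     0.203    0.0211   0.161      0.244             1
#> 2 ATE        delta_2     0.103    0.0222   0.0592     0.146             1
#> 3 ATE        delta_w     0.178    0.0176   0.142      0.212             1
#> 4 low        delta_1     0.271    0.0360   0.200      0.342             1
#> 5 low        delta_2     0.172    0.0400   0.0936     0.250             1
#> 6 low        delta_w     0.247    0.0304   0.188      0.306             1
```

The average effects recover the generating truth (0.20, 0.10; weighted
0.175) and the low-covariate conditional effects are larger, as the
mechanism prescribes; the two-chain multivariate Gelman-Rubin statistic for
this fit is 1.005. Under the null preset (`dgm_preset("ES1", ...)`) the
same pipeline concludes superiority in about 5% of repetitions, the
designed error rate. `autoplot()` and `plot_effect_profile()` draw the
posterior densities and the effect-versus-covariate profile.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the framework's operating characteristics from scratch by
simulation with the installed package — Type I error and power of the
average-effect decisions (at a priori computed sample sizes), maximum
absolute bias of posterior-mean treatment differences, the upper bound of
the multivariate Gelman-Rubin statistic across fitted datasets, and
conditional-effect power and Type I error across the three analysis methods
— and writes one JSON object with a `value` and problem size `n` per check.
Repetition counts and chain lengths are desk-scaled (noted in the script);
all randomness derives from `--seed`.
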