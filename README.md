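# coexmi

Threshold-free marker co-expression analysis for multiplex imaging data.

## The problem

Multiplex tissue-imaging platforms (mIHC, MIBI, imaging mass cytometry)
produce segmented cell-level data: for each subject, thousands of cells with
a continuous intensity per marker. A recurring question is whether two or
more markers *co-express* in a subject's tumor microenvironment, and whether
the degree of co-expression predicts clinical outcomes such as survival or
recurrence.

The traditional answer binarizes each marker at a positivity cutoff
`t_k` (cell positive iff `X_k > t_k`), summarizes each subject by the
proportions of single- and double-positive cells, clusters subjects on those
proportions, and tests the cluster labels against the outcome. The
conclusions can swing with the choice of cutoffs, and binarizing continuous
intensities costs power.

`coexmi` instead treats the `p` marker intensities of subject `j` as jointly
distributed random variables on `[0, 1]` and measures their dependence with
the Euclidean quadratic mutual information

```
EQMI  = V_J − 2 V_C + V_M
V_J   = ∫ f_{1..p}(x)²  dx          (squared joint density)
V_C   = ∫ f_{1..p}(x) ∏_k f_k(x_k) dx
V_M   = ∫ ∏_k f_k(x_k)² dx          (squared product of marginals)
```

which equals `∫ (f_joint − ∏ f_marginals)²` and is zero iff the markers are
independent. The standardized statistic

```
EQMI* = (V_J − 2 V_C + V_M) / (V_J + V_M)  ∈ [0, 1]
```

is comparable across subjects. The key computational point is that with
Gaussian kernel density estimates (per-marker bandwidths `h_k`), all three
integrals have *exact* closed forms in the `n × n` per-marker kernel
matrices `K_k(i, s) = G_{√2 h_k}(X_ki − X_ks)` — cost `O(n² p)`, with no
p-dimensional grid — so the statistic scales to many markers where a
gridded joint density cannot.

The per-subject vector `E = (EQMI*_1, …, EQMI*_N)` is then tested against
outcomes: linear Wald test (continuous), logistic (binary), or a Cox
proportional-hazards likelihood-ratio test (right-censored survival), with
optional covariate adjustment, plus an exhaustive marker-combination scan
with per-size Bonferroni correction. The traditional quantile-thresholding
pipeline and the absolute-Pearson-correlation statistic are included as
comparators, together with Gaussian-copula / parabolic / circular cell-level
simulators and an empirical-power engine that compares all methods.

## Worked example

Simulate 20 subjects (800 cells each) from a bivariate Gaussian copula with
Beta marginals, where roughly half the subjects have high latent
marker correlation (group 0) and half nearly none (group 1):

```r
library(coexmi)
library(dplyr)

scn <- sim_scenario("copula2", N = 20, ncells = 800, seed = 42)
sim <- simulate_copula2(scn)
eq  <- compute_eqmi(sim$cells, bw_method = "plugin")
head(left_join(eq, sim$groups, by = "subject_id") %>%
       select(subject_id, eqmi_star, csqmi, n_cells, group), 6)
#> # A tibble: 6 × 5
#>   subject_id eqmi_star  csqmi n_cells group
#>   <chr>          <dbl>  <dbl>   <int> <int>
#> 1 S001         0.0175  0.0342     800     1
#> 2 S002         0.0100  0.0201     800     1
#> 3 S003         0.269   0.499      800     0
#> 4 S004         0.0121  0.0243     800     1
#> 5 S005         0.0106  0.0212     800     1
#> 6 S006         0.00903 0.0180     800     1
```

High-co-expression subjects (group 0) stand out an order of magnitude above
the independence group, whose EQMI* sits near its null value (≈ 0.01 at
n = 800). Testing the statistic against a continuous outcome carrying a
group effect:

```r
oc  <- simulate_outcomes(sim$groups, beta = 1.5, sigma = 1,
                         outcome_reps = 1, seed = 43)[[1]]
fit <- linear_association(eq, oc)
fit
#> <coex_assoc> continuous outcome, wald test: coef = 8.606, p = 0.003331 (n = 20)
tidy(fit)
#> # A tibble: 1 × 5
#>   term  estimate hazard_ratio p.value test
#>   <chr>    <dbl>        <dbl>   <dbl> <chr>
#> 1 E         8.61           NA 0.00333 wald
```

The positive coefficient says subjects with higher marker co-expression have
the higher outcome values, recovered at p ≈ 0.003 from 20 subjects. For
survival data use `cox_lrt_association()` (reports the hazard ratio
`exp(γ̂)` and a 1-df LRT p-value); for several markers,
`combination_scan()` tests every subset of size ≥ 2 with per-size Bonferroni
levels. Real data enter through `read_cell_table()` +
`normalize_intensities()`, and `autoplot()` draws power tables from
`run_power_study()`. A command-line wrapper with `eqmi`, `scan`, `baseline`,
`simulate` and `power` subcommands is installed at `inst/cli/coexmi`.

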