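# snailtrail

Continuum and agent-based models of angiogenic sprouting, and the
machinery to decide when they agree.

During angiogenesis, tip endothelial cells migrate up gradients of a
tumour angiogenic factor (TAF) while stalk cells proliferate along their
paths, forming new vessels; tips branch, and fuse with other vessels
(anastomosis). Two one-dimensional continuum descriptions of this process
coexist in the literature. The phenomenological **snail-trail model**
(ST-PDE) evolves the tip density `N(x,t)` by

```
N_t = D N_xx − χ (N C_x)_x + λ N C − a_n μ N² − a_e μ N E,
E_t = κ(x) |D N_x − χ N C_x|,          κ = μ / (χ |C_x|),
```

with the stalk density `E` growing in proportion to the magnitude of the
net tip flux. The **coarse-grained model** (P-PDE) is derived from a
biased-random-walk lattice agent-based model (ABM) with volume exclusion:

```
N_t = (D N_xx − χ (N C_x)_x)(1 − a_n N − a_e E) + λ N C − a_n μ N² − a_e μ N E,
E_t = μ N + a_n μ N² + a_n N (D N_xx − χ (N C_x)_x).
```

Both use the quasi-steady linear TAF field `C(x) = ν x`. The package
implements both PDE systems (method of lines, flux-limited chemotactic
advection), the underlying lattice ABM (Rcpp, with ensemble column
averaging — also the package's synthetic-data generator), their shared
leading-order reduction in a frame moving with the chemotactic drift
(valid when `ε = √(Dλ)/(χν) ≪ 1` and `α = λ/μ ≪ 1`), the early-time
self-similar tip profiles (a nonlinear two-point boundary-value problem,
and the closed-form Gaussian with exponent −1/2 in the strong
tip-to-sprout limit), and the comparison metrics: normalized
pointwise-difference curves, pulse-peak and half-maximum leading-edge
speeds, log-log decay-slope fits, and nonlinear least-squares calibration
of `(λ, a_e)` against ensemble data with broom-style `tidy()`/`glance()`
accessors.

## Worked example

Compare the two models in the chemotaxis-dominated regime, initialised
from a lattice ensemble:

```r
library(snailtrail)

p <- continuum_params(D = 1e-3, chi = 0.4, mu = 160, lambda = 0.16,
                      a_e = 0.0391, a_n = 1, L = 10, nu = 1)
dimensionless_groups(p)
#> # A tibble: 1 × 4
#>   epsilon alpha  beta   Psi
#>     <dbl> <dbl> <dbl> <dbl>
#> 1  0.0316 0.001  39.1     1

abm <- abm_params(p, Lx = 0.4)                       # h = 5e-3, k = 100, Pp = 1e-3
ens <- simulate_abm_ensemble(abm, n = 100, t_out = 0.2, seed = 1)

st <- solve_st_pde(ens, p, times = c(0.2, 1.8, 3.4), nx = 2001)
pp <- solve_p_pde(ens, p, times = c(0.2, 1.8, 3.4), nx = 2001)
compare_solutions(st, pp)
#> # A tibble: 6 × 3
#>       t field max_rel_diff
#>   <dbl> <chr>        <dbl>
#> 1   0.2 N           0
#> 2   0.2 E           0
#> 3   1.8 N           0.0363
#> 4   1.8 E           0.0164
#> 5   3.4 N           0.0332
#> 6   3.4 E           0.0164

estimate_wave_speed(pp)
#> # A tibble: 3 × 3
#>       t position speed
#>   <dbl>    <dbl> <dbl>
#> 1   0.2   0.0868 0.411
#> 2   1.8   0.744  0.411
#> 3   3.4   1.40   0.411
```

So with `ε ≈ 0.03` the two models' tip densities differ by under 4% of
the maximum tip density (stalks under 2%) while the pulse travels at the
chemotactic drift speed `χν = 0.4` (slightly above it, since the waves
accelerate towards the TAF source). The early-time pulse shape is the
bell-curve solution of the similarity problem
`Ũ″ + (z/2)Ũ′ + Ũ = Ũ²`:

```r
bvp <- solve_similarity_bvp()
max(bvp$U)
#> [1] 0.6898
autoplot(bvp)
```

Five pre-registered experiment configurations (`regime("fig1")` …
`regime("fig5")`) bundle the published parameter sets; `run_regime()`
executes a full pipeline (ensemble → PDEs → metrics, plus leading-order
and self-similar stages where relevant). `fit_continuum_params()`
calibrates `(λ, a_e)` to ensemble data; `tidy()` returns estimates with
Gauss-Newton confidence intervals.

The methods vignette (`vignettes/model-comparison.Rmd`) documents the
model assumptions, the lattice update rules (sprout-identity anastomosis),
the numerical scheme, and the known limitations.

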