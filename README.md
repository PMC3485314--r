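# demopriors

Monte-Carlo elicitation of demographic priors for fish stock assessment:
the intrinsic population growth rate *r* of the surplus-production model
and the steepness *h* of the Beverton–Holt stock–recruitment
relationship, with explicit propagation of the uncertainty in
young-of-the-year natural mortality (*M₀*). The shipped default is an
Atlantic bluefin tuna (*Thunnus thynnus*) parameterization; every
life-history trait is a declarative distribution that can be overridden
from YAML or through scenario presets.

Intended users are stock-assessment and quantitative population
ecologists who need defensible informative priors for *r* and *h* when
the data cannot estimate them — and who want the early-life survival
bottleneck, rather than a convenient constant, to drive the answer.

## The model in brief

**Young-of-the-year mortality.** A stochastic daily dry-weight
trajectory w_d(x) is built over the 180 days after fertilization
(incubation at egg weight; yolk-sac weight loss to first feeding; power,
exponential and juvenile growth stages; interpolation to the year-0
endpoint of the von Bertalanffy curve). Daily mortality follows the
McGurk allometric regressions μ = a·w^b (two weight regimes split at
0.00504 g dry) with lognormal residuals redrawn independently each day,
and

M₀ = M_fh + Σₓ₌₁¹⁸⁰ M_d(x),  S₀ = e^(−M₀),

where M_fh is the fertilization/hatching loss (~50% survival).

**Population growth rate.** For each draw, mortality-at-age
M(i) ~ N(μ_M(i), 0.1 μ_M(i)), lengths-at-age (von Bertalanffy, CV 10%),
weights W = 1.96·10⁻⁵·L^3.0092 kg and annual fecundities
F(i) = sr·g(i)·bf·1000·W(i)·N_batch·(1/Spe) fill a Leslie matrix with
e^(−M₀)·F(i) in the first row and survivals S(i) on the sub-diagonal;
r = ln λ of its dominant eigenvalue.

**Steepness.** On simulated unfished populations (ages ∝ survivorship
l(a)), α = e^(−M₀)·F_sim/B_sim recruits per kg of spawning biomass,
W_bpr = Σ l(a)·W(a)·g(a) kg per recruit, and

h = α·sr·W_bpr / (4 + α·sr·W_bpr) ∈ (0.2, 1).

An acceptance-rejection step (`accept_reject()`) removes draws with
r < 0 or h < 0.2 — the two conditions coincide analytically — yielding
priors usable in biomass-dynamic or age-structured assessments.

## Worked example

```r
library(demopriors)
cfg <- load_config("abft_baseline")
ens <- run_ensemble(cfg, seed = 1, n_draws = 2000, n_pops = 500)
summary(ens)
#>            q5     q25     q50     q75     q95    mean     sd
#> M_0     7.884  10.192  12.542  15.539  22.532  13.418  4.650
#> W_bpr 400.712 433.683 466.334 502.394 547.992 470.456 46.682
#> alpha   0.000   0.015   0.366   6.501  77.119  19.032 75.890
#> r      -0.242   0.138   0.532   0.968   1.518   0.570  0.549
#> h       0.003   0.462   0.954   0.997   1.000   0.728  0.370
#> Spearman(M_0, r) = -0.963 | Spearman(M_0, h) = -0.964
```

Reading the table: the age-0 mortality prior is wide (median 12.5 yr⁻¹,
90% interval roughly 8–22), which makes the *r* prior weakly informative
(mean 0.57, sd 0.55, stretching below zero) while *h* piles up near 1 —
a 100 kg spawner produces so many eggs that recruitment barely senses
spawning biomass unless M₀ is extreme. The Spearman correlations show
M₀, not fecundity or adult mortality, drives both parameters.

```r
priors <- accept_reject(ens)          # keep r >= 0 and h >= 0.2
attr(priors, "rejection")[["draws"]]  # 0.164 of draws removed
summarize_ensemble(priors)[c("r", "h"), c("q25", "q50", "q75", "mean", "sd")]
#>     q25   q50   q75  mean    sd
#> r 0.331 0.685 1.046 0.720 0.466
#> h 0.876 0.987 0.998 0.879 0.202
```

Sensitivity presets (`builtin_scenarios()` lists all of them):

```r
run_ensemble(cfg, scenario = "western_maturity", seed = 1)   # maturity at 9 y
run_ensemble(cfg, scenario = "correlated_rho_0.9", seed = 1) # coupled M0-fecundity
```

A thin CLI wraps the same calls:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/demopriors-cli.R", package = "demopriors"))') \
    run --seed 1 --n-draws 2000 --k-pops 500 --out run1
```

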