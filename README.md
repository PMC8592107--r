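# valseq

Value-based Bayesian sequential clinical trial design with delayed
outcome observation.

## The problem

Conventional trial monitoring asks whether accumulating evidence has
crossed a significance boundary. valseq implements a different
question, aimed at trial funders and health-economics-minded trials
units: **is the next patient pair worth its research cost?** A two-arm
trial randomises patients in pairs (one per arm) and monitors
*incremental net monetary benefit*

$$X_j = \lambda\,(E_{N,j} - E_{S,j}) - (C_{N,j} - C_{S,j}),$$

with $\lambda$ the willingness to pay per QALY. $X$ is normal with
unknown mean $W$ and known SD $\sigma_X$; beliefs about $W$ are
conjugate normal (prior mean $\mu_0$, effective sample size $n_0$).
Recruitment should continue while the expected value of one more
pair's information — valued over the $P$ future patients the adoption
decision covers — exceeds its variable cost $c$. Because outcomes
arrive a delay $\tau$ pairs after allocation, stopping still leaves a
*pipeline* of $\tau$ pairs to follow up before the adoption decision,
which goes to the new technology exactly when the final posterior
mean is positive.

The package solves the optimal stopping problem by backward induction
(`solve_boundary()`), classifies the optimal design from the prior
mean — no trial / one-stage / sequential (`classify_prior()`,
`one_stage_design()`) — replays block-level trial data against the
boundary with scheduled interim analyses and pipeline accounting
(`run_path()`), and measures operating characteristics by block
bootstrap, Monte Carlo simulation and a no-stopping fixed design
(`bootstrap_paths()`, `monte_carlo_paths()`, `fixed_design_paths()`).
A synthetic-data module (`generate_blocks()`,
`synthetic_profher_blocks()`) emulates the worked example — a UK
pragmatic trial of surgery versus sling immobilisation for displaced
proximal humeral fracture — so every analysis runs without access to
patient-level data. Results are tibbles with `tidy()`/`glance()`
methods and `autoplot()` figures throughout.

## Worked example

The shipped parameters (`profher_params()`): λ = £20,000/QALY,
c = £4,080 per pair (a 50:50 fixed:variable split of the £1.02m
recruitment/follow-up spend over 125 pairs), τ = 47 pairs (one year at
the observed recruitment rate), interim analyses every 10 pairs,
near non-informative prior (μ0 = 0, n0 = 2), σ_X ≈ £14,157 derived
from published confidence intervals, and P = 2,000 patients (an
estimate; see the methods vignette for both derivations).

```r
library(valseq)

pf <- profher_params(q_max = 250)
b  <- solve_boundary(pf$params, pf$prior)
classify_prior(b)
#> <valseq_design>
#>   optimal design at mu0 = 0 GBP: sequential
#>   prior-mean thresholds (GBP):
#>     A = 22675  (above: adopt new, no trial)
#>     C = 5842  (upper sequential limit)
#>     D = -5842  (lower sequential limit)
#>     B = -22675  (below: adopt standard, no trial)
```

A prior mean of zero lies between D and C, so sequential monitoring is
the optimal design: prior evidence alone decides nothing, and a fixed
sample size would ignore what the interim data are worth. Replaying a
synthetic 250-pair outcome stream against the boundary:

```r
blocks <- synthetic_profher_blocks(seed = 3, n_pairs = 250)
run_path(blocks, b)
#> <valseq_path>
#>   stopped at interim 3 (30 observed pairs, 77 allocations)
#>   posterior mean -4732 GBP at stop, -2335 GBP after pipeline follow-up
#>   decision: standard technology (crossing: lower)
#>   variable cost 314160 GBP; budget change -195840 GBP (-13.3%)
```

This path crosses the lower boundary at the third interim look: 30
pairs observed plus the 47-pair pipeline makes 77 allocations, the
posterior mean after pipeline follow-up stays negative (surgery is not
cost-effective at £20,000/QALY), so the standard technology (sling) is
recommended — 48 pairs and £195,840 (13.3% of the £1.47m budget) short
of the reference 125-pair fixed design. Operating characteristics over
5000 bootstrap resamples of the trial-sized table:

```r
oc <- bootstrap_paths(synthetic_profher_blocks(seed = 42), 5000, b, seed = 43)
oc
#> <valseq_oc> sequential design, bootstrap source, 5000 paths (seed 43)
#>   allocations: mean 91.1 (sd 34.2, min 57, max 250); change -27% vs 125
#>   budget change: mean -138128 GBP (-9.4% of 1,470,000)
#>   terminal posterior mean: -1898 GBP (sd 1614)
#>   P(standard) = 0.888, P(new) = 0.112; crossings: lower 0.827, upper 0.171, reached max 0.002
```

The design stops early for most resampled histories (the minimum, 57,
is one interim block plus the pipeline), recommends sling with
probability 0.89, and most stops cross the lower boundary.
`glance(oc)` returns the same numbers as a one-row tibble,
`tidy(oc)` the per-path results, and `autoplot(oc)` the sample-size
histogram. `run_pipeline()` drives boundary → replay → bootstrap →
Monte Carlo → fixed design from a single YAML configuration and
writes seed-stamped CSV/JSON reports.

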