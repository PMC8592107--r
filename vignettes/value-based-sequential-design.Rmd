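---
title: "Value-based sequential trial design with delayed outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value-based sequential trial design with delayed outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valseq)
```

## The decision problem

valseq implements a Bayesian decision-theoretic design for a two-arm
trial that randomises patients in pairs — one to a new technology, one
to the standard — and monitors *incremental net monetary benefit*
as outcomes accrue. For pair $j$,

$$X_j = \lambda\,(E_{N,j} - E_{S,j}) - (C_{N,j} - C_{S,j}),$$

where $E$ is effectiveness (QALYs), $C$ is treatment cost and
$\lambda$ is the willingness to pay per QALY. $X$ is modelled as
normal with unknown mean $W$ and known sampling SD $\sigma_X$.
Beliefs about $W$ are conjugate normal: a prior with mean $\mu_0$ and
effective sample size $n_0 = \sigma_X^2/\sigma_0^2$ (the prior's
weight, in pairs), updated to posterior mean
$\mu_n = (\mu_0 n_0 + \sum_j x_j)/(n_0 + n)$ after $n$ observed pairs.

What distinguishes the design from conventional group-sequential
monitoring is its objective: recruitment should continue exactly while
the expected value of the information from another pair exceeds the
cost $c$ of recruiting it. Value accrues to the $P$ future patients to
whom the adoption decision applies; with switching cost $I = 0$ the
terminal rule is simply "adopt the new technology iff the final
posterior mean is positive", worth
$P \cdot \mathrm{E}[\max(W, 0)]$ in expectation.

Outcomes are observed a delay $\tau$ (in pairs, at the observed
recruitment rate) after allocation, which creates three stages:

* **Stage I** — the first $\tau$ pairs are recruited with nothing yet
  observed;
* **Stage II** — outcomes stream in, the posterior is updated at
  interim analyses, and recruitment may stop;
* **Stage III** — recruitment has stopped but the $\tau$ *pipeline*
  pairs already allocated are still followed up before the adoption
  decision.

## Solving for the stopping boundary

With $N = Q_{\max} - \tau$ observable pairs, the value of being at
state $(n, \mu)$ satisfies

$$V(n, \mu) = \max\Big\{ S(n,\mu),\; -c + \mathrm{E}\,[V(n+1, \mu')] \Big\},
\qquad \mu' \sim \mathrm{N}(\mu, v_n^2),$$

with terminal condition $V(N, \mu) = S(N, \mu)$. Here
$S(n,\mu) = P\,[\mu\,\Phi(\mu/s_n) + s_n\,\phi(\mu/s_n)]$ is the
stopping value — the expected payoff of deciding after the pipeline's
$\min(\tau, Q_{\max}-n)$ outcomes resolve, with
$s_n = \sigma_X\sqrt{1/(n_0+n) - 1/(n_0+n+p)}$ — and
$v_n = \sigma_X\sqrt{1/(n_0+n) - 1/(n_0+n+1)}$ is the preposterior SD
of one more observation. `solve_boundary()` runs this backward
induction on a uniform grid of posterior means; the set where
continuation strictly beats stopping is an interval at each $n$, and
its endpoints are the lower and upper stopping boundary. The interval
shrinks as $n$ grows and is empty at $n = N$, where recruitment cannot
continue.

Numerical choices, all overridable:

* **Grid**: 1001 points spanning $\mu_0 \pm 6\,\sigma_X/\sqrt{n_0}$
  — six prior standard deviations covers the prior-predictive spread
  of the terminal posterior mean. If a computed boundary comes within
  5% of a grid edge the solver errors and asks for a wider grid rather
  than silently truncating.
* **Expectation**: Gauss–Hermite quadrature, 21 nodes (computed
  internally by Golub–Welsch), with linear interpolation of
  $V(n+1,\cdot)$ between grid points; quadrature points beyond the
  grid use the analytic stopping value, which is exact far outside the
  continuation region. A two-point $\pm v_n$ discretisation is
  available for validation against exhaustive policy enumeration on
  tiny instances (the test suite does exactly this).
* **Tie-break**: stop when continuation is not *strictly* better, so
  the boundary itself belongs to the continuation region's complement
  in value but paths sitting exactly on it continue — mirrored by the
  monitoring engine.
* **Degenerate cases**: a prohibitive $c$ yields an everywhere-empty
  continuation region (no Stage II); $\tau = 0$ collapses the pipeline
  so stopping decides immediately on the sign of $\mu$.

`classify_prior()` compares, at $\mu_0$, the no-trial value
$P\max(\mu_0,0)$, the best *one-stage* design (a fixed $n \in
(0,\tau)$ maximising expected value of sample information minus
$c\,n$ — with fewer pairs than the delay there is nothing to monitor),
and the sequential value $-c\,\tau + V(0,\mu_0)$ (Stage I's variable
costs are committed at entry; they are sunk by Stage II and so do not
affect the boundary). Bisection on the pairwise differences locates
the four prior-mean thresholds: reading downward, above A adopt the
new technology outright, (C, A] one-stage, [D, C] sequential, [B, D)
one-stage, below B adopt the standard outright. With $I=0$ and no
discounting the problem is symmetric
($V(n,\mu) - P\mu = V(n,-\mu)$), so B $= -$A and D $= -$C.

## Monitoring, replay and operating characteristics

`run_path()` replays an ordered stream of block summaries: interim
analyses every `block_size` observed pairs (plus a forced final look
at $N$ when $N$ is not a multiple), stop at the first look with
$\mu < \mathrm{lower}(n)$ or $\mu > \mathrm{upper}(n)$, then consume
the pipeline pairs and decide by the sign of the final posterior mean
(a tie favours the standard technology). A block mean enters the
update with multiplicity equal to its pair count, which is exactly
equivalent to the per-pair update for the posterior mean under known
$\sigma_X$; partial blocks (including a pipeline that ends mid-block)
use fractional multiplicity the same way. Total allocations are
$T = n_{\text{stop}} + \tau$, variable cost $c\,T$, and budget impact
is reported against a reference design
($(T - 125) \times c$, as GBP and as a share of a £1.47m budget).

`bootstrap_paths()` resamples whole blocks with replacement — the
resampling unit is the block because that is the granularity of
published trial summaries — until $Q_{\max}$ pairs are available per
path; `monte_carlo_paths()` draws per-pair values
$\mathrm{N}(\text{mean}, \sigma_X^2)$ and assembles them into blocks so
look times match the bootstrap exactly; `fixed_design_paths()` runs
every path to $Q_{\max}$ with no stopping. All are seeded and
bit-reproducible. `summarize_paths()` reports mean/SD (sample SD,
$n-1$ denominator)/min/max of the sample size, budget change and
terminal posterior mean, the decision-by-crossing probability matrix
and look-by-look stopping fractions. The shipped analyses use 5000
paths, enough to put the Monte Carlo standard error of a mean sample
size near half a pair.

## The worked example and its two estimated inputs

The shipped configuration (`profher_params()`) is patterned on a UK
pragmatic trial of surgery versus sling immobilisation for displaced
proximal humeral fracture: $\lambda = £20{,}000$/QALY, $Q_{\max} \in
\{125, 250\}$ pairs, interim analyses every 10 pairs, a one-year delay
equal to $\tau = 47$ pairs at the observed recruitment rate, and a
near non-informative prior $\mu_0 = 0$, $n_0 = 2$. The variable cost
$c = £4{,}080$ per pair follows from splitting the £1.02m
recruitment-and-follow-up spend 50:50 into fixed and variable parts
over 125 pairs (`derive_variable_cost()`).

Two inputs are *estimates*, because their source values were never
published in a main text:

* $\sigma_X$ is back-derived from the published 95% confidence
  intervals for incremental cost (£1126–£2389) and incremental QALYs
  ($-0.13$–$0.11$): each CI width is $3.92$ standard errors of a mean
  over 125 pairs, giving a per-pair SD of about £14,157
  (`derive_pair_sd()`), under an assumed zero effect–cost correlation
  — the key free parameter of the derivation. The CIs are two-year
  quantities while the monitored net-benefit stream is a one-year one,
  so this likely overstates $\sigma_X$ somewhat; published
  fixed-design dispersion is consistent with a value nearer £11,500.
* $P$, the population to benefit, is set to 2,000 patients — a round
  incidence-times-horizon figure for UK patients with displaced
  proximal humeral fracture for whom the surgery-versus-sling choice
  is genuinely open, and the scale at which, under the $\sigma_X$
  above, the sequential design is the optimal choice at $\mu_0 = 0$
  (below roughly 1,900 the one-stage design narrowly wins). Both
  knobs are plain arguments; users with better estimates should
  override them, and boundary geometry responds materially to both.

## What the synthetic generator does and does not emulate

`generate_pairs()` / `generate_blocks()` draw per-pair (incremental
effectiveness, incremental cost) from a bivariate normal — matching
the model's own normality assumption — and aggregate into blocks of
10 (a final partial block holds any remainder). Defaults target a mean
incremental net monetary benefit of $-£1{,}808$ per pair, carried
entirely by the cost term, with component SDs from the same CI
decomposition as $\sigma_X$ and zero correlation.
`synthetic_profher_blocks()` additionally *conditions* the table on
its realised moments: the published $-£1{,}808$ is the realised sample
mean of the observed table (the quantity the real bootstrap resampled
around), and a dozen blocks estimate their own spread very noisily, so
the table mean is pinned exactly and the full blocks' mean-SD is pinned
to $\sigma_X/\sqrt{10}$. Without conditioning, every downstream
statistic inherits roughly ±£900 of table-mean noise per seed.

The emulator reproduces the statistical structure the analysis
assumes, not the realised trial data. In particular its block means
are exactly normal with the theoretical spread: real block summaries
are overdispersed (secular trends, centre effects, heavy tails), which
produces more early boundary exits and hence smaller realised sample
sizes than normal theory predicts. Tests passing under the emulation
therefore validate the machinery — updating, boundary, schedule,
accounting, resampling — and the qualitative design behaviour; they do
not certify operating characteristics on real data, and the package's
bootstrap mean sample size under the emulation sits visibly above the
published one for exactly this reason. The emulator also ignores
missing data, loss to follow-up and treatment crossovers, which are
outside the model's scope.

## Known limitations

* $\sigma_X$ is treated as known and is never re-estimated from the
  stream; the unknown-variance (normal-gamma) extension is out of
  scope.
* Nonzero switching cost $I$ is carried in the parameter object but
  rejected by the solver; it would shift the terminal rule away from
  the sign of the posterior mean.
* No discounting, and no benefit accrues to in-trial patients: the
  reward term covers only the $P$ post-trial patients.
* Calendar-time accrual is not modelled; the delay is a fixed number
  of pairs.
* The discrete-time recursion on a grid is the contract; a
  continuous-time free-boundary treatment exists in the literature and
  is not implemented.

## Reproducibility

Every stochastic entry point takes an explicit seed and is
bit-reproducible under it. `run_pipeline()` executes a whole analysis
from one YAML configuration and writes CSV/JSON reports whose headers
carry the seed and a configuration hash; identical configurations give
byte-identical outputs. `scripts/acceptance.R` (repository root)
recomputes the headline quantities from scratch against the installed
package.
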