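---
title: "Methods: calibrated differentially private chi-squared testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated differentially private chi-squared testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(privchisq)
```

## Setting and threat model

An I×J contingency table cross-classifies n individuals by group (rows,
e.g. case/control or genotype class) and condition (columns). Pearson's
statistic

$$\chi^2 = \sum_{i,j} \frac{(E_{ij} - O_{ij})^2}{E_{ij}}, \qquad
  E_{ij} = \frac{s_j m_i}{n},$$

with $v = (I-1)(J-1)$ degrees of freedom tests independence of the two
classifications. Releasing $\chi^2$ (or its p-value) exactly can reveal
whether a target individual's record is in the table, so we release it under
ε-differential privacy: the output distribution may change by at most a
factor $e^\varepsilon$ between *neighboring* tables. Following the
convention of this literature, the row totals $m_i$ are public (they are
needed to interpret the statistic at all), so neighboring tables share all
row totals and differ by one record moving between two columns within one
row. The trusted curator holds the raw table; local privacy models are out
of scope.

Row orientation matters throughout the package: `contingency_table()` and
the CSV reader treat **rows as the groups whose totals are public**.
Transposing a table changes the sensitivity and hence the noise scale.

## Global sensitivity

The Laplace mechanism adds zero-mean Laplace noise with scale
$\Delta/\varepsilon$, where $\Delta$ is the statistic's global sensitivity —
the largest $|\chi^2(D_1) - \chi^2(D_2)|$ over neighboring pairs. With
$m_\alpha \le m_\beta$ the two smallest row totals,

$$\Delta_R = \frac{(m_\alpha + m_\beta)\,n}{m_\alpha(1+m_\beta)}
  \;\; (J \ge 3), \qquad
  \Delta_R = \frac{n^2}{m_\alpha(n - m_\alpha + 1)} \;\; (J = 2).$$

For two-row tables this reduces algebraically to the classical two-margin
bound $\Delta_Y = \frac{n^2}{m_1 m_2}\bigl(1 - \frac{1}{\max(m_1,m_2)+1}\bigr)$,
and under equal margins to $\Delta_F = 4n/(n+2)$; both reductions are
verified to $10^{-12}$ in the test suite.

Rather than re-deriving the extremal-table argument, the package validates
the formula *executably*: `brute_force_sensitivity()` (compiled, Rcpp)
enumerates every table with the given row margins and every in-row
unit-move neighbor, and maximizes the statistic's change. The test suite
runs it over all margin vectors with $I \in \{2,3\}$, $J \in \{2,3,4\}$ and
$m_i \in [2,6]$ and finds agreement with $\Delta_R$ to $10^{-9}$.

One domain decision deserves a note. The extremal neighbor pairs concentrate
whole rows into single columns, which routinely empties the remaining
columns; a zero-total column has $E_{ij} = 0$ and the term $(E-O)^2/E$ is
formally undefined there, though its limit as $E \to 0$ with $O = 0$ is 0.
The oracle's default (`zero_columns = "drop_term"`) adopts that limit, which
is the domain over which the closed form is tight — this is how the
sensitivity-maximizing configurations are actually realized. The stricter
`"skip_table"` mode, which excludes any pair touching a zero-column table,
can give a strictly smaller maximum for very small margins (e.g. margins
(2,2) with J = 3: 2 instead of 8/3). Either way $\Delta_R$ upper-bounds the
realizable change, so the privacy guarantee is unaffected.

## The privatized null distribution and calibration

The released statistic is $\chi^{2*} = \chi^2 + L$,
$L \sim \mathrm{Laplace}(\beta)$, $\beta = \Delta_R/\varepsilon$. Under the
null, $\chi^{2*}$ follows the convolution
$g_{v,\Delta,\varepsilon} = \chi^2_v * \mathrm{Laplace}(\beta)$. Comparing
$\chi^{2*}$ against the classical percentage point ignores the noise and
inflates type-I error (that baseline is `rand_chi()`); RandChiDist instead
solves

$$\int_t^\infty g_{v,\Delta,\varepsilon}(x)\,dx = \alpha$$

for the threshold $t$ and rejects iff $\chi^{2*} \ge t$, with the private
p-value $\int_{\chi^{2*}}^\infty g$. Both the decision rule and the p-value
come from the *same single* noisy statistic, so each invocation spends
exactly one ε; the p-value lets an analyst test at any level without
re-querying.

### Numerics

The tail is never computed by integrating the convolved density twice.
Exchanging the order of integration gives

$$P(\chi^2_v + L \ge x) = \int_0^\infty f_v(\mu)\, S_L(x-\mu;\beta)\,d\mu,$$

with $S_L$ the closed-form Laplace survival function, and the implementation
further splits around the classical tail so the zero-noise limit is exact:
$P = P(\chi^2_v \ge x) + \tfrac12\int_0^x f_v e^{-(x-\mu)/\beta}
- \tfrac12\int_x^\infty f_v e^{-(\mu-x)/\beta}$. For $x \le 0$ the whole
expression collapses to the chi-squared Laplace transform,
$1 - \tfrac12 e^{x/\beta}(1+2/\beta)^{-v/2}$, in closed form. Negative
arguments are fully in-domain — the noise is never truncated, which would
break the privacy proof.

Two scales coexist in the integrands: the Laplace kernel varies over $\beta$
(anywhere from $10^{-9}$ to $10^3$ across sensible ε) and the chi-squared
density over a few units. A single adaptive quadrature over the whole range
can overlook a boundary layer much narrower than the interval, so the
integrals are cut at logarithmically spaced offsets from both the kernel
kink $\mu = x$ and the origin before `stats::integrate` is applied per
piece; regions carrying kernel weight below $e^{-60}$ are dropped. For
$v = 1$ every piece is integrated under the substitution $\mu = y^2$, which
removes the density's inverse-square-root singularity at zero ($v = 2$ is
bounded and needs nothing special). Absolute tolerances: $10^{-10}$ for the
density, $10^{-8}$ for the tail. Against high-precision reference values the
implementation is accurate to about $3\times10^{-11}$ (density) and
$10^{-13}$ (tail) across $\beta \in [10^{-6}, 400]$, $v \in \{1,2,4,9\}$.

`critical_value()` inverts the strictly decreasing tail by Brent root
refinement. For $\beta > 3$ the starting bracket comes from the far-tail
approximation $t \approx \beta[\ln\frac{1}{2\alpha} -
\tfrac{v}{2}\ln(1 - 2/\beta)]$ (the chi-squared moment generating function
evaluated at $1/\beta$), otherwise from
$[-\beta\ln\frac{1}{2\alpha} - 1,\; q_{\chi^2_v}(1-\alpha) +
\beta\ln\frac{1}{2\alpha} + 1]$; the bracket auto-extends if needed, the
root is refined to $10^{-10}$, and a post-check aborts if the round-trip
residual exceeds $10^{-6}$. Thresholds are memoized per
$(v, \beta, \alpha)$ within the session — simulations revisit the same
margin configurations constantly — and never cached on disk.

## Baseline mechanisms

* `rand_chi()`: same noisy statistic, classical threshold and p-value.
  Private, but with no threshold correction its empirical significance falls
  well below $1-\alpha$ at small ε.
* `rand_cell()`: independent Laplace$(2/\varepsilon)$ noise on every cell
  (one record changes two cells by one each, so the table's sensitivity
  is 2). If any noisy cell is below 5 the mechanism fails to reject — the
  usual rule of thumb that the chi-squared approximation is unreliable below
  five counts, applied to the noisy values since those are all the mechanism
  may look at. Otherwise the statistic is recomputed on the noisy
  real-valued table with its noisy margins (kept real: no rounding or
  clamping) and compared classically. Degenerate non-positive noisy margins
  are recorded with a flag, not raised as errors.
* `mc_indep()`: privatizes the table as RandCell does, estimates the
  independence multinomial $\hat p_{ij} = (\tilde m_i/\tilde n)(\tilde
  s_j/\tilde n)$ from the noisy margins (negatives floored at zero before
  normalizing, $\tilde n$ rounded and floored at 1), draws reference tables
  from it with fresh same-scale Laplace perturbations so reference and
  observed statistics are comparable, fails to reject outright if any
  reference cell falls below 5, and otherwise rejects iff the observed noisy
  statistic exceeds the empirical $(1-\alpha)$ quantile of the reference
  statistics. The published description of this baseline leaves some
  parameters to its original source; the choices here — full ε on the
  observed-table noise, fresh same-scale noise on references, the
  rule-of-thumb gate on the noisy reference cells, and
  `n_mc_tables = max(ceiling(2/alpha), 1000)` (at least $1/\alpha$ tables
  are required) — are interpretive and confined to this one function.
* `non_private_test()`: the classical test, as the yardstick.

## Simulation harness

`sample_multinomial_table()` draws counts from Multinomial(n, p). Tables
with a zero row or column margin are resampled — the statistic does not
exist there, and how such draws were handled in comparable experiments is
never stated — with the resample count reported so the conditioning is
visible (at the default designs it is essentially zero). The optional
`min_cell_filter` additionally conditions on all cells ≥ 5; it exists
because the rule-of-thumb filter is documented only for real-data
experiments in this literature, so it defaults to off for the synthetic
designs.

`run_experiment()` runs every requested mechanism on the *same* table per
replicate (paired design, chosen for variance reduction in mechanism
contrasts; whether the original experiments paired tables is unstated).
Substreams are derived from the master seed so that the table sequence is
bit-identical whatever mechanisms are requested, and each mechanism gets an
independent per-replicate noise stream. Decisions are scored against the
design's truth — derived from whether the cell probabilities factorize into
their margins, never taken on faith from a label — giving empirical
significance under null designs and empirical power under alternatives,
with binomial standard errors. Per-replicate mechanism failures are counted
and reported, never silently dropped.

The stock designs mirror the standard evaluation: uniform 2×2 and 4×4
nulls; alternatives built by `effect_probs()` as base + δ·pattern, e.g.
(0.25±0.01), (0.25±0.15), the unbalanced (0.3±0.15, 0.2∓0.15), and a 3×4
pattern at δ = 0.07; n ∈ {100, 300, 500, 700, 900}; α ∈ {0.005, 0.01,
0.05}; ε = 0.1 as the headline budget; 1000 replicates by default. No
multiple-testing correction is applied: each simulated test is treated as an
independent release, matching how these mechanisms are compared. For
associated-pair designs standing in for linkage-disequilibrium tables (real
genotype data are out of scope), `correlated_pair_probs()` mixes an
independence outer product with a diagonal concentration; `mixing = 0` is
exact independence.

Problem sizes used by the shipped checks: the type-I experiments run 2000
replicates per grid point (2×2 at α = 0.05, 4×4 at α = 0.005), the power
bound 1000 per point, the mechanism-ordering comparisons 500 per point, and
the sensitivity oracle covers all margin vectors with $m_i \in [2,6]$ up to
3×4 tables — about $8.6\times10^6$ enumerated tables in total.

### What the generator does and does not emulate

The multinomial generator reproduces the sampling model under which the
type-I and power claims are stated: i.i.d. individuals, fixed cell
probabilities, total n fixed. It does not emulate features of real genotype
data — linkage structure along the genome, population stratification,
missingness, or margin imbalance beyond what the designs encode. Passing
tests therefore demonstrate calibration and relative power under the stated
sampling model, not performance on any particular real cohort.

## Known limitations

* Choosing ε is the analyst's problem; the package takes it as given.
* Row totals are assumed public. If they are sensitive, $\Delta_R$ does not
  apply.
* The brute-force oracle is exponential and guarded at $10^7$ tables; it is
  a validation instrument for small margins, not a production path.
* Zero row/column margins are a hard error for the statistic (no continuity
  correction, no automatic dropping); Yates correction, Fisher's exact test
  and G-tests are deliberately absent.
* `mc_indep()` operationalizes a baseline whose full parameterization is not
  published alongside its description; see above for the choices made.
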