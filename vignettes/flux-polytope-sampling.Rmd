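---
title: "Estimating flux distributions over the steady-state polytope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating flux distributions over the steady-state polytope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A constraint-based metabolic model describes a network of $N$ reactions
transforming $M$ metabolites through a signed stoichiometric matrix
$\xi = \{\xi_{i\mu}\}$ (negative entries for substrates, positive for
products). At non-equilibrium steady state every metabolite's production
balances its consumption,

$$\sum_{i=1}^{N} \xi_{i\mu}\, x_i \;=\; \gamma^\mu , \qquad
  m_i \le x_i \le M_i ,$$

where $x_i$ is the flux of reaction $i$, the box bounds encode capacity and
reversibility (a negative lower bound allows reverse flux), and $\gamma^\mu$
is the exchange rate of metabolite $\mu$ with the environment: identically 0
for internal metabolites, a known value $z_0$, or a value known only to lie
in a window $[m^\mu, M^\mu]$. The feasible flux vectors form a bounded convex
polytope $S$. Beyond optimizing a single objective over $S$, many questions
(robustness, flux variability, experiment design) need the *marginal
probability density* $P_i(x)$ of each flux when $S$ is sampled uniformly.
Computing these marginals is the purpose of this package, by two independent
routes:

* **weighted Belief Propagation (wBP)** — a message-passing approximation on
  the bipartite reaction–metabolite graph whose cost grows *linearly* with
  the number of reactions, so it remains usable at sizes where exact
  samplers become impractical;
* **Kernel Hit-and-Run (KHR)** — a provably uniform Markov-chain sampler,
  run in the null space of the internal stoichiometry, used here both as a
  production sampler for moderate sizes and as the reference against which
  wBP is validated.

## Weighted Belief Propagation

On a locally tree-like bipartite graph, removing one metabolite makes the
reactions that process it statistically independent; this yields two coupled
sets of cavity quantities on directed edges: $L_{\mu\to i}(x)$, the
probability that metabolite $\mu$'s balance holds when flux $i$ is fixed at
$x$, obtained by integrating the cavity marginals of $\mu$'s other reactions
over the shifted constraint row; and $P_{i\to\mu}(x)$, the cavity marginal of
flux $i$ with $\mu$ removed, proportional to the product of
$L_{\nu\to i}(x)$ over the reaction's other metabolites $\nu$. At the fixed
point, the marginal of flux $i$ is the full product
$P_i(x) \propto \prod_{\nu\in i} L_{\nu\to i}(x)$, and the posterior of an
unknown exchange rate $\gamma^\mu$ follows from the same assembly with
$\gamma$ as the queried variable. These relations are exact on trees and a
controlled heuristic on graphs whose cycles are long.

Two implementation choices define this engine:

**Weighted populations instead of bins.** Each message is a population of
$Q$ flux values on a fixed equispaced grid spanning $[m_i, M_i]$, carrying
evolving nonnegative weights. Because the grid adapts to each flux's own
bounds, fluxes living on wildly different scales (orders of magnitude apart)
are represented equally well — the motivation for this representation over a
global discretization. Only the weights are updated; the abscissae never
move.

**Rejection-free weighted integration.** The cavity integrals are estimated
by Monte Carlo, but naive sampling of a constraint row would reject every
draw that cannot satisfy the row. Instead, variables are drawn sequentially,
each restricted to its *feasible window* — the interval of values for which
the remaining variables can still close the constraint, computed by interval
arithmetic over the not-yet-sampled supports. Each truncated draw
contributes a factor equal to the truncated probability mass (the discrete
analogue of the reweighting factor $w(y)$ of importance sampling), so no
draw is ever discarded; infeasibility shows up only as a zero weight. For an
equality row one variable is *solved for* rather than sampled; its
contribution is its population density at the solved value divided by the
Jacobian $|\xi_k|$ of the delta constraint.

### Numerical choices

* **Solved-variable density.** The population density at the solved point is
  evaluated from a piecewise-constant histogram with $B = 50$ equal-width
  bins over the variable's support (configurable). The choice is cheap and
  deterministic given the population; any consistent density estimate works
  because messages are renormalized.
* **Solved-variable selection.** Per constraint row, the solved variable is
  the one with the widest feasible window, ties broken by largest
  coefficient magnitude, then declaration order. Dividing by a large
  $|\xi_k|$ is numerically safest, and a wide window keeps the histogram
  density well populated; in particular a flux pinned by degenerate bounds
  (zero-width window) is never solved for when an alternative exists.
* **Sampling order.** The non-solved variables are drawn in a fresh uniform
  random permutation per draw, which symmetrizes any residual order bias.
* **Window emptiness** is decided with a relative tolerance of $10^{-12}$.
* **Update schedule.** Messages are updated sequentially in a fixed edge
  order (metabolites in declared order, reactions within), so runs with the
  same seed are bitwise reproducible. Damping
  $\lambda$ mixes new and old weights; the default is 0, and $\lambda = 0.5$
  is the preset the package uses on loopy instances.
* **Deterministic shortcuts.** A cavity row with a single free variable is a
  forced assignment; it is evaluated once instead of `n_draws` times. This
  makes linear chains essentially free without changing any estimate.
* **Starved messages** (all population weights zero, indicating an
  infeasible or near-infeasible instance) abort with a diagnostic naming the
  edge, rather than silently renormalizing.
* **Exchange windows.** A metabolite with a window prior enters its
  constraint row as an equality with the exchange rate appended as one extra
  variable (coefficient $-1$, uniform population over the window), so its
  posterior is available by the same machinery.

The default protocol — $Q = 500$ population values per message, 30
iterations with $10^3 t$ draws per population point at iteration $t$, and
$10^5$ draws per point for the final assembly — follows the run protocol
used for the human red-blood-cell benchmark. The draw schedule is exposed
separately from the final-assembly count because the two budgets play
different roles (fixed-point refinement vs final variance reduction).

## Kernel Hit-and-Run

The internal balances $S_{\rm int}\,x = 0$ confine $x$ to a linear subspace
of dimension $K = N - \mathrm{rank}(S_{\rm int})$, typically far smaller
than $N$ (for a red-blood-cell-shaped system, $K = 12$ against $N = 46$).
An orthonormal basis $\Phi$ of the null space (by SVD; singular values below
$10^{-10}$ of the largest are treated as zero) turns the box and window
constraints into a $K$-dimensional polytope
$\{\,y : \mathrm{lo} \le \Psi y \le \mathrm{hi}\,\}$ with one row per flux
bound pair and one row per exchange window. Hit-and-Run — an isotropic
random direction, then a uniform point on the feasible chord — converges to
the uniform law on this polytope, with mixing time $O(K^3)$ rather than
$O(N^3)$; the linear lift $x = x_p + \Phi y$ preserves uniformity, so the
flux-space sample is uniform by construction, and no artificial enclosing
box is ever introduced.

Design choices:

* **Equalities are folded, not squeezed.** Fixed-rate exchanges
  ($\xi_{\cdot\mu} x = z_0$) and fluxes pinned by $m_i = M_i$ are appended
  to the equality system before the null-space step, with the affine offset
  $x_p$ obtained as the minimum-norm solution via the pseudoinverse. This
  keeps the polytope full-dimensional in $y$ instead of leaving zero-width
  inequality rows. An inconsistent equality system is reported as
  infeasible.
* **Boundedness certificate.** The polytope is certified bounded by
  checking that the rows with two finite bounds span all $K$ directions
  (full column rank); since flux bounds are finite in a valid network and
  the unpinned rows of $\Phi$ have rank $K$, the certificate always holds
  there, and a rank deficiency is reported with an unbounded direction.
  This algebraic certificate replaces per-coordinate linear programs and is
  exact for the constraint systems this package builds.
* **Interior points by MinOver.** A perceptron-style relaxation steps from
  the current point along the inward unit normal of the worst row
  (smallest slack relative to its own slab width), with step size
  $\eta_t = \eta_0 / (1 + t/10^3)$, $\eta_0$ the polytope scale, capped by a
  slightly overrelaxed move to a per-row target slack of 30% of the slab
  width. Per-row targets matter when bounds span orders of magnitude: a
  single global margin either ignores narrow slabs or never terminates.
  After feasibility, up to 100 extra centering steps of the same form push
  the point further inside. A `chebyshev` alternative maximizes the minimum
  normalized slack by subgradient ascent (the maximizer is the Chebyshev
  center); it exists for polytopes where MinOver's first feasible point is
  too close to a face.
* **Burn-in, thinning, chains.** Defaults: $10^4$ discarded steps, record
  every $10K$-th step, 3 chains from independently randomized interior
  starting points whose samples are pooled (averaging over initial
  conditions). The $O(K^3)$ mixing budget is the reason thinning scales
  with $K$. All three are configurable.
* **Hard output guarantees.** Every emitted sample is checked against the
  internal balances ($10^{-8}$ relative) and all box/exchange windows
  ($10^{-9}$ relative); violations raise errors rather than warnings.
* A zero-dimensional polytope ($K = 0$) returns the unique solution once,
  with a warning. A zero-*volume* polytope with $K > 0$ (e.g. bounds that
  pin the feasible set to a face) has no strictly interior point and is
  reported by the interior-point search; the wBP route still handles such
  instances, placing its mass on the degenerate support.

## Synthetic networks and what the tests show

`random_network()` draws sparse bipartite instances: each metabolite's
degree is $2 + \mathrm{Poisson}(d - 2)$ (mean $d$, default 3, never below
2); a reaction left untouched takes over a slot from a reaction that has
several, conserving the drawn degrees; signs are flipped where needed so
every metabolite has at least one producer and one consumer (otherwise its
balance would pin all its fluxes to zero); coefficients are $\pm 1$ or
signed uniform magnitudes in $[0.1, 2]$; bounds default to $[0, 1]$, with an
optional log-spread factor that rescales each reaction's bounds by
$10^{U(-s, s)}$. Generated instances are certified: full-row-rank internal
submatrix, bounded projected polytope, and a strictly interior point;
failures are regenerated (the draw of a fresh attempt is part of the
ensemble definition). The default ensemble uses $M = N/2$ metabolites, the
shape used for the cost-scaling experiments.

These instances emulate the *geometry* of metabolic polytopes — sparse
signed stoichiometry, mixed flux scales, low-dimensional null spaces — but
not the biology: no currency-metabolite hubs with degree in the dozens, no
gene rules, no realistic pathway structure. Consequently, passing tests
demonstrate correctness of the machinery and the quality of the tree
approximation at low loop density; they do not bound wBP's error on a real
reconstruction whose cofactor hubs create many short loops. On random
instances at $N = 40$, $M = 20$ the package's own cross-validation finds
mean per-flux total variation against KHR of a few percent, with the worst
flux of a typical instance at 0.05--0.08; instances whose draw happens to
contain short loops can push a worst flux to $\sim$0.18, an error that is
insensitive to more iterations, draws or damping — it is the tree
approximation itself, concentrated on the looped reactions (verified
against dense quadrature on a 4-cycle toy, where KHR stays within 0.01 of
the exact marginals). On trees (stars, chains) wBP is exact up to Monte
Carlo noise.

Problem sizes in the test-suite and acceptance runs (star fixtures to
$n = 6$, chains to 5 metabolites, ten $N = 40$ cross-method instances,
cost-scaling to $N = 400$ with reduced draw schedules) were chosen so the
full suite completes in minutes on one core while keeping every estimator
within its stated tolerance; the run protocol itself ($Q$, iteration count,
draw schedule) is never reduced where a check pins it.

## Known limitations

* wBP convergence is not guaranteed on loopy graphs; damping is exposed and
  a starved message aborts loudly, but densely connected currency
  metabolites remain best-effort (their marginals are the ones wBP is known
  to capture least well).
* The KHR chain is run without preconditioning (no rounding of elongated
  polytopes); strongly anisotropic instances may need larger thinning.
* Only marginal densities are produced — no joint distributions, no volume
  or entropy estimates, and no optimality-biased priors.
* File formats are the package's own JSON/TSV dialects; full SBML/COBRA
  import, gene–protein–reaction rules and compartments are out of scope.

## A worked example

```{r, eval = FALSE}
library(fluxpdf)

net <- star_network(5)            # 5 producers, one drain pinned at 1
wb  <- run_wbp(net, wbp_config(seed = 1))
kh  <- khr_sample(net, khr_config(n_samples = 1e5, seed = 2))
compare_marginals(wb, marginals_from_samples(kh))
```

The star's polytope is the 4-simplex, whose exact per-flux marginal is
$\mathrm{Beta}(1,4)$ with density $4(1-x)^3$; both methods reproduce it and
the comparison report shows per-flux total-variation distances at the Monte
Carlo noise level.
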