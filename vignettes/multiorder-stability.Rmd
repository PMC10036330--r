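---
title: "Multiorder Laplacian stability of synchronization in higher-order networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiorder Laplacian stability of synchronization in higher-order networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadsync)
```

## The model and its assumptions

triadsync studies `n` *identical* phase oscillators coupled through
unweighted, undirected interactions of two orders: pairwise edges and
triadic 2-simplices. The phases evolve under a triadic generalization of the
Kuramoto model,

$$\dot\theta_i = \omega
 + \frac{1-\alpha}{\langle k^{(1)}\rangle}\sum_j A_{ij}\sin(\theta_j-\theta_i)
 + \frac{\alpha}{\langle k^{(2)}\rangle}\sum_{\{i,j,k\}\in T}
   \tfrac12\sin(\theta_j+\theta_k-2\theta_i),$$

where the triadic sum runs over the 2-simplices containing node $i$. Two
normalizations matter and are both built in:

* **Budget conservation.** The coupling strengths are $\gamma_1 = 1-\alpha$
  and $\gamma_2 = \alpha$, so moving along $\alpha\in[0,1]$ reallocates a
  *fixed* total coupling budget between orders rather than adding coupling.
* **Mean-degree normalization.** Each order is divided by its mean
  generalized degree, so structures of different densities are comparable
  and a single interaction contributes with the same weight regardless of
  how many oscillators it involves (whence the extra factor $\tfrac12$ on
  the triadic sine).

The alternative triadic coupling $\sin(2\theta_j-\theta_k-\theta_i)$ is not
implemented: once normalized by the coefficient of $\theta_i$, it
contributes identically to the linearization below, so nothing in the
stability analysis would change.

Full synchrony $\theta_i\equiv\theta_j$ is always a solution. Linearizing
around it gives $\dot{\delta\theta} = -L^{(\mathrm{mul})}\delta\theta$ with

$$L^{(\mathrm{mul})} = \frac{1-\alpha}{\langle k^{(1)}\rangle}L^{(1)}
 + \frac{\alpha}{\langle k^{(2)}\rangle}L^{(2)},\qquad
 L^{(2)}_{ij} = k^{(2)}_i\delta_{ij} - \tfrac12 A^{(2)}_{ij},$$

where $A^{(2)}_{ij}$ counts 2-simplices containing both $i$ and $j$ and
$k^{(2)}_i$ counts those containing $i$. `lambda2()` sorts the spectrum
$0=\Lambda_n\le\dots\le\Lambda_1$ and reports the second Lyapunov exponent
$\lambda_2=-\Lambda_{n-1}$: negative iff the $\alpha$-weighted coupling
support is connected, with larger magnitude meaning faster recovery from
perturbations. The diagonal of $L^{(\mathrm{mul})}$ is the multiorder degree
$k^{(\mathrm{mul})}_i$, and the classical bounds
$2k_{\min}-n+2 \le |\lambda_2| \le \frac{n}{n-1}k_{\min}$ and
$\frac{n}{n-1}k_{\max} \le |\lambda_n| \le 2k_{\max}$ (evaluated with
multiorder degrees by `degree_bounds()`) are what link stability to degree
statistics: maximizing the minimum multiorder degree over $\alpha$ predicts
the optimal coupling mixture, including the interior optimum (U-shaped
$\lambda_2(\alpha)$) of random hypergraphs whose pairwise wiring dominates.

## Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `alpha` | fraction of coupling budget on triadic interactions (dimensionless) | — | the experiment variable; sweeps default to 21 evenly spaced points in $[0,1]$, matching the resolution needed to locate interior optima within $0.05$ |
| `p`, `p_tri` | independent wiring probabilities of pairs / triples | — | the structural density knobs; study conditions follow the figure-level analyses (see below) |
| `p_s` | per-simplex shuffle probability | — | distance-to-simplicial-complex proxy |
| `tol` (in `lambda2()`) | relative zero threshold for eigenvalues | `1e-9` | well above LAPACK rounding at $n\le 2000$, far below any physical eigenvalue gap encountered |
| `dt`, `t_end` | integrator step and horizon (normalized time) | `0.01`, `50` | resolves the $O(1)$ normalized coupling rates by two orders of magnitude; halving `dt` moves final phases by $<10^{-6}$ on the standard test instance |
| `y0` | Gumbel quantile parameter | $-\ln\ln 2 \approx 0.3665$ | the exact median of the standard Gumbel law, consistent with using the median to approximate expected extreme degrees; exposed rather than hard-coded |

## What the generators emulate — and what they do not

`random_hypergraph(n, p, p_tri)` places each of the $\binom n2$ pairs and
$\binom n3$ triples independently; `flag_complex()` attaches a 2-simplex to
every 3-clique of a pairwise substrate (Erdős–Rényi, small-world or
preferential-attachment graphs via `er_graph()`, `smallworld_graph()`,
`scalefree_graph()`); `fill_triangles()` fills 3-cliques with probability
`p_fill`; `fixed_budget_hypergraph()` fixes exact hyperedge counts so
families can be compared at equal connection budgets. Internally, Bernoulli
placement is sampled by scanning with geometric gaps (exact, $O(Np)$, and
the basis for a degrees-only fast path used by large heterogeneity
ensembles: `flag_degrees()`, `empirical_hetero_indexes()`).

Two rewiring procedures explore the hypergraph space between these
families:

* `shuffle_simplices()` relocates each 2-simplex, independently with
  probability $p_s$, to a uniformly random *unoccupied* triple. The
  reference analyses do not specify how landing on an occupied triple is
  handled; triadsync rejection-resamples, because exact conservation of the
  triangle count is the binding constraint (accepting collisions as
  multiset entries would slightly alter the statistics). Edges are never
  touched.
* `swap_memberships()` is formalized as a *transposition of node labels
  acting on the triadic layer only*: nodes are ranked by $k^{(2)}$ (ties
  broken by ascending node ID — a determinism choice), the $m$-th lowest is
  paired with the $m$-th highest, and each pair is swapped inside every
  triangle. This is the only reading under which both degree sequences are
  exactly preserved as multisets, $k^{(2)}$ values are exchanged pairwise,
  and the $\alpha\in\{0,1\}$ stability endpoints are exactly invariant (the
  order-2 layer is merely relabeled). Simplices containing both swapped
  nodes map to themselves.

These synthetic families emulate the structural features the stability
analysis depends on — independent vs. inclusion-constrained triadic
placement, degree heterogeneity at each order, cross-order degree
correlation — under homogeneous node dynamics. They do *not* emulate
weighted or directed interactions, hyperedges beyond order two, degree
sequences of real connectomes, or community/spatial structure. Passing
tests on these ensembles therefore demonstrates the representation effect
and its degree-based mechanism, not quantitative predictions for any
particular empirical network; real pairwise networks can be loaded through
`read_pairwise_graph()` (edge list or GraphML) and pushed through exactly
the same pipeline.

## Degree-heterogeneity theory

For flag complexes of $G(n,p)$, conditioning on a node's pairwise degree
makes its triadic degree exactly $\mathrm{Binomial}\!\left(\binom{k^{(1)}}2,
p\right)$, giving the quadratic law $E[k^{(2)}|k^{(1)}] =
p\,k^{(1)}(k^{(1)}-1)/2$ (`expected_k2()`): pairwise-rich nodes become
triadically richer, so the heterogeneity ratio
$r=(k^{(2)}_{\max}/k^{(2)}_{\min})/(k^{(1)}_{\max}/k^{(1)}_{\min})$
exceeds 1 and grows as the substrate gets sparser.

For random hypergraphs, degrees at order $\ell$ are (weakly correlated)
binomials over sample spaces of size $n$ and $N=(n-1)(n-2)/2$; Gumbel
extreme-value asymptotics (`gumbel_extreme_estimate()`) estimate the
expected extreme degrees and yield heterogeneity indexes $h^{(\ell)}$
(`heterogeneity_indexes()`) whose ratio scales as $\sqrt n/2$. Two numerical
subtleties are worth recording:

* The quantile parameter solving $e^{-e^{-y_0}}=\tfrac12$ is
  $y_0=-\ln\ln 2\approx 0.3665$ (sometimes misquoted as $\approx 0.52$);
  triadsync defaults to the analytic value and exposes `y0`.
* The finite-size correction $f(m,y)$ converges to 1 only logarithmically,
  and with $f$ retained the *theoretical* ratio $h^{(1)}/h^{(2)}$ sits a few
  percent **below** $\sqrt n/2$ for practically relevant $n$; the
  $\sqrt n/2$ bound is a property of the large-$n$ simplification (reported
  separately as `ratio_asymptotic`) and of the empirical indexes, which
  exceed it comfortably at every tested size. Tests and the degree-scaling
  analysis use the empirical and asymptotic forms accordingly.

`cross_order_degree_correlation()` is the Pearson product-moment correlation
of the two degree vectors — the cited degree-correlation literature uses
Pearson, and the degree vectors are plain numeric — and
`exact_max_binomial_median()` provides the closed order-statistics oracle
($F(k)^{n}$) against which the Gumbel estimate is validated.

## Numerical choices

* **Eigensolver.** Full dense symmetric spectra (`eigen(symmetric =
  TRUE)`): at the package's scales ($n\lesssim 2000$) these are cheap,
  deterministic, and avoid iterative-solver edge cases near the degenerate
  $\lambda_2$ of disconnected or near-disconnected supports. Eigenvalues
  below $10^{-9}$ of the spectral radius are reported as exact zeros, and a
  disconnected support yields $\lambda_2=0$, not an error.
* **Integration.** Classical fixed-step RK4. Perturbation decay rates are
  measured on the log-norm of the phases *projected off the uniform mode*
  (the zero mode never decays and would otherwise corrupt the fit), over
  the late half of the trajectory where the slowest transverse mode
  dominates. When validating the linearization quantitatively, the initial
  perturbation is aligned with that slowest eigenmode: a generic random
  perturbation mixes modes whose decay-rate gaps can be small, and the
  mixture biases a finite-window slope fit by more than the comparison
  tolerance, whereas the full nonlinear dynamics of an eigenmode-aligned
  perturbation isolates exactly the rate that $\lambda_2$ predicts.
* **Seeding.** Every stochastic routine accepts a scoped `seed`; ensembles
  spawn per-realization child seeds by the fixed rule
  $(\mathrm{master} + 1000003\,i) \bmod (2^{31}-1)$ (`child_seeds()`), so
  any single realization can be regenerated in isolation and experiment
  outputs are byte-reproducible.
* **Ensemble statistics** use the sample standard deviation ($n-1$
  denominator).

## Problem sizes

The test suite and experiment defaults run at deliberately moderate scales,
which are ample for every qualitative effect and for the stated tolerances:
ensembles of 10 realizations at $n=100$ for the stability trends, U-shape
and shuffle transition; $n=300$ with 10 realizations per density for the
quadratic degree law; 100 degree samples at $n\in\{100,300,1000\}$ for the
heterogeneity scaling; 20 instances at $n=50$ for the dynamics-vs-spectrum
equivalence. `run_experiment()` exposes all counts, so figure-scale
ensembles (50–1000 realizations) are configuration switches.

## Known limitations

* Interactions are unweighted, undirected, and at most triadic; no orders
  $d>2$, no nonreciprocal coupling.
* Oscillators are identical; frequency disorder, noise, and partial
  synchronization phenomena (twisted states, chimeras) are out of scope.
* The membership-swap pairing rule (ties by node ID) is one deterministic
  choice among the possible "lowest-vs-highest" orderings.
* Dense spectra limit single computations to $n$ of a few thousand.
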