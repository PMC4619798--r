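---
title: "Methods: homophily-driven evolutionary games on multiplex networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homophily-driven evolutionary games on multiplex networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homoplex)
```

## The model

`homoplex` studies how cooperation spreads through a population whose
members interact on several social layers at once (a *multiplex*: the same
$N$ individuals replicated across $M$ layers, each layer with its own edge
set), and how that spread is shaped by *homophily* — the tendency of
similar individuals to influence each other more strongly.

The building blocks:

1. **Homophily field.** Every unordered pair $(x, y)$ carries a
   nonnegative *homophily difference* $\delta_{xy}$ (0 = maximally
   similar). The homophily measure is $h_{xy} = 1/(1 + \delta_{xy}) \in
   (0, 1]$.

2. **Weighted layers.** Each layer's adjacency matrix $A^\alpha$ is
   weighted entrywise: $Z^\alpha = H^\alpha \circ A^\alpha$, so
   $z^\alpha_{xy} = a^\alpha_{xy}/(1+\delta_{xy})$. With $\delta \equiv 0$
   the weighting disappears and $Z^\alpha = A^\alpha$.

3. **Heterogeneous centrality.** Layers influence one another through a
   nonnegative $M \times M$ influence matrix $W$. The $NM \times NM$
   Khatri–Rao supra matrix with blocks $w^{\alpha\beta} (Z^\beta)^T$ has
   (when irreducible) a positive leading eigenvector $o^\otimes$,
   normalized to unit entry sum. Summing a node's entries across layers
   gives its weight $\lambda_x$, with $\sum_x \lambda_x = 1$: a joint
   measure of how central and how homophilous the node is in the whole
   multiplex.

4. **Critical mass.** On the aggregate layer of $NM$ individuals, the
   critical-mass size $\bar n$ is the smallest coalition size $n$ such
   that at least $n$ individuals weakly prefer mutual cooperation (reward
   $R_i(n)$) to unilateral defection (temptation $T_i(n)$). Because a
   critical node adopts the same behaviour on every layer, the multiplex
   needs only $\bar{\bar n} = \lceil \bar n / M \rceil$ *nodes*; the
   critical-mass density is $\tau_{CM} = \bar{\bar n}/N$. The concrete
   node set is the $\bar{\bar n}$ nodes with the largest $\lambda_x$ —
   the subset maximizing $\Lambda_S = \sum_{x \in S}\lambda_x$.

5. **Communicability.** Interlayer coupling strengths
   $\omega_{\alpha\beta}$ join each node to its own replicas. The
   communicability matrix $G = \exp(Z_L + C_{LL})$ counts all walks
   between any two replicas, discounting walks of length $k$ by $1/k!$;
   its blocks $[G_{\alpha\beta}]_{xy}$ quantify how easily information
   travels from node $x$ on layer $\alpha$ to node $y$ on layer $\beta$.

6. **Evolutionary dynamics.** The population plays the Prisoner's Dilemma
   (cooperation gives the opponent $b$ at own cost $c$; defection gives
   and costs nothing) under Monte Carlo imitation dynamics. An elementary
   step draws a replica $(x, \alpha)$, computes its accumulated payoff
   against its layer-$\alpha$ neighbors, draws a comparison layer $\beta$
   and a model $y$ among the layer-$\beta$ neighbors of $x$'s counterpart,
   and adopts $S_y$ with probability
   $$W(S_y \to S_x) \;=\; \eta_x \,
     \frac{1}{1 + \exp\!\big[(P_x - P_y)/(\delta_{xy} K)\big]}.$$
   Homophily *sharpens* the Fermi rule ($\delta_{xy}$ multiplies the
   temperature $K$), and the scaling factor $\eta_x \in [\eta_{min}, 1]$
   *slows* the revision of strategies that already agree with the node's
   counterpart neighborhood on the other layer, weighted by
   communicability:
   $$\eta_x = 1 - (\eta_{max} - \eta_{min})
     \frac{\sum_{y \in N_\beta(x'),\, S_y = S_x} [G_{\alpha\beta}]_{xy}}
          {\sum_{y \in N_\beta(x')} [G_{\alpha\beta}]_{xy}},$$
   where $N_\beta(x')$ is the counterpart $x'$ plus its layer-$\beta$
   neighbors. One round = $N M$ elementary steps (one expected revision
   opportunity per replica).

## Parameters, defaults, and why

| parameter | default | meaning / rationale |
|---|---|---|
| `N`, `M` | — | nodes, layers; the reference experiments use $N = 1000$, $M = 3$ |
| `attachment_m` | 3 | preferential-attachment edges per new node; mean degree ≈ 6, degree exponent in the usual scale-free range $2 < \gamma < 3$ |
| `delta_mean` | 1.0 | mean of the homophily-difference distribution (dimensionless) |
| `sigma` | — | its standard deviation; $\sigma = 1$ is the high-homophily condition, $\sigma = 8$ the low-homophily one |
| `b`, `c` | 1, 0.04 | PD benefit and cost. See "calibration" below |
| `K` | 0.05 | Fermi temperature; multiplied by $\delta_{xy}$ in the update |
| `eta_min`, `eta_max` | 0.1, 1 | bounds of the scaling factor; the lower bound avoids frozen states |
| `omega` presets | uniform 0.4 / dominant 0.6–0.3 | interlayer strengths of the two reference coupling settings (dominant layer 2) |
| coalition scheme | $a{=}1$, $c_0{=}10$, $c_1{=}0.5$ | $R_i(n) - T_i(n) = a n - (c_0 + c_1 i)$, a heterogeneous-threshold population; gives $\bar n = 20$ for any aggregate population of at least 20 |

**Calibration of $(b, c, K)$.** With the one-shot PD there is no parameter
printed for the simulations, and the qualitative behaviour depends
strongly on the cost-benefit ratio. At $c/b \gtrsim 0.1$ a small central
cooperative seed is always out-earned by the defectors around it and dies
within a few rounds. The frozen default $(1, 0.04, 0.05)$ sits in the
scale-free network-reciprocity regime: hub cooperators seeded by the
critical mass earn more than the defecting leaves around them, so
cooperation spreads to fixation, quickly under high homophily
(near-deterministic imitation, $\delta_{xy} K \ll$ payoff differences)
and slowly under low homophily (noisy imitation). These are the
conditions under which all simulation-based checks in the test suite run.

**Influence matrix $W$.** Never printed for the reference experiments; the
package ties it to the coupling — $w^{\alpha\beta} = \omega_{\alpha\beta}$
off-diagonal, 1 on the diagonal, rows normalized. Row normalization only
rescales the leading eigenvalue, not the weights $\Lambda$. Fully
configurable.

## The synthetic generator

`generate_multiplex()` grows each layer independently by linear
preferential attachment (via igraph) over the same node identity set, and
`sample_homophily()` draws $\delta_{xy} \sim$ Normal(`delta_mean`,
`sigma`) for each pair, clamped below at zero and mirrored symmetrically.
Clamping (rather than resampling) keeps "larger $\sigma$ ⇒ lower
homophily" monotone; at $\sigma = 8$ nearly half the pairs sit exactly at
$\delta = 0$, which is handled by the exact zero-noise limit of the Fermi
rule rather than an epsilon.

What the generator emulates: heavy-tailed degree distributions,
independent layer topologies, a continuous symmetric (dis)similarity
field shared by all layers (optionally per layer). What it does not:
degree correlations between layers, edge overlap, assortativity of the
homophily field with topology, community structure, or any coupling
between $\delta$ and edge formation. Passing tests therefore show the
dynamics behave as designed *under these statistical assumptions*, not
that real multiplex social data would behave identically.

## Numerical choices

- **Eigenvector**: power iteration with a deterministic uniform start,
  L1 tolerance $10^{-12}$, cap $10^5$ iterations; irreducibility is
  checked first (strong connectivity of the nonzero pattern) and a
  reducible supra matrix raises an error naming the component count and
  sizes. Sum-normalization at every step keeps the iterate in the
  simplex.
- **Matrix exponential**: the supra matrix is symmetric by construction,
  so $G = V e^D V^T$ is computed from the (LAPACK) symmetric
  eigendecomposition — exact up to round-off and fast enough for
  $NM = 3000$ dense. The test suite cross-checks it against a 30-term
  Taylor series and against `Matrix::expm` (a Padé scaling-and-squaring
  implementation) at tolerance $10^{-9}$.
- **$\delta_{xy} = 0$** in the Fermi denominator: the exact
  zero-temperature limit (adopt if better: $\eta_x$; tie: $\eta_x/2$;
  worse: 0), not an epsilon.
- **$\eta$ endpoints**: computed as
  $\eta_{min} + (\eta_{max}-\eta_{min})(1 - \text{ratio})$, which is
  exact at full agreement and full disagreement.
- **Ceiling in $\bar{\bar n}$**: a fractional $\bar n / M$ is rounded up
  so the triggered set stays sufficient.
- **Heaviside**: $H(0) = 1$ (indifference counts as weak preference);
  switchable via `heaviside_zero`.
- **Ties in the critical-mass set**: broken by smallest node id for a
  canonical answer; all maximizers can be enumerated for $N \le 12$.
- **Monte Carlo kernel**: the elementary-step loop is C++ (Rcpp) and uses
  R's own RNG stream, so trajectories are bit-reproducible from
  `set.seed()`. Payoffs are recomputed fresh at every elementary step; a
  replica whose counterpart is isolated on the drawn comparison layer
  redraws the layer (at most $M$ attempts) and otherwise skips.

## Design decisions on open model questions

- **Which layer's neighbors supply the model $y$:** the counterpart
  reading (neighbors of $x' = x$ on the comparison layer $\beta$), which
  is the one consistent with the $\eta$ definition; the alternative
  (focal-layer neighbors, payoff still evaluated on $\beta$) is behind
  `neighbor_source = "focal"`.
- **Comparison layer:** drawn uniformly over all $M$ layers including
  $\alpha$ (so self-layer imitation recovers the classic monoplex
  update); `beta_excludes_alpha = TRUE` forces an interlayer comparison.
- **$\eta$ and multiple layers:** the scaling factor uses the single
  drawn comparison layer by default. An aggregated variant
  (`eta_layers = "all"`) pools the counterpart neighborhoods of all other
  layers into one communicability-weighted ratio, which makes strongly
  coupled layers dominate the scaling factor.
- **Strategy bookkeeping:** a node may hold different strategies on
  different layers (otherwise $\eta$ would be constant); critical nodes
  are only *initialized* uniformly cooperating on all layers.
- **Convergence reporting:** the convergence round is the first round
  after which the cooperator density stays within 0.02 of its final
  value, the final value being the mean over the last 10 recorded rounds.

## Problem sizes used by the test suite

Analytic and oracle checks run on instances with $NM \le 50$ where
truncated series, exhaustive subset enumeration and naive double-loop
assembly are exact references. The simulation comparisons use $N = 200$,
$M = 3$, 20 paired network seeds with 3 Monte Carlo replicates per seed
and a 600-round horizon (per-seed mean convergence rounds, one-sided
paired t-test); the full-scale convergence check uses $N = 1000$,
$M = 3$, one network and 10 Monte Carlo seeds over 500 rounds. These
sizes give each comparison stable per-seed summaries while keeping a full
suite run in the low minutes.

## Known limitations

- **The interlayer coupling has only a second-order effect on the
  dynamics.** $\eta_x$ is a *ratio* of communicability entries within one
  layer-pair block. For small coupling, $G_{\alpha\beta} \approx
  \omega_{\alpha\beta} F(Z)$, so the strength $\omega_{\alpha\beta}$
  cancels from the ratio at first order; it enters only through
  multi-layer walks ($\omega^2$ terms and higher). Empirically, across
  the parameter ranges we examined, dominant-layer versus uniform
  coupling changes the mean convergence round by much less than its
  between-run variability and with no stable sign — under this update
  rule the package does not resolve a coupling-ordering effect at
  conventional significance, and the corresponding check in the
  acceptance suite documents exactly that. The aggregated
  `eta_layers = "all"` variant makes $\omega$ first-order in $\eta$ but
  did not produce a stable ordering either.
- The convergence-round statistic is heavy-tailed near the boundary of
  the reciprocity regime: occasional runs stall at intermediate densities
  for hundreds of rounds. Comparisons should always average replicates.
- Directed or weighted input graphs, time-varying networks, other games,
  strategy mutation, and replicator (infinite-population) analysis are
  out of scope.
- The $\tau_{CM}$ surface depends entirely on the chosen coalition payoff
  scheme; only its qualitative shape (non-increasing in $N$ and $M$,
  approaching a plateau) is meaningful, not absolute values.
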