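# homoplex

Evolutionary game dynamics on multiplex social networks, with homophily
and interlayer communicability built into the update rule.

## The problem

Human populations interact on several social layers at once — kin,
colleagues, friends — and whether cooperation spreads depends not only on
who is connected to whom on each layer, but on how *similar* connected
people are (homophily) and how strongly the layers are coupled. This
package provides a complete simulation framework for that question, aimed
at researchers in evolutionary game theory and network science:

- **Homophily-weighted multiplex networks.** Each pair of nodes carries a
  homophily difference δ<sub>xy</sub> ≥ 0; the homophily measure is
  h<sub>xy</sub> = 1/(1+δ<sub>xy</sub>), and each layer's adjacency matrix
  A<sup>α</sup> is weighted entrywise to Z<sup>α</sup> = H<sup>α</sup> ∘
  A<sup>α</sup>.
- **Global heterogeneous eigenvector-like centrality.** The positive,
  sum-normalized leading eigenvector of the Khatri–Rao supra matrix with
  blocks w<sup>αβ</sup>(Z<sup>β</sup>)<sup>T</sup>; summing a node's
  entries across layers gives its weight λ<sub>x</sub> (Σλ<sub>x</sub> = 1).
- **Critical mass.** The smallest coalition n̄ on the aggregate layer such
  that at least n̄ individuals weakly prefer mutual cooperation, reduced to
  n̄̄ = ⌈n̄/M⌉ nodes on the multiplex (density τ<sub>CM</sub> = n̄̄/N), and
  realized as the n̄̄ nodes with the largest λ<sub>x</sub>.
- **Communicability.** G = exp(Z<sub>L</sub> + C<sub>LL</sub>), the
  factorially weighted count of all intra- and interlayer walks, with
  interlayer blocks ω<sub>αβ</sub>I.
- **Monte Carlo Prisoner's Dilemma** with a modified Fermi rule: node x
  adopts model y's strategy with probability
  η<sub>x</sub> · 1/(1 + exp[(P<sub>x</sub> − P<sub>y</sub>)/(δ<sub>xy</sub>K)]),
  where homophily sharpens the imitation noise and the communicability
  scaling factor η<sub>x</sub> ∈ [0.1, 1] slows the revision of strategies
  that already agree with the node's counterpart neighborhood on another
  layer.

A generator for synthetic scale-free multiplexes with normally
distributed homophily differences (truncated at 0) defines the study
conditions; experiment drivers, plain-text multilayer edge-list I/O, and
a thin command-line interface (`inst/cli/homoplex`) round out the tool.
See `vignette("homoplex-methods")` for the model, all defaults, and known
limitations.

## Worked example

```r
library(homoplex)

cfg <- netgen_config(N = 300, M = 3, sigma = 1, seed = 1)  # high homophily
net <- generate_multiplex(cfg)
hom <- sample_homophily(cfg)
z   <- build_z_layers(net, hom)
om  <- preset_coupling("dominant", 3)   # 0.6 to/from layer 2, 0.3 otherwise

cent <- heterogeneous_centrality(
  build_khatri_rao_supra(z, default_influence_matrix(om)), N = net$N)
cm <- critical_mass(cent$lambda, net$M)
cm
#> critical_mass_result: n_bar=20 n_bbar=7 tau=0.02333 lambda_S=0.1426
#>   nodes: 1 2 3 4 5 6 9
```

Out of 900 individuals on the aggregate layer, a coalition of 20 suffices
under the default threshold scheme; on the multiplex that is 7 *nodes*
(density 0.023), chosen as the 7 nodes with the largest
centrality-homophily weight λ. Seed those 7 nodes with cooperation on all
three layers and let the population play:

```r
g    <- communicability(z, om)
init <- initialize_state("critical_mass", net$N, net$M, cm_nodes = cm$nodes)
traj <- run_evolution(net, hom, g, game_params(), init, rounds = 200, seed = 7)
traj
#> pd_trajectory: 200 rounds, rho 0.0233 -> 1.0000, converged at round 47 (seed 7)
cluster_sizes(traj$final_state, net, layer = 1)
#> [1] 300
```

Starting from a 2.3% cooperator density, the population reaches full
cooperation (ρ = 1, a single cooperative cluster spanning the layer)
within ~50 rounds: the central, homophilous seed out-earns the defectors
around it and near-deterministic imitation under high homophily carries
cooperation to fixation. Re-running with `sigma = 8` (low homophily)
leaves the same seed spreading much more slowly — the package's central
qualitative result.

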