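#' Game and update parameters
#'
#' Parameters of the Prisoner's Dilemma and of the imitation rule.
#' Cooperation grants a benefit \code{b} to the opponent at cost \code{c} to
#' the cooperator (b > c > 0); defection costs and yields nothing. \code{K}
#' is the selection temperature of the Fermi rule (uncertainty of strategy
#' adoption); in the update it is multiplied by the pairwise homophily
#' difference \eqn{\delta_{xy}}, so high homophily sharpens imitation and
#' low homophily blurs it. \code{eta_min}/\code{eta_max} bound the
#' communicability scaling factor; the interval [0.1, 1] avoids frozen
#' states.
#'
#' The frozen default triple (b = 1, c = 0.04, K = 0.05) sits in the regime
#' where scale-free network reciprocity operates: the cost-benefit ratio is
#' low enough for a small, central cooperative seed to out-earn the
#' defectors around it and spread, and imitation under high homophily
#' (small \eqn{\delta_{xy} K}) is close to deterministic while low
#' homophily leaves it noisy.
#'
#' @param b benefit of receiving cooperation (default 1).
#' @param c cost of cooperating (default 0.04; must satisfy 0 < c < b).
#' @param K Fermi temperature (default 0.05).
#' @param eta_min,eta_max bounds of the communicability scaling factor
#'   (defaults 0.1 and 1).
#' @return Object of class \code{game_params}.
#' @export
game_params <- function(b = 1, c = 0.04, K = 0.05, eta_min = 0.1, eta_max = 1) {
  if (!(b > c && c > 0)) stop("need b > c > 0")
  if (K <= 0) stop("K must be positive")
  if (!(eta_min > 0 && eta_min < eta_max && eta_max <= 1))
    stop("need 0 < eta_min < eta_max <= 1")
  structure(list(b = b, c = c, K = K, eta_min = eta_min, eta_max = eta_max),
            class = "game_params")
}

#' @export
print.game_params <- function(x, ...) {
  cat(sprintf("game_params: b=%g c=%g K=%g eta=[%g, %g]\n",
              x$b, x$c, x$K, x$eta_min, x$eta_max))
  invisible(x)
}

# normalize "C"/"D" (or 1/0) coding to integer 1 = cooperate, 0 = defect
as_strategy <- function(s) {
  if (is.character(s)) {
    out <- ifelse(s == "C", 1L, ifelse(s == "D", 0L, NA_integer_))
  } else {
    out <- as.integer(s)
    out[!(out %in% c(0L, 1L))] <- NA_integer_
  }
  if (anyNA(out)) stop("strategies must be \"C\"/\"D\" (or 1/0)")
  out
}

#' Pairwise Prisoner's Dilemma payoff
#'
#' Payoff to the focal player: C vs C gives b - c, C vs D gives -c,
#' D vs C gives b, D vs D gives 0. Vectorized over strategies.
#'
#' @param s_self,s_opp strategies, \code{"C"}/\code{"D"} or 1/0.
#' @param params a [game_params()].
#' @return Numeric payoff(s) to the focal player.
#' @export
pd_payoff <- function(s_self, s_opp, params = game_params()) {
  s1 <- as_strategy(s_self); s2 <- as_strategy(s_opp)
  params$b * s2 - params$c * s1
}

#' Payoff of a replica on its layer
#'
#' A replica (node x, layer alpha) accumulates its payoff by playing the
#' Prisoner's Dilemma with every one of its layer-alpha neighbors. Payoffs
#' are recomputed fresh at each elementary step; nothing carries over
#' between steps. An isolated replica earns 0.
#'
#' @param net a \code{multiplex_network}.
#' @param state strategy matrix (N x M, 1 = cooperate, 0 = defect).
#' @param x node id (1-based).
#' @param alpha layer id (1-based).
#' @param params a [game_params()].
#' @return Numeric payoff.
#' @export
layer_payoff <- function(net, state, x, alpha, params = game_params()) {
  nbrs <- neighbors_of(net, x, alpha)
  if (length(nbrs) == 0) return(0)
  sum(pd_payoff(rep(state[x, alpha], length(nbrs)), state[nbrs, alpha], params))
}

neighbors_of <- function(net, x, alpha) {
  a <- net$adj[[alpha]]
  which(a[, x] != 0)
}

#' Communicability scaling factor of a replica
#'
#' The scaling factor \eqn{\eta_x} of replica (x, alpha) relative to layer
#' beta interpolates linearly between \code{eta_max} and \code{eta_min}
#' with the communicability-weighted fraction of x's counterpart
#' neighborhood on beta that shares x's current strategy:
#' \deqn{\eta_x = 1 - (\eta_{max} - \eta_{min}) \frac{\sum_{y \in N_\beta(x'),
#'   S_y^\beta = S_x^\alpha} [G_{\alpha\beta}]_{xy}}{\sum_{y \in N_\beta(x')}
#'   [G_{\alpha\beta}]_{xy}}}
#' where \eqn{N_\beta(x')} is the counterpart x' of x on layer beta together
#' with its layer-beta neighbors. Full agreement across layers gives
#' \code{eta_min} (the replica is hard to displace), full disagreement gives
#' \code{eta_max}. A zero denominator (no communicability at all) falls back
#' to \code{eta_max}.
#'
#' With \code{beta = NULL} the sums instead aggregate the counterpart
#' neighborhoods of every other layer into one ratio. Because the blocks
#' \eqn{G_{\alpha\beta}} scale with the coupling \eqn{\omega_{\alpha\beta}},
#' strongly coupled layers then dominate the scaling factor. The
#' per-layer-pair form is the default in [run_evolution()]; the aggregated
#' form is available as \code{eta_layers = "all"}.
#'
#' @param g a [communicability()] result.
#' @param net the \code{multiplex_network}.
#' @param state strategy matrix (N x M, 1/0).
#' @param x node id (1-based).
#' @param alpha,beta layer ids (1-based); \code{beta = NULL} aggregates over
#'   all layers other than \code{alpha}.
#' @param params a [game_params()].
#' @return Numeric scaling factor in \code{[eta_min, 1]}.
#' @export
eta_scaling <- function(g, net, state, x, alpha, beta = NULL,
                        params = game_params()) {
  betas <- if (is.null(beta)) {
    if (g$M > 1) setdiff(seq_len(g$M), alpha) else alpha
  } else beta
  gi <- (alpha - 1) * g$N + x
  num <- den <- 0
  for (b in betas) {
    set_y <- c(x, neighbors_of(net, x, b))
    gvals <- g$G[gi, (b - 1) * g$N + set_y]
    den <- den + sum(gvals)
    num <- num + sum(gvals[state[set_y, b] == state[x, alpha]])
  }
  if (den <= 0) return(params$eta_max)
  # algebraically 1 - (eta_max - eta_min) * ratio when eta_max = 1; this
  # form is exact at both endpoints
  params$eta_min + (params$eta_max - params$eta_min) * (1 - num / den)
}

#' Fermi imitation probability
#'
#' Probability that the focal replica adopts the model's strategy:
#' \deqn{W(S_y \to S_x) = \eta_x \frac{1}{1 + \exp[(P_x - P_y) /
#'   (\delta_{xy} K)]}}
#' The homophily difference \eqn{\delta_{xy}} multiplies the temperature:
#' highly homophilous pairs (\eqn{\delta \to 0}) imitate almost
#' deterministically, dissimilar pairs almost at random. At exactly
#' \eqn{\delta_{xy} = 0} the zero-noise limit applies: \eqn{\eta_x} if the
#' model earns more, \eqn{\eta_x/2} on a tie, 0 otherwise.
#'
#' @param P_x focal payoff, \code{P_y} model payoff.
#' @param P_y model payoff.
#' @param delta_xy homophily difference between the two nodes (>= 0).
#' @param params a [game_params()].
#' @param eta_x communicability scaling factor (default 1).
#' @return Probability in \code{[0, eta_x]}.
#' @export
fermi_probability <- function(P_x, P_y, delta_xy, params = game_params(),
                              eta_x = 1) {
  if (delta_xy < 0) stop("delta_xy must be nonnegative")
  if (delta_xy == 0) {
    return(if (P_y > P_x) eta_x else if (P_y == P_x) eta_x / 2 else 0)
  }
  eta_x / (1 + exp((P_x - P_y) / (delta_xy * params$K)))
}

#' One elementary Monte Carlo step
#'
#' Performs a single update attempt: draw a replica (x, alpha) uniformly;
#' compute its payoff on alpha; draw a comparison layer beta and a model y
#' among the layer-beta neighbors of x's counterpart; compute y's payoff on
#' beta; evaluate the communicability scaling factor and the Fermi
#' probability; adopt y's strategy with that probability. Exactly one
#' replica may change. Any of the draws can be forced through \code{force}
#' (used for calibration and testing).
#'
#' @param net,hom,g network, homophily field and communicability matrix.
#' @param state strategy matrix (N x M, 1/0).
#' @param params a [game_params()].
#' @param beta_excludes_alpha if TRUE the comparison layer is always a
#'   different layer; by default it may equal alpha (the monoplex update).
#' @param eta_layers \code{"selected"} (default): only the drawn comparison
#'   layer enters the scaling factor; \code{"all"}: aggregate the
#'   counterpart neighborhoods of all other layers.
#' @param force optional named list fixing any of \code{x}, \code{alpha},
#'   \code{beta}, \code{y} (1-based).
#' @return List with \code{state} (possibly updated), \code{changed},
#'   \code{skipped}, and \code{info} (x, alpha, beta, y, P_x, P_y, eta,
#'   prob).
#' @export
elementary_step <- function(net, hom, g, state, params = game_params(),
                            beta_excludes_alpha = FALSE,
                            eta_layers = c("selected", "all"),
                            force = list()) {
  eta_layers <- match.arg(eta_layers)
  N <- net$N; M <- net$M
  if (is.null(force$x) || is.null(force$alpha)) {
    r <- sample.int(N * M, 1)
    x <- if (is.null(force$x)) (r - 1) %% N + 1 else force$x
    alpha <- if (is.null(force$alpha)) (r - 1) %/% N + 1 else force$alpha
  } else {
    x <- force$x; alpha <- force$alpha
  }
  beta <- force$beta
  nbrs <- NULL
  if (is.null(beta)) {
    pool <- if (beta_excludes_alpha && M > 1) setdiff(seq_len(M), alpha) else seq_len(M)
    for (att in seq_len(M)) {
      cand <- pool[sample.int(length(pool), 1)]
      nb <- neighbors_of(net, x, cand)
      if (length(nb) > 0) { beta <- cand; nbrs <- nb; break }
    }
    if (is.null(beta))
      return(list(state = state, changed = FALSE, skipped = TRUE, info = NULL))
  } else {
    nbrs <- neighbors_of(net, x, beta)
    if (length(nbrs) == 0)
      return(list(state = state, changed = FALSE, skipped = TRUE, info = NULL))
  }
  y <- if (!is.null(force$y)) force$y else nbrs[sample.int(length(nbrs), 1)]
  P_x <- layer_payoff(net, state, x, alpha, params)
  P_y <- layer_payoff(net, state, y, beta, params)
  eta <- eta_scaling(g, net, state, x, alpha,
                     beta = if (eta_layers == "all") NULL else beta,
                     params = params)
  dxy <- delta_for_layer(hom, alpha)[x, y]
  prob <- fermi_probability(P_x, P_y, dxy, params, eta)
  changed <- FALSE
  if (stats::runif(1) < prob) {
    changed <- state[x, alpha] != state[y, beta]
    state[x, alpha] <- state[y, beta]
  }
  list(state = state, changed = changed, skipped = FALSE,
       info = list(x = x, alpha = alpha, beta = beta, y = y,
                   P_x = P_x, P_y = P_y, eta = eta, prob = prob))
}

#' Initial strategy configuration
#'
#' \code{critical_mass} mode seeds cooperation in the critical node set: a
#' critical node cooperates on every layer (critical nodes adopt the same
#' behaviour in all layers they belong to), every other replica defects, so
#' the initial cooperator density is |S|/N. \code{random_fraction} mode sets
#' each replica independently to cooperate with the given probability.
#'
#' @param mode \code{"critical_mass"} or \code{"random_fraction"}.
#' @param N,M node and layer counts.
#' @param cm_nodes node ids (1-based) for \code{critical_mass} mode.
#' @param fraction cooperation probability for \code{random_fraction} mode.
#' @param seed optional RNG seed for \code{random_fraction}.
#' @return N x M integer matrix (1 = cooperate, 0 = defect).
#' @export
initialize_state <- function(mode = c("critical_mass", "random_fraction"),
                             N, M, cm_nodes = NULL, fraction = NULL,
                             seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "critical_mass") {
    if (is.null(cm_nodes) || length(cm_nodes) == 0)
      stop("critical_mass mode needs a non-empty cm_nodes set")
    if (any(cm_nodes < 1 | cm_nodes > N)) stop("cm_nodes out of range")
    S <- matrix(0L, N, M)
    S[cm_nodes, ] <- 1L
  } else {
    if (is.null(fraction) || fraction < 0 || fraction > 1)
      stop("random_fraction mode needs fraction in [0, 1]")
    if (!is.null(seed)) set.seed(seed)
    S <- matrix(stats::rbinom(N * M, 1L, fraction), N, M)
  }
  S
}

#' Run the Monte Carlo evolutionary dynamics
#'
#' Simulates the Prisoner's Dilemma on the multiplex. One round (Monte Carlo
#' step) consists of N*M elementary steps, giving every replica one
#' strategy-revision opportunity on average. The per-round cooperator
#' density rho is recorded overall, per layer, and at node level (a node
#' counts as cooperating only if it cooperates on every layer). The run is
#' deterministic given the seed.
#'
#' @param net a \code{multiplex_network}.
#' @param hom a \code{homophily_field}.
#' @param g the [communicability()] matrix (static over the run).
#' @param params a [game_params()].
#' @param init initial strategy matrix from [initialize_state()].
#' @param rounds number of Monte Carlo rounds (>= 1).
#' @param seed RNG seed.
#' @param beta_excludes_alpha forwarded to the update rule; by default the
#'   comparison layer may equal the focal layer.
#' @param neighbor_source \code{"counterpart"} (default: the model y is a
#'   layer-beta neighbor of x's counterpart) or \code{"focal"} (y is one of
#'   x's layer-alpha neighbors, evaluated on beta).
#' @param eta_layers \code{"selected"} (default) uses only the drawn
#'   comparison layer in the scaling factor; \code{"all"} aggregates over
#'   all other layers, communicability-weighted (see [eta_scaling()]).
#' @param snapshot_rounds integer vector of rounds at which to keep a full
#'   copy of the strategy state (for cluster analysis).
#' @param band,tail convergence detection: first round after which rho stays
#'   within \code{band} (default 0.02) of its final value, the mean of the
#'   last \code{tail} (default 10) rounds.
#' @return Object of class \code{pd_trajectory}: list with \code{rho} (a
#'   data.frame: round, rho_total, rho_layer1..M, rho_node),
#'   \code{convergence_round}, \code{final_state} (N x M), \code{snapshots}
#'   (named list of N x M matrices), \code{skipped}, \code{seed},
#'   \code{params}, \code{digest}.
#' @export
run_evolution <- function(net, hom, g, params, init, rounds, seed,
                          beta_excludes_alpha = FALSE,
                          neighbor_source = c("counterpart", "focal"),
                          eta_layers = c("selected", "all"),
                          snapshot_rounds = integer(0),
                          band = 0.02, tail = 10) {
  eta_layers <- match.arg(eta_layers)
  stopifnot(inherits(net, "multiplex_network"),
            inherits(hom, "homophily_field"),
            inherits(g, "communicability_matrix"),
            inherits(params, "game_params"))
  neighbor_source <- match.arg(neighbor_source)
  if (rounds < 1) stop("rounds must be >= 1")
  N <- net$N; M <- net$M
  init <- matrix(as_strategy(init), N, M)
  adj_ptr <- lapply(net$adj, function(a) a@p)
  adj_idx <- lapply(net$adj, function(a) a@i)
  set.seed(seed)
  res <- mc_run_cpp(adj_ptr, adj_idx, hom$delta, g$G, as.integer(init),
                    params$b, params$c, params$K,
                    params$eta_min, params$eta_max,
                    N, M, as.integer(rounds),
                    isTRUE(beta_excludes_alpha),
                    neighbor_source == "focal",
                    eta_layers == "all",
                    as.integer(snapshot_rounds))
  rho <- as.data.frame(res$rho)
  names(rho) <- c("rho_total", paste0("rho_layer", seq_len(M)), "rho_node")
  rho <- cbind(round = 0:rounds, rho)
  snaps <- lapply(res$snapshots, function(s) matrix(s, N, M))
  cfg <- list(N = N, M = M, params = unclass(params), rounds = rounds,
              seed = seed, beta_excludes_alpha = beta_excludes_alpha,
              neighbor_source = neighbor_source, eta_layers = eta_layers)
  structure(list(rho = rho,
                 convergence_round = convergence_round(rho$rho_total,
                                                       band = band, tail = tail),
                 final_state = matrix(res$final_state, N, M),
                 snapshots = snaps, skipped = res$skipped,
                 seed = seed, params = params, digest = config_digest(cfg)),
            class = "pd_trajectory")
}

#' @export
print.pd_trajectory <- function(x, ...) {
  R <- nrow(x$rho) - 1
  cat(sprintf(
    "pd_trajectory: %d rounds, rho %0.4f -> %0.4f, converged at round %d (seed %d)\n",
    R, x$rho$rho_total[1], x$rho$rho_total[R + 1], x$convergence_round, x$seed))
  invisible(x)
}

#' Convergence round of a density trajectory
#'
#' The first round r such that the density stays within \code{band} of its
#' final value (the mean over the last \code{tail} recorded rounds) for all
#' rounds >= r. Returns 0 when the whole trajectory is already inside the
#' band.
#'
#' @param rho numeric vector of densities, one per round starting at
#'   round 0.
#' @param band tolerance band (default 0.02).
#' @param tail number of final rounds averaged into the reference value
#'   (default 10).
#' @return Integer round index.
#' @export
convergence_round <- function(rho, band = 0.02, tail = 10) {
  final <- mean(utils::tail(rho, tail))
  bad <- which(abs(rho - final) > band)
  if (length(bad) == 0) 0L else as.integer(max(bad))
}
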