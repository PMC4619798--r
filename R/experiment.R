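#' Interlayer coupling presets
#'
#' \code{"uniform"}: the same strength between every layer pair.
#' \code{"dominant"}: one dominant layer coupled strongly (default 0.6) to
#' all others, with weak coupling (default 0.3) among the rest — the
#' configuration in which the dominant layer acts as a behaviour polarizer.
#'
#' @param type \code{"uniform"} or \code{"dominant"}.
#' @param M layer count.
#' @param strength uniform coupling strength (default 0.4).
#' @param strong,weak dominant-layer strengths (defaults 0.6 and 0.3).
#' @param dominant_layer index of the dominant layer (default 2).
#' @return A [coupling_matrix()].
#' @export
preset_coupling <- function(type = c("uniform", "dominant"), M,
                            strength = 0.4, strong = 0.6, weak = 0.3,
                            dominant_layer = 2) {
  type <- match.arg(type)
  om <- matrix(if (type == "uniform") strength else weak, M, M)
  if (type == "dominant") {
    if (dominant_layer > M) stop("dominant_layer out of range")
    om[dominant_layer, ] <- strong
    om[, dominant_layer] <- strong
  }
  diag(om) <- 0
  coupling_matrix(om)
}

#' Experiment configuration
#'
#' Assembles and validates the full pipeline configuration: generator block,
#' game block, coupling block, initialization, rounds, seeds and output
#' prefix. Can be read from a YAML file with [read_experiment_config()].
#' Unknown keys are rejected.
#'
#' @param netgen a [netgen_config()] or list of its arguments (without
#'   \code{seed}; the per-run seed comes from \code{seeds}).
#' @param game a [game_params()] or list of its arguments.
#' @param coupling a [coupling_matrix()], or a list such as
#'   \code{list(uniform = 0.4)} or \code{list(dominant = 2, strong = 0.6,
#'   weak = 0.3)}.
#' @param init list: \code{mode} ("critical_mass" or "random_fraction") and
#'   mode-specific fields (\code{fraction} for random_fraction).
#' @param rounds Monte Carlo rounds per run.
#' @param seeds integer vector; each seed is an independent run.
#' @param out_prefix output path prefix (files are written only by
#'   [run_experiment()] when non-NULL).
#' @return Object of class \code{experiment_config}.
#' @export
experiment_config <- function(netgen, game = game_params(),
                              coupling = list(uniform = 0.4),
                              init = list(mode = "critical_mass"),
                              rounds = 200, seeds = 1:3, out_prefix = NULL) {
  if (!inherits(netgen, "netgen_config")) {
    known <- c("N", "M", "attachment_m", "delta_mean", "sigma", "shared_delta")
    bad <- setdiff(names(netgen), known)
    if (length(bad)) stop("unknown netgen keys: ", paste(bad, collapse = ", "))
    netgen <- do.call(netgen_config, c(netgen, list(seed = 1L)))
  }
  if (!inherits(game, "game_params")) {
    known <- c("b", "c", "K", "eta_min", "eta_max")
    bad <- setdiff(names(game), known)
    if (length(bad)) stop("unknown game keys: ", paste(bad, collapse = ", "))
    game <- do.call(game_params, game)
  }
  if (!inherits(coupling, "coupling_matrix")) {
    if (!is.null(coupling$uniform)) {
      coupling <- preset_coupling("uniform", netgen$M, strength = coupling$uniform)
    } else if (!is.null(coupling$dominant)) {
      coupling <- preset_coupling("dominant", netgen$M,
                                  strong = coupling$strong %||% 0.6,
                                  weak = coupling$weak %||% 0.3,
                                  dominant_layer = coupling$dominant)
    } else stop("coupling must be a matrix or a {uniform}/{dominant} preset")
  }
  if (!init$mode %in% c("critical_mass", "random_fraction"))
    stop("init mode must be critical_mass or random_fraction")
  bad <- setdiff(names(init), c("mode", "fraction"))
  if (length(bad)) stop("unknown init keys: ", paste(bad, collapse = ", "))
  structure(list(netgen = netgen, game = game, coupling = coupling,
                 init = init, rounds = as.integer(rounds),
                 seeds = as.integer(seeds), out_prefix = out_prefix),
            class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an experiment configuration from YAML
#'
#' @param path YAML file with top-level blocks \code{netgen}, \code{game},
#'   \code{coupling}, \code{init}, \code{rounds}, \code{seeds},
#'   \code{out_prefix}.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare N/Y key as a boolean; map it back to the node count
  if (!is.null(y$netgen)) {
    names(y$netgen)[names(y$netgen) %in% c("FALSE", "no")] <- "N"
  }
  known <- c("netgen", "game", "coupling", "init", "rounds", "seeds",
             "out_prefix")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- y[intersect(names(y), known)]
  do.call(experiment_config, args)
}

#' Run a configured experiment
#'
#' Executes the full pipeline for each seed: generate the multiplex and
#' homophily field, weight the layers, compute the heterogeneous centrality
#' and the critical mass, compute the communicability matrix, initialize the
#' strategies and run the Monte Carlo dynamics. When \code{out_prefix} is
#' set, writes one trajectory CSV per seed, a node table, and a summary TSV;
#' on error the partial outputs are removed.
#'
#' @param config an [experiment_config()].
#' @param scheme coalition scheme for the critical mass (default
#'   [linear_coalition_scheme()]).
#' @return List with \code{trajectories} (one \code{pd_trajectory} per
#'   seed), \code{summary} (data.frame: seed, convergence_round, final_rho,
#'   final_rho_node), \code{cm} (the \code{critical_mass_result} of the
#'   first seed's multiplex), \code{centrality}.
#' @export
run_experiment <- function(config, scheme = linear_coalition_scheme()) {
  stopifnot(inherits(config, "experiment_config"))
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok && length(written)) unlink(written), add = TRUE)
  trajs <- vector("list", length(config$seeds))
  cm1 <- NULL; cent1 <- NULL
  for (i in seq_along(config$seeds)) {
    s <- config$seeds[i]
    ng <- config$netgen; ng$seed <- s
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e)
        stop("[", name, "] ", conditionMessage(e), call. = FALSE))
    }
    net <- stage("netgen", generate_multiplex(ng))
    hom <- stage("netgen", sample_homophily(ng))
    z <- stage("core", build_z_layers(net, hom))
    cent <- stage("centrality", heterogeneous_centrality(
      build_khatri_rao_supra(z, default_influence_matrix(config$coupling)),
      N = net$N))
    cm <- stage("critical_mass", critical_mass(cent$lambda, net$M, scheme))
    g <- stage("communicability", communicability(z, config$coupling))
    init <- stage("evolution", switch(config$init$mode,
      critical_mass = initialize_state("critical_mass", net$N, net$M,
                                       cm_nodes = cm$nodes),
      random_fraction = initialize_state("random_fraction", net$N, net$M,
                                         fraction = config$init$fraction,
                                         seed = s)))
    trajs[[i]] <- stage("evolution", run_evolution(
      net, hom, g, config$game, init, config$rounds, seed = s))
    if (i == 1) { cm1 <- cm; cent1 <- cent }
    if (!is.null(config$out_prefix)) {
      p <- paste0(config$out_prefix, "_seed", s, "_trajectory.csv")
      write_trajectory(trajs[[i]], p)
      written <- c(written, p)
      if (i == 1) {
        p2 <- paste0(config$out_prefix, "_nodes.tsv")
        write_node_table(cent, p2)
        written <- c(written, p2)
      }
    }
  }
  summ <- data.frame(
    seed = config$seeds,
    convergence_round = vapply(trajs, function(t) t$convergence_round, numeric(1)),
    final_rho = vapply(trajs, function(t) utils::tail(t$rho$rho_total, 1), numeric(1)),
    final_rho_node = vapply(trajs, function(t) utils::tail(t$rho$rho_node, 1), numeric(1)))
  if (!is.null(config$out_prefix)) {
    p <- paste0(config$out_prefix, "_summary.tsv")
    utils::write.table(summ, p, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, p)
  }
  ok <- TRUE
  list(trajectories = trajs, summary = summ, cm = cm1, centrality = cent1)
}

#' Cooperator cluster sizes on a layer
#'
#' Sizes of the connected components of the subgraph induced by the
#' cooperating replicas of one layer, sorted descending — the group-size
#' statistic used to compare cooperative cluster formation under high and
#' low homophily.
#'
#' @param state strategy matrix (N x M, 1 = cooperate).
#' @param net the \code{multiplex_network}.
#' @param layer layer index in 1..M.
#' @return Integer vector of component sizes (possibly empty).
#' @export
cluster_sizes <- function(state, net, layer) {
  if (layer < 1 || layer > net$M) stop("layer out of range 1..", net$M)
  coop <- which(state[, layer] == 1)
  if (length(coop) == 0) return(integer(0))
  sub <- net$adj[[layer]][coop, coop, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  sort(igraph::components(g)$csize, decreasing = TRUE)
}
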