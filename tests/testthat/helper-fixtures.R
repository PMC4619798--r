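# In-code fixtures and independent oracles used across the suite.

# multiplex from explicit 0/1 adjacency matrices
mk_net <- function(...) multiplex_network(list(...))

# symmetric adjacency from an edge list matrix (rows = c(u, v)), N nodes
adj_from_edges <- function(N, edges) {
  a <- matrix(0, N, N)
  for (k in seq_len(nrow(edges))) {
    a[edges[k, 1], edges[k, 2]] <- 1
    a[edges[k, 2], edges[k, 1]] <- 1
  }
  a
}

# path graph adjacency
path_adj <- function(N) adj_from_edges(N, cbind(1:(N - 1), 2:N))

# complete graph adjacency
complete_adj <- function(N) {
  a <- matrix(1, N, N); diag(a) <- 0; a
}

# constant-delta homophily field
const_delta <- function(N, d) {
  m <- matrix(d, N, N); diag(m) <- 0
  homophily_field(m)
}

# random connected small multiplex + homophily field, for property loops
random_instance <- function(N, M, seed, sigma = 1, delta_mean = 1) {
  cfg <- netgen_config(N = N, M = M, attachment_m = min(2, N - 1),
                       delta_mean = delta_mean, sigma = sigma, seed = seed)
  list(net = generate_multiplex(cfg), hom = sample_homophily(cfg), cfg = cfg)
}

# z_layers built by hand (bypasses the network constructor; used for
# degenerate shapes like N = 1)
mk_z <- function(Zlist) {
  structure(list(Z = lapply(Zlist, function(z) Matrix::Matrix(z, sparse = TRUE)),
                 N = nrow(Zlist[[1]]), M = length(Zlist)), class = "z_layers")
}

# neighbor lookup without touching package internals
nbrs_of <- function(net, x, alpha) which(as.matrix(net$adj[[alpha]])[, x] != 0)

# truncated 30-term exponential series oracle, independent of the spectral
# implementation
expm_series <- function(S, terms = 30) {
  S <- as.matrix(S)
  acc <- diag(nrow(S))
  term <- diag(nrow(S))
  for (k in seq_len(terms)) {
    term <- term %*% S / k
    acc <- acc + term
  }
  acc
}

# fixed-count power-iteration oracle for the leading eigenvector
power_iter_oracle <- function(S, iters = 10000) {
  v <- rep(1, nrow(S))
  for (i in seq_len(iters)) {
    v <- as.numeric(S %*% v)
    v <- v / sum(v)
  }
  v
}

# naive double-loop supra assembly oracle
supra_oracle <- function(Zlist, omega) {
  N <- nrow(Zlist[[1]]); M <- length(Zlist)
  S <- matrix(0, N * M, N * M)
  for (a in 1:M) for (b in 1:M) for (x in 1:N) for (y in 1:N) {
    S[(a - 1) * N + x, (b - 1) * N + y] <-
      if (a == b) as.matrix(Zlist[[a]])[x, y] else if (x == y) omega[a, b] else 0
  }
  S
}

# flood-fill connected-component oracle over the cooperator subgraph
cluster_oracle <- function(state, adj, layer) {
  coop <- which(state[, layer] == 1)
  a <- as.matrix(adj[[layer]])
  seen <- logical(length(coop))
  sizes <- integer(0)
  for (i in seq_along(coop)) {
    if (seen[i]) next
    queue <- i; seen[i] <- TRUE; size <- 0
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]; size <- size + 1
      nb <- which(a[coop[j], coop] != 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

# standard small pipeline: weighted layers, centrality, communicability
small_pipeline <- function(N = 30, M = 2, sigma = 1, seed = 3,
                           coupling = 0.3) {
  inst <- random_instance(N, M, seed, sigma = sigma)
  z <- build_z_layers(inst$net, inst$hom)
  om <- coupling_matrix({
    o <- matrix(coupling, M, M); diag(o) <- 0; o
  })
  g <- communicability(z, om)
  c(inst, list(z = z, omega = om, g = g))
}
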