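#' Configuration for the synthetic multiplex generator
#'
#' Bundles and validates the parameters of the synthetic study system: M
#' independently grown scale-free layers over a shared node set, and a field
#' of homophily differences drawn from a normal distribution truncated below
#' at zero.
#'
#' @param N node count (>= 2).
#' @param M layer count (>= 1).
#' @param attachment_m edges added per new node during preferential
#'   attachment (>= 1, < N). The default 3 gives mean degree near 6 and a
#'   degree exponent in the usual scale-free regime (2 < gamma < 3).
#' @param delta_mean mean of the homophily-difference distribution
#'   (nonnegative; default 1).
#' @param sigma standard deviation of that distribution (nonnegative). Large
#'   sigma spreads the differences out and, after truncation at zero,
#'   inflates them: sigma is the package's low-homophily dial (sigma = 1 is
#'   the high-homophily condition, sigma = 8 the low-homophily one).
#' @param shared_delta one homophily field shared by all layers (default)
#'   or an independent field per layer.
#' @param seed master RNG seed (integer).
#' @return Object of class \code{netgen_config}.
#' @export
netgen_config <- function(N, M, attachment_m = 3, delta_mean = 1, sigma = 1,
                          shared_delta = TRUE, seed = 1L) {
  N <- as.integer(N); M <- as.integer(M); attachment_m <- as.integer(attachment_m)
  if (is.na(N) || N < 2) stop("N must be an integer >= 2")
  if (is.na(M) || M < 1) stop("M must be an integer >= 1")
  if (is.na(attachment_m) || attachment_m < 1) stop("attachment_m must be >= 1")
  if (attachment_m >= N) stop("attachment_m must be smaller than N")
  if (sigma < 0) stop("sigma must be nonnegative")
  if (delta_mean < 0) stop("delta_mean must be nonnegative")
  structure(list(N = N, M = M, attachment_m = attachment_m,
                 delta_mean = delta_mean, sigma = sigma,
                 shared_delta = isTRUE(shared_delta), seed = as.integer(seed)),
            class = "netgen_config")
}

#' @export
print.netgen_config <- function(x, ...) {
  cat(sprintf(
    "netgen_config: N=%d M=%d m=%d delta~N(%g, %g^2) trunc. at 0 (%s), seed=%d\n",
    x$N, x$M, x$attachment_m, x$delta_mean, x$sigma,
    if (x$shared_delta) "shared" else "per-layer", x$seed))
  invisible(x)
}

# Deterministic sub-seed streams derived from the master seed. Layer growth
# and homophily sampling consume disjoint sub-seeds so that changing sigma
# never perturbs the network topology drawn under the same master seed.
derive_subseeds <- function(seed, n, stream = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  all <- sample.int(.Machine$integer.max - 1L, n * 8L)
  all[seq.int((stream - 1L) * n + 1L, length.out = n)]
}

#' Generate a synthetic scale-free multiplex
#'
#' Grows M independent Barabasi-Albert preferential-attachment layers (via
#' \pkg{igraph}) over the same node identity set. Each layer is simple,
#' undirected, connected, and binary. Layers are grown from distinct
#' sub-seeds derived from the master seed, so the result is bitwise
#' reproducible.
#'
#' @param config a [netgen_config()].
#' @return A [multiplex_network()].
#' @examples
#' net <- generate_multiplex(netgen_config(N = 50, M = 2, seed = 7))
#' net
#' @export
generate_multiplex <- function(config) {
  stopifnot(inherits(config, "netgen_config"))
  seeds <- derive_subseeds(config$seed, config$M, stream = 1L)
  adj <- vector("list", config$M)
  for (a in seq_len(config$M)) {
    g <- NULL
    s <- seeds[a]
    for (try in seq_len(100L)) {
      set.seed(s)
      cand <- igraph::sample_pa(config$N, power = 1, m = config$attachment_m,
                                directed = FALSE)
      cand <- igraph::simplify(cand)
      if (igraph::is_connected(cand)) { g <- cand; break }
      s <- (s + 104729L) %% (.Machine$integer.max - 1L) + 1L
    }
    if (is.null(g)) stop("layer ", a, ": could not grow a connected layer in 100 attempts")
    adj[[a]] <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  }
  multiplex_network(adj)
}

# one symmetric truncated-normal delta matrix
sample_delta_matrix <- function(N, mean, sigma, seed) {
  set.seed(seed)
  d <- matrix(0, N, N)
  vals <- pmax(stats::rnorm(N * (N - 1) / 2, mean = mean, sd = sigma), 0)
  d[upper.tri(d)] <- vals
  d + t(d)
}

#' Sample a homophily field
#'
#' Draws pairwise homophily differences \eqn{\delta_{xy}} from
#' Normal(\code{delta_mean}, \code{sigma}) for each unordered pair x < y,
#' clamps negative draws to zero, and mirrors to a symmetric matrix with a
#' zero diagonal. Clamping (rather than resampling) keeps the mapping
#' "larger sigma, lower homophily" monotone. With \code{shared_delta = FALSE}
#' an independent field is drawn per layer.
#'
#' @param config a [netgen_config()].
#' @return A [homophily_field()].
#' @export
sample_homophily <- function(config) {
  stopifnot(inherits(config, "netgen_config"))
  nf <- if (config$shared_delta) 1L else config$M
  seeds <- derive_subseeds(config$seed, nf, stream = 2L)
  dl <- lapply(seq_len(nf), function(i)
    sample_delta_matrix(config$N, config$delta_mean, config$sigma, seeds[i]))
  homophily_field(if (config$shared_delta) dl[[1]] else dl)
}
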