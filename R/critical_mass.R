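#' Coalition payoff scheme
#'
#' The critical-mass size is the smallest coalition size n such that at
#' least n of the NM individuals on the aggregate layer weakly prefer mutual
#' cooperation (reward R) to unilateral defection (temptation T) at that
#' coalition size. With the one-shot Prisoner's Dilemma payoffs T > R always
#' and no coalition can ever form, so the scheme takes coalition-size
#' dependent payoff functions \code{R_fn(i, n)} and \code{T_fn(i, n)} for
#' individual i in a coalition of size n.
#'
#' @param R_fn vectorized function (i, n) -> reward payoff.
#' @param T_fn vectorized function (i, n) -> temptation payoff.
#' @return Object of class \code{coalition_scheme}.
#' @seealso [linear_coalition_scheme()] for the package default.
#' @export
coalition_scheme <- function(R_fn, T_fn) {
  stopifnot(is.function(R_fn), is.function(T_fn))
  structure(list(R_fn = R_fn, T_fn = T_fn), class = "coalition_scheme")
}

#' Default linear coalition scheme
#'
#' Reward grows linearly with coalition size, \eqn{R_i(n) = a n}, while the
#' temptation is an individual threshold linear in rank,
#' \eqn{T_i(n) = c_0 + c_1 i}: individual i joins once the coalition is
#' large enough to beat its personal threshold (a Granovetter-style
#' heterogeneous-threshold population). With the defaults a = 1, c0 = 10,
#' c1 = 0.5 the resulting critical-mass size is 20 on any aggregate
#' population of at least 20 individuals, so the critical-mass density
#' decays with both N and M towards its large-population limit.
#'
#' @param a reward slope per coalition member (default 1).
#' @param c0 baseline temptation (default 10).
#' @param c1 temptation increment per individual rank (default 0.5; must be
#'   < \code{a} for a finite critical mass).
#' @return A [coalition_scheme()].
#' @export
linear_coalition_scheme <- function(a = 1, c0 = 10, c1 = 0.5) {
  force(a); force(c0); force(c1)
  coalition_scheme(R_fn = function(i, n) a * n,
                   T_fn = function(i, n) c0 + c1 * i)
}

#' Critical-mass size on the aggregate layer
#'
#' Treats the multiplex as a single aggregate layer of NM individuals and
#' returns the smallest n in 1..NM such that
#' \eqn{\sum_i H(R_i(n) - T_i(n)) \ge n}, where H is the Heaviside step.
#' By default \eqn{H(0) = 1} (indifference counts as weak preference for
#' cooperation); set \code{heaviside_zero = FALSE} for the strict reading.
#' Returns \code{NA} (the "no critical mass" sentinel) when no n qualifies.
#'
#' @param scheme a [coalition_scheme()].
#' @param NM aggregate population size (N nodes times M layers).
#' @param heaviside_zero logical, value of H at 0 (default TRUE, i.e. 1).
#' @return Integer n-bar, or \code{NA_integer_} if no critical mass exists.
#' @export
critical_mass_size <- function(scheme, NM, heaviside_zero = TRUE) {
  stopifnot(inherits(scheme, "coalition_scheme"), NM >= 1)
  NM <- as.integer(NM)
  i <- seq_len(NM)
  for (n in seq_len(NM)) {
    d <- scheme$R_fn(i, n) - scheme$T_fn(i, n)
    if (any(!is.finite(d))) stop("coalition payoffs must be finite")
    cnt <- if (heaviside_zero) sum(d >= 0) else sum(d > 0)
    if (cnt >= n) return(n)
  }
  NA_integer_
}

#' Multiplex critical-mass size and density
#'
#' A critical node adopts the same behaviour on every layer, so its M - 1
#' replicas come for free: the multiplex critical-mass size is
#' \eqn{\bar{\bar n} = \lceil \bar n / M \rceil} nodes, and the
#' critical-mass density is \eqn{\tau_{CM} = \bar{\bar n} / N}.
#'
#' @param n_bar aggregate-layer critical-mass size (or \code{NA} sentinel,
#'   which propagates).
#' @param M layer count.
#' @param N node count.
#' @return List with \code{n_bbar} and \code{tau}.
#' @export
multiplex_cm <- function(n_bar, M, N) {
  stopifnot(M >= 1, N >= 1)
  if (is.na(n_bar)) return(list(n_bbar = NA_integer_, tau = NA_real_))
  stopifnot(n_bar >= 1)
  n_bbar <- as.integer(ceiling(n_bar / M))
  list(n_bbar = n_bbar, tau = n_bbar / N)
}

#' Select the critical-mass node set
#'
#' Among all size-k node subsets, the critical mass is the one maximizing the
#' total centrality-and-homophily weight \eqn{\Lambda_S = \sum_{x \in S}
#' \lambda_x}. Because the weights are fixed per node, the maximizer is
#' simply the k nodes with the largest \eqn{\lambda_x}; ties are broken by
#' smallest node id for a canonical answer. For small populations
#' (\code{N <= 12}) \code{enumerate = TRUE} returns all maximizing subsets.
#'
#' @param lambda per-node weight vector (positive, sums to 1).
#' @param k subset size (<= N).
#' @param enumerate return every maximizing subset (only for N <= 12).
#' @return List with \code{nodes} (1-based ids, ascending), \code{lambda_S}
#'   (their total weight), and, when \code{enumerate}, \code{all_sets}.
#' @export
select_cm_nodes <- function(lambda, k, enumerate = FALSE) {
  N <- length(lambda)
  if (k > N) stop("k must not exceed the node count")
  if (k < 1) stop("k must be at least 1")
  ord <- order(-lambda, seq_len(N))
  nodes <- sort(ord[seq_len(k)])
  out <- list(nodes = nodes, lambda_S = sum(lambda[nodes]))
  if (enumerate) {
    if (N > 12) stop("enumerate is supported only for N <= 12")
    sets <- utils::combn(N, k)
    tot <- colSums(matrix(lambda[sets], nrow = k))
    best <- which(tot >= max(tot) - 1e-12)
    out$all_sets <- lapply(best, function(j) sets[, j])
  }
  out
}

#' Critical-mass density over a (N, M) grid
#'
#' Computes \eqn{\tau_{CM}} for every combination of node count N and layer
#' count M under a common coalition scheme, the quantity whose surface
#' decays with both population size and layer count towards its
#' large-population plateau.
#'
#' @param N_values vector of node counts.
#' @param M_values vector of layer counts.
#' @param scheme a [coalition_scheme()] (default [linear_coalition_scheme()]).
#' @param heaviside_zero passed to [critical_mass_size()].
#' @return data.frame with columns N, M, n_bar, n_bbar, tau (NA rows where no
#'   critical mass exists).
#' @export
tau_sweep <- function(N_values, M_values, scheme = linear_coalition_scheme(),
                      heaviside_zero = TRUE) {
  grid <- expand.grid(N = as.integer(N_values), M = as.integer(M_values))
  res <- lapply(seq_len(nrow(grid)), function(r) {
    N <- grid$N[r]; M <- grid$M[r]
    nb <- critical_mass_size(scheme, N * M, heaviside_zero = heaviside_zero)
    mc <- multiplex_cm(nb, M, N)
    data.frame(N = N, M = M, n_bar = nb, n_bbar = mc$n_bbar, tau = mc$tau)
  })
  do.call(rbind, res)
}

#' End-to-end critical-mass analysis of a multiplex
#'
#' Convenience wrapper: computes the aggregate critical-mass size, the
#' multiplex size and density, and selects the critical node set by
#' centrality-homophily weight.
#'
#' @param lambda per-node weight vector from [heterogeneous_centrality()].
#' @param M layer count.
#' @param scheme a [coalition_scheme()].
#' @param heaviside_zero passed to [critical_mass_size()].
#' @return Object of class \code{critical_mass_result}: list with
#'   \code{n_bar}, \code{n_bbar}, \code{tau}, \code{nodes},
#'   \code{lambda_S}.
#' @export
critical_mass <- function(lambda, M, scheme = linear_coalition_scheme(),
                          heaviside_zero = TRUE) {
  N <- length(lambda)
  n_bar <- critical_mass_size(scheme, N * M, heaviside_zero = heaviside_zero)
  mc <- multiplex_cm(n_bar, M, N)
  if (is.na(n_bar)) {
    return(structure(list(n_bar = NA_integer_, n_bbar = NA_integer_,
                          tau = NA_real_, nodes = integer(0), lambda_S = NA_real_),
                     class = "critical_mass_result"))
  }
  sel <- select_cm_nodes(lambda, mc$n_bbar)
  structure(list(n_bar = n_bar, n_bbar = mc$n_bbar, tau = mc$tau,
                 nodes = sel$nodes, lambda_S = sel$lambda_S),
            class = "critical_mass_result")
}

#' @export
print.critical_mass_result <- function(x, ...) {
  if (is.na(x$n_bar)) {
    cat("critical_mass_result: no critical mass under this scheme\n")
  } else {
    cat(sprintf(
      "critical_mass_result: n_bar=%d n_bbar=%d tau=%.4g lambda_S=%.4g\n",
      x$n_bar, x$n_bbar, x$tau, x$lambda_S))
    cat("  nodes:", paste(x$nodes, collapse = " "), "\n")
  }
  invisible(x)
}
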