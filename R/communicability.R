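#' Multiplex communicability matrix
#'
#' Computes \eqn{G = \exp(Z_L + C_{LL})}, the matrix exponential of the
#' supra-adjacency matrix: entry \eqn{[G_{\alpha\beta}]_{xy}} is the
#' factorially weighted count of all walks between node x on layer alpha and
#' node y on layer beta, mixing intra-layer hops (homophily-weighted edges)
#' and interlayer hops (coupling \eqn{\omega_{\alpha\beta}}). Short walks
#' dominate; long walks are discounted by 1/k!.
#'
#' The supra matrix is symmetric by construction, so the exponential is
#' evaluated exactly through its spectral decomposition
#' \eqn{\exp(S) = V e^D V^T}. The network and homophily field are static
#' during a simulation, so G is computed once per run and reused by the
#' strategy-update rule.
#'
#' @param z a \code{z_layers} object.
#' @param omega interlayer [coupling_matrix()].
#' @return Object of class \code{communicability_matrix}: list with \code{G}
#'   (dense NM x NM symmetric matrix), \code{N}, \code{M}, \code{omega}.
#' @examples
#' a <- matrix(0, 2, 2); a[1, 2] <- a[2, 1] <- 1
#' net <- multiplex_network(list(a))
#' hom <- homophily_field(matrix(0, 2, 2))
#' z <- build_z_layers(net, hom)
#' cm <- communicability(z, coupling_matrix(matrix(0, 1, 1)))
#' cm$G  # [[cosh 1, sinh 1], [sinh 1, cosh 1]]
#' @export
communicability <- function(z, omega) {
  S <- build_supra_adjacency(z, omega)
  S <- as.matrix(S)
  if (any(!is.finite(S))) stop("supra matrix has non-finite entries")
  e <- eigen(S, symmetric = TRUE)
  G <- e$vectors %*% (exp(e$values) * t(e$vectors))
  G <- (G + t(G)) / 2  # restore exact symmetry lost to round-off
  structure(list(G = G, N = z$N, M = z$M, omega = as.matrix(omega)),
            class = "communicability_matrix")
}

#' @export
print.communicability_matrix <- function(x, ...) {
  cat("communicability_matrix: ", x$N, " nodes x ", x$M,
      " layers (", x$N * x$M, "^2 entries)\n", sep = "")
  invisible(x)
}

#' Layer-pair block of the communicability matrix
#'
#' Extracts the N x N block \eqn{G_{\alpha\beta}} holding the
#' communicability between every node on layer alpha and every node on
#' layer beta. \code{comm_block(g, a, b)} is the transpose of
#' \code{comm_block(g, b, a)}.
#'
#' @param g a \code{communicability_matrix}.
#' @param alpha,beta layer indices in 1..M.
#' @return N x N numeric matrix.
#' @export
comm_block <- function(g, alpha, beta) {
  stopifnot(inherits(g, "communicability_matrix"))
  if (alpha < 1 || alpha > g$M || beta < 1 || beta > g$M)
    stop("layer index out of range 1..", g$M)
  ia <- (alpha - 1) * g$N + seq_len(g$N)
  ib <- (beta - 1) * g$N + seq_len(g$N)
  g$G[ia, ib, drop = FALSE]
}
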