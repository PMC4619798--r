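#' Multiplex network object
#'
#' A multiplex network replicates the same set of \code{N} nodes across
#' \code{M} layers, each layer carrying its own set of undirected, unweighted
#' intra-layer edges. Node identities are shared between layers: node \code{x}
#' on layer \code{alpha} and node \code{x} on layer \code{beta} are replicas
#' of the same individual.
#'
#' @param adj list of M adjacency matrices (dense or \pkg{Matrix} sparse),
#'   each N x N, binary, symmetric, zero diagonal.
#' @return An object of class \code{multiplex_network} with fields \code{N},
#'   \code{M} and \code{adj} (a list of \code{dgCMatrix} adjacency matrices).
#' @examples
#' a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- 1
#' net <- multiplex_network(list(a, a))
#' net$N; net$M
#' @export
multiplex_network <- function(adj) {
  stopifnot(is.list(adj), length(adj) >= 1)
  adj <- lapply(adj, function(a) {
    a <- methods::as(methods::as(Matrix::Matrix(a), "generalMatrix"), "CsparseMatrix")
    a
  })
  N <- nrow(adj[[1]])
  if (N < 2) stop("multiplex network needs at least 2 nodes")
  for (i in seq_along(adj)) {
    a <- adj[[i]]
    if (nrow(a) != N || ncol(a) != N)
      stop("layer ", i, ": adjacency must be ", N, "x", N)
    if (!all(a@x %in% c(0, 1)))
      stop("layer ", i, ": adjacency entries must be 0/1")
    if (any(Matrix::diag(a) != 0))
      stop("layer ", i, ": adjacency diagonal must be zero")
    if (!Matrix::isSymmetric(a, tol = 0))
      stop("layer ", i, ": adjacency must be symmetric")
  }
  structure(list(N = N, M = length(adj), adj = adj),
            class = "multiplex_network")
}

#' @export
print.multiplex_network <- function(x, ...) {
  ec <- vapply(x$adj, function(a) Matrix::nnzero(a) / 2, numeric(1))
  cat("multiplex_network: ", x$N, " nodes x ", x$M, " layers\n", sep = "")
  cat("  intra-layer edges:", paste(ec, collapse = ", "), "\n")
  invisible(x)
}

#' Homophily field over node pairs
#'
#' Stores the homophily differences \eqn{\delta_{xy} \ge 0} between all node
#' pairs and the derived homophily measure \eqn{h_{xy} = 1/(1+\delta_{xy})}.
#' \eqn{\delta_{xy} = 0} means maximal homophily (\eqn{h = 1}); as
#' \eqn{\delta_{xy} \to \infty} homophily vanishes. The field is either one
#' matrix shared by all layers, or one matrix per layer.
#'
#' @param delta a symmetric nonnegative N x N matrix with zero diagonal, or a
#'   list of M such matrices (one per layer).
#' @return Object of class \code{homophily_field} with fields \code{delta}
#'   (list of matrices), \code{h} (list of matrices), \code{shared} (logical),
#'   \code{N}, and \code{n_fields}.
#' @seealso [build_homophily_matrix()] for the single-matrix constructor.
#' @export
homophily_field <- function(delta) {
  shared <- !is.list(delta)
  dl <- if (shared) list(delta) else delta
  dl <- lapply(seq_along(dl), function(i) {
    d <- as.matrix(dl[[i]])
    if (any(d < 0)) stop("homophily differences must be nonnegative")
    if (!isSymmetric(unname(d))) stop("homophily differences must be symmetric")
    if (any(diag(d) != 0)) stop("homophily difference diagonal must be zero")
    unname(d)
  })
  structure(list(delta = dl, h = lapply(dl, function(d) 1 / (1 + d)),
                 shared = shared, N = nrow(dl[[1]]), n_fields = length(dl)),
            class = "homophily_field")
}

#' @export
print.homophily_field <- function(x, ...) {
  off <- x$delta[[1]][upper.tri(x$delta[[1]])]
  cat("homophily_field: ", x$N, " nodes, ",
      if (x$shared) "shared across layers" else
        paste0(x$n_fields, " per-layer fields"), "\n", sep = "")
  cat(sprintf("  delta: mean %.3f, range [%.3f, %.3f]\n",
              mean(off), min(off), max(off)))
  invisible(x)
}

# delta matrix for layer alpha (recycles the shared field)
delta_for_layer <- function(hom, alpha) {
  if (hom$shared) hom$delta[[1]] else hom$delta[[alpha]]
}

#' Build the homophily matrix from pairwise differences
#'
#' Converts a symmetric nonnegative matrix of homophily differences
#' \eqn{\delta_{xy}} into a [homophily_field()] carrying
#' \eqn{h_{xy} = 1/(1+\delta_{xy})}.
#'
#' @param delta symmetric nonnegative matrix, zero diagonal.
#' @return A \code{homophily_field}.
#' @examples
#' d <- matrix(1, 2, 2); diag(d) <- 0
#' build_homophily_matrix(d)$h[[1]][1, 2]  # 0.5
#' @export
build_homophily_matrix <- function(delta) homophily_field(delta)

#' Homophily-weighted layer matrices
#'
#' Forms, for each layer \eqn{\alpha}, the Hadamard (entrywise) product
#' \eqn{Z^\alpha = H^\alpha \circ A^\alpha}, i.e.
#' \eqn{z^\alpha_{xy} = a^\alpha_{xy} / (1+\delta_{xy})}. Edges between highly
#' homophilous nodes keep weight close to 1; edges between dissimilar nodes
#' are attenuated. With \eqn{\delta \equiv 0} the layer matrices reduce to the
#' plain adjacency matrices.
#'
#' @param net a \code{multiplex_network}.
#' @param hom a \code{homophily_field} on the same node set.
#' @return Object of class \code{z_layers}: list with \code{Z} (list of M
#'   sparse symmetric matrices), \code{N}, \code{M}.
#' @export
build_z_layers <- function(net, hom) {
  stopifnot(inherits(net, "multiplex_network"), inherits(hom, "homophily_field"))
  if (hom$N != net$N) stop("node count mismatch between network and homophily field")
  if (!hom$shared && hom$n_fields != net$M)
    stop("per-layer homophily field must have one delta matrix per layer")
  Z <- lapply(seq_len(net$M), function(a) net$adj[[a]] * hom$h[[if (hom$shared) 1 else a]])
  structure(list(Z = Z, N = net$N, M = net$M), class = "z_layers")
}

#' @export
print.z_layers <- function(x, ...) {
  cat("z_layers: ", x$M, " homophily-weighted layers on ", x$N, " nodes\n", sep = "")
  invisible(x)
}

#' Interlayer coupling matrix
#'
#' Validates an M x M symmetric nonnegative matrix of interlayer interaction
#' strengths \eqn{\omega_{\alpha\beta}} with zero diagonal. In the supra
#' matrix the coupling contributes blocks \eqn{\omega_{\alpha\beta} I},
#' linking each node only to its own replicas on other layers.
#'
#' @param omega M x M matrix; or see [preset_coupling()] for the presets used
#'   in the experiments.
#' @return The validated matrix (plain numeric), class \code{coupling_matrix}.
#' @export
coupling_matrix <- function(omega) {
  omega <- as.matrix(omega)
  if (nrow(omega) != ncol(omega)) stop("omega must be square")
  if (!isSymmetric(unname(omega))) stop("omega must be symmetric")
  if (any(omega < 0)) stop("omega must be nonnegative")
  if (any(diag(omega) != 0)) stop("omega diagonal must be zero")
  structure(unname(omega), class = c("coupling_matrix", "matrix"))
}

#' Interlayer influence matrix
#'
#' Validates the nonnegative M x M matrix \eqn{W} whose entry
#' \eqn{w^{\alpha\beta}} measures the influence of layer \eqn{\beta} on layer
#' \eqn{\alpha} in the heterogeneous centrality calculation. Every row must
#' contain at least one positive entry.
#'
#' @param W M x M nonnegative matrix.
#' @return The validated matrix, class \code{influence_matrix}.
#' @seealso [default_influence_matrix()]
#' @export
influence_matrix <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (any(W < 0)) stop("W must be nonnegative")
  if (any(rowSums(W) == 0)) stop("every row of W needs a positive entry")
  structure(unname(W), class = c("influence_matrix", "matrix"))
}

#' Default influence matrix derived from the coupling
#'
#' The centrality influence matrix \eqn{W} is a free parameter of the model.
#' The package default ties it to the communicated interlayer coupling:
#' \eqn{w^{\alpha\beta} = \omega_{\alpha\beta}} off the diagonal,
#' \eqn{w^{\alpha\alpha} = 1}, with rows normalized to sum to one. Row
#' normalization only rescales the leading eigenvalue of the supra matrix,
#' not the per-node weights.
#'
#' @param omega a \code{coupling_matrix} (or plain M x M matrix).
#' @return An \code{influence_matrix}.
#' @export
default_influence_matrix <- function(omega) {
  omega <- as.matrix(omega)
  W <- omega
  diag(W) <- 1
  influence_matrix(W / rowSums(W))
}

#' Supra-adjacency matrix of the multiplex
#'
#' Assembles the NM x NM supra matrix \eqn{Z_L + C_{LL}}: the direct sum of
#' the homophily-weighted layer matrices \eqn{Z^\alpha} on the block
#' diagonal, plus interlayer blocks \eqn{\omega_{\alpha\beta} I} coupling
#' each node to its replicas. Replica (node x, layer alpha) maps to
#' supra-index \code{(alpha-1)*N + x} (layer-major order), the convention
#' used throughout the package.
#'
#' @param z a \code{z_layers} object.
#' @param omega interlayer \code{coupling_matrix} (M x M).
#' @return A symmetric sparse \code{dgCMatrix} of dimension NM x NM.
#' @export
build_supra_adjacency <- function(z, omega) {
  stopifnot(inherits(z, "z_layers"))
  omega <- coupling_matrix(omega)
  if (nrow(omega) != z$M) stop("omega dimension must equal layer count")
  S <- Matrix::bdiag(z$Z)
  if (z$M > 1) {
    S <- S + Matrix::kronecker(Matrix::Matrix(unclass(omega), sparse = TRUE),
                               Matrix::Diagonal(z$N))
  }
  methods::as(methods::as(S, "generalMatrix"), "CsparseMatrix")
}
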