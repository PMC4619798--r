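#' Khatri-Rao centrality supra matrix
#'
#' Assembles the NM x NM supra matrix whose (alpha, beta) block is
#' \eqn{w^{\alpha\beta} (Z^\beta)^T}: the Khatri-Rao product of the
#' interlayer influence matrix \eqn{W} with the stacked transposed layer
#' matrices. With the symmetric homophily field used throughout,
#' \eqn{(Z^\beta)^T = Z^\beta}. The positive, sum-normalized leading
#' eigenvector of this matrix defines the global heterogeneous
#' eigenvector-like centrality of the multiplex.
#'
#' @param z a \code{z_layers} object.
#' @param W an [influence_matrix()] (M x M); defaults to a uniform matrix of
#'   ones when \code{NULL}.
#' @return NM x NM sparse matrix (layer-major replica order).
#' @export
build_khatri_rao_supra <- function(z, W = NULL) {
  stopifnot(inherits(z, "z_layers"))
  if (is.null(W)) W <- influence_matrix(matrix(1, z$M, z$M))
  W <- as.matrix(W)
  if (nrow(W) != z$M) stop("W dimension must equal layer count")
  rows <- lapply(seq_len(z$M), function(a)
    do.call(cbind, lapply(seq_len(z$M), function(b) W[a, b] * Matrix::t(z$Z[[b]]))))
  S <- do.call(rbind, rows)
  methods::as(methods::as(S, "generalMatrix"), "CsparseMatrix")
}

# strong connectivity of the graph induced by nonzero entries; returns the
# membership vector so errors can name the components
supra_components <- function(S) {
  g <- igraph::graph_from_adjacency_matrix(S != 0, mode = "directed")
  igraph::components(g, mode = "strong")
}

#' Global heterogeneous eigenvector-like centrality
#'
#' Computes the positive leading eigenvector \eqn{o^\otimes} of the
#' Khatri-Rao centrality supra matrix by power iteration, normalizes it to
#' unit entry sum, reshapes it into the N x M matrix \eqn{O^\otimes} (column
#' alpha = centrality profile on layer alpha) and sums each node's entries
#' across layers into the per-node weight vector \eqn{\Lambda}
#' (\eqn{\sum_x \lambda_x = 1}). \eqn{\lambda_x} is the node's overall
#' weight in terms of centrality and homophily, and is the quantity the
#' critical-mass selection maximizes.
#'
#' The Perron vector exists and is strictly positive only when the supra
#' matrix is irreducible; this is checked first and a descriptive error is
#' raised otherwise.
#'
#' @param z_supra NM x NM nonnegative supra matrix from
#'   [build_khatri_rao_supra()].
#' @param N node count (to undo the layer-major stacking).
#' @param tol convergence tolerance on the L1 change of the normalized
#'   iterate (default 1e-12).
#' @param max_iter iteration cap (default 1e5).
#' @return Object of class \code{multiplex_centrality}: list with
#'   \code{o_supra} (length NM), \code{O_matrix} (N x M), \code{lambda}
#'   (length N, sums to 1), \code{iterations}.
#' @export
heterogeneous_centrality <- function(z_supra, N, tol = 1e-12, max_iter = 1e5) {
  NM <- nrow(z_supra)
  if (NM %% N != 0) stop("supra dimension is not a multiple of N")
  M <- NM %/% N
  if (any(z_supra@x < 0)) stop("supra matrix must be nonnegative")
  comp <- supra_components(z_supra)
  if (comp$no > 1) {
    sizes <- sort(comp$csize, decreasing = TRUE)
    stop("no positive eigenvector: supra matrix is reducible (",
         comp$no, " strongly connected components, sizes ",
         paste(utils::head(sizes, 5), collapse = ", "),
         if (comp$no > 5) ", ..." else "", ")")
  }
  v <- rep(1 / NM, NM)
  it <- 0L
  repeat {
    it <- it + 1L
    w <- as.numeric(z_supra %*% v)
    s <- sum(w)
    if (s <= 0) stop("power iteration collapsed to zero vector")
    w <- w / s
    if (sum(abs(w - v)) < tol || it >= max_iter) { v <- w; break }
    v <- w
  }
  if (it >= max_iter) warning("power iteration hit max_iter before tolerance")
  O <- matrix(v, nrow = N, ncol = M)
  lambda <- rowSums(O)
  structure(list(o_supra = v, O_matrix = O, lambda = lambda, iterations = it),
            class = "multiplex_centrality")
}

#' @export
print.multiplex_centrality <- function(x, ...) {
  cat("multiplex_centrality: ", length(x$lambda), " nodes x ",
      ncol(x$O_matrix), " layers (", x$iterations, " iterations)\n", sep = "")
  top <- order(-x$lambda)[seq_len(min(5, length(x$lambda)))]
  cat("  top lambda:", paste(sprintf("%d=%.4g", top, x$lambda[top]),
                             collapse = " "), "\n")
  invisible(x)
}
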