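#' Write / read a multilayer edge list
#'
#' Plain tab-separated format, one record per intra-layer edge with header
#' \code{layer  node_u  node_v}; layers and node ids are 0-based in the
#' file. Each undirected edge is written once (u < v). The round trip is
#' lossless.
#'
#' @param net a \code{multiplex_network}.
#' @param path file path.
#' @return \code{write_multiplex_edgelist} returns \code{path} invisibly;
#'   \code{read_multiplex_edgelist} returns a \code{multiplex_network}.
#' @export
write_multiplex_edgelist <- function(net, path) {
  rows <- lapply(seq_len(net$M), function(a) {
    s <- Matrix::summary(Matrix::triu(net$adj[[a]]))
    s <- s[s$i < s$j, , drop = FALSE]
    data.frame(layer = a - 1L, node_u = s$i - 1L, node_v = s$j - 1L)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_multiplex_edgelist
#' @param N,M node / layer counts; inferred from the file when NULL.
#' @export
read_multiplex_edgelist <- function(path, N = NULL, M = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("layer", "node_u", "node_v") %in% names(df)))
    stop("edge list needs columns layer, node_u, node_v")
  if (is.null(M)) M <- max(df$layer) + 1L
  if (is.null(N)) N <- max(df$node_u, df$node_v) + 1L
  adj <- lapply(seq_len(M) - 1L, function(a) {
    e <- df[df$layer == a, , drop = FALSE]
    m <- Matrix::sparseMatrix(i = c(e$node_u, e$node_v) + 1L,
                              j = c(e$node_v, e$node_u) + 1L,
                              x = 1, dims = c(N, N))
    m
  })
  multiplex_network(adj)
}

#' Write / read a homophily pair table
#'
#' Tab-separated table with header \code{node_u  node_v  delta} (0-based
#' ids, each unordered pair once). Per-layer fields gain a leading
#' \code{layer} column. Unlisted pairs read back as delta = 0.
#'
#' @param hom a \code{homophily_field}.
#' @param path file path.
#' @return \code{write_homophily_pairs} returns \code{path} invisibly;
#'   \code{read_homophily_pairs} returns a \code{homophily_field}.
#' @export
write_homophily_pairs <- function(hom, path) {
  one <- function(d, layer = NULL) {
    ut <- which(upper.tri(d), arr.ind = TRUE)
    df <- data.frame(node_u = ut[, 1] - 1L, node_v = ut[, 2] - 1L,
                     delta = d[ut])
    if (!is.null(layer)) df <- cbind(layer = layer, df)
    df
  }
  df <- if (hom$shared) one(hom$delta[[1]]) else
    do.call(rbind, lapply(seq_along(hom$delta),
                          function(a) one(hom$delta[[a]], a - 1L)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_homophily_pairs
#' @param N node count; inferred from the file when NULL.
#' @export
read_homophily_pairs <- function(path, N = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (is.null(N)) N <- max(df$node_u, df$node_v) + 1L
  fill <- function(e) {
    d <- matrix(0, N, N)
    d[cbind(e$node_u + 1L, e$node_v + 1L)] <- e$delta
    d[cbind(e$node_v + 1L, e$node_u + 1L)] <- e$delta
    d
  }
  if ("layer" %in% names(df)) {
    layers <- sort(unique(df$layer))
    homophily_field(lapply(layers, function(a) fill(df[df$layer == a, ])))
  } else {
    homophily_field(fill(df))
  }
}

#' Write a centrality node table
#'
#' Tab-separated table \code{node  lambda  o_layer1 ... o_layerM} (0-based
#' node ids) with the per-node weight and the per-layer centrality profile.
#'
#' @param cent a \code{multiplex_centrality}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_node_table <- function(cent, path) {
  O <- cent$O_matrix
  df <- data.frame(node = seq_len(nrow(O)) - 1L, lambda = cent$lambda)
  colnames(O) <- paste0("o_layer", seq_len(ncol(O)))
  utils::write.table(cbind(df, O), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a trajectory CSV
#'
#' Comma-separated \code{round, rho_total, rho_layer1..M, rho_node} with a
#' header comment line carrying the run's config digest and seed.
#'
#' @param traj a \code{pd_trajectory}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d digest=%s", traj$seed, traj$digest), con)
  utils::write.csv(traj$rho, con, row.names = FALSE)
  invisible(path)
}
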