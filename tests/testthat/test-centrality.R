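test_that("Khatri-Rao supra blocks equal w[a,b] * t(Z[b])", {
  set.seed(7)
  for (rep in 1:4) {
    N <- 3; M <- 2
    Zl <- lapply(1:M, function(a) {
      z <- matrix(runif(N * N), N, N); z <- (z + t(z)) / 2; diag(z) <- 0; z
    })
    W <- matrix(runif(M * M) + 0.1, M, M)
    S <- as.matrix(build_khatri_rao_supra(mk_z(Zl), influence_matrix(W)))
    oracle <- rbind(cbind(W[1, 1] * t(Zl[[1]]), W[1, 2] * t(Zl[[2]])),
                    cbind(W[2, 1] * t(Zl[[1]]), W[2, 2] * t(Zl[[2]])))
    expect_equal(S, oracle, tolerance = 1e-14)
  }
  # single layer with unit influence is the layer itself
  z <- mk_z(list(path_adj(3)))
  expect_equal(as.matrix(build_khatri_rao_supra(z, influence_matrix(matrix(1, 1, 1)))),
               path_adj(3))
})

test_that("complete graph with no homophily difference has uniform weights", {
  net <- mk_net(complete_adj(6))
  z <- build_z_layers(net, const_delta(6, 0))
  cent <- heterogeneous_centrality(build_khatri_rao_supra(z), N = 6)
  expect_equal(cent$lambda, rep(1 / 6, 6), tolerance = 1e-10)
})

test_that("identical layers with uniform influence reduce to monoplex eigencentrality", {
  a <- adj_from_edges(6, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6),
                               c(6, 1), c(1, 4), c(2, 5)))
  net <- mk_net(a, a)
  z <- build_z_layers(net, const_delta(6, 0))
  cent <- heterogeneous_centrality(build_khatri_rao_supra(z), N = 6)
  e <- eigen(a, symmetric = TRUE)
  mono <- abs(e$vectors[, 1]); mono <- mono / sum(mono)
  expect_equal(cent$lambda, mono, tolerance = 1e-8)
})

test_that("centrality matches independent eigen and power-iteration oracles", {
  for (s in 1:4) {
    inst <- random_instance(6, 2, seed = s)
    z <- build_z_layers(inst$net, inst$hom)
    W <- influence_matrix(matrix(c(1, 0.4, 0.4, 1), 2))
    S <- build_khatri_rao_supra(z, W)
    cent <- heterogeneous_centrality(S, N = 6)
    expect_equal(sum(cent$lambda), 1, tolerance = 1e-10)
    expect_true(all(cent$o_supra > 0))
    expect_equal(cent$o_supra, power_iter_oracle(S), tolerance = 1e-8)
    ev <- eigen(as.matrix(S))
    v <- abs(Re(ev$vectors[, which.max(Re(ev$values))])); v <- v / sum(v)
    expect_equal(cent$o_supra, v, tolerance = 1e-8)
    # O matrix stacks the supra vector layer-major; lambda sums rows
    expect_equal(as.numeric(cent$O_matrix), cent$o_supra)
    expect_equal(cent$lambda, rowSums(cent$O_matrix))
  }
})

test_that("weights are invariant to positive rescaling of the supra matrix", {
  inst <- random_instance(8, 2, seed = 11)
  z <- build_z_layers(inst$net, inst$hom)
  S <- build_khatri_rao_supra(z)
  l1 <- heterogeneous_centrality(S, N = 8)$lambda
  l2 <- heterogeneous_centrality(S * 7.3, N = 8)$lambda
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("reducible supra matrices raise a descriptive error", {
  a <- matrix(0, 4, 4); a[1, 2] <- a[2, 1] <- 1; a[3, 4] <- a[4, 3] <- 1
  z <- mk_z(list(a))
  S <- build_khatri_rao_supra(z, influence_matrix(matrix(1, 1, 1)))
  expect_error(heterogeneous_centrality(S, N = 4),
               "no positive eigenvector.*components")
})

test_that("raising a node's homophily never lowers its weight", {
  inst <- random_instance(7, 2, seed = 3)
  z <- build_z_layers(inst$net, inst$hom)
  base <- heterogeneous_centrality(build_khatri_rao_supra(z), N = 7)$lambda
  for (fac in c(0.5, 0.2)) {
    d <- inst$hom$delta[[1]]
    d[4, ] <- d[4, ] * fac; d[, 4] <- d[, 4] * fac  # more similar to everyone
    z2 <- build_z_layers(inst$net, homophily_field(d))
    l2 <- heterogeneous_centrality(build_khatri_rao_supra(z2), N = 7)$lambda
    expect_gte(l2[4], base[4] - 1e-12)
    base <- l2
  }
})
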