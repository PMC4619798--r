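# tiny fixed two-layer instance used throughout
evo_fixture <- function(seed = 3, N = 12) {
  inst <- random_instance(N, 2, seed = seed)
  z <- build_z_layers(inst$net, inst$hom)
  om <- coupling_matrix(matrix(c(0, 0.4, 0.4, 0), 2))
  c(inst, list(g = communicability(z, om)))
}

test_that("pairwise payoffs follow the b/c payoff matrix", {
  p <- game_params(b = 1, c = 0.3)
  expect_equal(pd_payoff("C", "C", p), 0.7)
  expect_equal(pd_payoff("C", "D", p), -0.3)
  expect_equal(pd_payoff("D", "C", p), 1)
  expect_equal(pd_payoff("D", "D", p), 0)
  expect_error(pd_payoff("X", "C", p), "strategies")
})

test_that("layer payoff accumulates over neighbors and isolates earn zero", {
  # star: node 1 connected to 2, 3, 4; node 5 isolated on this layer
  a <- adj_from_edges(5, rbind(c(1, 2), c(1, 3), c(1, 4)))
  b2 <- adj_from_edges(5, rbind(c(1, 2), c(3, 4), c(4, 5)))
  net <- mk_net(a, b2)
  p <- game_params(b = 1, c = 0.3)
  S <- matrix(0L, 5, 2)
  S[c(1, 2, 3), 1] <- 1L  # node 1 cooperates with neighbors C, C, D
  expect_equal(layer_payoff(net, S, 1, 1, p), 2 * 0.7 - 0.3)
  S2 <- matrix(1L, 5, 2); S2[1, 1] <- 0L  # defector among 3 cooperators
  expect_equal(layer_payoff(net, S2, 1, 1, p), 3)
  S3 <- matrix(0L, 5, 2)
  expect_equal(layer_payoff(net, S3, 1, 1, p), 0)
  expect_equal(layer_payoff(net, S3, 5, 1, p), 0)  # isolated
})

test_that("scaling factor hits its bounds and interpolates linearly", {
  fx <- evo_fixture()
  p <- game_params()
  S <- matrix(1L, 12, 2)
  expect_equal(eta_scaling(fx$g, fx$net, S, 1, 1, 2, p), 0.1)
  S2 <- S; S2[, 2] <- 0L
  expect_equal(eta_scaling(fx$g, fx$net, S2, 1, 1, 2, p), 1)
  # two members with equal communicability, one sharing -> midpoint
  a1 <- adj_from_edges(3, cbind(1, 3))
  a2 <- adj_from_edges(3, cbind(1, 2))   # on layer 2, node 1 neighbors node 2
  net <- mk_net(a1, a2)
  Gfake <- matrix(0, 6, 6)
  Gfake[1, 4] <- 1  # (x=1, layer1) vs counterpart (1, layer2)
  Gfake[1, 5] <- 1  # vs neighbor (2, layer2)
  gf <- structure(list(G = Gfake, N = 3, M = 2),
                  class = "communicability_matrix")
  Sm <- matrix(0L, 3, 2)
  Sm[1, 1] <- 1L; Sm[1, 2] <- 1L; Sm[2, 2] <- 0L
  expect_equal(eta_scaling(gf, net, Sm, 1, 1, 2, p), 1 - 0.9 * 0.5)
  # zero communicability falls back to eta_max
  gf0 <- structure(list(G = matrix(0, 6, 6), N = 3, M = 2),
                   class = "communicability_matrix")
  expect_equal(eta_scaling(gf0, net, Sm, 1, 1, 2, p), 1)
})

test_that("Fermi probability follows the homophily-sharpened logistic", {
  p <- game_params(K = 0.1)
  expect_equal(fermi_probability(1, 1, 2, p, eta_x = 1), 0.5)
  # (P_x - P_y)/(delta K) = -1
  expect_equal(fermi_probability(-0.1, 0, 1, p, eta_x = 1),
               1 / (1 + exp(-1)), tolerance = 1e-12)
  # delta = 0 is the deterministic zero-noise limit
  expect_equal(fermi_probability(1, 2, 0, p, eta_x = 0.7), 0.7)
  expect_equal(fermi_probability(1, 1, 0, p, eta_x = 0.7), 0.35)
  expect_equal(fermi_probability(2, 1, 0, p, eta_x = 0.7), 0)
  expect_error(fermi_probability(1, 1, -1, p), "nonnegative")
  # bounded by eta
  for (eta in c(0.1, 0.55, 1)) {
    pr <- fermi_probability(runif(1, -3, 3), runif(1, -3, 3), runif(1, 0, 5),
                            p, eta_x = eta)
    expect_gte(pr, 0); expect_lte(pr, eta)
  }
})

test_that("homogeneous states are fixed points of the elementary step", {
  fx <- evo_fixture()
  for (val in c(0L, 1L)) {
    S <- matrix(val, fx$net$N, 2)
    set.seed(1)
    for (i in 1:50) {
      out <- elementary_step(fx$net, fx$hom, fx$g, S)
      expect_identical(out$state, S)
    }
  }
})

test_that("forced elementary steps adopt at the closed-form rate", {
  fx <- evo_fixture()
  p <- game_params()
  set.seed(99)
  S <- matrix(rbinom(24, 1, 0.5), 12, 2)
  frc <- list(x = 1, alpha = 1, beta = 2, y = nbrs_of(fx$net, 1, 2)[1])
  out <- elementary_step(fx$net, fx$hom, fx$g, S, p, force = frc)
  expected <- fermi_probability(
    layer_payoff(fx$net, S, 1, 1, p),
    layer_payoff(fx$net, S, frc$y, 2, p),
    fx$hom$delta[[1]][1, frc$y], p,
    eta_scaling(fx$g, fx$net, S, 1, 1, 2, p))
  expect_equal(out$info$prob, expected, tolerance = 1e-12)
  n <- 20000
  set.seed(123)
  hits <- sum(vapply(seq_len(n), function(i) {
    o <- elementary_step(fx$net, fx$hom, fx$g, S, p, force = frc)
    o$state[1, 1] == S[frc$y, 2]
  }, logical(1)))
  if (S[1, 1] == S[frc$y, 2]) {
    expect_equal(hits, n)  # adopting an identical strategy is invisible
  } else {
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(hits / n - expected), 3 * se + 1e-9)
  }
})

test_that("absorbing states persist and densities stay in [0, 1]", {
  fx <- evo_fixture()
  p <- game_params()
  allD <- matrix(0L, 12, 2); allC <- matrix(1L, 12, 2)
  tD <- run_evolution(fx$net, fx$hom, fx$g, p, allD, rounds = 50, seed = 5)
  expect_true(all(tD$rho$rho_total == 0))
  tC <- run_evolution(fx$net, fx$hom, fx$g, p, allC, rounds = 50, seed = 5)
  expect_true(all(tC$rho$rho_total == 1))
  init <- initialize_state("random_fraction", 12, 2, fraction = 0.5, seed = 2)
  tr <- run_evolution(fx$net, fx$hom, fx$g, p, init, rounds = 100, seed = 7)
  expect_true(all(tr$rho$rho_total >= 0 & tr$rho$rho_total <= 1))
  # overall density is the mean of the layer densities
  expect_equal(tr$rho$rho_total, rowMeans(tr$rho[, c("rho_layer1", "rho_layer2")]),
               tolerance = 1e-12)
  # node-level density never exceeds the replica-level one
  expect_true(all(tr$rho$rho_node <= tr$rho$rho_total + 1e-12))
})

test_that("trajectories are deterministic given the seed", {
  fx <- evo_fixture()
  init <- initialize_state("random_fraction", 12, 2, fraction = 0.3, seed = 4)
  t1 <- run_evolution(fx$net, fx$hom, fx$g, game_params(), init, 80, seed = 42,
                      snapshot_rounds = c(10, 40))
  t2 <- run_evolution(fx$net, fx$hom, fx$g, game_params(), init, 80, seed = 42,
                      snapshot_rounds = c(10, 40))
  expect_identical(t1$rho, t2$rho)
  expect_identical(t1$final_state, t2$final_state)
  expect_identical(t1$snapshots, t2$snapshots)
  # snapshots agree with the recorded densities
  expect_equal(mean(t1$snapshots[["10"]]), t1$rho$rho_total[11])
})

test_that("initial configurations match their specification", {
  S <- initialize_state("critical_mass", 10, 3, cm_nodes = c(2, 5, 9))
  expect_equal(mean(S), 0.3)
  expect_true(all(S[c(2, 5, 9), ] == 1))
  expect_true(all(S[-c(2, 5, 9), ] == 0))
  expect_error(initialize_state("critical_mass", 10, 3, cm_nodes = integer(0)),
               "non-empty")
  expect_true(all(initialize_state("random_fraction", 6, 2, fraction = 0) == 0))
  expect_true(all(initialize_state("random_fraction", 6, 2, fraction = 1) == 1))
})

test_that("convergence round flags the last excursion from the final band", {
  expect_equal(convergence_round(rep(0.5, 30)), 0L)
  rho <- c(0.2, 0.4, 0.6, 0.9, rep(1, 26))
  expect_equal(convergence_round(rho), 4L)  # round 3 (value 0.9) still outside
  # within-band wiggles do not count
  rho2 <- c(0.2, 0.6, rep(c(0.995, 1), 14))
  expect_equal(convergence_round(rho2), 2L)
})
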