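# independent linear-scan oracle over all coalition sizes
cm_oracle <- function(diff_fn, NM, h0 = 1) {
  for (n in 1:NM) {
    cnt <- sum(vapply(1:NM, function(i) {
      d <- diff_fn(i, n)
      if (d > 0) 1 else if (d == 0) h0 else 0
    }, numeric(1)))
    if (cnt >= n) return(n)
  }
  NA_integer_
}

test_that("critical-mass size scans coalition sizes with the Heaviside count", {
  always <- coalition_scheme(function(i, n) n + 1, function(i, n) n)  # R - T = +1
  expect_equal(critical_mass_size(always, 10), 1)
  never <- coalition_scheme(function(i, n) n, function(i, n) n + 1)   # R - T = -1
  expect_true(is.na(critical_mass_size(never, 10)))
  ramp <- coalition_scheme(function(i, n) n, function(i, n) rep(5, length(i)))
  expect_equal(critical_mass_size(ramp, 10), 5)
  expect_equal(critical_mass_size(ramp, 10),
               cm_oracle(function(i, n) n - 5, 10))
  # H(0) convention is switchable
  tie <- coalition_scheme(function(i, n) rep(1, length(i)),
                          function(i, n) rep(1, length(i)))
  expect_equal(critical_mass_size(tie, 5, heaviside_zero = TRUE), 1)
  expect_true(is.na(critical_mass_size(tie, 5, heaviside_zero = FALSE)))
})

test_that("default linear scheme matches the scan oracle across populations", {
  sch <- linear_coalition_scheme()
  for (NM in c(25, 60, 300, 3000)) {
    expect_equal(critical_mass_size(sch, NM),
                 cm_oracle(function(i, n) n - (10 + 0.5 * i), NM))
  }
})

test_that("multiplex critical mass divides by layers with a ceiling", {
  expect_equal(multiplex_cm(9, 3, 1000), list(n_bbar = 3L, tau = 0.003))
  expect_equal(multiplex_cm(10, 3, 100)$n_bbar, 4L)
  expect_equal(multiplex_cm(7, 1, 100), list(n_bbar = 7L, tau = 0.07))
  expect_true(is.na(multiplex_cm(NA_integer_, 3, 100)$n_bbar))
  # ceiling keeps the triggered set sufficient: n_bbar * M >= n_bar >= n_bbar
  for (nb in 1:20) for (M in 1:4) {
    r <- multiplex_cm(nb, M, 100)
    expect_gte(r$n_bbar * M, nb)
    expect_lte(r$n_bbar, nb)
  }
})

test_that("top-k selection equals exhaustive subset maximization", {
  expect_equal(select_cm_nodes(c(0.4, 0.3, 0.2, 0.1), 2),
               list(nodes = c(1L, 2L), lambda_S = 0.7))
  expect_equal(select_cm_nodes(rep(0.25, 4), 2)$nodes, c(1L, 2L))  # id tie-break
  set.seed(5)
  for (rep in 1:5) {
    lam <- runif(8); lam <- lam / sum(lam)
    sel <- select_cm_nodes(lam, 3, enumerate = TRUE)
    best <- max(combn(8, 3, function(s) sum(lam[s])))
    expect_equal(sel$lambda_S, best, tolerance = 1e-12)
    expect_true(any(vapply(sel$all_sets, function(s)
      identical(sort(s), sel$nodes), logical(1))))
  }
  expect_error(select_cm_nodes(rep(0.1, 10), 11), "exceed")
})

test_that("critical-mass density is non-increasing in N and M and bounded", {
  tab <- tau_sweep(c(100, 200, 400), 1:3)
  expect_true(all(tab$tau > 0 & tab$tau <= 1))
  for (M in 1:3) {
    s <- tab[tab$M == M, ]
    expect_true(all(diff(s$tau[order(s$N)]) <= 0))
  }
  for (N in c(100, 200, 400)) {
    s <- tab[tab$N == N, ]
    expect_true(all(diff(s$tau[order(s$M)]) <= 0))
  }
})

test_that("end-to-end critical mass on a multiplex picks the heaviest nodes", {
  inst <- random_instance(40, 2, seed = 4)
  z <- build_z_layers(inst$net, inst$hom)
  cent <- heterogeneous_centrality(build_khatri_rao_supra(z), N = 40)
  cm <- critical_mass(cent$lambda, 2)
  expect_equal(cm$n_bar, 20)
  expect_equal(cm$n_bbar, 10)
  expect_equal(cm$tau, 0.25)
  expect_equal(cm$nodes, sort(order(-cent$lambda)[1:10]))
  expect_lte(cm$lambda_S, 1)
})
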