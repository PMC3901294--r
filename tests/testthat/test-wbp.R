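test_that("edge index matches the nonzero stoichiometric pattern", {
  net <- star_network(5)
  ed <- build_edges(net)
  expect_equal(ed$n_edges, 6)
  net2 <- scrappy_random_net(seed = 3)
  ed2 <- build_edges(net2)
  expect_equal(ed2$n_edges, nrow(net2$stoichiometry))
  # neighbor queries agree with the matrix
  S <- as.matrix(stoichiometric_matrix(net2))
  for (m in seq_len(nrow(S)))
    expect_setequal(ed2$met_adj[[m]]$rxn, which(S[m, ] != 0))
  for (r in seq_len(ncol(S)))
    expect_setequal(ed2$rxn_adj[[r]], which(S[, r] != 0))
})

test_that("messages initialize to equispaced uniform populations", {
  net <- tiny_net()
  msg <- init_messages(net, wbp_config(Q = 5))
  p <- message_population(msg, "r1", "A")
  expect_equal(p$values, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(p$weights, rep(0.2, 5))
  # degenerate bound: single-value population with weight 1
  netd <- metabolic_network(
    data.frame(id = c("r1", "r2"), lb = c(0.3, 0), ub = c(0.3, 1)),
    data.frame(id = "A", kind = "internal", p1 = NA, p2 = NA),
    data.frame(met = "A", rxn = c("r1", "r2"), coeff = c(1, -1)))
  msgd <- init_messages(netd, wbp_config(Q = 5))
  pd <- message_population(msgd, "r1", "A")
  expect_equal(pd$values, 0.3)
  expect_equal(pd$weights, 1)
})

test_that("cavity field on the star is the (1-x)^3 convolution", {
  set.seed(5)
  net <- star_network(5)
  msg <- init_messages(net, wbp_config(Q = 200))
  xg <- seq(0, 1, length.out = 50)
  L <- estimate_L(msg, "pool", "in1", xg, n_draws = 4000)
  est <- marginal_estimate("L", "flux", grid = xg, density = as.numeric(L))
  exact <- marginal_estimate("e", "flux", grid = xg,
                             density = 4 * (1 - xg)^3)
  expect_lt(total_variation(est, exact), 0.03)
  expect_gt(attr(L, "n_var_draws"), 0)
})

test_that("unsatisfiable shifted constraints give exactly zero", {
  # pool balance needs sum(in) = out = 1; fixing in1 above 1 is impossible
  net <- star_network(2, total = 1, bounds = c(0, 3))
  msg <- init_messages(net, wbp_config(Q = 100))
  L <- estimate_L(msg, "pool", "in1", c(2.5, 3), n_draws = 100)
  expect_equal(as.numeric(L), c(0, 0))
  L2 <- estimate_L(msg, "pool", "in1", c(0.2, 0.9), n_draws = 100)
  expect_true(all(L2 > 0))
})

test_that("single-neighbor metabolite forces the flux value", {
  # one reaction feeding one internal metabolite: balance iff x = 0
  net <- metabolic_network(
    data.frame(id = c("r1", "r2"), lb = c(-1, 0), ub = 1),
    data.frame(id = c("A", "B"), kind = "internal", p1 = NA, p2 = NA),
    data.frame(met = c("A", "A", "B"), rxn = c("r1", "r2", "r2"),
               coeff = c(1, -1, 1)))
  msg <- init_messages(net, wbp_config(Q = 101))
  # metabolite B touches only r2: L_{B->r2}(x) > 0 iff x = 0
  L <- estimate_L(msg, "B", "r2", c(0, 0.5, 1), n_draws = 10)
  expect_true(L[1] > 0)
  expect_equal(as.numeric(L[2:3]), c(0, 0))
})

test_that("message updates: empty products are uniform, single factors match L", {
  set.seed(9)
  net <- star_network(3)
  cfg <- wbp_config(Q = 50, draws_per_point = 100)
  msg <- init_messages(net, cfg)
  up <- update_message(msg, "in1", "pool", t = 1, config = cfg)
  expect_equal(up$weights, rep(1 / 50, 50))  # leaf reaction: empty product
  # two-metabolite reaction: message to one equals the field of the other
  net2 <- chain_network(2)
  msg2 <- init_messages(net2, cfg)
  up2 <- update_message(msg2, "conv1", "M1", t = 1, config = cfg)
  L <- estimate_L(msg2, "M2", "conv1", msg2$grids[, 2], 100)
  expect_equal(up2$weights, as.numeric(L) / sum(L), tolerance = 1e-10)
})

test_that("sweeps are deterministic under a fixed seed and stable at the fixed point", {
  net <- chain_network(3)
  cfg <- wbp_config(Q = 100, iterations = 4, draws_per_point = 50, seed = 2)
  set.seed(2); m1 <- init_messages(net, cfg)
  s1 <- wbp_sweep(m1, 1, cfg)
  set.seed(2); m2 <- init_messages(net, cfg)
  s2 <- wbp_sweep(m2, 1, cfg)
  expect_identical(s1$messages$weights, s2$messages$weights)
  expect_identical(s1$max_change, s2$max_change)
  # repeated sweeps settle: late change well below the first
  m <- m1
  ch <- numeric(6)
  for (t in 1:6) {
    sw <- wbp_sweep(m, t, cfg)
    m <- sw$messages
    ch[t] <- sw$max_change
  }
  expect_lt(mean(tail(ch, 2)), mean(head(ch, 1)) + 1e-12)
})

test_that("draw counters follow the configured schedule", {
  # every metabolite has 3+ reactions, so no deterministic shortcuts apply
  net <- metabolic_network(
    data.frame(id = sprintf("r%d", 1:4), lb = 0, ub = 1),
    data.frame(id = c("A", "B"), kind = "internal", p1 = NA, p2 = NA),
    data.frame(met = c("A", "A", "A", "B", "B", "B"),
               rxn = c("r1", "r2", "r3", "r2", "r3", "r4"),
               coeff = c(1, -1, 1, 1, -1, 1)))
  cfg <- wbp_config(Q = 20, iterations = 2, draws_per_point = 10)
  msg <- init_messages(net, cfg)
  # edges touching a 3-reaction metabolite sample 2 variables per draw when
  # the equality solve removes one
  nvd <- 0
  for (t in 1:2) {
    sw <- wbp_sweep(msg, t, cfg)
    msg <- sw$messages
    nvd <- nvd + sw$n_var_draws
  }
  # directed edges with a non-empty cavity product: r2->A, r3->A (factor B)
  # and r2->B, r3->B (factor A); each factor's estimate_L sees a 3-neighbor
  # metabolite minus the pivot, i.e. 2 variables, of which 1 is solved and
  # 1 sampled per draw
  factors_per_sweep <- 4
  expected <- sum(10 * (1:2)) * 20 * factors_per_sweep * 1
  expect_equal(nvd, expected)
})

test_that("star marginals reproduce the Dirichlet limit and pinned fluxes", {
  net <- star_network(5)
  res <- run_wbp(net, wbp_config(Q = 150, iterations = 2,
                                 draws_per_point = 50, final_draws = 1e4,
                                 seed = 8))
  for (i in 1:5) {
    m <- res$marginals[[sprintf("in%d", i)]]
    expect_lt(total_variation(m, star_exact_marginal(5, m$grid)), 0.05)
    # normalization and support confinement
    expect_equal(fluxpdf:::trapz(m$grid, m$density), 1, tolerance = 1e-6)
    expect_true(all(m$grid >= 0 & m$grid <= 1))
  }
  out <- res$marginals[["out"]]
  expect_true(out$point_mass)
  expect_equal(out$value, 1)
})

test_that("fully pinned networks give point masses everywhere", {
  net <- metabolic_network(
    data.frame(id = c("r1", "r2"), lb = 0.4, ub = 0.4),
    data.frame(id = "A", kind = "internal", p1 = NA, p2 = NA),
    data.frame(met = "A", rxn = c("r1", "r2"), coeff = c(1, -1)))
  res <- run_wbp(net, wbp_config(Q = 10, iterations = 1,
                                 draws_per_point = 10, final_draws = 10))
  expect_true(all(vapply(res$marginals, function(m) m$point_mass,
                         logical(1))))
  expect_equal(res$marginals$r1$value, 0.4)
})

test_that("identical seeds give bitwise-identical densities", {
  net <- chain_network(2)
  cfg <- wbp_config(Q = 80, iterations = 2, draws_per_point = 50,
                    final_draws = 500, seed = 123)
  r1 <- run_wbp(net, cfg)
  r2 <- run_wbp(net, cfg)
  expect_identical(r1$marginals$entry$density, r2$marginals$entry$density)
})

test_that("exchange posteriors are recovered for window priors", {
  # A fed by r1 in [0,1], drained to the environment with gamma in [-1, 1]:
  # gamma = -r1... sign: balance x1 * 1 = gamma, so gamma in [0, 1] uniform
  net <- metabolic_network(
    data.frame(id = c("r1", "r2"), lb = 0, ub = 1),
    data.frame(id = c("A", "B"),
               kind = c("uniform", "internal"),
               p1 = c(-1, NA), p2 = c(1, NA)),
    data.frame(met = c("A", "B", "B"), rxn = c("r1", "r1", "r2"),
               coeff = c(1, -1, 1)))
  res <- run_wbp(net, wbp_config(Q = 200, iterations = 3,
                                 draws_per_point = 100, final_draws = 2e4,
                                 seed = 17))
  g <- res$marginals[["A"]]
  expect_equal(g$kind, "exchange")
  exact <- marginal_estimate("e", "exchange", grid = g$grid,
                             density = as.numeric(g$grid >= 0))
  expect_lt(total_variation(g, exact), 0.05)
})

test_that("tree instances match exact marginals (stars and chains)", {
  cfg <- wbp_config(Q = 200, iterations = 3, draws_per_point = 100,
                    final_draws = 2e4, seed = 29)
  for (n in c(2, 4)) {
    res <- run_wbp(star_network(n), cfg)
    m <- res$marginals[["in1"]]
    expect_lt(total_variation(m, star_exact_marginal(n, m$grid)), 0.05)
  }
  net <- chain_network(4)
  res <- run_wbp(net, cfg)
  exact <- chain_exact_marginals(net)
  for (id in names(exact))
    expect_lt(total_variation(res$marginals[[id]], exact[[id]]), 0.05)
})
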