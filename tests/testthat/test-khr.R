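test_that("null space basis: shape, orthonormality, rank-nullity", {
  ns <- null_space_basis(matrix(c(1, -1), 1, 2))
  expect_equal(ns$K, 1)
  expect_equal(abs(ns$basis[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-12)
  nz <- null_space_basis(matrix(0, 3, 5))
  expect_equal(nz$K, 5)
  # hRBC-shaped: 34 independent constraints on 46 fluxes leave K = 12
  set.seed(2)
  A <- matrix(rnorm(34 * 46), 34, 46)
  ns2 <- null_space_basis(A)
  expect_equal(ns2$K, 12)
  expect_equal(max(abs(A %*% ns2$basis)), 0, tolerance = 1e-9)
  expect_equal(crossprod(ns2$basis), diag(12), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("K = N - rank on random matrices (rank-nullity property)", {
  set.seed(14)
  for (rep in 1:200) {
    n <- sample(2:8, 1); m <- sample(1:6, 1); r <- sample(1:min(m, n), 1)
    A <- matrix(rnorm(m * r), m, r) %*% matrix(rnorm(r * n), r, n)
    ns <- null_space_basis(A)
    expect_equal(ns$K, n - qr(A, tol = 1e-9)$rank)
    if (ns$K > 0)
      expect_lt(max(abs(A %*% ns$basis)), 1e-8 * max(abs(A)))
  }
})

test_that("diagonal segment polytope projects to [0, sqrt(2)]", {
  net <- tiny_net()  # x1 = x2, both in [0,1]
  poly <- project_constraints(net)
  expect_equal(poly$K, 1)
  # rows are Phi restricted to each flux; the segment has length sqrt(2)
  lims <- c(max(poly$lo / poly$Psi[, 1]), min(poly$hi / poly$Psi[, 1]))
  expect_equal(abs(diff(sort(lims))), sqrt(2), tolerance = 1e-10)
  y0 <- find_interior_point(poly)
  expect_true(y0 > min(lims) && y0 < max(lims))
})

test_that("all-exchanged network recovers its box exactly", {
  net <- metabolic_network(
    data.frame(id = c("r1", "r2"), lb = c(0, -1), ub = c(1, 2)),
    data.frame(id = "A", kind = "uniform", p1 = -5, p2 = 5),
    data.frame(met = "A", rxn = c("r1", "r2"), coeff = c(1, -1)))
  poly <- project_constraints(net)
  expect_equal(poly$K, 2)
  # flux rows of Psi form a permutation/rotation of the identity; the box is
  # recovered up to the orthonormal change of basis
  X <- khr_sample(net, khr_config(n_samples = 5000, burn_in = 500,
                                  seed = 4))$X
  expect_true(all(X[, 1] >= -1e-9 & X[, 1] <= 1 + 1e-9))
  expect_true(all(X[, 2] >= -1 - 1e-9 & X[, 2] <= 2 + 1e-9))
})

test_that("pinned fluxes and fixed exchanges fold into the affine offset", {
  net <- star_network(3)  # out pinned at 1
  poly <- project_constraints(net)
  expect_equal(poly$K, 2)  # 4 fluxes - 1 balance - 1 pin
  expect_equal(poly$x_p[4], 1, tolerance = 1e-10)
  # contradictory pins are infeasible
  bad <- metabolic_network(
    data.frame(id = c("r1", "r2"), lb = c(0.2, 0.7), ub = c(0.2, 0.7)),
    data.frame(id = "A", kind = "internal", p1 = NA, p2 = NA),
    data.frame(met = "A", rxn = c("r1", "r2"), coeff = c(1, -1)))
  expect_error(project_constraints(bad), "infeasible")
})

test_that("interior points are strictly inside; empty sets error", {
  net <- star_network(4)
  poly <- project_constraints(net)
  for (m in c("minover", "chebyshev")) {
    y0 <- find_interior_point(poly, method = m)
    expect_gt(min(fluxpdf:::poly_slacks(poly, y0)), 0)
  }
  # box polytope: any returned point is strictly inside (0,1)^K
  netb <- metabolic_network(
    data.frame(id = c("r1", "r2"), lb = 0, ub = 1),
    data.frame(id = "A", kind = "uniform", p1 = -5, p2 = 5),
    data.frame(met = "A", rxn = c("r1", "r2"), coeff = c(1, -1)))
  polyb <- project_constraints(netb)
  x0 <- polyb$Phi %*% find_interior_point(polyb)
  expect_true(all(x0 > 0 & x0 < 1))
  # empty polytope: two rows demanding incompatible values
  poly_bad <- poly
  poly_bad$lo <- rep(10, length(poly_bad$lo))
  poly_bad$hi <- rep(11, length(poly_bad$hi))
  expect_error(find_interior_point(poly_bad, max_iter = 2000), "interior")
})

test_that("hit-and-run steps stay on the feasible chord", {
  netb <- metabolic_network(
    data.frame(id = c("r1", "r2"), lb = 0, ub = 1),
    data.frame(id = "A", kind = "uniform", p1 = -5, p2 = 5),
    data.frame(met = "A", rxn = c("r1", "r2"), coeff = c(1, -1)))
  poly <- project_constraints(netb)
  set.seed(6)
  y <- find_interior_point(poly)
  diam <- sqrt(2)  # diameter of the unit square
  for (i in 1:200) {
    y2 <- hit_and_run_step(poly, y)
    expect_lte(sqrt(sum((y2 - y)^2)), diam + 1e-9)
    expect_gte(min(fluxpdf:::poly_slacks(poly, y2)), 0)
    y <- y2
  }
})

test_that("uniformity on a box: means and per-coordinate KS", {
  netb <- metabolic_network(
    data.frame(id = c("r1", "r2", "r3"), lb = 0, ub = 1),
    data.frame(id = "A", kind = "uniform", p1 = -5, p2 = 5),
    data.frame(met = "A", rxn = c("r1", "r2", "r3"), coeff = c(1, 1, -1)))
  s <- khr_sample(netb, khr_config(n_samples = 2e4, burn_in = 2000,
                                   n_chains = 2, seed = 10))
  for (j in 1:3) {
    x <- s$X[, j]
    expect_equal(mean(x), 0.5, tolerance = 3 * sqrt(1 / 12 / length(x)) * 5)
    ks <- suppressWarnings(stats::ks.test(x, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("simplex marginals match Beta(1,4); samples satisfy all constraints", {
  net <- star_network(5)
  s <- khr_sample(net, khr_config(n_samples = 4e4, burn_in = 5000,
                                  seed = 12))
  expect_lt(s$max_balance_violation, 1e-8 * 5)
  expect_lt(s$max_bound_violation, 1e-9 * 1)
  ks <- suppressWarnings(
    stats::ks.test(s$X[, "in1"], function(q) 1 - (1 - q)^4))
  expect_lt(unname(ks$statistic), 0.015)
  m <- marginals_from_samples(s)
  expect_lt(total_variation(m$in1, star_exact_marginal(5, m$in1$grid)), 0.05)
  expect_true(m$out$point_mass)
})

test_that("chains with different seeds agree (self-consistency)", {
  net <- star_network(4)
  s1 <- khr_sample(net, khr_config(n_samples = 2e4, burn_in = 2000,
                                   n_chains = 1, seed = 21))
  s2 <- khr_sample(net, khr_config(n_samples = 2e4, burn_in = 2000,
                                   n_chains = 1, seed = 22))
  for (j in 1:4) {
    d <- suppressWarnings(stats::ks.test(s1$X[, j], s2$X[, j]))$statistic
    expect_lt(unname(d), 0.02)
  }
})

test_that("the lift is the linear map it claims to be", {
  net <- star_network(4)
  s <- khr_sample(net, khr_config(n_samples = 2e4, burn_in = 2000,
                                  n_chains = 1, seed = 31))
  poly <- s$poly
  Y <- sweep(s$X, 2, poly$x_p) %*% poly$Phi  # orthonormal lift inverted
  CX <- stats::cov(s$X)
  CY <- stats::cov(Y)
  expect_equal(CX, poly$Phi %*% CY %*% t(poly$Phi), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("K = 0 networks return the unique solution with a warning", {
  net <- metabolic_network(
    data.frame(id = c("r1", "r2"), lb = 0.4, ub = 0.4),
    data.frame(id = "A", kind = "internal", p1 = NA, p2 = NA),
    data.frame(met = "A", rxn = c("r1", "r2"), coeff = c(1, -1)))
  expect_warning(s <- khr_sample(net), "point polytope")
  expect_equal(nrow(s$X), 1)
  expect_equal(as.numeric(s$X), c(0.4, 0.4))
})

test_that("histogram marginals: flat boxes, degenerate points", {
  set.seed(41)
  X <- cbind(runif(5000), rep(0.3, 5000))
  colnames(X) <- c("r1", "r2")
  net <- metabolic_network(
    data.frame(id = c("r1", "r2"), lb = 0, ub = 1),
    data.frame(id = "A", kind = "uniform", p1 = -5, p2 = 5),
    data.frame(met = "A", rxn = c("r1", "r2"), coeff = c(1, -1)))
  m <- marginals_from_samples(X, bins = 20, net = net)
  flat <- marginal_estimate("f", "flux", grid = m$r1$grid,
                            density = rep(1, 20))
  expect_lt(total_variation(m$r1, flat), 0.05)
  expect_true(m$r2$point_mass)
  expect_equal(m$r2$value, 0.3)
})
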