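# Small network fixtures built in code, plus independent oracles used to
# check the samplers against ground truth.

# the smallest valid instance: one metabolite A with x1 - x2 = 0
tiny_net <- function(lb = 0, ub = 1) {
  metabolic_network(
    reactions = data.frame(id = c("r1", "r2"), lb = lb, ub = ub),
    metabolites = data.frame(id = "A", kind = "internal", p1 = NA, p2 = NA),
    stoichiometry = data.frame(met = "A", rxn = c("r1", "r2"),
                               coeff = c(1, -1)))
}

# random valid network for round-trip / property tests (no feasibility
# certification needed, so built directly)
scrappy_random_net <- function(N = 8, M = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    met <- sample.int(M, 2 * N, replace = TRUE)
    rxn <- sample.int(N, 2 * N, replace = TRUE)
    keep <- !duplicated(cbind(met, rxn))
    met <- met[keep]; rxn <- rxn[keep]
    if (length(unique(met)) == M && length(unique(rxn)) == N) break
  }
  kinds <- sample(c("internal", "fixed", "uniform"), M, replace = TRUE)
  p1 <- ifelse(kinds == "fixed", round(runif(M, -1, 1), 3),
               ifelse(kinds == "uniform", -1, NA))
  p2 <- ifelse(kinds == "uniform", 1, NA)
  lb <- round(runif(N, -1, 0), 4)
  metabolic_network(
    reactions = data.frame(id = sprintf("r%d", 1:N), lb = lb,
                           ub = lb + round(runif(N, 0.1, 2), 4)),
    metabolites = data.frame(id = sprintf("m%d", 1:M), kind = kinds,
                             p1 = p1, p2 = p2),
    stoichiometry = data.frame(met = sprintf("m%d", met),
                               rxn = sprintf("r%d", rxn),
                               coeff = round(runif(length(met), 0.2, 2), 4) *
                                 sample(c(-1, 1), length(met), TRUE)))
}

expect_same_network <- function(a, b) {
  expect_equal(a$reactions, b$reactions)
  expect_equal(a$metabolites, b$metabolites)
  expect_equal(a$stoichiometry, b$stoichiometry)
}

# exact scaled-simplex marginal of a star fixture: Beta(1, n - 1) stretched
# to [0, total] (valid when total <= bounds, the case used in tests)
star_exact_marginal <- function(n, grid, total = 1) {
  d <- ifelse(grid <= total, (n - 1) / total * (1 - grid / total)^(n - 2), 0)
  marginal_estimate("exact", "flux", grid = grid, density = d)
}

# exact marginals of a chain fixture by 1-D interval propagation: every flux
# is a fixed multiple of the entry flux, so each marginal is uniform on the
# interval its multiplier allows
chain_exact_marginals <- function(net) {
  S <- as.matrix(internal_submatrix(net))
  ns <- null_space_basis(S)
  stopifnot(ns$K == 1)
  v <- ns$basis[, 1]
  if (v[1] < 0) v <- -v  # orient along increasing entry flux
  lo <- max((net$reactions$lb / v)[v > 0], (net$reactions$ub / v)[v < 0])
  hi <- min((net$reactions$ub / v)[v > 0], (net$reactions$lb / v)[v < 0])
  stopifnot(hi > lo)
  out <- list()
  for (i in seq_len(nrow(net$reactions))) {
    id <- net$reactions$id[i]
    g <- sort(c(seq(net$reactions$lb[i], net$reactions$ub[i],
                    length.out = 401), v[i] * c(lo, hi)))
    a <- v[i] * lo; b <- v[i] * hi
    out[[id]] <- marginal_estimate(id, "flux", grid = g,
                                   density = as.numeric(g >= a & g <= b))
  }
  out
}

# weighted histogram density of draws on [lo, hi]
weighted_density <- function(x, w, lo, hi, bins = 50) {
  br <- seq(lo, hi, length.out = bins + 1)
  cut_idx <- findInterval(pmin(pmax(x, lo), hi), br,
                          rightmost.closed = TRUE, all.inside = TRUE)
  mass <- tapply(w, factor(cut_idx, levels = seq_len(bins)), sum)
  mass[is.na(mass)] <- 0
  marginal_estimate("draws", "flux", grid = (br[-1] + br[-length(br)]) / 2,
                    density = as.numeric(mass) / sum(mass) / diff(br))
}
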