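#' Configuration for the random network generator
#'
#' The ensemble emulates sparse bipartite reaction-metabolite networks with
#' half as many metabolites as reactions (`M = N/2`), low metabolite degree
#' and signed stoichiometry, the shape used for the linear-runtime scaling
#' experiments. Degree/coefficient/bound laws are this package's own
#' documented choices (see the methods vignette).
#'
#' @param N number of reactions (>= 2).
#' @param M number of metabolites (default `N/2`; must satisfy `1 <= M < N`).
#' @param d mean metabolite degree (>= 2); degrees are `2 + Poisson(d - 2)`.
#' @param coeff_law `"unit"` (coefficients +-1) or `"uniform"` (signed
#'   magnitudes uniform on `[0.1, 2]`).
#' @param bounds baseline flux bounds, default `c(0, 1)`.
#' @param log_spread s >= 0: each reaction's bounds are scaled by
#'   `10^U(-s, s)`, so fluxes span up to `2s` orders of magnitude; 0 (the
#'   default) keeps all bounds at the baseline.
#' @param exch_frac fraction of metabolites given a uniform exchange window
#'   (`[-1, 1]` times the bound scale) instead of an exact balance; default 0
#'   (all metabolites internal).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(N, M = N %/% 2, d = 3,
                             coeff_law = c("unit", "uniform"),
                             bounds = c(0, 1), log_spread = 0,
                             exch_frac = 0, seed = NULL) {
  coeff_law <- match.arg(coeff_law)
  stopifnot(N >= 2, M >= 1, M < N, d >= 2, length(bounds) == 2,
            bounds[1] < bounds[2], log_spread >= 0,
            exch_frac >= 0, exch_frac <= 1)
  structure(list(N = as.integer(N), M = as.integer(M), d = d,
                 coeff_law = coeff_law, bounds = bounds,
                 log_spread = log_spread, exch_frac = exch_frac, seed = seed),
            class = "generator_config")
}

#' Generate a random sparse metabolic network
#'
#' Draws a bipartite network from the ensemble described by
#' [generator_config()] and certifies it: every reaction is connected, every
#' metabolite has at least one substrate and one product (so the zero flux
#' vector is never forced), the internal stoichiometric submatrix has full
#' row rank, and the projected polytope is feasible with a strictly interior
#' point and certified bounded. Instances failing any check are regenerated,
#' up to `retry_cap` attempts.
#'
#' @param cfg a [generator_config()].
#' @param retry_cap maximum regeneration attempts.
#' @return a valid `metabolic_network`.
#' @export
random_network <- function(cfg, retry_cap = 50) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  last <- "no attempt made"
  for (attempt in seq_len(retry_cap)) {
    net <- try(random_network_once(cfg), silent = TRUE)
    if (inherits(net, "try-error")) { last <- as.character(net); next }
    S_int <- as.matrix(internal_submatrix(net))
    if (nrow(S_int) > 0 && qr(S_int)$rank < nrow(S_int)) {
      last <- "internal submatrix rank-deficient"
      next
    }
    ok <- try({
      poly <- project_constraints(net)
      invisible(find_interior_point(poly))
    }, silent = TRUE)
    if (inherits(ok, "try-error")) { last <- as.character(ok); next }
    return(net)
  }
  stop("random_network: gave up after ", retry_cap, " attempts (last: ",
       trimws(last), ")")
}

random_network_once <- function(cfg) {
  N <- cfg$N; M <- cfg$M
  rxn_ids <- sprintf("r%d", seq_len(N))
  met_ids <- sprintf("m%d", seq_len(M))
  deg <- 2 + stats::rpois(M, cfg$d - 2)
  deg <- pmin(deg, N)
  met <- rxn <- integer(0)
  for (m in seq_len(M)) {
    r <- sample.int(N, deg[m])
    met <- c(met, rep(m, deg[m])); rxn <- c(rxn, r)
  }
  # cover every untouched reaction by reassigning a slot from a reaction
  # that has several, conserving the drawn metabolite degrees
  for (r in setdiff(seq_len(N), unique(rxn))) {
    counts <- tabulate(rxn, N)
    movable <- which(counts[rxn] >= 2 & !(met %in% met[rxn == r]))
    if (length(movable) == 0) {
      m <- sample.int(M, 1)
      while (any(met == m & rxn == r)) m <- sample.int(M, 1)
      met <- c(met, m); rxn <- c(rxn, r)
    } else {
      rxn[movable[sample.int(length(movable), 1)]] <- r
    }
  }
  mag <- switch(cfg$coeff_law,
                unit = rep(1, length(met)),
                uniform = stats::runif(length(met), 0.1, 2))
  sgn <- ifelse(stats::runif(length(met)) < 0.5, -1, 1)
  # every metabolite needs at least one producer and one consumer
  for (m in seq_len(M)) {
    idx <- which(met == m)
    if (all(sgn[idx] > 0) || all(sgn[idx] < 0))
      sgn[sample(idx, 1)] <- -sgn[idx[1]]
  }
  coeff <- mag * sgn
  scale <- 10^stats::runif(N, -cfg$log_spread, cfg$log_spread)
  rx <- data.frame(id = rxn_ids, lb = cfg$bounds[1] * scale,
                   ub = cfg$bounds[2] * scale, stringsAsFactors = FALSE)
  n_ex <- floor(cfg$exch_frac * M)
  ex <- if (n_ex > 0) sample.int(M, n_ex) else integer(0)
  wscale <- max(abs(cfg$bounds))
  mt <- data.frame(id = met_ids,
                   kind = ifelse(seq_len(M) %in% ex, "uniform", "internal"),
                   p1 = ifelse(seq_len(M) %in% ex, -wscale, NA_real_),
                   p2 = ifelse(seq_len(M) %in% ex, wscale, NA_real_),
                   stringsAsFactors = FALSE)
  st <- data.frame(met = met_ids[met], rxn = rxn_ids[rxn], coeff = coeff,
                   stringsAsFactors = FALSE)
  metabolic_network(rx, mt, st)
}

#' Star fixture: n producers feeding one consumed pool
#'
#' One internal metabolite produced by `n` unit-coefficient reactions and
#' drained by a single exchange reaction pinned at flux `total`. The flux
#' polytope is the scaled simplex `sum x_i = total`, `x_i` within `bounds`,
#' whose exact per-flux marginal is the scaled Dirichlet marginal
#' `Beta(1, n - 1)`; with `total = 1`, `bounds = c(0, 1)` the density is
#' `(n-1) (1-x)^(n-2)`.
#'
#' @param n number of producing reactions (>= 2).
#' @param total pinned drain flux.
#' @param bounds common bounds of the producing fluxes.
#' @return a `metabolic_network` with reactions `in1..inn`, `out`.
#' @export
star_network <- function(n, total = 1, bounds = c(0, 1)) {
  stopifnot(n >= 2, bounds[1] <= bounds[2])
  if (total < n * bounds[1] - 1e-12 || total > n * bounds[2] + 1e-12)
    stop("infeasible star: total ", total, " outside achievable [",
         n * bounds[1], ", ", n * bounds[2], "]")
  rx <- data.frame(id = c(sprintf("in%d", seq_len(n)), "out"),
                   lb = c(rep(bounds[1], n), total),
                   ub = c(rep(bounds[2], n), total), stringsAsFactors = FALSE)
  mt <- data.frame(id = "pool", kind = "internal", p1 = NA_real_,
                   p2 = NA_real_, stringsAsFactors = FALSE)
  st <- data.frame(met = "pool", rxn = rx$id, coeff = c(rep(1, n), -1),
                   stringsAsFactors = FALSE)
  metabolic_network(rx, mt, st)
}

#' Chain fixture: a linear pathway with entry and exit exchanges
#'
#' `n_met` internal metabolites in a row: an entry reaction produces the
#' first, conversion reaction k consumes metabolite k (coefficient -1) and
#' produces metabolite k+1 (coefficient `produce[k]`), and an exit reaction
#' drains the last. The polytope is one-dimensional, so each flux's exact
#' marginal is uniform on the interval its bounds and the stoichiometric
#' ratios allow -- a small loopless fixture whose truth is computable in
#' closed form.
#'
#' @param n_met number of metabolites (>= 1).
#' @param produce product coefficients of the conversion steps, recycled to
#'   length `n_met - 1`; the default alternates 1, 2, 0.5 so the fluxes live
#'   on genuinely different scales.
#' @param bounds per-reaction bounds: a 2-vector recycled to all `n_met + 1`
#'   reactions, or a `(n_met + 1) x 2` matrix.
#' @return a `metabolic_network` with reactions `entry`, `conv1..`, `exit`.
#' @export
chain_network <- function(n_met, produce = NULL, bounds = c(0, 1)) {
  stopifnot(n_met >= 1)
  n_rxn <- n_met + 1
  if (is.null(produce)) produce <- rep(c(1, 2, 0.5), length.out = n_met - 1)
  else produce <- rep(produce, length.out = n_met - 1)
  if (is.matrix(bounds)) stopifnot(nrow(bounds) == n_rxn)
  else bounds <- matrix(bounds, n_rxn, 2, byrow = TRUE)
  ids <- c("entry", if (n_met > 1) sprintf("conv%d", seq_len(n_met - 1)),
           "exit")
  rx <- data.frame(id = ids, lb = bounds[, 1], ub = bounds[, 2],
                   stringsAsFactors = FALSE)
  mt <- data.frame(id = sprintf("M%d", seq_len(n_met)), kind = "internal",
                   p1 = NA_real_, p2 = NA_real_, stringsAsFactors = FALSE)
  met <- rxn <- character(0); coeff <- numeric(0)
  met <- c(met, "M1"); rxn <- c(rxn, "entry"); coeff <- c(coeff, 1)
  for (k in seq_len(n_met - 1)) {
    met <- c(met, sprintf("M%d", k), sprintf("M%d", k + 1))
    rxn <- c(rxn, rep(sprintf("conv%d", k), 2))
    coeff <- c(coeff, -1, produce[k])
  }
  met <- c(met, sprintf("M%d", n_met)); rxn <- c(rxn, "exit")
  coeff <- c(coeff, -1)
  metabolic_network(rx, mt, data.frame(met = met, rxn = rxn, coeff = coeff,
                                       stringsAsFactors = FALSE))
}

#' The triangle toy instance for the rejection-free integrator
#'
#' Three variables y, z, x uniform on `[0, 1]` tied by the single equality
#' `y + z + x = 1` with x solved for: the feasible region in the (y, z)
#' plane is the triangle below `z = 1 - y`, the density of x is `2 (1 - x)`
#' on `[0, 1]`, and the reweighting factor observed when sampling y first is
#' `w(y) = 1 - y`.
#'
#' @param Q atoms per uniform population.
#' @return list: `constraint` (a [linear_constraint()]), `pops` (three
#'   uniform [weighted_population()]s), `solved` (index of x), `labels`.
#' @export
toy_triangle <- function(Q = 2000) {
  list(constraint = linear_constraint(c(1, 1, 1), 1),
       pops = list(uniform_population(Q, 0, 1), uniform_population(Q, 0, 1),
                   uniform_population(Q, 0, 1)),
       solved = 3L, labels = c("y", "z", "x"))
}

#' Rescale one flux and its stoichiometric column consistently
#'
#' Multiplies reaction `rxn`'s bounds by `factor` and divides its column of
#' the stoichiometry by `factor`, which changes the units of that one flux
#' while leaving the flux polytope (and hence every other flux's marginal)
#' unchanged. Used to probe robustness to fluxes spanning different orders
#' of magnitude.
#'
#' @param net a `metabolic_network`.
#' @param rxn reaction id.
#' @param factor positive scale factor.
#' @return the rescaled `metabolic_network`.
#' @export
rescale_flux <- function(net, rxn, factor) {
  stopifnot(factor > 0)
  i <- rxn_index(net, rxn)
  net$reactions$lb[i] <- net$reactions$lb[i] * factor
  net$reactions$ub[i] <- net$reactions$ub[i] * factor
  sel <- net$stoichiometry$rxn == net$reactions$id[i]
  net$stoichiometry$coeff[sel] <- net$stoichiometry$coeff[sel] / factor
  net
}
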