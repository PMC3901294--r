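#' Configuration for the weighted Belief Propagation engine
#'
#' Defaults follow the run protocol used for the human red-blood-cell
#' benchmark: populations of `Q = 500` weighted values per message, 30
#' population-dynamics iterations with `10^3 * t` Monte Carlo draws per
#' population point at iteration `t`, and `10^5` draws per point for the
#' final marginal assembly.
#'
#' @param Q population size per message (>= 2).
#' @param iterations number of sweeps `T` (>= 1).
#' @param draws_per_point either a function of the iteration index `t`
#'   returning the number of draws used to estimate each cavity field value,
#'   or a single number `c` meaning `c * t`.
#' @param final_draws draws per point in the final marginal assembly.
#' @param bins histogram bins used when a population density must be
#'   evaluated at a point (the delta-solved variable).
#' @param damping lambda in `[0, 1)`: new weights are
#'   `(1 - lambda) * alpha + lambda * old`. 0 (none) reproduces plain
#'   population dynamics; positive values help on loopy graphs.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param early_stop_tol stop sweeping when the maximal L1 weight change
#'   falls below this value; 0 disables early stopping.
#' @return object of class `wbp_config`.
#' @export
wbp_config <- function(Q = 500, iterations = 30, draws_per_point = 1000,
                       final_draws = 1e5, bins = 50, damping = 0,
                       seed = NULL, early_stop_tol = 0) {
  stopifnot(Q >= 2, iterations >= 1, final_draws >= 1,
            damping >= 0, damping < 1, bins >= 1)
  sched <- if (is.function(draws_per_point)) draws_per_point
           else function(t) draws_per_point * t
  ns <- vapply(seq_len(iterations), sched, numeric(1))
  if (any(ns < 1) || any(diff(ns) < 0))
    stop("draw schedule must be positive and nondecreasing")
  structure(list(Q = as.integer(Q), iterations = as.integer(iterations),
                 draws_per_point = sched,
                 final_draws = as.integer(final_draws),
                 bins = as.integer(bins), damping = damping, seed = seed,
                 early_stop_tol = early_stop_tol),
            class = "wbp_config")
}

#' Bipartite edge index of a network
#'
#' One directed message lives on every edge (reaction i, metabolite mu) with
#' nonzero stoichiometric coefficient. The index provides O(degree) neighbor
#' queries in both directions and fixes the deterministic edge order used by
#' [wbp_sweep()]: metabolites in declared order, and within a metabolite its
#' reactions in declared order.
#'
#' @param net a `metabolic_network`.
#' @return object of class `wbp_edges`: `edges` (data.frame `rxn`, `met`,
#'   integer indices), `met_adj` (per-metabolite reaction indices and
#'   coefficients), `rxn_adj` (per-reaction metabolite indices), `eid`
#'   (edge-id lookup), `n_edges`.
#' @export
build_edges <- function(net) {
  S <- stoichiometric_matrix(net)
  M <- nrow(S); N <- ncol(S)
  tri <- Matrix::summary(S)  # i = met, j = rxn
  o <- order(tri$i, tri$j)
  tri <- tri[o, ]
  edges <- data.frame(rxn = tri$j, met = tri$i)
  eid <- new.env(hash = TRUE, parent = emptyenv())
  for (e in seq_len(nrow(edges)))
    assign(paste(edges$rxn[e], edges$met[e]), e, envir = eid)
  met_adj <- lapply(seq_len(M), function(m) {
    sel <- tri$i == m
    list(rxn = tri$j[sel], coeff = tri$x[sel])
  })
  rxn_adj <- lapply(seq_len(N), function(r) sort(tri$i[tri$j == r]))
  structure(list(edges = edges, met_adj = met_adj, rxn_adj = rxn_adj,
                 eid = eid, n_edges = nrow(edges)),
            class = "wbp_edges")
}

edge_id <- function(edges, rxn, met) {
  e <- get0(paste(rxn, met), envir = edges$eid)
  if (is.null(e)) stop("no edge between reaction ", rxn, " and metabolite ",
                       met)
  e
}

#' Initialize the message set
#'
#' Every message (reaction i -> metabolite mu) is a weighted population on
#' the flux support `[m_i, M_i]`: `Q` values on an equispaced grid including
#' both endpoints, with equal weights. A degenerate bound `m_i == M_i` gives
#' the single-value population. The grid positions stay fixed throughout the
#' run; only the weights evolve.
#'
#' @param net a `metabolic_network`.
#' @param config a [wbp_config()].
#' @return object of class `wbp_messages` holding the network, the edge
#'   index, the per-reaction value grids and the per-edge weight vectors.
#' @export
init_messages <- function(net, config = wbp_config()) {
  edges <- build_edges(net)
  Q <- config$Q
  N <- nrow(net$reactions)
  grids <- matrix(0, Q, N)
  for (i in seq_len(N)) {
    lb <- net$reactions$lb[i]; ub <- net$reactions$ub[i]
    grids[, i] <- if (ub - lb <= 1e-12 * max(1, abs(lb), abs(ub)))
      rep(lb, Q) else seq(lb, ub, length.out = Q)
  }
  weights <- matrix(1 / Q, Q, edges$n_edges)
  structure(list(net = net, edges = edges, Q = Q, grids = grids,
                 weights = weights, bins = config$bins),
            class = "wbp_messages")
}

#' Extract one message as a weighted population
#'
#' @param messages a `wbp_messages` object.
#' @param rxn,met reaction and metabolite (index or id).
#' @return the [weighted_population()] carried by the directed edge
#'   reaction -> metabolite (degenerate supports collapse to one atom).
#' @export
message_population <- function(messages, rxn, met) {
  net <- messages$net
  if (is.character(rxn)) rxn <- rxn_index(net, rxn)
  if (is.character(met)) met <- met_index(net, met)
  e <- edge_id(messages$edges, rxn, met)
  vals <- messages$grids[, rxn]
  w <- messages$weights[, e]
  lb <- net$reactions$lb[rxn]; ub <- net$reactions$ub[rxn]
  if (ub - lb <= 1e-12 * max(1, abs(lb), abs(ub)))
    return(weighted_population(lb, 1, lo = lb, hi = lb))
  weighted_population(vals, w, lo = lb, hi = ub)
}

# constraint pieces for metabolite `met` with reaction `excl` taken out:
# neighbor populations (message populations l -> met, plus the exchange-rate
# variable for a uniform prior), their coefficients, and the equality target
met_constraint <- function(messages, met, excl) {
  net <- messages$net
  adj <- messages$edges$met_adj[[met]]
  keep <- adj$rxn != excl
  pops <- lapply(which(keep), function(j) {
    r <- adj$rxn[j]
    list(values = messages$grids[, r],
         weights = messages$weights[, edge_id(messages$edges, r, met)],
         lo = net$reactions$lb[r], hi = net$reactions$ub[r])
  })
  coeffs <- adj$coeff[keep]
  kind <- net$metabolites$kind[met]
  target <- 0
  if (kind == "fixed") {
    target <- net$metabolites$p1[met]
  } else if (kind == "uniform") {
    # the exchange rate enters as an explicit extra variable (coefficient -1,
    # uniform population over its window) so the constraint stays an equality
    gl <- net$metabolites$p1[met]; gu <- net$metabolites$p2[met]
    gp <- uniform_population(messages$Q, gl, gu)
    pops <- c(pops, list(list(values = gp$values, weights = gp$weights,
                              lo = gl, hi = gu)))
    coeffs <- c(coeffs, -1)
  }
  list(pops = pops, coeffs = coeffs, target = target)
}

#' Monte Carlo estimate of a cavity field L_{mu -> i}
#'
#' Estimates, for each value `x` of reaction `rxn`'s flux, the (unnormalized)
#' probability that metabolite `met`'s mass balance holds when `rxn` is fixed
#' at `x`: the metabolite's constraint row, with the residual shifted by
#' `-coeff * x`, is integrated over the cavity populations of the remaining
#' neighbor reactions (plus the exchange-rate variable when the metabolite is
#' exchanged) by `n_draws` rejection-free weighted draws per value.
#'
#' @param messages a `wbp_messages` object.
#' @param met metabolite (index or id).
#' @param rxn reaction (index or id); must be a neighbor of `met`.
#' @param x numeric vector of flux values within `rxn`'s bounds.
#' @param n_draws Monte Carlo draws per value (>= 1).
#' @return numeric vector of nonnegative estimates, one per entry of `x`,
#'   with attribute `n_var_draws` (elementary draw counter).
#' @export
estimate_L <- function(messages, met, rxn, x, n_draws) {
  stopifnot(n_draws >= 1)
  net <- messages$net
  if (is.character(rxn)) rxn <- rxn_index(net, rxn)
  if (is.character(met)) met <- met_index(net, met)
  adj <- messages$edges$met_adj[[met]]
  j <- match(rxn, adj$rxn)
  if (is.na(j)) stop("reaction ", net$reactions$id[rxn],
                     " does not process metabolite ", net$metabolites$id[met])
  ct <- met_constraint(messages, met, excl = rxn)
  res <- cpp_estimate_L_grid(as.numeric(x), adj$coeff[j],
                             c(ct$target, ct$target), ct$coeffs, ct$pops,
                             as.integer(n_draws), as.integer(messages$bins))
  structure(res$means, n_var_draws = res$n_var_draws)
}

#' Update one message by population dynamics
#'
#' Recomputes the weights of the message reaction -> metabolite: for each
#' population point `x_q`, the new raw weight is the product of the cavity
#' fields of all *other* metabolites the reaction processes, each estimated
#' with `draws_per_point(t)` draws; weights are then normalized to sum to 1,
#' and combined with the old ones when damping is on. An empty product (a
#' reaction touching a single metabolite) gives uniform weights.
#'
#' @param messages a `wbp_messages` object.
#' @param rxn,met the directed edge to update (index or id).
#' @param t iteration index (drives the draw schedule).
#' @param config a [wbp_config()].
#' @return list: `weights` (the new normalized weight vector),
#'   `n_var_draws`.
#' @export
update_message <- function(messages, rxn, met, t, config = wbp_config()) {
  net <- messages$net
  if (is.character(rxn)) rxn <- rxn_index(net, rxn)
  if (is.character(met)) met <- met_index(net, met)
  nd <- config$draws_per_point(t)
  xg <- messages$grids[, rxn]
  alpha <- rep(1, messages$Q)
  nvd <- 0
  for (nu in setdiff(messages$edges$rxn_adj[[rxn]], met)) {
    L <- estimate_L(messages, nu, rxn, xg, nd)
    nvd <- nvd + attr(L, "n_var_draws")
    alpha <- alpha * as.numeric(L)
  }
  s <- sum(alpha)
  if (!is.finite(s) || s <= 0)
    stop("starved message: all weights vanished on edge (",
         net$reactions$id[rxn], " -> ", net$metabolites$id[met], ")")
  alpha <- alpha / s
  e <- edge_id(messages$edges, rxn, met)
  if (config$damping > 0)
    alpha <- (1 - config$damping) * alpha +
      config$damping * messages$weights[, e]
  list(weights = alpha, n_var_draws = nvd)
}

#' One full sweep of the cavity equations
#'
#' Updates every directed message once, sequentially, in the fixed edge-index
#' order (so that runs with the same seed are reproducible), each update
#' seeing the messages refreshed before it.
#'
#' @param messages a `wbp_messages` object.
#' @param t iteration index.
#' @param config a [wbp_config()].
#' @return list: `messages` (updated), `max_change` (maximal L1 distance
#'   between old and new weight vectors over edges), `n_var_draws`.
#' @export
wbp_sweep <- function(messages, t, config = wbp_config()) {
  max_change <- 0
  nvd <- 0
  for (e in seq_len(messages$edges$n_edges)) {
    rxn <- messages$edges$edges$rxn[e]
    met <- messages$edges$edges$met[e]
    up <- update_message(messages, rxn, met, t, config)
    nvd <- nvd + up$n_var_draws
    max_change <- max(max_change, sum(abs(messages$weights[, e] - up$weights)))
    messages$weights[, e] <- up$weights
  }
  list(messages = messages, max_change = max_change, n_var_draws = nvd)
}

#' Run weighted Belief Propagation on a network
#'
#' Full pipeline: initialize uniform messages, iterate population-dynamics
#' sweeps of the cavity equations, then assemble the final marginals: the
#' density of flux i at grid point `x_q` is the product over all metabolites
#' the reaction processes of their cavity fields, estimated with
#' `final_draws` draws per point, normalized to integrate to 1 on the grid.
#' For every exchanged metabolite with a window prior, the posterior density
#' of its exchange rate is assembled the same way on a grid over the window
#' (fixed-rate priors give point masses).
#'
#' @param net a valid `metabolic_network`.
#' @param config a [wbp_config()].
#' @return object of class `wbp_result`: `marginals` (named list of
#'   [marginal_estimate()], fluxes then exchange rates), `trace` (max L1
#'   change per sweep), `n_var_draws` (elementary draw counter), `config`.
#' @export
run_wbp <- function(net, config = wbp_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  bad <- validate_network(net)
  if (length(bad) > 0) stop("invalid network: ", bad[1])
  messages <- init_messages(net, config)
  trace <- numeric(0)
  nvd <- 0
  for (t in seq_len(config$iterations)) {
    sw <- wbp_sweep(messages, t, config)
    messages <- sw$messages
    nvd <- nvd + sw$n_var_draws
    trace <- c(trace, sw$max_change)
    if (config$early_stop_tol > 0 && sw$max_change < config$early_stop_tol)
      break
  }
  N <- nrow(net$reactions)
  marg <- list()
  for (i in seq_len(N)) {
    lb <- net$reactions$lb[i]; ub <- net$reactions$ub[i]
    id <- net$reactions$id[i]
    if (ub - lb <= 1e-12 * max(1, abs(lb), abs(ub))) {
      marg[[id]] <- marginal_estimate(id, "flux", point_mass = TRUE,
                                      value = lb)
      next
    }
    xg <- messages$grids[, i]
    dens <- rep(1, messages$Q)
    for (nu in messages$edges$rxn_adj[[i]]) {
      L <- estimate_L(messages, nu, i, xg, config$final_draws)
      nvd <- nvd + attr(L, "n_var_draws")
      dens <- dens * as.numeric(L)
    }
    if (any(!is.finite(dens)))
      stop("non-finite density for flux ", id)
    if (sum(dens) <= 0)
      stop("starved message: zero density everywhere for flux ", id)
    marg[[id]] <- marginal_estimate(id, "flux", grid = xg, density = dens)
  }
  for (m in which(net$metabolites$kind != "internal")) {
    id <- net$metabolites$id[m]
    if (net$metabolites$kind[m] == "fixed") {
      marg[[id]] <- marginal_estimate(id, "exchange", point_mass = TRUE,
                                      value = net$metabolites$p1[m])
      next
    }
    gl <- net$metabolites$p1[m]; gu <- net$metabolites$p2[m]
    gg <- seq(gl, gu, length.out = messages$Q)
    adj <- messages$edges$met_adj[[m]]
    pops <- lapply(seq_along(adj$rxn), function(j) {
      r <- adj$rxn[j]
      list(values = messages$grids[, r],
           weights = messages$weights[, edge_id(messages$edges, r, m)],
           lo = net$reactions$lb[r], hi = net$reactions$ub[r])
    })
    # posterior of gamma: probability that the balance row hits gamma exactly,
    # times the (uniform, hence constant) prior over the window
    res <- cpp_estimate_L_grid(gg, -1, c(0, 0), adj$coeff, pops,
                               config$final_draws, messages$bins)
    nvd <- nvd + res$n_var_draws
    if (sum(res$means) <= 0)
      stop("starved message: zero posterior for exchange rate of ", id)
    marg[[id]] <- marginal_estimate(id, "exchange", grid = gg,
                                    density = res$means)
  }
  structure(list(marginals = marg, trace = trace, n_var_draws = nvd,
                 config = config),
            class = "wbp_result")
}

#' @export
print.wbp_result <- function(x, ...) {
  cat(sprintf(
    "<wbp_result> %d marginals, %d sweeps (last max change %.3g), %.3g elementary draws\n",
    length(x$marginals), length(x$trace), utils::tail(x$trace, 1),
    x$n_var_draws))
  invisible(x)
}
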