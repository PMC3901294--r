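#' Orthonormal null-space basis of the internal stoichiometry
#'
#' Computes, by singular value decomposition, an orthonormal basis Phi of the
#' null space of the internal stoichiometric matrix: the steady-state
#' constraints S_int x = 0 confine the flux vector to a K-dimensional linear
#' subspace with K = N - rank(S_int), and every feasible flux vector can be
#' written x = Phi y in the reduced coordinates y.
#'
#' @param S_int internal stoichiometric matrix (rows = internal metabolites);
#'   dense or sparse.
#' @param tol_rel singular values below `tol_rel * max(singular value)` are
#'   treated as zero when determining the rank.
#' @return object of class `null_space_model`: `basis` (N x K, orthonormal
#'   columns), `K`, `rank`, `tol_rel`. `K = 0` signals a point polytope.
#' @export
null_space_basis <- function(S_int, tol_rel = 1e-10) {
  S <- as.matrix(S_int)
  N <- ncol(S)
  if (nrow(S) == 0 || all(S == 0)) {
    return(structure(list(basis = diag(N), K = N, rank = 0L,
                          tol_rel = tol_rel), class = "null_space_model"))
  }
  sv <- svd(S, nu = 0, nv = N)
  rank <- sum(sv$d > tol_rel * sv$d[1])
  K <- N - rank
  basis <- if (K > 0) sv$v[, seq(rank + 1, N), drop = FALSE]
           else matrix(0, N, 0)
  structure(list(basis = basis, K = as.integer(K), rank = as.integer(rank),
                 tol_rel = tol_rel), class = "null_space_model")
}

#' Project all box and exchange constraints into null-space coordinates
#'
#' Builds the K-dimensional polytope `{y : lo <= Psi y <= hi}` that the
#' Hit-and-Run chain samples. All *equality* constraints -- internal mass
#' balances, fixed-rate exchanges (`sum_i xi_imu x_i = z0`) and fluxes pinned
#' by `lb == ub` -- are folded into an affine system `A x = b` solved by a
#' minimum-norm particular solution `x_p` plus an orthonormal null-space
#' basis `Phi`, so the polytope stays full-dimensional in `y`. The inequality
#' rows are then one row `Phi[i, ]` per unpinned flux with bounds
#' `[m_i - x_p[i], M_i - x_p[i]]`, and one row `xi_mu %*% Phi` per
#' window-prior metabolite with its window similarly shifted.
#'
#' Boundedness is certified by checking that the rows with two finite bounds
#' have full column rank K (a sufficient condition: the polytope is then
#' contained in an affine image of a box). Since flux bounds are always
#' finite and the unpinned rows of `Phi` have rank K, this certificate holds
#' for every valid network.
#'
#' @param net a valid `metabolic_network`.
#' @param nsm optional precomputed [null_space_basis()] of
#'   [internal_submatrix()]; only used when the network has no fixed-rate
#'   exchanges and no pinned fluxes (otherwise the augmented system is
#'   rebuilt).
#' @param tol_rel rank tolerance passed to the SVD steps.
#' @return object of class `projected_polytope`: `Phi` (N x K), `x_p`
#'   (particular solution, length N), `Psi`, `lo`, `hi` (constraint rows),
#'   `row_id` (reaction/metabolite id per row), `K`, `net`.
#' @export
project_constraints <- function(net, nsm = NULL, tol_rel = 1e-10) {
  N <- nrow(net$reactions)
  S <- as.matrix(stoichiometric_matrix(net))
  kinds <- net$metabolites$kind
  pinned <- which(net$reactions$ub - net$reactions$lb <=
                    1e-12 * pmax(1, abs(net$reactions$lb),
                                 abs(net$reactions$ub)))
  A <- S[kinds == "internal", , drop = FALSE]
  b <- rep(0, nrow(A))
  fx <- which(kinds == "fixed")
  if (length(fx) > 0) {
    A <- rbind(A, S[fx, , drop = FALSE])
    b <- c(b, net$metabolites$p1[fx])
  }
  if (length(pinned) > 0) {
    E <- matrix(0, length(pinned), N)
    E[cbind(seq_along(pinned), pinned)] <- 1
    A <- rbind(A, E)
    b <- c(b, net$reactions$lb[pinned])
  }
  scale <- max(1, abs(A), abs(b))
  if (length(fx) == 0 && length(pinned) == 0 && !is.null(nsm)) {
    Phi <- nsm$basis; K <- nsm$K
    x_p <- rep(0, N)
  } else if (nrow(A) == 0) {
    Phi <- diag(N); K <- N; x_p <- rep(0, N)
  } else {
    sv <- svd(A)
    rank <- sum(sv$d > tol_rel * sv$d[1])
    K <- N - rank
    dinv <- ifelse(seq_along(sv$d) <= rank, 1 / sv$d, 0)
    x_p <- as.numeric(sv$v %*% (dinv * (t(sv$u) %*% b)))
    if (max(abs(A %*% x_p - b)) > 1e-8 * scale)
      stop("infeasible equality system: the internal/fixed/pinned ",
           "constraints have no solution")
    Phi <- if (K > 0) {
      svf <- svd(A, nu = 0, nv = N)
      svf$v[, seq(rank + 1, N), drop = FALSE]
    } else matrix(0, N, 0)
  }
  unpinned <- setdiff(seq_len(N), pinned)
  Psi <- Phi[unpinned, , drop = FALSE]
  lo <- net$reactions$lb[unpinned] - x_p[unpinned]
  hi <- net$reactions$ub[unpinned] - x_p[unpinned]
  row_id <- net$reactions$id[unpinned]
  un <- which(kinds == "uniform")
  if (length(un) > 0) {
    Pu <- S[un, , drop = FALSE] %*% Phi
    Psi <- rbind(Psi, Pu)
    off <- as.numeric(S[un, , drop = FALSE] %*% x_p)
    lo <- c(lo, net$metabolites$p1[un] - off)
    hi <- c(hi, net$metabolites$p2[un] - off)
    row_id <- c(row_id, net$metabolites$id[un])
  }
  # rows whose projected normal vanishes constrain nothing in y; they are
  # feasibility conditions on x_p alone
  nrm <- sqrt(rowSums(Psi^2))
  zero <- nrm < 1e-12
  if (any(zero)) {
    viol <- lo[zero] > 1e-9 * scale | hi[zero] < -1e-9 * scale
    if (any(viol))
      stop("infeasible polytope: constraint on ",
           paste(row_id[zero][viol], collapse = ", "),
           " cannot be met")
    Psi <- Psi[!zero, , drop = FALSE]
    lo <- lo[!zero]; hi <- hi[!zero]; row_id <- row_id[!zero]
  }
  if (K > 0) {
    finite <- is.finite(lo) & is.finite(hi)
    rk <- if (any(finite)) qr(Psi[finite, , drop = FALSE])$rank else 0L
    if (rk < K) {
      dir <- if (any(finite)) {
        ns <- null_space_basis(Psi[finite, , drop = FALSE])
        round(ns$basis[, 1], 6)
      } else rep(NA_real_, K)
      stop("unbounded polytope: direction (", paste(dir, collapse = ", "),
           ") in null-space coordinates is not constrained by any ",
           "finitely-bounded row")
    }
  }
  structure(list(Phi = Phi, x_p = x_p, Psi = Psi, lo = lo, hi = hi,
                 row_id = row_id, K = as.integer(K), net = net),
            class = "projected_polytope")
}

#' @export
print.projected_polytope <- function(x, ...) {
  cat(sprintf("<projected_polytope> K = %d, %d constraint rows\n",
              x$K, nrow(x$Psi)))
  invisible(x)
}

poly_scale <- function(poly) {
  f <- c(poly$lo, poly$hi)
  max(1, abs(f[is.finite(f)]))
}

poly_slacks <- function(poly, y) {
  a <- as.numeric(poly$Psi %*% y)
  nrm <- sqrt(rowSums(poly$Psi^2))
  pmin(a - poly$lo, poly$hi - a) / nrm
}

#' Find a strictly interior point of a projected polytope
#'
#' `method = "minover"` uses a perceptron-style relaxation: repeatedly step
#' from the current point along the inward unit normal of the
#' smallest-slack row, with step size `eta_t = eta0 / (1 + t / 1000)`
#' (`eta0` = polytope scale); once feasible, 100 extra centering steps of the
#' same form push the point further inside. `method = "chebyshev"` maximizes
#' the minimum normalized slack (a concave piecewise-linear function whose
#' maximizer is the Chebyshev center) by subgradient ascent.
#'
#' @param poly a [project_constraints()] polytope.
#' @param method `"minover"` or `"chebyshev"`.
#' @param max_iter iteration budget.
#' @param y0 optional starting point (defaults to the origin).
#' @return a strictly feasible `y` (all normalized slacks positive); errors
#'   with the best slack attained if the budget is exhausted, which signals
#'   an infeasible (or lower-dimensional) polytope.
#' @export
find_interior_point <- function(poly, method = c("minover", "chebyshev"),
                                max_iter = 20000, y0 = NULL) {
  method <- match.arg(method)
  K <- poly$K
  if (K == 0) return(numeric(0))
  scale <- poly_scale(poly)
  eps <- 1e-9 * scale
  nrm <- sqrt(rowSums(poly$Psi^2))
  y <- if (is.null(y0)) rep(0, K) else as.numeric(y0)
  eta0 <- scale
  tau <- 1000
  # per-row target slack: a fraction of each slab's own width, so rows whose
  # bounds live on very different scales are all honored
  width <- (poly$hi - poly$lo) / nrm
  margin <- 0.3 * pmin(width, scale)
  best <- -Inf; ybest <- y
  feasible_at <- NA_integer_
  t <- 0
  while (t < max_iter) {
    t <- t + 1
    a <- as.numeric(poly$Psi %*% y)
    sl <- pmin(a - poly$lo, poly$hi - a) / nrm
    j <- which.min(sl / margin)
    if (min(sl) > best) { best <- min(sl); ybest <- y }
    decay <- 1 / (1 + t / tau)
    if (sl[j] >= margin[j] * decay) break  # comfortably interior
    if (method == "minover" && !is.na(feasible_at) && t - feasible_at > 100)
      break  # feasibility reached earlier; centering budget spent
    if (min(sl) > eps && is.na(feasible_at)) feasible_at <- t
    # step toward the worst row's inward normal: the schedule eta_t capped by
    # a slightly overrelaxed move to that row's margin
    inward <- if (a[j] - poly$lo[j] <= poly$hi[j] - a[j]) 1 else -1
    d <- min(eta0 * decay, 1.1 * (margin[j] * decay - sl[j]))
    y <- y + d * inward * poly$Psi[j, ] / nrm[j]
  }
  sl <- poly_slacks(poly, ybest)
  if (min(sl) <= eps)
    stop(sprintf(
      "could not find a strictly interior point (best slack %.3g after %d iterations); polytope may be infeasible or lower-dimensional",
      min(sl), t))
  ybest
}

#' One Hit-and-Run step
#'
#' From a strictly feasible point, draws an isotropic direction (normalized
#' standard normal vector), computes the feasible chord through the polytope
#' along it, and returns a uniform point on that chord.
#'
#' @param poly a [project_constraints()] polytope.
#' @param y current strictly feasible point.
#' @return the next point `y'` (always feasible).
#' @export
hit_and_run_step <- function(poly, y) {
  res <- cpp_hit_and_run(poly$Psi, poly$lo, poly$hi, as.numeric(y),
                         1L, 0L, 1L)
  as.numeric(res$samples[1, ])
}

#' Chain configuration for the KHR sampler
#'
#' @param n_samples total number of recorded flux samples (split across
#'   chains).
#' @param burn_in steps discarded at the start of each chain.
#' @param thin record every `thin`-th step; `NULL` means `10 * K`, chosen at
#'   run time.
#' @param n_chains independent chains, each from its own interior starting
#'   point; averaging over initial conditions guards against an unconverged
#'   chain.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param init interior-point method, `"minover"` or `"chebyshev"`.
#' @return object of class `khr_config`.
#' @export
khr_config <- function(n_samples = 1e5, burn_in = 1e4, thin = NULL,
                       n_chains = 3, seed = NULL,
                       init = c("minover", "chebyshev")) {
  init <- match.arg(init)
  stopifnot(n_samples >= 1, burn_in >= 0, n_chains >= 1,
            is.null(thin) || thin >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), thin = thin,
                 n_chains = as.integer(n_chains), seed = seed, init = init),
            class = "khr_config")
}

#' Uniformly sample the flux polytope by Kernel Hit-and-Run
#'
#' Full pipeline: compute the null-space reduction
#' ([project_constraints()]), find one strictly interior point per chain
#' (each chain's search starts from its own random point, so the chains have
#' distinct initial conditions), run the Hit-and-Run chain in the reduced
#' coordinates with burn-in and thinning, and lift the recorded states back
#' to flux space via `x = x_p + Phi y`. Uniformity in `y` is preserved by
#' the linear lift, so the flux-space sample is uniform on the polytope by
#' construction. Every returned sample is checked against the internal mass
#' balances (to `1e-8` relative) and all box/exchange windows (`1e-9`
#' relative).
#'
#' @param net a valid `metabolic_network`.
#' @param config a [khr_config()].
#' @return object of class `khr_samples`: `X` (`n_samples x N` flux matrix,
#'   columns named by reaction id), `chain`, `step` (provenance vectors),
#'   `gamma` (matrix of exchange rates for window-prior metabolites, possibly
#'   0 columns), `poly`, `max_balance_violation`, `max_bound_violation`.
#' @export
khr_sample <- function(net, config = khr_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  bad <- validate_network(net)
  if (length(bad) > 0) stop("invalid network: ", bad[1])
  poly <- project_constraints(net)
  N <- nrow(net$reactions)
  if (poly$K == 0) {
    warning("point polytope (K = 0): returning the unique solution once")
    X <- matrix(poly$x_p, 1, N, dimnames = list(NULL, net$reactions$id))
    return(structure(list(X = X, chain = 1L, step = 0L,
                          gamma = gamma_of(net, X), poly = poly,
                          max_balance_violation = 0,
                          max_bound_violation = 0),
                     class = "khr_samples"))
  }
  thin <- if (is.null(config$thin)) 10L * poly$K else as.integer(config$thin)
  per_chain <- ceiling(config$n_samples / config$n_chains)
  scale <- poly_scale(poly)
  Xs <- list(); chains <- list(); steps <- list()
  for (ch in seq_len(config$n_chains)) {
    y0 <- find_interior_point(poly, method = config$init,
                              y0 = stats::rnorm(poly$K, sd = 0.1 * scale))
    res <- cpp_hit_and_run(poly$Psi, poly$lo, poly$hi, y0,
                           as.integer(per_chain), config$burn_in, thin)
    Y <- res$samples
    Xs[[ch]] <- sweep_add(Y %*% t(poly$Phi), poly$x_p)
    chains[[ch]] <- rep(ch, nrow(Y))
    steps[[ch]] <- config$burn_in + thin * seq_len(nrow(Y))
  }
  X <- do.call(rbind, Xs)[seq_len(config$n_samples), , drop = FALSE]
  colnames(X) <- net$reactions$id
  chain <- do.call(c, chains)[seq_len(config$n_samples)]
  step <- do.call(c, steps)[seq_len(config$n_samples)]
  S_int <- as.matrix(internal_submatrix(net))
  bal <- if (nrow(S_int) > 0) max(abs(S_int %*% t(X))) else 0
  s_scale <- max(1, abs(S_int)) * max(1, abs(X))
  if (bal > 1e-8 * s_scale)
    stop("internal mass balance violated by a sample: max residual ", bal)
  lb <- net$reactions$lb; ub <- net$reactions$ub
  bscale <- max(1, abs(lb), abs(ub))
  bnd <- max(0, max(t(lb - t(X))), max(t(t(X) - ub)))
  if (bnd > 1e-9 * bscale)
    stop("flux bounds violated by a sample: max excess ", bnd)
  G <- gamma_of(net, X)
  if (ncol(G) > 0) {
    un <- which(net$metabolites$kind == "uniform")
    gex <- max(0, max(t(net$metabolites$p1[un] - t(G))),
               max(t(t(G) - net$metabolites$p2[un])))
    if (gex > 1e-9 * max(1, abs(net$metabolites$p1[un]),
                         abs(net$metabolites$p2[un])))
      stop("exchange window violated by a sample: max excess ", gex)
  }
  structure(list(X = X, chain = chain, step = step, gamma = G, poly = poly,
                 max_balance_violation = bal, max_bound_violation = bnd),
            class = "khr_samples")
}

# exchange rates implied by flux samples, for window-prior metabolites
gamma_of <- function(net, X) {
  un <- which(net$metabolites$kind == "uniform")
  S <- as.matrix(stoichiometric_matrix(net))
  G <- X %*% t(S[un, , drop = FALSE])
  colnames(G) <- net$metabolites$id[un]
  G
}

sweep_add <- function(M, v) t(t(M) + v)

#' @export
print.khr_samples <- function(x, ...) {
  cat(sprintf(
    "<khr_samples> %d samples of %d fluxes, K = %d, %d chain(s), max balance residual %.2g\n",
    nrow(x$X), ncol(x$X), x$poly$K, length(unique(x$chain)),
    x$max_balance_violation))
  invisible(x)
}

#' Histogram marginal estimates from polytope samples
#'
#' Per-flux (and, when present, per-exchange-rate) normalized histogram
#' densities on the variable's declared support. Variables whose samples are
#' all (numerically) identical give point masses.
#'
#' @param samples a [khr_sample()] result, or a numeric sample matrix with
#'   named columns.
#' @param bins number of histogram bins.
#' @param net required when `samples` is a bare matrix: the network supplying
#'   declared supports.
#' @return named list of [marginal_estimate()].
#' @export
marginals_from_samples <- function(samples, bins = 50, net = NULL) {
  if (inherits(samples, "khr_samples")) {
    net <- samples$poly$net
    X <- samples$X
    G <- samples$gamma
  } else {
    X <- as.matrix(samples)
    G <- NULL
    if (is.null(net)) stop("`net` is required for a bare sample matrix")
  }
  if (nrow(X) < 2) stop("need at least 2 samples")
  out <- list()
  hist_marginal <- function(id, kind, v, lo, hi) {
    if (hi - lo <= 1e-12 * max(1, abs(lo), abs(hi)) ||
        max(v) - min(v) <= 1e-12 * max(1, abs(lo), abs(hi)))
      return(marginal_estimate(id, kind, point_mass = TRUE, value = mean(v)))
    br <- seq(lo, hi, length.out = bins + 1)
    v <- pmin(pmax(v, lo), hi)
    h <- graphics::hist(v, breaks = br, plot = FALSE)
    marginal_estimate(id, kind, grid = h$mids, density = h$density)
  }
  for (i in seq_len(ncol(X)))
    out[[colnames(X)[i]]] <- hist_marginal(
      colnames(X)[i], "flux", X[, i],
      net$reactions$lb[i], net$reactions$ub[i])
  if (!is.null(G) && ncol(G) > 0) {
    un <- which(net$metabolites$kind == "uniform")
    for (j in seq_len(ncol(G)))
      out[[colnames(G)[j]]] <- hist_marginal(
        colnames(G)[j], "exchange", G[, j],
        net$metabolites$p1[un[j]], net$metabolites$p2[un[j]])
  }
  out
}
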