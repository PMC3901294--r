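#' Weighted population representation of a density
#'
#' A density on a bounded support represented by `Q` support points ("atoms")
#' with nonnegative weights. This replaces binned discretization throughout
#' the package: the atoms stay fixed while the weights evolve, which makes the
#' representation insensitive to fluxes spanning different orders of
#' magnitude.
#'
#' @param values numeric vector of atoms, all within `[lo, hi]`; stored
#'   sorted ascending.
#' @param weights nonnegative finite weights, at least one strictly positive;
#'   defaults to equal weights.
#' @param lo,hi support bounds; default to the range of `values`.
#' @return object of class `weighted_population` with fields `values`,
#'   `weights`, `lo`, `hi`.
#' @export
weighted_population <- function(values, weights = NULL, lo = NULL, hi = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1) stop("population needs at least one value")
  if (is.null(weights)) weights <- rep(1 / length(values), length(values))
  weights <- as.numeric(weights)
  if (length(weights) != length(values))
    stop("values and weights must have equal length")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and nonnegative")
  if (sum(weights) <= 0) stop("at least one weight must be positive")
  if (is.null(lo)) lo <- min(values)
  if (is.null(hi)) hi <- max(values)
  if (any(values < lo - 1e-12 * max(1, abs(lo))) ||
      any(values > hi + 1e-12 * max(1, abs(hi))))
    stop("all values must lie within [lo, hi]")
  o <- order(values)
  structure(list(values = values[o], weights = weights[o],
                 lo = as.numeric(lo), hi = as.numeric(hi)),
            class = "weighted_population")
}

# equispaced equal-weight population on [lo, hi] (endpoints included)
uniform_population <- function(Q, lo, hi) {
  if (hi - lo <= 1e-12 * max(1, abs(lo), abs(hi)))
    return(weighted_population(lo, 1, lo = lo, hi = lo))
  weighted_population(seq(lo, hi, length.out = Q), rep(1 / Q, Q),
                      lo = lo, hi = hi)
}

#' One linear constraint over a set of variables
#'
#' Represents `sum_l coeff_l x_l = c` (equality `target` of length 1) or
#' `c_lo <= sum_l coeff_l x_l <= c_hi` (interval `target` of length 2).
#' An interval target realizes a mass-balance row whose exchange rate is only
#' known to lie in a window.
#'
#' @param coeffs nonzero signed coefficients, one per variable.
#' @param target length-1 (equality) or length-2 nondecreasing (interval).
#' @return object of class `linear_constraint`.
#' @export
linear_constraint <- function(coeffs, target) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) < 1) stop("constraint needs at least one variable")
  if (any(!is.finite(coeffs)) || any(coeffs == 0))
    stop("coefficients must be finite and nonzero")
  target <- as.numeric(target)
  if (!length(target) %in% c(1, 2) || any(!is.finite(target)))
    stop("target must be a finite value or interval")
  if (length(target) == 2 && target[1] > target[2])
    stop("interval target must have c_lo <= c_hi")
  structure(list(coeffs = coeffs, target = target),
            class = "linear_constraint")
}

#' Exact range of a linear form over a box
#'
#' Interval arithmetic for `sum_l coeff_l x_l` when each `x_l` ranges over its
#' support `[lo_l, hi_l]`: the achievable range is
#' `[sum_l min(c_l lo_l, c_l hi_l), sum_l max(c_l lo_l, c_l hi_l)]`.
#' The empty sum yields `[0, 0]`.
#'
#' @param coeffs signed coefficients (may be empty).
#' @param supports list of length-2 vectors, or a 2-column matrix, of
#'   per-variable supports.
#' @return length-2 numeric `c(lo, hi)`.
#' @export
achievable_range <- function(coeffs, supports) {
  if (length(coeffs) == 0) return(c(0, 0))
  if (is.list(supports)) supports <- do.call(rbind, supports)
  supports <- matrix(as.numeric(supports), ncol = 2)
  a <- coeffs * supports[, 1]
  b <- coeffs * supports[, 2]
  c(sum(pmin(a, b)), sum(pmax(a, b)))
}

#' Feasible window for the next variable under a linear constraint
#'
#' Given the still-required residual (a value for equality targets, an
#' interval otherwise), the next variable's coefficient and support, and the
#' achievable range of every variable not yet sampled (including a solved
#' variable, if any), returns the closed interval of values `v` of the next
#' variable for which the constraint remains satisfiable, i.e. for which
#' `residual - coeff * v` intersects `remaining_range`. Linearity guarantees
#' the set is an interval. An empty window is a value (`NULL`), not an error:
#' it is exactly the event that gives a weight-0 draw.
#'
#' @param residual length-1 (equality) or length-2 (interval) numeric.
#' @param coeff nonzero coefficient of the next variable.
#' @param support length-2 support of the next variable.
#' @param remaining_range achievable range ([achievable_range()]) of the
#'   not-yet-sampled variables; `c(0, 0)` when none remain.
#' @return length-2 numeric window, or `NULL` if empty.
#' @export
feasible_window <- function(residual, coeff, support, remaining_range) {
  rlo <- residual[1]; rhi <- residual[length(residual)]
  # coeff * v must lie in [rlo - rem_hi, rhi - rem_lo]
  alo <- rlo - remaining_range[2]
  ahi <- rhi - remaining_range[1]
  w <- sort(c(alo, ahi) / coeff)
  wlo <- max(w[1], support[1]); whi <- min(w[2], support[2])
  tol <- 1e-12 * max(1, abs(wlo), abs(whi))
  if (whi - wlo < -tol) return(NULL)
  c(wlo, max(whi, wlo))
}

#' Draw one value from a weighted population restricted to a window
#'
#' Samples an atom of the population lying inside `window` with probability
#' proportional to its weight, and returns the *window weight*: the fraction
#' of total population weight inside the window. This is the discrete
#' analogue of the reweighting factor `w(y)` (the integral of a density over
#' its truncated support) that makes the scheme rejection-free.
#'
#' @param pop a [weighted_population()].
#' @param window length-2 numeric interval, or `NULL` (empty).
#' @return list with `value` (numeric, or `NA` if the window is empty or
#'   holds no atom) and `window_weight` (0 in that case).
#' @export
truncated_weighted_draw <- function(pop, window) {
  if (is.null(window))
    return(list(value = NA_real_, window_weight = 0))
  tol <- 1e-12 * max(1, abs(window[1]), abs(window[2]))
  inside <- pop$values >= window[1] - tol & pop$values <= window[2] + tol
  mass <- sum(pop$weights[inside])
  if (mass <= 0) return(list(value = NA_real_, window_weight = 0))
  idx <- which(inside)
  j <- idx[sample.int(length(idx), 1, prob = pop$weights[idx])]
  list(value = pop$values[j], window_weight = mass / sum(pop$weights))
}

#' Rejection-free weighted joint draws under one linear constraint
#'
#' Draws `n` joint configurations of the variables of `constraint`, each
#' variable sampled from its weighted population truncated to the dynamically
#' feasible window, so that no draw is ever rejected; every draw instead
#' carries an importance weight.
#'
#' For an **equality** target one variable is solved for
#' (`x_k = (c - sum_{l != k} coeff_l x_l) / coeff_k`) rather than sampled; its
#' contribution to the weight is its population density at the solved value
#' (piecewise-constant histogram with `bins` bins) divided by `|coeff_k|`
#' (the Jacobian of the delta constraint). In `solved = "auto"` mode the
#' solved variable is the one with the widest feasible window, ties broken by
#' largest `|coeff|` then declaration order. For an **interval** target all
#' variables are sampled and the weight is the product of window weights.
#'
#' A weight of 0 signals that some feasible window was empty (or contained no
#' population atom); it is a valid outcome, never an error.
#'
#' @param constraint a [linear_constraint()].
#' @param pops list of [weighted_population()], one per variable.
#' @param n number of draws.
#' @param solved `"auto"`, or the index of the variable to solve for
#'   (equality targets only).
#' @param bins histogram bins for the solved variable's density evaluation.
#' @return list of class `weighted_draws`: `values` (`n x V` matrix),
#'   `weights` (length `n`), `solved` (index used, 0 for interval targets),
#'   `n_zero_weight`, `n_var_draws` (elementary draw counter).
#' @export
constrained_joint_sample <- function(constraint, pops, n = 1,
                                     solved = "auto", bins = 50) {
  stopifnot(inherits(constraint, "linear_constraint"),
            length(pops) == length(constraint$coeffs))
  pl <- lapply(pops, function(p)
    list(values = p$values, weights = p$weights, lo = p$lo, hi = p$hi))
  s <- if (identical(solved, "auto")) 0L else as.integer(solved)
  res <- cpp_joint_draws(pl, constraint$coeffs,
                         range(constraint$target), as.integer(n), s,
                         as.integer(bins))
  res$values <- matrix(res$values, nrow = n)
  class(res) <- "weighted_draws"
  res
}
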