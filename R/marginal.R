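#' Marginal density estimate of one flux or exchange rate
#'
#' A normalized density on a grid over the variable's support. Construction
#' renormalizes so that the trapezoid-rule integral over the grid equals 1;
#' degenerate variables (support of zero width, e.g. a flux pinned by
#' `lb == ub`) are represented as point masses instead.
#'
#' @param id variable id (reaction id, or metabolite id for an exchange rate).
#' @param kind `"flux"` or `"exchange"`.
#' @param grid increasing numeric vector of support points.
#' @param density nonnegative weights on the grid (any positive scale; they
#'   are renormalized).
#' @param point_mass logical; if `TRUE` the marginal is a Dirac mass at
#'   `value` and `grid`/`density` are ignored.
#' @param value location of the point mass.
#' @return object of class `marginal_estimate` with fields `id`, `kind`,
#'   `grid`, `density`, `normalization` (the constant divided out),
#'   `point_mass`, `value`.
#' @export
marginal_estimate <- function(id, kind = c("flux", "exchange"),
                              grid = NULL, density = NULL,
                              point_mass = FALSE, value = NA_real_) {
  kind <- match.arg(kind)
  if (point_mass) {
    return(structure(list(id = as.character(id), kind = kind, grid = value,
                          density = Inf, normalization = 1,
                          point_mass = TRUE, value = value),
                     class = "marginal_estimate"))
  }
  stopifnot(length(grid) == length(density), length(grid) >= 2,
            !is.unsorted(grid))
  if (any(!is.finite(density)) || any(density < 0))
    stop("marginal ", id, ": density must be finite and nonnegative")
  Z <- trapz(grid, density)
  if (Z <= 0) stop("marginal ", id, ": density integrates to zero")
  structure(list(id = as.character(id), kind = kind, grid = as.numeric(grid),
                 density = as.numeric(density) / Z, normalization = Z,
                 point_mass = FALSE, value = NA_real_),
            class = "marginal_estimate")
}

#' @export
print.marginal_estimate <- function(x, ...) {
  if (x$point_mass)
    cat(sprintf("<marginal_estimate> %s (%s): point mass at %.6g\n",
                x$id, x$kind, x$value))
  else
    cat(sprintf(
      "<marginal_estimate> %s (%s): %d grid points on [%.6g, %.6g], mean %.6g\n",
      x$id, x$kind, length(x$grid), min(x$grid), max(x$grid),
      trapz(x$grid, x$grid * x$density)))
  invisible(x)
}

#' Mean of a marginal estimate
#' @param x a `marginal_estimate`.
#' @param ... ignored.
#' @return the trapezoid-rule mean of the density.
#' @export
mean.marginal_estimate <- function(x, ...) {
  if (x$point_mass) return(x$value)
  trapz(x$grid, x$grid * x$density)
}

# trapezoid-rule integral; grid need not be uniform
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
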