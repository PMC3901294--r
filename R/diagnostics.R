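#' Total-variation distance between two marginal estimates
#'
#' `TV = 0.5 * integral |p - q|` over the union of the supports, evaluated by
#' the trapezoid rule on the merged grid (each density linearly interpolated
#' on its own grid, 0 outside its own support). Two point masses compare to
#' 0 (same location) or 1; a point mass against a continuous density is 1.
#' Disjoint supports return 1 with a warning.
#'
#' @param p,q [marginal_estimate()] objects.
#' @return a number in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  pm <- point_mass_tv(p, q)
  if (!is.null(pm)) return(pm)
  if (min(max(p$grid), max(q$grid)) <= max(min(p$grid), min(q$grid))) {
    warning("disjoint supports: total variation is 1")
    return(1)
  }
  g <- sort(unique(c(p$grid, q$grid)))
  dp <- interp_density(p, g)
  dq <- interp_density(q, g)
  min(1, max(0, trapz(g, abs(dp - dq)) / 2))
}

#' Kolmogorov-Smirnov distance between two marginal estimates
#'
#' Maximal absolute difference of the two cumulative distribution functions,
#' built by cumulative trapezoid integration on the merged grid. Point
#' masses are handled as step functions.
#'
#' @param p,q [marginal_estimate()] objects.
#' @return a number in `[0, 1]`.
#' @export
ks_distance <- function(p, q) {
  if (p$point_mass && q$point_mass)
    return(as.numeric(abs(p$value - q$value) >
                        1e-9 * max(1, abs(p$value), abs(q$value))))
  if (p$point_mass || q$point_mass) {
    pt <- if (p$point_mass) p else q
    ct <- if (p$point_mass) q else p
    Fc <- cdf_at(ct, pt$value)
    return(min(1, max(Fc, 1 - Fc)))
  }
  g <- sort(unique(c(p$grid, q$grid)))
  Fp <- cum_cdf(p, g)
  Fq <- cum_cdf(q, g)
  min(1, max(abs(Fp - Fq)))
}

point_mass_tv <- function(p, q) {
  if (p$point_mass && q$point_mass)
    return(as.numeric(abs(p$value - q$value) >
                        1e-9 * max(1, abs(p$value), abs(q$value))))
  if (p$point_mass || q$point_mass) return(1)
  NULL
}

interp_density <- function(m, g) {
  d <- suppressWarnings(
    stats::approx(m$grid, m$density, xout = g, yleft = 0, yright = 0,
                  rule = 2, ties = max)$y)
  d[g < min(m$grid) | g > max(m$grid)] <- 0
  d
}

cum_cdf <- function(m, g) {
  d <- interp_density(m, g)
  n <- length(g)
  cs <- c(0, cumsum((g[-1] - g[-n]) * (d[-1] + d[-n]) / 2))
  if (cs[n] > 0) cs / cs[n] else cs
}

cdf_at <- function(m, x) {
  g <- m$grid
  if (x <= min(g)) return(0)
  if (x >= max(g)) return(1)
  cum_cdf(m, sort(unique(c(g, x))))[match(x, sort(unique(c(g, x))))]
}

#' Compare two sets of marginal estimates
#'
#' Computes, for every variable id shared by the two inputs, the
#' total-variation and Kolmogorov-Smirnov distances and the support overlap
#' fraction (length of the support intersection over the union), plus a
#' global summary. Typical use: wBP marginals against KHR histogram
#' marginals on the same network.
#'
#' @param a,b named lists of [marginal_estimate()] (e.g. `$marginals` of a
#'   [run_wbp()] result, or [marginals_from_samples()] output). A
#'   `wbp_result` or `khr_samples` object is accepted directly.
#' @return object of class `comparison_report`: `table` (one row per shared
#'   id: `id`, `kind`, `tv`, `ks`, `support_overlap`), `max_tv`, `mean_tv`,
#'   `only_a`, `only_b` (unmatched ids).
#' @export
compare_marginals <- function(a, b) {
  a <- as_marginal_list(a)
  b <- as_marginal_list(b)
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0) stop("no shared variable ids to compare")
  rows <- lapply(shared, function(id) {
    p <- a[[id]]; q <- b[[id]]
    data.frame(id = id, kind = p$kind,
               tv = suppressWarnings(total_variation(p, q)),
               ks = suppressWarnings(ks_distance(p, q)),
               support_overlap = support_overlap(p, q),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, max_tv = max(tab$tv), mean_tv = mean(tab$tv),
                 only_a = setdiff(names(a), shared),
                 only_b = setdiff(names(b), shared)),
            class = "comparison_report")
}

support_overlap <- function(p, q) {
  lo <- c(min(p$grid), min(q$grid))
  hi <- c(max(p$grid), max(q$grid))
  if (p$point_mass && q$point_mass)
    return(as.numeric(abs(p$value - q$value) <=
                        1e-9 * max(1, abs(p$value), abs(q$value))))
  inter <- max(0, min(hi) - max(lo))
  uni <- max(hi) - min(lo)
  if (uni <= 0) 1 else inter / uni
}

as_marginal_list <- function(x) {
  if (inherits(x, "wbp_result")) return(x$marginals)
  if (inherits(x, "khr_samples")) return(marginals_from_samples(x))
  if (inherits(x, "marginal_estimate")) return(stats::setNames(list(x), x$id))
  stopifnot(is.list(x))
  if (is.null(names(x)))
    names(x) <- vapply(x, function(m) m$id, character(1))
  x
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d shared variables: max TV %.4f, mean TV %.4f\n",
              nrow(x$table), x$max_tv, x$mean_tv))
  if (length(x$only_a) > 0)
    cat("  only in first:", paste(x$only_a, collapse = ", "), "\n")
  if (length(x$only_b) > 0)
    cat("  only in second:", paste(x$only_b, collapse = ", "), "\n")
  invisible(x)
}
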