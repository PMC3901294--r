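#' Construct a constraint-based metabolic network
#'
#' A `metabolic_network` bundles the three ingredients of a constraint-based
#' model: a list of reactions with flux bounds `[lb, ub]` (reversibility is
#' encoded purely through the bounds -- a negative lower bound allows reverse
#' flux), a list of metabolites each carrying an exchange prior, and the signed
#' sparse stoichiometry as (metabolite, reaction, coefficient) triples with the
#' usual sign convention (negative = substrate, positive = product).
#'
#' Metabolites are classified by their prior (see [exchange_prior()]):
#' `internal` metabolites must balance exactly (exchange rate 0), `fixed` ones
#' exchange at a known rate `z0`, and `uniform` ones exchange at an unknown
#' rate distributed uniformly over a window `[lb, ub]`.
#'
#' @param reactions data.frame with columns `id` (character, unique),
#'   `lb`, `ub` (numeric flux bounds, `lb <= ub`).
#' @param metabolites data.frame with columns `id` (character, unique),
#'   `kind` (one of `"internal"`, `"fixed"`, `"uniform"`), `p1`, `p2`
#'   (numeric prior parameters: `z0` for `fixed` in `p1`; window bounds for
#'   `uniform` in `p1`, `p2`; both `NA` for `internal`).
#' @param stoichiometry data.frame with columns `met`, `rxn` (character ids)
#'   and `coeff` (numeric, finite, nonzero).
#' @return An object of class `metabolic_network`.
#' @seealso [validate_network()], [stoichiometric_matrix()], [load_network()]
#' @examples
#' net <- metabolic_network(
#'   reactions = data.frame(id = c("r1", "r2"), lb = 0, ub = 1),
#'   metabolites = data.frame(id = "A", kind = "internal", p1 = NA, p2 = NA),
#'   stoichiometry = data.frame(met = "A", rxn = c("r1", "r2"),
#'                              coeff = c(1, -1))
#' )
#' stoichiometric_matrix(net)
#' @export
metabolic_network <- function(reactions, metabolites, stoichiometry) {
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  stoichiometry <- as.data.frame(stoichiometry, stringsAsFactors = FALSE)
  if (!all(c("id", "lb", "ub") %in% names(reactions)))
    stop("`reactions` needs columns id, lb, ub")
  if (!"kind" %in% names(metabolites))
    stop("`metabolites` needs columns id, kind, p1, p2")
  if (!"p1" %in% names(metabolites)) metabolites$p1 <- NA_real_
  if (!"p2" %in% names(metabolites)) metabolites$p2 <- NA_real_
  if (!all(c("met", "rxn", "coeff") %in% names(stoichiometry)))
    stop("`stoichiometry` needs columns met, rxn, coeff")
  reactions$id <- as.character(reactions$id)
  metabolites$id <- as.character(metabolites$id)
  metabolites$kind <- as.character(metabolites$kind)
  metabolites$p1 <- as.numeric(metabolites$p1)
  metabolites$p2 <- as.numeric(metabolites$p2)
  stoichiometry$met <- as.character(stoichiometry$met)
  stoichiometry$rxn <- as.character(stoichiometry$rxn)
  stoichiometry$coeff <- as.numeric(stoichiometry$coeff)
  rownames(reactions) <- rownames(metabolites) <- rownames(stoichiometry) <- NULL
  net <- structure(
    list(reactions = reactions[c("id", "lb", "ub")],
         metabolites = metabolites[c("id", "kind", "p1", "p2")],
         stoichiometry = stoichiometry[c("met", "rxn", "coeff")]),
    class = "metabolic_network")
  bad <- validate_network(net)
  if (length(bad) > 0)
    stop("invalid metabolic_network:\n  ", paste(bad, collapse = "\n  "))
  net
}

#' Describe an exchange prior
#'
#' Helper returning one row of the `metabolites` table of
#' [metabolic_network()]. `internal` encodes an exact mass balance (exchange
#' rate identically 0); `fixed` a known exchange rate `z0`; `uniform` an
#' exchange rate known only to lie in `[lb, ub]`, weighted uniformly.
#'
#' @param id metabolite id.
#' @param kind `"internal"`, `"fixed"` or `"uniform"`.
#' @param z0 exchange rate (kind `"fixed"` only).
#' @param lb,ub window bounds (kind `"uniform"` only, `lb < ub`).
#' @return one-row data.frame with columns `id`, `kind`, `p1`, `p2`.
#' @export
exchange_prior <- function(id, kind = c("internal", "fixed", "uniform"),
                           z0 = NULL, lb = NULL, ub = NULL) {
  kind <- match.arg(kind)
  p1 <- p2 <- NA_real_
  if (kind == "fixed") {
    if (is.null(z0)) stop("kind='fixed' requires z0")
    p1 <- as.numeric(z0)
  } else if (kind == "uniform") {
    if (is.null(lb) || is.null(ub)) stop("kind='uniform' requires lb and ub")
    p1 <- as.numeric(lb); p2 <- as.numeric(ub)
  }
  data.frame(id = as.character(id), kind = kind, p1 = p1, p2 = p2,
             stringsAsFactors = FALSE)
}

#' Validate a metabolic network
#'
#' Checks every structural invariant and returns a character vector of
#' violations (empty when the network is valid). Each message names the
#' offending id and the rule broken. [metabolic_network()] calls this and
#' refuses to construct an invalid object; `validate_network()` itself never
#' throws, so it can be used to inspect hand-built lists.
#'
#' @param net a `metabolic_network` (or a bare list with the same fields).
#' @return character vector of violation messages; `character(0)` if valid.
#' @export
validate_network <- function(net) {
  v <- character(0)
  rx <- net$reactions; mt <- net$metabolites; st <- net$stoichiometry
  if (anyDuplicated(rx$id))
    v <- c(v, paste0("duplicate reaction id: ",
                     paste(unique(rx$id[duplicated(rx$id)]), collapse = ", ")))
  if (anyDuplicated(mt$id))
    v <- c(v, paste0("duplicate metabolite id: ",
                     paste(unique(mt$id[duplicated(mt$id)]), collapse = ", ")))
  bad_b <- !is.finite(rx$lb) | !is.finite(rx$ub) | rx$lb > rx$ub
  for (i in which(bad_b))
    v <- c(v, paste0("reaction ", rx$id[i], ": bounds violated (lb=",
                     rx$lb[i], " > ub=", rx$ub[i], " or non-finite)"))
  bad_kind <- !mt$kind %in% c("internal", "fixed", "uniform")
  for (i in which(bad_kind))
    v <- c(v, paste0("metabolite ", mt$id[i], ": unknown prior kind '",
                     mt$kind[i], "'"))
  for (i in which(mt$kind == "fixed"))
    if (!is.finite(mt$p1[i]))
      v <- c(v, paste0("metabolite ", mt$id[i], ": fixed prior needs finite z0"))
  for (i in which(mt$kind == "uniform"))
    if (!is.finite(mt$p1[i]) || !is.finite(mt$p2[i]) || mt$p1[i] >= mt$p2[i])
      v <- c(v, paste0("metabolite ", mt$id[i],
                       ": uniform prior needs finite lb < ub"))
  dang_m <- setdiff(st$met, mt$id)
  if (length(dang_m) > 0)
    v <- c(v, paste0("dangling metabolite reference: ",
                     paste(dang_m, collapse = ", ")))
  dang_r <- setdiff(st$rxn, rx$id)
  if (length(dang_r) > 0)
    v <- c(v, paste0("dangling reaction reference: ",
                     paste(dang_r, collapse = ", ")))
  key <- paste(st$met, st$rxn, sep = "\r")
  if (anyDuplicated(key)) {
    d <- unique(key[duplicated(key)])
    v <- c(v, paste0("duplicate (metabolite, reaction) pair: ",
                     paste(gsub("\r", "/", d), collapse = ", ")))
  }
  bad_c <- !is.finite(st$coeff) | st$coeff == 0
  for (i in which(bad_c))
    v <- c(v, paste0("triple (", st$met[i], ", ", st$rxn[i],
                     "): coefficient must be finite and nonzero"))
  orphan_m <- setdiff(mt$id, st$met)
  if (length(orphan_m) > 0)
    v <- c(v, paste0("metabolite in no reaction: ",
                     paste(orphan_m, collapse = ", ")))
  orphan_r <- setdiff(rx$id, st$rxn)
  if (length(orphan_r) > 0)
    v <- c(v, paste0("reaction touching no metabolite: ",
                     paste(orphan_r, collapse = ", ")))
  v
}

#' @export
print.metabolic_network <- function(x, ...) {
  n_int <- sum(x$metabolites$kind == "internal")
  cat(sprintf(
    "<metabolic_network> %d reactions, %d metabolites (%d internal), %d stoichiometric entries\n",
    nrow(x$reactions), nrow(x$metabolites), n_int, nrow(x$stoichiometry)))
  invisible(x)
}

#' Stoichiometric matrix of a network
#'
#' Returns the sparse stoichiometric matrix with one row per metabolite (in
#' declared order) and one column per reaction (in declared order); entry
#' (mu, i) is the signed coefficient of reaction i on metabolite mu, 0 when the
#' reaction does not process the metabolite. Note the orientation: rows are
#' the mass-balance constraints.
#'
#' @param net a `metabolic_network`.
#' @return a `dgCMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
stoichiometric_matrix <- function(net) {
  m <- match(net$stoichiometry$met, net$metabolites$id)
  r <- match(net$stoichiometry$rxn, net$reactions$id)
  Matrix::sparseMatrix(
    i = m, j = r, x = net$stoichiometry$coeff,
    dims = c(nrow(net$metabolites), nrow(net$reactions)),
    dimnames = list(net$metabolites$id, net$reactions$id))
}

#' Internal stoichiometric submatrix
#'
#' The rows of [stoichiometric_matrix()] restricted to metabolites whose
#' prior kind is `internal`, i.e. the equality constraints S x = 0 whose null
#' space the KHR sampler reduces to. Column order is unchanged.
#'
#' @param net a `metabolic_network`.
#' @return sparse matrix with `sum(kind == "internal")` rows.
#' @export
internal_submatrix <- function(net) {
  S <- stoichiometric_matrix(net)
  S[net$metabolites$kind == "internal", , drop = FALSE]
}

#' @keywords internal
#' @noRd
rxn_index <- function(net, id) {
  i <- match(id, net$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", id)
  i
}

#' @keywords internal
#' @noRd
met_index <- function(net, id) {
  i <- match(id, net$metabolites$id)
  if (is.na(i)) stop("unknown metabolite id: ", id)
  i
}
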