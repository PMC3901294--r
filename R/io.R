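#' Read a metabolic network from disk
#'
#' Two plain-text dialects are supported.
#'
#' **JSON**: a single file with top-level keys `reactions` (list of
#' `{id, lb, ub}`), `metabolites` (list of `{id, prior: {kind, z0?, lb?, ub?}}`)
#' and `stoichiometry` (list of `[met_id, rxn_id, coeff]` triples).
#'
#' **TSV**: three tab-separated files sharing a basename:
#' `<base>.reactions.tsv` (columns `id`, `lb`, `ub`),
#' `<base>.metabolites.tsv` (columns `id`, `kind`, `p1`, `p2`) and
#' `<base>.stoich.tsv` (columns `met`, `rxn`, `coeff`); header row required,
#' UTF-8, `.` decimal separator. For `format = "tsv"` pass the basename
#' (with or without a trailing `.reactions.tsv` etc. stripped off by the
#' caller).
#'
#' Declaration order of reactions and metabolites is preserved exactly, so a
#' round trip through [save_network()] reproduces the network field by field.
#'
#' @param path file path (JSON) or basename (TSV).
#' @param format `"json"` or `"tsv"`; default guesses from the extension.
#' @return a validated [metabolic_network()].
#' @export
load_network <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    if (!file.exists(path)) stop("no such file: ", path)
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!all(c("reactions", "metabolites", "stoichiometry") %in% names(doc)))
      stop("JSON network needs keys reactions, metabolites, stoichiometry: ",
           path)
    rx <- do.call(rbind, lapply(doc$reactions, function(r)
      data.frame(id = as.character(r$id), lb = as.numeric(r$lb),
                 ub = as.numeric(r$ub), stringsAsFactors = FALSE)))
    mt <- do.call(rbind, lapply(doc$metabolites, function(m) {
      pr <- m$prior
      exchange_prior(m$id, pr$kind, z0 = pr$z0, lb = pr$lb, ub = pr$ub)
    }))
    st <- do.call(rbind, lapply(doc$stoichiometry, function(tr)
      data.frame(met = as.character(tr[[1]]), rxn = as.character(tr[[2]]),
                 coeff = as.numeric(tr[[3]]), stringsAsFactors = FALSE)))
    return(metabolic_network(rx, mt, st))
  }
  base <- sub("\\.(reactions|metabolites|stoich)\\.tsv$", "", path)
  paths <- paste0(base, c(".reactions.tsv", ".metabolites.tsv", ".stoich.tsv"))
  for (p in paths) if (!file.exists(p)) stop("no such file: ", p)
  rd <- function(p) utils::read.delim(p, header = TRUE, sep = "\t",
                                      colClasses = NA, stringsAsFactors = FALSE,
                                      fileEncoding = "UTF-8")
  rx <- rd(paths[1]); mt <- rd(paths[2]); st <- rd(paths[3])
  mt$p1 <- suppressWarnings(as.numeric(mt$p1))
  mt$p2 <- suppressWarnings(as.numeric(mt$p2))
  metabolic_network(rx, mt, st)
}

#' Write a metabolic network to disk
#'
#' Inverse of [load_network()]; see that help page for the two dialects.
#'
#' @param net a `metabolic_network`.
#' @param path file path (JSON) or basename (TSV).
#' @param format `"json"` or `"tsv"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  stopifnot(inherits(net, "metabolic_network"))
  if (format == "json") {
    mets <- lapply(seq_len(nrow(net$metabolites)), function(i) {
      m <- net$metabolites[i, ]
      pr <- switch(m$kind,
        internal = list(kind = "internal"),
        fixed = list(kind = "fixed", z0 = m$p1),
        uniform = list(kind = "uniform", lb = m$p1, ub = m$p2))
      list(id = m$id, prior = pr)
    })
    rxs <- lapply(seq_len(nrow(net$reactions)), function(i)
      as.list(net$reactions[i, c("id", "lb", "ub")]))
    tri <- lapply(seq_len(nrow(net$stoichiometry)), function(i)
      list(net$stoichiometry$met[i], net$stoichiometry$rxn[i],
           net$stoichiometry$coeff[i]))
    jsonlite::write_json(
      list(reactions = rxs, metabolites = mets, stoichiometry = tri),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  base <- sub("\\.(reactions|metabolites|stoich)\\.tsv$", "", path)
  wr <- function(df, p) utils::write.table(
    df, p, sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8")
  wr(net$reactions, paste0(base, ".reactions.tsv"))
  wr(net$metabolites, paste0(base, ".metabolites.tsv"))
  wr(net$stoichiometry, paste0(base, ".stoich.tsv"))
  invisible(path)
}

#' Write marginal estimates to a TSV file
#'
#' Long format with columns `variable_id`, `kind` (`flux` or `exchange`),
#' `grid_value`, `density`. Point-mass marginals (pinned fluxes) are written
#' as a single row with density `Inf`.
#'
#' @param marginals list of [marginal_estimate()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_marginals <- function(marginals, path) {
  rows <- lapply(marginals, function(m) {
    if (isTRUE(m$point_mass))
      data.frame(variable_id = m$id, kind = m$kind, grid_value = m$value,
                 density = Inf, stringsAsFactors = FALSE)
    else
      data.frame(variable_id = m$id, kind = m$kind, grid_value = m$grid,
                 density = m$density, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read marginal estimates from a TSV file written by [write_marginals()]
#'
#' @param path input file.
#' @return named list of [marginal_estimate()] objects.
#' @export
read_marginals <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  out <- lapply(split(df, factor(df$variable_id, unique(df$variable_id))),
                function(d) {
    if (nrow(d) == 1 && !is.finite(d$density[1]))
      marginal_estimate(d$variable_id[1], d$kind[1], point_mass = TRUE,
                        value = d$grid_value[1])
    else
      marginal_estimate(d$variable_id[1], d$kind[1], grid = d$grid_value,
                        density = d$density)
  })
  out[unique(df$variable_id)]
}
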