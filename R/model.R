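#' Construct a metabolic model
#'
#' Holds the stoichiometric matrix, per-reaction flux bounds
#' (mmol gDW^-1 h^-1 by convention), the biomass objective reaction, parsed
#' gene-protein-reaction rules, and the set of exchange reactions. Bounds
#' must be finite (use a large value such as 1000 for practically unbounded
#' fluxes); this keeps the flux LP bounded by construction.
#'
#' @param S numeric matrix, metabolites x reactions, with dimnames.
#' @param lb,ub numeric vectors of lower/upper flux bounds, one per reaction.
#' @param objective reaction id of the (biomass) objective.
#' @param gpr named list mapping reaction id to a GPR rule string or a parsed
#'   GPRTree; reactions without a rule may be omitted.
#' @param exchange character vector of exchange reaction ids, or NULL to
#'   auto-detect reactions whose stoichiometric column has a single nonzero
#'   entry (the default rule; SBML boundary conventions vary by dialect, so
#'   an explicit list always overrides detection).
#' @return object of class \code{MetabolicModel}.
#' @export
metabolic_model <- function(S, lb, ub, objective, gpr = list(),
                            exchange = NULL) {
  if (!is.matrix(S) || !is.numeric(S))
    stop("S must be a numeric matrix")
  mets <- rownames(S)
  rxns <- colnames(S)
  if (is.null(mets) || is.null(rxns))
    stop("S must carry metabolite rownames and reaction colnames")
  if (anyDuplicated(mets)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxns)) stop("duplicate reaction ids")
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  if (length(lb) != ncol(S) || length(ub) != ncol(S))
    stop("lb/ub must have one entry per reaction")
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("bounds must be finite (use e.g. +/-1000 for unbounded fluxes)")
  bad <- which(lb > ub)
  if (length(bad) > 0L)
    stop("lb > ub for reaction(s): ", paste(rxns[bad], collapse = ", "))
  names(lb) <- names(ub) <- rxns
  if (!objective %in% rxns)
    stop("objective reaction not in model: ", objective)
  gpr_trees <- list()
  for (r in names(gpr)) {
    if (!r %in% rxns) stop("GPR for unknown reaction: ", r)
    g <- gpr[[r]]
    tree <- if (is.character(g)) parse_gpr(g) else g
    if (!is.null(tree)) gpr_trees[[r]] <- tree
  }
  if (is.null(exchange)) {
    nnz <- colSums(S != 0)
    exchange <- rxns[nnz == 1L]
  } else {
    exchange <- as.character(exchange)
    if (!all(exchange %in% rxns)) stop("unknown exchange reaction id")
  }
  structure(list(S = S, lb = lb, ub = ub, objective = objective,
                 gpr = gpr_trees, exchange = exchange,
                 metabolites = mets, reactions = rxns),
            class = "MetabolicModel")
}

#' @export
print.MetabolicModel <- function(x, ...) {
  cat(sprintf(
    "MetabolicModel: %d metabolites, %d reactions (%d with GPR, %d exchange)\n",
    length(x$metabolites), length(x$reactions), length(x$gpr),
    length(x$exchange)))
  cat("objective:", x$objective, "\n")
  invisible(x)
}

#' Genes referenced by a model's GPR rules
#' @param model MetabolicModel
#' @return character vector of unique gene ids.
#' @export
model_genes <- function(model) {
  unique(unlist(lapply(model$gpr, gpr_genes), use.names = FALSE))
}

#' Exchange reaction carrying a given metabolite
#'
#' @param model MetabolicModel
#' @param metabolite metabolite id
#' @return reaction id of the unique exchange reaction whose only nonzero
#'   stoichiometric entry is this metabolite.
#' @export
exchange_for <- function(model, metabolite) {
  if (!metabolite %in% model$metabolites)
    stop("unknown metabolite: ", metabolite)
  hits <- model$exchange[vapply(model$exchange, function(r) {
    col <- stats::setNames(model$S[, r], model$metabolites)
    sum(col != 0) == 1L && col[metabolite] != 0
  }, logical(1))]
  if (length(hits) == 0L)
    stop("no exchange reaction for metabolite: ", metabolite)
  if (length(hits) > 1L)
    stop("multiple exchange reactions for metabolite: ", metabolite)
  hits
}

#' Read a metabolic model
#'
#' Dispatches on format: \code{"sbml"} reads an SBML Level 3 + FBC file,
#' \code{"tabular"} reads this package's two-file plain-text layout (see
#' \code{\link{read_tabular_model}}).
#'
#' @param path file path (SBML) or directory path (tabular).
#' @param format "sbml" or "tabular".
#' @param exchange optional explicit exchange-reaction list overriding the
#'   single-nonzero-column detection rule.
#' @return MetabolicModel
#' @export
read_metabolic_model <- function(path, format = c("sbml", "tabular"),
                                 exchange = NULL) {
  format <- match.arg(format)
  switch(format,
         sbml = read_sbml_model(path, exchange = exchange),
         tabular = read_tabular_model(path, exchange = exchange))
}

#' Read a model in the tabular layout
#'
#' The layout is a directory with two tab-separated files:
#' \itemize{
#'   \item \code{reactions.tsv}: columns \code{id}, \code{lb}, \code{ub},
#'     \code{gpr} (boolean rule string, may be empty), \code{objective}
#'     (0/1, exactly one 1).
#'   \item \code{stoichiometry.tsv}: triplet columns \code{metabolite},
#'     \code{reaction}, \code{coefficient}.
#' }
#'
#' @param dir directory containing the two files.
#' @param exchange optional explicit exchange-reaction list.
#' @return MetabolicModel
#' @export
read_tabular_model <- function(dir, exchange = NULL) {
  rf <- file.path(dir, "reactions.tsv")
  sf <- file.path(dir, "stoichiometry.tsv")
  if (!file.exists(rf) || !file.exists(sf))
    stop("tabular model needs reactions.tsv and stoichiometry.tsv in ", dir)
  rx <- utils::read.delim(rf, stringsAsFactors = FALSE)
  st <- utils::read.delim(sf, stringsAsFactors = FALSE)
  need <- c("id", "lb", "ub", "gpr", "objective")
  if (!all(need %in% names(rx)))
    stop("reactions.tsv must have columns: ", paste(need, collapse = ", "))
  if (!all(c("metabolite", "reaction", "coefficient") %in% names(st)))
    stop("stoichiometry.tsv must have columns metabolite, reaction, coefficient")
  if (!all(st$reaction %in% rx$id))
    stop("stoichiometry.tsv references unknown reaction: ",
         setdiff(st$reaction, rx$id)[1L])
  mets <- sort_c(unique(st$metabolite))
  S <- matrix(0, length(mets), nrow(rx), dimnames = list(mets, rx$id))
  S[cbind(match(st$metabolite, mets), match(st$reaction, rx$id))] <-
    as.numeric(st$coefficient)
  if (sum(rx$objective != 0) != 1L)
    stop("reactions.tsv must flag exactly one objective reaction")
  gpr <- as.list(rx$gpr)
  names(gpr) <- rx$id
  gpr <- gpr[!is.na(gpr) & nzchar(trimws(unlist(gpr)))]
  metabolic_model(S, rx$lb, rx$ub, rx$id[rx$objective != 0], gpr = gpr,
                  exchange = exchange)
}

#' Write a model in the tabular layout
#' @param model MetabolicModel
#' @param dir output directory (created if absent).
#' @export
write_tabular_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gpr_str <- vapply(model$reactions, function(r) {
    if (r %in% names(model$gpr)) gpr_to_string(model$gpr[[r]]) else ""
  }, character(1))
  rx <- data.frame(id = model$reactions, lb = model$lb, ub = model$ub,
                   gpr = gpr_str,
                   objective = as.integer(model$reactions == model$objective),
                   stringsAsFactors = FALSE)
  utils::write.table(rx, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nz <- which(model$S != 0, arr.ind = TRUE)
  st <- data.frame(metabolite = model$metabolites[nz[, 1L]],
                   reaction = model$reactions[nz[, 2L]],
                   coefficient = model$S[nz],
                   stringsAsFactors = FALSE)
  st <- st[order(st$reaction, st$metabolite), ]
  utils::write.table(st, file.path(dir, "stoichiometry.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
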