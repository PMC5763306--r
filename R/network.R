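#' Construct a signed regulatory network
#'
#' A regulatory network is a signed bipartite graph: each regulator activates
#' one set of target genes and represses another. A (regulator, target) pair
#' may carry at most one sign. Regulators may themselves be targets of other
#' regulators. Edges can carry an optional evidence score in [0, 1], used when
#' merging data-driven fits with external interaction databases.
#'
#' @param edges data.frame with columns \code{regulator}, \code{target},
#'   \code{sign} (+1 activation, -1 repression) and optionally \code{score}.
#' @return an object of class \code{RegulatoryNetwork}.
#' @export
regulatory_network <- function(edges) {
  need <- c("regulator", "target", "sign")
  if (!all(need %in% names(edges)))
    stop("edges must have columns regulator, target, sign")
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  edges$sign <- as.numeric(edges$sign)
  if (!all(edges$sign %in% c(-1, 1)))
    stop("sign must be +1 or -1")
  if ("score" %in% names(edges)) {
    edges$score <- as.numeric(edges$score)
    if (any(!is.na(edges$score) & (edges$score < 0 | edges$score > 1)))
      stop("evidence scores must lie in [0, 1]")
  }
  key <- paste(edges$regulator, edges$target, sep = "\r")
  dupsign <- tapply(edges$sign, key, function(s) length(unique(s)))
  if (any(dupsign > 1L)) {
    bad <- names(dupsign)[dupsign > 1L][1L]
    stop("pair listed with both signs: ", gsub("\r", " -> ", bad))
  }
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 regulators = sort_c(unique(edges$regulator))),
            class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat(sprintf("RegulatoryNetwork: %d regulators, %d signed edges (%d +, %d -)\n",
              length(x$regulators), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

#' Targets activated by a regulator
#' @param net RegulatoryNetwork
#' @param regulator regulator id
#' @return character vector of target gene ids
#' @export
activated_targets <- function(net, regulator) {
  e <- net$edges
  e$target[e$regulator == regulator & e$sign > 0]
}

#' Targets repressed by a regulator
#' @inheritParams activated_targets
#' @return character vector of target gene ids
#' @export
repressed_targets <- function(net, regulator) {
  e <- net$edges
  e$target[e$regulator == regulator & e$sign < 0]
}

#' Regulator set Pa(i) of a gene
#'
#' @param net RegulatoryNetwork
#' @param gene target gene id
#' @return character vector of regulators with an edge (either sign) to
#'   \code{gene}.
#' @export
regulators_of <- function(net, gene) {
  e <- net$edges
  sort_c(unique(e$regulator[e$target == gene]))
}

#' Read a regulatory network from TSV
#'
#' Columns: regulator, target, sign (+1/-1), optional evidence score in [0,1].
#' A header line is detected by a non-numeric third field.
#'
#' @param path input file path.
#' @return RegulatoryNetwork
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- utils::read.delim(path, header = FALSE, sep = "\t", nrows = 1,
                             stringsAsFactors = FALSE)
  has_header <- ncol(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[[3]])))
  df <- utils::read.delim(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("network file needs >= 3 columns: ", path)
  names(df)[1:3] <- c("regulator", "target", "sign")
  if (ncol(df) >= 4L) names(df)[4L] <- "score"
  regulatory_network(df[, seq_len(min(4L, ncol(df))), drop = FALSE])
}

#' Write a regulatory network to TSV
#' @param net RegulatoryNetwork
#' @param path output file path.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
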