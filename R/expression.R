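#' Validate a gene expression matrix
#'
#' Expression values are continuous and assumed to be on a log scale. Rows are
#' genes, columns are samples; both must carry unique, non-empty identifiers.
#' Missing values (\code{NA}) are permitted; every downstream statistic either
#' skips or rejects them deterministically.
#'
#' @param values numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @return the validated matrix (invisibly the same object).
#' @export
as_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || anyNA(genes) || any(genes == ""))
    stop("expression matrix must have non-empty gene rownames")
  if (is.null(samples) || anyNA(samples) || any(samples == ""))
    stop("expression matrix must have non-empty sample colnames")
  if (anyDuplicated(genes))
    stop("duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  values
}

#' Read an expression matrix from TSV
#'
#' The file has a header row of sample ids and a first column of gene ids.
#'
#' @param path path to a tab-separated file.
#' @param aggregate_duplicates average rows sharing a gene id (e.g. replicate
#'   probes mapping to one ORF) instead of rejecting them. Default is to
#'   reject, so silent identifier collisions surface early.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path, aggregate_duplicates = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e)
      stop("expression file is empty or unreadable: ", path, " (",
           conditionMessage(e), ")"))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("expression file is empty or has no sample columns: ", path)
  genes <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2L, as.numeric))
  num <- matrix(num, nrow = nrow(vals), dimnames = dimnames(vals))
  bad <- which(is.na(num) & !(is.na(vals) | vals %in% c("NA", "")),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
                 colnames(vals)[bad[1L, 2L]]))
  rownames(num) <- genes
  if (anyDuplicated(genes)) {
    if (!aggregate_duplicates)
      stop("duplicate gene ids: ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "),
           " (set aggregate_duplicates = TRUE to average them)")
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
  }
  as_expression_matrix(num)
}

#' Rename expression rows through an alias map
#'
#' Gene ids are matched between GPR rules, networks and expression rows by
#' exact string comparison; the only renaming mechanism is an explicit alias
#' map, a two-column TSV (\code{alias}, \code{gene}) translating row ids to
#' the namespace the model uses. Rows without an alias keep their id.
#'
#' @param expr expression matrix (genes x samples).
#' @param path path to the alias TSV (header optional; first column alias,
#'   second column replacement id).
#' @return the matrix with renamed rows (duplicates after renaming are an
#'   error).
#' @export
apply_gene_aliases <- function(expr, path) {
  expr <- as_expression_matrix(expr)
  if (!file.exists(path)) stop("file not found: ", path)
  map <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 2L) stop("alias map needs two columns: alias, gene")
  if (identical(tolower(map[1L, 1L]), "alias")) map <- map[-1L, , drop = FALSE]
  aliases <- stats::setNames(as.character(map[[2L]]), as.character(map[[1L]]))
  ids <- rownames(expr)
  hit <- ids %in% names(aliases)
  ids[hit] <- unname(aliases[ids[hit]])
  rownames(expr) <- ids
  as_expression_matrix(expr)
}

#' Write an expression matrix to TSV
#'
#' @param expr numeric matrix, genes x samples.
#' @param path output file path.
#' @export
write_expression <- function(expr, path) {
  expr <- as_expression_matrix(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
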