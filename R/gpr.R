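#' Parse a boolean gene-protein-reaction rule
#'
#' Grammar: gene identifiers, case-insensitive \code{and} / \code{or},
#' parentheses; \code{and} binds tighter than \code{or}. Chains of the same
#' operator are flattened into a single n-ary node, so evaluation is
#' commutative and associative by construction.
#'
#' @param rule GPR string, e.g. \code{"(G1 and G2) or G3"}. Empty or
#'   whitespace-only strings return \code{NULL} (no rule).
#' @return a \code{GPRTree}: nested list with \code{op} in
#'   \code{"leaf"/"and"/"or"}; leaves carry \code{gene}, inner nodes
#'   \code{children}.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st, rule)
  if (st$pos <= length(st$toks))
    stop(sprintf("GPR parse error in '%s': unexpected token '%s' at position %d",
                 rule, st$toks[[st$pos]]$text, st$toks[[st$pos]]$at))
  tree
}

gpr_tokenize <- function(rule) {
  toks <- list()
  i <- 1L
  n <- nchar(rule)
  while (i <= n) {
    ch <- substr(rule, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, at = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(rule, i, n),
                    regexpr("^[A-Za-z0-9_.:-]+", substr(rule, i, n)))
    if (length(m) == 0L)
      stop(sprintf("GPR parse error in '%s': illegal character '%s' at position %d",
                   rule, ch, i))
    low <- tolower(m)
    type <- if (low == "and") "and" else if (low == "or") "or" else "id"
    toks[[length(toks) + 1L]] <- list(type = type, text = m, at = i)
    i <- i + nchar(m)
  }
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL

gpr_parse_or <- function(st, rule) {
  kids <- list(gpr_parse_and(st, rule))
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "or") break
    st$pos <- st$pos + 1L
    kids[[length(kids) + 1L]] <- gpr_parse_and(st, rule)
  }
  gpr_node("or", kids)
}

gpr_parse_and <- function(st, rule) {
  kids <- list(gpr_parse_primary(st, rule))
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "and") break
    st$pos <- st$pos + 1L
    kids[[length(kids) + 1L]] <- gpr_parse_primary(st, rule)
  }
  gpr_node("and", kids)
}

gpr_parse_primary <- function(st, rule) {
  tk <- gpr_peek(st)
  if (is.null(tk))
    stop(sprintf("GPR parse error in '%s': missing operand at end of rule", rule))
  if (tk$type == "id") {
    st$pos <- st$pos + 1L
    return(list(op = "leaf", gene = tk$text))
  }
  if (tk$type == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st, rule)
    tk2 <- gpr_peek(st)
    if (is.null(tk2) || tk2$type != ")")
      stop(sprintf("GPR parse error in '%s': unbalanced parenthesis opened at position %d",
                   rule, tk$at))
    st$pos <- st$pos + 1L
    return(inner)
  }
  stop(sprintf("GPR parse error in '%s': unexpected token '%s' at position %d",
               rule, tk$text, tk$at))
}

# collapse single-child nodes, splice same-operator children (n-ary flat form)
gpr_node <- function(op, kids) {
  if (length(kids) == 1L) return(kids[[1L]])
  flat <- list()
  for (k in kids) {
    if (!is.null(k$op) && k$op == op) flat <- c(flat, k$children)
    else flat[[length(flat) + 1L]] <- k
  }
  list(op = op, children = flat)
}

#' Genes referenced by a GPR tree
#' @param tree GPRTree (or NULL).
#' @return character vector of gene ids (unique).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (tree$op == "leaf") return(tree$gene)
  unique(unlist(lapply(tree$children, gpr_genes)))
}

#' Render a GPR tree back to a rule string
#' @param tree GPRTree (or NULL, giving "").
#' @return character scalar.
#' @export
gpr_to_string <- function(tree) {
  if (is.null(tree)) return("")
  if (tree$op == "leaf") return(tree$gene)
  parts <- vapply(tree$children, function(k) {
    s <- gpr_to_string(k)
    # AND binds tighter than OR, so only an OR child under AND needs parens
    if (tree$op == "and" && k$op == "or") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}

#' Evaluate a GPR rule continuously
#'
#' Boolean rules are evaluated on continuous (predicted) expression: OR nodes
#' (isoenzymes) take the maximum of their children, AND nodes (enzyme
#' complexes) the minimum. A gene whose expression is not available is
#' discarded from the rule; this applies at every nesting level, and a node
#' all of whose children are discarded is itself discarded. A fully discarded
#' tree evaluates to \code{NA} (the reaction then keeps its default bounds).
#' Negative values pass through unchanged: the downstream softplus bound maps
#' any real to a positive flux limit.
#'
#' @param tree GPRTree from \code{\link{parse_gpr}} (or NULL).
#' @param values named numeric vector mapping gene id to expression; genes
#'   absent from the vector, or mapped to \code{NA}, count as missing.
#' @return numeric scalar, or \code{NA} if the whole rule is discarded.
#' @export
evaluate_gpr <- function(tree, values) {
  if (is.null(tree)) return(NA_real_)
  pruned <- gpr_discard_missing(tree, values)
  if (is.null(pruned)) return(NA_real_)
  gpr_eval_pruned(pruned, values)
}

gpr_discard_missing <- function(tree, values) {
  if (tree$op == "leaf") {
    v <- values[tree$gene]
    if (tree$gene %in% names(values) && length(v) == 1L && !is.na(v)) return(tree)
    return(NULL)
  }
  kept <- Filter(Negate(is.null),
                 lapply(tree$children, gpr_discard_missing, values = values))
  if (length(kept) == 0L) return(NULL)
  if (length(kept) == 1L) return(kept[[1L]])
  list(op = tree$op, children = kept)
}

gpr_eval_pruned <- function(tree, values) {
  if (tree$op == "leaf") return(unname(values[[tree$gene]]))
  vals <- vapply(tree$children, gpr_eval_pruned, numeric(1), values = values)
  if (tree$op == "and") min(vals) else max(vals)
}
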