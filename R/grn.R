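#' Discretize an expression matrix
#'
#' Each gene is centered (its mean across samples subtracted), then values
#' above +threshold map to +1, below -threshold to -1, and to 0 otherwise.
#' With \code{scale = "sd"} the threshold is expressed in units of each
#' gene's standard deviation (so \code{threshold = 1} means one gene-wise SD,
#' the package default for network inference); with \code{scale =
#' "absolute"} it is applied as given on the centered values.
#'
#' @param expr expression matrix (genes x samples).
#' @param threshold positive scalar.
#' @param scale "absolute" or "sd".
#' @return integer matrix in \{-1, 0, +1\} with the threshold and scale
#'   recorded as attributes.
#' @export
discretize <- function(expr, threshold = 1, scale = c("absolute", "sd")) {
  scale <- match.arg(scale)
  expr <- as_expression_matrix(expr)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a positive scalar")
  centered <- expr - rowMeans(expr, na.rm = TRUE)
  cut <- if (scale == "sd") {
    sds <- apply(expr, 1L, stats::sd, na.rm = TRUE)
    matrix(threshold * sds, nrow(expr), ncol(expr))
  } else matrix(threshold, nrow(expr), ncol(expr))
  disc <- matrix(0L, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  disc[centered > cut] <- 1L
  disc[centered < -cut] <- -1L
  attr(disc, "threshold") <- threshold
  attr(disc, "scale") <- scale
  disc
}

# combined discrete signal of a signed regulator set: min over coactivator
# states and negated corepressor states
grn_combined_state <- function(disc, coact, corep) {
  parts <- rbind(disc[coact, , drop = FALSE], -disc[corep, , drop = FALSE])
  apply(parts, 2L, min)
}

#' Mine candidate co-regulator sets for a target
#'
#' Enumerates signed regulator sets (coactivators, corepressors) whose
#' combined discrete signal — the minimum over coactivator states and
#' negated corepressor states — matches the target's discrete state in at
#' least \code{min_support} of the samples where the target is nonzero.
#' Enumeration is level-wise by total set size up to \code{max_set_size};
#' no support-based pruning is applied between levels because match support
#' is not anti-monotone under the min combination (an AND pair can match
#' where neither singleton does). Regulators whose discrete profile is all
#' zero are excluded up front.
#'
#' @param disc discretized matrix from \code{\link{discretize}}.
#' @param target target gene id (must not be listed in \code{regulators}).
#' @param regulators candidate regulator ids (rows of \code{disc}).
#' @param max_set_size maximum total number of regulators in a set (>= 1).
#' @param min_support minimum match fraction in [0, 1].
#' @return list of candidates, each \code{list(coactivators, corepressors,
#'   support)}; empty list when the target is never nonzero or nothing
#'   reaches the support threshold.
#' @export
mine_coregulators <- function(disc, target, regulators, max_set_size = 2,
                              min_support = 0.5) {
  if (target %in% regulators) stop("target must not be among the regulators")
  if (max_set_size < 1) stop("max_set_size must be >= 1")
  stopifnot(target %in% rownames(disc), all(regulators %in% rownames(disc)))
  tgt <- disc[target, ]
  active <- which(tgt != 0L)
  if (length(active) == 0L) return(list())
  regulators <- regulators[rowSums(disc[regulators, , drop = FALSE] != 0L) > 0L]
  if (length(regulators) == 0L) return(list())
  out <- list()
  for (size in seq_len(min(max_set_size, length(regulators)))) {
    combos <- utils::combn(sort_c(regulators), size, simplify = FALSE)
    for (set in combos) {
      # every split of the set into coactivators/corepressors
      for (mask in 0:(2^size - 1)) {
        rep_idx <- which(bitwAnd(mask, 2^(seq_len(size) - 1L)) > 0L)
        coact <- set[setdiff(seq_len(size), rep_idx)]
        corep <- set[rep_idx]
        comb <- grn_combined_state(disc, coact, corep)
        support <- mean(comb[active] == tgt[active])
        if (support >= min_support)
          out[[length(out) + 1L]] <- list(coactivators = coact,
                                          corepressors = corep,
                                          support = support)
      }
    }
  }
  out
}

#' Score a candidate co-regulator set by regression
#'
#' Fits the target's continuous expression on up to two synthetic
#' covariates — the minimum over the coactivators' expression and the
#' minimum over the corepressors' expression (a class that is empty
#' contributes no covariate) — by ordinary least squares with intercept, and
#' returns the coefficient of determination clipped to [0, 1].
#'
#' @param expr expression matrix (genes x samples).
#' @param target target gene id.
#' @param coactivators,corepressors regulator id vectors (one may be empty).
#' @return R^2 in [0, 1].
#' @export
score_local_grn <- function(expr, target, coactivators,
                            corepressors = character()) {
  expr <- as_expression_matrix(expr)
  if (length(coactivators) == 0L && length(corepressors) == 0L)
    stop("candidate must name at least one regulator")
  y <- expr[target, ]
  X <- NULL
  if (length(coactivators) > 0L)
    X <- cbind(X, act = apply(expr[coactivators, , drop = FALSE], 2L, min))
  if (length(corepressors) > 0L)
    X <- cbind(X, rep = apply(expr[corepressors, , drop = FALSE], 2L, min))
  if (length(y) < ncol(X) + 2L)
    stop("fewer samples than covariates + intercept")
  fit <- stats::lm.fit(cbind(1, X), y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  r2 <- 1 - sum(fit$residuals^2) / tss
  min(max(r2, 0), 1)
}

#' Infer a signed regulatory network from expression data
#'
#' A simplified co-regulator inference stage: expression is discretized (one
#' gene-wise SD by default), candidate signed regulator sets are mined per
#' target (\code{\link{mine_coregulators}}), each candidate is scored by the
#' regression R^2 of \code{\link{score_local_grn}}, optionally merged with
#' external evidence scores as
#' \code{(1 - w) * r2 + w * mean(edge evidence)}, and the best-scoring
#' candidate per target is selected. Ties break toward the smallest total
#' regulator count, then lexicographically, so results do not depend on
#' enumeration order. The procedure is deterministic given data and
#' parameters.
#'
#' @param expr expression matrix (genes x samples).
#' @param regulators regulator gene ids (subset of rows of \code{expr}).
#' @param targets genes to find regulators for; default all non-regulator
#'   rows.
#' @param threshold,scale discretization control (see
#'   \code{\link{discretize}}); default one gene-wise SD.
#' @param max_set_size,min_support mining control.
#' @param evidence optional data.frame (regulator, target, score in [0, 1])
#'   of external evidence.
#' @param evidence_weight weight w of evidence in the merged score
#'   (default 0: pure data).
#' @return RegulatoryNetwork of the selected signed edges, with a
#'   \code{"local_grns"} attribute holding the per-target winning candidate
#'   (coactivators, corepressors, r2, merged score).
#' @export
infer_network <- function(expr, regulators, targets = NULL, threshold = 1,
                          scale = "sd", max_set_size = 2, min_support = 0.5,
                          evidence = NULL, evidence_weight = 0) {
  expr <- as_expression_matrix(expr)
  if (!all(regulators %in% rownames(expr)))
    stop("regulators must be rows of the expression matrix")
  if (is.null(targets)) targets <- setdiff(rownames(expr), regulators)
  if (length(regulators) == 0L || length(targets) == 0L)
    return(regulatory_network(data.frame(regulator = character(),
                                         target = character(),
                                         sign = numeric())))
  disc <- discretize(expr, threshold, scale = scale)
  ev_key <- if (!is.null(evidence))
    stats::setNames(evidence$score,
                    paste(evidence$regulator, evidence$target, sep = "\r"))
  edges <- list()
  locals <- list()
  for (g in targets) {
    cands <- mine_coregulators(disc, g, regulators,
                               max_set_size = max_set_size,
                               min_support = min_support)
    if (length(cands) == 0L) next
    scored <- lapply(cands, function(cd) {
      r2 <- score_local_grn(expr, g, cd$coactivators, cd$corepressors)
      ev <- 0
      if (!is.null(ev_key)) {
        keys <- paste(c(cd$coactivators, cd$corepressors), g, sep = "\r")
        vals <- ev_key[keys]
        vals[is.na(vals)] <- 0
        ev <- mean(vals)
      }
      merged <- (1 - evidence_weight) * r2 + evidence_weight * ev
      c(cd, list(r2 = r2, merged_score = merged))
    })
    score <- vapply(scored, `[[`, numeric(1), "merged_score")
    sizes <- vapply(scored, function(cd)
      length(cd$coactivators) + length(cd$corepressors), numeric(1))
    lab <- vapply(scored, function(cd)
      paste(c(cd$coactivators, "~", cd$corepressors), collapse = ","),
      character(1))
    ord <- order(-score, sizes, match(lab, sort_c(lab)))
    best <- scored[[ord[1L]]]
    locals[[g]] <- best
    if (length(best$coactivators) > 0L)
      edges[[length(edges) + 1L]] <-
        data.frame(regulator = best$coactivators, target = g, sign = 1)
    if (length(best$corepressors) > 0L)
      edges[[length(edges) + 1L]] <-
        data.frame(regulator = best$corepressors, target = g, sign = -1)
  }
  if (length(edges) == 0L)
    return(regulatory_network(data.frame(regulator = character(),
                                         target = character(),
                                         sign = numeric())))
  net <- regulatory_network(do.call(rbind, edges))
  attr(net, "local_grns") <- locals
  net
}
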