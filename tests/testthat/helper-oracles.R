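# Independent oracles used across the suite. Each one is deliberately a
# different code path from the implementation it checks.

# Welch two-sample statistic via stats::t.test
oracle_welch <- function(a, r) {
  unname(stats::t.test(a, r, var.equal = FALSE)$statistic)
}

# naive recursive GPR evaluator: evaluate children, drop NAs, min/max
oracle_gpr_eval <- function(tree, values) {
  if (tree$op == "leaf") {
    if (!tree$gene %in% names(values)) return(NA_real_)
    return(unname(values[[tree$gene]]))
  }
  vs <- vapply(tree$children, oracle_gpr_eval, numeric(1), values = values)
  vs <- vs[!is.na(vs)]
  if (length(vs) == 0L) return(NA_real_)
  if (tree$op == "and") min(vs) else max(vs)
}

# random GPR tree over a gene pool
random_gpr_tree <- function(genes, depth = 3) {
  if (depth == 0L || stats::runif(1) < 0.4)
    return(list(op = "leaf", gene = sample(genes, 1)))
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  kids <- lapply(seq_len(k), function(i) random_gpr_tree(genes, depth - 1L))
  list(op = op, children = kids)
}

# brute-force FBA oracle: enumerate vertices of {S v = 0, lb <= v <= ub}
# (n - rank(S) variables at a bound, solve for the rest), return best
# objective among feasible vertices
oracle_fba_vertex <- function(model) {
  S <- model$S
  n <- ncol(S)
  r <- qr(S)$rank
  k <- n - r
  iobj <- which(model$reactions == model$objective)
  best <- -Inf
  for (idx in utils::combn(n, k, simplify = FALSE)) {
    for (mask in 0:(2^k - 1)) {
      at_ub <- bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L
      v_fix <- ifelse(at_ub, model$ub[idx], model$lb[idx])
      rest <- setdiff(seq_len(n), idx)
      A <- S[, rest, drop = FALSE]
      b <- -as.vector(S[, idx, drop = FALSE] %*% v_fix)
      sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
      if (is.null(sol)) next
      v <- numeric(n)
      v[idx] <- v_fix
      v[rest] <- sol
      if (max(abs(S %*% v)) > 1e-8) next
      if (any(v < model$lb - 1e-8) || any(v > model$ub + 1e-8)) next
      best <- max(best, v[iobj])
    }
  }
  best
}

# ordinary least squares by the normal equations
oracle_ols <- function(X, y) {
  as.vector(solve(crossprod(X), crossprod(X, y)))
}

# exhaustive signed-set miner: all (coactivator, corepressor) splits of all
# regulator subsets up to max_size that reach min_support
oracle_mine_exhaustive <- function(disc, target, regulators, max_size,
                                   min_support) {
  tgt <- disc[target, ]
  active <- which(tgt != 0L)
  out <- character()
  if (length(active) == 0L) return(out)
  for (size in seq_len(max_size)) {
    for (set in utils::combn(regulators, size, simplify = FALSE)) {
      for (mask in 0:(2^size - 1)) {
        rep_idx <- which(bitwAnd(mask, 2^(seq_len(size) - 1L)) > 0L)
        coact <- set[setdiff(seq_len(size), rep_idx)]
        corep <- set[rep_idx]
        parts <- rbind(disc[coact, , drop = FALSE],
                       -disc[corep, , drop = FALSE])
        comb <- apply(parts, 2L, min)
        if (mean(comb[active] == tgt[active]) >= min_support)
          out <- c(out, paste(paste(sort(coact), collapse = ","), "|",
                              paste(sort(corep), collapse = ",")))
      }
    }
  }
  out
}

candidate_key <- function(cand) {
  paste(paste(sort(cand$coactivators), collapse = ","), "|",
        paste(sort(cand$corepressors), collapse = ","))
}

# signed-edge F1 between a truth edge table and an estimated one
edge_f1 <- function(truth, est) {
  tk <- paste(truth$regulator, truth$target, truth$sign)
  ek <- paste(est$regulator, est$target, est$sign)
  tp <- length(intersect(tk, ek))
  if (length(ek) == 0L || tp == 0L) return(0)
  prec <- tp / length(ek)
  rec <- tp / length(tk)
  2 * prec * rec / (prec + rec)
}
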