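#' Softplus flux bound
#'
#' Converts a continuous GPR evaluation g into a flux upper bound
#' \eqn{\ln(1 + e^{g + \theta})}. The softplus maps any real to (0, Inf), so
#' negative predicted expression still yields a small positive bound, and the
#' condition-specific offset theta shifts all bounds up or down. Computed
#' overflow-safely: for large arguments the linear asymptote g + theta is
#' used (plus the exact log1p correction).
#'
#' @param g GPR evaluation (any real); vectorized.
#' @param theta condition-specific offset.
#' @return positive numeric of the same length.
#' @export
softplus_bound <- function(g, theta) {
  z <- g + theta
  out <- numeric(length(z))
  hi <- z > 30
  out[hi] <- z[hi] + log1p(exp(-z[hi]))
  out[!hi] <- log1p(exp(z[!hi]))
  out
}

#' Build a softplus constraint set from predicted expression
#'
#' Evaluates each reaction's GPR on the predicted expression and converts the
#' result to a softplus bound. Reactions whose GPR evaluation is undefined
#' (all genes missing) are absent from the set and keep their default bounds.
#'
#' @param model MetabolicModel.
#' @param x_pred named numeric vector of (predicted) gene expression.
#' @param theta condition-specific offset.
#' @return object of class \code{SoftplusConstraintSet}: data.frame with
#'   columns \code{reaction}, \code{gpr_value}, \code{bound}; theta stored as
#'   an attribute.
#' @export
softplus_constraints <- function(model, x_pred, theta) {
  g <- vapply(names(model$gpr), function(r)
    evaluate_gpr(model$gpr[[r]], x_pred), numeric(1))
  keep <- !is.na(g)
  cs <- data.frame(reaction = names(model$gpr)[keep],
                   gpr_value = unname(g[keep]),
                   bound = softplus_bound(unname(g[keep]), theta),
                   stringsAsFactors = FALSE)
  stopifnot(all(cs$bound > 0))
  structure(cs, theta = theta, class = c("SoftplusConstraintSet",
                                         "data.frame"))
}

#' Apply softplus constraints to a model
#'
#' For each constrained reaction the upper bound is tightened to
#' \code{min(ub, b)}; reversible reactions (lb < 0) additionally get
#' \code{lb = max(lb, -b)}, since enzyme limitation caps flux magnitude in
#' either direction. Bounds are combined with the model's existing bounds by
#' min/max, never replaced, so irreversibility encoded in the model is never
#' relaxed. Returns a new model; the input is unmodified.
#'
#' @param model MetabolicModel.
#' @param cs SoftplusConstraintSet from \code{\link{softplus_constraints}}.
#' @return constrained MetabolicModel.
#' @export
apply_constraints <- function(model, cs) {
  out <- model
  for (i in seq_len(nrow(cs))) {
    r <- cs$reaction[i]
    b <- cs$bound[i]
    out$ub[r] <- min(out$ub[r], b)
    if (out$lb[r] < 0) out$lb[r] <- max(out$lb[r], -b)
  }
  stopifnot(all(out$lb <= out$ub))
  out
}

#' Build the condition-specific constrained model
#'
#' Composes the pipeline for one context sample: influence scores (if raw
#' expression is given), predicted metabolic-gene expression, continuous GPR
#' evaluation, softplus bounds, and bound application.
#'
#' @param model MetabolicModel.
#' @param net RegulatoryNetwork used for influence and prediction.
#' @param lin_model LinearInfluenceModel from \code{\link{fit_influence_model}}.
#' @param context expression matrix (genes x samples) or influence matrix
#'   (regulators x samples), per \code{context_type}.
#' @param theta condition-specific softplus offset.
#' @param sample column of \code{context} to use; defaults to the only column.
#' @param context_type "expression" (influences are computed first) or
#'   "influence" (matrix already holds influences).
#' @param use_raw_expression bypass the influence/prediction stage and feed
#'   the context expression values directly into the GPR rules (ablation
#'   mode; requires \code{context_type = "expression"}).
#' @param min_targets passed to \code{\link{compute_influence}}.
#' @return constrained MetabolicModel with attributes \code{constraints}
#'   (the SoftplusConstraintSet) and \code{x_pred}.
#' @export
condition_model <- function(model, net, lin_model, context, theta,
                            sample = NULL,
                            context_type = c("expression", "influence"),
                            use_raw_expression = FALSE, min_targets = 2) {
  context_type <- match.arg(context_type)
  if (is.null(sample)) {
    if (ncol(context) != 1L)
      stop("context has ", ncol(context), " samples; pick one with sample=")
    sample <- colnames(context)[1L]
  }
  if (!sample %in% colnames(context)) stop("unknown sample: ", sample)
  if (use_raw_expression) {
    if (context_type != "expression")
      stop("use_raw_expression requires an expression context")
    x_pred <- context[, sample]
    names(x_pred) <- rownames(context)
  } else {
    infl <- if (context_type == "expression")
      compute_influence(net, context, min_targets = min_targets)
    else context
    x_pred <- predict(lin_model, infl[, sample, drop = FALSE])[, 1L]
  }
  cs <- softplus_constraints(model, x_pred, theta)
  out <- apply_constraints(model, cs)
  attr(out, "constraints") <- cs
  attr(out, "x_pred") <- x_pred
  out
}

#' Simulate fluxes under regulatory constraints
#'
#' Builds the condition-specific constrained model (see
#' \code{\link{condition_model}}) and solves its FBA problem.
#'
#' @inheritParams condition_model
#' @param sense objective sense, "max" or "min".
#' @return FluxSolution with attributes \code{constraints}, \code{x_pred} and
#'   \code{model} (the constrained model).
#' @export
simulate_fluxes <- function(model, net, lin_model, context, theta,
                            sample = NULL,
                            context_type = c("expression", "influence"),
                            use_raw_expression = FALSE, min_targets = 2,
                            sense = "max") {
  cm <- condition_model(model, net, lin_model, context, theta,
                        sample = sample, context_type = context_type,
                        use_raw_expression = use_raw_expression,
                        min_targets = min_targets)
  sol <- solve_fba(cm, sense = sense)
  attr(sol, "constraints") <- attr(cm, "constraints")
  attr(sol, "x_pred") <- attr(cm, "x_pred")
  attr(sol, "model") <- cm
  sol
}

#' Compare plain-FBA and regulator-constrained fluxes
#'
#' Per-reaction log2 fold change of constrained over plain fluxes, filtered
#' to changes of at least \code{min_fold}. Reactions with (near-)zero plain
#' flux but nonzero constrained flux cannot be given a finite fold change;
#' they are kept with a \code{"from_zero"} note instead of a number (and
#' symmetrically \code{"to_zero"}).
#'
#' @param sol_fba FluxSolution of the unconstrained model.
#' @param sol_reg FluxSolution of the constrained model.
#' @param min_fold fold-change filter threshold (default 2).
#' @param zero_tol fluxes below this magnitude count as zero.
#' @return data.frame with columns reaction, flux_fba, flux_reg, log2_fc,
#'   note.
#' @export
flux_fold_change <- function(sol_fba, sol_reg, min_fold = 2,
                             zero_tol = 1e-9) {
  stopifnot(sol_fba$status == "optimal", sol_reg$status == "optimal")
  rxns <- union(names(sol_fba$fluxes), names(sol_reg$fluxes))
  a <- sol_fba$fluxes[rxns]; a[is.na(a)] <- 0
  b <- sol_reg$fluxes[rxns]; b[is.na(b)] <- 0
  za <- abs(a) <= zero_tol
  zb <- abs(b) <= zero_tol
  fc <- rep(NA_real_, length(rxns))
  note <- rep("", length(rxns))
  both <- !za & !zb
  fc[both] <- log2(abs(b[both]) / abs(a[both]))
  note[za & !zb] <- "from_zero"
  note[!za & zb] <- "to_zero"
  keep <- (both & abs(fc) >= log2(min_fold)) | note != ""
  data.frame(reaction = rxns, flux_fba = unname(a), flux_reg = unname(b),
             log2_fc = fc, note = note,
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}
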